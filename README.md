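# chromnmf

Combinatorial chromatin profiles from multi-mark epigenomic signal by
consensus non-negative matrix factorization.

Histone modifications, chromatin proteins and accessibility signals mark
functional genomic elements in recurrent *combinations*, not in
isolation. `chromnmf` discovers those combinations from a panel of
ChIP-seq / DNase-seq experiments: read alignments are binned (200 bp),
converted to mappability- and depth-normalized fold-enrichment coverage
`S(j,k) = Σᵢ R(j,k,i) / Σᵢ E(j,k,i)` with `E(j,k,i) = C(i)·M(j)/G`,
filtered by a per-mark negative-binomial (Poisson–Gamma) background
model at a 1% upper-tail threshold, and rescaled per mark with the
sigmoid `X' = 2/(1 + e^(−2x/y)) − 1 = tanh(x/y)` (`y` = 95th
percentile). The resulting bins × marks matrix `V` is factorized,

    V ≈ W H,    W ≥ 0 (bins × r),   H ≥ 0 (r × marks),

by minimizing the generalized Kullback–Leibler divergence with
multiplicative updates (compiled core). Each row of `H` is a *chromatin
profile* — a weighted combination of marks — and each bin is assigned to
its maximum-weight profile, with relative weight contributions
(`RWC(j,c) = W(j,c)/max_c W(j,·)`) quantifying ambiguity. The
factorization rank is chosen by consensus clustering over random
restarts: the cophenetic correlation coefficient of the real matrix is
compared, rank by rank, against column-permuted null matrices (smallest
rank exceeding the null mean by 4 null SDs, persisting at the next
rank). Downstream evaluators cover Fisher-exact feature enrichment
(fold enrichment `ad/bc`), profile-transition enrichment, strand-aware
anchor-distance distributions, ROC recovery of functional elements,
expression-stratified profile patterns, and cross-run profile
correlation. A fully seeded synthetic generator (reads, matrices,
annotations, expression) makes every stage testable offline.

See the methods vignette (`vignettes/chromatin-profiles.Rmd`) for the
models, parameter choices, and an honest account of how the
rank-selection rule behaves on planted archetypal data.

## Worked example

Simulate a 6,000-bin dataset from the default 7-profile, 13-mark
library, transform, factorize at rank 7, assign bins and test TSS
enrichment:

```r
library(chromnmf)
sim <- simulate_dataset(n_bins = 6000, seed = 7)
Vt  <- sigmoid_transform(sim$matrix)
fit <- multirun(Vt, r = 7, n_runs = 10, seed = 7)
fit$best
#> nmf_fit: r=7, 6000 x 13, KL=1775.15, RSS=649.489, 82 iter (connectivity)
fit$stats
#> consensus_stats [real]: r=7, cophenetic=0.9979, best RSS=649.489 (10 runs)

track <- assign_profiles(fit$best, bins = Vt$bins)
m <- match_labels(sim$truth$labels, track$label, r = 7)
sprintf("planted-label agreement (matched): %.3f", m$agreement)
#> "planted-label agreement (matched): 0.953"

contingency_enrichment(track, sim$annotations$tss)[2, c("profile", "a", "b", "ratio", "p")]
#>    profile   a   b   ratio p
#> 2 profile2 362 342 146.46  0
```

Reading the output: the ten restarts agree almost perfectly on how the
13 marks cluster (cophenetic 0.998), 95.3% of bins are assigned to
their planted profile after matching the arbitrary profile order, and
the profile that captured the planted promoter state overlaps the
synthetic TSS set 146-fold more than the other profiles combined
(one-tail Fisher p below machine precision) — the generator placed 90%
of TSSs on bins of that profile, so a large but finite odds ratio is
the expected read-out.

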