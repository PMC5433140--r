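test_that("enrichment ratio and Fisher p match direct computation", {
  # plant a feature overlapping 30 of 100 profile-1 bins and 100 of 1000
  # profile-2 bins
  W <- matrix(0, 1100, 2)
  W[1:100, 1] <- 1
  W[101:1100, 2] <- 1
  tr <- toy_track(W)
  hit_idx <- c(1:30, 101:200)
  feat <- feature_set(data.frame(chrom = "chrT1",
                                 start = tr$bins$start[hit_idx] + 50L,
                                 end = tr$bins$start[hit_idx] + 60L),
                      name = "f")
  res <- contingency_enrichment(tr, feat)
  expect_equal(res$a, c(30, 100))
  expect_equal(res$b, c(70, 900))
  expect_equal(res$c, c(100, 30))
  expect_equal(res$d, c(900, 70))
  expect_equal(res$ratio[1], (30 * 900) / (70 * 100))
  expect_equal(res$p[1],
               stats::fisher.test(matrix(c(30, 70, 100, 900), 2,
                                         byrow = TRUE),
                                  alternative = "greater")$p.value)
})

test_that("Fisher p equals brute-force hypergeometric enumeration (N <= 60)", {
  # one-tail p = P(X >= a) for X ~ Hypergeom(row1 = a+b draws from
  # a+c hits out of N)
  brute_p <- function(a, b, c_, d) {
    n1 <- a + b; hits <- a + c_; N <- a + b + c_ + d
    ks <- max(0, n1 + hits - N):min(n1, hits)
    ks <- ks[ks >= a]
    sum(choose(hits, ks) * choose(N - hits, n1 - ks)) / choose(N, n1)
  }
  set.seed(17)
  cases <- 0L
  for (rep in 1:200) {
    N <- sample(4:60, 1)
    a <- sample(0:N, 1); b <- sample(0:(N - a), 1)
    c_ <- sample(0:(N - a - b), 1); d <- N - a - b - c_
    if ((a + b) == 0 || (c_ + d) == 0) next
    p_pkg <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                                alternative = "greater")$p.value
    expect_equal(p_pkg, brute_p(a, b, c_, d), tolerance = 1e-9)
    cases <- cases + 1L
  }
  expect_gt(cases, 150L)
})

test_that("degenerate contingency tables yield flagged sentinels", {
  W <- matrix(0, 10, 2)
  W[1:5, 1] <- 1; W[6:10, 2] <- 1
  tr <- toy_track(W)
  whole <- feature_set(data.frame(chrom = "chrT1", start = 0L,
                                  end = 2000L), name = "all")
  res <- contingency_enrichment(tr, whole)
  expect_true(all(is.infinite(res$ratio)))
  empty <- feature_set(data.frame(chrom = "chrT9", start = 0L,
                                  end = 10L), name = "none")
  res2 <- suppressWarnings(contingency_enrichment(tr, empty))
  expect_true(all(is.nan(res2$ratio)))
})

test_that("ROC staircase and AUC match hand enumeration and the U statistic", {
  # 4 bins, scores 4..1, positives are the top two
  r <- roc_recovery(scores = c(4, 3, 2, 1),
                    labels = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 1)
  expect_equal(r$roc$tpr, c(0, 0.5, 1, 1, 1))
  expect_equal(r$roc$fpr, c(0, 0, 0, 0.5, 1))

  # perfect separation and permutation null
  set.seed(19)
  lab <- rep(c(TRUE, FALSE), each = 500)
  expect_equal(roc_recovery(ifelse(lab, 2, 1), lab)$auc, 1)
  auc_null <- roc_recovery(rnorm(1000), lab)$auc
  expect_lt(abs(auc_null - 0.5), 3 * sqrt(1 / 12 * (1 / 500 + 1 / 500)))

  # AUC equals the normalized Mann-Whitney U statistic, ties included
  for (i in 1:5) {
    sc <- sample(1:20, 60, replace = TRUE)
    lb <- sample(c(TRUE, FALSE), 60, replace = TRUE, prob = c(0.4, 0.6))
    if (!any(lb) || all(lb)) next
    u <- sum(rank(sc)[lb]) - sum(lb) * (sum(lb) + 1) / 2
    expect_equal(roc_recovery(sc, lb)$auc, u / (sum(lb) * sum(!lb)))
  }
  expect_error(roc_recovery(1:4, rep(TRUE, 4)), "undefined")
})

test_that("anchor distances are signed by anchor strand", {
  W <- matrix(0, 200, 2); W[, 1] <- 1
  tr <- toy_track(W)  # bins [0,200) ... on chrT1
  # '+' anchor at 10000: bin centered 10100 -> +100
  plus <- feature_set(data.frame(chrom = "chrT1", start = 10000L,
                                 end = 10001L, strand = "+"), name = "a")
  d <- anchor_distance_distribution(tr, plus, window_bp = 5000L)
  # bin [10000,10200) has midpoint 10100 -> distance +100
  expect_true(100 %in% d$distances$distance)
  expect_equal(min(abs(d$distances$distance)), 100)
  # distances are odd multiples of 100 around the anchor
  expect_true(all(sort(unique(abs(d$distances$distance))) ==
                    seq(100, 4900, by = 200)))
  # '-' anchor at the same base: bin 100 bp to its right is upstream -> -100
  minus <- feature_set(data.frame(chrom = "chrT1", start = 10000L,
                                  end = 10001L, strand = "-"), name = "a")
  dm <- anchor_distance_distribution(tr, minus, window_bp = 5000L)
  idx_plus <- which(d$distances$distance == 100)
  expect_equal(dm$distances$distance[idx_plus], -100)
  # total histogram mass = number of assigned bins within the window
  expect_equal(sum(d$histogram), sum(abs(d$distances$distance) <= 5000))
})

test_that("normalized gene mode maps gene midpoints to 0", {
  W <- matrix(0, 100, 1); W[, 1] <- 1
  tr <- toy_track(W)
  gene <- feature_set(data.frame(chrom = "chrT1", start = 0L,
                                 end = 20000L, strand = "+"),
                      name = "gene")
  d <- anchor_distance_distribution(tr, gene, mode = "normalized_gene")
  expect_equal(nrow(d$distances), 100L)
  expect_true(all(d$distances$distance >= -50 & d$distances$distance <= 50))
  expect_equal(mean(d$distances$distance), 0, tolerance = 1)
})

test_that("mean overlap/coverage summarize per-profile fractions", {
  W <- matrix(0, 100, 3)
  W[1:20, 1] <- 1; W[21:60, 2] <- 1; W[61:100, 3] <- 1
  tr <- toy_track(W)
  # feature = exactly the bins of profile 1
  f1 <- feature_set(data.frame(chrom = "chrT1",
                               start = tr$bins$start[1:20],
                               end = tr$bins$end[1:20]), name = "f1")
  mo <- mean_overlap_and_coverage(tr, f1, enriched_profiles = 1L)
  expect_equal(mo$mean_overlap_pct, 100)
  expect_equal(mo$mean_coverage_pct, 100)
  mo2 <- mean_overlap_and_coverage(tr, f1, enriched_profiles = 2L)
  expect_equal(mo2$mean_overlap_pct, 0)
  expect_equal(mo2$mean_coverage_pct, 0)
  # mean over a two-profile set; overlaps 100% and 0% average to 50%
  mo3 <- mean_overlap_and_coverage(tr, f1, enriched_profiles = c(1L, 2L),
                                   enumerate = TRUE)
  expect_equal(mo3$mean_overlap_pct, 50)
  expect_equal(nrow(mo3$subsets), 3L)
  expect_error(mean_overlap_and_coverage(tr, f1, integer(0)), "empty")
})

test_that("profile correlation matches and respects Pearson invariances", {
  H <- withr::with_seed(23L, matrix(runif(4 * 10), 4, 10,
                                    dimnames = list(paste0("p", 1:4),
                                                    paste0("m", 1:10))))
  pc <- profile_correlation(H, H)
  expect_equal(unname(diag(pc$cor)), rep(1, 4), tolerance = 1e-12)
  expect_equal(pc$matching$r, rep(1, 4), tolerance = 1e-12)
  # scale invariance
  pc2 <- profile_correlation(H, 2 * H)
  expect_equal(pc2$matching$r, rep(1, 4), tolerance = 1e-12)
  # orthogonal one-hot profiles anti-correlate under centering
  I3 <- diag(3); dimnames(I3) <- list(paste0("p", 1:3), paste0("m", 1:3))
  pc3 <- profile_correlation(I3, I3)
  expect_true(all(pc3$cor[upper.tri(pc3$cor)] <= 0))
  # zero-variance profile gives NaN cells
  H0 <- H; H0[2, ] <- 5
  pc4 <- profile_correlation(H0, H)
  expect_true(all(is.nan(pc4$cor[2, ])))
})

test_that("label matching resolves profile-order indeterminacy", {
  lt <- c(1L, 1L, 2L, 2L, 3L, 3L)
  le <- c(3L, 3L, 1L, 1L, 2L, 2L)   # same partition, relabeled
  m <- match_labels(lt, le)
  expect_equal(m$agreement, 1)
  le2 <- le; le2[1] <- 1L
  expect_equal(match_labels(lt, le2)$agreement, 5 / 6)
})

test_that("expression patterns recover a planted stratified profile", {
  # profile 1 occupies TSS bins of high-expression genes only
  n <- 4000L
  lab <- withr::with_seed(29L, sample(2:4, n, replace = TRUE))
  genes_hi <- seq(10, 1800, by = 20)     # bins hosting high-expr genes
  genes_lo <- seq(2010, 3800, by = 20)   # bins hosting low-expr genes
  lab[genes_hi] <- 1L
  W <- matrix(0, n, 4)
  W[cbind(seq_len(n), lab)] <- 1
  tr <- toy_track(W)
  expr <- data.frame(
    gene = sprintf("g%03d", seq_len(length(genes_hi) + length(genes_lo))),
    chrom = "chrT1",
    tss = c(tr$bins$start[genes_hi] + 100L, tr$bins$start[genes_lo] + 100L),
    strand = "+",
    rpkm = c(withr::with_seed(1L, runif(length(genes_hi), 50, 100)),
             withr::with_seed(2L, runif(length(genes_lo), 0, 1)))
  )
  ep <- expression_pattern(tr, expr, window = c(-400L, 600L),
                           percentile_step = 25, n_permutations = 20,
                           seed = 5L)
  # profile 1 is enriched at position 0 in the top stratum only
  top <- nrow(ep$logfc[[1]])
  expect_gt(ep$logfc[[1]][top, "0"], 0.5)
  expect_gt(ep$stratum_profile_freq[top, 1],
            3 * ep$stratum_profile_freq[1, 1])
  # monotone trend across strata
  expect_gt(stats::cor(seq_len(top), ep$stratum_profile_freq[, 1],
                       method = "spearman"), 0.8)
  # degenerate stratification warns
  expr2 <- expr; expr2$rpkm <- 1
  expect_warning(expression_pattern(tr, expr2, window = c(-200L, 200L),
                                    n_permutations = 5, seed = 1L),
                 "single stratum")
})
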