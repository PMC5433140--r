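#' Default synthetic chromatin-profile library
#'
#' Seven combinatorial profiles over the 13-mark panel, encoding the
#' canonical mark combinations of the major chromatin states: an active
#' promoter profile (H3K27ac + Pol2 + DNase HS), a transcription
#' initiation profile (H3K4me2/me3 + H3K9ac + H2A.Z), an enhancer
#' profile (H3K4me1-dominated), an insulator/regulatory-element profile
#' (CTCF + DNase HS), a gene-body transcription profile (H3K36me3 +
#' H3K79me1), and two repressive profiles (H3K9me3; H3K27me3). The
#' magnitudes are synthetic constants on a 0-1 scale mirroring
#' post-sigmoid signal.
#'
#' @return A `profile_library`: list with `names`, `mark_names`, `H0`
#'   (profiles x marks template).
#' @export
default_profile_library <- function() {
  marks <- default_marks()
  p <- function(...) {
    v <- setNames(numeric(length(marks)), marks)
    loads <- c(...)
    v[names(loads)] <- loads
    v
  }
  H0 <- rbind(
    ActProm = p(H3K27ac = 0.90, Pol2 = 0.80, DNaseHS = 0.35),
    RepChr  = p(H3K9me3 = 0.90, H2A.Z = 0.10),
    TxInit  = p(H3K4me2 = 0.90, H3K4me3 = 0.85, H3K9ac = 0.50,
                H2A.Z = 0.30),
    RepReg  = p(H3K27me3 = 0.90),
    GenBd   = p(H3K36me3 = 0.90, H3K79me1 = 0.40, Pol2 = 0.20,
                H3K9ac = 0.15),
    Enh     = p(H3K4me1 = 0.90, H2A.Z = 0.15, H3K4me2 = 0.15,
                H3K27ac = 0.20, H3K79me1 = 0.10),
    RegEl   = p(CTCF = 0.85, DNaseHS = 0.60, H2A.Z = 0.15)
  )
  structure(list(names = rownames(H0), mark_names = marks, H0 = H0),
            class = "profile_library")
}

#' @export
print.profile_library <- function(x, ...) {
  cat(sprintf("profile_library: %d profiles x %d marks\n",
              nrow(x$H0), ncol(x$H0)))
  print(round(x$H0, 2))
  invisible(x)
}

.synthetic_bins <- function(n_bins, bin_width = 200L, n_chroms = 4L) {
  per <- ceiling(n_bins / n_chroms)
  sizes <- integer(n_chroms)
  counts <- rep(per, n_chroms)
  counts[n_chroms] <- n_bins - per * (n_chroms - 1L)
  sizes <- counts * bin_width
  names(sizes) <- sprintf("chrS%d", seq_len(n_chroms))
  make_bins(sizes, bin_width = bin_width)
}

#' Simulate a bins-by-marks coverage matrix with planted profiles
#'
#' Draws a sparse planted weight matrix `W0` (each signal bin loads on
#' one profile with a small cross-loading on a second), forms the mean
#' signal `signal_scale * W0 H0 + background_mean`, and corrupts it
#' entry-wise with negative-binomial noise of the given shape
#' (`nb_shape = Inf` disables the noise, returning the mean itself, so
#' with `signal_scale = 1` and `background_mean = 0` the matrix equals
#' `W0 H0` exactly). A `background_fraction` of bins carries no planted
#' profile and fluctuates at the background level only.
#'
#' @param library A `profile_library` (default [default_profile_library()]).
#' @param n_bins Total number of bins (>= 10 x profiles).
#' @param background_fraction Fraction of pure-background bins.
#' @param signal_scale Mean fold-enrichment scale of a fully loaded
#'   profile (default 20, a strongly enriched ChIP signal).
#' @param background_mean Baseline coverage added to every bin
#'   (default 1, the background fold-enrichment level).
#' @param nb_shape Negative-binomial shape (size) of the noise
#'   (default 4: moderate overdispersion, reflecting coverage pooled
#'   over two or three replicates); `Inf` = no noise.
#' @param cross_loading Secondary profile load as a fraction of the
#'   primary (default 0.1).
#' @param proportions Genome share of each profile among signal bins.
#'   The default is unbalanced the way chromatin states are: broad
#'   repressed and transcribed states cover most of the significant
#'   genome, punctate promoter/insulator states little of it.
#' @param seed Integer seed; same seed, same matrix.
#' @return List with `matrix` (a raw-stage `coverage_matrix` with
#'   synthetic coordinates) and `truth` (a `synthetic_truth`: `labels`
#'   with `NA` for background bins, `W0`, `H0`, `params`).
#' @export
simulate_matrix <- function(library = default_profile_library(),
                            n_bins = 20000L,
                            background_fraction = 0.1,
                            signal_scale = 20,
                            background_mean = 1,
                            nb_shape = 4,
                            cross_loading = 0.1,
                            proportions = c(0.10, 0.22, 0.10, 0.16,
                                            0.20, 0.12, 0.10),
                            seed = 1L) {
  r <- nrow(library$H0)
  .assert(n_bins >= 10L * r, "n_bins must be at least 10 x profiles")
  .assert(is.finite(background_fraction) && background_fraction >= 0 &&
            background_fraction < 1, "background_fraction must be in [0, 1)")
  .assert(nb_shape > 0, "nb_shape must be > 0 (Inf disables noise)")
  .assert(length(proportions) == r && all(proportions > 0),
          "proportions must give one positive share per profile")
  proportions <- proportions / sum(proportions)

  out <- withr::with_seed(seed, {
    n_sig <- n_bins - round(n_bins * background_fraction)
    labels <- rep(NA_integer_, n_bins)
    sig_idx <- sort(sample.int(n_bins, n_sig))
    per_profile <- diff(round(cumsum(c(0, proportions)) * n_sig))
    labels[sig_idx] <- sample(rep.int(seq_len(r), per_profile))

    W0 <- matrix(0, n_bins, r,
                 dimnames = list(NULL, library$names))
    # signal bins emulate a significance-filtered matrix: their
    # enrichment has a floor (sub-threshold bins would not be in it)
    base <- runif(n_sig, 0.75, 1.5)
    W0[cbind(sig_idx, labels[sig_idx])] <- base
    if (cross_loading > 0) {
      second <- vapply(labels[sig_idx], function(c0) {
        sample(setdiff(seq_len(r), c0), 1L)
      }, integer(1))
      W0[cbind(sig_idx, second)] <- cross_loading * base
    }

    MU <- signal_scale * (W0 %*% library$H0) + background_mean
    V <- if (is.infinite(nb_shape)) MU else {
      matrix(rnbinom(length(MU), size = nb_shape, mu = MU),
             nrow = n_bins)
    }
    colnames(V) <- library$mark_names
    list(labels = labels, W0 = W0, V = V)
  })

  bins <- .synthetic_bins(n_bins)
  cm <- coverage_matrix(out$V, bins = bins$bins, stage = "raw")
  truth <- structure(list(
    labels = out$labels, W0 = out$W0, H0 = library$H0,
    profile_names = library$names,
    coverage = out$V,
    bins = bins,
    params = list(n_bins = n_bins,
                  background_fraction = background_fraction,
                  signal_scale = signal_scale,
                  background_mean = background_mean,
                  nb_shape = nb_shape, cross_loading = cross_loading,
                  seed = seed)
  ), class = "synthetic_truth")
  list(matrix = cm, truth = truth)
}

#' Simulate per-mark BED read files from a planted truth
#'
#' Samples Poisson read counts per (bin, mark) with intensity
#' proportional to the planted mean signal (scaled to `depth` reads per
#' bin on average per mark) and writes one BED file per mark plus a
#' `chrom.sizes` file. Reads are emitted bin-aligned at the full
#' fragment footprint (`read_length` defaults to the bin width), so
#' re-running the coverage stage on these files reproduces the planted
#' matrix up to Poisson sampling noise; a positive `jitter_bp` shifts
#' read starts to also exercise boundary-spanning assignment.
#'
#' @param truth A `synthetic_truth` from [simulate_matrix()].
#' @param out_dir Output directory (created if missing).
#' @param depth Mean reads per bin per mark.
#' @param read_length Read footprint in bp (default: bin width).
#' @param jitter_bp Uniform start jitter in bp (default 0).
#' @param seed Integer seed.
#' @return List with `bed_files` (named per mark), `chrom_sizes_file`,
#'   `counts` (bins x marks read-count matrix).
#' @export
simulate_reads <- function(truth, out_dir, depth = 30,
                           read_length = NULL, jitter_bp = 0L,
                           seed = 1L) {
  .assert(is(truth, "synthetic_truth"), "truth must be a synthetic_truth")
  .assert(depth > 0, "depth must be > 0")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bins <- truth$bins
  # read intensity follows the realized planted coverage so the read-level
  # data carries the planted dispersion and the coverage stage round-trips
  # to the planted matrix
  MU <- truth$coverage
  if (is.null(MU)) {
    p <- truth$params
    MU <- p$signal_scale * (truth$W0 %*% truth$H0) + p$background_mean
    colnames(MU) <- colnames(truth$H0)
  }
  cmeans <- pmax(colMeans(MU), .CHROMNMF_EPS)
  lam <- sweep(MU, 2, cmeans, "/") * depth

  bw <- bins$bin_width
  if (is.null(read_length)) read_length <- bw
  starts0 <- bins$bins$start
  chroms <- bins$bins$chrom
  sizes <- bins$chrom_sizes

  counts <- withr::with_seed(seed, {
    matrix(rpois(length(lam), lam), nrow = nrow(lam),
           dimnames = dimnames(lam))
  })
  read_seeds <- derive_seeds(seed, ncol(lam))

  bed_files <- setNames(character(ncol(lam)), colnames(lam))
  for (k in seq_len(ncol(lam))) {
    cnt <- counts[, k]
    idx <- rep.int(seq_along(cnt), cnt)
    df <- withr::with_seed(read_seeds[k], {
      offs <- if (jitter_bp > 0) {
        floor(runif(length(idx), -jitter_bp, jitter_bp + 1))
      } else 0L
      start <- pmax(starts0[idx] + offs, 0)
      end <- pmin(start + read_length, sizes[chroms[idx]])
      strand <- sample(c("+", "-"), length(idx), replace = TRUE)
      data.frame(chrom = chroms[idx], start = start, end = end,
                 name = ".", score = 0L, strand = strand)
    })
    f <- file.path(out_dir, sprintf("%s.bed", colnames(lam)[k]))
    data.table::fwrite(df, f, sep = "\t", col.names = FALSE, quote = FALSE)
    bed_files[k] <- f
  }

  cs_file <- file.path(out_dir, "chrom.sizes")
  utils::write.table(data.frame(names(sizes), as.integer(sizes)),
                     cs_file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  list(bed_files = bed_files, chrom_sizes_file = cs_file, counts = counts)
}

#' Simulate annotations and an expression table from a planted truth
#'
#' Places TSS-like point features preferentially on bins of a target
#' profile (with the stated precision) and enhancer-like features on a
#' second profile, and generates a gene expression table whose genes sit
#' on target-profile bins with a probability increasing in their
#' expression percentile, planting a monotone profile-frequency trend
#' across expression strata.
#'
#' @param truth A `synthetic_truth`.
#' @param n_tss Number of TSS-like features.
#' @param n_enhancers Number of enhancer-like features.
#' @param tss_profile,enhancer_profile Target profile indices.
#' @param precision Fraction of features placed on target-profile bins.
#' @param n_genes Genes in the expression table.
#' @param trend Two probabilities `c(low, high)`: chance that a gene at
#'   the lowest/highest expression percentile sits on a target-profile
#'   bin (linear in between).
#' @param rpkm_meanlog,rpkm_sdlog Log-normal expression parameters.
#' @param seed Integer seed.
#' @return List with `tss` and `enhancers` (`feature_set`s) and
#'   `expression` (data.frame `gene`, `chrom`, `tss`, `strand`, `rpkm`,
#'   `on_target`), plus `params`.
#' @export
simulate_annotations <- function(truth, n_tss = 400L, n_enhancers = 200L,
                                 tss_profile = 1L, enhancer_profile = 6L,
                                 precision = 0.9, n_genes = 1000L,
                                 trend = c(0.1, 0.9),
                                 rpkm_meanlog = 1, rpkm_sdlog = 1.5,
                                 seed = 1L) {
  .assert(is(truth, "synthetic_truth"), "truth must be a synthetic_truth")
  .assert(precision >= 0 && precision <= 1, "precision must lie in [0, 1]")
  bins <- truth$bins
  bw <- bins$bin_width
  lab <- truth$labels

  pick_bins <- function(target, n, prec) {
    on_t <- which(!is.na(lab) & lab == target)
    off_t <- which(is.na(lab) | lab != target)
    n_on <- round(prec * n)
    c(sample(on_t, n_on, replace = n_on > length(on_t)),
      sample(off_t, n - n_on, replace = (n - n_on) > length(off_t)))
  }
  point_feature <- function(idx, name) {
    feature_set(data.frame(
      chrom = bins$bins$chrom[idx],
      start = bins$bins$start[idx] + floor(bw / 2),
      end = bins$bins$start[idx] + floor(bw / 2) + 1L,
      strand = sample(c("+", "-"), length(idx), replace = TRUE)
    ), name = name)
  }

  withr::with_seed(seed, {
    tss <- point_feature(pick_bins(tss_profile, n_tss, precision), "RfTSS")
    enh_idx <- pick_bins(enhancer_profile, n_enhancers, precision)
    enhancers <- feature_set(data.frame(
      chrom = bins$bins$chrom[enh_idx],
      start = bins$bins$start[enh_idx],
      end = bins$bins$end[enh_idx]
    ), name = "Enhancers")

    u <- runif(n_genes)
    p_target <- trend[1] + (trend[2] - trend[1]) * u
    on_target <- runif(n_genes) < p_target
    on_t <- which(!is.na(lab) & lab == tss_profile)
    off_t <- which(is.na(lab) | lab != tss_profile)
    gidx <- integer(n_genes)
    gidx[on_target] <- sample(on_t, sum(on_target), replace = TRUE)
    gidx[!on_target] <- sample(off_t, sum(!on_target), replace = TRUE)
    rpkm <- stats::qlnorm(u, meanlog = rpkm_meanlog, sdlog = rpkm_sdlog)

    expression <- data.frame(
      gene = sprintf("gene%04d", seq_len(n_genes)),
      chrom = bins$bins$chrom[gidx],
      tss = bins$bins$start[gidx] + floor(bw / 2),
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      rpkm = rpkm,
      on_target = on_target
    )
    list(tss = tss, enhancers = enhancers, expression = expression,
         params = list(n_tss = n_tss, n_enhancers = n_enhancers,
                       tss_profile = tss_profile,
                       enhancer_profile = enhancer_profile,
                       precision = precision, n_genes = n_genes,
                       trend = trend, seed = seed))
  })
}

#' One-call synthetic dataset generator
#'
#' Bundles [simulate_matrix()], optionally [simulate_reads()] and
#' [simulate_annotations()] under one master seed. The `"hesc13"`
#' preset is the default 13-mark, 7-profile configuration.
#'
#' @param preset Currently `"hesc13"`.
#' @param n_bins Number of bins.
#' @param seed Master seed.
#' @param out_dir When non-NULL, BED reads, chrom.sizes, the matrix TSV,
#'   annotation BEDs, the expression TSV and a truth JSON are written
#'   there.
#' @param reads Also simulate read files (requires `out_dir`).
#' @param ... Overrides passed to [simulate_matrix()].
#' @return List with `matrix`, `truth`, `annotations`, and (with
#'   `out_dir`) `files`.
#' @export
simulate_dataset <- function(preset = "hesc13", n_bins = 20000L,
                             seed = 1L, out_dir = NULL, reads = FALSE,
                             ...) {
  .assert(identical(preset, "hesc13"), "unknown preset")
  seeds <- derive_seeds(seed, 3L)
  sim <- simulate_matrix(default_profile_library(), n_bins = n_bins,
                         seed = seeds[1], ...)
  ann <- simulate_annotations(sim$truth, seed = seeds[2])
  out <- list(matrix = sim$matrix, truth = sim$truth, annotations = ann)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- list(matrix = file.path(out_dir, "matrix.tsv"))
    write_coverage_tsv(sim$matrix, files$matrix)
    if (reads) {
      rd <- simulate_reads(sim$truth, file.path(out_dir, "reads"),
                           seed = seeds[3])
      files$reads <- rd$bed_files
      files$chrom_sizes <- rd$chrom_sizes_file
    }
    files$tss <- file.path(out_dir, "tss.bed")
    files$enhancers <- file.path(out_dir, "enhancers.bed")
    rtracklayer::export(ann$tss$gr, files$tss, format = "BED")
    rtracklayer::export(ann$enhancers$gr, files$enhancers, format = "BED")
    files$expression <- file.path(out_dir, "expression.tsv")
    utils::write.table(ann$expression, files$expression, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files$truth <- file.path(out_dir, "truth.json")
    jsonlite::write_json(list(
      labels = sim$truth$labels, profile_names = sim$truth$profile_names,
      params = sim$truth$params
    ), files$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$files <- files
  }
  out
}
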