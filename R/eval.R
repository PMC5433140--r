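#' Construct a feature set
#'
#' A named collection of genomic intervals (BED semantics, 0-based
#' half-open input) used as an evaluation benchmark. Point-like features
#' (TSS) can be expanded by a symmetric window.
#'
#' @param x BED file path, a data.frame (`chrom`, `start`, `end`,
#'   optional `strand`), or a `GRanges`.
#' @param name Feature identifier.
#' @param expand_bp Half-window added on both sides (default 0).
#' @return A `feature_set`: list with `name` and `gr` (`GRanges`).
#' @export
feature_set <- function(x, name = "feature", expand_bp = 0L) {
  if (is.character(x) && length(x) == 1L) {
    x <- rtracklayer::import(x, format = "BED")
  }
  if (is.data.frame(x)) {
    .assert(all(x$start < x$end), "feature starts must be < ends")
    x <- GenomicRanges::GRanges(
      seqnames = x$chrom,
      ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
      strand = if (!is.null(x$strand)) x$strand else "*"
    )
  }
  .assert(is(x, "GRanges"), "unsupported feature input")
  if (expand_bp > 0L) {
    x <- GenomicRanges::resize(x, GenomicRanges::width(x) + 2L * expand_bp,
                               fix = "center")
    x <- GenomicRanges::trim(x)
  }
  x <- GenomicRanges::sort(x, ignore.strand = TRUE)
  structure(list(name = name, gr = x), class = "feature_set")
}

.track_granges <- function(track) {
  .assert(!is.null(track$bins), "profile_track carries no bin coordinates")
  GenomicRanges::GRanges(
    seqnames = track$bins$chrom,
    ranges = IRanges::IRanges(start = track$bins$start + 1L,
                              end = track$bins$end)
  )
}

#' Fisher-exact enrichment of each profile in a feature
#'
#' Builds, per profile `u`, the 2x2 table of bins: `a` = u-bins
#' overlapping the feature by >= 1 bp, `b` = u-bins not overlapping,
#' `c`/`d` = the same split for bins of all other profiles. The
#' fold-enrichment is the odds ratio `(a d)/(b c)` and significance is a
#' one-tail Fisher exact test in the enrichment direction.
#'
#' @param track A `profile_track` with coordinates.
#' @param feature A `feature_set`.
#' @param p_threshold Significance flag threshold (default 1e-5).
#' @return Data frame with one row per profile: `profile`, `a`, `b`,
#'   `c`, `d`, `ratio` (`Inf` when `b c = 0`, `NaN` for an empty
#'   feature), `p`, `significant`.
#' @export
contingency_enrichment <- function(track, feature, p_threshold = 1e-5) {
  .assert(is(track, "profile_track"), "track must be a profile_track")
  .assert(is(feature, "feature_set"), "feature must be a feature_set")
  gr <- .track_granges(track)
  hit <- GenomicRanges::countOverlaps(gr, feature$gr, minoverlap = 1L,
                                      ignore.strand = TRUE) > 0
  assigned <- !is.na(track$label)
  r <- ncol(track$weights)

  rows <- lapply(seq_len(r), function(u) {
    in_u <- assigned & track$label == u
    other <- assigned & track$label != u
    a <- sum(in_u & hit); b <- sum(in_u & !hit)
    cc <- sum(other & hit); d <- sum(other & !hit)
    ratio <- if (length(feature$gr) == 0L || (a == 0 && cc == 0)) NaN
             else if (b * cc == 0) Inf
             else (a * d) / (b * cc)
    p <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE),
                            alternative = "greater")$p.value
    data.frame(profile = track$profile_names[u], a = a, b = b, c = cc,
               d = d, ratio = ratio, p = p,
               significant = is.finite(p) && p <= p_threshold)
  })
  do.call(rbind, rows)
}

#' Signed distance of each bin to the closest anchor
#'
#' Each assigned bin contributes its signed distance (bin midpoint to
#' anchor point, strand-aware: upstream of a gene is negative) to the
#' histogram of its profile. In `"normalized_gene"` mode the bin's
#' position inside its overlapping gene is mapped to \[-50, 50\] around
#' the gene midpoint instead.
#'
#' @param track A `profile_track` with coordinates.
#' @param anchors A `feature_set`; in anchor mode, interval starts
#'   (strand-aware) are the anchor points; in normalized mode the
#'   intervals are genes.
#' @param window_bp Half-window (bp) for the distance histogram.
#' @param breaks Histogram breaks (default: bins of the track width).
#' @param mode `"anchor"` (signed bp distance) or `"normalized_gene"`.
#' @return List with `distances` (data.frame `profile`, `distance`) and
#'   `histogram` (profiles x distance-bin count matrix).
#' @export
anchor_distance_distribution <- function(track, anchors, window_bp = 10000L,
                                         breaks = NULL,
                                         mode = c("anchor",
                                                  "normalized_gene")) {
  mode <- match.arg(mode)
  .assert(is(track, "profile_track"), "track must be a profile_track")
  .assert(length(anchors$gr) > 0L, "anchors must be non-empty")
  gr <- .track_granges(track)
  mid <- floor((GenomicRanges::start(gr) - 1 + GenomicRanges::end(gr)) / 2)
  assigned <- which(!is.na(track$label))

  if (mode == "anchor") {
    astrand <- as.character(GenomicRanges::strand(anchors$gr))
    astrand[astrand == "*"] <- "+"
    apos <- ifelse(astrand == "+",
                   GenomicRanges::start(anchors$gr) - 1L,
                   GenomicRanges::end(anchors$gr) - 1L)
    apts <- GenomicRanges::GRanges(
      seqnames = GenomeInfoDb::seqnames(anchors$gr),
      ranges = IRanges::IRanges(start = apos + 1L, width = 1L)
    )
    midpts <- GenomicRanges::GRanges(
      seqnames = GenomeInfoDb::seqnames(gr)[assigned],
      ranges = IRanges::IRanges(start = mid[assigned] + 1L, width = 1L)
    )
    nn <- GenomicRanges::nearest(midpts, apts, ignore.strand = TRUE)
    ok <- !is.na(nn)
    sgn <- ifelse(astrand[nn[ok]] == "+", 1, -1)
    d <- sgn * (mid[assigned][ok] - apos[nn[ok]])
    prof <- track$label[assigned][ok]
    keep <- abs(d) <= window_bp
    d <- d[keep]; prof <- prof[keep]
    if (is.null(breaks)) {
      bw <- track$bins$end[1] - track$bins$start[1]
      breaks <- seq(-window_bp, window_bp + bw, by = bw) - bw / 2
    }
  } else {
    hits <- GenomicRanges::findOverlaps(gr[assigned], anchors$gr,
                                        ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    g <- anchors$gr[si]
    gstrand <- as.character(GenomicRanges::strand(g))
    gstrand[gstrand == "*"] <- "+"
    relpos <- (mid[assigned][qi] - (GenomicRanges::start(g) - 1)) /
      GenomicRanges::width(g)
    relpos[gstrand == "-"] <- 1 - relpos[gstrand == "-"]
    d <- relpos * 100 - 50
    prof <- track$label[assigned][qi]
    keep <- d >= -50 & d <= 50
    d <- d[keep]; prof <- prof[keep]
    if (is.null(breaks)) breaks <- seq(-50, 50, by = 2)
  }

  cut_d <- cut(d, breaks = breaks, include.lowest = TRUE)
  hist <- table(factor(prof, levels = seq_len(ncol(track$weights)),
                       labels = track$profile_names), cut_d)
  list(distances = data.frame(profile = track$profile_names[prof],
                              distance = d),
       histogram = unclass(hist))
}

#' ROC recovery of a feature from per-bin scores
#'
#' Sweeps a descending score threshold (equal scores grouped) over bins,
#' with positives the bins overlapping the feature, and reports the ROC
#' staircase and its trapezoidal AUC.
#'
#' @param scores Numeric per-bin scores (a `W` column or a transformed
#'   mark column), aligned with `bins`.
#' @param labels Logical per-bin positives, or `NULL` to derive from
#'   `bins`/`feature`.
#' @param bins Data frame of bin coordinates (needed when `labels` is
#'   `NULL`).
#' @param feature A `feature_set` defining positives (>= 1 bp overlap).
#' @return List with `roc` (data.frame `threshold`, `tpr`, `fpr`) and
#'   `auc`.
#' @export
roc_recovery <- function(scores, labels = NULL, bins = NULL,
                         feature = NULL) {
  if (is.null(labels)) {
    .assert(!is.null(bins) && !is.null(feature),
            "either labels or bins+feature must be given")
    gr <- GenomicRanges::GRanges(
      seqnames = bins$chrom,
      ranges = IRanges::IRanges(start = bins$start + 1L, end = bins$end)
    )
    labels <- GenomicRanges::countOverlaps(gr, feature$gr,
                                           minoverlap = 1L,
                                           ignore.strand = TRUE) > 0
  }
  .assert(length(scores) == length(labels), "scores/labels length mismatch")
  P <- sum(labels); N <- sum(!labels)
  if (P == 0L || N == 0L) {
    stop(structure(class = c("chromnmf_undefined_auc", "chromnmf_error",
                             "error", "condition"),
                   list(message = "AUC undefined: need both positives and negatives",
                        call = sys.call())))
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  grp_end <- cumsum(rle(s)$lengths)
  tp <- cumsum(l)[grp_end]
  fp <- cumsum(!l)[grp_end]
  roc <- data.frame(threshold = s[grp_end], tpr = tp / P, fpr = fp / N)
  roc <- rbind(data.frame(threshold = Inf, tpr = 0, fpr = 0), roc)
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
  list(roc = roc, auc = auc)
}

#' Profile frequency patterns stratified by gene expression
#'
#' Bins genes into expression-percentile strata and, for every profile,
#' counts its occurrences in fixed-width position bins across a window
#' around the TSS. Observed frequencies are compared to label-permuted
#' tracks (`log(observed/random)`), and the expression strata are grouped
#' into subclusters by average-linkage hierarchical clustering of their
#' profile-frequency rows.
#'
#' @param track A `profile_track` with coordinates.
#' @param expression Data frame with `gene`, `chrom`, `tss` (0-based
#'   position), `strand`, `rpkm`.
#' @param window Two-element window around the TSS in bp, strand-oriented
#'   (default `c(-2000, 2000)`; the asymmetric gene-panel view uses
#'   `c(-2000, 10000)`).
#' @param percentile_step Width of each expression stratum in percent
#'   (default 2.5, i.e. 40 strata).
#' @param n_permutations Label permutations for the random expectation.
#' @param n_subclusters Subclusters cut from the stratum clustering.
#' @param seed Integer seed.
#' @return List with `freq` (per-profile stratum x position frequency
#'   matrices, each normalized by the profile's total bin count),
#'   `logfc` (same shape, vs. permuted labels), `stratum_profile_freq`
#'   (strata x profiles aggregate over the window), `subclusters`,
#'   `strata` (per-gene stratum index, 1 = lowest expression),
#'   `positions` (bp offsets), `n_genes_used`, `n_skipped`.
#' @export
expression_pattern <- function(track, expression,
                               window = c(-2000L, 2000L),
                               percentile_step = 2.5,
                               n_permutations = 50L,
                               n_subclusters = 5L,
                               seed = 1L) {
  .assert(is(track, "profile_track"), "track must be a profile_track")
  need <- c("gene", "chrom", "tss", "strand", "rpkm")
  .assert(all(need %in% names(expression)),
          "expression table needs gene/chrom/tss/strand/rpkm")
  .assert(!anyDuplicated(expression$gene), "gene ids must be unique")
  .assert(all(expression$rpkm >= 0), "rpkm must be >= 0")

  skip <- is.na(expression$tss) | is.na(expression$chrom)
  n_skipped <- sum(skip)
  expr <- expression[!skip, , drop = FALSE]
  r <- ncol(track$weights)
  bw <- track$bins$end[1] - track$bins$start[1]

  # expression strata (1 = lowest); degenerate when all values identical
  n_strata <- max(1L, round(100 / percentile_step))
  if (length(unique(expr$rpkm)) == 1L) {
    warning("all genes share one expression value; single stratum used")
    strata <- rep(1L, nrow(expr))
    n_strata <- 1L
  } else {
    qs <- stats::quantile(expr$rpkm, probs = seq(0, 1, length.out = n_strata + 1))
    qs <- unique(qs)
    strata <- as.integer(cut(expr$rpkm, breaks = qs, include.lowest = TRUE))
    n_strata <- length(qs) - 1L
  }

  offsets <- seq(window[1], window[2] - bw, by = bw)
  n_pos <- length(offsets)

  # map every (gene, position bin) to a track bin (NA when filtered out);
  # position 0 is the bin containing the TSS, offsets advance in the
  # gene's direction
  sgn <- ifelse(expr$strand == "-", -1L, 1L)
  base <- floor(expr$tss / bw) * bw
  centers <- outer(base + bw / 2, rep(1, n_pos)) + outer(sgn, offsets)
  qgr <- GenomicRanges::GRanges(
    seqnames = rep(expr$chrom, n_pos),
    ranges = IRanges::IRanges(start = as.integer(centers) + 1L, width = 1L)
  )
  gr <- .track_granges(track)
  ov <- GenomicRanges::findOverlaps(qgr, gr, select = "first",
                                    ignore.strand = TRUE)
  bin_idx <- matrix(ov, nrow = nrow(expr), ncol = n_pos)

  cell_strata <- matrix(strata, nrow(expr), n_pos)
  mapped <- !is.na(bin_idx)

  count_cells <- function(labels) {
    lab_cell <- matrix(NA_integer_, nrow(expr), n_pos)
    lab_cell[mapped] <- labels[bin_idx[mapped]]
    lapply(seq_len(r), function(p) {
      sel <- !is.na(lab_cell) & lab_cell == p
      m <- matrix(0, n_strata, n_pos)
      if (any(sel)) {
        t3 <- table(factor(cell_strata[sel], levels = seq_len(n_strata)),
                    factor(col(lab_cell)[sel], levels = seq_len(n_pos)))
        m <- unclass(t3)
      }
      dimnames(m) <- list(paste0("stratum", seq_len(n_strata)),
                          as.character(offsets))
      m
    })
  }

  obs_counts <- count_cells(track$label)
  totals <- vapply(obs_counts, sum, numeric(1))
  freq <- lapply(seq_len(r), function(p) {
    obs_counts[[p]] / max(totals[p], 1)
  })

  perm_seeds <- derive_seeds(seed, n_permutations)
  rand_sum <- lapply(seq_len(r), function(p) matrix(0, n_strata, n_pos))
  for (pp in seq_len(n_permutations)) {
    lab_p <- withr::with_seed(perm_seeds[pp], sample(track$label))
    cnt <- count_cells(lab_p)
    for (p in seq_len(r)) {
      rand_sum[[p]] <- rand_sum[[p]] + cnt[[p]] / max(sum(cnt[[p]]), 1)
    }
  }
  logfc <- lapply(seq_len(r), function(p) {
    rand <- rand_sum[[p]] / n_permutations
    out <- log(freq[[p]] / rand)
    out[rand == 0] <- NaN
    dimnames(out) <- dimnames(freq[[p]])
    out
  })
  names(freq) <- names(logfc) <- track$profile_names

  # aggregate profile frequency per stratum (share of mapped cells)
  tot_cells <- table(factor(cell_strata[mapped], levels = seq_len(n_strata)))
  stratum_profile_freq <- vapply(seq_len(r), function(p) {
    rowSums(obs_counts[[p]]) / pmax(as.numeric(tot_cells), 1)
  }, numeric(n_strata))
  stratum_profile_freq <- matrix(stratum_profile_freq, nrow = n_strata,
                                 dimnames = list(NULL,
                                                 track$profile_names))

  sub <- NULL
  if (n_strata > n_subclusters) {
    M <- do.call(cbind, freq)
    hc <- stats::hclust(stats::dist(M), method = "average")
    sub <- stats::cutree(hc, k = n_subclusters)
  }

  list(freq = freq, logfc = logfc,
       stratum_profile_freq = stratum_profile_freq,
       subclusters = sub, strata = strata, positions = offsets,
       n_genes_used = nrow(expr), n_skipped = n_skipped)
}

#' Mean profile overlap and mean feature coverage
#'
#' For a set of profiles enriched in a feature: per profile, the fraction
#' of its bins overlapping the feature (profile overlap) and the fraction
#' of feature elements touched by at least one of its bins (feature
#' coverage); both averaged over the enriched set and reported as
#' percentages. With `enumerate = TRUE`, all subsets of the enriched set
#' (sizes 1..N) are evaluated.
#'
#' @param track A `profile_track` with coordinates.
#' @param feature A `feature_set`.
#' @param enriched_profiles Character or integer subset of profiles.
#' @param enumerate Also evaluate every subset of the enriched set.
#' @return List with `mean_overlap_pct`, `mean_coverage_pct`,
#'   `per_profile` (data.frame), and optionally `subsets`.
#' @export
mean_overlap_and_coverage <- function(track, feature, enriched_profiles,
                                      enumerate = FALSE) {
  .assert(is(track, "profile_track"), "track must be a profile_track")
  .assert(length(enriched_profiles) >= 1L, "enriched profile set is empty")
  if (is.character(enriched_profiles)) {
    idx <- match(enriched_profiles, track$profile_names)
    .assert(!anyNA(idx), "unknown profile name in enriched_profiles")
  } else {
    idx <- as.integer(enriched_profiles)
    .assert(all(idx >= 1 & idx <= ncol(track$weights)),
            "profile index out of range")
  }

  gr <- .track_granges(track)
  per <- lapply(idx, function(u) {
    in_u <- which(!is.na(track$label) & track$label == u)
    if (length(in_u) == 0L) {
      return(data.frame(profile = track$profile_names[u],
                        overlap_pct = NaN, coverage_pct = NaN))
    }
    gu <- gr[in_u]
    ov <- mean(GenomicRanges::countOverlaps(gu, feature$gr,
                                            minoverlap = 1L,
                                            ignore.strand = TRUE) > 0) * 100
    cov <- mean(GenomicRanges::countOverlaps(feature$gr, gu,
                                             minoverlap = 1L,
                                             ignore.strand = TRUE) > 0) * 100
    data.frame(profile = track$profile_names[u], overlap_pct = ov,
               coverage_pct = cov)
  })
  per <- do.call(rbind, per)

  out <- list(mean_overlap_pct = mean(per$overlap_pct),
              mean_coverage_pct = mean(per$coverage_pct),
              per_profile = per)
  if (enumerate) {
    subs <- unlist(lapply(seq_along(idx), function(L) {
      utils::combn(seq_along(idx), L, simplify = FALSE)
    }), recursive = FALSE)
    out$subsets <- do.call(rbind, lapply(subs, function(s) {
      data.frame(profiles = paste(per$profile[s], collapse = "+"),
                 size = length(s),
                 mean_overlap_pct = mean(per$overlap_pct[s]),
                 mean_coverage_pct = mean(per$coverage_pct[s]))
    }))
  }
  out
}

#' Pearson correlation between two sets of profiles
#'
#' Correlates every profile of run A with every profile of run B using
#' either their mark coefficients (rows of `H`) or their feature
#' enrichment vectors, and reports a greedy maximum-correlation 1-1
#' matching.
#'
#' @param A,B Matrices with profiles as rows over a shared column set
#'   (marks or features), or `nmf_fit` objects (their `H` is used).
#' @return List with `cor` (profiles_A x profiles_B Pearson matrix,
#'   `NaN` for zero-variance profiles) and `matching` (data.frame
#'   `profile_a`, `profile_b`, `r`).
#' @export
profile_correlation <- function(A, B) {
  if (is(A, "nmf_fit")) A <- A$H
  if (is(B, "nmf_fit")) B <- B$H
  A <- as.matrix(A); B <- as.matrix(B)
  .assert(ncol(A) == ncol(B),
          "profile sets must share the same columns (marks or features)")
  C <- matrix(NaN, nrow(A), nrow(B),
              dimnames = list(rownames(A), rownames(B)))
  for (i in seq_len(nrow(A))) {
    if (stats::sd(A[i, ]) == 0) next
    for (j in seq_len(nrow(B))) {
      if (stats::sd(B[j, ]) == 0) next
      C[i, j] <- stats::cor(A[i, ], B[j, ])
    }
  }
  # greedy max-r matching
  M <- C
  pairs <- list()
  for (step in seq_len(min(dim(C)))) {
    if (all(!is.finite(M))) break
    ij <- which(M == max(M, na.rm = TRUE), arr.ind = TRUE)[1, ]
    pairs[[step]] <- data.frame(
      profile_a = rownames(C)[ij[1]] %||% ij[1],
      profile_b = colnames(C)[ij[2]] %||% ij[2],
      r = C[ij[1], ij[2]]
    )
    M[ij[1], ] <- NA; M[, ij[2]] <- NA
  }
  list(cor = C, matching = do.call(rbind, pairs))
}

#' Optimal profile matching between two labelings
#'
#' Finds the one-to-one profile permutation maximizing label agreement
#' (exhaustive for up to 9 profiles, greedy beyond) and returns the
#' matched agreement rate; used to score recovery of planted labels
#' under the factorization's profile-order indeterminacy.
#'
#' @param labels_true,labels_est Integer label vectors (NA ignored).
#' @param r Number of profiles (default: max label).
#' @return List with `agreement` (fraction), `permutation` (estimated ->
#'   true), `n_used`.
#' @export
match_labels <- function(labels_true, labels_est, r = NULL) {
  ok <- !is.na(labels_true) & !is.na(labels_est)
  lt <- labels_true[ok]; le <- labels_est[ok]
  if (is.null(r)) r <- max(lt, le)
  conf <- table(factor(le, levels = seq_len(r)),
                factor(lt, levels = seq_len(r)))
  if (r <= 9L) {
    perms <- .permutations(r)
    scores <- vapply(perms, function(p) {
      sum(conf[cbind(seq_len(r), p)])
    }, numeric(1))
    best <- perms[[which.max(scores)]]
  } else {
    best <- integer(r)
    M <- unclass(conf)
    for (step in seq_len(r)) {
      ij <- which(M == max(M), arr.ind = TRUE)[1, ]
      best[ij[1]] <- ij[2]
      M[ij[1], ] <- -1; M[, ij[2]] <- -1
    }
  }
  agreement <- sum(conf[cbind(seq_len(r), best)]) / length(lt)
  list(agreement = agreement, permutation = best, n_used = length(lt))
}

.permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- .permutations(n - 1L)
  unlist(lapply(seq_len(n), function(i) {
    lapply(sub, function(p) c(i, p + (p >= i)))
  }), recursive = FALSE)
}
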