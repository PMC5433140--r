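#' Assign each bin to its maximum-weight profile
#'
#' The label of bin `j` is `argmax_c W(j, c)`; ties go to the lowest
#' profile index (counted), and all-zero rows get the unassigned sentinel
#' label `NA`.
#'
#' @param W Weight matrix (bins x profiles) or an `nmf_fit`.
#' @param bins Optional data.frame of bin coordinates (`chrom`, `start`,
#'   `end`), one row per row of `W`.
#' @param profile_names Optional character labels for the profiles
#'   (default `colnames(W)`).
#' @return A `profile_track`: list with `bins`, `label` (integer per bin,
#'   `NA` = unassigned), `weights`, `rwc`, `profile_names`, `n_ties`.
#' @export
assign_profiles <- function(W, bins = NULL, profile_names = NULL) {
  if (is(W, "nmf_fit")) W <- W$W
  W <- as.matrix(W)
  .assert(all(W >= 0), "W must be non-negative")
  if (is.null(profile_names)) {
    profile_names <- colnames(W) %||% paste0("profile", seq_len(ncol(W)))
  }
  .assert(length(profile_names) == ncol(W),
          "one profile name per W column required")
  if (!is.null(bins)) {
    .assert(nrow(bins) == nrow(W), "bins/W row mismatch")
  }

  rmax <- apply(W, 1, max)
  label <- max.col(W, ties.method = "first")
  n_ties <- sum(rowSums(W == rmax) > 1L & rmax > 0)
  if (n_ties > 0L) {
    message(sprintf("%d tied bin(s) assigned to the lowest profile index",
                    n_ties))
  }
  label[rmax == 0] <- NA_integer_

  structure(list(
    bins = bins, label = label, weights = W, rwc = rwc(W),
    profile_names = profile_names, n_ties = n_ties
  ), class = "profile_track")
}

#' @export
print.profile_track <- function(x, ...) {
  tab <- table(factor(x$label, levels = seq_along(x$profile_names),
                      labels = x$profile_names), useNA = "ifany")
  cat(sprintf("profile_track: %d bins, %d profiles (%d unassigned)\n",
              length(x$label), length(x$profile_names),
              sum(is.na(x$label))))
  print(tab)
  invisible(x)
}

#' Relative weight contribution (RWC)
#'
#' Normalizes each bin's weight row by its maximum:
#' `R^w(j, c) = W(j, c) / max_c W(j, .)`. The assigned profile always has
#' RWC 1; secondary profiles with RWC near 1 flag ambiguous assignments.
#' All-zero rows are returned as zeros (unassigned).
#'
#' @param W Weight matrix (bins x profiles) or an `nmf_fit`.
#' @return Matrix of the same shape with entries in \[0, 1\].
#' @export
rwc <- function(W) {
  if (is(W, "nmf_fit")) W <- W$W
  W <- as.matrix(W)
  .assert(all(W >= 0), "W must be non-negative")
  rmax <- apply(W, 1, max)
  out <- W / ifelse(rmax > 0, rmax, 1)
  dimnames(out) <- dimnames(W)
  out
}

#' Profile co-occurrence at RWC thresholds
#'
#' For each ordered profile pair `(u, v)` and each threshold `t`, the
#' fraction of bins assigned to `u` whose RWC on `v` is at least `t`.
#' The diagonal is 1 by construction; entries grow as the threshold
#' decreases. Profiles with no assigned bins give `NaN` rows.
#'
#' @param track A `profile_track`.
#' @param thresholds Decreasing RWC thresholds.
#' @return Named list of r x r matrices, one per threshold.
#' @export
cooccurrence <- function(track, thresholds = c(0.95, 0.85, 0.75, 0.5)) {
  .assert(is(track, "profile_track"), "track must be a profile_track")
  r <- ncol(track$weights)
  out <- lapply(thresholds, function(t) {
    m <- matrix(NaN, r, r,
                dimnames = list(track$profile_names, track$profile_names))
    for (u in seq_len(r)) {
      in_u <- which(!is.na(track$label) & track$label == u)
      if (length(in_u) == 0L) next
      m[u, ] <- colMeans(track$rwc[in_u, , drop = FALSE] >= t)
      m[u, u] <- 1
    }
    m
  })
  names(out) <- as.character(thresholds)
  out
}

# Merge genome-ordered per-bin labels into runs of identical labels.
# Unassigned bins and chromosome changes break runs; unassigned bins are
# separators (regions across them are not consecutive).
.label_regions <- function(track) {
  lab <- track$label
  chrom <- if (!is.null(track$bins)) track$bins$chrom
           else rep("genome", length(lab))
  n <- length(lab)
  if (n == 0L) {
    return(data.frame(chrom = character(), label = integer(),
                      block = integer()))
  }
  # block id increments at chromosome change or at unassigned gaps
  gap <- is.na(lab)
  newblock <- c(TRUE, chrom[-1] != chrom[-n] | gap[-n] | gap[-1])
  block <- cumsum(newblock)
  keep <- !gap
  runs <- rle(paste(block[keep], lab[keep]))
  idx <- cumsum(runs$lengths)
  first <- c(1L, head(idx, -1) + 1L)
  pos <- which(keep)
  data.frame(
    chrom = chrom[pos[first]],
    label = lab[pos[first]],
    block = block[pos[first]]
  )
}

#' Transition enrichment between consecutive profile regions
#'
#' Merges runs of identically labeled bins into regions (never across
#' chromosomes or unassigned gaps) and, for every ordered pair `(A, B)`,
#' compares the observed fraction of A-regions immediately followed by a
#' B-region with the same fraction in label-permuted tracks:
#' `log(f_AB(s) / f_AB(r))` (natural log by default). Cells with zero
#' random frequency are `NaN`.
#'
#' @param track A `profile_track` with genome-ordered bins.
#' @param n_permutations Number of label permutations for the null.
#' @param seed Integer seed for the permutations.
#' @param log_base `exp(1)` (natural, default) or `2`.
#' @param permute `"regions"` permutes region labels (preserving region
#'   count and label multiset, default); `"bins"` permutes bin labels.
#' @return List with `logfc` (r x r matrix), `observed`, `random`
#'   (expected fractions), `n_regions`; empty matrices when fewer than
#'   two regions exist.
#' @export
transition_enrichment <- function(track, n_permutations = 100L, seed = 1L,
                                  log_base = exp(1),
                                  permute = c("regions", "bins")) {
  permute <- match.arg(permute)
  .assert(is(track, "profile_track"), "track must be a profile_track")
  r <- ncol(track$weights)
  pn <- track$profile_names

  regions <- .label_regions(track)
  if (nrow(regions) < 2L) {
    empty <- matrix(numeric(0), 0, 0)
    return(list(logfc = empty, observed = empty, random = empty,
                n_regions = nrow(regions)))
  }

  count_trans <- function(labels, blocks) {
    # transitions only within a block (same chromosome, no gaps)
    n <- length(labels)
    from <- labels[-n]; to <- labels[-1]
    ok <- blocks[-n] == blocks[-1]
    m <- matrix(0, r, r)
    if (any(ok)) {
      t2 <- table(factor(from[ok], levels = seq_len(r)),
                  factor(to[ok], levels = seq_len(r)))
      m <- m + unclass(t2)
    }
    m
  }
  freq_from <- function(counts) {
    tot <- table(factor(regions$label, levels = seq_len(r)))
    sweep(counts, 1, pmax(as.numeric(tot), 1), "/")
  }

  obs <- freq_from(count_trans(regions$label, regions$block))

  # a permuted label sequence can place identical labels side by side;
  # re-merge such runs so the null is a proper region track like the
  # observed one
  remerge <- function(labels, blocks) {
    runs <- rle(paste(blocks, labels))
    first <- c(1L, head(cumsum(runs$lengths), -1) + 1L)
    list(label = labels[first], block = blocks[first])
  }
  rand_sum <- matrix(0, r, r)
  perm_seeds <- derive_seeds(seed, n_permutations)
  if (permute == "regions") {
    for (p in seq_len(n_permutations)) {
      lab_p <- withr::with_seed(perm_seeds[p],
                                sample(regions$label))
      m <- remerge(lab_p, regions$block)
      tot_p <- table(factor(m$label, levels = seq_len(r)))
      cnt_p <- count_trans(m$label, m$block)
      rand_sum <- rand_sum +
        sweep(cnt_p, 1, pmax(as.numeric(tot_p), 1), "/")
    }
  } else {
    base_lab <- track$label
    for (p in seq_len(n_permutations)) {
      lab_p <- withr::with_seed(perm_seeds[p], sample(base_lab))
      tr2 <- track
      tr2$label <- lab_p
      reg2 <- .label_regions(tr2)
      tot2 <- table(factor(reg2$label, levels = seq_len(r)))
      cnt2 <- count_trans(reg2$label, reg2$block)
      rand_sum <- rand_sum + sweep(cnt2, 1, pmax(as.numeric(tot2), 1), "/")
    }
  }
  rand <- rand_sum / n_permutations

  logfc <- log(obs / rand) / log(log_base)
  logfc[!is.finite(rand) | rand == 0] <- NaN
  dimnames(logfc) <- dimnames(obs) <- dimnames(rand) <- list(pn, pn)
  list(logfc = logfc, observed = obs, random = rand,
       n_regions = nrow(regions))
}
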