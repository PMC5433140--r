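#' Single NMF run with KL multiplicative updates
#'
#' Factorizes a non-negative bins-by-marks matrix `V ~ W H` at rank `r`
#' by minimizing the generalized Kullback-Leibler divergence with
#' Lee-Seung multiplicative updates (the algorithm popularized for
#' molecular-pattern discovery by Brunet and colleagues). `W` and `H` are
#' initialized i.i.d. uniform on `[0, max(V)]` under the given seed.
#' Iteration stops when the relative loss change drops below `tol`, when
#' the mark-cluster assignment of `H` is stationary for
#' `conn_stop` consecutive iterations, or at `max_iter`.
#'
#' @param V A `coverage_matrix` (any stage) or a non-negative matrix.
#' @param r Factorization rank, `2 <= r < ncol(V)` (`r = 1` allowed for
#'   the degenerate rank-1 model).
#' @param seed Integer RNG seed for the initialization.
#' @param max_iter Maximum number of update iterations.
#' @param tol Relative KL-loss change tolerance.
#' @param conn_stop Connectivity-stationarity window (iterations); `0`
#'   disables this stopping rule.
#' @param trace_loss Keep the full per-iteration loss trace.
#' @return An `nmf_fit`: list with `W` (bins x r), `H` (r x marks), `r`,
#'   `loss` (final KL divergence), `rss`, `seed`, `n_iter`, `stopped`,
#'   `loss_trace`.
#' @export
nmf_run <- function(V, r, seed = 1L, max_iter = 2000L, tol = 1e-5,
                    conn_stop = 40L, trace_loss = FALSE) {
  X <- if (is(V, "coverage_matrix")) V$values else as.matrix(V)
  .assert(all(is.finite(X)) && all(X >= 0), "V must be non-negative and finite")
  .assert(r >= 1 && r <= ncol(X), "rank r must satisfy 1 <= r <= ncol(V)")
  vmax <- max(X)
  if (vmax == 0) {
    stop(structure(class = c("chromnmf_degenerate_input", "chromnmf_error",
                             "error", "condition"),
                   list(message = "all-zero input matrix", call = sys.call())))
  }
  init <- withr::with_seed(seed, list(
    W = matrix(runif(nrow(X) * r, 0, vmax), nrow(X), r),
    H = matrix(runif(r * ncol(X), 0, vmax), r, ncol(X))
  ))
  res <- .nmf_kl_cpp(X, init$W, init$H, as.integer(max_iter), tol,
                     as.integer(conn_stop), .CHROMNMF_EPS, trace_loss)
  rownames(res$W) <- rownames(X)
  colnames(res$H) <- colnames(X)
  colnames(res$W) <- rownames(res$H) <- paste0("profile", seq_len(r))
  structure(list(W = res$W, H = res$H, r = as.integer(r), loss = res$loss,
                 rss = res$rss, seed = as.integer(seed),
                 n_iter = res$n_iter, stopped = res$stopped,
                 loss_trace = res$loss_trace),
            class = "nmf_fit")
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf("nmf_fit: r=%d, %d x %d, KL=%.6g, RSS=%.6g, %d iter (%s)\n",
              x$r, nrow(x$W), ncol(x$H), x$loss, x$rss, x$n_iter, x$stopped))
  invisible(x)
}

#' Connectivity matrix of marks from one factorization
#'
#' Two marks are connected (entry 1) when they load maximally on the same
#' profile, i.e. share `argmax_c H(c, k)`. Ties are broken toward the
#' lowest profile index; an all-zero column is assigned to profile 1 with
#' a warning.
#'
#' @param H Coefficient matrix (r x marks) or an `nmf_fit`.
#' @return Binary marks-by-marks matrix.
#' @export
connectivity <- function(H) {
  if (is(H, "nmf_fit")) H <- H$H
  H <- as.matrix(H)
  .assert(all(H >= 0), "H must be non-negative")
  zero_cols <- colSums(H) == 0
  if (any(zero_cols)) {
    warning(sprintf("%d all-zero column(s) of H assigned to profile 1",
                    sum(zero_cols)))
  }
  cl <- apply(H, 2, which.max)  # which.max takes the first (lowest) index on ties
  C <- outer(cl, cl, `==`) * 1L
  dimnames(C) <- list(colnames(H), colnames(H))
  C
}

#' Consensus matrix and cophenetic correlation coefficient
#'
#' Averages the connectivity matrices of repeated factorizations into a
#' consensus matrix (entries estimate the probability that two marks
#' co-cluster), converts it to the distance `1 - consensus`, clusters the
#' distance with average-linkage hierarchical clustering, and reports the
#' Pearson correlation between the observed and the cophenetic distances.
#' A perfectly stable clustering gives a coefficient of 1. When all
#' pairwise distances are identical the coefficient is undefined and is
#' returned as 1 with `degenerate = TRUE` (the clustering is trivially
#' stable).
#'
#' @param connectivity_list List of >= 2 binary connectivity matrices of
#'   identical shape (or averaged consensus contributions).
#' @return List with `consensus`, `cophenetic`, `hclust`, `degenerate`.
#' @export
consensus_cophenetic <- function(connectivity_list) {
  .assert(length(connectivity_list) >= 1L,
          "need at least one connectivity matrix")
  dims <- unique(lapply(connectivity_list, dim))
  .assert(length(dims) == 1L, "connectivity matrices must share a shape")
  consensus <- Reduce(`+`, connectivity_list) / length(connectivity_list)
  d <- stats::as.dist(1 - consensus)
  hc <- stats::hclust(d, method = "average")
  degenerate <- stats::sd(d) == 0
  coph <- if (degenerate) 1.0 else {
    val <- suppressWarnings(stats::cor(d, stats::cophenetic(hc)))
    if (!is.finite(val)) 1.0 else val
  }
  list(consensus = consensus, cophenetic = coph, hclust = hc,
       degenerate = degenerate)
}

#' Repeated NMF runs with consensus statistics
#'
#' Runs [nmf_run()] `n_runs` times from different random initializations,
#' returns the run with the smallest reconstruction error (residual sum
#' of squares) and the consensus/cophenetic statistics over all runs.
#'
#' @param V Input matrix or `coverage_matrix`.
#' @param r Factorization rank.
#' @param n_runs Number of random restarts (>= 2 for meaningful
#'   consensus).
#' @param seed Master seed; per-run seeds are derived deterministically.
#' @param seeds Optional explicit per-run seeds (overrides `seed`).
#' @param source Label stored in the statistics (`"real"` or `"random"`).
#' @param ... Passed to [nmf_run()].
#' @return List with `best` (`nmf_fit`), `stats` (a `consensus_stats`:
#'   `r`, `consensus`, `cophenetic`, `rss`, `rss_all`, `source`,
#'   `n_runs`, `sparseness`), `fits` (all runs' RSS and seeds).
#' @export
multirun <- function(V, r, n_runs = 30L, seed = 1L, seeds = NULL,
                     source = "real", ...) {
  .assert(n_runs >= 1L, "n_runs must be >= 1")
  if (is.null(seeds)) seeds <- derive_seeds(seed, n_runs)
  .assert(length(seeds) == n_runs, "need one seed per run")

  fits <- lapply(seeds, function(s) nmf_run(V, r, seed = s, ...))
  rss_all <- vapply(fits, `[[`, numeric(1), "rss")
  best <- fits[[which.min(rss_all)]]
  conn_list <- lapply(fits, connectivity)
  cons <- consensus_cophenetic(conn_list)

  stats <- structure(list(
    r = as.integer(r),
    consensus = cons$consensus,
    cophenetic = cons$cophenetic,
    rss = min(rss_all),
    rss_all = rss_all,
    source = source,
    n_runs = as.integer(n_runs),
    sparseness = c(W = hoyer_sparseness(best$W),
                   H = hoyer_sparseness(best$H))
  ), class = "consensus_stats")

  list(best = best, stats = stats,
       fits = data.frame(seed = seeds, rss = rss_all))
}

#' @export
print.consensus_stats <- function(x, ...) {
  cat(sprintf("consensus_stats [%s]: r=%d, cophenetic=%.4f, best RSS=%.6g (%d runs)\n",
              x$source, x$r, x$cophenetic, x$rss, x$n_runs))
  invisible(x)
}

#' Hoyer sparseness of a non-negative matrix
#'
#' `(sqrt(n) - l1/l2) / (sqrt(n) - 1)` over all entries: 0 for a flat
#' matrix, 1 for a one-hot matrix. Reported as a factorization
#' diagnostic.
#'
#' @param X Non-negative matrix.
#' @return Sparseness in \[0, 1\].
#' @export
hoyer_sparseness <- function(X) {
  x <- as.numeric(X)
  n <- length(x)
  l2 <- sqrt(sum(x^2))
  if (l2 == 0) return(0)
  (sqrt(n) - sum(abs(x)) / l2) / (sqrt(n) - 1)
}

#' Column-permuted null matrix
#'
#' Independently permutes each column of the matrix over rows, preserving
#' every column's marginal distribution exactly while destroying
#' across-mark correlation; the standard null for consensus-based rank
#' selection.
#'
#' @param V A `coverage_matrix` or matrix.
#' @param seed Integer seed (same seed, same permutation).
#' @return A `coverage_matrix` with stage `"random"` (coordinates
#'   dropped).
#' @export
permute_columns <- function(V, seed = 1L) {
  X <- if (is(V, "coverage_matrix")) V$values else as.matrix(V)
  P <- withr::with_seed(seed, {
    apply(X, 2, function(col) col[sample.int(length(col))])
  })
  colnames(P) <- colnames(X)
  coverage_matrix(P, bins = NULL, stage = "random")
}

#' Select the factorization rank against column-permuted null data
#'
#' For each rank in `r_range`, computes the cophenetic coefficient of the
#' real matrix over `n_runs` restarts and the mean/SD of the coefficient
#' over `random_repeats` independent column permutations (each factorized
#' with the same settings). The selected rank `r*` is the smallest rank
#' whose real cophenetic coefficient exceeds the random mean by more than
#' `sd_factor` random SDs, with the same condition holding at the next
#' rank (single-rank spikes are ignored). RSS curves are returned as a
#' secondary diagnostic.
#'
#' @param V A `coverage_matrix` or matrix (typically the transformed
#'   significant-bin matrix).
#' @param r_range Integer vector of candidate ranks (default 3..13).
#' @param n_runs Restarts per factorization.
#' @param random_repeats Independent column permutations per rank.
#' @param sd_factor Threshold in units of the random SD (default 4).
#' @param seed Master seed.
#' @param ... Passed to [nmf_run()].
#' @return A `rank_selection`: list with `r_star` (`NA` when no rank
#'   passes), `table` (per-rank diagnostics), `passed` (per-rank rule
#'   indicator), `random` (per-rank random cophenetic draws), and the
#'   call settings.
#' @export
select_rank <- function(V, r_range = 3:13, n_runs = 30L,
                        random_repeats = 20L, sd_factor = 4,
                        seed = 1L, ...) {
  X <- if (is(V, "coverage_matrix")) V$values else as.matrix(V)
  K <- ncol(X)
  .assert(min(r_range) >= 2 && max(r_range) <= K,
          "r_range must lie within [2, ncol(V)]")
  .assert(random_repeats >= 2L, "random_repeats must be >= 2")
  r_range <- sort(unique(as.integer(r_range)))

  seeds <- derive_seeds(seed, length(r_range) * (1L + random_repeats))
  seed_idx <- 0L
  next_seed <- function() {
    seed_idx <<- seed_idx + 1L
    seeds[seed_idx]
  }

  rows <- list()
  random_draws <- list()
  for (ri in seq_along(r_range)) {
    r <- r_range[ri]
    real <- multirun(X, r, n_runs = n_runs, seed = next_seed(),
                     source = "real", ...)
    rand_coph <- numeric(random_repeats)
    rand_rss <- numeric(random_repeats)
    for (rep in seq_len(random_repeats)) {
      s <- next_seed()
      VR <- permute_columns(X, seed = s)
      mr <- multirun(VR$values, r, n_runs = n_runs, seed = s + 1L,
                     source = "random", ...)
      rand_coph[rep] <- mr$stats$cophenetic
      rand_rss[rep] <- mr$stats$rss
    }
    rows[[ri]] <- data.frame(
      r = r,
      cophenetic_real = real$stats$cophenetic,
      rss_real = real$stats$rss,
      cophenetic_random_mean = mean(rand_coph),
      cophenetic_random_sd = stats::sd(rand_coph),
      rss_random_mean = mean(rand_rss),
      sparseness_W = real$stats$sparseness["W"],
      sparseness_H = real$stats$sparseness["H"]
    )
    random_draws[[as.character(r)]] <- rand_coph
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  passed <- tab$cophenetic_real >
    (tab$cophenetic_random_mean + sd_factor * tab$cophenetic_random_sd)
  # require the rule to also hold at the next scanned rank (plateau check)
  persistent <- passed & c(passed[-1], FALSE)
  r_star <- if (any(persistent)) tab$r[which(persistent)[1]] else NA_integer_

  structure(list(
    r_star = r_star, table = tab, passed = passed, random = random_draws,
    r_range = r_range, n_runs = as.integer(n_runs),
    random_repeats = as.integer(random_repeats), sd_factor = sd_factor,
    seed = as.integer(seed)
  ), class = "rank_selection")
}

#' @export
print.rank_selection <- function(x, ...) {
  cat("rank_selection over r =", paste(range(x$r_range), collapse = ".."),
      "\n")
  print(x$table[, c("r", "cophenetic_real", "cophenetic_random_mean",
                    "cophenetic_random_sd")], row.names = FALSE)
  if (is.na(x$r_star)) {
    cat("no rank satisfied the selection rule (r* undefined)\n")
  } else {
    cat(sprintf("selected rank r* = %d\n", x$r_star))
  }
  invisible(x)
}
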