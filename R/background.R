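#' Fit the per-mark negative-binomial background model
#'
#' Models a mark's coverage vector as a Poisson-Gamma mixture (negative
#' binomial): the Poisson mean is Gamma-distributed with shape `beta` and
#' scale `alpha`. The shape is the gamma maximum-likelihood estimate on the
#' strictly positive coverage values (the gamma support excludes zero);
#' the mixture mean is anchored to `mu = mean over all bins` by setting
#' `alpha = mu / beta`, so the implied NB mean equals the observed mean
#' coverage. A non-convergent MLE falls back to the method-of-moments
#' shape with a warning.
#'
#' @param z Numeric coverage vector for one mark (length >= 100, at least
#'   10 strictly positive entries).
#' @param mark Mark identifier stored in the model.
#' @return A `mark_background` object: list with `mark`, `mu`, `beta`,
#'   `alpha`, `fit_info` (log-likelihood, n bins, n positive, fallback
#'   flag).
#' @export
fit_mark_background <- function(z, mark = "mark") {
  .assert(is.numeric(z) && length(z) >= 100L,
          "coverage vector must be numeric with length >= 100")
  .assert(all(is.finite(z)) && all(z >= 0), "coverage must be finite and >= 0")
  pos <- z[z > 0]
  if (length(pos) == 0L) {
    stop(structure(class = c("chromnmf_model_unfit", "chromnmf_error",
                             "error", "condition"),
                   list(message = "all-zero coverage vector: model unfit",
                        call = sys.call())))
  }
  .assert(length(pos) >= 10L, "need at least 10 positive coverage values")

  mu <- mean(z)
  fallback <- FALSE
  loglik <- NA_real_
  beta <- tryCatch({
    fit <- suppressWarnings(MASS::fitdistr(pos, "gamma"))
    loglik <- as.numeric(fit$loglik)
    unname(fit$estimate["shape"])
  }, error = function(e) NA_real_)
  if (!is.finite(beta) || beta <= 0) {
    fallback <- TRUE
    v <- stats::var(pos)
    beta <- if (is.finite(v) && v > 0) mean(pos)^2 / v else 1e6
    warning("gamma MLE did not converge; using method-of-moments shape")
  }
  alpha <- mu / beta

  structure(list(
    mark = mark, mu = mu, beta = beta, alpha = alpha,
    fit_info = list(loglik = loglik, n_bins = length(z),
                    n_positive = length(pos), fallback = fallback)
  ), class = "mark_background")
}

#' @export
print.mark_background <- function(x, ...) {
  cat(sprintf("mark_background [%s]: mu=%.4g beta=%.4g alpha=%.4g%s\n",
              x$mark, x$mu, x$beta, x$alpha,
              if (x$fit_info$fallback) " (moment fallback)" else ""))
  invisible(x)
}

#' Upper-tail p-value under the fitted negative-binomial background
#'
#' Computes `P(N >= ceiling(x))` for the NB distribution with
#' Poisson-Gamma parameters `(alpha, beta)`, i.e. pmf
#' `C(n+beta-1, n) (alpha/(alpha+1))^n (1/(alpha+1))^beta`. Continuous
#' coverage values are ceiled to the integer count scale. `x = 0` gives
#' p = 1.
#'
#' @param model A `mark_background`.
#' @param x Coverage value(s), >= 0.
#' @return Upper-tail probabilities in (0, 1\].
#' @export
nb_tail_pvalue <- function(model, x) {
  .assert(is(model, "mark_background"), "model must be a mark_background")
  .assert(all(is.finite(x)), "x must be finite")
  if (any(x < 0)) .config_error("coverage values must be >= 0")
  prob <- 1 / (model$alpha + 1)
  stats::pnbinom(ceiling(x) - 1, size = model$beta, prob = prob,
                 lower.tail = FALSE)
}

#' Signal threshold at a given upper-tail probability
#'
#' Inverts the fitted negative binomial's survival function on the
#' continuous coverage scale: the returned threshold `t` satisfies
#' `P(N > t) = tail` under the continuous interpolation of the
#' Poisson-Gamma survival (via the regularized incomplete beta identity
#' `P(N <= n) = pbeta(1/(alpha+1), beta, n + 1)`). Bins whose coverage
#' exceeds `t` are the `tail` upper fraction under the background model;
#' because the interpolation is continuous, the realized pass rate on
#' null data matches the nominal tail up to the discreteness of the
#' counts immediately above `t`.
#'
#' @param model A `mark_background`.
#' @param tail Upper-tail probability, strictly inside (0, 1).
#' @return Signal threshold on the coverage scale.
#' @export
nb_signal_threshold <- function(model, tail = 0.01) {
  .assert(is(model, "mark_background"), "model must be a mark_background")
  if (!is.numeric(tail) || length(tail) != 1L || tail <= 0 || tail >= 1) {
    .config_error("tail probability must lie strictly inside (0, 1)")
  }
  prob <- 1 / (model$alpha + 1)
  # P(N <= t) = pbeta(prob, beta, t + 1), continuous in t
  surv <- function(t) 1 - stats::pbeta(prob, model$beta, t + 1)
  hi <- stats::qnbinom(tail, size = model$beta, prob = prob,
                       lower.tail = FALSE) + 2
  stats::uniroot(function(t) surv(t) - tail, lower = 0, upper = hi,
                 tol = 1e-9)$root
}

#' Filter bins with significant signal in at least one mark
#'
#' Computes, per mark, the background signal threshold at the given
#' upper-tail probability (default 1%) and retains every bin whose
#' coverage exceeds the threshold in one or more marks, preserving row
#' order and coordinates. This yields the significant-bin matrix fed to
#' the factorization. The per-cell upper-tail p-value matrix `Q(j,k)` is
#' computed alongside for reporting.
#'
#' @param V A `coverage_matrix` (stage `"raw"`).
#' @param models Named list of `mark_background` models, or `NULL` to fit
#'   one per column of `V`.
#' @param tail Upper-tail probability threshold, strictly inside (0, 1).
#' @return List with `filtered` (`coverage_matrix`, stage `"filtered"`),
#'   `pvalues` (full `Q(j,k)` matrix), `keep` (logical per input row),
#'   `thresholds` (per-mark signal thresholds), `models`.
#' @export
filter_significant_bins <- function(V, models = NULL, tail = 0.01) {
  .assert(is(V, "coverage_matrix"), "V must be a coverage_matrix")
  if (!is.numeric(tail) || length(tail) != 1L || tail <= 0 || tail >= 1) {
    .config_error("tail probability must lie strictly inside (0, 1)")
  }
  marks <- colnames(V$values)
  if (is.null(models)) {
    models <- lapply(marks, function(k) fit_mark_background(V$values[, k], k))
    names(models) <- marks
  }
  .assert(all(marks %in% names(models)),
          "a background model is required for every mark column")

  Q <- vapply(marks, function(k) nb_tail_pvalue(models[[k]], V$values[, k]),
              numeric(nrow(V$values)))
  Q <- matrix(Q, nrow = nrow(V$values),
              dimnames = list(rownames(V$values), marks))

  thresholds <- vapply(marks, function(k) {
    nb_signal_threshold(models[[k]], tail)
  }, numeric(1))
  keep <- rowSums(sweep(V$values, 2, thresholds, `>`)) > 0

  filtered <- coverage_matrix(V$values[keep, , drop = FALSE],
                              bins = if (!is.null(V$bins))
                                V$bins[keep, , drop = FALSE] else NULL,
                              stage = "filtered")
  list(filtered = filtered, pvalues = Q, keep = keep,
       thresholds = thresholds, models = models)
}
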