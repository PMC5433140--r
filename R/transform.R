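#' Per-mark sigmoid transform parameters
#'
#' The anchor `y` of the sigmoid is, per mark, the 95th percentile (linear
#' interpolation, zeros included) of the coverage distribution, so that the
#' transform is close to linear below `y` and saturates above it.
#'
#' @param V A `coverage_matrix`.
#' @param percentile Percentile level in (0, 100\], default 95.
#' @return A `transform_params` object: list with `y` (named per-mark
#'   anchors) and `percentile`.
#' @export
transform_params <- function(V, percentile = 95) {
  .assert(is(V, "coverage_matrix"), "V must be a coverage_matrix")
  .assert(percentile > 0 && percentile <= 100,
          "percentile must lie in (0, 100]")
  y <- apply(V$values, 2, stats::quantile, probs = percentile / 100,
             names = FALSE)
  structure(list(y = y, percentile = percentile),
            class = "transform_params")
}

#' Sigmoid signal transform
#'
#' Rescales each mark's coverage into \[0, 1) with
#' `X' = 2 / (1 + exp(-2 x / y)) - 1` (equivalently `tanh(x / y)`), where
#' `y` is the mark's 95th-percentile anchor. The map is approximately
#' linear up to `y` and compresses the heavy right tail, putting all
#' marks on a common scale before factorization. A mark whose anchor is 0
#' passes through as zeros with a warning.
#'
#' @param V A `coverage_matrix` with non-negative entries.
#' @param params A `transform_params`, or `NULL` to compute them from `V`.
#' @param percentile Used when `params` is `NULL`.
#' @return A `coverage_matrix` with stage `"transformed"` and attribute
#'   `params`.
#' @export
sigmoid_transform <- function(V, params = NULL, percentile = 95) {
  .assert(is(V, "coverage_matrix"), "V must be a coverage_matrix")
  if (any(V$values < 0)) .config_error("sigmoid transform requires x >= 0")
  if (is.null(params)) params <- transform_params(V, percentile)
  .assert(is(params, "transform_params"), "params must be transform_params")
  .assert(length(params$y) == ncol(V$values),
          "one anchor per mark column required")

  out <- V$values
  for (k in seq_len(ncol(out))) {
    yk <- params$y[k]
    if (yk <= 0) {
      if (any(out[, k] > 0)) {
        warning(sprintf("mark '%s' has zero transform anchor; column passed through as zeros",
                        colnames(out)[k]))
      }
      out[, k] <- 0
    } else {
      out[, k] <- 2 / (1 + exp(-2 * out[, k] / yk)) - 1
    }
  }
  res <- coverage_matrix(out, bins = V$bins, stage = "transformed")
  attr(res, "params") <- params
  res
}
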