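#' Expected per-bin read counts under uniform read placement
#'
#' For every replicate `i` of a mark's dataset `P`, computes the expected
#' number of reads falling into each bin given the replicate's sequencing
#' depth `C(i)` and the bin's mappable length `M(j)`. The scaling factor
#' `Q(i,P) = A(P)/C(i)` (with `A(P)` the mean depth across replicates)
#' equalizes depths within the dataset.
#'
#' Two modes are provided. `"uniform"` (default) is the expected read count
#' under uniform placement of the replicate's reads over mappable
#' positions, `E(j,k,i) = C(i) * M(j) / G`, so the downstream coverage
#' ratio is a fold-enrichment over background. `"literal"` computes
#' `E(j,k,i) = M(j) / (G * Q(i,P))`, an alternative normalization in which
#' the expected count is scaled by the dataset's mean depth rather than the
#' replicate's own; see the methods vignette for the rationale for the
#' default.
#'
#' @param bins A `genome_bins`.
#' @param samples List of `read_set` objects, all replicates of one mark.
#' @param mode `"uniform"` or `"literal"`.
#' @return A `count_tensor`: list with `counts` (bins x samples matrix
#'   `R`), `expected` (`E`), `scale` (`Q(i,P)` per sample), `dataset_mean`
#'   (`A(P)`), `mark`, `mode`, `bins`.
#' @export
expected_counts <- function(bins, samples, mode = c("uniform", "literal")) {
  mode <- match.arg(mode)
  .assert(is(bins, "genome_bins"), "bins must be a genome_bins")
  .assert(length(samples) >= 1L, "need at least one sample")
  .assert(all(vapply(samples, function(s) is(s, "read_set"), logical(1))),
          "samples must be read_set objects")
  M <- bins$mappable_bp
  G <- bins$genome_mappable
  .assert(any(M > 0), "no mappable genome: M(j) = 0 for all bins")
  .assert(G > 0, "genome mappable size G must be > 0")

  C <- vapply(samples, function(s) as.numeric(s$total_mapped), numeric(1))
  bad <- which(C == 0)
  if (length(bad) > 0L) {
    .config_error(sprintf("sample(s) with zero mapped reads rejected: %s",
                          paste(vapply(samples[bad], `[[`, "", "sample"),
                                collapse = ", ")))
  }
  A <- mean(C)
  Q <- A / C

  R <- vapply(samples, function(s) as.numeric(count_reads(s, bins)),
              numeric(n_bins(bins)))
  R <- matrix(R, nrow = n_bins(bins))
  E <- switch(mode,
    uniform = outer(M / G, C),
    literal = outer(M / G, 1 / Q)
  )
  colnames(R) <- colnames(E) <- vapply(samples, `[[`, "", "sample")

  structure(list(
    counts = R, expected = E, scale = Q, dataset_mean = A,
    mark = samples[[1]]$mark, mode = mode, bins = bins
  ), class = "count_tensor")
}

#' Normalized coverage of one mark over all bins
#'
#' Collapses replicates into the per-bin coverage estimate
#' `S(j,k) = sum_i R(j,k,i) / sum_i E(j,k,i)`, a fold-enrichment of the
#' observed over the expected read count. Unmappable bins (`M(j) = 0`, so
#' `sum_i E = 0`) get coverage 0 and are flagged.
#'
#' @param tensor A `count_tensor` from [expected_counts()].
#' @return Numeric vector of per-bin coverage `S(j)`, with attribute
#'   `unmappable` (logical per-bin flag).
#' @export
normalized_coverage_vector <- function(tensor) {
  .assert(is(tensor, "count_tensor"), "tensor must be a count_tensor")
  .assert(all(tensor$counts >= 0), "negative read counts: internal inconsistency")
  num <- rowSums(tensor$counts)
  den <- rowSums(tensor$expected)
  unmappable <- den == 0
  s <- ifelse(unmappable, 0, num / ifelse(unmappable, 1, den))
  attr(s, "unmappable") <- unmappable
  s
}

#' Assemble the bins-by-marks coverage matrix
#'
#' Builds the `coverage_matrix` `V(j,k)` from per-mark replicate read
#' sets: one [expected_counts()] + [normalized_coverage_vector()] pass per
#' mark, columns in the order of `mark_reads`.
#'
#' @param bins A `genome_bins`.
#' @param mark_reads Named list: one entry per mark, each a list of
#'   `read_set` replicates.
#' @param mode Normalization mode passed to [expected_counts()].
#' @return A `coverage_matrix` (stage `"raw"`).
#' @export
normalized_coverage <- function(bins, mark_reads, mode = c("uniform", "literal")) {
  mode <- match.arg(mode)
  .assert(length(mark_reads) >= 1L, "need at least one mark")
  .assert(!is.null(names(mark_reads)) && all(nzchar(names(mark_reads))),
          "mark_reads must be a named list")
  .assert(!anyDuplicated(names(mark_reads)), "mark names must be unique")
  cols <- lapply(mark_reads, function(samples) {
    normalized_coverage_vector(expected_counts(bins, samples, mode = mode))
  })
  V <- do.call(cbind, cols)
  colnames(V) <- names(mark_reads)
  coverage_matrix(V, bins = bins$bins, stage = "raw")
}

#' Construct a coverage_matrix container
#'
#' The central data container: a non-negative bins-by-marks matrix with
#' bin coordinates and a processing-stage tag.
#'
#' @param values Numeric matrix, rows = bins, columns = marks.
#' @param bins Data frame with `chrom`, `start`, `end` (0-based,
#'   half-open), one row per matrix row, ordered by `(chrom, start)`, or
#'   `NULL` for coordinate-free matrices (e.g. purely synthetic input).
#' @param stage One of `"raw"`, `"filtered"`, `"transformed"`, `"random"`.
#' @return A `coverage_matrix` object.
#' @export
coverage_matrix <- function(values,
                            bins = NULL,
                            stage = c("raw", "filtered", "transformed",
                                      "random")) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  .assert(all(is.finite(values)), "coverage values must be finite")
  .assert(all(values >= 0), "coverage values must be non-negative")
  .assert(!is.null(colnames(values)) && !anyDuplicated(colnames(values)),
          "coverage matrix needs unique column (mark) labels")
  if (!is.null(bins)) {
    .assert(nrow(bins) == nrow(values), "bins/values row mismatch")
    ord <- order(bins$chrom, bins$start)
    .assert(all(ord == seq_len(nrow(bins))),
            "bin coordinates must be ordered by (chrom, start)")
    rownames(values) <- sprintf("%s:%d-%d", bins$chrom, bins$start, bins$end)
  }
  structure(list(values = values, bins = bins, stage = stage),
            class = "coverage_matrix")
}

#' @export
print.coverage_matrix <- function(x, ...) {
  cat(sprintf("coverage_matrix [%s]: %d bins x %d marks\n",
              x$stage, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.coverage_matrix <- function(x) dim(x$values)

#' Write / read a coverage matrix as TSV
#'
#' Rows are labeled `chrom:start-end` when coordinates are available;
#' floats are written with 9 significant digits so reruns are
#' byte-comparable.
#'
#' @param x A `coverage_matrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_coverage_tsv <- function(x, path) {
  .assert(is(x, "coverage_matrix"), "x must be a coverage_matrix")
  df <- data.frame(bin = rownames(x$values) %||%
                     sprintf("bin%06d", seq_len(nrow(x$values))),
                   apply(x$values, 2, function(v) sprintf("%.9g", v)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("bin", colnames(x$values))
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_coverage_tsv
#' @param stage Stage tag for the matrix read back.
#' @export
read_coverage_tsv <- function(path, stage = "raw") {
  df <- data.table::fread(path, sep = "\t", data.table = FALSE)
  ids <- df[[1]]
  V <- as.matrix(df[, -1, drop = FALSE])
  bins <- .parse_bin_ids(ids)
  if (is.null(bins)) rownames(V) <- ids
  coverage_matrix(V, bins = bins, stage = stage)
}

#' Export one mark's coverage as a bedGraph track
#'
#' Writes the per-bin coverage of a single mark as bedGraph for genome
#' browsers; zero-coverage bins are omitted.
#'
#' @param x A `coverage_matrix` with bin coordinates.
#' @param mark Column (mark) name to export.
#' @param path Output bedGraph path.
#' @return `path`, invisibly.
#' @export
write_coverage_bedgraph <- function(x, mark, path) {
  .assert(is(x, "coverage_matrix"), "x must be a coverage_matrix")
  .assert(!is.null(x$bins), "coverage matrix carries no coordinates")
  .assert(mark %in% colnames(x$values), "unknown mark column")
  v <- x$values[, mark]
  keep <- v > 0
  gr <- GenomicRanges::GRanges(
    seqnames = x$bins$chrom[keep],
    ranges = IRanges::IRanges(start = x$bins$start[keep] + 1L,
                              end = x$bins$end[keep]),
    score = unname(v[keep])
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

.parse_bin_ids <- function(ids) {
  m <- regmatches(ids, regexec("^(.+):([0-9]+)-([0-9]+)$", ids))
  if (any(lengths(m) != 4L)) return(NULL)
  data.frame(chrom = vapply(m, `[`, "", 2),
             start = as.integer(vapply(m, `[`, "", 3)),
             end = as.integer(vapply(m, `[`, "", 4)),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
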