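#' Load a BED file of read alignments for one mark/replicate
#'
#' Reads BED records (3+ columns; strand taken from column 6 when present,
#' otherwise assumed "+", with a message), optionally removes exact
#' duplicates, and extends each read in its 3' direction to a total
#' footprint of `extension_bp` (half a typical ChIP fragment). Reads
#' already at least `extension_bp` long are left unchanged; extension is
#' clipped at chromosome ends. Records with `start >= end` or on unknown
#' chromosomes are skipped and tallied.
#'
#' @param path BED file path, or a data frame with columns
#'   `chrom`, `start`, `end` (0-based half-open) and optionally `strand`.
#' @param mark Mark identifier `k`.
#' @param sample Replicate identifier `i`.
#' @param chrom_sizes Named chromosome lengths (or table/path accepted by
#'   [make_bins()]); used to clip extension and drop unknown chromosomes.
#' @param dedup Remove exact `(chrom, start, end, strand)` duplicates.
#' @param extension_bp Target read footprint in bp; `0` disables extension.
#' @param extension_mode `"to"` extends the footprint *to* `extension_bp`
#'   total length (default); `"by"` extends *by* `extension_bp`.
#' @return A `read_set`: list with `mark`, `sample`, `intervals`
#'   (data.frame `chrom`, `start`, `end`, `strand`), `total_mapped`
#'   (`C(i)`), and counters `n_malformed`, `n_unknown_chrom`,
#'   `n_duplicates`, `n_unstranded`.
#' @export
load_reads <- function(path, mark, sample = "rep1", chrom_sizes,
                       dedup = FALSE, extension_bp = 200L,
                       extension_mode = c("to", "by")) {
  extension_mode <- match.arg(extension_mode)
  sizes <- .as_chrom_sizes(chrom_sizes)

  if (is.character(path)) {
    raw <- suppressWarnings(
      data.table::fread(path, header = FALSE, sep = "\t",
                        data.table = FALSE, fill = TRUE))
    if (nrow(raw) == 0L) {
      raw <- data.frame(V1 = character(), V2 = numeric(), V3 = numeric())
    }
    .assert(ncol(raw) >= 3, "BED input needs at least 3 columns")
    df <- data.frame(chrom = as.character(raw[[1]]),
                     start = as.numeric(raw[[2]]),
                     end = as.numeric(raw[[3]]),
                     strand = if (ncol(raw) >= 6) as.character(raw[[6]])
                              else rep(NA_character_, nrow(raw)),
                     stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(path, stringsAsFactors = FALSE)
    .assert(all(c("chrom", "start", "end") %in% names(df)),
            "read table needs chrom/start/end columns")
    if (is.null(df$strand)) df$strand <- NA_character_
  }

  n_malformed <- sum(!is.finite(df$start) | !is.finite(df$end) |
                       df$start >= df$end)
  df <- df[is.finite(df$start) & is.finite(df$end) & df$start < df$end, ,
           drop = FALSE]

  unknown <- !(df$chrom %in% names(sizes))
  n_unknown <- sum(unknown)
  if (n_unknown > 0L) {
    warning(sprintf("%d read(s) on chromosomes absent from chrom_sizes skipped",
                    n_unknown))
    df <- df[!unknown, , drop = FALSE]
  }

  n_unstranded <- sum(is.na(df$strand) | !(df$strand %in% c("+", "-")))
  if (n_unstranded > 0L) {
    message(sprintf("%d read(s) without strand treated as '+'", n_unstranded))
  }
  df$strand[is.na(df$strand) | !(df$strand %in% c("+", "-"))] <- "+"

  n_dup <- 0L
  if (dedup && nrow(df) > 0L) {
    key <- paste(df$chrom, df$start, df$end, df$strand)
    dup <- duplicated(key)
    n_dup <- sum(dup)
    df <- df[!dup, , drop = FALSE]
  }

  if (extension_bp > 0L && nrow(df) > 0L) {
    len <- df$end - df$start
    target <- if (extension_mode == "to") pmax(len, extension_bp)
              else len + extension_bp
    plus <- df$strand == "+"
    df$end[plus] <- df$start[plus] + target[plus]
    df$start[!plus] <- df$end[!plus] - target[!plus]
    # clip at chromosome ends
    df$start <- pmax(df$start, 0)
    df$end <- pmin(df$end, sizes[df$chrom])
  }

  structure(list(
    mark = mark, sample = sample,
    intervals = df[, c("chrom", "start", "end", "strand")],
    total_mapped = nrow(df),
    n_malformed = n_malformed, n_unknown_chrom = n_unknown,
    n_duplicates = n_dup, n_unstranded = n_unstranded
  ), class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: mark=%s sample=%s C(i)=%d (malformed=%d, dup=%d)\n",
              x$mark, x$sample, x$total_mapped, x$n_malformed,
              x$n_duplicates))
  invisible(x)
}

#' Count reads per genomic bin
#'
#' Assigns each read to every bin it overlaps by at least 1 bp, so a read
#' spanning a bin boundary increments both bins.
#'
#' @param reads A `read_set` from [load_reads()].
#' @param bins A `genome_bins` from [make_bins()].
#' @return Integer vector of per-bin counts `R(j)`.
#' @export
count_reads <- function(reads, bins) {
  .assert(is(reads, "read_set"), "reads must be a read_set")
  .assert(is(bins, "genome_bins"), "bins must be a genome_bins")
  if (nrow(reads$intervals) == 0L) return(integer(n_bins(bins)))
  gr <- GenomicRanges::GRanges(
    seqnames = reads$intervals$chrom,
    ranges = IRanges::IRanges(start = reads$intervals$start + 1L,
                              end = reads$intervals$end)
  )
  GenomicRanges::countOverlaps(bins_granges(bins), gr, minoverlap = 1L)
}
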