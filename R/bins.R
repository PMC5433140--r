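#' Tile a genome into fixed-width bins
#'
#' Partitions every chromosome into non-overlapping, half-open, 0-based
#' intervals of `bin_width` bp (default 200 bp, roughly one nucleosome).
#' The last bin of a chromosome may be shorter; it is retained. Per-bin
#' mappable length `M(j)` and the genome-wide mappable size `G` are taken
#' from an optional mappability track, or default to the bin/chromosome
#' lengths when no track is supplied.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp), or a
#'   two-column data frame `(chrom, length)`, or the path of a two-column
#'   `chrom.sizes` text file.
#' @param bin_width Bin width in bp (> 0).
#' @param mappability Optional mappability track: a `GRanges` with a
#'   numeric `score` in \[0, 1\] (bedGraph semantics: score = fraction of
#'   uniquely mappable positions), the path of a bedGraph file, or `NULL`
#'   for a fully mappable genome.
#' @return A `genome_bins` object: list with `bins` (data.frame of
#'   `chrom`, `start`, `end`), `mappable_bp` (per-bin `M(j)`),
#'   `genome_mappable` (`G`), `chrom_sizes`, `bin_width`.
#' @export
make_bins <- function(chrom_sizes, bin_width = 200L, mappability = NULL) {
  sizes <- .as_chrom_sizes(chrom_sizes)
  if (length(sizes) == 0L) .config_error("empty chrom_sizes")
  .assert(bin_width > 0, "bin_width must be > 0")
  .assert(all(sizes > 0), "chromosome lengths must be > 0")

  tiles <- GenomicRanges::tileGenome(sizes, tilewidth = bin_width,
                                     cut.last.tile.in.chrom = TRUE)
  bins <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(tiles)),
    start = GenomicRanges::start(tiles) - 1L,   # back to 0-based half-open
    end   = GenomicRanges::end(tiles),
    stringsAsFactors = FALSE
  )
  widths <- bins$end - bins$start

  if (is.null(mappability)) {
    mappable <- as.numeric(widths)
    genome_mappable <- sum(as.numeric(sizes))
  } else {
    map_gr <- .as_mappability_granges(mappability)
    bad <- setdiff(unique(as.character(GenomeInfoDb::seqnames(map_gr))),
                   names(sizes))
    if (length(bad) > 0L) {
      .config_error(sprintf(
        "mappability track references chromosome(s) not in chrom_sizes: %s",
        paste(bad, collapse = ", ")))
    }
    mappable <- .binned_mappable_bp(tiles, map_gr)
    genome_mappable <- sum(as.numeric(GenomicRanges::width(map_gr)) *
                             map_gr$score)
  }

  structure(list(
    bins = bins,
    mappable_bp = mappable,
    genome_mappable = genome_mappable,
    chrom_sizes = sizes,
    bin_width = as.integer(bin_width)
  ), class = "genome_bins")
}

#' @export
print.genome_bins <- function(x, ...) {
  cat(sprintf("genome_bins: %d bins of %d bp over %d chromosome(s); G = %s bp\n",
              nrow(x$bins), x$bin_width, length(x$chrom_sizes),
              format(x$genome_mappable, big.mark = ",")))
  invisible(x)
}

n_bins <- function(bins) nrow(bins$bins)

bin_ids <- function(bins) {
  sprintf("%s:%d-%d", bins$bins$chrom, bins$bins$start, bins$bins$end)
}

bins_granges <- function(bins) {
  GenomicRanges::GRanges(
    seqnames = bins$bins$chrom,
    ranges = IRanges::IRanges(start = bins$bins$start + 1L,
                              end = bins$bins$end),
    seqlengths = bins$chrom_sizes
  )
}

.as_chrom_sizes <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    tab <- utils::read.table(x, header = FALSE, sep = "",
                             col.names = c("chrom", "length"),
                             colClasses = c("character", "numeric"))
    x <- tab
  }
  if (is.data.frame(x)) {
    .assert(ncol(x) >= 2, "chrom_sizes table needs two columns")
    sizes <- as.numeric(x[[2]])
    names(sizes) <- as.character(x[[1]])
  } else {
    .assert(!is.null(names(x)), "chrom_sizes vector must be named")
    sizes <- as.numeric(x)
    names(sizes) <- names(x)
  }
  .assert(!anyDuplicated(names(sizes)), "duplicated chromosome names")
  sizes
}

.as_mappability_granges <- function(mappability) {
  if (is.character(mappability) && length(mappability) == 1L) {
    mappability <- rtracklayer::import(mappability, format = "bedGraph")
  }
  .assert(is(mappability, "GRanges"),
          "mappability must be a GRanges or a bedGraph path")
  if (is.null(mappability$score)) mappability$score <- 1
  .assert(all(mappability$score >= 0 & mappability$score <= 1),
          "mappability scores must lie in [0, 1]")
  mappability
}

# Sum of score-weighted overlap widths of the mappability track per bin.
.binned_mappable_bp <- function(tiles, map_gr) {
  hits <- GenomicRanges::findOverlaps(tiles, map_gr)
  if (length(hits) == 0L) return(numeric(length(tiles)))
  ov <- IRanges::pintersect(
    tiles[S4Vectors::queryHits(hits)],
    map_gr[S4Vectors::subjectHits(hits)]
  )
  w <- as.numeric(GenomicRanges::width(ov)) *
    map_gr$score[S4Vectors::subjectHits(hits)]
  out <- numeric(length(tiles))
  agg <- rowsum(w, S4Vectors::queryHits(hits))
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}
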