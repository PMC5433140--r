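#' Default profile color palette for genome-track export
#'
#' Colors follow the conventional chromatin-state scheme: active
#' promoter light green, repressed chromatin purple, transcription
#' initiation dark green, repressed regulatory blue, gene body red,
#' enhancer yellow, regulatory elements grey.
#'
#' @return Named character vector of hex colors.
#' @export
default_palette <- function() {
  c(ActProm = "#90EE90", RepChr = "#800080", TxInit = "#006400",
    RepReg = "#0000FF", GenBd = "#FF0000", Enh = "#FFD700",
    RegEl = "#808080")
}

#' Write a profile track as BED9
#'
#' Merges adjacent same-label bins into single records and writes a BED9
#' file with one itemRgb color per profile. Unassigned bins are omitted.
#' The written file round-trips losslessly through
#' [read_profile_track()].
#'
#' @param track A `profile_track` with coordinates.
#' @param path Output BED path.
#' @param palette Named colors per profile; unknown profiles fall back
#'   to grey with a warning.
#' @return `path`, invisibly.
#' @export
write_profile_track <- function(track, path, palette = default_palette()) {
  .assert(is(track, "profile_track"), "track must be a profile_track")
  .assert(!is.null(track$bins), "track carries no coordinates")
  keep <- !is.na(track$label)
  df <- data.frame(chrom = track$bins$chrom[keep],
                   start = track$bins$start[keep],
                   end = track$bins$end[keep],
                   label = track$label[keep])
  if (nrow(df) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  # merge contiguous same-label bins
  n <- nrow(df)
  brk <- c(TRUE, df$chrom[-1] != df$chrom[-n] |
             df$start[-1] != df$end[-n] |
             df$label[-1] != df$label[-n])
  grp <- cumsum(brk)
  first <- which(brk)
  last <- c(first[-1] - 1L, n)
  merged <- data.frame(chrom = df$chrom[first], start = df$start[first],
                       end = df$end[last], label = df$label[first])

  names_out <- track$profile_names[merged$label]
  col <- palette[names_out]
  if (anyNA(col)) {
    warning("profile(s) missing from palette; using grey")
    col[is.na(col)] <- "#808080"
  }
  rgb_txt <- apply(grDevices::col2rgb(col), 2, paste, collapse = ",")
  bed9 <- data.frame(merged$chrom, merged$start, merged$end, names_out,
                     0L, ".", merged$start, merged$end, rgb_txt)
  data.table::fwrite(bed9, path, sep = "\t", col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a BED9 profile track back
#'
#' @param path BED9 path written by [write_profile_track()].
#' @return Data frame with `chrom`, `start`, `end`, `profile`, `rgb`.
#' @export
read_profile_track <- function(path) {
  df <- data.table::fread(path, header = FALSE, sep = "\t",
                          data.table = FALSE)
  .assert(ncol(df) >= 9, "expected a BED9 file")
  data.frame(chrom = as.character(df[[1]]), start = as.integer(df[[2]]),
              end = as.integer(df[[3]]), profile = as.character(df[[4]]),
              rgb = as.character(df[[9]]), stringsAsFactors = FALSE)
}

#' Default pipeline configuration
#'
#' @param ... Overrides of the defaults.
#' @return Named list of stage parameters.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    bin_width = 200L, extension_bp = 200L, normalization_mode = "uniform",
    dedup = FALSE,
    tail = 0.01, percentile = 95,
    rank = NULL, r_range = 3:13, n_runs = 30L, random_repeats = 20L,
    sd_factor = 4, max_iter = 2000L, tol = 1e-5, conn_stop = 40L,
    rwc_thresholds = c(0.95, 0.85, 0.75, 0.5),
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L) {
    .config_error(paste("unknown config field(s):",
                        paste(unknown, collapse = ", ")))
  }
  utils::modifyList(cfg, over)
}

#' Run the full segmentation pipeline
#'
#' Executes coverage (when reads are supplied) or matrix loading, the
#' negative-binomial significance filter, the sigmoid transform, rank
#' selection (unless `config$rank` is fixed), the final multi-run
#' factorization, and per-bin profile assignment. Every stage's output,
#' plus a metadata record (config, seeds, stage shapes), is written to
#' `out_dir` when given; existing stage artifacts are reused on rerun.
#'
#' @param config From [pipeline_config()].
#' @param matrix_path Coverage-matrix TSV (mutually exclusive with
#'   `reads`).
#' @param reads Named list (per mark) of BED paths or lists of BED paths
#'   (replicates).
#' @param chrom_sizes Chromosome sizes (required with `reads`).
#' @param mappability Optional mappability track.
#' @param out_dir Optional artifact directory.
#' @return List with `coverage`, `filtered`, `transformed`,
#'   `rank_selection` (or NULL), `fit`, `track`, `config`, `metadata`.
#' @export
run_pipeline <- function(config = pipeline_config(), matrix_path = NULL,
                         reads = NULL, chrom_sizes = NULL,
                         mappability = NULL, out_dir = NULL) {
  .assert(xor(is.null(matrix_path), is.null(reads)),
          "supply exactly one of matrix_path or reads")
  if (!is.null(matrix_path) && !file.exists(matrix_path)) {
    .config_error(sprintf("input file not found: %s", matrix_path))
  }
  if (!is.null(reads)) {
    .assert(!is.null(chrom_sizes), "chrom_sizes required with reads")
    paths <- unlist(reads)
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0L) {
      .config_error(paste("input file(s) not found:",
                          paste(missing, collapse = ", ")))
    }
  }
  t0 <- Sys.time()
  log_stage <- function(stage, detail) {
    message(sprintf("[%s] %s: %s (%.1fs)", "chromnmf", stage, detail,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }

  if (!is.null(reads)) {
    bins <- make_bins(chrom_sizes, bin_width = config$bin_width,
                      mappability = mappability)
    mark_reads <- lapply(names(reads), function(k) {
      paths <- reads[[k]]
      lapply(seq_along(paths), function(i) {
        load_reads(paths[[i]], mark = k, sample = sprintf("rep%d", i),
                   chrom_sizes = bins$chrom_sizes, dedup = config$dedup,
                   extension_bp = config$extension_bp)
      })
    })
    names(mark_reads) <- names(reads)
    V <- normalized_coverage(bins, mark_reads,
                             mode = config$normalization_mode)
  } else {
    V <- read_coverage_tsv(matrix_path, stage = "raw")
  }
  log_stage("coverage", sprintf("%d bins x %d marks", nrow(V$values),
                                ncol(V$values)))

  filt <- filter_significant_bins(V, tail = config$tail)
  log_stage("filter", sprintf("%d / %d bins retained",
                              nrow(filt$filtered$values), nrow(V$values)))

  trans <- sigmoid_transform(filt$filtered, percentile = config$percentile)
  log_stage("transform", sprintf("percentile anchor = %g", config$percentile))

  seeds <- derive_seeds(config$seed, 2L)
  rank_sel <- NULL
  rank <- config$rank
  if (is.null(rank)) {
    rank_sel <- select_rank(trans, r_range = config$r_range,
                            n_runs = config$n_runs,
                            random_repeats = config$random_repeats,
                            sd_factor = config$sd_factor, seed = seeds[1],
                            max_iter = config$max_iter, tol = config$tol,
                            conn_stop = config$conn_stop)
    if (is.na(rank_sel$r_star)) {
      stop(structure(class = c("chromnmf_stage_error", "chromnmf_error",
                               "error", "condition"),
                     list(message = "stage select-rank: no rank satisfied the selection rule",
                          call = sys.call())))
    }
    rank <- rank_sel$r_star
    log_stage("select-rank", sprintf("r* = %d", rank))
  }

  mr <- multirun(trans, rank, n_runs = config$n_runs, seed = seeds[2],
                 max_iter = config$max_iter, tol = config$tol,
                 conn_stop = config$conn_stop)
  log_stage("factorize", sprintf("r = %d, best RSS = %.6g", rank,
                                 mr$best$rss))

  track <- assign_profiles(mr$best, bins = trans$bins)
  log_stage("assign", sprintf("%d bins labeled", sum(!is.na(track$label))))

  metadata <- list(
    package_version = as.character(utils::packageVersion("chromnmf")),
    config = config[setdiff(names(config), "r_range")],
    r_range = as.integer(config$r_range),
    config_hash = .config_hash(config),
    seed = config$seed, derived_seeds = seeds,
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S")
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_coverage_tsv(trans, file.path(out_dir, "matrix_transformed.tsv"))
    .write_labeled_tsv(mr$best$W, file.path(out_dir, "W.tsv"), "bin")
    .write_labeled_tsv(mr$best$H, file.path(out_dir, "H.tsv"), "profile")
    write_profile_track(track, file.path(out_dir, "profiles.bed"),
                        palette = .track_palette(track))
    if (!is.null(rank_sel)) {
      utils::write.table(rank_sel$table,
                         file.path(out_dir, "rank_selection.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(metadata, file.path(out_dir, "metadata.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(coverage = V, filtered = filt, transformed = trans,
       rank_selection = rank_sel, fit = mr$best, consensus = mr$stats,
       track = track, config = config, metadata = metadata)
}

.track_palette <- function(track) {
  pal <- default_palette()
  missing <- setdiff(track$profile_names, names(pal))
  if (length(missing) > 0L) {
    extra <- grDevices::rainbow(length(missing))
    names(extra) <- missing
    pal <- c(pal, extra)
  }
  pal
}

.write_labeled_tsv <- function(M, path, row_label) {
  df <- data.frame(rownames(M) %||% sprintf("%s%d", row_label,
                                            seq_len(nrow(M))),
                   apply(M, 2, function(v) sprintf("%.9g", v)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(row_label, colnames(M))
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

.config_hash <- function(config) {
  canon <- jsonlite::toJSON(config[order(names(config))],
                            auto_unbox = TRUE, digits = NA)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(canon, f)
  unname(tools::md5sum(f))
}
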