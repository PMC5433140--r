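# Small in-code fixtures shared across test files.

toy_chrom_sizes <- function() c(chrT1 = 2000L, chrT2 = 1000L)

# write a BED data.frame (0-based half-open) to a temp file
write_bed <- function(df, path = tempfile(fileext = ".bed")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  path
}

# reads fully contained in single 200-bp bins of chrT1
contained_reads <- function(n_per_bin, bin_width = 200L) {
  rows <- do.call(rbind, lapply(seq_along(n_per_bin), function(j) {
    n <- n_per_bin[j]
    if (n == 0L) return(NULL)
    start <- (j - 1L) * bin_width + 10L
    data.frame(chrom = "chrT1", start = start, end = start + 50L,
               name = ".", score = 0L, strand = "+")
  }))
  rows
}

# deterministic small planted matrix for NMF tests
planted_matrix <- function(n = 500L, r = 3L, k = 10L, seed = 42L) {
  withr::with_seed(seed, {
    W0 <- matrix(rexp(n * r), n, r)
    H0 <- matrix(rexp(r * k), r, k)
    V <- W0 %*% H0
    colnames(V) <- paste0("m", seq_len(k))
    list(V = V, W0 = W0, H0 = H0)
  })
}

# profile_track built directly from a weight matrix with synthetic coords
toy_track <- function(W, chrom = "chrT1", bin_width = 200L) {
  n <- nrow(W)
  bins <- data.frame(chrom = chrom,
                     start = (seq_len(n) - 1L) * bin_width,
                     end = seq_len(n) * bin_width)
  suppressMessages(assign_profiles(W, bins = bins))
}
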