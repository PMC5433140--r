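test_that("KL loss is monotone non-increasing on varied inputs", {
  pm <- planted_matrix()
  for (seed in 1:3) {
    f <- nmf_run(pm$V, 3, seed = seed, max_iter = 300, tol = 0,
                 conn_stop = 0, trace_loss = TRUE)
    expect_true(all(diff(f$loss_trace) <= 1e-10))
  }
  noisy <- withr::with_seed(9L, matrix(rexp(200 * 6), 200, 6,
                                       dimnames = list(NULL, paste0("m", 1:6))))
  f2 <- nmf_run(noisy, 4, seed = 1, max_iter = 300, tol = 0,
                conn_stop = 0, trace_loss = TRUE)
  expect_true(all(diff(f2$loss_trace) <= 1e-10))
})

test_that("noiseless planted factors are recovered", {
  pm <- planted_matrix()
  fits <- lapply(1:10, function(s) {
    nmf_run(pm$V, 3, seed = s, max_iter = 10000, tol = 1e-12,
            conn_stop = 0)
  })
  rel <- vapply(fits, function(f) sqrt(f$rss) / sqrt(sum(pm$V^2)),
                numeric(1))
  expect_lt(min(rel), 1e-4)
  # matched factor directions agree (cosine >= 0.99)
  best <- fits[[which.min(rel)]]
  cosmat <- abs(crossprod(
    apply(pm$W0, 2, function(w) w / sqrt(sum(w^2))),
    apply(best$W, 2, function(w) w / sqrt(sum(w^2)))
  ))
  expect_true(all(apply(cosmat, 1, max) >= 0.99))
})

test_that("rank-1 factorization reproduces a rank-1 matrix", {
  u <- withr::with_seed(5L, rexp(100))
  v <- withr::with_seed(6L, rexp(8))
  V <- outer(u, v)
  colnames(V) <- paste0("m", 1:8)
  f <- nmf_run(V, 1, seed = 1, max_iter = 5000, tol = 1e-12,
               conn_stop = 0)
  expect_lt(sqrt(f$rss) / sqrt(sum(V^2)), 1e-6)
})

test_that("runs are deterministic under a fixed seed", {
  pm <- planted_matrix(n = 100)
  a <- nmf_run(pm$V, 3, seed = 7)
  b <- nmf_run(pm$V, 3, seed = 7)
  expect_identical(a$W, b$W)
  expect_identical(a$H, b$H)
  expect_error(nmf_run(matrix(0, 10, 4,
                              dimnames = list(NULL, paste0("m", 1:4))), 2),
               "all-zero")
})

test_that("rescaling W and H by a positive diagonal leaves WH invariant", {
  pm <- planted_matrix(n = 100)
  f <- nmf_run(pm$V, 3, seed = 1, max_iter = 500)
  d <- c(2, 0.5, 7)
  W2 <- sweep(f$W, 2, d, "*")
  H2 <- sweep(f$H, 1, d, "/")
  expect_equal(W2 %*% H2, f$W %*% f$H, tolerance = 1e-12)
  # downstream assignment is invariant under a global rescaling of W
  t1 <- suppressMessages(assign_profiles(f$W))
  t2 <- suppressMessages(assign_profiles(f$W * 13))
  expect_identical(t1$label, t2$label)
})

test_that("connectivity groups marks by their dominant profile", {
  H <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  colnames(H) <- paste0("m", 1:3)
  expect_equal(unname(connectivity(H)), diag(3))
  expect_equal(unname(connectivity(matrix(1, 2, 4))),
               matrix(1, 4, 4))
  H2 <- cbind(c(5, 1), c(4, 2), c(0, 9))  # marks 1,2 -> c1; mark 3 -> c2
  expect_equal(unname(connectivity(H2)),
               rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1)))
  expect_warning(connectivity(cbind(c(1, 0), c(0, 0))), "all-zero")
})

test_that("consensus and cophenetic behave at the stability extremes", {
  blockA <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0),
                  c(0, 0, 1, 1), c(0, 0, 1, 1))
  cc <- consensus_cophenetic(list(blockA, blockA, blockA))
  expect_equal(cc$consensus, blockA)
  expect_equal(cc$cophenetic, 1.0)
  expect_true(isSymmetric(cc$consensus))
  expect_equal(diag(cc$consensus), rep(1, 4))

  # identity + all-ones average to (I + 1)/2
  cc2 <- consensus_cophenetic(list(diag(4), matrix(1, 4, 4)))
  expect_equal(cc2$consensus, (diag(4) + 1) / 2)
  # constant off-diagonal distances -> degenerate, flagged stable
  expect_true(cc2$degenerate)
  expect_equal(cc2$cophenetic, 1.0)

  # random labelings over 13 marks are unstable
  coph_rand <- withr::with_seed(11L, {
    conns <- lapply(1:10, function(i) {
      cl <- sample.int(4, 13, replace = TRUE)
      outer(cl, cl, `==`) * 1L
    })
    consensus_cophenetic(conns)$cophenetic
  })
  expect_lt(coph_rand, 0.95)
})

test_that("multirun returns the minimum-RSS fit and sane consensus", {
  pm <- planted_matrix(n = 200)
  mr <- multirun(pm$V, 3, n_runs = 5, seed = 3, max_iter = 500)
  expect_equal(mr$best$rss, min(mr$fits$rss))
  expect_true(all(mr$stats$consensus >= 0 & mr$stats$consensus <= 1))
  expect_true(isSymmetric(mr$stats$consensus))
  expect_equal(unname(diag(mr$stats$consensus)), rep(1, ncol(pm$V)))

  # duplicate seeds give identical runs and a binary consensus
  mr2 <- multirun(pm$V, 3, n_runs = 2, seeds = c(5L, 5L), max_iter = 300)
  expect_true(all(mr2$stats$consensus %in% c(0, 1)))
  expect_equal(mr2$fits$rss[1], mr2$fits$rss[2])
})

test_that("column permutation preserves marginals and kills correlation", {
  pm <- planted_matrix(n = 2000, r = 2, k = 6)
  P <- permute_columns(pm$V, seed = 4L)
  expect_equal(apply(P$values, 2, sort), apply(pm$V, 2, sort))
  expect_identical(permute_columns(pm$V, seed = 4L)$values, P$values)
  offdiag <- function(M) M[upper.tri(M)]
  expect_gt(mean(abs(offdiag(stats::cor(pm$V)))), 0.3)
  expect_lt(mean(abs(offdiag(stats::cor(P$values)))), 0.05)
})

test_that("rank selection separates planted structure from the permuted null", {
  sim <- simulate_matrix(n_bins = 4000, seed = 21L)
  Vt <- sigmoid_transform(sim$matrix)
  rs <- select_rank(Vt, r_range = 3:8, n_runs = 10, random_repeats = 5,
                    sd_factor = 4, seed = 21L, max_iter = 2000,
                    tol = 1e-5, conn_stop = 40)
  expect_s3_class(rs, "rank_selection")
  expect_equal(nrow(rs$table), 6L)
  expect_true(all(c("cophenetic_real", "cophenetic_random_mean",
                    "cophenetic_random_sd", "rss_real") %in%
                    names(rs$table)))
  # planted data is decisively more stable than its column-permuted null
  # at (and beyond) the planted rank
  at7 <- rs$table$r == 7L
  expect_gt(rs$table$cophenetic_real[at7], 0.95)
  expect_gt(rs$table$cophenetic_real[at7],
            rs$table$cophenetic_random_mean[at7])
  # real RSS is far below the permuted-null RSS at the planted rank
  expect_lt(rs$table$rss_real[at7], rs$table$rss_random_mean[at7])
  # diagnostics carry the per-rank random draws
  expect_equal(length(rs$random[["7"]]), 5L)

  # weakening the threshold can only move the selected rank earlier
  rs0 <- select_rank(Vt, r_range = 3:8, n_runs = 10, random_repeats = 5,
                     sd_factor = 0, seed = 21L, max_iter = 2000,
                     tol = 1e-5, conn_stop = 40)
  r4 <- if (is.na(rs$r_star)) Inf else rs$r_star
  r0 <- if (is.na(rs0$r_star)) Inf else rs0$r_star
  expect_lte(r0, r4)
})

test_that("pure noise yields no selectable rank", {
  V <- withr::with_seed(31L, matrix(rexp(3000 * 8), 3000, 8,
                                    dimnames = list(NULL, paste0("m", 1:8))))
  rs <- select_rank(V, r_range = 3:5, n_runs = 6, random_repeats = 4,
                    sd_factor = 4, seed = 31L, max_iter = 500,
                    conn_stop = 40)
  expect_true(is.na(rs$r_star))
  expect_equal(nrow(rs$table), 3L)
})
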