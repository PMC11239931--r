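A_ref <- contrast_design(scaling_params(0.4, 0.8, 0.7),
                         regularity_stats(0.05, 0.2),
                         regularity_stats(0.20, 0.2))

test_that("exact rank-2 tensors are recovered to numerical zero", {
  ex <- exact_rank2_tensor(A_ref)
  fit <- parafac_fixed(ex$X, A_ref, seed = 3)
  expect_lt(fit$rss, 1e-8 * sum(ex$X^2))
  expect_true(fit$converged)
  expect_true(fit$monotone)
  expect_equal(fit$core_consistency, 100, tolerance = 1e-6)
  # C columns are unit-norm with positive dominant entry; reconstruction
  # matches up to the fixed-mode scale convention
  expect_equal(unname(sqrt(colSums(fit$C^2))), c(1, 1), tolerance = 1e-8)
  recon <- array(0, dim(ex$X))
  for (r in 1:2) recon <- recon + outer(A_ref[, r],
                                        outer(fit$B[, r], fit$C[, r]))
  expect_equal(recon, ex$X, tolerance = 1e-6)
})

test_that("with noise the residual matches the unabsorbed noise energy", {
  ex <- exact_rank2_tensor(A_ref)
  set.seed(8)
  E <- array(rnorm(length(ex$X), sd = 0.05), dim(ex$X))
  fit <- parafac_fixed(ex$X + E, A_ref, seed = 6)
  # free B and C absorb roughly dim(B)+dim(C) of the noise dof
  expect_gt(fit$rss, 0.45 * sum(E^2))
  expect_lt(fit$rss, 1.0 * sum(E^2))
  expect_gt(fit$core_consistency, 95)
})

test_that("degenerate inputs are rejected or reported", {
  ex <- exact_rank2_tensor(A_ref)
  expect_error(parafac_fixed(ex$X, matrix(c(1, 1, 1, 1), 2, 2)),
               "rank deficient")
  z <- array(0, c(2, 3, 10))
  fit0 <- parafac_fixed(z, A_ref, seed = 1)
  expect_equal(fit0$rss, 0)
  expect_true(is.na(fit0$core_consistency) || fit0$core_consistency == 100)
  bad <- ex$X
  bad[1] <- NA
  expect_error(parafac_fixed(bad, A_ref), "finite")
})

test_that("core consistency reacts to trilinear violations, not noise alone", {
  set.seed(3)
  B <- qr.Q(qr(matrix(rnorm(9), 3, 3)))[, 1:2]
  C <- qr.Q(qr(matrix(rnorm(120), 40, 3)))[, 1:2]
  build <- function(core) {
    X <- array(0, c(2, 3, 40))
    for (p in 1:2) for (q in 1:2) for (r in 1:2) {
      if (core[p, q, r] != 0) {
        X <- X + core[p, q, r] * outer(A_ref[, p], outer(B[, q], C[, r]))
      }
    }
    X
  }
  cc_at <- function(g) {
    core <- array(0, c(2, 2, 2))
    core[1, 1, 1] <- core[2, 2, 2] <- 1
    core[1, 2, 2] <- core[2, 1, 1] <- g
    parafac_fixed(build(core), A_ref, seed = 5)$core_consistency
  }
  ccs <- vapply(c(0, 0.3, 0.9), cc_at, numeric(1))
  expect_equal(ccs[1], 100, tolerance = 1e-6)
  expect_true(all(diff(ccs) < 0))          # monotone degradation
  expect_lt(ccs[3], 80)                    # strong interaction fails the bar

  # additive noise degrades consistency only gently and monotonically
  ex <- exact_rank2_tensor(A_ref)
  cc_noise <- vapply(c(0.05, 0.3, 1), function(sdn) {
    set.seed(8)
    E <- array(rnorm(length(ex$X), sd = sdn), dim(ex$X))
    parafac_fixed(ex$X + E, A_ref, seed = 6)$core_consistency
  }, numeric(1))
  expect_true(all(diff(cc_noise) < 0))
  expect_gt(cc_noise[3], 80)
})

test_that("core_consistency() recomputes the fit diagnostic", {
  ex <- exact_rank2_tensor(A_ref)
  fit <- parafac_fixed(ex$X, A_ref, seed = 3)
  expect_equal(core_consistency(fit, ex$X), fit$core_consistency,
               tolerance = 1e-9)
})

test_that("grid search covers the full factorial and degenerates to one fit", {
  g <- scaling_grid()
  expect_equal(length(g$s0) * length(g$s1) * length(g$s2), 9261L)

  ex <- exact_rank2_tensor(A_ref, n_tf = 30)
  g1 <- scaling_grid(s0 = 0.4, s1 = 0.8, s2 = 0.7)
  gr <- grid_search(ex$X, g1, seed = 4)
  expect_equal(nrow(gr$table), 1L)
  fit <- parafac_fixed(ex$X, A_ref, seed = 4)
  expect_equal(gr$table$rss, fit$rss, tolerance = 1e-9)
})

test_that("best-model selection honours the consistency threshold", {
  ex <- exact_rank2_tensor(A_ref, n_tf = 30)
  gr <- grid_search(ex$X, scaling_grid(s0 = c(0.2, 0.4), s1 = c(0.6, 0.8),
                                       s2 = c(0.5, 0.7)), seed = 4)
  b0 <- select_best(gr, threshold = 0)
  expect_false(b0$empty)
  expect_equal(b0$rss, min(gr$table$rss))
  b_hi <- select_best(gr, threshold = 100 + 1e-9)
  expect_true(b_hi$empty)
  expect_true(is.null(b_hi$params))
  # refit at the selected cell reproduces the recorded rss
  fit <- best_fit(b0, ex$X, gr)
  expect_equal(fit$rss, b0$rss, tolerance = 1e-6)
})
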