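test_that("contrast of identical groups is exactly zero", {
  set.seed(1)
  a <- array(rnorm(10 * 8 * 12), c(10, 8, 12))
  ct <- ersp_contrast(a, a)
  expect_equal(max(abs(ct$diff)), 0)
  expect_equal(max(abs(ct$tmap)), 0)
  res <- cluster_permutation(a, a, n_perm = 50, seed = 2)
  expect_false(any(res$mask))
  expect_equal(max(abs(res$masked_diff)), 0)
  expect_error(ersp_contrast(a[1, , , drop = FALSE], a), ">= 2 trials")
})

test_that("a uniform offset appears verbatim in the difference map", {
  set.seed(2)
  a <- array(rnorm(12 * 6 * 9), c(12, 6, 9))
  b <- a[c(1:12), , ] * 0 + array(rnorm(12 * 6 * 9), c(12, 6, 9))
  b2 <- b
  b2[, 3:4, 5:6] <- b2[, 3:4, 5:6] + 1
  ct <- ersp_contrast(b2, b)
  expect_equal(ct$diff[3:4, 5:6], matrix(1, 2, 2), tolerance = 1e-12)
})

test_that("4-connected labelling separates diagonal touches", {
  m <- matrix(FALSE, 4, 4)
  m[1, 1] <- m[2, 2] <- TRUE          # diagonal neighbours: two clusters
  lab <- hierpc:::.label_components_cpp(m)
  expect_equal(max(lab), 2L)
  m2 <- matrix(FALSE, 4, 4)
  m2[1, 1:3] <- TRUE; m2[2, 3] <- TRUE # L-shape: one cluster
  expect_equal(max(hierpc:::.label_components_cpp(m2)), 1L)
})

test_that("planted effects are detected where they were planted", {
  cfg <- small_config(trial_gain_sd = 0.1, noise_sd = 0.5,
                      n_trials_per_type = 48, component_scale = 40,
                      seed = 19)
  ds <- simulate_ersp_dataset(cfg)
  ks <- make_kernels(cfg$kernel_spec, cfg$freqs, cfg$times)
  dev <- ds$ersp[ds$labels == "xy|xx", 1, , ]
  std <- ds$ersp[ds$labels == "xx|xx", 1, , ]
  ct <- ersp_contrast(dev, std)
  support <- (ks$PE1 > 0.5 * max(ks$PE1)) | (ks$PE2 > 0.5 * max(ks$PE2))
  expect_true(support[arrayInd(which.max(ct$tmap), dim(ct$tmap))])

  res <- cluster_permutation(dev, std, n_perm = 200, seed = 20)
  expect_gte(sum(res$mask & support) / sum(support), 0.5)
  # sign preservation: swapping the groups flips the masked difference
  res_neg <- cluster_permutation(std, dev, n_perm = 200, seed = 20)
  expect_lt(min(res_neg$masked_diff), 0)
  expect_true(all(res_neg$clusters$sign[res_neg$clusters$p <= 0.05] == -1))
})

test_that("permutation p-values are reproducible and order-invariant", {
  set.seed(4)
  a <- array(rnorm(16 * 10 * 12), c(16, 10, 12)) + 0.8
  b <- array(rnorm(16 * 10 * 12), c(16, 10, 12))
  r1 <- cluster_permutation(a, b, n_perm = 100, seed = 5)
  r2 <- cluster_permutation(a, b, n_perm = 100, seed = 5)
  expect_identical(r1$clusters$p, r2$clusters$p)
  perm <- sample(16)
  r3 <- cluster_permutation(a[perm, , ], b, n_perm = 100, seed = 5)
  expect_identical(r1$clusters$mass, r3$clusters$mass)
  expect_warning(cluster_permutation(a, b, n_perm = 10, alpha = 0.05),
                 "resolution")
})

test_that("significant-IC selection finds exactly the loaded sources", {
  cfg <- small_config(n_ics = 6, n_loaded = 3, trial_gain_sd = 0.1,
                      noise_sd = 0.5, n_trials_per_type = 32,
                      component_scale = 40, seed = 23)
  ds <- simulate_ersp_dataset(cfg)
  sel <- select_significant_ics(ds, n_perm = 120, seed = 24)
  expect_equal(sel$significant, 1:3)
  # masked maps: zero outside clusters, sign kept inside
  resp <- sel$responses[[1]]$c1
  expect_true(all(resp$masked_diff[!resp$mask] == 0))
  expect_gt(max(resp$masked_diff), 0)
})

test_that("the deviant tensor stacks masked contrasts frequency-major", {
  cfg <- small_config(n_ics = 4, n_loaded = 2, trial_gain_sd = 0,
                      noise_sd = 0, n_trials_per_type = 4, seed = 3)
  ds <- simulate_ersp_dataset(cfg)
  tensor <- build_deviant_tensor(ds, ics = 1:2)
  expect_equal(dim(tensor), c(2L, 2L, length(cfg$freqs) * length(cfg$times)))
  expect_equal(attr(tensor, "tf_order"), "frequency-major")
  # entry (c1, ic1, bin) equals the difference of mean maps at that bin
  m1 <- colMeans(ds$ersp[ds$labels == "xy|xx", 1, , , drop = FALSE][, 1, , ])
  m0 <- colMeans(ds$ersp[ds$labels == "xx|xx", 1, , , drop = FALSE][, 1, , ])
  expect_equal(tensor[1, 1, ], as.vector(m1 - m0), tolerance = 1e-12)
  expect_error(build_deviant_tensor(ds, ics = integer()), "no ICs")
})
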