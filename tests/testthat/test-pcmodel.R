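stats_xx <- regularity_stats(0.05, 0.2)
stats_xy <- regularity_stats(0.20, 0.2)

test_that("stream state reproduces hand-enumerated reference values", {
  p <- scaling_params(0.4, 0.85, 0.75)
  st <- trial_state(p, stats_xx, "xx|xx")
  expect_equal(unname(st$e1), c(0.077, -0.0425), tolerance = 1e-12)
  expect_equal(pe_values(st)[["PE1"]], 0.1195, tolerance = 1e-12)

  st2 <- trial_state(p, stats_xy, "xy|xy")
  expect_equal(unname(st2$e2), c(-0.128, 0.3575), tolerance = 1e-12)
  expect_equal(pe_values(st2)[["PE2"]], 0.4855, tolerance = 1e-12)
})

test_that("limiting parameter values behave as the model dictates", {
  # no first-level prediction: the deviant tone arrives unreduced
  st <- trial_state(scaling_params(1, 0, 0.5), stats_xx, "xy|xx")
  expect_equal(unname(st$P1), c(0, 0))
  expect_equal(st$e1[["x"]], 0)
  expect_equal(st$e1[["y"]], 1)

  # no second-level prediction: e2 equals e1 for every trial type
  for (tt in c("xx|xx", "xy|xx", "xy|xy", "xx|xy")) {
    stats <- if (endsWith(tt, "xx")) stats_xx else stats_xy
    st <- trial_state(scaling_params(0.6, 1.3, 0), stats, tt)
    expect_equal(st$e2, st$e1)
  }

  # unit input with no predictions: both sequences carry identical
  # unpredicted magnitude, so the contrasts cancel
  A <- contrast_design(scaling_params(1, 0, 0), stats_xx, stats_xy)
  expect_equal(unname(A), matrix(0, 2, 2))

  # with s2 = 0 the PE2 column duplicates PE1
  A0 <- contrast_design(scaling_params(0.5, 0.9, 0), stats_xx, stats_xy)
  expect_equal(A0[, "PE1"], A0[, "PE2"])

  expect_error(trial_state(scaling_params(0.5, 1, 1), stats_xx, "zz|xx"),
               "unknown trial type")
  expect_error(scaling_params(1.2, 1, 1), "s0")
  expect_error(scaling_params(0.5, 2.5, 1), "s1")
})

test_that("contrast design matches the frozen reference matrix", {
  A <- contrast_design(scaling_params(0.4, 0.85, 0.75), stats_xx, stats_xy)
  expect_equal(unname(A),
               rbind(c(1.1610, 0.92025), c(0.8040, -0.42900)),
               tolerance = 1e-10)
})

test_that("contrast design agrees with the brute-force enumerator", {
  set.seed(42)
  for (adapted in c(TRUE, FALSE)) {
    for (i in 1:100) {
      s0 <- runif(1); s1 <- runif(1, 0, 2); s2 <- runif(1, 0, 2)
      A <- contrast_design(scaling_params(s0, s1, s2), stats_xx, stats_xy,
                           adapt_before_predict = adapted)
      expect_equal(unname(A),
                   unname(brute_force_contrast(s0, s1, s2,
                                               adapted = adapted)),
                   tolerance = 1e-12)
    }
  }
})

test_that("vectorized grid evaluation equals the scalar contrast design", {
  set.seed(9)
  s0 <- runif(60); s1 <- runif(60, 0, 2); s2 <- runif(60, 0, 2)
  for (adapted in c(TRUE, FALSE)) {
    Av <- hierpc:::.contrast_grid_matrices(s0, s1, s2, stats_xx, stats_xy,
                                           adapted)
    for (i in seq_along(s0)) {
      expect_equal(Av[, , i],
                   unname(contrast_design(scaling_params(s0[i], s1[i], s2[i]),
                                          stats_xx, stats_xy, adapted)),
                   tolerance = 1e-14)
    }
  }
})

test_that("signed contrast structure matches the expected physiology", {
  # near-optimal predictions: full violation evokes the larger local PE
  A <- contrast_design(scaling_params(0.4, 0.85, 0.75), stats_xx, stats_xy)
  expect_gt(A[1, "PE1"], A[2, "PE1"])
  expect_gt(A[2, "PE1"], 0)
  # hyper global prediction turns the global-standard contrast negative
  Ah <- contrast_design(scaling_params(0.95, 1.0, 1.7), stats_xx, stats_xy)
  expect_lt(Ah[2, "PE2"], 0)
})

test_that("per-trial-type PE table covers all four types non-negatively", {
  tab <- pe_table(scaling_params(0.4, 0.8, 0.7), stats_xx, stats_xy)
  expect_setequal(tab$trial_type, c("xx|xx", "xy|xx", "xy|xy", "xx|xy"))
  expect_true(all(tab$PE1 >= 0) && all(tab$PE2 >= 0))
})
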