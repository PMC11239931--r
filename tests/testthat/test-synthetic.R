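test_that("kernels are unit-energy bumps at their nominal coordinates", {
  spec <- synthetic_config()$kernel_spec
  ks <- make_kernels(spec)
  g <- standard_grid()
  idx <- arrayInd(which.max(ks$PE1), dim(ks$PE1))
  expect_equal(g$freqs[idx[1]], 95)
  expect_equal(g$times[idx[2]], 0.865, tolerance = 1 / 300)
  expect_equal(sum(ks$PE1^2), 1, tolerance = 1e-12)
  expect_equal(sum(ks$PE2^2), 1, tolerance = 1e-12)

  bad <- spec
  bad$PE1$sd_ms <- 0
  expect_error(make_kernels(bad), "widths must be positive")
  far <- spec
  far$PE1$freq_hz <- 500
  expect_error(make_kernels(far), "outside the analysis grid")
})

test_that("noise-free simulation reproduces the planted component sum", {
  cfg <- small_config(trial_gain_sd = 0, noise_sd = 0,
                      n_trials_per_type = 2)
  ds <- simulate_ersp_dataset(cfg)
  ks <- make_kernels(cfg$kernel_spec, cfg$freqs, cfg$times)
  m <- hierpc:::.type_amplitudes(cfg)
  for (tt in c("xx|xx", "xy|xx")) {
    j <- which(ds$labels == tt)[1]
    for (ic in c(1L, 5L)) {
      expected <- cfg$component_scale *
        (m[tt, 1] * cfg$ic_loadings[ic, 1] * ks$PE1 +
         m[tt, 2] * cfg$ic_loadings[ic, 2] * ks$PE2)
      got <- ds$ersp[j, ic, , ]
      expect_equal(got, unname(expected), tolerance = 1e-12)
    }
  }
})

test_that("simulation is reproducible and validates its inputs", {
  d1 <- simulate_ersp_dataset(small_config(seed = 5))
  d2 <- simulate_ersp_dataset(small_config(seed = 5))
  expect_identical(d1$ersp, d2$ersp)
  expect_error(small_config(n_trials_per_type = 0), "positive")
  expect_error(small_config(trial_gain_sd = -0.1), ">= 0")
  expect_error(small_config(n_loaded = 20), "n_loaded")
})

test_that("mean type-contrasts unmix into the model contrast columns", {
  cfg <- small_config(trial_gain_sd = 0.05, noise_sd = 0.2,
                      n_trials_per_type = 128, seed = 13)
  ds <- simulate_ersp_dataset(cfg)
  ks <- make_kernels(cfg$kernel_spec, cfg$freqs, cfg$times)
  A <- contrast_design(cfg$true_params, cfg$stats_xx, cfg$stats_xy)
  mean_map <- function(tt, ic) {
    sel <- ds$labels == tt
    colMeans(ds$ersp[sel, ic, , , drop = FALSE][, 1, , ])
  }
  for (ic in 1:2) {
    for (ci in 1:2) {
      dev <- if (ci == 1) "xy|xx" else "xy|xy"
      std <- if (ci == 1) "xx|xx" else "xx|xy"
      contrast <- mean_map(dev, ic) - mean_map(std, ic)
      # least-squares unmixing onto the two planted kernels
      co <- coef(lm(as.vector(contrast) ~ 0 + as.vector(ks$PE1) +
                      as.vector(ks$PE2)))
      expected <- cfg$component_scale * A[ci, ] * cfg$ic_loadings[ic, ]
      expect_equal(unname(co), unname(expected), tolerance = 0.1)
    }
  }
})

test_that("trial gains have unit mean and the requested spread", {
  cfg <- small_config(trial_gain_sd = 0.4, n_trials_per_type = 500, seed = 3)
  g <- simulate_ersp_dataset(cfg)$ground_truth$gains
  expect_true(all(g > 0))
  expect_equal(mean(g), 1, tolerance = 0.05)
  expect_equal(sd(g), 0.4, tolerance = 0.05)
})

test_that("simulated time series carry recoverable spectro-temporal bursts", {
  g <- standard_grid()
  cfg <- synthetic_config(n_ics = 3, n_loaded = 3, n_trials_per_type = 4,
                          trial_gain_sd = 0, seed = 11)
  ts <- simulate_timeseries(cfg, burst_amplitude = 6)
  js <- which(ts$labels == "xy|xx")
  em <- Reduce(`+`, lapply(js, function(j) {
    unclass(ersp_trial(ts$signals[j, 1, ]))
  })) / length(js)
  sub <- em[60:130, ]
  idx <- arrayInd(which.max(sub), dim(sub))
  peak_f <- (60:130)[idx[1]]
  peak_t <- (g$times[idx[2]] - 0.8) * 1000
  # contract: within the kernel widths (15 Hz, 30 ms); the 7-cycle Morlet
  # SNR tilt shifts high-frequency peaks down by ~2 Hz
  expect_lt(abs(peak_f - 95), 5)
  expect_lt(abs(peak_t - 65), 10)

  # noise-only trials: trial-averaged power shows no post-onset deviation
  silent <- synthetic_config(n_ics = 2, n_loaded = 2, n_trials_per_type = 12,
                             trial_gain_sd = 0, seed = 12)
  ts0 <- simulate_timeseries(silent, burst_amplitude = 0)
  p0 <- Reduce(`+`, lapply(seq_len(dim(ts0$signals)[1]), function(j) {
    unclass(morlet_tfr(ts0$signals[j, 1, ]))
  })) / dim(ts0$signals)[1]
  e0 <- baseline_db(structure(p0, class = "trial_tfr", freqs = 1:150,
                              times = g$times))
  central <- g$times > 0.3 & g$times < 1.3
  expect_lt(abs(mean(e0[40:140, central])), 1)

  # doubling the burst amplitude adds ~6 dB at the peak
  ts2 <- simulate_timeseries(cfg, burst_amplitude = 12)
  e1 <- ersp_trial(ts$signals[js[1], 1, ])
  e2 <- ersp_trial(ts2$signals[js[1], 1, ])
  pk <- which.max(e1)
  expect_equal(e2[pk] - e1[pk], 20 * log10(2), tolerance = 1)
})
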