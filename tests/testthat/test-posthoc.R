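test_that("joint topography normalizes and averages spatial maps", {
  m1 <- c(0.5, -1, 0.25, 0)
  expect_equal(joint_topography(m1), abs(m1) / 1)
  two <- rbind(m1, m1)
  expect_equal(joint_topography(two), abs(m1))
  m2 <- c(2, 1, 0, 1)
  expect_equal(joint_topography(rbind(m1, m2)),
               (abs(m1) / 1 + m2 / 2) / 2)
  expect_error(joint_topography(rbind(m1, rep(0, 4))), "all-zero")
})

test_that("region fractions are proportional masses summing with the rest to 1", {
  labels <- c(rep("pTC", 24), rep("aTC", 24), rep("aPFC", 16),
              rep("other", 32))
  map <- rep(1, 96)
  fr <- region_contribution(map, labels)
  expect_equal(fr[["pTC"]], 0.25)
  expect_equal(sum(fr) + sum(map[labels == "other"]) / sum(map), 1)
  conc <- ifelse(labels == "pTC", 1, 0)
  expect_equal(region_contribution(conc, labels)[["pTC"]], 1)
  expect_error(region_contribution(map[1:10], labels), "lengths differ")
})

test_that("peak latency uses the post-onset frequency-mean with early ties", {
  times <- seq(0.75, 1.0, by = 0.001)
  map <- matrix(0, 5, length(times))
  map[3, which(times == 0.867)] <- 1
  expect_equal(peak_latency(map, times), 67)
  map2 <- matrix(0, 5, length(times))
  map2[2, which(times == 0.850)] <- 1
  map2[4, which(times == 0.890)] <- 1
  expect_equal(peak_latency(map2, times), 50)
  expect_true(is.na(peak_latency(matrix(1, 5, length(times)), times)))
})

test_that("mean frequency is the amplitude-weighted spectral centroid", {
  freqs <- 1:150
  map <- matrix(0, 150, 10)
  map[92, ] <- 1
  expect_equal(mean_frequency(map, freqs), 92)
  expect_equal(mean_frequency(matrix(1, 150, 10), freqs), 75.5)
  expect_true(is.na(mean_frequency(matrix(0, 150, 10), freqs)))
})

test_that("component brain maps weight normalized topographies by loadings", {
  maps <- rbind(c(1, 2, 0), c(0, 4, 4))
  B <- rbind(c(1, 0), c(0, 0.5))
  out <- component_brain_map(maps, B)
  expect_equal(out[1, ], c(0.5, 1, 0))
  expect_equal(out[2, ], 0.5 * c(0, 1, 1))
  expect_equal(component_brain_map(maps, matrix(0, 2, 2))[1, ], c(0, 0, 0))
  expect_error(component_brain_map(maps, matrix(1, 3, 2)), "IC count")
})

test_that("high-gamma mask keeps the top quantile of high frequencies", {
  freqs <- seq(10, 150, by = 10)
  set.seed(6)
  map <- matrix(runif(15 * 40), 15, 40)
  FT <- st_mask(map, freqs = freqs)
  hg <- freqs > 40
  cover <- sum(attr(FT, "mask")[hg, ]) / sum(hg * 40)
  expect_equal(cover, 0.75, tolerance = 0.01)
  expect_true(all(FT[!hg, ] == 0))
  expect_true(all(FT[attr(FT, "mask")] > 0))
  # binary variant
  FTb <- st_mask(map, freqs = freqs, weighted = FALSE)
  expect_setequal(unique(as.vector(FTb)), c(0, 1))
  # no high-gamma energy: empty mask
  low <- matrix(0, 15, 40)
  low[freqs <= 40, ] <- runif(sum(freqs <= 40) * 40)
  expect_equal(sum(attr(st_mask(low, freqs = freqs), "mask")), 0)
  expect_error(st_mask(matrix(1, 15, 40), freqs = freqs), "constant")
  expect_error(st_mask(map, freqs = freqs / 100), "above")
})

test_that("projection is the counting bilinear form", {
  FT <- matrix(0, 4, 5)
  FT[2:3, 2:4] <- 1                       # 6 active bins
  ersp <- array(1, c(2, 4, 5))
  expect_equal(project_trial(c(1, 1), ersp, FT), 2 * 6)
  expect_equal(project_trial(c(1, 1), 3 * ersp, FT), 3 * 12)
  # invariant to a consistent IC permutation
  set.seed(7)
  ersp2 <- array(rnorm(3 * 4 * 5), c(3, 4, 5))
  S <- c(0.2, -1, 0.5)
  perm <- c(3, 1, 2)
  expect_equal(project_trial(S, ersp2, FT),
               project_trial(S[perm], ersp2[perm, , ], FT))
  expect_error(project_trial(c(1, 1), ersp2, FT), "dimension mismatch")
})

test_that("variability statistics follow the worked arithmetic", {
  records <- data.frame(
    trial_index = 1:6,
    trial_type = rep(c("xx|xx", "xy|xx"), each = 3),
    component = "PE1",
    value = c(0.9, 1.0, 1.1, 2.7, 3.0, 3.3))
  vs <- variability_stats(records)
  pe1 <- vs$by_component[vs$by_component$component == "PE1", ]
  expect_equal(pe1$mean, 2)
  expect_equal(pe1$sd, 0.2)
  expect_equal(pe1$cv, 0.1)
  expect_equal(vs$sv, 0.2)
  const <- within(records, value <- 5)
  vc <- variability_stats(const)
  expect_equal(vc$by_component$sd, 0)
  expect_equal(vc$by_component$cv, 0)
  expect_error(variability_stats(records[c(1, 4:6), ]), ">= 2 trials")
})

test_that("rank tests apply Bonferroni over the pairwise family", {
  set.seed(8)
  vals <- c(rnorm(10), rnorm(10) + 5)
  grp <- rep(c("a", "b"), each = 10)
  out <- group_compare(vals, grp)
  expect_true(out$significant)
  same <- group_compare(rep(1, 20), grp)
  expect_equal(same$p, 1)
  expect_false(same$significant)
  # five groups: 10 pairs, correction multiplies p by 10 (capped at 1)
  set.seed(9)
  vals5 <- rnorm(50)
  grp5 <- rep(letters[1:5], each = 10)
  out5 <- group_compare(vals5, grp5)
  expect_equal(nrow(out5), 10L)
  expect_equal(out5$p_adj, pmin(1, out5$p * 10))
  # paired signed-rank detects a consistent shift
  x <- rnorm(15)
  paired <- group_compare(c(x, x + 2), rep(c("pre", "post"), each = 15),
                          paired = TRUE)
  expect_true(paired$significant)
  expect_error(group_compare(c(x, 1), c(rep("a", 15), "b")), ">= 2")
})

test_that("sensitivity sweep yields one row per threshold", {
  cfg <- small_config(n_ics = 3, n_loaded = 3, trial_gain_sd = 0.1,
                      noise_sd = 0.3, n_trials_per_type = 32, seed = 31)
  ds <- simulate_ersp_dataset(cfg)
  tensor <- build_deviant_tensor(ds, ics = 1:3)
  gr <- grid_search(tensor, scaling_grid(s0 = seq(0.2, 0.6, 0.1),
                                         s1 = seq(0.6, 1.0, 0.1),
                                         s2 = seq(0.5, 0.9, 0.1)),
                    seed = 32)
  sw <- sensitivity_sweep(gr, tensor, ds, 1:3, thresholds = 40:100)
  expect_equal(nrow(sw), 61L)
  expect_equal(sw$threshold, 40:100)
  one <- sensitivity_sweep(gr, tensor, ds, 1:3, thresholds = 80)
  expect_equal(nrow(one), 1L)
  # thresholds above every cell's consistency give NA rows
  top <- sensitivity_sweep(gr, tensor, ds, 1:3, thresholds = 100)
  expect_true(is.na(top$s0) || top$core_consistency > 100)
  # below the true model's consistency the selected cell is stable
  ok <- sw[!is.na(sw$s0) & sw$threshold <= 95, ]
  expect_equal(length(unique(paste(ok$s0, ok$s1, ok$s2))), 1L)
})
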