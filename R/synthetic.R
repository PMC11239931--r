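#' Configuration for synthetic local-global ERSP datasets
#'
#' Describes a ground-truth-known dataset: per-trial dB time-frequency maps
#' for a set of independent components (ICs), built from two planted
#' spectro-temporal kernels (the local PE1 and global PE2 prediction-error
#' components) whose per-trial-type amplitudes follow the hierarchical
#' predictive-coding model under `true_params`, multiplied by per-trial
#' log-normal gains (mean 1) and embedded in white dB noise. The baseline
#' period carries noise only.
#'
#' Defaults emulate an unexposed-animal recording: 96 electrodes with
#' posterior-temporal / anterior-temporal / anterior-prefrontal region
#' labels, 10 ICs of which 3 carry signal, PE1 peaking earlier and
#' posterior, PE2 later and anterior.
#'
#' @param n_electrodes Electrode count (default 96).
#' @param n_ics Number of independent components (default 10).
#' @param n_loaded Number of signal-carrying ICs (default 3).
#' @param true_params [scaling_params()] generating the planted component
#'   amplitudes (default `(0.4, 0.8, 0.7)`, an on-grid unexposed-like
#'   optimum).
#' @param kernel_spec List of two lists (`PE1`, `PE2`) with fields
#'   `latency_ms` (center, ms after fifth-tone onset), `freq_hz` (center),
#'   `sd_ms`, `sd_hz` (Gaussian widths). Defaults: PE1 at 65 ms / 95 Hz,
#'   PE2 at 100 ms / 90 Hz.
#' @param trial_gain_sd SD of the per-trial multiplicative gain (natural
#'   scale, mean 1; default 0.3).
#' @param noise_sd White-noise SD in dB per bin (default 1).
#' @param component_scale Peak response scale in dB per unit model PE
#'   (default 20), applied through the unit-energy kernels.
#' @param n_trials_per_type Trials per trial type (default 64).
#' @param freqs,times Analysis grid; defaults to the standard 150 x 600
#'   grid. Reduced grids are accepted for desk-scale studies.
#' @param stats_xx,stats_xy Regularity statistics per block context.
#' @param adapt_before_predict Model convention used to plant the
#'   component amplitudes (see [trial_state()]).
#' @param seed Integer seed.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_electrodes = 96L,
                             n_ics = 10L,
                             n_loaded = 3L,
                             true_params = scaling_params(0.4, 0.8, 0.7),
                             kernel_spec = list(
                               PE1 = list(latency_ms = 65, freq_hz = 95,
                                          sd_ms = 30, sd_hz = 15),
                               PE2 = list(latency_ms = 100, freq_hz = 90,
                                          sd_ms = 40, sd_hz = 15)),
                             trial_gain_sd = 0.3,
                             noise_sd = 1,
                             component_scale = 20,
                             n_trials_per_type = 64L,
                             freqs = NULL, times = NULL,
                             stats_xx = default_stats()$xx,
                             stats_xy = default_stats()$xy,
                             adapt_before_predict = TRUE,
                             seed = 1L) {
  if (is.null(freqs)) freqs <- standard_grid()$freqs
  if (is.null(times)) times <- standard_grid()$times
  if (n_trials_per_type < 1) {
    stop("synthetic_config: n_trials_per_type must be positive")
  }
  if (trial_gain_sd < 0) stop("synthetic_config: trial_gain_sd must be >= 0")
  if (n_loaded > n_ics) stop("synthetic_config: n_loaded cannot exceed n_ics")
  stopifnot(inherits(true_params, "scaling_params"))
  cfg <- list(
    n_electrodes = as.integer(n_electrodes),
    n_ics = as.integer(n_ics),
    n_loaded = as.integer(n_loaded),
    true_params = true_params,
    kernel_spec = kernel_spec,
    trial_gain_sd = trial_gain_sd,
    noise_sd = noise_sd,
    component_scale = component_scale,
    n_trials_per_type = as.integer(n_trials_per_type),
    freqs = freqs, times = times,
    stats_xx = stats_xx, stats_xy = stats_xy,
    adapt_before_predict = adapt_before_predict,
    seed = as.integer(seed)
  )
  cfg$region_labels <- default_region_labels(cfg$n_electrodes)
  cfg$spatial_maps <- .default_spatial_maps(cfg)
  cfg$ic_loadings <- .default_ic_loadings(cfg)
  structure(cfg, class = "synthetic_config")
}

#' Default electrode region labels
#'
#' A fixed assignment over the electrode index: the first quarter posterior
#' temporal (pTC), the next quarter anterior temporal (aTC), the next
#' sixth anterior prefrontal (aPFC), the remainder unlabelled cortex.
#'
#' @param n_electrodes Electrode count.
#' @return Character vector of labels in `{pTC, aTC, aPFC, other}`.
#' @export
default_region_labels <- function(n_electrodes = 96L) {
  n1 <- ceiling(n_electrodes / 4)
  n2 <- ceiling(n_electrodes / 4)
  n3 <- ceiling(n_electrodes / 6)
  rep(c("pTC", "aTC", "aPFC", "other"),
      c(n1, n2, n3, n_electrodes - n1 - n2 - n3))
}

# smooth unimodal spatial maps: loaded ICs from posterior to anterior,
# nuisance ICs spread over the remaining electrodes
.default_spatial_maps <- function(cfg) {
  centers <- round(seq(cfg$n_electrodes * 0.1, cfg$n_electrodes * 0.9,
                       length.out = cfg$n_ics))
  # loaded ICs: first on pTC, last on aPFC
  region_centers <- round(stats::quantile(seq_len(cfg$n_electrodes),
                                          c(0.12, 0.38, 0.6)))
  centers[seq_len(cfg$n_loaded)] <-
    region_centers[pmin(seq_len(cfg$n_loaded), 3)]
  e <- seq_len(cfg$n_electrodes)
  maps <- t(vapply(centers, function(ct) {
    exp(-(e - ct)^2 / (2 * (cfg$n_electrodes / 14)^2))
  }, numeric(cfg$n_electrodes)))
  rownames(maps) <- paste0("IC", seq_len(cfg$n_ics))
  maps
}

# nonnegative per-IC weights of the two components: PE1 posterior-loaded,
# PE2 anterior-loaded, overlapping on the middle loaded IC
.default_ic_loadings <- function(cfg) {
  w <- matrix(0, cfg$n_ics, 2, dimnames = list(
    paste0("IC", seq_len(cfg$n_ics)), c("PE1", "PE2")))
  idx <- seq_len(cfg$n_loaded)
  w[idx, 1] <- rev(seq_along(idx)) / length(idx)   # PE1: posterior heavy
  w[idx, 2] <- seq_along(idx) / length(idx)        # PE2: anterior heavy
  w
}

#' Planted spectro-temporal kernels
#'
#' Separable Gaussian bumps on the analysis grid, one per prediction-error
#' component, normalized to unit energy (`sum(K^2) = 1`) and zeroed before
#' first-tone onset so the baseline stays signal-free.
#'
#' @param kernel_spec As in [synthetic_config()].
#' @param freqs,times Analysis grid.
#' @param fifth_tone_onset_s Fifth-tone onset relative to first-tone onset
#'   (default 0.8 s: 50 ms tones, 150 ms inter-tone intervals).
#' @return Named list of `freq x time` matrices (`PE1`, `PE2`).
#' @export
make_kernels <- function(kernel_spec, freqs = NULL, times = NULL,
                         fifth_tone_onset_s = 0.8) {
  g <- standard_grid()
  if (is.null(freqs)) freqs <- g$freqs
  if (is.null(times)) times <- g$times
  lapply(kernel_spec, function(ks) {
    if (ks$sd_ms <= 0 || ks$sd_hz <= 0) {
      stop("make_kernels: kernel widths must be positive")
    }
    t0 <- fifth_tone_onset_s + ks$latency_ms / 1000
    if (t0 < min(times) || t0 > max(times) ||
        ks$freq_hz < min(freqs) || ks$freq_hz > max(freqs)) {
      stop("make_kernels: kernel centered outside the analysis grid")
    }
    kf <- exp(-(freqs - ks$freq_hz)^2 / (2 * ks$sd_hz^2))
    kt <- exp(-(times - t0)^2 / (2 * (ks$sd_ms / 1000)^2))
    kt[times < 0] <- 0
    K <- outer(kf, kt)
    K / sqrt(sum(K^2))
  })
}

# model PE amplitudes per trial type under the config's true parameters
.type_amplitudes <- function(cfg) {
  tab <- pe_table(cfg$true_params, cfg$stats_xx, cfg$stats_xy,
                  cfg$adapt_before_predict)
  m <- as.matrix(tab[, c("PE1", "PE2")])
  rownames(m) <- tab$trial_type
  m
}

#' Simulate a per-trial ERSP dataset with known ground truth
#'
#' For trial `j` of type `tau`:
#' `ERSP_j(ic, f, t) = sum_k g_jk * m_k(tau) * w_k(ic) * scale * K_k(f, t) + eps`,
#' where `m_k(tau)` is the model PE value of the type, `g_jk` a log-normal
#' gain with mean 1 and SD `trial_gain_sd`, `w_k` the per-IC loading,
#' `K_k` the unit-energy kernel and `eps` white dB noise. The baseline
#' period (t < 0) carries noise only.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `"lg_dataset"`: `ersp` (array
#'   `trial x ic x freq x time`), `labels` (trial types), `spatial_maps`,
#'   `region_labels`, `freqs`, `times`, and `ground_truth` (true
#'   parameters, kernels, loadings, gains, amplitudes).
#' @export
simulate_ersp_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  kernels <- make_kernels(config$kernel_spec, config$freqs, config$times)
  m <- .type_amplitudes(config)
  types <- rownames(m)
  n_per <- config$n_trials_per_type
  labels <- rep(types, each = n_per)
  n_trial <- length(labels)
  nf <- length(config$freqs)
  nt <- length(config$times)
  sd_log <- sqrt(log(1 + config$trial_gain_sd^2))
  gains <- matrix(rlnorm(n_trial * 2, meanlog = -sd_log^2 / 2,
                         sdlog = sd_log), n_trial, 2)
  ersp <- array(rnorm(n_trial * config$n_ics * nf * nt,
                      sd = config$noise_sd),
                c(n_trial, config$n_ics, nf, nt))
  w <- config$ic_loadings
  for (k in 1:2) {
    Kk <- kernels[[k]] * config$component_scale
    amp <- gains[, k] * m[labels, k]             # n_trial
    loaded <- which(w[, k] > 0)
    for (ic in loaded) {
      # outer product trial-amplitude x kernel, added in one sweep
      add <- outer(amp * w[ic, k], Kk)
      ersp[, ic, , ] <- ersp[, ic, , ] + add
    }
  }
  structure(list(
    ersp = ersp,
    labels = labels,
    spatial_maps = config$spatial_maps,
    region_labels = config$region_labels,
    freqs = config$freqs,
    times = config$times,
    ground_truth = list(
      true_params = config$true_params,
      kernels = kernels,
      ic_loadings = w,
      gains = gains,
      type_amplitudes = m
    ),
    config = config
  ), class = "lg_dataset")
}

#' Simulate raw per-trial source time series
#'
#' Amplitude-modulated narrow-band bursts (one per planted component:
#' Gaussian envelope at the kernel's latency, carrier at its center
#' frequency) on top of white noise, sampled at 300 Hz over the standard
#' epoch. The Morlet ERSP of these series approximates the target ERSP
#' qualitatively (peak within the kernel widths).
#'
#' @param config A [synthetic_config()] (full standard grid recommended).
#' @param burst_amplitude Carrier amplitude per unit model PE (default 2;
#'   the baseline white noise has SD 1).
#' @return List of class `"lg_timeseries"`: `signals` (array
#'   `trial x ic x sample`), `labels`, `sfreq`, `times`.
#' @export
simulate_timeseries <- function(config, burst_amplitude = 2) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  g <- standard_grid()
  times <- g$times
  m <- .type_amplitudes(config)
  types <- rownames(m)
  labels <- rep(types, each = config$n_trials_per_type)
  n_trial <- length(labels)
  n_samp <- length(times)
  sd_log <- sqrt(log(1 + config$trial_gain_sd^2))
  gains <- matrix(rlnorm(n_trial * 2, meanlog = -sd_log^2 / 2,
                         sdlog = sd_log), n_trial, 2)
  w <- config$ic_loadings
  sig <- array(rnorm(n_trial * config$n_ics * n_samp),
               c(n_trial, config$n_ics, n_samp))
  for (k in 1:2) {
    ks <- config$kernel_spec[[k]]
    t0 <- 0.8 + ks$latency_ms / 1000
    env <- exp(-(times - t0)^2 / (2 * (ks$sd_ms / 1000)^2))
    carrier <- cos(2 * pi * ks$freq_hz * (times - t0))
    burst <- env * carrier
    amp <- burst_amplitude * gains[, k] * m[labels, k]
    for (ic in which(w[, k] > 0)) {
      sig[, ic, ] <- sig[, ic, ] + outer(amp * w[ic, k], burst)
    }
  }
  structure(list(signals = sig, labels = labels, sfreq = 300,
                 times = times, ground_truth = list(gains = gains)),
            class = "lg_timeseries")
}
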