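#' Standard ERSP analysis grid
#'
#' The canonical epoch runs from 0.3 s before the first tone to 0.9 s after
#' the fifth tone at 300 Hz sampling (600 time bins), analysed at 150
#' center frequencies (1-150 Hz in 1-Hz steps).
#'
#' @return List with `freqs` (Hz) and `times` (s, relative to first-tone
#'   onset).
#' @export
standard_grid <- function() {
  list(freqs = 1:150, times = -0.3 + (0:599) / 300)
}

#' Morlet wavelet time-frequency power
#'
#' Convolves the signal with complex Morlet wavelets (width 7 cycles,
#' unit-energy normalized) at each center frequency and returns squared
#' magnitude. Convolution is computed by FFT with zero-padding; bins whose
#' wavelet support extends beyond the epoch are retained and flagged in
#' the `edge_half_len` attribute rather than masked.
#'
#' @param x Numeric vector, the sampled source signal.
#' @param sfreq Sampling rate in Hz (default 300).
#' @param freqs Center frequencies in Hz (default 1-150).
#' @param times Time axis of `x` in s; defaults to the standard epoch when
#'   `x` has 600 samples.
#' @param n_cycles Morlet width in cycles (default 7).
#' @return A `freq x time` matrix of class `"trial_tfr"` with attributes
#'   `freqs`, `times`, and `edge_half_len` (per-frequency wavelet
#'   half-length in samples: bins closer than this to either epoch edge
#'   have truncated wavelet support).
#' @examples
#' g <- standard_grid()
#' p <- morlet_tfr(sin(2 * pi * 40 * g$times), times = g$times)
#' @export
morlet_tfr <- function(x, sfreq = 300, freqs = 1:150, times = NULL,
                       n_cycles = 7) {
  if (!is.numeric(x) || anyNA(x)) stop("morlet_tfr: signal must be numeric")
  n <- length(x)
  if (is.null(times)) {
    if (n == 600L && sfreq == 300) {
      times <- standard_grid()$times
    } else {
      times <- (seq_len(n) - 1) / sfreq
    }
  }
  if (length(times) != n) {
    stop("morlet_tfr: times must match the signal length (", n, " samples)")
  }
  # half-length of each wavelet in samples; the coarsest (1 Hz) wavelet
  # spans n_cycles/freq seconds
  half_len <- ceiling(n_cycles / (2 * freqs) * sfreq)
  nfft <- stats::nextn(n + 2 * max(half_len), 2)
  xf <- stats::fft(c(x, numeric(nfft - n)))
  power <- matrix(NA_real_, length(freqs), n)
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    h <- half_len[i]
    t_w <- (-h:h) / sfreq
    sigma_t <- n_cycles / (2 * pi * f)
    w <- exp(2i * pi * f * t_w) * exp(-t_w^2 / (2 * sigma_t^2))
    w <- w / sqrt(sum(Mod(w)^2))
    wf <- stats::fft(c(w, complex(real = numeric(nfft - length(w)))))
    conv <- stats::fft(xf * wf, inverse = TRUE) / nfft
    # centre of the wavelet aligns at lag h
    power[i, ] <- Mod(conv[h + seq_len(n)])^2
  }
  structure(power, class = "trial_tfr", freqs = freqs, times = times,
            edge_half_len = half_len)
}

#' Decibel baseline normalization of time-frequency power
#'
#' `10 * log10(power / baseline mean)`, where the baseline mean is taken
#' per frequency across the time bins of the baseline window of the same
#' trial. A per-condition-average baseline can be supplied instead via
#' `baseline_power`.
#'
#' @param power A `freq x time` power matrix (e.g. from [morlet_tfr()]).
#' @param times Time axis in s; taken from the `times` attribute if absent.
#' @param window Baseline window `c(from, to)` in s (default `c(-0.3, 0)`).
#' @param baseline_power Optional per-frequency baseline mean (e.g. from a
#'   condition average) overriding the within-trial window.
#' @return Matrix of dB values of class `"trial_tfr"` with the input's
#'   attributes.
#' @export
baseline_db <- function(power, times = NULL, window = c(-0.3, 0),
                        baseline_power = NULL) {
  if (is.null(times)) times <- attr(power, "times")
  if (is.null(times)) stop("baseline_db: times must be supplied")
  if (is.null(baseline_power)) {
    sel <- times >= window[1] & times <= window[2]
    if (!any(sel)) stop("baseline_db: baseline window outside the epoch")
    baseline_power <- rowMeans(power[, sel, drop = FALSE])
  }
  if (any(baseline_power <= 0)) {
    stop("baseline_db: zero or negative baseline mean (degenerate input)")
  }
  out <- 10 * log10(sweep(unclass(power), 1, baseline_power, "/"))
  structure(out, class = "trial_tfr", freqs = attr(power, "freqs"),
            times = times, edge_half_len = attr(power, "edge_half_len"))
}

#' ERSP of a raw trial: Morlet power plus dB baseline
#'
#' @inheritParams morlet_tfr
#' @inheritParams baseline_db
#' @return A `"trial_tfr"` dB matrix on the analysis grid.
#' @export
ersp_trial <- function(x, sfreq = 300, freqs = 1:150, times = NULL,
                       n_cycles = 7, window = c(-0.3, 0)) {
  p <- morlet_tfr(x, sfreq = sfreq, freqs = freqs, times = times,
                  n_cycles = n_cycles)
  baseline_db(p, window = window)
}

#' Polyphase resampling utility
#'
#' Thin wrapper over `signal::resample` (polyphase FIR anti-aliasing
#' filter, Kaiser-windowed) for bringing acquisition-rate series to the
#' 300 Hz analysis rate. The default filter's passband gain depends on the
#' rate ratio, so the output is renormalized by the measured steady-state
#' DC gain. Plumbing only; the filter itself is the one documented by the
#' signal package (which also leaves a small, possibly fractional, group
#' delay).
#'
#' @param x Numeric vector.
#' @param from,to Original and target sampling rates in Hz.
#' @return Resampled numeric vector.
#' @export
resample_ts <- function(x, from, to) {
  if (!requireNamespace("signal", quietly = TRUE)) {
    stop("resample_ts requires the 'signal' package")
  }
  r <- .rational_ratio(to / from)
  ref <- signal::resample(rep(1, 40L * r[2]), p = r[1], q = r[2])
  gain <- mean(ref[seq(10L * r[1], 30L * r[1])])
  signal::resample(x, p = r[1], q = r[2]) / gain
}

.rational_ratio <- function(ratio, max_den = 10000L) {
  # continued-fraction rational approximation
  num <- ratio
  a <- floor(num)
  p0 <- 1; q0 <- 0; p1 <- a; q1 <- 1
  while (abs(p1 / q1 - ratio) > 1e-9 && q1 < max_den) {
    num <- 1 / (num - a)
    a <- floor(num)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
  }
  c(as.integer(p1), as.integer(q1))
}
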