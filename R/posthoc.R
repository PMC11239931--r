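#' Joint topographic map of significant ICs
#'
#' Each IC's spatial coefficients are rectified and normalized by their
#' maximum (values in `[0, 1]`), then averaged across ICs.
#'
#' @param sig_ic_maps Matrix `n_ic x n_electrode` of spatial coefficients.
#' @return Per-electrode numeric vector in `[0, 1]`.
#' @export
joint_topography <- function(sig_ic_maps) {
  sig_ic_maps <- rbind(sig_ic_maps)
  if (nrow(sig_ic_maps) < 1) stop("joint_topography: need >= 1 IC map")
  mx <- apply(abs(sig_ic_maps), 1, max)
  if (any(mx == 0)) stop("joint_topography: all-zero spatial map")
  colMeans(abs(sig_ic_maps) / mx)
}

#' Regional contribution fractions of a topographic map
#'
#' Sum of the spatial distribution within each named region divided by the
#' total over all electrodes; the remainder (unlabelled electrodes) is
#' implicit.
#'
#' @param map Per-electrode values.
#' @param region_labels Per-electrode labels; `"other"` marks unlabelled
#'   electrodes.
#' @param regions Regions to report (default pTC, aTC, aPFC).
#' @return Named numeric vector of fractions in `[0, 1]`.
#' @export
region_contribution <- function(map, region_labels,
                                regions = c("pTC", "aTC", "aPFC")) {
  if (length(map) != length(region_labels)) {
    stop("region_contribution: map and region_labels lengths differ")
  }
  total <- sum(map)
  vapply(regions, function(r) sum(map[region_labels == r]) / total,
         numeric(1))
}

#' Peak latency of a joint time-frequency response
#'
#' Averages the absolute map across frequency and reports the time of the
#' maximum after fifth-tone onset, in ms relative to that onset. Ties are
#' broken toward the earlier bin; a flat post-onset profile is undefined
#' (`NA`).
#'
#' @param map `freq x time` matrix.
#' @param times Time axis in s (first-tone onset at 0); defaults to the
#'   map's `times` attribute.
#' @param fifth_tone_onset_s Fifth-tone onset (default 0.8 s).
#' @return Latency in ms after fifth-tone onset, or `NA`.
#' @export
peak_latency <- function(map, times = NULL, fifth_tone_onset_s = 0.8) {
  if (is.null(times)) times <- attr(map, "times")
  prof <- colMeans(abs(map))
  sel <- which(times >= fifth_tone_onset_s)
  if (length(sel) == 0) stop("peak_latency: no bins after fifth-tone onset")
  p <- prof[sel]
  if (diff(range(p)) == 0) return(NA_real_)
  (times[sel[which.max(p)]] - fifth_tone_onset_s) * 1000
}

#' Amplitude-weighted mean frequency
#'
#' Averages the absolute map across time and reports the weighted mean of
#' frequency under that spectral profile.
#'
#' @param map `freq x time` matrix.
#' @param freqs Frequency axis in Hz; defaults to the map's `freqs`
#'   attribute.
#' @return Mean frequency in Hz, or `NA` for an all-zero profile.
#' @export
mean_frequency <- function(map, freqs = NULL) {
  if (is.null(freqs)) freqs <- attr(map, "freqs")
  prof <- rowMeans(abs(map))
  if (sum(prof) == 0) return(NA_real_)
  sum(freqs * prof) / sum(prof)
}

#' Min/max contrast values of a deviant response
#'
#' @param map `freq x time` difference map (dB).
#' @return Named vector `c(min = , max = )`.
#' @export
contrast_minmax <- function(map) {
  c(min = min(map), max = max(map))
}

#' Component brain maps from IC loadings
#'
#' Linear combination of the max-normalized rectified spatial maps of the
#' significant ICs, weighted by the absolute IC loadings of each PARAFAC
#' component.
#'
#' @param sig_ic_maps Matrix `n_ic x n_electrode`.
#' @param B IC loading matrix `n_ic x n_component` (from a
#'   `"parafac_fit"`).
#' @return Matrix `n_component x n_electrode`.
#' @export
component_brain_map <- function(sig_ic_maps, B) {
  sig_ic_maps <- rbind(sig_ic_maps)
  B <- rbind(B)
  if (nrow(B) != nrow(sig_ic_maps)) {
    stop("component_brain_map: loadings and maps disagree in IC count")
  }
  mx <- apply(abs(sig_ic_maps), 1, max)
  mx[mx == 0] <- 1
  norm_maps <- abs(sig_ic_maps) / mx
  out <- t(abs(B)) %*% norm_maps
  rownames(out) <- colnames(B)
  out
}

#' High-gamma spectro-temporal mask and weighted structure
#'
#' Each component time-frequency map is min-max normalized to `[0, 1]` and
#' the normalized maps are averaged. Within frequencies above `freq_min`
#' the top `top_frac` of values are kept (threshold at the
#' `1 - top_frac` quantile); the weighted structure equals the averaged
#' normalized values inside the mask and 0 outside. A binary (0/1) mask
#' variant is available via `weighted = FALSE`.
#'
#' @param maps A `freq x time` matrix or list of such maps (e.g. one per
#'   dataset or subject).
#' @param freqs Frequency axis; defaults to the first map's attribute.
#' @param freq_min High-gamma lower bound in Hz (default 40, exclusive).
#' @param top_frac Fraction of high-gamma bins kept (default 0.75).
#' @param weighted Return averaged values inside the mask (`TRUE`,
#'   default) or a 0/1 mask.
#' @return `freq x time` matrix (the structure `FT` used for projection),
#'   with attribute `mask` (logical matrix).
#' @export
st_mask <- function(maps, freqs = NULL, freq_min = 40, top_frac = 0.75,
                    weighted = TRUE) {
  if (!is.list(maps)) maps <- list(maps)
  if (length(maps) < 1) stop("st_mask: need >= 1 map")
  if (is.null(freqs)) freqs <- attr(maps[[1]], "freqs")
  if (is.null(freqs)) stop("st_mask: freqs must be supplied")
  norm <- lapply(maps, function(m) {
    rng <- range(m)
    if (diff(rng) == 0) stop("st_mask: constant map cannot be normalized")
    (m - rng[1]) / (rng[2] - rng[1])
  })
  avg <- Reduce(`+`, norm) / length(norm)
  hg <- freqs > freq_min
  if (!any(hg)) stop("st_mask: no frequencies above ", freq_min, " Hz")
  vals <- avg[hg, , drop = FALSE]
  thr <- stats::quantile(vals, probs = 1 - top_frac, names = FALSE)
  mask <- matrix(FALSE, nrow(avg), ncol(avg))
  mask[hg, ] <- vals >= thr & vals > 0  # value-free regions never enter
  out <- if (weighted) avg * mask else mask * 1
  attr(out, "mask") <- mask
  attr(out, "freqs") <- freqs
  out
}

#' Project a single trial onto a component structure
#'
#' `S * ERSP * FT`: the scalar
#' `sum_i sum_f sum_t S_i * ERSP[i, f, t] * FT[f, t]`, quantifying the
#' presence of a component (via its IC contributions `S` and
#' spectro-temporal structure `FT`) in one trial's multi-IC ERSP.
#'
#' @param S Numeric vector of IC contributions (length `n_sig`).
#' @param ersp_trial Array `n_sig x freq x time`.
#' @param FT `freq x time` structure (see [st_mask()]).
#' @return A single numeric value.
#' @export
project_trial <- function(S, ersp_trial, FT) {
  d <- dim(ersp_trial)
  if (length(d) != 3 || d[1] != length(S) ||
      d[2] != nrow(FT) || d[3] != ncol(FT)) {
    stop("project_trial: dimension mismatch between S, ERSP and FT")
  }
  sum(S * matrix(ersp_trial, d[1], d[2] * d[3]) %*% as.vector(FT))
}

#' Single-trial projections of a dataset onto fitted components
#'
#' For every trial, projects the ERSP of the selected ICs onto the PE1 and
#' PE2 spectro-temporal structures derived from a fixed-mode PARAFAC fit
#' (the time-frequency loadings reshaped to maps, mask-gated via
#' [st_mask()]), weighted by the fit's IC loadings.
#'
#' @param dataset An `"lg_dataset"`.
#' @param fit A `"parafac_fit"` for the tensor built from `ics`.
#' @param ics IC indices the fit's `B` rows refer to.
#' @param freq_min,top_frac,weighted Passed to [st_mask()].
#' @return A `data.frame` of projection records: `trial_index`,
#'   `trial_type`, `component`, `value`.
#' @export
project_dataset <- function(dataset, fit, ics, freq_min = 40,
                            top_frac = 0.75, weighted = TRUE) {
  stopifnot(inherits(dataset, "lg_dataset"), inherits(fit, "parafac_fit"))
  nf <- length(dataset$freqs); nt <- length(dataset$times)
  n_trial <- dim(dataset$ersp)[1]
  comp <- colnames(fit$B)
  if (is.null(comp)) comp <- c("PE1", "PE2")
  records <- vector("list", 2L)
  for (k in 1:2) {
    map <- matrix(fit$C[, k], nf, nt)
    FT <- st_mask(map, freqs = dataset$freqs, freq_min = freq_min,
                  top_frac = top_frac, weighted = weighted)
    S <- fit$B[, k]
    vals <- vapply(seq_len(n_trial), function(j) {
      sub <- dataset$ersp[j, ics, , , drop = FALSE]
      dim(sub) <- dim(sub)[-1]
      project_trial(S, sub, FT)
    }, numeric(1))
    records[[k]] <- data.frame(trial_index = seq_len(n_trial),
                               trial_type = dataset$labels,
                               component = comp[k], value = vals)
  }
  do.call(rbind, records)
}

#' Variability statistics of single-trial projection values
#'
#' Per trial type and component: mean and SD of the projection values.
#' Cross-type averages of those means and SDs give, per component, the CV
#' (average SD / average mean). The signal variability `SV` is the mean SD
#' across components and trial types.
#'
#' @param records Projection records from [project_dataset()] (columns
#'   `trial_type`, `component`, `value`).
#' @return List of class `"variability_stats"`: `by_type` (data.frame of
#'   per-type/component mean and sd), `by_component` (cross-type averaged
#'   mean, sd and cv per component), `sv`.
#' @export
variability_stats <- function(records) {
  stopifnot(all(c("trial_type", "component", "value") %in% names(records)))
  counts <- table(records$trial_type, records$component)
  if (any(counts < 2)) {
    stop("variability_stats: need >= 2 trials per type and component")
  }
  dt <- data.table::as.data.table(records)
  by_type <- as.data.frame(dt[, list(mean = mean(value), sd = sd(value)),
                              by = c("component", "trial_type")])
  bt <- data.table::as.data.table(by_type)
  by_comp <- as.data.frame(bt[, list(mean = mean(mean), sd = mean(sd)),
                              by = "component"])
  by_comp$cv <- ifelse(by_comp$mean != 0, by_comp$sd / by_comp$mean,
                       NA_real_)
  structure(list(by_type = by_type, by_component = by_comp,
                 sv = mean(by_type$sd)),
            class = "variability_stats")
}

#' Consistency-threshold sensitivity sweep
#'
#' Re-selects the optimal model at every consistency threshold (default
#' 40-100% in 1% steps, 61 evaluations) and records the selected scaling
#' factors together with the signal variability of that model's
#' single-trial projections. Thresholds with no qualifying model yield a
#' row of `NA`s.
#'
#' @param grid A `"pc_grid"` from [grid_search()].
#' @param tensor The deviant tensor the grid was fitted to.
#' @param dataset The `"lg_dataset"` the tensor came from.
#' @param ics IC indices of the tensor's second mode.
#' @param thresholds Consistency thresholds in percent (default `40:100`).
#' @param freq_min,top_frac Passed to the projection mask.
#' @return A `data.frame` with one row per threshold: `threshold`, `s0`,
#'   `s1`, `s2`, `rss`, `core_consistency`, `sv`.
#' @export
sensitivity_sweep <- function(grid, tensor, dataset, ics,
                              thresholds = 40:100, freq_min = 40,
                              top_frac = 0.75) {
  stopifnot(inherits(grid, "pc_grid"))
  cache <- new.env(parent = emptyenv())
  rows <- lapply(thresholds, function(th) {
    best <- select_best(grid, th)
    if (best$empty) {
      return(data.frame(threshold = th, s0 = NA_real_, s1 = NA_real_,
                        s2 = NA_real_, rss = NA_real_,
                        core_consistency = NA_real_, sv = NA_real_))
    }
    key <- as.character(best$row)
    if (is.null(cache[[key]])) {
      fit <- best_fit(best, tensor, grid)
      recs <- project_dataset(dataset, fit, ics, freq_min = freq_min,
                              top_frac = top_frac)
      cache[[key]] <- variability_stats(recs)$sv
    }
    data.frame(threshold = th, s0 = best$params$s0, s1 = best$params$s1,
               s2 = best$params$s2, rss = best$rss,
               core_consistency = best$core_consistency,
               sv = cache[[key]])
  })
  do.call(rbind, rows)
}

#' Rank-based group comparisons with Bonferroni correction
#'
#' Pairwise Wilcoxon tests over the levels of `group`: rank-sum
#' (Mann-Whitney) for independent groups or signed-rank for paired data,
#' exact when sample sizes permit, midranks for ties. P-values are
#' Bonferroni-corrected over the pairwise family. Degenerate all-equal
#' comparisons report `p = 1`.
#'
#' @param values Numeric vector of observations.
#' @param group Factor or character vector of group labels.
#' @param paired Use the paired signed-rank test (groups must then have
#'   equal lengths in matching order).
#' @param alpha Family significance level (default 0.05).
#' @return A `data.frame` with one row per pair: `group1`, `group2`,
#'   `statistic`, `p`, `p_adj`, `significant`.
#' @export
group_compare <- function(values, group, paired = FALSE, alpha = 0.05) {
  stopifnot(length(values) == length(group))
  levs <- unique(as.character(group))
  if (length(levs) < 2) stop("group_compare: need >= 2 groups")
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    x <- values[group == pr[1]]
    y <- values[group == pr[2]]
    if (length(x) < 2 || length(y) < 2) {
      stop("group_compare: need >= 2 observations per group")
    }
    if (paired && length(x) != length(y)) {
      stop("group_compare: paired comparison needs equal group sizes")
    }
    if (all(x == y[1]) && all(y == y[1])) {
      return(data.frame(group1 = pr[1], group2 = pr[2],
                        statistic = NA_real_, p = 1))
    }
    wt <- suppressWarnings(wilcox.test(x, y, paired = paired))
    data.frame(group1 = pr[1], group2 = pr[2],
               statistic = unname(wt$statistic), p = wt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "bonferroni")
  out$significant <- out$p_adj <= alpha
  out
}
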