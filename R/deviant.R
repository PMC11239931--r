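#' Deviant-response contrast between two trial groups
#'
#' Difference of group-mean ERSP maps per time-frequency bin, plus the
#' pooled-variance two-sample t statistic used as the cluster-forming
#' statistic.
#'
#' @param trials_a,trials_b Arrays `trial x freq x time` (deviant and
#'   standard groups).
#' @return List with `diff` (mean A - mean B), `tmap`, `df`.
#' @export
ersp_contrast <- function(trials_a, trials_b) {
  stopifnot(length(dim(trials_a)) == 3, length(dim(trials_b)) == 3)
  na <- dim(trials_a)[1]; nb <- dim(trials_b)[1]
  if (na < 2 || nb < 2) stop("ersp_contrast: need >= 2 trials per group")
  ma <- colMeans(trials_a); mb <- colMeans(trials_b)
  va <- colMeans(trials_a^2) - ma^2
  vb <- colMeans(trials_b^2) - mb^2
  # pooled (equal-variance) t
  sp2 <- (va * na + vb * nb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tmap <- (ma - mb) / se
  tmap[se == 0] <- 0
  list(diff = ma - mb, tmap = tmap, df = na + nb - 2)
}

# cluster masses of a thresholded t map: positive and negative clusters
# separately, 4-connectivity; returns data.frame(id, sign, mass) and labels
.cluster_masses <- function(tmap, tcrit) {
  out <- list()
  labels_all <- matrix(0L, nrow(tmap), ncol(tmap))
  next_id <- 0L
  for (sgn in c(1, -1)) {
    mask <- (sgn * tmap) > tcrit
    if (!any(mask)) next
    lab <- .label_components_cpp(mask)
    k <- max(lab)
    if (k == 0) next
    mass <- vapply(seq_len(k), function(i) sum(tmap[lab == i]), numeric(1))
    for (i in seq_len(k)) {
      labels_all[lab == i] <- next_id + i
    }
    out[[length(out) + 1L]] <- data.frame(
      id = next_id + seq_len(k), sign = sgn, mass = mass)
    next_id <- next_id + k
  }
  list(clusters = do.call(rbind, out), labels = labels_all)
}

.tmap_from_stack <- function(stack, idx_a, idx_b, nf, nt) {
  # stack: n_trial x nbins matrix
  na <- length(idx_a); nb <- length(idx_b)
  ma <- colMeans(stack[idx_a, , drop = FALSE])
  mb <- colMeans(stack[idx_b, , drop = FALSE])
  va <- colMeans(stack[idx_a, , drop = FALSE]^2) - ma^2
  vb <- colMeans(stack[idx_b, , drop = FALSE]^2) - mb^2
  sp2 <- (va * na + vb * nb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tm <- (ma - mb) / se
  tm[se == 0] <- 0
  matrix(tm, nf, nt)
}

#' Cluster-based permutation test on time-frequency maps
#'
#' Nonparametric control of the family-wise error over the time-frequency
#' grid. Per-bin two-sample t statistics are thresholded at the two-sided
#' `cluster_alpha` quantile; suprathreshold bins are grouped into clusters
#' by 4-connectivity (positive and negative clusters separately); each
#' cluster's mass is its summed t statistic. The null distribution is the
#' maximum absolute cluster mass over random relabellings of the trials,
#' and clusters with corrected `p <= alpha` are kept.
#'
#' @inheritParams ersp_contrast
#' @param n_perm Number of permutations (default 500).
#' @param alpha Cluster-level significance level (default 0.05).
#' @param cluster_alpha Per-bin two-sided cluster-forming alpha
#'   (default 0.05).
#' @param seed Optional RNG seed for the permutations.
#' @return List of class `"cluster_test"`: `diff`, `tmap`, `mask`
#'   (logical, significant bins), `masked_diff` (difference with
#'   non-significant bins set to 0), `clusters` (data.frame with `id`,
#'   `sign`, `mass`, `p`), `null_max`, `df`, `n_perm`.
#' @export
cluster_permutation <- function(trials_a, trials_b, n_perm = 500L,
                                alpha = 0.05, cluster_alpha = 0.05,
                                seed = NULL) {
  stopifnot(length(dim(trials_a)) == 3, length(dim(trials_b)) == 3)
  if (n_perm < 1 / alpha) {
    warning("cluster_permutation: n_perm < 1/alpha; permutation resolution ",
            "is insufficient for the requested alpha")
  }
  if (!is.null(seed)) set.seed(seed)
  na <- dim(trials_a)[1]; nb <- dim(trials_b)[1]
  nf <- dim(trials_a)[2]; nt <- dim(trials_a)[3]
  obs <- ersp_contrast(trials_a, trials_b)
  tcrit <- qt(1 - cluster_alpha / 2, df = obs$df)
  cm <- .cluster_masses(obs$tmap, tcrit)

  stack <- rbind(matrix(trials_a, na, nf * nt), matrix(trials_b, nb, nf * nt))
  n <- na + nb
  null_max <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    idx <- sample.int(n, na)
    tm <- .tmap_from_stack(stack, idx, setdiff(seq_len(n), idx), nf, nt)
    pm <- .cluster_masses(tm, tcrit)$clusters
    null_max[p] <- if (is.null(pm)) 0 else max(abs(pm$mass))
  }

  mask <- matrix(FALSE, nf, nt)
  clusters <- cm$clusters
  if (!is.null(clusters)) {
    clusters$p <- vapply(clusters$mass, function(m) {
      (1 + sum(null_max >= abs(m))) / (n_perm + 1)
    }, numeric(1))
    keep <- clusters$id[clusters$p <= alpha]
    mask <- matrix(cm$labels %in% keep, nf, nt)
  } else {
    clusters <- data.frame(id = integer(), sign = numeric(),
                           mass = numeric(), p = numeric())
  }
  masked_diff <- obs$diff
  masked_diff[!mask] <- 0
  structure(list(diff = obs$diff, tmap = obs$tmap, mask = mask,
                 masked_diff = masked_diff, clusters = clusters,
                 null_max = null_max, df = obs$df, n_perm = n_perm),
            class = "cluster_test")
}

.contrast_groups <- list(
  c1 = c(dev = "xy|xx", std = "xx|xx"),
  c2 = c(dev = "xy|xy", std = "xx|xy")
)

# trial x freq x time slab of one IC for one trial type
.ic_trials <- function(dataset, ic, type) {
  sel <- dataset$labels == type
  dataset$ersp[sel, ic, , , drop = FALSE][, 1, , , drop = TRUE]
}

#' Deviant responses and significant-IC selection
#'
#' Runs the cluster permutation test for both contrasts
#' (`c1 = xy|xx - xx|xx`, `c2 = xy|xy - xx|xy`) on every IC of a dataset.
#' An IC with at least one significant cluster in either contrast is a
#' significant IC. Masked difference maps keep the sign of significant
#' clusters and are 0 elsewhere.
#'
#' @param dataset An `"lg_dataset"` (see [simulate_ersp_dataset()]).
#' @param n_perm,alpha,cluster_alpha,seed Passed to
#'   [cluster_permutation()].
#' @return List of class `"deviant_set"`: `responses` (per IC, per
#'   contrast `"cluster_test"` objects), `significant` (IC indices),
#'   `cluster_table` (data.frame over all ICs/contrasts).
#' @export
select_significant_ics <- function(dataset, n_perm = 500L, alpha = 0.05,
                                   cluster_alpha = 0.05, seed = NULL) {
  stopifnot(inherits(dataset, "lg_dataset"))
  if (!is.null(seed)) set.seed(seed)
  n_ic <- dim(dataset$ersp)[2]
  responses <- vector("list", n_ic)
  rows <- list()
  for (ic in seq_len(n_ic)) {
    per_contrast <- lapply(names(.contrast_groups), function(cn) {
      gp <- .contrast_groups[[cn]]
      cluster_permutation(.ic_trials(dataset, ic, gp["dev"]),
                          .ic_trials(dataset, ic, gp["std"]),
                          n_perm = n_perm, alpha = alpha,
                          cluster_alpha = cluster_alpha)
    })
    names(per_contrast) <- names(.contrast_groups)
    responses[[ic]] <- per_contrast
    for (cn in names(per_contrast)) {
      cl <- per_contrast[[cn]]$clusters
      if (nrow(cl) > 0) {
        rows[[length(rows) + 1L]] <- data.frame(ic = ic, contrast = cn, cl)
      }
    }
  }
  significant <- which(vapply(responses, function(pc) {
    any(vapply(pc, function(ct) any(ct$clusters$p <= alpha), logical(1)))
  }, logical(1)))
  cluster_table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ic = integer(), contrast = character(), id = integer(),
               sign = numeric(), mass = numeric(), p = numeric())
  structure(list(responses = responses, significant = significant,
                 cluster_table = cluster_table),
            class = "deviant_set")
}

#' Assemble the Contrast x IC x Time-Frequency deviant tensor
#'
#' Stacks the (optionally significance-masked) contrast difference maps of
#' the selected ICs into the 3-way tensor consumed by [parafac_fixed()].
#' The time-frequency mode is flattened frequency-major (frequency index
#' varying fastest), recorded in the `tf_order` attribute.
#'
#' @param dataset An `"lg_dataset"`.
#' @param ics IC indices to include (e.g. the significant set).
#' @param deviants Optional `"deviant_set"`; when supplied, its masked
#'   difference maps are used. Otherwise raw mean contrasts are used.
#' @return A `2 x length(ics) x (freq * time)` array with attributes
#'   `freqs`, `times`, `tf_order`, `ics`.
#' @export
build_deviant_tensor <- function(dataset, ics = NULL, deviants = NULL) {
  stopifnot(inherits(dataset, "lg_dataset"))
  if (is.null(ics)) {
    ics <- if (!is.null(deviants)) deviants$significant
           else seq_len(dim(dataset$ersp)[2])
  }
  if (length(ics) == 0) stop("build_deviant_tensor: no ICs to include")
  nf <- length(dataset$freqs); nt <- length(dataset$times)
  tensor <- array(NA_real_, c(2, length(ics), nf * nt))
  for (j in seq_along(ics)) {
    ic <- ics[j]
    for (ci in 1:2) {
      if (!is.null(deviants)) {
        map <- deviants$responses[[ic]][[ci]]$masked_diff
      } else {
        gp <- .contrast_groups[[ci]]
        map <- colMeans(.ic_trials(dataset, ic, gp["dev"])) -
               colMeans(.ic_trials(dataset, ic, gp["std"]))
      }
      tensor[ci, j, ] <- as.vector(map)  # column-major: frequency fastest
    }
  }
  structure(tensor, freqs = dataset$freqs, times = dataset$times,
            tf_order = "frequency-major", ics = ics)
}
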