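#' Fixed-mode PARAFAC decomposition of a deviant-response tensor
#'
#' Fits the rank-2 CP model `X ~ sum_r A[, r] o B[, r] o C[, r]` to a
#' Contrast x IC x Time-Frequency tensor by alternating least squares, with
#' the first (Contrast) mode frozen to the model-derived design matrix `A`.
#' Only the IC loadings `B` and the time-frequency loadings `C` are updated.
#' No constraint is placed on any mode. Two starts are run — a random start
#' and a deterministic start from the leading left singular vectors of the
#' mode-3 unfolding — and the lower-RSS solution is kept. The scale
#' indeterminacy left by the frozen mode is fixed by normalizing the columns
#' of `C` to unit norm, absorbing the magnitude into `B`.
#'
#' @param tensor Numeric array, `2 x n_ic x n_tf` (a flattened
#'   time-frequency third mode; see [build_deviant_tensor()]).
#' @param A 2 x 2 contrast design matrix from [contrast_design()].
#' @param tol Convergence criterion: relative change in residual sum of
#'   squares below which iteration stops (default `1e-6`).
#' @param max_iter Maximum ALS iterations per start (default 500).
#' @param seed Optional seed for the random start.
#' @return An object of class `"parafac_fit"`: list with `A`, `B`
#'   (`n_ic x 2`), `C` (`n_tf x 2`, unit-norm columns), `rss`,
#'   `core_consistency` (percent, `NA` if degenerate), `converged`,
#'   `n_iter`, `monotone`.
#' @export
parafac_fixed <- function(tensor, A, tol = 1e-6, max_iter = 500L,
                          seed = NULL) {
  stopifnot(is.array(tensor), length(dim(tensor)) == 3)
  d <- dim(tensor)
  if (d[1] != nrow(A)) stop("parafac_fixed: tensor mode 1 must match nrow(A)")
  if (!all(is.finite(tensor))) stop("parafac_fixed: tensor must be finite")
  if (!all(is.finite(A))) stop("parafac_fixed: A must be finite")
  if (abs(det(A)) < 1e-12 * max(abs(A), 1e-300)) {
    stop("parafac_fixed: fixed contrast matrix A is rank deficient")
  }
  if (!is.null(seed)) set.seed(seed)
  C0 <- matrix(rnorm(d[3] * ncol(A)), d[3], ncol(A))
  res <- .cp_als_fixed_cpp(tensor, A, C0, tol, as.integer(max_iter), TRUE)
  if (!is.finite(res$core_consistency)) res$core_consistency <- NA_real_
  structure(list(
    A = A, B = res$B, C = res$C,
    rss = res$rss,
    core_consistency = res$core_consistency,
    converged = res$converged,
    n_iter = res$n_iter,
    monotone = res$monotone
  ), class = "parafac_fit")
}

#' Core consistency diagnostic
#'
#' `100 * (1 - sum((g - t)^2) / sum(t^2))`, where `g` is the least-squares
#' Tucker core given the CP loadings (the frozen contrast matrix included
#' as an ordinary factor) and `t` the superdiagonal identity core. Values
#' near 100 indicate an appropriate trilinear model; 80-90 a robust
#' decomposition; 40 a somewhat satisfactory floor.
#'
#' @param fit A `"parafac_fit"` object.
#' @param tensor The tensor the fit was obtained from.
#' @return Consistency in percent (can be very negative), or `NA` for
#'   degenerate loadings.
#' @export
core_consistency <- function(fit, tensor) {
  stopifnot(inherits(fit, "parafac_fit"))
  cc <- .core_consistency_cpp(tensor, fit$A, fit$B, fit$C)
  if (!is.finite(cc)) NA_real_ else cc
}

#' Default scaling-factor grid
#'
#' 21 uniformly spaced values of `s0` in `[0, 1]` (step 0.05) and of `s1`
#' and `s2` in `[0, 2]` (step 0.1), for 21^3 = 9261 candidate models.
#'
#' @param s0,s1,s2 Numeric grids for each scaling factor.
#' @return A list of the three axes, class `"scaling_grid"`.
#' @export
scaling_grid <- function(s0 = seq(0, 1, length.out = 21),
                         s1 = seq(0, 2, length.out = 21),
                         s2 = seq(0, 2, length.out = 21)) {
  structure(list(s0 = s0, s1 = s1, s2 = s2), class = "scaling_grid")
}

#' Grid search over scaling factors
#'
#' For every `(s0, s1, s2)` cell the contrast design matrix is built from
#' the model and a fixed-mode PARAFAC fit of the tensor is computed; RSS
#' and core consistency are recorded per cell. Deterministic given the
#' tensor and seed (one shared seeded random start plus a per-tensor
#' deterministic start).
#'
#' @inheritParams parafac_fixed
#' @param grid A [scaling_grid()].
#' @param stats_xx,stats_xy [regularity_stats()] per block context
#'   (defaults from [default_stats()]).
#' @param max_iter Maximum ALS iterations per start (default 200 for grid
#'   evaluation).
#' @param adapt_before_predict Passed to [contrast_design()].
#' @return An object of class `"pc_grid"`: list with `table` (a
#'   `data.table` with columns `s0`, `s1`, `s2`, `rss`,
#'   `core_consistency`, `n_iter`), the `grid`, and fit settings.
#' @export
grid_search <- function(tensor, grid = scaling_grid(),
                        stats_xx = default_stats()$xx,
                        stats_xy = default_stats()$xy,
                        tol = 1e-6, max_iter = 200L, seed = NULL,
                        adapt_before_predict = TRUE) {
  stopifnot(inherits(grid, "scaling_grid"))
  cells <- expand.grid(s0 = grid$s0, s1 = grid$s1, s2 = grid$s2,
                       KEEP.OUT.ATTRS = FALSE)
  ncell <- nrow(cells)
  Amats <- .contrast_grid_matrices(cells$s0, cells$s1, cells$s2,
                                   stats_xx, stats_xy, adapt_before_predict)
  if (!is.null(seed)) set.seed(seed)
  C0 <- matrix(rnorm(dim(tensor)[3] * 2), dim(tensor)[3], 2)
  res <- .cp_grid_cpp(tensor, Amats, C0, tol, as.integer(max_iter))
  tab <- data.table::data.table(
    cells,
    rss = as.numeric(res$rss),
    core_consistency = ifelse(is.finite(res$core_consistency),
                              as.numeric(res$core_consistency), NA_real_),
    n_iter = as.integer(res$n_iter)
  )
  structure(list(
    table = tab, grid = grid,
    stats_xx = stats_xx, stats_xy = stats_xy,
    tol = tol, max_iter = max_iter, seed = seed,
    adapt_before_predict = adapt_before_predict
  ), class = "pc_grid")
}

# vectorized evaluation of contrast_design over many (s0, s1, s2) cells;
# identical to contrast_design (asserted in the test suite), written out
# elementwise so the 9261-cell grid costs milliseconds
.contrast_grid_matrices <- function(s0, s1, s2, stats_xx, stats_xy,
                                    adapt_before_predict = TRUE) {
  n <- length(s0)
  A <- array(NA_real_, c(2, 2, n))
  for (ctx in 1:2) {
    st <- if (ctx == 1) stats_xx else stats_xy
    q <- st$q_local; d <- st$d_global
    target_x <- if (adapt_before_predict) (1 - q) * s0 else (1 - q)
    e1x_xx <- s0 - s1 * target_x; e1y_xx <- -s1 * q
    e1x_xy <- -s1 * target_x;     e1y_xy <- 1 - s1 * q
    if (ctx == 1) { # standard sequence ends on x
      P2x <- s2 * ((1 - d) * e1x_xx + d * e1x_xy)
      P2y <- s2 * ((1 - d) * e1y_xx + d * e1y_xy)
    } else {        # standard sequence ends on y
      P2x <- s2 * ((1 - d) * e1x_xy + d * e1x_xx)
      P2y <- s2 * ((1 - d) * e1y_xy + d * e1y_xx)
    }
    pe1_xx <- abs(e1x_xx) + abs(e1y_xx)
    pe1_xy <- abs(e1x_xy) + abs(e1y_xy)
    pe2_xx <- abs(e1x_xx - P2x) + abs(e1y_xx - P2y)
    pe2_xy <- abs(e1x_xy - P2x) + abs(e1y_xy - P2y)
    A[ctx, 1, ] <- pe1_xy - pe1_xx
    A[ctx, 2, ] <- pe2_xy - pe2_xx
  }
  A
}

#' Select the best-fitting model from a grid search
#'
#' Among grid cells whose core consistency exceeds `threshold`, returns the
#' cell with the smallest RSS. An empty qualifying set is reported
#' explicitly, never silently relaxed.
#'
#' @param grid A `"pc_grid"` from [grid_search()].
#' @param threshold Core-consistency threshold in percent (default 80).
#' @return A list of class `"pc_best"`: `params` ([scaling_params()] or
#'   `NULL` if no cell qualifies), `rss`, `core_consistency`, `row`
#'   (row index into `grid$table`), `threshold`, `empty`.
#' @export
select_best <- function(grid, threshold = 80) {
  stopifnot(inherits(grid, "pc_grid"))
  tab <- grid$table
  ok <- which(!is.na(tab$core_consistency) & tab$core_consistency > threshold)
  if (length(ok) == 0) {
    return(structure(list(params = NULL, rss = NA_real_,
                          core_consistency = NA_real_, row = NA_integer_,
                          threshold = threshold, empty = TRUE),
                     class = "pc_best"))
  }
  best <- ok[which.min(tab$rss[ok])]
  structure(list(
    params = scaling_params(tab$s0[best], tab$s1[best], tab$s2[best]),
    rss = tab$rss[best],
    core_consistency = tab$core_consistency[best],
    row = best, threshold = threshold, empty = FALSE
  ), class = "pc_best")
}

#' Refit the selected model to obtain loadings
#'
#' @param best A `"pc_best"` selection.
#' @param tensor The deviant tensor used for the grid search.
#' @param grid The `"pc_grid"` the selection came from.
#' @return A `"parafac_fit"` with IC and time-frequency loadings.
#' @export
best_fit <- function(best, tensor, grid) {
  stopifnot(inherits(best, "pc_best"), !best$empty)
  A <- contrast_design(best$params, grid$stats_xx, grid$stats_xy,
                       grid$adapt_before_predict)
  parafac_fixed(tensor, A, tol = grid$tol, max_iter = 500L,
                seed = grid$seed)
}

#' @export
print.pc_grid <- function(x, ...) {
  cat("Scaling-factor grid search:", nrow(x$table), "models\n")
  cat("  RSS range:", format(range(x$table$rss), digits = 4), "\n")
  cat("  consistency > 80%:",
      sum(x$table$core_consistency > 80, na.rm = TRUE), "cells\n")
  invisible(x)
}

#' @export
print.pc_best <- function(x, ...) {
  if (x$empty) {
    cat("No model exceeds the consistency threshold of", x$threshold, "%\n")
  } else {
    p <- x$params
    cat(sprintf("Best model: s0 = %.2f, s1 = %.2f, s2 = %.2f (RSS %.4g, consistency %.1f%%)\n",
                p$s0, p$s1, p$s2, x$rss, x$core_consistency))
  }
  invisible(x)
}
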