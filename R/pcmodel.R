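#' Scaling parameters of the hierarchical predictive-coding model
#'
#' Three unitless factors tune the model away from the optimal observer:
#' `s0` scales the (adapted) sensory input on the repeated-tone stream,
#' `s1` the first-level predictions, and `s2` the second-level predictions.
#' `s1 = s2 = 1` is optimal prediction; values below 1 are hypo-prediction
#' (the prediction underreacts and fails to cancel its input), values above
#' 1 are hyper-prediction (the regularity is overestimated and extra error
#' is created).
#'
#' @param s0 Sensory scaling in `[0, 1]` (1 = no adaptation).
#' @param s1,s2 Prediction scalings in `[0, 2]`.
#' @return An object of class `"scaling_params"`.
#' @export
scaling_params <- function(s0, s1, s2) {
  stopifnot(is.numeric(s0), is.numeric(s1), is.numeric(s2),
            length(s0) == 1, length(s1) == 1, length(s2) == 1)
  if (s0 < 0 || s0 > 1) stop("scaling_params: s0 must be in [0, 1]")
  if (s1 < 0 || s1 > 2) stop("scaling_params: s1 must be in [0, 2]")
  if (s2 < 0 || s2 > 2) stop("scaling_params: s2 must be in [0, 2]")
  structure(list(s0 = s0, s1 = s1, s2 = s2), class = "scaling_params")
}

#' Temporal-regularity statistics consumed by the model
#'
#' @param q_local Transition probability (TP) of an x-to-y transition in the
#'   trial's block context, in `[0, 1]`.
#' @param d_global Sequence probability (SP) of the block's deviant
#'   sequence, in `[0, 1]`.
#' @return An object of class `"regularity_stats"`.
#' @export
regularity_stats <- function(q_local, d_global) {
  stopifnot(q_local >= 0, q_local <= 1, d_global >= 0, d_global <= 1)
  structure(list(q_local = q_local, d_global = d_global),
            class = "regularity_stats")
}

#' Default regularity statistics of the standard block design
#'
#' The default mixture (64 standard + 16 deviant sequences after 20
#' habituation trials, habituation excluded) gives a transition probability
#' of 0.05 in the XX context and 0.20 in the XY context, and a
#' deviant-sequence probability of 0.2 in both contexts.
#'
#' @return A list with `"regularity_stats"` elements `xx` and `xy`.
#' @export
default_stats <- function() {
  list(xx = regularity_stats(0.05, 0.2),
       xy = regularity_stats(0.20, 0.2))
}

.trial_types <- c("xx|xx", "xy|xx", "xy|xy", "xx|xy")

# split a trial type into sequence ("xx"/"xy") and context ("xx"/"xy")
.parse_trial_type <- function(trial_type) {
  if (!trial_type %in% .trial_types) {
    stop("unknown trial type: ", trial_type,
         " (expected one of ", paste(.trial_types, collapse = ", "), ")")
  }
  parts <- strsplit(trial_type, "|", fixed = TRUE)[[1]]
  list(seq = parts[1], context = parts[2])
}

# signed level-S errors (e1_x, e1_y) for one sequence type in a block.
# fifth: "x" or "y". With adapt_before_predict the level-1 prediction of the
# x stream targets the adapted input (1-q)*s0 rather than (1-q).
.e1 <- function(params, q, fifth, adapt_before_predict = TRUE) {
  I_x <- if (fifth == "x") params$s0 else 0
  I_y <- if (fifth == "y") 1 else 0
  x_target <- if (adapt_before_predict) (1 - q) * params$s0 else (1 - q)
  P1_x <- params$s1 * x_target
  P1_y <- params$s1 * q
  c(x = I_x - P1_x, y = I_y - P1_y)
}

#' Model state for one trial type
#'
#' Evaluates the two-stream, three-level model at the fifth tone of a
#' sequence, after both regularities have been learned. Level S receives
#' the thalamic input (strength 1, scaled by `s0` on the adapted x stream)
#' and a first-level prediction; Level 1 receives the level-S error and a
#' second-level prediction of that error formed from the sequence
#' probability. Errors propagate signed between levels.
#'
#' @param params A [scaling_params()] object.
#' @param stats [regularity_stats()] for the trial's block context.
#' @param trial_type One of `"xx|xx"`, `"xy|xx"`, `"xy|xy"`, `"xx|xy"`.
#' @param adapt_before_predict If `TRUE` (default) the first-level
#'   prediction of the x stream targets the adapted input `(1 - q) * s0`;
#'   if `FALSE` it targets the unadapted transition probability `(1 - q)`.
#' @return A list of class `"stream_state"` with per-stream input `I`,
#'   predictions `P1`, `P2` and signed errors `e1`, `e2` (named vectors
#'   with elements `x` and `y`).
#' @examples
#' st <- trial_state(scaling_params(0.4, 0.85, 0.75),
#'                   regularity_stats(0.05, 0.2), "xx|xx")
#' st$e1
#' @export
trial_state <- function(params, stats, trial_type,
                        adapt_before_predict = TRUE) {
  stopifnot(inherits(params, "scaling_params"),
            inherits(stats, "regularity_stats"))
  tt <- .parse_trial_type(trial_type)
  q <- stats$q_local
  d <- stats$d_global
  # fifth tone of each sequence type; the context names the standard sequence
  fifth <- c(xx = "x", xy = "y")
  std_seq <- tt$context
  dev_seq <- setdiff(c("xx", "xy"), std_seq)
  e1_std <- .e1(params, q, fifth[[std_seq]], adapt_before_predict)
  e1_dev <- .e1(params, q, fifth[[dev_seq]], adapt_before_predict)
  P2 <- params$s2 * ((1 - d) * e1_std + d * e1_dev)
  e1 <- if (tt$seq == std_seq) e1_std else e1_dev
  I <- c(x = if (fifth[[tt$seq]] == "x") params$s0 else 0,
         y = if (fifth[[tt$seq]] == "y") 1 else 0)
  x_target <- if (adapt_before_predict) (1 - q) * params$s0 else (1 - q)
  structure(list(
    trial_type = trial_type,
    I = I,
    P1 = c(x = params$s1 * x_target, y = params$s1 * q),
    P2 = P2,
    e1 = e1,
    e2 = e1 - P2
  ), class = "stream_state")
}

#' Observable prediction-error magnitudes
#'
#' The local and global prediction errors observable in spectral power are
#' the sums of the absolute per-stream errors: `PE1 = |e1_x| + |e1_y|`,
#' `PE2 = |e2_x| + |e2_y|`.
#'
#' @param state A `"stream_state"` from [trial_state()].
#' @return Named numeric vector `c(PE1 = , PE2 = )`, both non-negative.
#' @export
pe_values <- function(state) {
  stopifnot(inherits(state, "stream_state"))
  c(PE1 = sum(abs(state$e1)), PE2 = sum(abs(state$e2)))
}

#' Model-derived contrast design matrix
#'
#' The 2 x 2 matrix of PE1/PE2 contributions to the two deviant-response
#' contrasts, obtained by subtracting the model values for
#' `xy|xx - xx|xx` (row 1) and `xy|xy - xx|xy` (row 2). This matrix fixes
#' the Contrast mode of the PARAFAC decomposition.
#'
#' @inheritParams trial_state
#' @param stats_xx,stats_xy [regularity_stats()] for the XX and XY block
#'   contexts.
#' @return A 2 x 2 numeric matrix with rows `c1`, `c2` and columns
#'   `PE1`, `PE2`.
#' @examples
#' contrast_design(scaling_params(0.4, 0.85, 0.75),
#'                 regularity_stats(0.05, 0.2),
#'                 regularity_stats(0.20, 0.2))
#' @export
contrast_design <- function(params, stats_xx, stats_xy,
                            adapt_before_predict = TRUE) {
  pe <- function(stats, type) {
    pe_values(trial_state(params, stats, type, adapt_before_predict))
  }
  A <- rbind(pe(stats_xx, "xy|xx") - pe(stats_xx, "xx|xx"),
             pe(stats_xy, "xy|xy") - pe(stats_xy, "xx|xy"))
  dimnames(A) <- list(c("xy|xx - xx|xx", "xy|xy - xx|xy"), c("PE1", "PE2"))
  A
}

#' Per-trial-type model PE values as a table
#'
#' @inheritParams contrast_design
#' @return A `data.frame` with columns `trial_type`, `PE1`, `PE2`.
#' @export
pe_table <- function(params, stats_xx, stats_xy,
                     adapt_before_predict = TRUE) {
  rows <- lapply(.trial_types, function(tt) {
    stats <- if (endsWith(tt, "xx")) stats_xx else stats_xy
    pe <- pe_values(trial_state(params, stats, tt, adapt_before_predict))
    data.frame(trial_type = tt, PE1 = pe[["PE1"]], PE2 = pe[["PE2"]])
  })
  do.call(rbind, rows)
}
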