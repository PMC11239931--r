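#' Block design for the local-global oddball paradigm
#'
#' Describes one stimulus block: a habituation phase in which the block's
#' standard 5-tone sequence is repeated, followed by a randomly permuted
#' mixture of standard and deviant sequences. In an XX block the standard
#' sequence repeats the same tone five times (e.g. AAAAA) and the deviant
#' ends on the other tone (AAAAB); in an XY block the roles are reversed.
#'
#' @param block_context `"XX"` or `"XY"`: whether the block's standard
#'   sequence ends on the repeated tone (XX) or on the other tone (XY).
#' @param standard_identity `"A"` or `"B"`: identity of the repeated tone x.
#' @param n_habituation Number of initial habituation sequences (default 20).
#' @param n_standard Number of standard sequences in the mixture (default 64).
#' @param n_deviant Number of deviant sequences in the mixture (default 16).
#' @param tone_duration_ms Tone duration in ms (default 50).
#' @param inter_tone_interval_ms Onset-to-onset gap between tones minus the
#'   tone itself, in ms (default 150, so onsets are 200 ms apart).
#' @param inter_sequence_gap_ms Length-2 numeric range (ms) from which the
#'   gap between the offset of one sequence and the onset of the next is
#'   drawn uniformly (default `c(950, 1150)`).
#' @param seed Integer seed controlling the mixture permutation and the
#'   inter-sequence gaps; `NULL` uses the current RNG state.
#' @return An object of class `"lg_design"` (a list of the above fields).
#' @seealso [generate_block()]
#' @export
block_design <- function(block_context = c("XX", "XY"),
                         standard_identity = c("A", "B"),
                         n_habituation = 20L,
                         n_standard = 64L,
                         n_deviant = 16L,
                         tone_duration_ms = 50,
                         inter_tone_interval_ms = 150,
                         inter_sequence_gap_ms = c(950, 1150),
                         seed = NULL) {
  block_context <- match.arg(block_context)
  standard_identity <- match.arg(standard_identity)
  counts <- c(n_habituation = n_habituation, n_standard = n_standard,
              n_deviant = n_deviant)
  if (any(counts < 0)) {
    stop("block_design: counts must be non-negative, got ",
         paste(names(counts)[counts < 0], collapse = ", "))
  }
  if (length(inter_sequence_gap_ms) != 2L ||
      diff(inter_sequence_gap_ms) < 0) {
    stop("block_design: inter_sequence_gap_ms must be a non-decreasing range")
  }
  structure(list(
    block_context = block_context,
    standard_identity = standard_identity,
    n_habituation = as.integer(n_habituation),
    n_standard = as.integer(n_standard),
    n_deviant = as.integer(n_deviant),
    tone_duration_ms = tone_duration_ms,
    inter_tone_interval_ms = inter_tone_interval_ms,
    inter_sequence_gap_ms = inter_sequence_gap_ms,
    seed = seed
  ), class = "lg_design")
}

# sequence strings and trial label for a design: returns list(std=, dev=, labels=)
.design_sequences <- function(design) {
  x <- design$standard_identity
  y <- setdiff(c("A", "B"), x)
  xx <- paste(rep(x, 5), collapse = "")
  xy <- paste(c(rep(x, 4), y), collapse = "")
  ctx <- tolower(design$block_context) # "xx" or "xy"
  if (design$block_context == "XX") {
    list(std = xx, dev = xy,
         std_label = paste0("xx|", ctx), dev_label = paste0("xy|", ctx))
  } else {
    list(std = xy, dev = xx,
         std_label = paste0("xy|", ctx), dev_label = paste0("xx|", ctx))
  }
}

#' Generate one stimulus block
#'
#' The first `n_habituation` trials are the block's standard sequence; the
#' remaining trials are a seeded random permutation of `n_standard` standard
#' and `n_deviant` deviant sequences. Trial labels (`xx|xx`, `xy|xx`,
#' `xy|xy`, `xx|xy`) encode the sequence type and block context. Tone onsets
#' are laid out with the design's tone duration, inter-tone interval and a
#' uniformly drawn inter-sequence gap.
#'
#' @param design An [block_design()] object.
#' @return A `data.frame` of class `"lg_block"` with one row per trial:
#'   `trial_index`, `block_context`, `label`, `tones` (5-character string),
#'   `phase` (`"habituation"` or `"test"`), `onset_ms` (first-tone onset)
#'   and `fifth_tone_onset_ms`.
#' @examples
#' blk <- generate_block(block_design(seed = 1))
#' table(blk$label)
#' @export
generate_block <- function(design) {
  stopifnot(inherits(design, "lg_design"))
  sq <- .design_sequences(design)
  if (!is.null(design$seed)) set.seed(design$seed)
  mix <- c(rep(sq$std, design$n_standard), rep(sq$dev, design$n_deviant))
  if (length(mix) > 1L) mix <- sample(mix)
  tones <- c(rep(sq$std, design$n_habituation), mix)
  n <- length(tones)
  label <- ifelse(tones == sq$std, sq$std_label, sq$dev_label)
  phase <- rep(c("habituation", "test"),
               c(design$n_habituation, n - design$n_habituation))
  # onset bookkeeping: 5 tones per sequence, onsets 0,200,400,... within trial
  onset_step <- design$tone_duration_ms + design$inter_tone_interval_ms
  seq_span <- 4 * onset_step + design$tone_duration_ms
  gaps <- stats::runif(n, design$inter_sequence_gap_ms[1],
                       design$inter_sequence_gap_ms[2])
  onset <- cumsum(c(0, (seq_span + gaps)[-n]))
  out <- data.frame(
    trial_index = seq_len(n),
    block_context = design$block_context,
    label = label,
    tones = tones,
    phase = phase,
    onset_ms = onset,
    fifth_tone_onset_ms = onset + 4 * onset_step,
    stringsAsFactors = FALSE
  )
  attr(out, "design") <- design
  class(out) <- c("lg_block", "data.frame")
  out
}

.block_counted <- function(block, include_habituation) {
  stopifnot(is.data.frame(block), nrow(block) > 0)
  if (include_habituation) block else block[block$phase != "habituation", , drop = FALSE]
}

#' Estimate the local (tone-to-tone) transition regularity
#'
#' Counts, over the four within-sequence transitions of every counted trial,
#' the fraction of transitions out of the standard tone x that land on the
#' deviant tone y. This is the transition probability (TP) encoded by the
#' first model level. Habituation trials are excluded by default.
#'
#' @param block An `"lg_block"` data frame from [generate_block()].
#' @param include_habituation Include the habituation phase in the counts?
#' @return The transition probability, a number in `[0, 1]`.
#' @examples
#' q <- estimate_local_regularity(generate_block(block_design(seed = 1)))
#' @export
estimate_local_regularity <- function(block, include_habituation = FALSE) {
  counted <- .block_counted(block, include_habituation)
  design <- attr(block, "design")
  x <- if (!is.null(design)) design$standard_identity else
    substr(counted$tones[1], 1, 1)
  mat <- do.call(rbind, strsplit(counted$tones, ""))
  from_x <- mat[, 1:4, drop = FALSE] == x
  to_y <- mat[, 2:5, drop = FALSE] != x
  n_out <- sum(from_x)
  if (n_out == 0) {
    stop("estimate_local_regularity: no transitions out of the standard tone")
  }
  sum(from_x & to_y) / n_out
}

#' Estimate the global (sequence) regularity
#'
#' Fraction of counted trials carrying the block's deviant sequence: the
#' sequence probability (SP) of the rare sequence, encoded by the second
#' model level. Habituation trials are excluded by default.
#'
#' @inheritParams estimate_local_regularity
#' @return The deviant-sequence probability, a number in `[0, 1]`.
#' @export
estimate_global_regularity <- function(block, include_habituation = FALSE) {
  counted <- .block_counted(block, include_habituation)
  if (nrow(counted) == 0) {
    stop("estimate_global_regularity: no trials counted")
  }
  mean(counted$label %in% c("xy|xx", "xx|xy"))
}

#' Write a block to CSV / a design to JSON
#'
#' @param block An `"lg_block"` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_block_csv <- function(block, path) {
  data.table::fwrite(as.data.frame(block), path)
  invisible(path)
}

#' @rdname write_block_csv
#' @param design An `"lg_design"` object.
#' @export
write_design_json <- function(design, path) {
  jsonlite::write_json(unclass(design), path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' @rdname write_block_csv
#' @export
read_design_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(block_design, raw)
}
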