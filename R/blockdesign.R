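#' Construct an alternating-condition block design for one run
#'
#' Builds the timing skeleton of a single fMRI run in which two conditions
#' (visual imagery and thought suppression) alternate in fixed-length blocks.
#' Each condition phase is made of `sub_blocks_per_condition` consecutive
#' sub-blocks of `block_len_s` seconds, and a brief visual cue marks every
#' sub-block transition. The default parameters reproduce a 408-s run:
#' a 24-s lead-in followed by four pairs of 48-s imagery and 48-s
#' suppression phases, cued every 24 s.
#'
#' @param block_len_s Sub-block length in seconds; must be a multiple of `tr`.
#' @param n_pairs Number of imagery/suppression pairs per run.
#' @param sub_blocks_per_condition Consecutive sub-blocks forming one
#'   condition phase (the imagery phase shows a different item per sub-block).
#' @param tr Repetition time (volume sampling interval) in seconds.
#' @param lead_in_s Initial task-free period in seconds; multiple of `tr`.
#' @param conditions Two condition labels, first one presented first.
#' @param cue_duration_s Duration of the visual cue flash in seconds.
#' @return An object of class `block_design`: a list with `blocks`
#'   (data.frame: condition, sub_index, onset, duration), `cues`
#'   (data.frame: onset, duration), `run_length_s`, `tr`, `lead_in_s`,
#'   `block_len_s`, `n_pairs`, `sub_blocks_per_condition`, `conditions`.
#' @examples
#' d <- build_block_design(24, 4, 2, 2.0, 24)
#' d$run_length_s  # 408
#' n_volumes(d)    # 204
#' @export
build_block_design <- function(block_len_s = 24, n_pairs = 4,
                               sub_blocks_per_condition = 2, tr = 2.0,
                               lead_in_s = 24,
                               conditions = c("imagery", "suppression"),
                               cue_duration_s = 2) {
  stopifnot(tr > 0, n_pairs >= 1, sub_blocks_per_condition >= 1,
            length(conditions) == 2)
  is_multiple <- function(x) abs(x / tr - round(x / tr)) < 1e-9
  if (!is_multiple(block_len_s))
    stop("`block_len_s` (", block_len_s, " s) is not a multiple of tr (", tr, " s)")
  if (!is_multiple(lead_in_s))
    stop("`lead_in_s` (", lead_in_s, " s) is not a multiple of tr (", tr, " s)")

  blocks <- expand.grid(sub_index = seq_len(sub_blocks_per_condition),
                        condition = conditions,
                        pair = seq_len(n_pairs),
                        stringsAsFactors = FALSE)
  blocks <- blocks[, c("condition", "sub_index", "pair")]
  blocks$duration <- block_len_s
  blocks$onset <- lead_in_s + (seq_len(nrow(blocks)) - 1) * block_len_s
  blocks <- blocks[, c("condition", "sub_index", "pair", "onset", "duration")]

  cues <- data.frame(onset = blocks$onset, duration = cue_duration_s)
  run_length_s <- lead_in_s + n_pairs * 2 * sub_blocks_per_condition * block_len_s

  structure(list(blocks = blocks, cues = cues, run_length_s = run_length_s,
                 tr = tr, lead_in_s = lead_in_s, block_len_s = block_len_s,
                 n_pairs = n_pairs,
                 sub_blocks_per_condition = sub_blocks_per_condition,
                 conditions = conditions),
            class = "block_design")
}

#' Number of volumes in a run
#' @param design A `block_design`.
#' @param trim_volumes Initial volumes discarded before analysis.
#' @return Integer volume count.
#' @export
n_volumes <- function(design, trim_volumes = 0) {
  as.integer(round(design$run_length_s / design$tr)) - trim_volumes
}

#' Condition phases of a block design
#'
#' Merges consecutive same-condition sub-blocks into condition phases
#' (the unit over which fluctuation and residual correlation are measured).
#'
#' @param design A `block_design`.
#' @return data.frame with columns condition, pair, onset, duration.
#' @export
design_phases <- function(design) {
  b <- design$blocks
  agg <- stats::aggregate(cbind(onset = b$onset) ~ condition + pair, data = b, FUN = min)
  agg$duration <- design$block_len_s * design$sub_blocks_per_condition
  agg <- agg[order(agg$onset), c("condition", "pair", "onset", "duration")]
  rownames(agg) <- NULL
  agg
}

# 1-based volume indices (into the trimmed series) of each phase,
# optionally dropping the first `block_trim` volumes of the phase.
phase_volume_indices <- function(design, trim_volumes = 0, block_trim = 0) {
  ph <- design_phases(design)
  tr <- design$tr
  lapply(seq_len(nrow(ph)), function(i) {
    v0 <- round(ph$onset[i] / tr)            # 0-based first volume of phase
    len <- round(ph$duration[i] / tr)
    idx <- (v0 + block_trim):(v0 + len - 1)  # 0-based, trimmed at block start
    idx <- idx - trim_volumes                # shift for discarded volumes
    idx <- idx[idx >= 0]
    idx + 1L
  })
}

#' Canonical double-gamma hemodynamic response function
#'
#' The conventional canonical HRF: a gamma density peaking about 5 s after
#' stimulus onset minus a later, smaller gamma undershoot. Sampled at the
#' repetition time and normalized.
#'
#' @param tr Sampling interval in seconds.
#' @param duration_s Kernel support in seconds.
#' @param peak Shape of the response gamma (delay parameter, s).
#' @param undershoot Shape of the undershoot gamma (s).
#' @param ratio Undershoot-to-peak amplitude ratio.
#' @param normalize `"sum"` (kernel sums to one, so convolving a constant
#'   returns the same constant) or `"peak"` (unit maximum).
#' @return Numeric kernel of length `duration_s / tr`.
#' @export
canonical_hrf <- function(tr, duration_s = 32, peak = 6, undershoot = 16,
                          ratio = 1 / 6, normalize = c("sum", "peak")) {
  stopifnot(tr > 0, duration_s > tr)
  normalize <- match.arg(normalize)
  t <- seq(0, by = tr, length.out = round(duration_s / tr))
  h <- stats::dgamma(t, shape = peak, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot, rate = 1)
  if (normalize == "sum") h / sum(h) else h / max(h)
}
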