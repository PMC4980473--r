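# The fluctuation index: a trial-variability measure in the spirit of the
# Fano factor. A component's band-passed time course is cut into
# same-condition blocks, the grand-average block response (over trials and
# subjects) is subtracted from each trial, and the standard deviation of a
# subject's residuals, divided by the grand-average response amplitude,
# gives that subject's index for the condition.

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward and backward
#' (zero phase); the mean is removed before and after filtering.
#'
#' @param x Time course.
#' @param tr Sampling interval in seconds.
#' @param low,high Band edges in Hz, `0 <= low < high <= ` Nyquist.
#' @return Filtered series of the same length.
#' @export
bandpass <- function(x, tr, low = 0.005, high = 0.1) {
  nyq <- 1 / (2 * tr)
  stopifnot(low >= 0, low < high, high <= nyq + 1e-12)
  if (length(x) < 24)
    stop("series too short for the band-pass filter warm-up (n = ",
         length(x), ")")
  bf <- signal::butter(4, c(low, high) / nyq, type = "pass")
  y <- signal::filtfilt(bf, x - mean(x))
  y - mean(y)
}

#' Extract same-condition block segments from a session time course
#'
#' @param tc Time course on the trimmed timeline (numeric vector).
#' @param design The `block_design`.
#' @param condition Condition label.
#' @param trim_volumes Volumes discarded at the start of the run.
#' @param block_trim Volumes dropped from the start of each block segment.
#' @return Matrix (blocks x segment length).
#' @export
extract_trials <- function(tc, design, condition, trim_volumes = 4,
                           block_trim = 4) {
  ph <- design_phases(design)
  idx <- phase_volume_indices(design, trim_volumes, block_trim)
  keep <- ph$condition == condition
  if (!any(keep)) stop("condition not present in design: ", condition)
  seg <- lapply(idx[keep], function(i) tc[i])
  len <- unique(lengths(seg))
  if (length(len) != 1) stop("condition blocks have unequal volume counts")
  do.call(rbind, seg)
}

#' Grand-average block response and its amplitude
#'
#' Averages all supplied trial segments (pooled over subjects and trials)
#' and returns the amplitude normalizer of the pooled response:
#' peak-to-trough range by default, or its standard deviation.
#'
#' @param trials Matrix (trials x segment length), all subjects pooled.
#' @param amplitude_mode `"range"` or `"sd"`.
#' @return List with `response` (segment-length vector) and `amplitude`.
#' @export
pooled_response <- function(trials, amplitude_mode = c("range", "sd")) {
  amplitude_mode <- match.arg(amplitude_mode)
  if (is.null(dim(trials)) || nrow(trials) == 0) stop("zero trials supplied")
  resp <- colMeans(trials)
  amp <- if (amplitude_mode == "range") diff(range(resp)) else stats::sd(resp)
  list(response = resp, amplitude = amp)
}

#' Fluctuation index of one subject's trials
#'
#' Subtracts the pooled response positionally from each trial segment,
#' takes the standard deviation over all residual time points, and divides
#' by the grand-average amplitude.
#'
#' @param trials Matrix (trials x segment length) for one subject.
#' @param pooled Pooled response vector (same segment length).
#' @param amplitude Grand-average signal amplitude (> 0).
#' @return The index (unitless, >= 0); `Inf` with a warning if
#'   `amplitude` is zero.
#' @export
fluctuation_index <- function(trials, pooled, amplitude) {
  stopifnot(ncol(trials) == length(pooled))
  resid <- sweep(trials, 2, pooled)
  s <- stats::sd(as.vector(t(resid)))
  if (amplitude == 0) {
    warning("zero grand-average amplitude; index is infinite")
    return(Inf)
  }
  s / amplitude
}

#' Fluctuation table for a cohort of component time courses
#'
#' Runs the full index workflow: band-pass each run's component time
#' course at the session level, extract condition blocks, pool the
#' grand-average block response over all subjects and trials per
#' condition, and compute the per-subject index. A subject's blocks from
#' all runs are concatenated before the residual sd is taken. The
#' amplitude normalizer is shared by both conditions of a component (the
#' peak-to-trough range across both pooled responses), so the
#' suppression/imagery index ratio reflects residual variability alone.
#'
#' @param tcs Nested list `tcs[[subject]][[run]]` of T x K time courses on
#'   the trimmed timeline.
#' @param design The `block_design`.
#' @param tr Sampling interval (defaults to the design's).
#' @param trim_volumes Volumes discarded at the start of each run.
#' @param block_trim Volumes dropped from the start of each block.
#' @param band Band-pass edges in Hz.
#' @param amplitude_mode Amplitude normalizer mode (see [pooled_response()]).
#' @return Object of class `fluctuation_table`: data.frame (subject,
#'   component, condition, index) with attributes `ratio` (subjects x
#'   components, suppression/imagery) and `amplitude` (per component and
#'   condition).
#' @export
fluctuation_table <- function(tcs, design, tr = design$tr, trim_volumes = 4,
                              block_trim = 4, band = c(0.005, 0.1),
                              amplitude_mode = "range") {
  n_sub <- length(tcs)
  K <- ncol(tcs[[1]][[1]])
  conds <- design$conditions
  rows <- list()
  ratio <- matrix(NA_real_, n_sub, K)
  amps <- matrix(NA_real_, K, 2, dimnames = list(NULL, conds))
  filtered <- lapply(tcs, function(runs) lapply(runs, function(tc)
    apply(tc, 2, bandpass, tr = tr, low = band[1], high = band[2])))
  for (k in seq_len(K)) {
    idx_val <- matrix(NA_real_, n_sub, 2, dimnames = list(NULL, conds))
    trials_by_cond <- pooled_by_cond <- list()
    for (cond in conds) {
      trials_by_cond[[cond]] <- lapply(seq_len(n_sub), function(s)
        do.call(rbind, lapply(filtered[[s]], function(tc)
          extract_trials(tc[, k], design, cond, trim_volumes, block_trim))))
      pooled_by_cond[[cond]] <-
        pooled_response(do.call(rbind, trials_by_cond[[cond]]), amplitude_mode)
    }
    # one amplitude per component: the typical response magnitude across
    # the whole task cycle, so the condition ratio reflects residual sd only
    both <- unlist(lapply(pooled_by_cond, `[[`, "response"))
    amp <- if (amplitude_mode == "range") diff(range(both)) else stats::sd(both)
    for (cond in conds) {
      amps[k, cond] <- amp
      for (s in seq_len(n_sub))
        idx_val[s, cond] <- fluctuation_index(trials_by_cond[[cond]][[s]],
                                              pooled_by_cond[[cond]]$response,
                                              amp)
    }
    ratio[, k] <- idx_val[, conds[2]] / idx_val[, conds[1]]
    rows[[k]] <- data.frame(subject = rep(seq_len(n_sub), 2),
                            component = k,
                            condition = rep(conds, each = n_sub),
                            index = c(idx_val[, conds[1]], idx_val[, conds[2]]))
  }
  tbl <- do.call(rbind, rows)
  attr(tbl, "ratio") <- ratio
  attr(tbl, "amplitude") <- amps
  attr(tbl, "conditions") <- conds
  class(tbl) <- c("fluctuation_table", "data.frame")
  tbl
}

#' Task comparison of fluctuation indices
#'
#' Paired two-sided t-test across subjects on log-converted indices,
#' suppression versus imagery, per component. Subjects with a zero index
#' in either condition are excluded with a warning count.
#'
#' @param tbl A `fluctuation_table`.
#' @return data.frame (component, t, p, n_excluded, geometric mean ratio).
#' @export
compare_conditions <- function(tbl) {
  conds <- attr(tbl, "conditions")
  comps <- sort(unique(tbl$component))
  out <- data.frame(component = comps, t = NA_real_, p = NA_real_,
                    n_excluded = 0L, gm_ratio = NA_real_)
  for (i in seq_along(comps)) {
    w <- tbl[tbl$component == comps[i], ]
    a <- w$index[w$condition == conds[2]]   # suppression
    b <- w$index[w$condition == conds[1]]   # imagery
    ok <- a > 0 & b > 0 & is.finite(a) & is.finite(b)
    out$n_excluded[i] <- sum(!ok)
    if (sum(ok) < 2) next
    d <- log(a[ok]) - log(b[ok])
    r <- safe_t_one(d)
    out$t[i] <- r$t
    out$p[i] <- r$p
    out$gm_ratio[i] <- exp(mean(d))
  }
  if (any(out$n_excluded > 0))
    warning(sum(out$n_excluded), " subject-component pairs with zero index excluded")
  out
}

#' Association of task-related fluctuation change with the self-report
#'
#' Two-sample two-sided t-test on log task-change ratios
#' (suppression index / imagery index) between the two self-report groups,
#' per component.
#'
#' @param ratio Subjects x components matrix of task-change ratios (the
#'   `ratio` attribute of a [fluctuation_table()]).
#' @param reports Binary self-report flag per subject.
#' @return data.frame (component, t, p).
#' @export
report_association <- function(ratio, reports) {
  ratio <- as.matrix(ratio)
  stopifnot(nrow(ratio) == length(reports))
  g <- unique(reports)
  if (length(g) < 2) stop("both self-report groups must be non-empty")
  K <- ncol(ratio)
  out <- data.frame(component = seq_len(K), t = NA_real_, p = NA_real_)
  for (k in seq_len(K)) {
    x <- log(ratio[reports == 1, k])
    y <- log(ratio[reports == 0, k])
    tt <- stats::t.test(x, y)
    out$t[k] <- unname(tt$statistic)
    out$p[k] <- tt$p.value
  }
  out
}
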