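# Between-component residual-correlation coupling: block-wise Pearson
# correlation on band-passed, per-block detrended time courses, Fisher-Z
# pooling over trials, per-task group tests, and a polarity label.

#' Block-wise residual correlation between two time courses
#'
#' Both series are band-pass filtered at the session level, cut into
#' same-condition blocks with the first `trim_volumes` volumes of each
#' block discarded (the cue/transition response), linearly detrended per
#' block, and correlated.
#'
#' @param tc_a,tc_b Time courses of equal length on the trimmed timeline.
#' @param design The `block_design`.
#' @param trim_volumes Volumes dropped from the start of each block.
#' @param run_trim Volumes discarded at the start of the run (timeline
#'   offset).
#' @param tr Sampling interval in seconds.
#' @param band Band-pass edges in Hz.
#' @return data.frame (block, condition, r); `r` is NA for a
#'   zero-variance segment.
#' @export
block_residual_r <- function(tc_a, tc_b, design, trim_volumes = 4,
                             run_trim = 4, tr = design$tr,
                             band = c(0.005, 0.1)) {
  stopifnot(length(tc_a) == length(tc_b))
  fa <- bandpass(tc_a, tr, band[1], band[2])
  fb <- bandpass(tc_b, tr, band[1], band[2])
  ph <- design_phases(design)
  idx <- phase_volume_indices(design, run_trim, trim_volumes)
  if (any(lengths(idx) <= 3))
    stop("blocks must retain more than 3 volumes after trimming")
  r <- vapply(idx, function(i) {
    a <- detrend_linear(fa[i])
    b <- detrend_linear(fb[i])
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, 0)
  data.frame(block = seq_along(r), condition = ph$condition, r = r)
}

#' Fisher-Z pooling and per-task group tests
#'
#' Converts block correlations to Fisher Z, averages over trials within
#' subject per task, runs a one-sample two-sided t-test across subjects
#' per task, and a paired two-sided t-test between tasks.
#'
#' @param r_by_subject List (one entry per subject) of data.frames as
#'   returned by [block_residual_r()]; blocks from all of a subject's runs
#'   concatenated.
#' @param conditions The two task labels (imagery first).
#' @return List with `per_task` (data.frame: task, mean_z, t, p, n),
#'   `paired` (t, p), `subject_z` (subjects x 2), `n_clipped`.
#' @export
pool_and_test <- function(r_by_subject,
                          conditions = c("imagery", "suppression")) {
  n_sub <- length(r_by_subject)
  if (n_sub < 3) stop("at least 3 subjects required")
  Z <- matrix(NA_real_, n_sub, 2, dimnames = list(NULL, conditions))
  n_clipped <- 0
  for (s in seq_len(n_sub)) {
    df <- r_by_subject[[s]]
    for (cond in conditions) {
      rr <- df$r[df$condition == cond & !is.na(df$r)]
      if (length(rr) == 0) stop("subject ", s, " has no valid block for ", cond)
      fz <- fisher_z(rr)
      n_clipped <- n_clipped + fz$n_clipped
      Z[s, cond] <- mean(fz$z)
    }
  }
  per_task <- data.frame(task = conditions, mean_z = NA_real_,
                         t = NA_real_, p = NA_real_, n = n_sub)
  for (i in 1:2) {
    r <- safe_t_one(Z[, i])
    per_task$mean_z[i] <- r$mean
    per_task$t[i] <- r$t
    per_task$p[i] <- r$p
  }
  pr <- safe_t_one(Z[, 2] - Z[, 1])
  if (n_clipped > 0)
    warning(n_clipped, " correlations clipped at |r| = 1 - 1e-6")
  list(per_task = per_task, paired = list(t = pr$t, p = pr$p),
       subject_z = Z, n_clipped = n_clipped)
}

#' Polarity label from pooled per-task statistics
#'
#' A pair is labelled `positive` (`negative`) only if its correlation is
#' significantly non-zero during both tasks with consistently positive
#' (negative) mean Z; anything else, including sign-discordant
#' significance, is `equivocal`.
#'
#' @param pooled Result of [pool_and_test()].
#' @param alpha Two-sided significance level per task.
#' @return Character label.
#' @export
label_pairs <- function(pooled, alpha = 0.05) {
  pt <- pooled$per_task
  sig <- pt$p < alpha
  if (all(sig) && all(pt$mean_z > 0)) return("positive")
  if (all(sig) && all(pt$mean_z < 0)) return("negative")
  "equivocal"
}

#' Coupling table: a reference component against all others
#'
#' For every other component, computes block-wise residual correlations
#' with the reference component's time course per subject (runs
#' concatenated), pools and tests them, and applies the polarity rule.
#'
#' @param tcs Nested list `tcs[[subject]][[run]]` of T x K time courses.
#' @param design The `block_design`.
#' @param reference Index of the reference component.
#' @param alpha Significance level for the polarity rule.
#' @param components Components to pair with the reference (default: all
#'   others).
#' @param ... Passed to [block_residual_r()].
#' @return Object of class `coupling_table`: data.frame with one row per
#'   (pair, task) carrying mean Z, t, p, plus per-pair paired-test p and
#'   label.
#' @export
coupling_table <- function(tcs, design, reference, alpha = 0.05,
                           components = NULL, ...) {
  K <- ncol(tcs[[1]][[1]])
  components <- components %||% setdiff(seq_len(K), reference)
  rows <- list()
  for (k in components) {
    r_by_subject <- lapply(tcs, function(runs) {
      do.call(rbind, lapply(runs, function(tc)
        block_residual_r(tc[, reference], tc[, k], design, ...)))
    })
    pooled <- pool_and_test(r_by_subject, design$conditions)
    lab <- label_pairs(pooled, alpha)
    pt <- pooled$per_task
    rows[[length(rows) + 1]] <-
      data.frame(reference = reference, component = k, task = pt$task,
                 mean_z = pt$mean_z, t = pt$t, p = pt$p,
                 paired_p = pooled$paired$p, label = lab)
  }
  tbl <- do.call(rbind, rows)
  class(tbl) <- c("coupling_table", "data.frame")
  tbl
}
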