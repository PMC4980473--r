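# Task-relatedness of component time courses: a random-effects regression
# analysis (per-subject GLM on the block/cue design followed by a group
# t-test on the imagery-minus-suppression contrast) and a pooled-cycle
# two-sample analysis.

#' Build the block/cue design matrix
#'
#' Eight task regressors at volume resolution: four HRF-convolved epoch
#' boxcars (one per condition sub-block type, e.g. imagery sub-block 1,
#' imagery sub-block 2, suppression sub-block 1, suppression sub-block 2)
#' and four HRF-convolved zero-duration cue impulses, one per epoch type's
#' onsets. The first `trim_volumes` rows are dropped, matching the
#' discarded initial volumes of each run.
#'
#' @param design A `block_design`.
#' @param hrf HRF kernel sampled at `design$tr`.
#' @param trim_volumes Initial volumes discarded.
#' @return T x 8 matrix of class `design_matrix` with named columns and
#'   attributes `imagery_cols`, `suppression_cols`, `tr`.
#' @export
build_design_matrix <- function(design, hrf = canonical_hrf(design$tr),
                                trim_volumes = 4) {
  stopifnot(trim_volumes >= 0)
  T_n <- n_volumes(design)
  tr <- design$tr
  b <- design$blocks
  epochs <- expand.grid(sub_index = seq_len(design$sub_blocks_per_condition),
                        condition = design$conditions,
                        stringsAsFactors = FALSE)
  cols <- list()
  for (i in seq_len(nrow(epochs))) {
    sel <- b$condition == epochs$condition[i] & b$sub_index == epochs$sub_index[i]
    if (!any(sel))
      stop("epoch type absent from design: ", epochs$condition[i],
           " sub-block ", epochs$sub_index[i])
    box <- imp <- rep(0, T_n)
    for (j in which(sel)) {
      v0 <- round(b$onset[j] / tr)
      len <- round(b$duration[j] / tr)
      box[(v0 + 1):(v0 + len)] <- 1
      imp[v0 + 1] <- 1
    }
    cols[[paste(epochs$condition[i], epochs$sub_index[i], sep = "_")]] <-
      convolve_hrf(box, hrf)
    cols[[paste("cue", epochs$condition[i], epochs$sub_index[i], sep = "_")]] <-
      convolve_hrf(imp, hrf)
  }
  X <- do.call(cbind, cols)
  epoch_names <- paste(epochs$condition, epochs$sub_index, sep = "_")
  X <- X[, c(epoch_names, paste0("cue_", epoch_names)), drop = FALSE]
  if (trim_volumes > 0) X <- X[-seq_len(trim_volumes), , drop = FALSE]
  if (any(colSums(abs(X)) == 0)) stop("design matrix has an all-zero column")
  structure(X, class = c("design_matrix", "matrix"),
            imagery_cols = paste(design$conditions[1],
                                 seq_len(design$sub_blocks_per_condition), sep = "_"),
            suppression_cols = paste(design$conditions[2],
                                     seq_len(design$sub_blocks_per_condition), sep = "_"),
            tr = tr)
}

# OLS coefficients for all columns of y on X plus an internal intercept.
ols_betas <- function(X, y) {
  Xa <- cbind(X, intercept = 1)
  qx <- qr(Xa)
  if (qx$rank < ncol(Xa)) {
    kap <- kappa(crossprod(Xa), exact = TRUE)
    stop("singular design matrix (condition number ", format(kap, digits = 3), ")")
  }
  qr.coef(qx, y)
}

#' Per-subject regression with group test on the condition contrast
#'
#' For every component: each subject/run time course is modelled by
#' ordinary least squares on the design matrix (plus an internal
#' intercept, excluded from contrasts); run-wise coefficient sets are
#' averaged within subject; the contrast is the mean of the imagery epoch
#' coefficients minus the mean of the suppression epoch coefficients; a
#' two-sided one-sample t-test across subjects tests the contrast against
#' zero.
#'
#' @param tcs Nested list `tcs[[subject]][[run]]` of T x K component time
#'   courses, rows matching the design matrix.
#' @param X A `design_matrix`.
#' @return Object of class `task_relatedness`: list with `delta_beta`
#'   (subjects x components), `t`, `p` (per component), `n_subjects`.
#' @export
analysis1 <- function(tcs, X) {
  n_sub <- length(tcs)
  if (n_sub < 3) stop("analysis1 requires at least 3 subjects")
  K <- ncol(tcs[[1]][[1]])
  img <- attr(X, "imagery_cols")
  sup <- attr(X, "suppression_cols")
  db <- matrix(NA_real_, n_sub, K)
  for (s in seq_len(n_sub)) {
    bs <- lapply(tcs[[s]], function(tc) ols_betas(unclass(X), tc))
    beta <- Reduce(`+`, bs) / length(bs)     # average runs within subject
    db[s, ] <- colMeans(beta[img, , drop = FALSE]) -
      colMeans(beta[sup, , drop = FALSE])
  }
  t_v <- p_v <- numeric(K)
  for (k in seq_len(K)) {
    r <- safe_t_one(db[, k])
    t_v[k] <- r$t
    p_v[k] <- r$p
  }
  structure(list(delta_beta = db, t = t_v, p = p_v, n_subjects = n_sub),
            class = "task_relatedness")
}

#' Pooled-cycle two-sample task test
#'
#' Folds all subjects, runs, and block pairs onto a single
#' imagery-plus-suppression cycle by averaging, then compares the
#' imagery-phase samples of the pooled cycle against the
#' suppression-phase samples with a two-sided two-sample t-test.
#'
#' @param tcs Nested list of T x K time courses on the trimmed timeline.
#' @param design The `block_design`.
#' @param trim_volumes Volumes discarded at the start of each run (the
#'   offset of the trimmed timeline).
#' @param exclude_cue_volumes Volumes dropped from the start of each phase
#'   before entering the test (0 keeps all, so the default full 48-s
#'   phases contribute 24 samples each at TR 2).
#' @return List with per-component `t`, `p`, the pooled `cycle`
#'   (cycle-length x K), and the per-phase sample counts.
#' @export
analysis2 <- function(tcs, design, trim_volumes = 4, exclude_cue_volumes = 0) {
  tr <- design$tr
  phase_len <- round(design$block_len_s * design$sub_blocks_per_condition / tr)
  cycle_len <- 2 * phase_len
  K <- ncol(tcs[[1]][[1]])
  T_trim <- n_volumes(design, trim_volumes)
  acc <- matrix(0, cycle_len, K)
  n_seg <- 0
  for (s in seq_along(tcs)) for (r in seq_along(tcs[[s]])) {
    tc <- tcs[[s]][[r]]
    if (nrow(tc) != T_trim)
      stop("run time course length ", nrow(tc),
           " does not match the trimmed design length ", T_trim,
           "; unequal cycle lengths are not supported")
    for (p in seq_len(design$n_pairs)) {
      v0 <- round((design$lead_in_s + (p - 1) * cycle_len * tr) / tr) - trim_volumes
      idx <- v0 + seq_len(cycle_len)
      if (any(idx < 1) || any(idx > nrow(tc))) next
      acc <- acc + tc[idx, , drop = FALSE]
      n_seg <- n_seg + 1
    }
  }
  if (n_seg < 2) stop("fewer than 2 full cycles available")
  cycle <- acc / n_seg
  keep1 <- setdiff(seq_len(phase_len), seq_len(exclude_cue_volumes))
  keep2 <- setdiff(phase_len + seq_len(phase_len),
                   phase_len + seq_len(exclude_cue_volumes))
  t_v <- p_v <- numeric(K)
  for (k in seq_len(K)) {
    a <- cycle[keep1, k]
    b <- cycle[keep2, k]
    tt <- stats::t.test(a, b)
    t_v[k] <- unname(tt$statistic)
    p_v[k] <- tt$p.value
  }
  list(t = t_v, p = p_v, cycle = cycle,
       n_imagery = length(keep1), n_suppression = length(keep2),
       n_segments = n_seg)
}
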