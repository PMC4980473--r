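# Reference voxelwise GLM: one condition-contrast regressor plus
# onset/cue nuisance regressors per run, random-effects group t-test on
# the per-subject contrast images, Bonferroni-corrected over in-mask
# voxels.

#' GLM design: condition contrast plus nuisance onset regressors
#'
#' A single regressor modelling the signal change between the two
#' conditions (imagery boxcar minus suppression boxcar, HRF-convolved)
#' and HRF-convolved zero-duration onset regressors of no interest, one
#' per condition's block onsets. A slot for motion regressors is accepted
#' but unused for synthetic data.
#'
#' @param design The `block_design`.
#' @param hrf HRF kernel.
#' @param trim_volumes Initial volumes discarded.
#' @param motion Optional T x m matrix of motion regressors (rows on the
#'   trimmed timeline).
#' @return T x p matrix; column 1 (`contrast`) is the regressor of
#'   interest.
#' @export
build_glm_design <- function(design, hrf = canonical_hrf(design$tr),
                             trim_volumes = 4, motion = NULL) {
  T_n <- n_volumes(design)
  tr <- design$tr
  b <- design$blocks
  box <- rep(0, T_n)
  ons <- list()
  for (cond in design$conditions) {
    sel <- b$condition == cond
    imp <- rep(0, T_n)
    for (j in which(sel)) {
      v0 <- round(b$onset[j] / tr)
      len <- round(b$duration[j] / tr)
      # +/- 0.5 coding: the coefficient is the imagery-minus-suppression
      # signal change itself
      box[(v0 + 1):(v0 + len)] <- box[(v0 + 1):(v0 + len)] +
        if (cond == design$conditions[1]) 0.5 else -0.5
      imp[v0 + 1] <- 1
    }
    ons[[paste0("onset_", cond)]] <- convolve_hrf(imp, hrf)
  }
  X <- cbind(contrast = convolve_hrf(box, hrf), do.call(cbind, ons))
  if (trim_volumes > 0) X <- X[-seq_len(trim_volumes), , drop = FALSE]
  if (!is.null(motion)) {
    if (nrow(motion) != nrow(X)) stop("motion regressors do not match the trimmed run length")
    X <- cbind(X, motion)
  }
  X
}

#' Voxelwise GLM with random-effects group test
#'
#' Per subject/run ordinary least squares at every analyzed voxel with the
#' contrast regressor and nuisance onset regressors (plus an intercept);
#' run-wise contrast estimates are averaged within subject; a one-sample
#' t-test across subjects is computed per voxel and thresholded at
#' `alpha`, Bonferroni-corrected over the in-mask voxels.
#'
#' @param data Nested list `data[[subject]][[run]]` of T x V matrices
#'   (trimmed timeline).
#' @param X GLM design from [build_glm_design()] (contrast in column 1).
#' @param mask Logical mask over the V voxels; the group test and the
#'   correction are restricted to in-mask voxels.
#' @param alpha Family-wise error level.
#' @return List with `t_map`, `p_map` (length V, NA outside the mask),
#'   `detected` (in-mask voxel indices surviving correction),
#'   `n_detected`, `contrast` (subjects x V), `bonferroni_threshold`.
#' @export
voxelwise_glm <- function(data, X, mask = NULL, alpha = 0.05) {
  n_sub <- length(data)
  V <- ncol(data[[1]][[1]])
  mask <- if (is.null(mask)) rep(TRUE, V) else as.vector(mask)
  T_n <- nrow(X)
  Xa <- cbind(X, intercept = 1)
  H <- solve(crossprod(Xa), t(Xa))       # p x T, shared across runs/voxels
  contrast <- matrix(NA_real_, n_sub, V)
  for (s in seq_len(n_sub)) {
    acc <- NULL
    for (r in seq_along(data[[s]])) {
      Y <- data[[s]][[r]]
      if (nrow(Y) != T_n)
        stop("subject ", s, " run ", r, ": ", nrow(Y),
             " volumes do not match the design (", T_n, ")")
      beta_c <- (H %*% Y)[1, ]
      acc <- if (is.null(acc)) beta_c else acc + beta_c
    }
    contrast[s, ] <- acc / length(data[[s]])
  }
  mu <- colMeans(contrast)
  sdv <- apply(contrast, 2, stats::sd)
  t_map <- mu / (sdv / sqrt(n_sub))
  p_map <- 2 * stats::pt(-abs(t_map), df = n_sub - 1)
  t_map[!mask] <- NA
  p_map[!mask] <- NA
  n_mask <- sum(mask)
  thr <- alpha / n_mask
  detected <- which(mask & !is.na(p_map) & p_map < thr)
  list(t_map = t_map, p_map = p_map, detected = detected,
       n_detected = length(detected), contrast = contrast,
       bonferroni_threshold = thr, n_mask = n_mask)
}
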