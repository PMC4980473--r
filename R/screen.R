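# Operational artifact screening of components: spectral content
# (low-frequency power ratio) and spatial plausibility (involvement
# outside the brain mask).

#' Low-frequency power ratio of a time course
#'
#' Ratio of summed periodogram power in a low-frequency band to summed
#' power in a high-frequency band. Component time courses dominated by
#' high-frequency power (low ratio) are characteristic of motion,
#' physiological, or scanner artifacts rather than hemodynamic signals.
#' The raw (untapered) periodogram of the demeaned series is used; band
#' membership is inclusive on both edges.
#'
#' @param x Time course (length >= 64).
#' @param tr Sampling interval in seconds.
#' @param low_band,high_band Frequency bands in Hz, within (0, Nyquist].
#' @return The power ratio; `Inf` if the high band carries zero power.
#' @export
lfpr <- function(x, tr, low_band = c(0.003, 0.10), high_band = c(0.15, 0.25)) {
  n <- length(x)
  if (n < 64) stop("time course too short for spectral screening (n = ", n, ")")
  stopifnot(tr > 0)
  nyq <- 1 / (2 * tr)
  for (b in list(low_band, high_band))
    if (length(b) != 2 || b[1] <= 0 || b[2] > nyq + 1e-12 || b[1] >= b[2])
      stop("bands must be ordered and lie within (0, Nyquist]")
  if (low_band[2] >= high_band[1])
    stop("low and high bands overlap or are inverted")
  xc <- x - mean(x)
  p <- Mod(stats::fft(xc))^2
  kk <- seq_len(floor(n / 2))
  freq <- kk / (n * tr)
  tol <- 1e-12
  low <- sum(p[kk + 1][freq >= low_band[1] - tol & freq <= low_band[2] + tol])
  high <- sum(p[kk + 1][freq >= high_band[1] - tol & freq <= high_band[2] + tol])
  # a numerically-zero denominator (below fft round-off of the total
  # power) is reported as the infinite sentinel
  if (high <= sum(p[kk + 1]) * 1e-14) return(Inf)
  low / high
}

#' Screen components for artifactual origin
#'
#' Computes the low-frequency power ratio of every back-projected
#' subject/run time course of each component, aggregates by arithmetic
#' mean, and combines it with a spatial screen: the fraction of
#' suprathreshold (|z| > `z_threshold`) voxels lying outside the brain
#' mask. A component dominated by out-of-mask voxels is labelled
#' `artifact_spatial` regardless of its spectrum; otherwise mean ratios
#' below the lower threshold give `artifact_spectral`, ratios between the
#' thresholds give `suspicious` (retained downstream), and the rest are
#' `valid`.
#'
#' @param cs A `component_set` from [group_ica()].
#' @param mask Logical brain mask over the analyzed voxels (or NULL to
#'   skip the spatial screen with a warning).
#' @param tr Sampling interval in seconds.
#' @param lfpr_thresholds Two thresholds: clear-artifact and suspicious.
#' @param z_threshold Map z threshold for the spatial screen.
#' @param spatial_threshold Maximum tolerated out-of-mask fraction.
#' @param low_band,high_band Spectral bands passed to [lfpr()].
#' @return Object of class `screen_report`: data.frame with per-component
#'   `lfpr_mean`, `nonbrain_fraction`, `label`, plus attribute
#'   `lfpr_per_subject` (list of per-run values).
#' @export
screen_components <- function(cs, mask, tr,
                              lfpr_thresholds = c(3.0, 3.5),
                              z_threshold = 2, spatial_threshold = 0.5,
                              low_band = c(0.003, 0.10),
                              high_band = c(0.15, 0.25)) {
  K <- cs$model_order
  spatial_ok <- !is.null(mask)
  if (!spatial_ok)
    warning("no brain mask supplied; spatial screen skipped")
  per_subj <- vector("list", K)
  lfpr_mean <- nonbrain <- numeric(K)
  label <- character(K)
  for (k in seq_len(K)) {
    vals <- unlist(lapply(cs$subject_timecourses, function(runs)
      vapply(runs, function(tc) lfpr(tc[, k], tr, low_band, high_band), 0)))
    per_subj[[k]] <- vals
    lfpr_mean[k] <- mean(vals)
    if (spatial_ok) {
      zs <- zscore_map(cs$group_maps[, k], mask, z_threshold)
      supra <- zs$supra
      nonbrain[k] <- if (length(supra) == 0) 0 else
        sum(!as.vector(mask)[supra]) / length(supra)
    } else nonbrain[k] <- NA_real_
    label[k] <- if (spatial_ok && nonbrain[k] > spatial_threshold)
      "artifact_spatial"
    else if (lfpr_mean[k] < lfpr_thresholds[1]) "artifact_spectral"
    else if (lfpr_mean[k] < lfpr_thresholds[2]) "suspicious"
    else "valid"
  }
  rep <- data.frame(component = seq_len(K), lfpr_mean = lfpr_mean,
                    nonbrain_fraction = nonbrain, label = label)
  attr(rep, "lfpr_per_subject") <- per_subj
  attr(rep, "spatial_screen") <- spatial_ok
  class(rep) <- c("screen_report", "data.frame")
  rep
}

#' Write a screen report as TSV and JSON
#' @param report A `screen_report`.
#' @param path_tsv,path_json Output paths (NULL to skip).
#' @return Invisibly, the report.
#' @export
write_screen_report <- function(report, path_tsv = NULL, path_json = NULL) {
  if (!is.null(path_tsv)) write_tsv(as.data.frame(report), path_tsv)
  if (!is.null(path_json))
    jsonlite::write_json(list(summary = as.data.frame(report),
                              lfpr_per_subject = attr(report, "lfpr_per_subject")),
                         path_json, digits = NA, auto_unbox = TRUE)
  invisible(report)
}
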