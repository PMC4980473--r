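#' Specification of one ground-truth component
#'
#' Describes a single source in the synthetic cohort: a compact spatial map
#' plus the statistical structure of its time course. Network components
#' carry a condition-dependent baseline (activation level), a
#' condition-dependent within-block fluctuation standard deviation, and
#' optional signed latent couplings of that fluctuation with other
#' components. Artifact components instead carry band-limited noise in a
#' stated spectral band and must have no baseline and no coupling.
#'
#' @param name Component name (unique within a spec list).
#' @param centers Matrix (n x 3) of 0-based blob centres for the map.
#' @param sigma Blob width in voxels.
#' @param baseline Named list mapping condition label to mean amplitude;
#'   each entry may be a vector with one value per sub-block (recycled).
#' @param fluct_sd Named numeric: stationary within-block fluctuation sd per
#'   condition; all values must be >= 0.
#' @param coupling Named numeric: signed latent coupling weight in [-1, 1]
#'   keyed by partner component name.
#' @param spectral_band NULL, or c(low_hz, high_hz) marking an artifact
#'   component whose time course is band-limited noise.
#' @param artifact_sd Time-course sd for an artifact component.
#' @param control Logical; the designated control component whose
#'   suppression/imagery fluctuation ratio drives the simulated self-report.
#' @return Object of class `component_spec`.
#' @export
component_spec <- function(name, centers, sigma = 1.8,
                           baseline = list(imagery = 0, suppression = 0),
                           fluct_sd = c(imagery = 0, suppression = 0),
                           coupling = numeric(0),
                           spectral_band = NULL,
                           artifact_sd = 1,
                           control = FALSE) {
  stopifnot(is.character(name), length(name) == 1)
  if (any(fluct_sd < 0)) stop("fluct_sd values must be >= 0")
  if (length(coupling) && any(abs(coupling) > 1))
    stop("|coupling| must be <= 1")
  if (!is.null(spectral_band)) {
    stopifnot(length(spectral_band) == 2, spectral_band[1] < spectral_band[2])
    if (any(unlist(baseline) != 0) || length(coupling))
      stop("an artifact component must have empty baseline and coupling")
  }
  structure(list(name = name, centers = matrix(centers, ncol = 3),
                 sigma = sigma, baseline = baseline, fluct_sd = fluct_sd,
                 coupling = coupling, spectral_band = spectral_band,
                 artifact_sd = artifact_sd, control = control),
            class = "component_spec")
}

#' Default component specifications for the synthetic cohort
#'
#' Eight network components plus two artifact components on the default
#' 16 x 16 x 8 grid, emulating the qualitative structure reported for the
#' imagery/suppression experiment: a suppression-active frontoparietal
#' network and an imagery-active network whose within-block fluctuation
#' doubles during suppression and which are negatively coupled to each
#' other; an executive-control ("control") component whose fluctuation
#' ratio drives the simulated self-report and which is positively coupled
#' to the suppression network; an imagery-active posterior default-mode
#' component whose fluctuation instead decreases during suppression;
#' visual, attention and task-null components; and two high-frequency
#' artifact components, one of them centred outside the brain mask.
#'
#' @param fluct_low Baseline within-block fluctuation sd.
#' @param fluct_ratio Suppression/imagery fluctuation-sd ratio injected in
#'   the suppression, imagery and control networks.
#' @param coupling_strength Magnitude of the injected latent couplings.
#' @param amplitude Condition baseline shift (arbitrary units).
#' @return Named list of `component_spec` objects.
#' @export
default_component_specs <- function(fluct_low = 0.5, fluct_ratio = 2,
                                    coupling_strength = 0.6, amplitude = 1) {
  fh <- fluct_low * fluct_ratio
  w <- coupling_strength
  specs <- list(
    component_spec("supp_net",
                   centers = rbind(c(11, 11, 4), c(4, 11, 4)),
                   baseline = list(imagery = 0, suppression = amplitude),
                   fluct_sd = c(imagery = fluct_low, suppression = fh),
                   coupling = c(img_net = -w, ecn = w)),
    component_spec("img_net",
                   centers = rbind(c(4, 4, 4), c(11, 4, 4)),
                   baseline = list(imagery = amplitude, suppression = 0),
                   fluct_sd = c(imagery = fluct_low, suppression = fh)),
    component_spec("ecn",
                   centers = rbind(c(7.5, 13.5, 3.5)),
                   baseline = list(imagery = 0.3 * amplitude, suppression = 0),
                   fluct_sd = c(imagery = fluct_low, suppression = fh),
                   control = TRUE),
    component_spec("dan",
                   centers = rbind(c(7.5, 1.5, 3.5)),
                   baseline = list(imagery = 0.8 * amplitude, suppression = 0),
                   fluct_sd = c(imagery = fluct_low, suppression = fluct_low)),
    component_spec("dmn_post",
                   centers = rbind(c(7.5, 7.5, 0.5)),
                   baseline = list(imagery = 0.4 * amplitude, suppression = 0),
                   fluct_sd = c(imagery = 0.8 * fluct_low / 0.5,
                                suppression = 0.4 * fluct_low / 0.5)),
    component_spec("v1",
                   centers = rbind(c(7.5, 7.5, 6.5)),
                   baseline = list(imagery = 0.6 * amplitude, suppression = 0),
                   fluct_sd = c(imagery = fluct_low, suppression = fluct_low)),
    component_spec("mog",
                   centers = rbind(c(2, 7.5, 3.5)),
                   baseline = list(imagery = 0, suppression = 0.25 * amplitude),
                   fluct_sd = c(imagery = fluct_low, suppression = fluct_low)),
    component_spec("motor",
                   centers = rbind(c(13, 7.5, 3.5)),
                   baseline = list(imagery = 0, suppression = 0),
                   fluct_sd = c(imagery = 1.6 * fluct_low,
                                suppression = 1.6 * fluct_low)),
    component_spec("art_hf",
                   centers = rbind(c(11, 7.5, 0.5)),
                   sigma = 1.5,
                   spectral_band = c(0.15, 0.25)),
    component_spec("art_edge",
                   centers = rbind(c(0, 0, 0), c(15, 0, 0), c(0, 15, 7), c(15, 15, 7)),
                   sigma = 1.2,
                   spectral_band = c(0.15, 0.25))
  )
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

is_artifact_spec <- function(spec) !is.null(spec$spectral_band)
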