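# Ground-truth time-course and cohort simulation.
#
# Each network component's time course is the sum of (a) an HRF-convolved
# condition baseline and (b) a within-block fluctuation process: an AR(1)
# recursion (coefficient `ar_coef`) restarted at every condition-phase
# boundary and scaled to a condition-specific stationary sd. Fluctuation
# innovations are drawn from shared standard-normal latent streams so that
# the latent correlation between coupled components equals the signed
# coupling weight exactly in expectation. Artifact components carry
# band-limited Gaussian noise confined to their spectral band.

# Build the latent correlation matrix implied by the pairwise couplings.
coupling_matrix <- function(specs) {
  net <- specs[!vapply(specs, is_artifact_spec, TRUE)]
  k <- length(net)
  nm <- vapply(net, `[[`, "", "name")
  C <- diag(k)
  dimnames(C) <- list(nm, nm)
  for (i in seq_len(k)) {
    cp <- net[[i]]$coupling
    for (partner in names(cp)) {
      if (!partner %in% nm)
        stop("coupling partner '", partner, "' is not a network component")
      j <- match(partner, nm)
      w <- unname(cp[partner])
      if (C[i, j] != 0 && i != j && C[i, j] != w && C[j, i] != w)
        stop("coupling between '", nm[i], "' and '", partner,
             "' is specified twice with different weights; not symmetrizable")
      C[i, j] <- w
      C[j, i] <- w
    }
  }
  if (k == 0) return(list(C = C, chol = C, names = character(0)))
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch))
    stop("coupling matrix is not positive definite; not symmetrizable")
  list(C = C, chol = ch, names = nm)
}

# Band-limited Gaussian noise via Fourier masking, scaled to unit sd.
band_limited_noise <- function(n, tr, band) {
  z <- stats::rnorm(n)
  X <- stats::fft(z)
  freq <- (0:(n - 1)) / (n * tr)
  freq <- pmin(freq, 1 / tr - freq)  # fold to [0, Nyquist]
  keep <- freq >= band[1] & freq <= band[2]
  X[!keep] <- 0
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Simulate ground-truth component time courses for one run
#'
#' @param design A `block_design`.
#' @param specs List of `component_spec` objects.
#' @param subject_id Subject index (bookkeeping only).
#' @param seed Integer seed for this run's random streams.
#' @param sd_scale Optional named-matrix (component x condition) of
#'   multiplicative per-subject scalings of `fluct_sd`.
#' @param hrf HRF kernel sampled at `design$tr`.
#' @param ar_coef AR(1) coefficient of the within-block fluctuation process.
#' @return List with `timecourses` (T x K), `baseline` (T x K),
#'   `fluct` (T x K latent fluctuation record, the exact injected
#'   residuals), and `realized_sd` (component x condition realized target sd).
#' @export
simulate_timecourses <- function(design, specs, subject_id = 1, seed = 1,
                                 sd_scale = NULL,
                                 hrf = canonical_hrf(design$tr),
                                 ar_coef = 0.5) {
  stopifnot(length(specs) > 0, inherits(design, "block_design"))
  set.seed(seed)
  T_n <- n_volumes(design)
  tr <- design$tr
  K <- length(specs)
  nm <- vapply(specs, `[[`, "", "name")

  cm <- coupling_matrix(specs)
  knet <- length(cm$names)
  ph <- design_phases(design)
  phase_idx <- phase_volume_indices(design)

  # Correlated innovations for all network components (T x knet).
  U <- matrix(0, T_n, knet, dimnames = list(NULL, cm$names))
  if (knet > 0) {
    E <- matrix(stats::rnorm(T_n * knet), T_n, knet) %*% cm$chol
    colnames(E) <- cm$names
    # AR(1) with unit stationary variance, restarted at each phase boundary.
    for (p in seq_along(phase_idx)) {
      idx <- phase_idx[[p]]
      u <- E[idx, , drop = FALSE]
      for (t in seq_along(idx)[-1])
        u[t, ] <- ar_coef * u[t - 1, ] + sqrt(1 - ar_coef^2) * u[t, ]
      U[idx, ] <- u
    }
  }

  # Per-volume condition label (NA in the lead-in).
  cond_at <- rep(NA_character_, T_n)
  for (p in seq_along(phase_idx)) cond_at[phase_idx[[p]]] <- ph$condition[p]

  tc <- base <- fl <- matrix(0, T_n, K, dimnames = list(NULL, nm))
  realized_sd <- matrix(NA_real_, K, 2,
                        dimnames = list(nm, design$conditions))
  for (k in seq_len(K)) {
    sp <- specs[[k]]
    if (is_artifact_spec(sp)) {
      tc[, k] <- sp$artifact_sd * band_limited_noise(T_n, tr, sp$spectral_band)
      next
    }
    # baseline boxcar per sub-block, HRF convolved
    box <- rep(0, T_n)
    b <- design$blocks
    for (i in seq_len(nrow(b))) {
      vals <- rep(sp$baseline[[b$condition[i]]],
                  length.out = design$sub_blocks_per_condition)
      v0 <- round(b$onset[i] / tr)
      len <- round(b$duration[i] / tr)
      box[(v0 + 1):(v0 + len)] <- vals[b$sub_index[i]]
    }
    base[, k] <- convolve_hrf(box, hrf)

    sdv <- rep(0, T_n)
    for (cond in design$conditions) {
      s <- unname(sp$fluct_sd[cond])
      if (!is.null(sd_scale)) s <- s * sd_scale[sp$name, cond]
      sdv[!is.na(cond_at) & cond_at == cond] <- s
      realized_sd[k, cond] <- s
    }
    fl[, k] <- sdv * U[, sp$name]
    tc[, k] <- base[, k] + fl[, k]
  }
  list(timecourses = tc, baseline = base, fluct = fl,
       realized_sd = realized_sd, subject_id = subject_id, seed = seed)
}

#' Simulate a full synthetic cohort
#'
#' Generates ground truth for `n_subjects` x `n_runs` runs on a common
#' spatial grid: component maps, per-run time courses with per-subject
#' fluctuation variability, and a binary self-report flag per subject
#' obtained by a median split on the control component's injected
#' suppression/imagery fluctuation-sd ratio (emulating the pre-scan
#' "could you suppress your thoughts?" answer).
#'
#' @param specs List of `component_spec`s (see [default_component_specs()]).
#' @param design A `block_design` shared by all runs.
#' @param n_subjects,n_runs Cohort size.
#' @param grid_dim Voxel grid dimensions.
#' @param mask Logical brain-mask array (default: ellipsoid on `grid_dim`).
#' @param voxel_noise_sd Sd of white voxel noise added when volumes are built.
#' @param subject_sd_jitter Log-scale sd of per-subject, per-condition
#'   multiplicative variability of the fluctuation sd.
#' @param master_seed Integer master seed; every downstream quantity is a
#'   deterministic function of the configuration and this seed.
#' @return Object of class `cohort_truth`.
#' @export
simulate_cohort <- function(specs = default_component_specs(),
                            design = build_block_design(),
                            n_subjects = 20, n_runs = 2,
                            grid_dim = c(16, 16, 8),
                            mask = ellipsoid_mask(grid_dim),
                            voxel_noise_sd = 0.7,
                            subject_sd_jitter = 0.25,
                            master_seed = 1) {
  nm <- names(specs) %||% vapply(specs, `[[`, "", "name")
  names(specs) <- nm
  K <- length(specs)
  V <- prod(grid_dim)
  maps <- vapply(specs, function(sp)
    as.vector(gaussian_blob_map(grid_dim, sp$centers, sp$sigma)), numeric(V))

  net_names <- nm[!vapply(specs, is_artifact_spec, TRUE)]
  conds <- design$conditions

  set.seed(derive_seed(master_seed, 101))
  sd_scale <- array(exp(stats::rnorm(n_subjects * length(net_names) * 2,
                                     sd = subject_sd_jitter)),
                    dim = c(n_subjects, length(net_names), 2),
                    dimnames = list(NULL, net_names, conds))
  subject_scale <- function(s)
    matrix(sd_scale[s, , ], length(net_names), 2,
           dimnames = list(net_names, conds))

  timecourses <- vector("list", n_subjects)
  fluct <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    timecourses[[s]] <- vector("list", n_runs)
    fluct[[s]] <- vector("list", n_runs)
    for (r in seq_len(n_runs)) {
      sim <- simulate_timecourses(design, specs, subject_id = s,
                                  seed = derive_seed(master_seed, s, r),
                                  sd_scale = subject_scale(s))
      timecourses[[s]][[r]] <- sim$timecourses
      fluct[[s]][[r]] <- sim$fluct
    }
  }

  control <- nm[vapply(specs, function(sp) isTRUE(sp$control), TRUE)]
  if (length(control) > 1)
    stop("at most one component_spec may have control = TRUE")
  if (length(control) == 0) control <- net_names[1]  # fallback: first network
  if (length(control) == 1 && !is.na(control)) {
    ctrl_sd <- specs[[control]]$fluct_sd
    ratio <- (sd_scale[, control, "suppression"] * ctrl_sd["suppression"]) /
      (sd_scale[, control, "imagery"] * ctrl_sd["imagery"])
    reports <- as.integer(ratio > stats::median(ratio))
  } else {
    control <- NA_character_
    ratio <- rep(NA_real_, n_subjects)
    reports <- rep(0L, n_subjects)
  }

  structure(list(specs = specs, design = design, n_subjects = n_subjects,
                 n_runs = n_runs, grid_dim = grid_dim, mask = mask,
                 true_maps = maps, timecourses = timecourses, fluct = fluct,
                 sd_scale = sd_scale, control = control,
                 control_ratio = unname(ratio), reports = reports,
                 voxel_noise_sd = voxel_noise_sd,
                 subject_sd_jitter = subject_sd_jitter,
                 master_seed = master_seed),
            class = "cohort_truth")
}

#' Build the voxel-by-time data matrix for one run
#'
#' Linear mixing of the true maps and time courses plus white voxel noise:
#' the value of voxel v at time t is `sum_k map[v, k] * tc[t, k] + noise`.
#'
#' @param truth A `cohort_truth`.
#' @param subject,run Indices.
#' @return T x V numeric matrix (V = prod(grid_dim)).
#' @export
cohort_data_matrix <- function(truth, subject, run) {
  tc <- truth$timecourses[[subject]][[run]]
  Y <- tc %*% t(truth$true_maps)
  if (truth$voxel_noise_sd > 0) {
    set.seed(derive_seed(truth$master_seed, 7000, subject, run))
    Y <- Y + truth$voxel_noise_sd * matrix(stats::rnorm(length(Y)), nrow(Y))
  }
  Y
}
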