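# Cohort serialization: NIfTI-1 volumes, BIDS-style events/participants
# tables, and a schema-versioned ground-truth JSON sidecar.

SIDECAR_SCHEMA_VERSION <- "1.0"

events_table <- function(design) {
  b <- design$blocks
  ev <- rbind(
    data.frame(onset = b$onset, duration = b$duration,
               trial_type = b$condition),
    data.frame(onset = design$cues$onset, duration = design$cues$duration,
               trial_type = "cue")
  )
  ev[order(ev$onset, ev$trial_type), ]
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

spec_to_list <- function(sp) {
  list(name = sp$name, centers = unname(as.matrix(sp$centers)),
       sigma = sp$sigma, baseline = sp$baseline,
       fluct_sd = as.list(sp$fluct_sd), coupling = as.list(sp$coupling),
       spectral_band = sp$spectral_band, artifact_sd = sp$artifact_sd,
       control = sp$control)
}

#' Write a simulated cohort to disk
#'
#' One 4D NIfTI per subject/run (TR recorded in the header), one BIDS-style
#' `events.tsv` per run, a cohort-level `participants.tsv` with the binary
#' self-report flag, and a `ground_truth.json` sidecar sufficient to score
#' recovery (configuration, seeds, per-subject fluctuation scalings, true
#' maps).
#'
#' @param truth A `cohort_truth`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a character vector of the files written.
#' @export
render_cohort <- function(truth, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  files <- character(0)
  tr <- truth$design$tr
  ev <- events_table(truth$design)
  for (s in seq_len(truth$n_subjects)) {
    sub <- sprintf("sub-%02d", s)
    dir.create(file.path(out_dir, sub), showWarnings = FALSE)
    for (r in seq_len(truth$n_runs)) {
      Y <- cohort_data_matrix(truth, s, r)             # T x V
      arr <- array(t(Y), dim = c(truth$grid_dim, nrow(Y)))
      img <- RNifti::asNifti(arr)
      RNifti::pixdim(img) <- c(1, 1, 1, tr)
      bold <- file.path(out_dir, sub, sprintf("%s_run-%02d_bold.nii.gz", sub, r))
      evf <- file.path(out_dir, sub, sprintf("%s_run-%02d_events.tsv", sub, r))
      ok <- tryCatch(RNifti::writeNifti(img, bold),
                     error = function(e) stop("failed writing ", bold, ": ",
                                              conditionMessage(e)))
      write_tsv(ev, evf)
      files <- c(files, bold, evf)
    }
  }
  part <- data.frame(participant_id = sprintf("sub-%02d", seq_len(truth$n_subjects)),
                     report_success = truth$reports)
  pf <- file.path(out_dir, "participants.tsv")
  write_tsv(part, pf)

  sidecar <- list(
    schema_version = SIDECAR_SCHEMA_VERSION,
    master_seed = truth$master_seed,
    n_subjects = truth$n_subjects, n_runs = truth$n_runs,
    grid_dim = truth$grid_dim, voxel_noise_sd = truth$voxel_noise_sd,
    subject_sd_jitter = truth$subject_sd_jitter,
    control = truth$control, reports = truth$reports,
    control_ratio = truth$control_ratio,
    design = list(block_len_s = truth$design$block_len_s,
                  n_pairs = truth$design$n_pairs,
                  sub_blocks_per_condition = truth$design$sub_blocks_per_condition,
                  tr = tr, lead_in_s = truth$design$lead_in_s,
                  conditions = truth$design$conditions),
    sd_scale = truth$sd_scale,
    specs = lapply(truth$specs, spec_to_list),
    true_maps = truth$true_maps
  )
  sf <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(sidecar, sf, digits = NA, auto_unbox = TRUE, pretty = FALSE)
  invisible(c(files, pf, sf))
}

#' Read a rendered cohort back from disk
#'
#' @param dir Directory written by [render_cohort()].
#' @return List with `data` (nested list of T x V matrices), `events`,
#'   `participants`, `design` (rebuilt from the sidecar), `grid_dim`,
#'   `tr`, and the parsed `sidecar`.
#' @export
read_cohort <- function(dir) {
  sf <- file.path(dir, "ground_truth.json")
  if (!file.exists(sf)) stop("missing ground-truth sidecar: ", sf)
  sidecar <- jsonlite::read_json(sf, simplifyVector = TRUE)
  d <- sidecar$design
  design <- build_block_design(d$block_len_s, d$n_pairs,
                               d$sub_blocks_per_condition, d$tr, d$lead_in_s,
                               conditions = d$conditions)
  n_sub <- sidecar$n_subjects
  n_runs <- sidecar$n_runs
  data <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    sub <- sprintf("sub-%02d", s)
    data[[s]] <- vector("list", n_runs)
    for (r in seq_len(n_runs)) {
      bold <- file.path(dir, sub, sprintf("%s_run-%02d_bold.nii.gz", sub, r))
      if (!file.exists(bold)) stop("missing volume file: ", bold)
      arr <- RNifti::readNifti(bold)
      dm <- dim(arr)
      data[[s]][[r]] <- t(matrix(arr, prod(dm[1:3]), dm[4]))
    }
  }
  ev <- read_tsv(file.path(dir, "sub-01", "sub-01_run-01_events.tsv"))
  part <- read_tsv(file.path(dir, "participants.tsv"))
  list(data = data, events = ev, participants = part, design = design,
       grid_dim = unlist(sidecar$grid_dim), tr = d$tr, sidecar = sidecar)
}
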