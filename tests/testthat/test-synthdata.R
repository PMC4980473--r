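test_that("zero fluctuation makes every same-condition trial identical", {
  d <- paper_design()
  sp <- list(component_spec("a", c(7, 7, 4),
                            baseline = list(imagery = 1, suppression = 0),
                            fluct_sd = c(imagery = 0, suppression = 0)))
  sim <- simulate_timecourses(d, sp, seed = 1)
  tr <- extract_trials(sim$timecourses[-(1:4), 1], d, "imagery",
                       trim_volumes = 4, block_trim = 0)
  for (i in 2:nrow(tr)) expect_equal(tr[i, ], tr[1, ], tolerance = 1e-12)
  expect_equal(max(abs(sim$fluct)), 0)
})

test_that("injected couplings appear as latent residual correlations", {
  d <- build_block_design(24, 100, 2, 2, 0)   # many blocks for Monte-Carlo
  for (w in c(0.8, -0.5)) {
    sim <- simulate_timecourses(d, null_pair_specs(w), seed = 11)
    r <- cor(sim$fluct[, 1], sim$fluct[, 2])
    expect_lt(abs(r - w), 0.05)
  }
})

test_that("fluctuation sd calibration converges to the target", {
  d <- build_block_design(24, 60, 2, 2, 0)    # > 1e4 in-block samples
  sp <- list(component_spec("a", c(7, 7, 4),
                            baseline = list(imagery = 0, suppression = 0.5),
                            fluct_sd = c(imagery = 0.7, suppression = 1.4)))
  sim <- simulate_timecourses(d, sp, seed = 2)
  for (cond in c("imagery", "suppression")) {
    tr <- extract_trials(sim$fluct[, 1], d, cond, trim_volumes = 0,
                         block_trim = 0)
    target <- sp[[1]]$fluct_sd[cond]
    expect_lt(abs(sd(as.vector(tr)) - target) / target, 0.05)
  }
})

test_that("artifact time courses are confined to their spectral band", {
  d <- paper_design()
  sp <- list(component_spec("art", c(7, 7, 4), spectral_band = c(0.15, 0.25)))
  sim <- simulate_timecourses(d, sp, seed = 3)
  x <- sim$timecourses[, 1]
  p <- Mod(fft(x - mean(x)))^2
  k <- seq_len(floor(length(x) / 2))
  f <- k / (length(x) * d$tr)
  expect_gte(sum(p[k + 1][f >= 0.15]) / sum(p[k + 1]), 0.95)
})

test_that("asymmetric duplicate couplings are rejected", {
  sp <- null_pair_specs(0.5)
  sp[[2]]$coupling <- c(a = -0.5)
  expect_error(simulate_timecourses(paper_design(), sp, seed = 1),
               "not symmetrizable")
})

test_that("per-sub-block baselines can differ within a condition", {
  d <- paper_design()
  sp <- list(component_spec("a", c(7, 7, 4),
                            baseline = list(imagery = c(1, 2), suppression = 0),
                            fluct_sd = c(imagery = 0, suppression = 0)))
  sim <- simulate_timecourses(d, sp, seed = 1)
  b <- d$blocks[d$blocks$condition == "imagery", ]
  v1 <- round(b$onset[b$sub_index == 1][1] / 2) + 10   # late in sub-block 1
  v2 <- round(b$onset[b$sub_index == 2][1] / 2) + 10
  expect_lt(sim$baseline[v1, 1], sim$baseline[v2, 1])
})

test_that("linear mixing is exact with zero voxel noise and one component", {
  sp <- default_component_specs()["supp_net"]
  sp$supp_net$coupling <- numeric(0)
  truth <- simulate_cohort(sp, paper_design(), n_subjects = 2, n_runs = 1,
                           voxel_noise_sd = 0, master_seed = 5)
  Y <- cohort_data_matrix(truth, 1, 1)
  v <- which.max(truth$true_maps[, 1])
  expect_equal(Y[, v], truth$true_maps[v, 1] * truth$timecourses[[1]][[1]][, 1],
               tolerance = 1e-12)
})

test_that("with zero noise the data rank equals the number of components", {
  truth <- simulate_cohort(default_component_specs(), paper_design(),
                           n_subjects = 1, n_runs = 1, voxel_noise_sd = 0,
                           master_seed = 5)
  Y <- cohort_data_matrix(truth, 1, 1)
  sv <- svd(Y, nu = 0, nv = 0)$d
  expect_equal(sum(sv > sv[1] * 1e-9), length(truth$specs))
})

test_that("the cohort is deterministic and the report flag is a median split", {
  t1 <- simulate_cohort(n_subjects = 6, master_seed = 42)
  t2 <- simulate_cohort(n_subjects = 6, master_seed = 42)
  expect_identical(t1$timecourses, t2$timecourses)
  expect_identical(t1$reports, t2$reports)
  t3 <- simulate_cohort(n_subjects = 6, master_seed = 43)
  expect_false(identical(t1$timecourses, t3$timecourses))
  expect_equal(sum(t1$reports), 3)               # both groups non-empty
  # flag is 1 exactly above the median control-component ratio
  expect_setequal(which(t1$reports == 1),
                  which(t1$control_ratio > median(t1$control_ratio)))
})

test_that("a rendered cohort round-trips through the standard formats", {
  truth <- simulate_cohort(n_subjects = 3, n_runs = 2, master_seed = 9)
  out <- file.path(tempdir(), "cohort-test")
  files <- render_cohort(truth, out)
  bolds <- list.files(out, pattern = "bold\\.nii\\.gz$", recursive = TRUE)
  evs <- list.files(out, pattern = "events\\.tsv$", recursive = TRUE)
  expect_length(bolds, 3 * 2)
  expect_length(evs, 3 * 2)
  expect_true(file.exists(file.path(out, "participants.tsv")))

  back <- read_cohort(out)
  expect_equal(back$design$run_length_s, 408)
  expect_equal(dim(back$data[[1]][[1]]), c(204, prod(truth$grid_dim)))
  expect_equal(back$data[[2]][[1]], cohort_data_matrix(truth, 2, 1),
               tolerance = 1e-6)
  expect_equal(back$participants$report_success, truth$reports)
  ev <- back$events
  expect_setequal(unique(ev$trial_type), c("imagery", "suppression", "cue"))
  expect_equal(sum(ev$trial_type == "cue"), 16)
  # TR recorded in the NIfTI header
  hdr <- RNifti::niftiHeader(RNifti::readNifti(
    file.path(out, "sub-01", "sub-01_run-01_bold.nii.gz")))
  expect_equal(unname(hdr$pixdim[5]), 2.0)

  # byte-identical ground-truth sidecar under the same master seed
  out2 <- file.path(tempdir(), "cohort-test2")
  render_cohort(simulate_cohort(n_subjects = 3, n_runs = 2, master_seed = 9), out2)
  expect_identical(unname(tools::md5sum(file.path(out, "ground_truth.json"))),
                   unname(tools::md5sum(file.path(out2, "ground_truth.json"))))
  unlink(c(out, out2), recursive = TRUE)
})
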