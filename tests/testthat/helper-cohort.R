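# Shared small fixtures, built in code.

minimal_design <- function() build_block_design(24, 1, 1, 2.0, 0)

paper_design <- function() build_block_design(24, 4, 2, 2.0, 24)

# A two-component, time-course-only cohort for coupling/fluct tests:
# both components are task-null (zero baseline) so that block-wise
# statistics isolate the injected fluctuation structure.
null_pair_specs <- function(w = 0, sd_a = 1, sd_b = 1) {
  list(
    component_spec("a", c(4, 4, 4),
                   baseline = list(imagery = 0, suppression = 0),
                   fluct_sd = c(imagery = sd_a, suppression = sd_a),
                   coupling = if (w != 0) c(b = w) else numeric(0)),
    component_spec("b", c(11, 11, 4),
                   baseline = list(imagery = 0, suppression = 0),
                   fluct_sd = c(imagery = sd_b, suppression = sd_b))
  )
}

# Simulate trimmed ground-truth time courses for n subjects x 2 runs.
simulate_tc_cohort <- function(specs, design = paper_design(),
                               n_subjects = 20, n_runs = 2, seed = 1,
                               trim = 4) {
  lapply(seq_len(n_subjects), function(s)
    lapply(seq_len(n_runs), function(r)
      simulate_timecourses(design, specs, subject_id = s,
                           seed = icafluct:::derive_seed(seed, s, r)
                           )$timecourses[-seq_len(trim), , drop = FALSE]))
}
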