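test_that("the band-pass filter has the stated pass/stop behaviour", {
  t <- (0:199) * 2
  mid <- 50:150
  pass <- bandpass(sin(2 * pi * 0.05 * t), 2)
  expect_gt(max(abs(pass[mid])), 0.95)
  stop_ <- bandpass(sin(2 * pi * 0.2 * t), 2)
  expect_lt(max(abs(stop_[mid])), 0.10)
  expect_equal(bandpass(rep(3, 200), 2), rep(0, 200), tolerance = 1e-9)
  expect_error(bandpass(rnorm(10), 2), "too short")
})

test_that("the pooled response averages trials and cancels antisymmetry", {
  s <- sin(seq(0, pi, length.out = 20))
  trials <- rbind(s, s, s)
  pr <- pooled_response(trials)
  expect_equal(pr$response, s)
  expect_equal(pr$amplitude, diff(range(s)))
  anti <- rbind(s, -s)
  expect_equal(pooled_response(anti)$response, rep(0, 20))
  expect_error(pooled_response(matrix(numeric(0), 0, 20)), "zero trials")
})

test_that("the pooled response converges at the root-n rate", {
  set.seed(51)
  s <- sin(seq(0, 2 * pi, length.out = 24))
  rmse <- sapply(c(25, 400), function(N) {
    mean(replicate(40, {
      trials <- matrix(rep(s, each = N), N) + matrix(rnorm(N * 24), N)
      sqrt(mean((pooled_response(trials)$response - s)^2))
    }))
  })
  expect_lt(abs(rmse[1] / rmse[2] - 4) / 4, 0.25)   # sqrt(400/25) = 4
})

test_that("the index is zero for identical trials and scale invariant", {
  s <- sin(seq(0, 2 * pi, length.out = 20)) + 2
  trials <- rbind(s, s, s, s)
  pr <- pooled_response(trials)
  expect_equal(fluctuation_index(trials, pr$response, pr$amplitude), 0)
  set.seed(52)
  noisy <- trials + matrix(rnorm(80, sd = 0.3), 4)
  pr2 <- pooled_response(noisy)
  i1 <- fluctuation_index(noisy, pr2$response, pr2$amplitude)
  c_ <- 7.3
  pr3 <- pooled_response(noisy * c_)
  i2 <- fluctuation_index(noisy * c_, pr3$response, pr3$amplitude)
  expect_lt(abs(i1 - i2), 1e-10)
  expect_warning(i3 <- fluctuation_index(noisy, pr2$response, 0), "amplitude")
  expect_identical(i3, Inf)
})

test_that("the vectorized index equals an explicit two-pass loop", {
  set.seed(53)
  trials <- matrix(rnorm(8 * 20), 8)
  pooled <- colMeans(trials)
  amp <- diff(range(pooled))
  v <- fluctuation_index(trials, pooled, amp)
  # oracle: explicit loops, two-pass sd over all residual points
  resid <- c()
  for (i in 1:8) for (j in 1:20) resid <- c(resid, trials[i, j] - pooled[j])
  m <- sum(resid) / length(resid)
  s2 <- 0
  for (r in resid) s2 <- s2 + (r - m)^2
  o <- sqrt(s2 / (length(resid) - 1)) / amp
  expect_lt(abs(v - o), 1e-10)
})

test_that("injected residual scale over amplitude is recovered", {
  set.seed(54)
  s <- 2 * sin(seq(0, 2 * pi, length.out = 40))     # amplitude 4
  for (sigma in c(0.4, 1.2)) {
    trials <- matrix(rep(s, each = 400), 400) +
      matrix(rnorm(400 * 40, sd = sigma), 400)
    pr <- pooled_response(trials)
    idx <- fluctuation_index(trials, pr$response, pr$amplitude)
    expect_lt(abs(idx - sigma / 4) / (sigma / 4), 0.05)
  }
})

test_that("identical indices across conditions give t = 0, p = 1", {
  idx <- runif(5) + 0.5
  tbl <- data.frame(subject = rep(1:5, 2),
                    component = 1,
                    condition = rep(c("imagery", "suppression"), each = 5),
                    index = rep(idx, 2))
  attr(tbl, "conditions") <- c("imagery", "suppression")
  class(tbl) <- c("fluctuation_table", "data.frame")
  cc <- compare_conditions(tbl)
  expect_equal(cc$t[1], 0)
  expect_equal(cc$p[1], 1)
})

test_that("a twofold fluctuation ratio is recovered from a simulated cohort", {
  d <- paper_design()
  specs <- list(component_spec("net", c(7, 7, 4),
                               baseline = list(imagery = 0.5, suppression = 0),
                               fluct_sd = c(imagery = 0.5, suppression = 1.0)))
  tcs <- simulate_tc_cohort(specs, d, n_subjects = 20, seed = 55)
  ft <- fluctuation_table(tcs, d)
  cc <- compare_conditions(ft)
  expect_lt(cc$p[1], 0.05)
  expect_gt(cc$t[1], 0)
  expect_gt(cc$gm_ratio[1], 1.8)
  expect_lt(cc$gm_ratio[1], 2.2)
})

test_that("the task comparison is calibrated under a unit ratio", {
  # direct trial-level nulls: same residual sd in both conditions
  set.seed(56)
  n_rep <- 400
  n_sub <- 12
  p <- replicate(n_rep, {
    idx <- matrix(NA_real_, n_sub, 2)
    for (s in seq_len(n_sub)) for (cc in 1:2) {
      trials <- matrix(rnorm(8 * 20), 8)
      idx[s, cc] <- sd(as.vector(trials))
    }
    t.test(log(idx[, 2]) - log(idx[, 1]))$p.value
  })
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.025)
  expect_lt(rate, 0.075)
})

test_that("report association flags the component that drives the split", {
  d <- paper_design()
  hits <- 0
  n_rep <- 12
  for (rep_i in seq_len(n_rep)) {
    truth <- simulate_cohort(default_component_specs(), d, n_subjects = 20,
                             master_seed = 100 + rep_i)
    tcs <- lapply(truth$timecourses, function(runs)
      lapply(runs, function(tc) tc[-(1:4), , drop = FALSE]))
    ft <- fluctuation_table(tcs, d)
    pa <- report_association(attr(ft, "ratio"), truth$reports)
    net <- which(!grepl("art", names(truth$specs)))
    if (which.min(pa$p[net]) == match("ecn", names(truth$specs))) hits <- hits + 1
  }
  expect_gte(hits, n_rep - 2)
})

test_that("clearly separated ratio groups give a small association p", {
  ratio <- cbind(c(2, 2, 2, 1, 1, 1) * exp(rnorm(6, sd = 0.01)))
  out <- report_association(ratio, c(1, 1, 1, 0, 0, 0))
  expect_lt(out$p[1], 0.01)
  expect_gt(out$t[1], 0)
  expect_error(report_association(ratio, rep(1, 6)), "non-empty")
})
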