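test_that("the full design yields a 200 x 8 design matrix", {
  X <- build_design_matrix(paper_design(), trim_volumes = 4)
  expect_equal(dim(unclass(X)), c(200L, 8L))
  expect_setequal(colnames(X),
                  c("imagery_1", "imagery_2", "suppression_1", "suppression_2",
                    "cue_imagery_1", "cue_imagery_2", "cue_suppression_1",
                    "cue_suppression_2"))
  expect_true(all(colSums(abs(X)) > 0))
  expect_true(all(is.finite(X)))
})

test_that("a single-pair design has one active block per epoch column", {
  d <- build_block_design(24, 1, 2, 2, 0)
  X <- build_design_matrix(d, trim_volumes = 0)
  for (cn in attr(X, "imagery_cols")) {
    col <- X[, cn]
    # one contiguous activation from one 24-s block
    expect_equal(sum(abs(col) > 1e-6 * max(abs(col))) <= 12 + 16, TRUE)
    expect_gt(max(col), 0)
  }
})

test_that("equal-duration epochs get regressors of matched height", {
  X <- build_design_matrix(paper_design())
  mx <- apply(X[, c(attr(X, "imagery_cols"), attr(X, "suppression_cols"))], 2, max)
  expect_lt((max(mx) - min(mx)) / max(mx), 0.05)
})

test_that("a pure imagery-regressor time course gives exact betas", {
  d <- paper_design()
  X <- build_design_matrix(d)
  tc <- rowSums(X[, attr(X, "imagery_cols")]) + 0.5   # plus intercept offset
  tcs <- lapply(1:5, function(s) list(cbind(tc), cbind(tc)))
  res <- analysis1(tcs, X)
  expect_equal(unname(res$delta_beta[, 1]), rep(1, 5), tolerance = 1e-8)
  expect_lt(abs(res$p[1]), 1e-10)
})

test_that("regression matches a brute-force normal-equations oracle", {
  d <- paper_design()
  X <- build_design_matrix(d)
  set.seed(41)
  tcs <- lapply(1:4, function(s)
    lapply(1:2, function(r) matrix(rnorm(200 * 3), 200)))
  res <- analysis1(tcs, X)
  Xa <- cbind(unclass(X), 1)
  img <- match(attr(X, "imagery_cols"), colnames(X))
  sup <- match(attr(X, "suppression_cols"), colnames(X))
  for (s in 1:4) for (k in 1:3) {
    db <- mean(sapply(1:2, function(r) {
      beta <- solve(t(Xa) %*% Xa, t(Xa) %*% tcs[[s]][[r]][, k])
      mean(beta[img]) - mean(beta[sup])
    }))
    expect_equal(res$delta_beta[s, k], db, tolerance = 1e-8)
  }
})

test_that("a singular design is rejected with its condition number", {
  X <- build_design_matrix(paper_design())
  Xs <- X
  Xs[, 2] <- Xs[, 1]
  tcs <- lapply(1:3, function(s) list(matrix(rnorm(200), 200)))
  expect_error(analysis1(tcs, Xs), "condition number|singular")
})

test_that("group contrast test is calibrated under the null", {
  # vectorized null replicates: white-noise components, 12 subjects
  d <- paper_design()
  X <- build_design_matrix(d)
  Xa <- cbind(unclass(X), 1)
  H <- solve(crossprod(Xa), t(Xa))
  img <- match(attr(X, "imagery_cols"), colnames(X))
  sup <- match(attr(X, "suppression_cols"), colnames(X))
  cvec <- rep(0, ncol(Xa))
  cvec[img] <- 0.5
  cvec[sup] <- -0.5
  hc <- drop(cvec %*% H)                    # contrast functional of the data
  set.seed(42)
  n_sub <- 12
  n_rep <- 500
  p <- replicate(n_rep, {
    db <- drop(hc %*% matrix(rnorm(200 * n_sub), 200))
    t.test(db)$p.value
  })
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.025)
  expect_lt(rate, 0.075)
})

test_that("empirical power follows the noncentral-t prediction", {
  # per-subject contrast d + between-subject noise, regression noise tiny
  d <- paper_design()
  X <- build_design_matrix(d)
  img <- rowSums(X[, attr(X, "imagery_cols")])
  sup <- rowSums(X[, attr(X, "suppression_cols")])
  set.seed(43)
  n_sub <- 10
  eff <- 0.4
  sigma_b <- 0.5
  n_rep <- 300
  rej <- replicate(n_rep, {
    tcs <- lapply(seq_len(n_sub), function(s) {
      a <- eff + rnorm(1, sd = sigma_b)
      list(cbind(a * img + 1e-4 * rnorm(200)))
    })
    analysis1(tcs, X)$p[1] < 0.05
  })
  ncp <- eff / (sigma_b / sqrt(n_sub))
  tc_ <- qt(0.975, n_sub - 1)
  power_theory <- 1 - pt(tc_, n_sub - 1, ncp) + pt(-tc_, n_sub - 1, ncp)
  se <- sqrt(power_theory * (1 - power_theory) / n_rep)
  expect_lt(abs(mean(rej) - power_theory), 4 * se + 0.02)
})

test_that("the pooled cycle enters the two-sample test with full phases", {
  d <- paper_design()
  tcs <- simulate_tc_cohort(default_component_specs(), d, n_subjects = 4,
                            seed = 44)
  res <- analysis2(tcs, d)
  expect_equal(res$n_imagery, 24)
  expect_equal(res$n_suppression, 24)
  expect_equal(nrow(res$cycle), 48)
  expect_equal(res$n_segments, 4 * 2 * 4)
  # imagery-active component has higher imagery-phase signal
  expect_gt(res$t[2], 0)     # img_net
  expect_lt(res$t[1], 0)     # supp_net
})

test_that("a step effect is detected and a null is not", {
  d <- paper_design()
  ph_img <- unlist(icafluct:::phase_volume_indices(d, 4)[c(1, 3, 5, 7)])
  set.seed(45)
  mk <- function(step) lapply(1:6, function(s) lapply(1:2, function(r) {
    x <- rnorm(200, sd = 0.1)
    x[ph_img] <- x[ph_img] + step
    cbind(x)
  }))
  expect_lt(analysis2(mk(1), d)$p[1], 0.001)
  p0 <- analysis2(mk(0), d)$p[1]
  expect_gt(p0, 0.001)
})

test_that("stronger injected baseline shifts rank as smaller contrast p", {
  d <- paper_design()
  tcs <- simulate_tc_cohort(default_component_specs(), d, n_subjects = 12,
                            seed = 46)
  X <- build_design_matrix(d)
  res <- analysis1(tcs, X)
  specs <- default_component_specs()
  inj <- vapply(specs, function(sp) {
    if (is_artifact_spec(sp)) return(NA_real_)
    abs(mean(unlist(sp$baseline$imagery)) - mean(unlist(sp$baseline$suppression)))
  }, 0)
  ok <- !is.na(inj) & inj > 0
  expect_gt(cor(inj[ok], -log10(res$p[ok]), method = "spearman"), 0.5)
})
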