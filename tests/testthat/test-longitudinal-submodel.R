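# Mixed-effects submodel: parameter recovery, closed-form marginal
# likelihood against brute-force integration, shrinkage, and analytic
# trajectory slopes.

test_that("ML estimates recover the generating parameters", {
  cfg <- recovery_config(500)
  co <- simulate_cohort(cfg, seed = 11)
  fit <- fit_lmm(co$longitudinal)
  # truths from the generator (marginal intercept has no grade shifts here)
  expect_lt(abs(fit$beta[1] - 16), 3 * 5.5 / sqrt(500))
  expect_lt(abs(fit$sigma - 2), 0.15)
  expect_lt(abs(sqrt(fit$D[1, 1]) - 5.5), 0.8)
  expect_lt(abs(sqrt(fit$D[2, 2]) - 0.15), 0.05)
  # optimizer sanity: optimum at least as good as the truth
  ll_true <- lmm_marginal_loglik(co$longitudinal, lmm_spec(),
                                 beta = c(16, 0.02),
                                 D = cfg$D, sigma = 2)
  expect_gte(fit$loglik, ll_true - 1e-6)
})

test_that("marginal likelihood equals brute-force integration over the random effects", {
  set.seed(4)
  n <- 5
  D <- matrix(c(9, 0.6, 0.6, 0.09), 2, 2)
  sigma <- 1.5
  beta <- c(18, 0.3)
  lg <- do.call(rbind, lapply(seq_len(n), function(i) {
    b <- drop(t(chol(D)) %*% rnorm(2))
    tt <- sort(runif(4, 0, 30))
    data.frame(patient_id = paste0("p", i), t = tt,
               meld_na = beta[1] + b[1] + (beta[2] + b[2]) * tt +
                 rnorm(4, 0, sigma))
  }))
  ll <- lmm_marginal_loglik(lg, lmm_spec(), beta, D, sigma)
  b0g <- seq(-18, 18, length.out = 481)
  b1g <- seq(-1.8, 1.8, length.out = 481)
  Dinv <- solve(D)
  ld_const <- -log(2 * pi) -
    0.5 * as.numeric(determinant(D, logarithm = TRUE)$modulus)
  brute <- sum(sapply(split(lg, lg$patient_id), function(d) {
    f <- matrix(NA_real_, length(b0g), length(b1g))
    # vectorised over the slope grid for each intercept value
    resid_slope <- outer(d$t, beta[2] + b1g)          # n_obs x n_b1
    for (a in seq_along(b0g)) {
      R <- d$meld_na - (beta[1] + b0g[a]) - resid_slope
      ly <- -0.5 * colSums(R^2) / sigma^2 -
        nrow(d) * log(sqrt(2 * pi) * sigma)
      lp <- ld_const - 0.5 * (Dinv[1, 1] * b0g[a]^2 +
                                2 * Dinv[1, 2] * b0g[a] * b1g +
                                Dinv[2, 2] * b1g^2)
      f[a, ] <- ly + lp
    }
    mx <- max(f)
    log(sum(exp(f - mx)) * diff(b0g)[1] * diff(b1g)[1]) + mx
  }))
  expect_lt(abs(ll - brute), 1e-5)
})

test_that("noise-free linear trajectories are interpolated exactly", {
  set.seed(9)
  n <- 40
  ic <- rnorm(n, 20, 5); sl <- rnorm(n, 0.1, 0.2)
  lg <- do.call(rbind, lapply(seq_len(n), function(i) {
    tt <- sort(runif(6, 0, 40))
    data.frame(patient_id = sprintf("p%02d", i), t = tt,
               meld_na = ic[i] + sl[i] * tt)
  }))
  fit <- fit_lmm(lg)
  expect_lt(fit$sigma, 0.05)
  for (i in c(1, 17, 40)) {
    tr <- trajectory(fit, sprintf("p%02d", i), c(0, 10, 25))
    expect_equal(tr$value, ic[i] + sl[i] * c(0, 10, 25), tolerance = 1e-4)
    expect_equal(tr$slope, rep(sl[i], 3), tolerance = 1e-4)
  }
})

test_that("EB estimates shrink sparse patients toward the population mean", {
  set.seed(21)
  lg <- do.call(rbind, lapply(1:60, function(i) {
    ni <- if (i == 1) 1 else 6
    tt <- sort(runif(ni, 0, 30))
    data.frame(patient_id = sprintf("p%02d", i), t = tt,
               meld_na = 20 + rnorm(1, 0, 4) + rnorm(ni, 0, 2))
  }))
  fit <- fit_lmm(lg)
  d1 <- lg[lg$patient_id == "p01", ]
  raw_dev <- d1$meld_na -
    drop(meldjm:::build_design(d1$t, fit$spec) %*% fit$beta)
  fitted_dev <- fit$ranef["p01", "b0"] + fit$ranef["p01", "b1"] * d1$t
  expect_lte(abs(fitted_dev), abs(raw_dev) + 1e-8)

  # BLUP limit: with a huge prior, a 2-point patient is interpolated exactly
  two <- data.frame(patient_id = "q", t = c(0, 10), meld_na = c(25, 31))
  blk <- meldjm:::build_blocks(two, meldjm:::prepare_spec(lmm_spec(), two$t))
  b <- meldjm:::eb_modes(blk, beta = c(20, 0), D = diag(c(1e8, 1e8)),
                         sigma = 1)
  expect_equal(20 + b["q", "b0"], 25, tolerance = 1e-4)
  expect_equal(b["q", "b1"], 0.6, tolerance = 1e-4)
})

test_that("estimates agree with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  co <- simulate_cohort(recovery_config(200), seed = 17)
  fit <- fit_lmm(co$longitudinal)
  lm4 <- suppressWarnings(
    lme4::lmer(meld_na ~ t + (t | patient_id), data = co$longitudinal,
               REML = FALSE))
  expect_equal(unname(fit$beta), unname(lme4::fixef(lm4)), tolerance = 1e-3)
  expect_equal(fit$loglik, as.numeric(stats::logLik(lm4)), tolerance = 1e-4)
  vc <- as.data.frame(lme4::VarCorr(lm4))
  expect_equal(fit$sigma, vc$sdcor[vc$grp == "Residual"], tolerance = 1e-3)
  expect_equal(sqrt(fit$D[1, 1]),
               vc$sdcor[vc$var1 == "(Intercept)" & is.na(vc$var2)][1],
               tolerance = 1e-3)
})

test_that("trajectory slopes are analytic: spline basis derivative matches finite differences", {
  set.seed(33)
  lg <- do.call(rbind, lapply(1:30, function(i) {
    tt <- sort(runif(8, 0, 60))
    data.frame(patient_id = sprintf("p%02d", i), t = tt,
               meld_na = 18 + 0.2 * tt - 0.002 * tt^2 + rnorm(1, 0, 3) +
                 rnorm(8, 0, 1))
  }))
  fit <- fit_lmm(lg, lmm_spec(time_basis = "ns", n_knots = 2))
  h <- 1e-4
  for (tt in c(5, 20, 41, 58)) {
    tr <- trajectory(fit, "p07", tt)
    fd <- (trajectory(fit, "p07", tt + h)$value -
             trajectory(fit, "p07", tt - h)$value) / (2 * h)
    expect_equal(tr$slope, fd, tolerance = 1e-6)
  }
  expect_error(trajectory(fit, "nobody", 1), "unknown patient")
})

test_that("rank-deficient designs fail loudly with the offending column", {
  lg <- data.frame(patient_id = rep(c("a", "b"), each = 3),
                   t = rep(c(0, 1, 2), 2), meld_na = rnorm(6, 20))
  bl <- data.frame(patient_id = c("a", "b"), dup = c(1, 1), dup2 = c(2, 2))
  spec <- lmm_spec(covariates = c("dup", "dup2"))
  expect_error(fit_lmm(lg, spec, bl), "rank-deficient")
})

test_that("longitudinal fits persist and restore as plain text", {
  co <- simulate_cohort(recovery_config(30), seed = 3)
  fit <- fit_lmm(co$longitudinal)
  tmp <- tempfile(fileext = ".json")
  write_lmm_fit(fit, tmp)
  back <- read_lmm_fit(tmp)
  expect_equal(back$beta, fit$beta, tolerance = 1e-12)
  expect_equal(back$D, fit$D, tolerance = 1e-12)
  tr1 <- trajectory(fit, fit$ids[1], c(1, 5))
  tr2 <- trajectory(back, fit$ids[1], c(1, 5))
  expect_equal(tr1$value, tr2$value, tolerance = 1e-10)
  unlink(tmp)
})
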