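# Joint likelihood correctness, estimation, and hazard-ratio algebra.

test_that("joint likelihood matches brute-force 2-D integration on a 3-patient instance", {
  tables <- tiny_cohort()
  params <- tiny_params()
  ssp <- tiny_sspec()
  ll <- joint_log_likelihood(params, tables, lmm_spec(), ssp,
                             per_patient = TRUE)
  bp <- attr(ll, "by_patient")
  for (i in 1:3) {
    brute <- brute_patient_loglik(i, tables, params, ssp$breaks,
                                  names(params$gamma))
    expect_lt(abs(bp[i] - brute), 1e-4)
  }
})

test_that("with zero association the joint likelihood factorizes into LMM + PH", {
  tables <- tiny_cohort()
  params <- tiny_params()
  params$alpha_value <- 0; params$alpha_slope <- 0
  ssp <- tiny_sspec()
  ll <- joint_log_likelihood(params, tables, lmm_spec(), ssp)
  ll_lmm <- lmm_marginal_loglik(tables$longitudinal, lmm_spec(),
                                params$beta, params$D, params$sigma)
  ll_ph <- ph_loglik(tables$outcomes, tables$baseline, names(params$gamma),
                     params$gamma, params$lambda, ssp$breaks)
  expect_lt(abs(ll - (ll_lmm + ll_ph)), 1e-6)
})

test_that("with no events, scaling the baseline hazard subtracts exactly the added cumulative hazard", {
  tables <- tiny_cohort()
  tables$outcomes$event_type <- "censored"
  params <- tiny_params()
  params$alpha_value <- 0; params$alpha_slope <- 0
  ssp <- tiny_sspec()
  ll1 <- joint_log_likelihood(params, tables, lmm_spec(), ssp)
  # cumulative hazard with zero events, computable in closed form
  W <- meldjm:::survival_design(tables$baseline, names(params$gamma))
  eta <- drop(W %*% params$gamma)
  seg_time <- function(Ti) c(min(Ti, 10), max(Ti - 10, 0))
  ch <- sum(sapply(seq_len(3), function(i)
    sum(params$lambda * seg_time(tables$outcomes$event_time[i])) *
      exp(eta[i])))
  params2 <- params; params2$lambda <- 2 * params$lambda
  ll2 <- joint_log_likelihood(params2, tables, lmm_spec(), ssp)
  expect_equal(ll2 - ll1, -ch, tolerance = 1e-8)
})

test_that("quadrature refinement does not move the likelihood", {
  co <- simulate_cohort(recovery_config(150), seed = 23)
  tables <- co[c("baseline", "longitudinal", "outcomes")]
  params <- list(beta = c(16, 0.02), D = matrix(c(30, 0.25, 0.25, 0.0225), 2, 2),
                 sigma = 2, gamma = c(-0.29, 0.3),
                 alpha_value = 0.14, alpha_slope = 0.6,
                 lambda = rep(2e-3, 3))
  ssp9 <- surv_spec(covariates = c("female", "life_support"), n_segments = 3,
                    gh_points = 9)
  ssp25 <- surv_spec(covariates = c("female", "life_support"), n_segments = 3,
                     gh_points = 25)
  ll9 <- joint_log_likelihood(params, tables, lmm_spec(), ssp9)
  ll25 <- joint_log_likelihood(params, tables, lmm_spec(), ssp25)
  expect_lt(abs(ll9 - ll25), 1e-3)
})

test_that("rescaling the time unit rescales the slope association and shifts the likelihood by the jacobian", {
  tables <- tiny_cohort()
  params <- tiny_params()
  ssp <- tiny_sspec()
  ll_days <- joint_log_likelihood(params, tables, lmm_spec(), ssp)
  # same model with time in 30-day months
  c30 <- 30
  tb2 <- tables
  tb2$longitudinal$t <- tb2$longitudinal$t / c30
  tb2$outcomes$event_time <- tb2$outcomes$event_time / c30
  p2 <- params
  p2$beta <- c(params$beta[1], params$beta[2] * c30)
  p2$D <- diag(c(1, c30)) %*% params$D %*% diag(c(1, c30))
  p2$alpha_slope <- params$alpha_slope / c30
  p2$lambda <- params$lambda * c30
  ssp2 <- ssp; ssp2$breaks <- c(0, 10 / c30, Inf)
  ll_months <- joint_log_likelihood(p2, tb2, lmm_spec(), ssp2)
  n_events <- 2
  expect_equal(ll_months, ll_days + n_events * log(c30), tolerance = 1e-6)
})

test_that("the joint fit recovers known generating parameters within 3 SEs", {
  co <- simulate_cohort(recovery_config(500), seed = 11)
  tables <- co[c("baseline", "longitudinal", "outcomes")]
  ssp <- surv_spec(covariates = c("female", "life_support"), n_segments = 3)
  fit <- fit_joint_model(tables, lmm_spec(), ssp)
  truth <- c(16, 0.02, log(0.75), log(1.35), log(1.15), 30 * log(1.02))
  est <- c(fit$beta, fit$gamma, fit$alpha_value, fit$alpha_slope)
  se <- fit$se[c("(Intercept)", "t", "female", "life_support",
                 "alpha_value", "alpha_slope")]
  expect_true(all(is.finite(se) & se > 0))
  expect_true(all(abs(est - truth) < 3 * se))
  expect_equal(fit$sigma, 2, tolerance = 0.1)
  # dropping the slope association cannot raise the maximized likelihood
  ssp_v <- surv_spec(covariates = c("female", "life_support"), n_segments = 3,
                     assoc = "value")
  fit_v <- fit_joint_model(tables, lmm_spec(), ssp_v, compute_se = FALSE)
  expect_lte(fit_v$loglik, fit$loglik + 1e-4)
})

test_that("two-stage and random starts reach the same optimum", {
  co <- simulate_cohort(recovery_config(150), seed = 29)
  tables <- co[c("baseline", "longitudinal", "outcomes")]
  ssp <- surv_spec(covariates = "female", n_segments = 2)
  f1 <- fit_joint_model(tables, lmm_spec(), ssp, init = "two_stage",
                        compute_se = FALSE)
  f2 <- fit_joint_model(tables, lmm_spec(), ssp, init = "random", seed = 4,
                        compute_se = FALSE)
  expect_lt(abs(f1$loglik - f2$loglik), 1e-4)
  expect_equal(f1$alpha_value, f2$alpha_value, tolerance = 1e-2)
})

test_that("degenerate inputs raise informative errors", {
  tables <- tiny_cohort()
  tables$outcomes$event_type <- c("transplant", "censored", "censored")
  expect_error(fit_joint_model(tables, lmm_spec(), tiny_sspec()),
               "no death events")
  tb2 <- tiny_cohort()
  tb2$longitudinal <- tb2$longitudinal[tb2$longitudinal$patient_id != "B", ]
  expect_error(meldjm:::build_jm_blocks(tb2$longitudinal, tb2$baseline,
                                        tb2$outcomes, lmm_spec(), tiny_sspec()),
               "at least one measurement")
})

test_that("hazard ratios follow the log-linear product rule", {
  fit <- flat_hazard_fit(alpha_value = log(1.15), alpha_slope = log(1.02))
  fit$gamma <- c(female = log(0.75), aclf3 = log(5.9))
  expect_equal(hazard_ratio(fit, value = 1), 1.15, tolerance = 1e-12)
  expect_equal(hazard_ratio(fit), 1.0)
  expect_equal(hazard_ratio(fit, covariates = list(aclf3 = 1)), 5.9,
               tolerance = 1e-12)
  expect_equal(hazard_ratio(fit, value = 1, slope = 1), 1.15 * 1.02,
               tolerance = 1e-12)
  expect_error(hazard_ratio(fit, covariates = list(bogus = 1)),
               "unknown covariate")
  # monotone hazard in value and slope under positive associations
  h0 <- hazard_ratio(fit, value = 10, slope = 0)
  h1 <- hazard_ratio(fit, value = 11, slope = 0)
  h2 <- hazard_ratio(fit, value = 11, slope = 2)
  expect_true(h0 < h1 && h1 < h2)
})

test_that("joint fits persist and restore as plain text", {
  co <- simulate_cohort(recovery_config(80), seed = 37)
  tables <- co[c("baseline", "longitudinal", "outcomes")]
  fit <- fit_joint_model(tables, lmm_spec(),
                         surv_spec(covariates = "female", n_segments = 2),
                         compute_se = FALSE)
  tmp <- tempfile(fileext = ".json")
  write_jm_fit(fit, tmp)
  back <- read_jm_fit(tmp)
  expect_equal(back$alpha_value, fit$alpha_value, tolerance = 1e-12)
  expect_equal(back$lambda, fit$lambda, tolerance = 1e-12)
  expect_equal(back$breaks, fit$breaks)
  p1 <- predict_survival(fit, data.frame(t = 0, meld_na = 25),
                         co$baseline[1, ], 0, c(14, 28), method = "plugin")
  p2 <- predict_survival(back, data.frame(t = 0, meld_na = 25),
                         co$baseline[1, ], 0, c(14, 28), method = "plugin")
  expect_equal(p1$pi, p2$pi, tolerance = 1e-10)
  unlink(tmp)
})
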