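# Shared fixtures and independent oracles. Everything is built in code at
# test time; no stored data.

# Tiny three-patient cohort with one censored and two death outcomes.
tiny_cohort <- function() {
  baseline <- data.frame(
    patient_id = c("A", "B", "C"),
    age = c(50, 60, 45),
    sex = c("male", "female", "male"),
    etiology = c("nash", "other", "alcohol_cirrhosis"),
    aclf_grade0 = c(0, 1, 2),
    sbp = c(FALSE, TRUE, FALSE),
    life_support = FALSE,
    listing_day = 0,
    stringsAsFactors = FALSE)
  longitudinal <- data.frame(
    patient_id = rep(c("A", "B", "C"), each = 2),
    t = c(0, 10, 0, 5, 0, 3),
    meld_na = c(18, 19, 25, 28, 31, 36))
  outcomes <- data.frame(
    patient_id = c("A", "B", "C"),
    event_time = c(40, 12, 6),
    event_type = c("transplant", "death", "death"),
    stringsAsFactors = FALSE)
  list(baseline = baseline, longitudinal = longitudinal, outcomes = outcomes)
}

tiny_params <- function() {
  list(beta = c(20, 0.1), D = matrix(c(25, 0.3, 0.3, 0.04), 2, 2), sigma = 2,
       gamma = c(age_c = 0.02, female = -0.3, aclf1 = 0.1, aclf2 = 0.6),
       alpha_value = 0.13, alpha_slope = 1.5, lambda = c(3e-4, 6e-4))
}

tiny_sspec <- function() {
  ssp <- surv_spec(covariates = c("age_c", "female", "aclf1", "aclf2"),
                   n_segments = 2, gh_points = 15, gl_points = 15)
  ssp$breaks <- c(0, 10, Inf)
  ssp
}

# Hand-built joint-model fit with a constant baseline hazard; closed forms
# are available against it.
flat_hazard_fit <- function(lambda = 0.001, alpha_value = 0.1,
                            alpha_slope = 0, D = diag(c(25, 0.01)),
                            sigma = 1, beta = c(`(Intercept)` = 20, t = 0)) {
  structure(list(
    beta = beta, D = D, sigma = sigma, gamma = c(female = 0),
    alpha_value = alpha_value, alpha_slope = alpha_slope,
    lambda = lambda, breaks = c(0, Inf),
    spec = list(lspec = meldjm:::prepare_spec(lmm_spec(), c(0, 100)),
                sspec = surv_spec(covariates = "female", n_segments = 1)),
    ranef = matrix(0, 1, 2, dimnames = list("X", c("b0", "b1")))),
    class = "meldjm_jm")
}

# Independent 2-D multivariate normal log-density.
log_dmvnorm2 <- function(x, mean, S) {
  d <- x - mean
  Si <- solve(S)
  -log(2 * pi) - 0.5 * as.numeric(determinant(S, logarithm = TRUE)$modulus) -
    0.5 * drop(t(d) %*% Si %*% d)
}

# Brute-force joint log-likelihood contribution of one patient by 2-D
# trapezoid integration over the random effects (independent of the
# package's quadrature path; cumulative hazards by fine trapezoid).
brute_patient_loglik <- function(i, tables, params, breaks, gamma_names,
                                 n_grid = 401, sd_mult = 6, n_time = 2001) {
  bl <- tables$baseline
  lg <- tables$longitudinal[tables$longitudinal$patient_id ==
                              bl$patient_id[i], ]
  oc <- tables$outcomes[tables$outcomes$patient_id == bl$patient_id[i], ]
  W <- meldjm:::survival_design(bl, gamma_names)
  gw <- sum(W[i, ] * params$gamma)
  Ti <- oc$event_time
  delta <- oc$event_type == "death"
  b0g <- seq(-sd_mult * sqrt(params$D[1, 1]), sd_mult * sqrt(params$D[1, 1]),
             length.out = n_grid)
  b1g <- seq(-sd_mult * sqrt(params$D[2, 2]), sd_mult * sqrt(params$D[2, 2]),
             length.out = n_grid)
  tgrid <- seq(0, Ti, length.out = n_time)
  seg <- pmin(pmax(findInterval(tgrid, breaks, left.open = TRUE), 1),
              length(params$lambda))
  lam <- params$lambda[seg]
  f <- matrix(NA_real_, n_grid, n_grid)
  for (a in seq_len(n_grid)) {
    for (b in seq_len(n_grid)) {
      b0 <- b0g[a]; b1 <- b1g[b]
      mu_obs <- params$beta[1] + b0 + (params$beta[2] + b1) * lg$t
      ly <- sum(stats::dnorm(lg$meld_na, mu_obs, params$sigma, log = TRUE))
      m <- params$beta[1] + b0 + (params$beta[2] + b1) * tgrid
      h <- lam * exp(gw + params$alpha_value * m +
                       params$alpha_slope * (params$beta[2] + b1))
      ch <- sum((h[-1] + h[-n_time]) / 2) * (tgrid[2] - tgrid[1])
      ls <- -ch + if (delta)
        log(lam[n_time]) + gw + params$alpha_value * m[n_time] +
          params$alpha_slope * (params$beta[2] + b1) else 0
      f[a, b] <- ly + ls + log_dmvnorm2(c(b0, b1), c(0, 0), params$D)
    }
  }
  mx <- max(f)
  log(sum(exp(f - mx)) * diff(b0g)[1] * diff(b1g)[1]) + mx
}

# Clean linear-trajectory generator for recovery tests: no ACLF trajectory
# shifts, continuous observations, two survival covariates.
recovery_config <- function(n_patients, sigma = 2, alpha_slope = 30 * log(1.02)) {
  sim_config(n_patients = n_patients, aclf_shift = c(0, 0, 0),
             registry_mode = FALSE, sigma = sigma,
             alpha_slope = alpha_slope,
             gamma = c(female = log(0.75), life_support = log(1.35)),
             transplant_rate = 0.004, removal_rate = 0.001, horizon = 120,
             gap_meanlog = log(14))
}
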