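# Synthetic waitlist cohorts with the statistical structure the joint model
# assumes: random-intercept/random-slope MELD-Na trajectories, an event
# hazard driven by the current trajectory value and slope plus baseline
# covariates, independent transplant censoring and an administrative
# horizon. Defaults are chosen once to mimic a US liver-waitlist registry;
# the methods vignette records the reasoning.

#' Simulation configuration for a synthetic waitlist cohort
#'
#' True parameters of the generating joint model plus the observation
#' process. Trajectories are linear in time at the patient level
#' (`m_i(t) = beta0 + beta_t t + shift(ACLF grade) + b0_i + b1_i t`), the
#' hazard is `h0 exp(gamma'w + alpha_value m_i(t) + alpha_slope m_i'(t))`,
#' transplant and other removal act as independent censoring, and
#' measurements arrive at irregular lognormal gaps. Time unit: days since
#' listing.
#'
#' @param n_patients cohort size.
#' @param beta fixed intercept and slope (MELD-Na points, points/day).
#' @param aclf_shift trajectory shift for baseline ACLF grades 1-3.
#' @param sd_intercept,sd_slope,cor_re random-effect SDs and correlation.
#' @param sigma residual SD of observed MELD-Na around the trajectory.
#' @param alpha_value association with the current value (per point).
#' @param alpha_slope association with the current slope (per point/day).
#' @param gamma named log-hazard-ratios for baseline covariates; names must
#'   be among `age_c` (years, centred at 56), `female`, `cirrhosis`,
#'   `aclf1`, `aclf2`, `aclf3`, `sbp`, `life_support`.
#' @param h0 constant baseline hazard (per day), or a function of time.
#' @param transplant_rate,removal_rate independent censoring intensities
#'   (per day); `transplant_severity` optionally scales the transplant
#'   intensity by `exp(transplant_severity * (m_i(t) - 25))` to stress-test
#'   downstream metrics (default 0, independent censoring).
#' @param horizon administrative censoring time (days).
#' @param gap_meanlog,gap_sdlog lognormal measurement-gap parameters
#'   (median 7 days by default); gaps are floored at half a day.
#' @param grade_probs baseline ACLF grade distribution (grades 0-3).
#' @param registry_mode if `TRUE`, observed MELD-Na is rounded to integers
#'   and clamped to \[6, 40\] as reported by the registry; if `FALSE` the
#'   raw Gaussian observation is kept (clean parameter-recovery setting).
#' @param grid_step time step (days) for cumulative-hazard inversion.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 500,
                       beta = c(16, 0.02),
                       aclf_shift = c(11, 16, 20),
                       sd_intercept = 5.5, sd_slope = 0.15, cor_re = 0.3,
                       sigma = 2.0,
                       alpha_value = log(1.15),
                       alpha_slope = 30 * log(1.02),
                       gamma = c(age_c = log(1.38) / 10, female = log(0.75),
                                 cirrhosis = log(0.95), aclf1 = log(1.06),
                                 aclf2 = log(1.98), aclf3 = log(5.90),
                                 sbp = log(1.18), life_support = log(1.35)),
                       h0 = 2e-4,
                       transplant_rate = 0.006, removal_rate = 0.002,
                       transplant_severity = 0,
                       horizon = 365,
                       gap_meanlog = log(7), gap_sdlog = 0.6,
                       grade_probs = c(0.667, 0.159, 0.103, 0.071),
                       registry_mode = TRUE,
                       grid_step = 0.25) {
  D <- matrix(c(sd_intercept^2,
                cor_re * sd_intercept * sd_slope,
                cor_re * sd_intercept * sd_slope,
                sd_slope^2), 2, 2)
  if (min(eigen(D, symmetric = TRUE, only.values = TRUE)$values) < 0)
    stop("random-effect covariance is not positive semi-definite", call. = FALSE)
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (transplant_rate < 0 || removal_rate < 0)
    stop("censoring intensities must be >= 0", call. = FALSE)
  bad <- setdiff(names(gamma),
                 c("age_c", "female", "cirrhosis", "aclf1", "aclf2", "aclf3",
                   "sbp", "life_support"))
  if (length(bad)) stop("unknown gamma names: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(list(n_patients = n_patients, beta = beta, aclf_shift = aclf_shift,
                 D = D, sigma = sigma, alpha_value = alpha_value,
                 alpha_slope = alpha_slope, gamma = gamma, h0 = h0,
                 transplant_rate = transplant_rate,
                 removal_rate = removal_rate,
                 transplant_severity = transplant_severity,
                 horizon = horizon, gap_meanlog = gap_meanlog,
                 gap_sdlog = gap_sdlog, grade_probs = grade_probs,
                 registry_mode = registry_mode, grid_step = grid_step),
            class = "sim_config")
}

# Baseline covariates: marginals loosely follow a US waitlist registry
# (etiology mix, age distribution, ~37% female).
draw_baseline <- function(n, config) {
  etio_levels <- c("hcv_cirrhosis", "nash", "alcohol_cirrhosis",
                   "other_cirrhosis", "cholestatic", "metabolic", "tumor",
                   "other")
  etio_probs <- c(0.131, 0.207, 0.305, 0.156, 0.079, 0.021, 0.078, 0.023)
  age <- pmin(pmax(stats::rnorm(n, 56, 9.5), 18), 80)
  grade <- sample(0:3, n, replace = TRUE, prob = config$grade_probs)
  data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    age = round(age, 1),
    sex = ifelse(stats::runif(n) < 0.37, "female", "male"),
    etiology = sample(etio_levels, n, replace = TRUE, prob = etio_probs),
    aclf_grade0 = grade,
    sbp = stats::runif(n) < 0.10,
    life_support = stats::runif(n) < 0.03,
    listing_day = 0,
    stringsAsFactors = FALSE
  )
}

# Survival design vector w_i in the order of the requested names; each
# column is built lazily from the registry-style baseline columns.
baseline_design <- function(baseline, gamma_names) {
  one <- function(nm) {
    switch(nm,
      age_c = baseline$age - 56,
      female = as.numeric(baseline$sex == "female"),
      cirrhosis = as.numeric(baseline$etiology %in%
        c("hcv_cirrhosis", "nash", "alcohol_cirrhosis", "other_cirrhosis")),
      aclf1 = as.numeric(baseline$aclf_grade0 == 1),
      aclf2 = as.numeric(baseline$aclf_grade0 == 2),
      aclf3 = as.numeric(baseline$aclf_grade0 == 3),
      sbp = as.numeric(baseline$sbp),
      life_support = as.numeric(baseline$life_support),
      stop("cannot construct covariate '", nm, "' from the baseline table",
           call. = FALSE))
  }
  W <- vapply(gamma_names, one, numeric(nrow(baseline)))
  if (nrow(baseline) == 1L) W <- matrix(W, nrow = 1,
                                        dimnames = list(NULL, gamma_names))
  W
}

#' Simulate a synthetic waitlist cohort
#'
#' Draws baseline covariates, patient random effects, irregular measurement
#' times, observed MELD-Na values and a waitlist outcome per patient. Death
#' times are drawn by inverse-transform sampling on the cumulative hazard,
#' accumulated by the trapezoid rule on a fine time grid, so the scheme is
#' auditable against the closed form when the baseline hazard is constant
#' and the trajectory linear.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; all randomness in the cohort flows from it.
#' @return list with elements `baseline`, `longitudinal` (columns
#'   `patient_id`, `t`, `meld_na`), `outcomes` (`patient_id`, `event_time`,
#'   `event_type` in death/transplant/removed_other/censored), `truth`
#'   (per-patient random effects and true trajectory coefficients),
#'   `config`, `seed` and `n_redrawn` (patients redrawn after hazard
#'   overflow).
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  n <- config$n_patients
  baseline <- draw_baseline(n, config)
  W <- baseline_design(baseline, names(config$gamma))
  eta_w <- drop(W %*% config$gamma)

  L <- t(chol(config$D))
  b <- t(L %*% matrix(stats::rnorm(2 * n), 2, n))
  shift <- c(0, config$aclf_shift)[baseline$aclf_grade0 + 1L]
  icpt <- config$beta[1] + shift + b[, 1]
  slope <- config$beta[2] + b[, 2]

  grid <- seq(0, config$horizon, by = config$grid_step)
  h0v <- if (is.function(config$h0)) config$h0(grid) else rep(config$h0, length(grid))

  long <- vector("list", n)
  out <- vector("list", n)
  n_redrawn <- 0L
  for (i in seq_len(n)) {
    for (attempt in 1:25) {
      # death time via inverse transform on the trapezoid cumulative hazard
      eta <- eta_w[i] + config$alpha_value * (icpt[i] + slope[i] * grid) +
        config$alpha_slope * slope[i]
      if (any(eta > 50)) { # trajectory divergence guard
        n_redrawn <- n_redrawn + 1L
        b[i, ] <- drop(L %*% stats::rnorm(2))
        icpt[i] <- config$beta[1] + shift[i] + b[i, 1]
        slope[i] <- config$beta[2] + b[i, 2]
        next
      }
      h <- h0v * exp(eta)
      ch <- c(0, cumsum((h[-1] + h[-length(h)]) / 2 * diff(grid)))
      target <- stats::rexp(1)
      if (target >= ch[length(ch)]) {
        t_death <- Inf
      } else {
        j <- findInterval(target, ch)  # ch[j] <= target < ch[j+1]
        t_death <- grid[j] + (target - ch[j]) / (ch[j + 1] - ch[j]) *
          (grid[j + 1] - grid[j])
      }
      break
    }
    if (config$transplant_severity != 0) {
      # severity-dependent transplant intensity (thinning on the grid)
      lam_tx <- config$transplant_rate *
        exp(config$transplant_severity * (icpt[i] + slope[i] * grid - 25))
      cht <- c(0, cumsum((lam_tx[-1] + lam_tx[-length(lam_tx)]) / 2 * diff(grid)))
      tt <- stats::rexp(1)
      t_tx <- if (tt >= cht[length(cht)]) Inf else {
        j <- findInterval(tt, cht)
        grid[j] + (tt - cht[j]) / (cht[j + 1] - cht[j]) * (grid[j + 1] - grid[j])
      }
    } else {
      t_tx <- if (config$transplant_rate > 0)
        stats::rexp(1, config$transplant_rate) else Inf
    }
    t_rm <- if (config$removal_rate > 0)
      stats::rexp(1, config$removal_rate) else Inf

    event_time <- min(t_death, t_tx, t_rm, config$horizon)
    event_type <- c("death", "transplant", "removed_other", "censored")[
      which.min(c(t_death, t_tx, t_rm, config$horizon))]
    event_time <- max(event_time, 1e-3)

    # irregular measurement times: listing day plus lognormal gaps
    tm <- 0
    repeat {
      gap <- max(stats::rlnorm(1, config$gap_meanlog, config$gap_sdlog), 0.5)
      nxt <- tm[length(tm)] + gap
      if (nxt >= event_time) break
      tm <- c(tm, nxt)
    }
    y <- icpt[i] + slope[i] * tm + stats::rnorm(length(tm), 0, config$sigma)
    if (config$registry_mode) y <- pmin(pmax(round(y), 6), 40)
    long[[i]] <- data.frame(patient_id = baseline$patient_id[i], t = tm,
                            meld_na = y, stringsAsFactors = FALSE)
    out[[i]] <- data.frame(patient_id = baseline$patient_id[i],
                           event_time = event_time, event_type = event_type,
                           stringsAsFactors = FALSE)
  }
  truth <- data.frame(patient_id = baseline$patient_id,
                      b0 = b[, 1], b1 = b[, 2],
                      true_intercept = icpt, true_slope = slope)
  list(baseline = baseline,
       longitudinal = do.call(rbind, long),
       outcomes = do.call(rbind, out),
       truth = truth, config = config, seed = seed, n_redrawn = n_redrawn)
}

#' Apply registry-style study filters
#'
#' Drops candidates carrying configured baseline exclusion flags (e.g.
#' hepatocellular carcinoma, acute liver failure) and censors follow-up at
#' an exception/high-urgency date when an `exception_day` column is
#' present: the outcome becomes `censored` at that day and later
#' measurements are removed.
#'
#' @param tables list with `baseline`, `longitudinal`, `outcomes`.
#' @param exclude_flags character vector of logical baseline columns whose
#'   carriers are excluded (missing columns are ignored).
#' @return list with the filtered `tables` and a `report` of per-rule counts.
#' @export
apply_study_filters <- function(tables,
                                exclude_flags = c("hcc", "acute_liver_failure")) {
  bl <- tables$baseline
  report <- list()
  drop <- rep(FALSE, nrow(bl))
  for (fl in exclude_flags) {
    if (!is.null(bl[[fl]])) {
      hit <- as.logical(bl[[fl]]) %in% TRUE
      report[[fl]] <- sum(hit)
      drop <- drop | hit
    }
  }
  keep_ids <- bl$patient_id[!drop]
  bl <- bl[!drop, , drop = FALSE]
  lg <- tables$longitudinal[tables$longitudinal$patient_id %in% keep_ids, ,
                            drop = FALSE]
  oc <- tables$outcomes[tables$outcomes$patient_id %in% keep_ids, ,
                        drop = FALSE]
  n_exc <- 0L
  if (!is.null(bl$exception_day)) {
    idx <- match(oc$patient_id, bl$patient_id)
    ed <- bl$exception_day[idx]
    cens <- !is.na(ed) & ed < oc$event_time
    n_exc <- sum(cens)
    oc$event_time[cens] <- ed[cens]
    oc$event_type[cens] <- "censored"
    cut <- bl$exception_day[match(lg$patient_id, bl$patient_id)]
    lg <- lg[is.na(cut) | lg$t <= cut, , drop = FALSE]
  }
  report$exception_censored <- n_exc
  list(tables = list(baseline = bl, longitudinal = lg, outcomes = oc),
       report = report)
}

#' Patient-level train/test split
#'
#' Randomly partitions patients (never rows) into a training and a testing
#' set; the default 67/33 split mirrors common development/validation
#' practice for waitlist prediction models.
#'
#' @param tables list with `baseline`, `longitudinal`, `outcomes`.
#' @param fraction training fraction in (0, 1).
#' @param seed integer seed.
#' @return list with `train` and `test`, each a tables list.
#' @export
split_train_test <- function(tables, fraction = 0.67, seed = 1) {
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly between 0 and 1", call. = FALSE)
  ids <- tables$baseline$patient_id
  if (length(ids) < 2) stop("need at least 2 patients to split", call. = FALSE)
  set.seed(as.integer(seed))
  n_train <- max(1L, min(length(ids) - 1L, round(fraction * length(ids))))
  train_ids <- sample(ids, n_train)
  pick <- function(keep) {
    list(baseline = tables$baseline[tables$baseline$patient_id %in% keep, ,
                                    drop = FALSE],
         longitudinal = tables$longitudinal[
           tables$longitudinal$patient_id %in% keep, , drop = FALSE],
         outcomes = tables$outcomes[tables$outcomes$patient_id %in% keep, ,
                                    drop = FALSE])
  }
  list(train = pick(train_ids), test = pick(setdiff(ids, train_ids)))
}

#' Crude lab panel consistent with a target MELD-Na (demo data only)
#'
#' Back-solves a synthetic lab panel whose UNOS score approximates a target
#' MELD-Na by spreading the required log-score equally across bilirubin,
#' creatinine and INR at sodium 137. Intended only for constructing demo
#' inputs for the scoring pipeline; real panels are not identifiable from a
#' score.
#'
#' @param meld_na target integer scores (6-40).
#' @return data.frame of synthetic `bilirubin`, `creatinine`, `inr`,
#'   `sodium` values.
#' @export
demo_labs_from_meldna <- function(meld_na) {
  s <- pmax((meld_na / 10 - 0.643) / (0.957 + 0.378 + 1.120), 0)
  data.frame(bilirubin = exp(s), creatinine = pmin(exp(s), 4),
             inr = exp(s), sodium = 137)
}
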