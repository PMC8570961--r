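# Landmarked discrimination and calibration. Subjects censored inside the
# prediction window contribute through inverse-probability-of-censoring
# (IPCW) weights estimated by Kaplan-Meier of the censoring distribution
# on the at-risk set, rather than being silently dropped.

# Censoring survivor function G at requested times, KM on the at-risk set.
censor_km <- function(time, death, eval_times) {
  cens <- 1 - death
  sf <- survival::survfit(survival::Surv(time, cens) ~ 1)
  approx_G <- stats::stepfun(sf$time, c(1, sf$surv), right = FALSE)
  g <- approx_G(eval_times)
  g
}

#' Time-dependent AUC (cumulative cases / dynamic controls, IPCW)
#'
#' Probability that a randomly chosen subject dying inside
#' `(t, t + horizon]` carries a higher risk score than one surviving past
#' `t + horizon`, among subjects still at risk at the landmark `t`.
#' Pairs are weighted by inverse censoring probabilities; with no
#' censoring in the window this reduces to the plain concordant-pair
#' fraction (ties count one half).
#'
#' @param risk numeric risk scores (higher = more ill) for the at-risk
#'   subjects.
#' @param time event/censoring times; `death` event indicator (1 = death).
#' @param t landmark; `horizon` window length.
#' @return AUC in \[0, 1\].
#' @export
dynamic_auc <- function(risk, time, death, t, horizon) {
  if (length(risk) != length(time)) stop("risk and time lengths differ",
                                         call. = FALSE)
  at <- time > t
  risk <- risk[at]; time <- time[at]; death <- death[at]
  if (any(!is.finite(risk))) stop("non-finite risk scores", call. = FALSE)
  u <- t + horizon
  case <- death == 1 & time <= u
  ctrl <- time > u
  if (!any(case) || !any(ctrl))
    stop("time-dependent AUC undefined: no ",
         if (!any(case)) "events" else "survivors",
         " in the prediction window", call. = FALSE)
  Gi <- censor_km(time, death, pmin(time, u) - 1e-9)
  Gu <- censor_km(time, death, u)
  if (any(Gi[case] <= 0) || Gu <= 0)
    stop("censoring distribution vanishes inside the window; ",
         "IPCW weights undefined", call. = FALSE)
  wc <- 1 / Gi[case]
  wk <- rep(1 / Gu, sum(ctrl))
  rc <- risk[case]; rk <- risk[ctrl]
  conc <- outer(rc, rk, ">") + 0.5 * outer(rc, rk, "==")
  wsum <- outer(wc, wk)
  sum(conc * wsum) / sum(wsum)
}

#' Censoring-weighted prediction error (Brier type)
#'
#' Mean squared difference between the survival indicator at
#' `t + horizon` and the predicted conditional survival probability,
#' IPCW-weighted. Without censoring this equals the plain Brier score.
#'
#' @param pi_pred predicted conditional survival probabilities
#'   `pi(t + horizon | t)` for the at-risk subjects.
#' @inheritParams dynamic_auc
#' @return non-negative prediction error.
#' @export
prediction_error <- function(pi_pred, time, death, t, horizon) {
  at <- time > t
  pi_pred <- pi_pred[at]; time <- time[at]; death <- death[at]
  u <- t + horizon
  died <- death == 1 & time <= u
  surv <- time > u
  Gi <- censor_km(time, death, pmin(time, u) - 1e-9)
  Gu <- censor_km(time, death, u)
  if (any(Gi[died] <= 0) || (any(surv) && Gu <= 0))
    stop("censoring distribution vanishes inside the window; ",
         "IPCW weights undefined", call. = FALSE)
  wt <- numeric(length(time))
  wt[died] <- 1 / Gi[died]
  wt[surv] <- 1 / Gu
  err <- numeric(length(time))
  err[died] <- (0 - pi_pred[died])^2
  err[surv] <- (1 - pi_pred[surv])^2
  sum(wt * err) / length(time)
}

#' Percentile bootstrap interval over patient-level resamples
#'
#' @param metric_fn function taking a data.frame (one row per patient) and
#'   returning a scalar.
#' @param data data.frame, one row per patient.
#' @param n_boot number of resamples (>= 100).
#' @param seed integer seed.
#' @param probs interval probabilities.
#' @return named vector `c(lo, hi)`.
#' @export
bootstrap_ci <- function(metric_fn, data, n_boot = 500, seed = 1,
                         probs = c(0.025, 0.975)) {
  if (n_boot < 100) stop("n_boot must be at least 100", call. = FALSE)
  set.seed(as.integer(seed))
  vals <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    ix <- sample.int(nrow(data), replace = TRUE)
    vals[b] <- tryCatch(metric_fn(data[ix, , drop = FALSE]),
                        error = function(e) NA_real_)
  }
  bad <- mean(is.na(vals))
  if (bad > 0.10)
    stop(sprintf(paste0("metric undefined in %.0f%% of resamples ",
                        "(> 10%%); interval not reported"), 100 * bad),
         call. = FALSE)
  q <- stats::quantile(vals, probs, na.rm = TRUE, names = FALSE)
  c(lo = q[1], hi = q[2])
}

# Landmark data: per at-risk patient, JM survival prediction and the
# last-observed MELD-Na at the landmark.
landmark_frame <- function(tables, jm_fit, t, horizons, method = "plugin") {
  oc <- tables$outcomes
  bl <- tables$baseline
  lg <- tables$longitudinal
  ids <- oc$patient_id[oc$event_time > t]
  rows <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    id <- ids[k]
    hist_k <- lg[lg$patient_id == id & lg$t <= t + 1e-9, , drop = FALSE]
    if (!nrow(hist_k)) next
    brow <- bl[bl$patient_id == id, , drop = FALSE]
    pr <- predict_survival(jm_fit, hist_k, brow, t, t + horizons,
                           method = method)
    oci <- oc[oc$patient_id == id, ]
    row <- data.frame(patient_id = id,
                      time = oci$event_time,
                      death = as.numeric(oci$event_type == "death"),
                      last_meldna = hist_k$meld_na[which.max(hist_k$t)])
    for (j in seq_along(horizons))
      row[[paste0("pi_", horizons[j])]] <- pr$pi[j]
    rows[[k]] <- row
  }
  do.call(rbind, rows)
}

#' Landmarked comparison of the joint model against a last-value benchmark
#'
#' For every landmark x horizon cell, computes time-dependent AUC and
#' IPCW prediction error for (i) the joint model's dynamic predictions and
#' (ii) a benchmark that scores patients by a Cox fit on the most recent
#' MELD-Na at the landmark (the current allocation logic, which ignores
#' earlier history). Confidence intervals use a paired bootstrap: both
#' models are evaluated on the same patient resamples.
#'
#' @param test tables list (held-out patients).
#' @param jm_fit a `meldjm_jm` fit (trained on disjoint patients).
#' @param landmarks,horizons evaluation grid (days).
#' @param n_boot bootstrap resamples for CIs (0 skips CIs).
#' @param seed bootstrap seed.
#' @param method prediction mode for the joint model.
#' @return data.frame with one row per landmark x horizon x model:
#'   `auc`, `auc_lo`, `auc_hi`, `pe`, `pe_lo`, `pe_hi`, `n_at_risk`,
#'   `n_events`, plus `auc_diff`/`p_auc_diff` on the joint-model rows.
#' @export
compare_models <- function(test, jm_fit, landmarks = c(0, 2, 7, 14),
                           horizons = c(28, 90), n_boot = 200, seed = 1,
                           method = "plugin") {
  out <- list()
  for (t in landmarks) {
    lf <- landmark_frame(test, jm_fit, t, horizons, method)
    if (is.null(lf) || !nrow(lf))
      stop("no patients usable at landmark ", t, call. = FALSE)
    # benchmark Cox on the most recent MELD-Na at this landmark
    cox <- survival::coxph(
      survival::Surv(time - t, death) ~ last_meldna, data = lf)
    bh <- survival::basehaz(cox, centered = FALSE)
    lp <- drop(as.matrix(lf$last_meldna) %*% stats::coef(cox))
    H0 <- stats::stepfun(bh$time, c(0, bh$hazard))
    for (h in horizons) {
      pi_jm <- lf[[paste0("pi_", h)]]
      pi_cox <- exp(-H0(h) * exp(lp))
      dat <- data.frame(time = lf$time, death = lf$death,
                        risk_jm = 1 - pi_jm, pi_jm = pi_jm,
                        risk_cox = lp, pi_cox = pi_cox)
      cell <- function(d, which) {
        risk <- d[[paste0("risk_", which)]]
        ppi <- d[[paste0("pi_", which)]]
        c(auc = dynamic_auc(risk, d$time, d$death, t, h),
          pe = prediction_error(ppi, d$time, d$death, t, h))
      }
      pt_jm <- cell(dat, "jm"); pt_cox <- cell(dat, "cox")
      ci <- list(jm = c(NA, NA, NA, NA), cox = c(NA, NA, NA, NA))
      p_diff <- NA_real_; d_lo <- NA_real_; d_hi <- NA_real_
      if (n_boot > 0) {
        set.seed(as.integer(seed))
        bs <- matrix(NA_real_, n_boot, 5)
        for (b in seq_len(n_boot)) {
          ix <- sample.int(nrow(dat), replace = TRUE)
          bs[b, ] <- tryCatch({
            cj <- cell(dat[ix, ], "jm"); cc <- cell(dat[ix, ], "cox")
            c(cj, cc, cj["auc"] - cc["auc"])
          }, error = function(e) rep(NA_real_, 5))
        }
        qs <- apply(bs, 2, stats::quantile, probs = c(0.025, 0.975),
                    na.rm = TRUE)
        # per model: (auc_lo, auc_hi, pe_lo, pe_hi)
        ci$jm <- c(qs[1, 1], qs[2, 1], qs[1, 2], qs[2, 2])
        ci$cox <- c(qs[1, 3], qs[2, 3], qs[1, 4], qs[2, 4])
        dd <- bs[, 5]; dd <- dd[!is.na(dd)]
        p_diff <- 2 * min(mean(dd <= 0), mean(dd >= 0))
        p_diff <- min(max(p_diff, 1 / length(dd)), 1)
        d_lo <- stats::quantile(dd, 0.025, names = FALSE)
        d_hi <- stats::quantile(dd, 0.975, names = FALSE)
      }
      out[[length(out) + 1]] <- data.frame(
        landmark = t, horizon = h,
        model = c("aclf_jm", "meld_na"),
        auc = c(pt_jm["auc"], pt_cox["auc"]),
        auc_lo = c(ci$jm[1], ci$cox[1]), auc_hi = c(ci$jm[2], ci$cox[2]),
        pe = c(pt_jm["pe"], pt_cox["pe"]),
        pe_lo = c(ci$jm[3], ci$cox[3]), pe_hi = c(ci$jm[4], ci$cox[4]),
        n_at_risk = nrow(lf), n_events = sum(lf$death & lf$time <= t + h),
        auc_diff = c(pt_jm["auc"] - pt_cox["auc"], NA),
        auc_diff_lo = c(d_lo, NA), auc_diff_hi = c(d_hi, NA),
        p_auc_diff = c(p_diff, NA), row.names = NULL)
    }
  }
  do.call(rbind, out)
}
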