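# Counterfactual graft-offer re-ranking over the first 28 waitlist days:
# at each sequential offer the top-ranked active candidate under a scoring
# rule is transplanted and leaves the pool; patients dying beforehand
# leave at their death time. Comparing the transplanted sets under the
# joint-model rule and the last-MELD-Na rule stratifies the cohort into
# four priority groups.

#' Graft-offer stream
#'
#' Offer times within `(0, follow_up]`. Only the offer count of the
#' registry period is known, so times default to the order statistics of
#' a uniform draw; a vector of real offer times can be supplied instead.
#'
#' @param n_offers number of grafts offered.
#' @param follow_up window length in days (28 by default).
#' @param seed seed for the uniform draw.
#' @param times optional explicit offer times (overrides the draw).
#' @return sorted numeric vector of offer times, class `offer_stream`.
#' @export
offer_stream <- function(n_offers, follow_up = 28, seed = 1, times = NULL) {
  if (is.null(times)) {
    set.seed(as.integer(seed))
    times <- sort(stats::runif(n_offers, 0, follow_up))
  } else {
    times <- sort(as.numeric(times))
    if (any(times <= 0) || any(times > follow_up))
      stop("offer times must lie in (0, follow_up]", call. = FALSE)
  }
  structure(times, follow_up = follow_up, class = "offer_stream")
}

#' Simulate allocation under a prioritization rule
#'
#' Iterates the offers in time order. At each offer, candidates still
#' active (listed, not yet transplanted in this simulation, not yet
#' dead/removed) are ranked by the rule - joint-model predicted 28-day
#' mortality from history up to the offer time (updated at every offer by
#' default, or frozen at a fixed landmark), or the most recent MELD-Na -
#' and the top candidate is removed as transplanted. Ties break on
#' lexicographic patient id.
#'
#' @param tables cohort tables (`baseline`, `longitudinal`, `outcomes`).
#' @param fit a `meldjm_jm` fit (used by the `"jm"` rule).
#' @param offers an [offer_stream()].
#' @param rule `"jm"` or `"meldna"`.
#' @param horizon risk horizon (days) for the joint-model rule.
#' @param update `"each_offer"` recomputes predictions at every offer
#'   time; `"fixed"` uses predictions frozen at time 0.
#' @return character vector of transplanted patient ids (offer order);
#'   attribute `skipped` counts offers with an empty active pool.
#' @export
simulate_allocation <- function(tables, fit, offers,
                                rule = c("jm", "meldna"), horizon = 28,
                                update = c("each_offer", "fixed")) {
  rule <- match.arg(rule); update <- match.arg(update)
  oc <- tables$outcomes; lg <- tables$longitudinal
  ids <- tables$baseline$patient_id
  n <- length(ids)
  event_time <- oc$event_time[match(ids, oc$patient_id)]

  # per-patient measurement history, time-sorted
  o <- order(match(lg$patient_id, ids), lg$t)
  lg <- lg[o, ]
  idx <- match(lg$patient_id, ids)
  h_t <- split(lg$t, factor(idx, levels = seq_len(n)))
  h_y <- split(lg$meld_na, factor(idx, levels = seq_len(n)))

  if (rule == "jm") {
    lspec <- fit$spec$lspec
    if (length(lspec$covariates))
      stop("the fast allocation path supports longitudinal specs without ",
           "baseline covariates in the trajectory", call. = FALSE)
    W <- survival_design(tables$baseline, names(fit$gamma))
    gw <- drop(W %*% fit$gamma)
    Dinv <- solve(fit$D); s2 <- fit$sigma^2
    mu <- matrix(NA_real_, n, 2)
    n_used <- integer(n)
    gl <- pracma::gaussLegendre(7, -1, 1)
    update_mu <- function(i, m) {
      tt <- h_t[[i]][seq_len(m)]
      X <- build_design(tt, lspec)
      Z <- rand_design(tt)
      A <- crossprod(Z) / s2 + Dinv
      r <- h_y[[i]][seq_len(m)] - drop(X %*% fit$beta)
      drop(solve(A, crossprod(Z, r) / s2))
    }
    # conditional death risk over (tm, tm+horizon] for a set of patients,
    # plug-in at the posterior mean of the random effects
    risk_batch <- function(tm, act) {
      taus <- c(tm, tm + horizon)
      cum <- matrix(0, length(act), 2)
      for (j in 1:2) {
        tau <- taus[j]
        if (tau <= 0) next
        nd <- seg_quad_nodes(fit$breaks, tau, gl$x, gl$w)
        tq <- nd$t; wq <- nd$w; lamq <- fit$lambda[nd$seg + 1L]
        fv <- drop(build_design(tq, lspec) %*% fit$beta)
        fs <- drop(build_design(tq, lspec, deriv = 1L) %*% fit$beta)
        val <- outer(mu[act, 1], rep(1, length(tq))) + outer(mu[act, 2], tq) +
          matrix(fv, length(act), length(tq), byrow = TRUE)
        slp <- matrix(fs, length(act), length(tq), byrow = TRUE) + mu[act, 2]
        eta <- gw[act] + fit$alpha_value * val + fit$alpha_slope * slp
        cum[, j] <- drop(exp(pmin(eta, 50)) %*% (wq * lamq))
      }
      1 - exp(-(cum[, 2] - cum[, 1]))
    }
  }

  transplanted_i <- integer(0)
  skipped <- 0L
  for (tm in as.numeric(offers)) {
    tt <- if (rule == "jm" && update == "fixed") 0 else tm
    active <- setdiff(which(event_time > tm), transplanted_i)
    if (!length(active)) { skipped <- skipped + 1L; next }
    if (rule == "meldna") {
      r <- vapply(active, function(i) {
        m <- findInterval(tm + 1e-9, h_t[[i]])
        if (m == 0L) -Inf else h_y[[i]][m]
      }, numeric(1))
    } else {
      for (i in active) {
        m <- findInterval(tt + 1e-9, h_t[[i]])
        if (m > 0L && m != n_used[i]) {
          mu[i, ] <- update_mu(i, m)
          n_used[i] <- m
        }
      }
      r <- rep(-Inf, length(active))
      has <- n_used[active] > 0L
      if (any(has)) r[has] <- risk_batch(tt, active[has])
    }
    ok <- is.finite(r)
    if (!any(ok)) { skipped <- skipped + 1L; next }
    cand <- active[ok]; r <- r[ok]
    pick <- cand[order(-r, ids[cand])][1]
    transplanted_i <- c(transplanted_i, pick)
  }
  transplanted <- ids[transplanted_i]
  attr(transplanted, "skipped") <- skipped
  transplanted
}

#' Four-way priority classification and group summaries
#'
#' Partitions the cohort by membership of the two transplanted sets:
#' prioritized by `both` rules, by the joint model only (`jm_only`), by
#' MELD-Na only (`meldna_only`), or by `neither`. Group summaries mirror
#' the registry comparison: size, age, sex, 28-day death, baseline ACLF
#' mix, etiology, median last MELD-Na, life support.
#'
#' @param jm_set,meldna_set transplanted id sets from
#'   [simulate_allocation()] under the two rules (same offer stream).
#' @param tables the cohort tables used for both runs.
#' @param follow_up window end for the death-rate summary (days).
#' @return list with `classification` (per-patient groups and
#'   `died_within_28d`) and `summary` (per-group table).
#' @export
classify_priority <- function(jm_set, meldna_set, tables, follow_up = 28) {
  bl <- tables$baseline; oc <- tables$outcomes
  if (!all(jm_set %in% bl$patient_id) || !all(meldna_set %in% bl$patient_id))
    stop("transplanted sets contain unknown patients", call. = FALSE)
  ids <- bl$patient_id
  in_jm <- ids %in% jm_set; in_me <- ids %in% meldna_set
  group <- ifelse(in_jm & in_me, "both",
                  ifelse(in_jm, "jm_only",
                         ifelse(in_me, "meldna_only", "neither")))
  oci <- oc[match(ids, oc$patient_id), ]
  died28 <- oci$event_type == "death" & oci$event_time <= follow_up
  lg <- tables$longitudinal
  last_meld <- vapply(ids, function(id) {
    h <- lg[lg$patient_id == id, , drop = FALSE]
    h$meld_na[which.max(h$t)]
  }, numeric(1), USE.NAMES = FALSE)
  cls <- data.frame(patient_id = ids, group = group,
                    died_within_28d = died28, stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(c("both", "jm_only", "meldna_only",
                                  "neither"), function(g) {
    ix <- group == g
    data.frame(group = g, n = sum(ix),
               median_age = as.numeric(stats::median(bl$age[ix])),
               pct_female = mean(bl$sex[ix] == "female") * 100,
               pct_death_28d = mean(died28[ix]) * 100,
               pct_aclf1 = mean(bl$aclf_grade0[ix] == 1) * 100,
               pct_aclf2 = mean(bl$aclf_grade0[ix] == 2) * 100,
               pct_aclf3 = mean(bl$aclf_grade0[ix] == 3) * 100,
               median_meld_na = as.numeric(stats::median(last_meld[ix])),
               pct_life_support = mean(bl$life_support[ix]) * 100,
               row.names = NULL)
  }))
  list(classification = cls, summary = summ)
}
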