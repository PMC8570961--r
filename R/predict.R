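# Dynamic survival prediction. For a patient with measurement history up
# to a landmark t, the conditional survival is
#   pi(u|t) = E[ S(u|b) / S(t|b) | history, T > t ]
# with the expectation over the posterior of the random effects. Because
# the longitudinal factor is Gaussian, conditioning on the history alone
# gives a closed-form normal posterior N(mu, Sigma); conditioning further
# on T > t multiplies it by S(t|b), and the ratio of expectations
#   pi(u|t) = E_N[S(u|b)] / E_N[S(t|b)]
# is exact. Modes: seeded importance sampling with a t(4) proposal
# (default), deterministic Gauss-Hermite quadrature, or a first-order
# plug-in at the empirical-Bayes mode.

# Gaussian posterior of b given the measurement history.
history_posterior <- function(fit, history, covar = NULL) {
  lspec <- fit$spec$lspec %||% fit$spec
  cv <- if (length(lspec$covariates))
    covar[rep(1, nrow(history)), lspec$covariates, drop = FALSE] else NULL
  X <- build_design(history$t, lspec, cv)
  Z <- rand_design(history$t)
  s2 <- fit$sigma^2
  A <- crossprod(Z) / s2 + solve(fit$D)
  Sigma <- solve(A)
  r <- history$meld_na - drop(X %*% fit$beta)
  mu <- drop(Sigma %*% (crossprod(Z, r) / s2))
  list(mu = mu, Sigma = Sigma)
}

# Cumulative hazard Lambda(tau | b) for a matrix of random-effect draws.
# Returns draws x taus.
cumhaz_draws <- function(fit, w, B, taus, covar = NULL) {
  lspec <- fit$spec$lspec %||% fit$spec
  breaks <- fit$breaks; lambda <- fit$lambda
  K <- length(lambda)
  gl <- pracma::gaussLegendre(7, -1, 1)
  out <- matrix(0, nrow(B), length(taus))
  gw <- sum(fit$gamma * w)
  for (j in seq_along(taus)) {
    tau <- taus[j]
    if (tau <= 0) next
    nd <- meldjm_seg_nodes(breaks, tau, gl)
    tq <- nd$t; wq <- nd$w; lamq <- lambda[nd$seg + 1L]
    cv <- if (length(lspec$covariates))
      covar[rep(1, length(tq)), lspec$covariates, drop = FALSE] else NULL
    fv <- drop(build_design(tq, lspec, cv) %*% fit$beta)
    fs <- drop(build_design(tq, lspec, cv, deriv = 1L) %*% fit$beta)
    # value/slope per draw: n_draws x nq
    val <- outer(B[, 1], rep(1, length(tq))) + outer(B[, 2], tq) +
      matrix(fv, nrow(B), length(tq), byrow = TRUE)
    slp <- matrix(fs, nrow(B), length(tq), byrow = TRUE) + B[, 2]
    eta <- gw + fit$alpha_value * val + fit$alpha_slope * slp
    out[, j] <- drop(exp(pmin(eta, 50)) %*% (wq * lamq))
  }
  out
}

#' Dynamic conditional survival prediction
#'
#' Computes the updating conditional survival curve `pi(u|t)` for one
#' patient given baseline covariates and all MELD-Na measurements up to
#' the landmark `t`.
#'
#' @param fit a `meldjm_jm` fit.
#' @param history data.frame of the patient's measurements (`t`,
#'   `meld_na`), all with `t <= landmark`.
#' @param baseline one-row data.frame of the patient's baseline covariates.
#' @param landmark landmark time t (days); must be at or after the first
#'   measurement.
#' @param u_grid horizon times u > t.
#' @param method `"mc"` (seeded importance sampling, with a Monte-Carlo
#'   percentile band), `"gh"` (deterministic Gauss-Hermite) or `"plugin"`
#'   (first-order plug-in at the EB mode; fastest).
#' @param n_draws Monte-Carlo draws for `method = "mc"`.
#' @param seed seed for the draws.
#' @return data.frame with `u`, `pi` and, for `"mc"`, `lo`/`hi` (2.5/97.5
#'   Monte-Carlo percentiles); attributes `landmark`, `method`, `n_draws`,
#'   `seed`.
#' @export
predict_survival <- function(fit, history, baseline, landmark, u_grid,
                             method = c("mc", "gh", "plugin"),
                             n_draws = 200, seed = 1) {
  method <- match.arg(method)
  if (!nrow(history)) stop("history is empty: at least one measurement is ",
                           "required", call. = FALSE)
  if (landmark < min(history$t))
    stop("landmark precedes the first measurement", call. = FALSE)
  if (any(history$t > landmark + 1e-9))
    stop("history contains measurements after the landmark", call. = FALSE)
  if (any(u_grid < landmark)) stop("u_grid must not precede the landmark",
                                   call. = FALSE)
  post <- history_posterior(fit, history, baseline)
  w <- drop(survival_design(baseline, names(fit$gamma)))

  taus <- c(landmark, u_grid)
  if (method == "plugin") {
    B <- matrix(post$mu, 1, 2)
    ch <- cumhaz_draws(fit, w, B, taus, baseline)
    pi_u <- exp(-(ch[1, -1] - ch[1, 1]))
    out <- data.frame(u = u_grid, pi = pmin(pmax(pi_u, 0), 1))
  } else if (method == "gh") {
    gh <- pracma::gaussHermite(15)
    Lq <- t(chol(post$Sigma))
    nodes <- as.matrix(expand.grid(gh$x, gh$x))
    wts <- as.vector(outer(gh$w, gh$w)) / pi
    B <- t(post$mu + sqrt(2) * Lq %*% t(nodes))
    ch <- cumhaz_draws(fit, w, B, taus, baseline)
    # log-sum-exp over nodes: robust when survival underflows
    lse <- apply(log(wts) - ch, 2, logsumexp)
    out <- data.frame(u = u_grid,
                      pi = pmin(pmax(exp(lse[-1] - lse[1]), 0), 1))
  } else {
    set.seed(as.integer(seed))
    Lq <- t(chol(post$Sigma))
    zz <- matrix(stats::rnorm(2 * n_draws), n_draws, 2)
    g <- stats::rchisq(n_draws, df = 4) / 4
    Tm <- zz / sqrt(g)                       # t(4) proposal in 2-D
    B <- t(post$mu + Lq %*% t(Tm))
    # log weights: normal posterior density over t(4) proposal density
    # densities in the standardized space (the chol factor cancels in the
    # ratio, so weights can be formed on Tm directly)
    log_phi <- -0.5 * rowSums(Tm^2)
    log_t <- lgamma(3) - lgamma(2) - log(4 * pi) -
      3 * log1p(rowSums(Tm^2) / 4)
    lw <- log_phi - log(2 * pi) - log_t
    lw <- lw - max(lw)
    ch <- cumhaz_draws(fit, w, B, taus, baseline)
    lse <- apply(lw - ch, 2, logsumexp)
    pi_u <- pmin(pmax(exp(lse[-1] - lse[1]), 0), 1)
    # draw-level conditional ratios S(u|b)/S(t|b), weighted by the
    # posterior-given-survival importance weights, for the MC band
    r <- exp(pmax(ch[, 1] - ch[, -1, drop = FALSE], -700))
    wc <- exp(lw - ch[, 1] - max(lw - ch[, 1]))
    qs <- apply(r, 2, weighted_quantile, w = wc, probs = c(0.025, 0.975))
    out <- data.frame(u = u_grid, pi = pi_u,
                      lo = pmin(qs[1, ], pi_u), hi = pmax(qs[2, ], pi_u))
  }
  attr(out, "landmark") <- landmark
  attr(out, "method") <- method
  attr(out, "n_draws") <- if (method == "mc") n_draws else NA_integer_
  attr(out, "seed") <- if (method == "mc") seed else NA_integer_
  out
}

meldjm_seg_nodes <- function(breaks, tau, gl) {
  seg_quad_nodes(breaks, tau, gl$x, gl$w)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  sapply(probs, function(p) x[o][which(cw >= p)[1]])
}

#' Rank patients by predicted short-horizon mortality
#'
#' Orders candidates from most to least ill by ascending conditional
#' survival `pi(t + horizon | t)`. Ties break on longer time since listing
#' first, then lexicographic patient id, so rankings are deterministic.
#'
#' @param fit a `meldjm_jm` fit.
#' @param tables list with `baseline` and `longitudinal`; only
#'   measurements at or before `t` are used.
#' @param t landmark time (days).
#' @param horizon prediction horizon (days).
#' @param ids optional subset of patient ids to rank (default: all with a
#'   measurement by `t`).
#' @param method prediction mode passed to [predict_survival()]
#'   (`"plugin"` by default for speed).
#' @return data.frame `patient_id`, `pi`, `rank` ordered most-ill first.
#' @export
rank_by_mortality <- function(fit, tables, t, horizon, ids = NULL,
                              method = "plugin") {
  bl <- tables$baseline
  if (is.null(ids)) ids <- bl$patient_id
  pis <- rep(NA_real_, length(ids))
  for (k in seq_along(ids)) {
    hist_k <- tables$longitudinal[
      tables$longitudinal$patient_id == ids[k] &
        tables$longitudinal$t <= t + 1e-9, , drop = FALSE]
    if (!nrow(hist_k)) next
    brow <- bl[bl$patient_id == ids[k], , drop = FALSE]
    pis[k] <- predict_survival(fit, hist_k, brow, t, t + horizon,
                               method = method)$pi
  }
  keep <- !is.na(pis)
  listed <- rep(0, sum(keep))  # all candidates share listing at day 0
  o <- order(pis[keep], -listed, ids[keep])
  data.frame(patient_id = ids[keep][o], pi = pis[keep][o],
             rank = seq_len(sum(keep)))
}
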