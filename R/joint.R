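# Joint model: mixed-effects MELD-Na trajectories coupled to a
# proportional-hazards survival submodel with piecewise-constant baseline
# hazard, associated through the current trajectory value and slope.
# The likelihood lives in src/jm_loglik.cpp; this file builds the
# parameter-independent design blocks, drives estimation, and exposes
# hazard ratios.

#' Survival submodel specification
#'
#' @param covariates names of baseline covariates entering the hazard.
#'   The registry-style names `age_c` (age in years centred at 56),
#'   `female`, `cirrhosis`, `aclf1`/`aclf2`/`aclf3` (baseline ACLF grade
#'   indicators), `sbp` and `life_support` are constructed from the
#'   baseline table; any other name is taken as a numeric baseline column.
#' @param n_segments number of piecewise-constant baseline-hazard segments
#'   (knots at event-time quantiles).
#' @param assoc association structure; `"value"`, `"slope"` or both.
#' @param gh_points Gauss-Hermite points per random-effect dimension.
#' @param gl_points Gauss-Legendre points per hazard-integration chunk.
#' @param gl_chunk maximum chunk width (days) when subdividing hazard
#'   segments for integration; steep trajectory exponents need bounded
#'   chunks to stay resolvable.
#' @return object of class `surv_spec`.
#' @export
surv_spec <- function(covariates = c("age_c", "female", "cirrhosis", "aclf1",
                                     "aclf2", "aclf3", "sbp", "life_support"),
                      n_segments = 7L,
                      assoc = c("value", "slope"),
                      gh_points = 9L, gl_points = 7L, gl_chunk = 14) {
  if (n_segments < 1L) stop("need at least one hazard segment", call. = FALSE)
  assoc <- match.arg(assoc, c("value", "slope"), several.ok = TRUE)
  structure(list(covariates = covariates, n_segments = as.integer(n_segments),
                 assoc = assoc, gh_points = as.integer(gh_points),
                 gl_points = as.integer(gl_points), gl_chunk = gl_chunk,
                 breaks = NULL),
            class = "surv_spec")
}

# Numeric survival design from the baseline table.
survival_design <- function(baseline, covariates) {
  special <- c("age_c", "female", "cirrhosis", "aclf1", "aclf2", "aclf3",
               "sbp", "life_support")
  cols <- lapply(covariates, function(nm) {
    if (!is.null(baseline[[nm]]) && !nm %in% special) {
      as.numeric(baseline[[nm]])
    } else if (nm %in% special) {
      if (!is.null(baseline[[nm]])) as.numeric(baseline[[nm]])
      else drop(baseline_design(baseline, nm)[, 1])
    } else {
      stop("unknown survival covariate: ", nm, call. = FALSE)
    }
  })
  W <- do.call(cbind, cols)
  colnames(W) <- covariates
  W
}

# Gauss-Legendre nodes for the cumulative hazard over (0, tau] under
# piecewise-constant segments. Long segments are subdivided into chunks of
# at most `chunk` days so steep trajectory exponents stay resolvable.
seg_quad_nodes <- function(breaks, tau, glx, glw, chunk = 10) {
  K <- length(breaks) - 1L
  tt <- ww <- numeric(0); ss <- integer(0)
  for (k in seq_len(K)) {
    a <- breaks[k]; b <- min(breaks[k + 1], tau)
    if (b <= a) break
    nc <- ceiling((b - a) / chunk)
    edges <- seq(a, b, length.out = nc + 1)
    for (j in seq_len(nc)) {
      lo <- edges[j]; hi <- edges[j + 1]
      tt <- c(tt, (lo + hi) / 2 + (hi - lo) / 2 * glx)
      ww <- c(ww, (hi - lo) / 2 * glw)
      ss <- c(ss, rep(k - 1L, length(glx)))
    }
  }
  list(t = tt, w = ww, seg = ss)
}

# Baseline-hazard segment breaks from observed death times.
hazard_breaks <- function(event_time, is_event, n_segments) {
  et <- event_time[is_event]
  if (!length(et)) stop("no death events: survival parameters are not ",
                        "estimable from these data", call. = FALSE)
  if (n_segments == 1L) return(c(0, Inf))
  qs <- unique(stats::quantile(et, probs = seq_len(n_segments - 1) / n_segments))
  qs <- qs[qs > 0]
  c(0, unname(qs), Inf)
}

# Parameter-independent design blocks consumed by the C++ likelihood.
build_jm_blocks <- function(longitudinal, baseline, outcomes, lspec, sspec) {
  ids <- baseline$patient_id
  if (!setequal(ids, outcomes$patient_id))
    stop("baseline and outcome tables cover different patients", call. = FALSE)
  if (!all(longitudinal$patient_id %in% ids))
    stop("longitudinal table has patients absent from baseline", call. = FALSE)
  cnt <- table(factor(longitudinal$patient_id, levels = ids))
  if (any(cnt == 0))
    stop("every patient needs at least one measurement; missing for e.g. ",
         names(cnt)[which(cnt == 0)[1]], call. = FALSE)
  oc <- outcomes[match(ids, outcomes$patient_id), ]
  delta <- as.numeric(oc$event_type == "death")
  Ti <- oc$event_time
  if (any(Ti <= 0)) stop("event times must be positive", call. = FALSE)

  lspec <- prepare_spec(lspec, longitudinal$t)
  if (is.null(sspec$breaks))
    sspec$breaks <- hazard_breaks(Ti, delta == 1, sspec$n_segments)
  breaks <- sspec$breaks
  K <- length(breaks) - 1L

  ord <- order(match(longitudinal$patient_id, ids), longitudinal$t)
  lg <- longitudinal[ord, ]
  covar <- NULL
  if (length(lspec$covariates))
    covar <- baseline[match(lg$patient_id, ids), lspec$covariates, drop = FALSE]
  X <- build_design(lg$t, lspec, covar)
  Z <- rand_design(lg$t)
  pid <- match(lg$patient_id, ids)
  obs_ptr <- c(0L, cumsum(as.integer(table(factor(pid, levels = seq_along(ids))))))

  W <- survival_design(baseline, sspec$covariates)

  # event-time designs
  xT <- build_design(Ti, lspec,
                     if (length(lspec$covariates))
                       baseline[, lspec$covariates, drop = FALSE] else NULL)
  dxT <- build_design(Ti, lspec,
                      if (length(lspec$covariates))
                        baseline[, lspec$covariates, drop = FALSE] else NULL,
                      deriv = 1L)
  zT <- rand_design(Ti); dzT <- rand_design(Ti, deriv = 1L)
  segT <- pmin(findInterval(Ti, breaks, left.open = TRUE), K) - 1L

  # Gauss-Legendre nodes per patient over (0, T_i], segment by segment
  gl <- pracma::gaussLegendre(sspec$gl_points, -1, 1)
  qt <- qw <- qseg <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    nd <- seg_quad_nodes(breaks, Ti[i], gl$x, gl$w,
                         chunk = sspec$gl_chunk %||% 14)
    qt[[i]] <- nd$t; qw[[i]] <- nd$w; qseg[[i]] <- nd$seg
  }
  q_ptr <- c(0L, cumsum(lengths(qt)))
  tq <- unlist(qt)
  covq <- if (length(lspec$covariates))
    baseline[rep(seq_along(ids), lengths(qt)), lspec$covariates, drop = FALSE]
  else NULL
  Xq <- build_design(tq, lspec, covq)
  dXq <- build_design(tq, lspec, covq, deriv = 1L)
  Zq <- rand_design(tq); dZq <- rand_design(tq, deriv = 1L)

  list(ids = ids, lspec = lspec, sspec = sspec, breaks = breaks, K = K,
       y = lg$meld_na, X = X, Z = Z, obs_ptr = as.integer(obs_ptr),
       delta = delta, Ti = Ti, W = W,
       xT = xT, zT = zT, dxT = dxT, dzT = dzT, segT = as.integer(segT),
       Xq = Xq, Zq = Zq, dXq = dXq, dZq = dZq,
       wq = unlist(qw), segq = as.integer(unlist(qseg)),
       q_ptr = as.integer(q_ptr))
}

# par packing: beta(p) | l11 l21 l22 log_sigma | gamma(q) | a_value a_slope |
# log_lambda(K)
pack_par <- function(beta, theta, gamma, a_value, a_slope, log_lambda)
  c(beta, theta, gamma, a_value, a_slope, log_lambda)

unpack_par <- function(par, p, q, K, assoc) {
  beta <- par[seq_len(p)]
  theta <- par[p + 1:4]
  gamma <- par[p + 4 + seq_len(q)]
  av <- if ("value" %in% assoc) par[p + 4 + q + 1] else 0
  as_ <- if ("slope" %in% assoc) par[p + 4 + q + 2] else 0
  ll <- par[p + 4 + q + 2 + seq_len(K)]
  list(beta = beta, theta = theta, gamma = gamma, a_value = av, a_slope = as_,
       log_lambda = ll)
}

blocks_loglik <- function(blk, beta, L, sigma, gamma, a_value, a_slope,
                          lambda, per_patient = FALSE) {
  res <- .jm_loglik_cpp(blk$y, blk$X, blk$Z, blk$obs_ptr, blk$delta, blk$W,
                        blk$xT, blk$zT, blk$dxT, blk$dzT, blk$segT,
                        blk$Xq, blk$Zq, blk$dXq, blk$dZq, blk$wq, blk$segq,
                        blk$q_ptr, blk$gh$x, blk$gh$w,
                        beta, L, sigma, gamma, a_value, a_slope, lambda,
                        per_patient)
  res
}

#' Joint log-likelihood at supplied parameter values
#'
#' Evaluates the full joint likelihood: per patient, the log of the
#' random-effects integral of (longitudinal Gaussian density) x (survival
#' likelihood under the hazard
#' `h0(t) exp(gamma'w + alpha_value m(t) + alpha_slope m'(t))`). The
#' 2-D integral uses a Gauss-Hermite rule adapted to the closed-form
#' longitudinal posterior of the random effects; cumulative hazards use
#' Gauss-Legendre on each piecewise-constant segment.
#'
#' @param params list with `beta`, `D` (2x2), `sigma`, `gamma`,
#'   `alpha_value`, `alpha_slope`, `lambda` (one height per segment).
#' @param tables list with `baseline`, `longitudinal`, `outcomes`.
#' @param lspec,sspec model specifications ([lmm_spec()], [surv_spec()]);
#'   set `sspec$breaks` explicitly to pin the hazard segments, otherwise
#'   they are placed at death-time quantiles of the supplied data.
#' @param per_patient return per-patient contributions as an attribute.
#' @return log-likelihood (scalar).
#' @export
joint_log_likelihood <- function(params, tables, lspec = lmm_spec(),
                                 sspec = surv_spec(), per_patient = FALSE) {
  blk <- build_jm_blocks(tables$longitudinal, tables$baseline,
                         tables$outcomes, lspec, sspec)
  blk$gh <- pracma::gaussHermite(sspec$gh_points)
  if (length(params$lambda) != blk$K)
    stop("lambda must have one height per hazard segment (", blk$K, ")",
         call. = FALSE)
  if (any(params$lambda < 0)) stop("lambda must be non-negative", call. = FALSE)
  if (params$sigma <= 0) stop("sigma must be positive", call. = FALSE)
  ev <- eigen(params$D, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("D must be positive definite", call. = FALSE)
  L <- t(chol(params$D))
  res <- blocks_loglik(blk, params$beta, L, params$sigma, params$gamma,
                       params$alpha_value %||% 0, params$alpha_slope %||% 0,
                       params$lambda, per_patient)
  if (!isTRUE(res$ok))
    stop("non-finite joint likelihood contribution for patient ",
         blk$ids[res$bad_patient], call. = FALSE)
  out <- res$loglik
  if (per_patient) attr(out, "by_patient") <- res$by_patient
  out
}

#' Parametric proportional-hazards log-likelihood (baseline covariates only)
#'
#' Piecewise-constant-hazard PH likelihood without longitudinal
#' association; the closed-form factor the joint likelihood collapses to
#' when both association coefficients are zero.
#'
#' @param outcomes outcome table; `baseline` baseline table.
#' @param covariates survival covariate names; `gamma` their coefficients.
#' @param lambda segment heights; `breaks` segment boundaries
#'   (length `length(lambda) + 1`, first 0, last may be `Inf`).
#' @return log-likelihood (scalar).
#' @export
ph_loglik <- function(outcomes, baseline, covariates, gamma, lambda, breaks) {
  W <- survival_design(baseline, covariates)
  oc <- outcomes[match(baseline$patient_id, outcomes$patient_id), ]
  delta <- as.numeric(oc$event_type == "death")
  Ti <- oc$event_time
  K <- length(lambda)
  seg <- pmin(findInterval(Ti, breaks, left.open = TRUE), K)
  # exact piecewise-constant cumulative baseline hazard
  width <- function(t) {
    lo <- breaks[-length(breaks)]; hi <- breaks[-1]
    sapply(t, function(ti) sum(lambda * pmax(pmin(ti, hi) - lo, 0)))
  }
  eta <- drop(W %*% gamma)
  sum(delta * (log(lambda[seg]) + eta)) - sum(width(Ti) * exp(eta))
}

#' Fit the joint model
#'
#' Maximizes the joint likelihood by quasi-Newton (BFGS) over all
#' parameters: longitudinal fixed effects, random-effect covariance
#' (log-Cholesky), residual SD (log), survival coefficients, both
#' association coefficients and log baseline-hazard heights. Initial values
#' come from a two-stage fit (longitudinal ML fit, then a time-dependent
#' Cox fit on the empirical-Bayes fitted value and slope), or from a seeded
#' random perturbation for multi-start checks. Standard errors come from
#' the observed information (numerical Hessian at the optimum).
#'
#' @param tables list with `baseline`, `longitudinal`, `outcomes`.
#' @param lspec,sspec specifications; see [lmm_spec()] and [surv_spec()].
#' @param init `"two_stage"` or `"random"`.
#' @param seed seed for the random-init path.
#' @param compute_se compute the observed-information standard errors.
#' @param control passed to [stats::optim()].
#' @return object of class `meldjm_jm`.
#' @export
fit_joint_model <- function(tables, lspec = lmm_spec(), sspec = surv_spec(),
                            init = c("two_stage", "random"), seed = 1,
                            compute_se = TRUE,
                            control = list(maxit = 400, reltol = 1e-9)) {
  init <- match.arg(init)
  blk <- build_jm_blocks(tables$longitudinal, tables$baseline,
                         tables$outcomes, lspec, sspec)
  blk$gh <- pracma::gaussHermite(blk$sspec$gh_points)
  p <- ncol(blk$X); q <- ncol(blk$W); K <- blk$K
  if (sum(blk$delta) == 0)
    stop("no death events: survival and association parameters are not ",
         "estimable", call. = FALSE)
  if (qr(cbind(1, blk$W))$rank < q + 1L)
    stop("survival covariate design is rank deficient (constant or ",
         "aliased column)", call. = FALSE)

  lfit <- fit_lmm(tables$longitudinal, blk$lspec, tables$baseline)
  if (init == "two_stage") {
    cox <- two_stage_cox(tables, lfit, blk)
    gamma0 <- cox$gamma; av0 <- cox$a_value; as0 <- cox$a_slope
  } else {
    set.seed(as.integer(seed))
    gamma0 <- stats::rnorm(q, 0, 0.1)
    av0 <- stats::runif(1, 0, 0.2); as0 <- stats::runif(1, -0.5, 0.5)
  }
  log_lambda0 <- init_lambda(blk, lfit, gamma0, av0, as0)

  theta0 <- lfit$theta
  par0 <- unname(pack_par(lfit$beta, theta0, gamma0, av0, as0, log_lambda0))

  negll <- function(par) {
    if (any(!is.finite(par)) || any(abs(par) > 30)) return(1e10)
    u <- unpack_par(par, p, q, K, c("value", "slope"))
    dl <- theta_to_DL(u$theta)
    res <- blocks_loglik(blk, u$beta, dl$L, dl$sigma, u$gamma,
                         if ("value" %in% blk$sspec$assoc) u$a_value else 0,
                         if ("slope" %in% blk$sspec$assoc) u$a_slope else 0,
                         exp(u$log_lambda))
    if (!isTRUE(res$ok) || !is.finite(res$loglik)) return(1e10)
    -res$loglik
  }
  opt <- stats::optim(par0, negll, method = "BFGS", control = control,
                      hessian = FALSE)
  if (opt$convergence != 0 && opt$convergence != 1)
    stop("joint-model optimization failed (optim code ", opt$convergence,
         "); two-stage start attached", call. = FALSE)
  H <- NULL; se <- rep(NA_real_, length(par0))
  if (compute_se) {
    H <- stats::optimHess(opt$par, negll)
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      dv <- diag(V)
      se <- ifelse(dv > 0, sqrt(pmax(dv, 0)), NA_real_)
    }
  }
  u <- unpack_par(opt$par, p, q, K, c("value", "slope"))
  dl <- theta_to_DL(u$theta)
  nm <- c(colnames(blk$X), "l11", "l21", "l22", "log_sigma",
          colnames(blk$W), "alpha_value", "alpha_slope",
          paste0("log_lambda", seq_len(K)))
  names(se) <- nm
  ranef <- eb_modes(list(y = blk$y, X = blk$X, Z = blk$Z,
                         pid = rep(seq_along(blk$ids),
                                   diff(blk$obs_ptr)),
                         ids = blk$ids),
                    u$beta, dl$D, dl$sigma)
  structure(list(beta = stats::setNames(unname(u$beta), colnames(blk$X)),
                 D = dl$D, sigma = unname(dl$sigma),
                 gamma = stats::setNames(unname(u$gamma), colnames(blk$W)),
                 alpha_value = if ("value" %in% blk$sspec$assoc)
                   unname(u$a_value) else 0,
                 alpha_slope = if ("slope" %in% blk$sspec$assoc)
                   unname(u$a_slope) else 0,
                 lambda = unname(exp(u$log_lambda)), breaks = blk$breaks,
                 se = se, par = stats::setNames(opt$par, nm), hessian = H,
                 loglik = -opt$value, ranef = ranef,
                 spec = list(lspec = blk$lspec, sspec = blk$sspec),
                 ids = blk$ids, seed = seed, init = init,
                 n_events = sum(blk$delta),
                 convergence = list(code = opt$convergence,
                                    counts = opt$counts)),
            class = "meldjm_jm")
}

# Two-stage initializer: time-dependent Cox on EB fitted value and slope.
two_stage_cox <- function(tables, lfit, blk) {
  ids <- blk$ids
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    ix <- (blk$obs_ptr[i] + 1):blk$obs_ptr[i + 1]
    tm <- sort(unique(c(0, blk$Z[ix, 2])))
    tm <- tm[tm < blk$Ti[i]]
    tr <- trajectory(lfit, ids[i], tm,
                     covar = tables$baseline[
                       match(ids[i], tables$baseline$patient_id), ,
                       drop = FALSE])
    stops <- c(tm[-1], blk$Ti[i])
    rows[[i]] <- data.frame(start = tm, stop = stops,
                            ev = c(rep(0, length(tm) - 1), blk$delta[i]),
                            value = tr$value, slope = tr$slope, i = i)
  }
  df <- do.call(rbind, rows)
  df <- cbind(df, blk$W[df$i, , drop = FALSE])
  fml <- stats::as.formula(paste(
    "survival::Surv(start, stop, ev) ~",
    paste(c(colnames(blk$W), "value", "slope"), collapse = " + ")))
  cf <- tryCatch(stats::coef(survival::coxph(fml, data = df)),
                 error = function(e) NULL)
  if (is.null(cf) || anyNA(cf))
    return(list(gamma = rep(0, ncol(blk$W)), a_value = 0.05, a_slope = 0))
  list(gamma = unname(cf[colnames(blk$W)]),
       a_value = unname(cf["value"]), a_slope = unname(cf["slope"]))
}

# Closed-form lambda given everything else, at EB plug-in trajectories.
init_lambda <- function(blk, lfit, gamma, av, as_) {
  ids <- blk$ids
  mu <- lfit$ranef[match(ids, rownames(lfit$ranef)), , drop = FALSE]
  i_of_q <- rep(seq_along(ids), diff(blk$q_ptr))
  beta <- lfit$beta
  val <- drop(blk$Xq %*% beta) + blk$Zq[, 1] * mu[i_of_q, 1] +
    blk$Zq[, 2] * mu[i_of_q, 2]
  slp <- drop(blk$dXq %*% beta) + blk$dZq[, 2] * mu[i_of_q, 2]
  eta <- drop(blk$W %*% gamma)[i_of_q] + av * val + as_ * slp
  expo <- blk$wq * exp(pmin(eta, 30))
  denom <- tapply(expo, factor(blk$segq, levels = 0:(blk$K - 1)), sum)
  denom[is.na(denom) | denom <= 0] <- 1e-8
  d_k <- tapply(blk$delta, factor(blk$segT, levels = 0:(blk$K - 1)), sum)
  d_k[is.na(d_k)] <- 0
  log(pmax(as.numeric(d_k), 0.5) / as.numeric(denom))
}

#' Hazard ratio between two covariate/trajectory configurations
#'
#' The fitted hazard is log-linear, so the ratio between a patient and a
#' reference is the product of per-term multipliers raised to the
#' covariate differences:
#' `exp(alpha_value d_value + alpha_slope d_slope + gamma' d_w)`.
#'
#' @param object a `meldjm_jm` fit or the published-coefficient predictor
#'   from [published_coefficients()].
#' @param covariates named list/vector of baseline-covariate values.
#' @param value,slope current MELD-Na value and slope.
#' @param reference same structure; defaults to the all-zero reference
#'   patient.
#' @param ... unused.
#' @return the hazard ratio (scalar).
#' @examples
#' hazard_ratio(published_coefficients(), value = 1)      # 1.15
#' hazard_ratio(published_coefficients(), covariates = list(aclf3 = 1))
#' @export
hazard_ratio <- function(object, ...) UseMethod("hazard_ratio")

#' @rdname hazard_ratio
#' @export
hazard_ratio.meldjm_jm <- function(object, covariates = list(), value = 0,
                                   slope = 0, reference = list(), ...) {
  dw <- covariate_delta(names(object$gamma), covariates, reference)
  ref_v <- reference$value %||% 0; ref_s <- reference$slope %||% 0
  exp(object$alpha_value * (value - ref_v) +
        object$alpha_slope * (slope - ref_s) + sum(object$gamma * dw))
}

covariate_delta <- function(known, covariates, reference) {
  bad <- setdiff(c(names(covariates), setdiff(names(reference),
                                              c("value", "slope"))), known)
  if (length(bad))
    stop("unknown covariate name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  sapply(known, function(nm)
    (covariates[[nm]] %||% 0) - (reference[[nm]] %||% 0))
}

#' Persist / restore a joint-model fit as plain text
#' @param fit a `meldjm_jm`; `path` file path.
#' @return `write_jm_fit`: the path, invisibly; `read_jm_fit`: the fit.
#' @export
write_jm_fit <- function(fit, path) {
  obj <- list(class = "meldjm_jm",
              beta = as.list(fit$beta), D = as.vector(fit$D),
              sigma = fit$sigma, gamma = as.list(fit$gamma),
              alpha_value = fit$alpha_value, alpha_slope = fit$alpha_slope,
              lambda = fit$lambda, breaks = fit$breaks,
              se = as.list(fit$se), loglik = fit$loglik,
              ranef = list(ids = rownames(fit$ranef), b0 = fit$ranef[, 1],
                           b1 = fit$ranef[, 2]),
              lspec = fit$spec$lspec[c("time_basis", "n_knots", "covariates",
                                       "knots", "boundary")],
              sspec = fit$spec$sspec[c("covariates", "n_segments", "assoc",
                                       "gh_points", "gl_points")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_jm_fit
#' @export
read_jm_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ranef <- cbind(b0 = obj$ranef$b0, b1 = obj$ranef$b1)
  rownames(ranef) <- obj$ranef$ids
  lspec <- structure(list(time_basis = obj$lspec$time_basis,
                          n_knots = obj$lspec$n_knots,
                          covariates = obj$lspec$covariates %||% character(),
                          knots = obj$lspec$knots,
                          boundary = obj$lspec$boundary),
                     class = "lmm_spec")
  sspec <- surv_spec(covariates = obj$sspec$covariates,
                     n_segments = obj$sspec$n_segments,
                     assoc = obj$sspec$assoc, gh_points = obj$sspec$gh_points,
                     gl_points = obj$sspec$gl_points)
  breaks <- obj$breaks
  breaks[is.na(breaks)] <- Inf
  structure(list(beta = unlist(obj$beta), D = matrix(obj$D, 2, 2),
                 sigma = obj$sigma, gamma = unlist(obj$gamma),
                 alpha_value = obj$alpha_value, alpha_slope = obj$alpha_slope,
                 lambda = obj$lambda, breaks = breaks,
                 se = unlist(obj$se), loglik = obj$loglik, ranef = ranef,
                 spec = list(lspec = lspec, sspec = sspec),
                 ids = obj$ranef$ids),
            class = "meldjm_jm")
}
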