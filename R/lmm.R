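# Mixed-effects submodel for repeated MELD-Na. Estimation maximizes the
# closed-form marginal Gaussian likelihood directly (random effects
# integrate out analytically), with beta profiled by GLS given the
# variance components. Random effects are patient intercept + linear time
# slope; the fixed time basis may be linear or a natural cubic spline.

# Per-patient design blocks used by both the LMM and the joint model.
build_blocks <- function(longitudinal, spec, baseline = NULL) {
  if (is.null(longitudinal$meld_na)) stop("longitudinal table needs a 'meld_na' column", call. = FALSE)
  ids <- unique(longitudinal$patient_id)
  spec <- prepare_spec(spec, longitudinal$t)
  covar <- NULL
  if (length(spec$covariates)) {
    if (is.null(baseline)) stop("spec covariates require a baseline table", call. = FALSE)
    covar <- baseline[match(longitudinal$patient_id, baseline$patient_id),
                      spec$covariates, drop = FALSE]
  }
  X <- build_design(longitudinal$t, spec, covar)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient fixed-effect design; offending column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  Z <- rand_design(longitudinal$t)
  ord <- order(match(longitudinal$patient_id, ids))
  list(spec = spec, ids = ids,
       y = longitudinal$meld_na[ord],
       X = X[ord, , drop = FALSE], Z = Z[ord, , drop = FALSE],
       pid = match(longitudinal$patient_id[ord], ids))
}

# theta = (l11, l21, l22, log_sigma); D = L L', L lower triangular with
# exponentiated diagonal.
theta_to_DL <- function(theta) {
  L <- matrix(c(exp(theta[1]), theta[2], 0, exp(theta[3])), 2, 2)
  list(L = L, D = L %*% t(L), sigma = exp(theta[4]))
}

# Profile marginal log-likelihood and GLS beta for given variance
# components. The random-effect design is always (1, t), so the per-patient
# 2x2 Woodbury algebra is written in closed form and vectorised across
# patients with rowsum(); no per-patient loop.
lmm_profile <- function(theta, blk) {
  dl <- theta_to_DL(theta)
  D <- dl$D; s2 <- dl$sigma^2
  Dinv <- solve(D)
  p <- ncol(blk$X)
  g <- blk$pid
  tt <- blk$Z[, 2]
  # per-patient sufficient statistics of the (1, t) random design
  n_i <- as.numeric(rowsum(rep(1, length(g)), g))
  St <- as.numeric(rowsum(tt, g))
  Stt <- as.numeric(rowsum(tt^2, g))
  a11 <- n_i / s2 + Dinv[1, 1]
  a12 <- St / s2 + Dinv[1, 2]
  a22 <- Stt / s2 + Dinv[2, 2]
  detA <- a11 * a22 - a12^2
  i11 <- a22 / detA; i12 <- -a12 / detA; i22 <- a11 / detA  # A^{-1}

  P1 <- rowsum(blk$X, g)                 # sum_j x_j
  Pt <- rowsum(blk$X * tt, g)            # sum_j t_j x_j
  # X' V^{-1} X = X'X/s2 - [P1 Pt] Ainv [P1; Pt]' / s2^2, summed over i
  sand <- crossprod(P1, P1 * i11) + crossprod(P1, Pt * i12) +
    crossprod(Pt, P1 * i12) + crossprod(Pt, Pt * i22)
  XtVX <- crossprod(blk$X) / s2 - sand / s2^2
  q1 <- as.numeric(rowsum(blk$y, g))
  qt <- as.numeric(rowsum(blk$y * tt, g))
  sv <- crossprod(P1, q1 * i11 + qt * i12) + crossprod(Pt, q1 * i12 + qt * i22)
  XtVy <- drop(crossprod(blk$X, blk$y) / s2 - sv / s2^2)
  beta <- solve(XtVX, XtVy)

  r <- blk$y - drop(blk$X %*% beta)
  u1 <- as.numeric(rowsum(r, g)); u2 <- as.numeric(rowsum(r * tt, g))
  rr <- as.numeric(rowsum(r^2, g))
  uAu <- u1^2 * i11 + 2 * u1 * u2 * i12 + u2^2 * i22
  quad <- sum((rr - uAu / s2) / s2)
  logdetD <- as.numeric(determinant(D, logarithm = TRUE)$modulus)
  logdetV <- sum(n_i) * log(s2) + length(n_i) * logdetD + sum(log(detA))
  ll <- -0.5 * (sum(n_i) * log(2 * pi) + logdetV + quad)
  list(loglik = ll, beta = beta, XtVX = XtVX)
}

#' Marginal log-likelihood of the longitudinal mixed model
#'
#' Closed-form Gaussian marginal log-likelihood (random effects integrated
#' analytically) at supplied parameter values. Used for optimizer sanity
#' checks and as one side of quadrature-equivalence tests.
#'
#' @param longitudinal table with `patient_id`, `t`, `meld_na`.
#' @param spec an [lmm_spec()] (knots are frozen from the supplied times if
#'   not already set).
#' @param beta fixed effects in design order.
#' @param D 2x2 random-effect covariance; `sigma` residual SD.
#' @param baseline baseline table when the spec has covariates.
#' @return log-likelihood (scalar).
#' @export
lmm_marginal_loglik <- function(longitudinal, spec, beta, D, sigma,
                                baseline = NULL) {
  blk <- build_blocks(longitudinal, spec, baseline)
  s2 <- sigma^2; Dinv <- solve(D)
  ll <- 0
  logdetD <- determinant(D, logarithm = TRUE)$modulus
  for (ix in split(seq_along(blk$y), blk$pid)) {
    Z <- blk$Z[ix, , drop = FALSE]; X <- blk$X[ix, , drop = FALSE]
    r <- blk$y[ix] - drop(X %*% beta)
    A <- crossprod(Z) / s2 + Dinv
    Ztr <- crossprod(Z, r)
    quad <- (sum(r^2) - drop(crossprod(Ztr, solve(A, Ztr))) / s2) / s2
    logdetV <- length(ix) * log(s2) + logdetD +
      determinant(A, logarithm = TRUE)$modulus
    ll <- ll - 0.5 * (length(ix) * log(2 * pi) + logdetV + quad)
  }
  as.numeric(ll)
}

#' Fit the mixed-effects model for repeated MELD-Na
#'
#' Maximum-likelihood fit by direct quasi-Newton maximization of the
#' closed-form marginal likelihood, beta profiled out by generalized least
#' squares at each variance-component value. Returns empirical-Bayes modes
#' of the patient random effects.
#'
#' @inheritParams lmm_marginal_loglik
#' @param control list passed to [stats::optim()].
#' @return object of class `meldjm_lmm`: `beta`, `D`, `sigma`, `ranef`
#'   (patients x 2 matrix of EB modes), `loglik`, `spec`, `convergence`.
#' @export
fit_lmm <- function(longitudinal, spec = lmm_spec(), baseline = NULL,
                    control = list(maxit = 500)) {
  blk <- build_blocks(longitudinal, spec, baseline)
  if (any(!is.finite(blk$y)) || any(!is.finite(longitudinal$t)))
    stop("non-finite values in longitudinal data", call. = FALSE)
  # moment-based start: residual spread after a pooled OLS line
  ols <- stats::lm.fit(blk$X, blk$y)
  s0 <- max(stats::sd(ols$residuals) / 2, 0.5)
  start <- c(log(max(s0, 1)), 0, log(max(s0 / 50, 1e-3)), log(s0))
  negll <- function(theta) {
    # sigma floored at 5e-4: below that V is numerically singular and the
    # likelihood surface is flat for any realistic MELD-Na data
    if (any(abs(theta) > 20) || theta[4] < log(5e-4)) return(1e10)
    val <- tryCatch(-lmm_profile(theta, blk)$loglik,
                    error = function(e) 1e10)
    if (!is.finite(val)) 1e10 else val
  }
  opt <- stats::optim(start, negll, method = "Nelder-Mead",
                      control = list(maxit = 300))
  opt <- stats::optim(opt$par, negll, method = "BFGS", control = control)
  if (!is.finite(opt$value))
    stop("longitudinal fit did not converge: non-finite likelihood",
         call. = FALSE)
  prof <- lmm_profile(opt$par, blk)
  dl <- theta_to_DL(opt$par)
  ranef <- eb_modes(blk, prof$beta, dl$D, dl$sigma)
  structure(list(beta = stats::setNames(prof$beta, colnames(blk$X)),
                 D = dl$D, sigma = dl$sigma, ranef = ranef,
                 loglik = prof$loglik, spec = blk$spec, ids = blk$ids,
                 theta = opt$par,
                 convergence = list(code = opt$convergence,
                                    counts = opt$counts)),
            class = "meldjm_lmm")
}

# Empirical-Bayes posterior modes (= means, Gaussian case) of b_i,
# vectorised over patients via the closed-form 2x2 solve.
eb_modes <- function(blk, beta, D, sigma) {
  s2 <- sigma^2; Dinv <- solve(D)
  g <- blk$pid
  tt <- blk$Z[, 2]
  n_i <- as.numeric(rowsum(rep(1, length(g)), g))
  St <- as.numeric(rowsum(tt, g))
  Stt <- as.numeric(rowsum(tt^2, g))
  a11 <- n_i / s2 + Dinv[1, 1]
  a12 <- St / s2 + Dinv[1, 2]
  a22 <- Stt / s2 + Dinv[2, 2]
  detA <- a11 * a22 - a12^2
  r <- blk$y - drop(blk$X %*% beta)
  u1 <- as.numeric(rowsum(r, g)) / s2
  u2 <- as.numeric(rowsum(r * tt, g)) / s2
  out <- cbind(b0 = (a22 * u1 - a12 * u2) / detA,
               b1 = (-a12 * u1 + a11 * u2) / detA)
  rownames(out) <- blk$ids
  out
}

#' Patient-specific trajectory value and slope
#'
#' Evaluates the fitted patient-specific mean MELD-Na curve and its
#' analytic time-derivative (fixed effects plus empirical-Bayes random
#' effects). Spline slopes come from basis derivatives, not finite
#' differences.
#'
#' @param fit a `meldjm_lmm` or `meldjm_jm` fit.
#' @param patient_id one patient identifier known to the fit.
#' @param t numeric vector of times (days since listing).
#' @param covar optional one-row data.frame of the patient's baseline
#'   covariates when the spec includes covariates.
#' @return data.frame with `t`, `value`, `slope`.
#' @export
trajectory <- function(fit, patient_id, t, covar = NULL) {
  k <- match(patient_id, rownames(fit$ranef))
  if (is.na(k)) stop("unknown patient: ", patient_id, call. = FALSE)
  b <- fit$ranef[k, ]
  if (length(fit$spec$covariates) && is.null(covar))
    stop("spec covariates require 'covar'", call. = FALSE)
  cv <- if (length(fit$spec$covariates))
    covar[rep(1, length(t)), fit$spec$covariates, drop = FALSE] else NULL
  X0 <- build_design(t, fit$spec, cv, deriv = 0L)
  X1 <- build_design(t, fit$spec, cv, deriv = 1L)
  Z0 <- rand_design(t); Z1 <- rand_design(t, deriv = 1L)
  data.frame(t = t,
             value = drop(X0 %*% fit$beta + Z0 %*% b),
             slope = drop(X1 %*% fit$beta + Z1 %*% b))
}

#' Persist / restore a longitudinal fit as plain text
#'
#' Key/value + matrix serialization so fits can be versioned and reused.
#' @param fit a `meldjm_lmm`; `path` file path.
#' @return `write_lmm_fit`: the path, invisibly; `read_lmm_fit`: the fit.
#' @export
write_lmm_fit <- function(fit, path) {
  obj <- list(class = "meldjm_lmm", beta = as.list(fit$beta),
              D = as.vector(fit$D), sigma = fit$sigma,
              ranef = list(ids = rownames(fit$ranef),
                           b0 = fit$ranef[, 1], b1 = fit$ranef[, 2]),
              loglik = fit$loglik,
              spec = fit$spec[c("time_basis", "n_knots", "covariates",
                                "knots", "boundary")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_lmm_fit
#' @export
read_lmm_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ranef <- cbind(b0 = obj$ranef$b0, b1 = obj$ranef$b1)
  rownames(ranef) <- obj$ranef$ids
  spec <- structure(list(time_basis = obj$spec$time_basis,
                         n_knots = obj$spec$n_knots,
                         covariates = obj$spec$covariates %||% character(),
                         knots = obj$spec$knots, boundary = obj$spec$boundary),
                    class = "lmm_spec")
  structure(list(beta = unlist(obj$beta), D = matrix(obj$D, 2, 2),
                 sigma = obj$sigma, ranef = ranef, loglik = obj$loglik,
                 spec = spec, ids = obj$ranef$ids),
            class = "meldjm_lmm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
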