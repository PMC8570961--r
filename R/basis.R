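# Time bases for the longitudinal trajectory. The natural cubic spline is
# built from the truncated-power representation so that both the basis and
# its first derivative are available in closed form (trajectory slopes must
# come from basis derivatives, never finite differences).

#' Longitudinal model specification
#'
#' Describes the fixed-effect design of the mixed model for repeated
#' MELD-Na: an intercept, a time basis (linear, or a natural cubic spline
#' with interior knots placed at quantiles of the observation times), and
#' optional baseline covariates. Random effects are a patient-level
#' intercept and linear time slope, a subset of either time basis.
#'
#' @param time_basis `"linear"` or `"ns"`.
#' @param n_knots number of interior knots when `time_basis = "ns"`.
#' @param covariates character vector of baseline-covariate column names
#'   entering the fixed effects (centred internally is left to the caller).
#' @return object of class `lmm_spec`.
#' @export
lmm_spec <- function(time_basis = c("linear", "ns"), n_knots = 2L,
                     covariates = character()) {
  time_basis <- match.arg(time_basis)
  structure(list(time_basis = time_basis, n_knots = as.integer(n_knots),
                 covariates = covariates, knots = NULL, boundary = NULL),
            class = "lmm_spec")
}

# Freeze knot locations from observed times (33rd/67th percentiles by
# default for 2 interior knots); boundary knots at the observed range.
prepare_spec <- function(spec, times) {
  if (spec$time_basis == "ns" && is.null(spec$knots)) {
    probs <- seq_len(spec$n_knots) / (spec$n_knots + 1)
    spec$knots <- unname(stats::quantile(times, probs))
    spec$boundary <- range(times)
    if (diff(spec$boundary) <= 0)
      stop("degenerate time range for spline basis", call. = FALSE)
  }
  spec
}

# Natural cubic spline basis on the truncated-power construction
# (linear tail beyond the boundary knots). Columns: x, then one per
# interior knot. deriv = 0 or 1.
ncs_basis <- function(x, interior, boundary, deriv = 0L) {
  xi <- sort(c(boundary[1], interior, boundary[2]))
  K <- length(xi)
  dk <- function(x, k) {
    num0 <- pmax(x - xi[k], 0)^3 - pmax(x - xi[K], 0)^3
    num0 / (xi[K] - xi[k])
  }
  dk1 <- function(x, k) {
    (3 * pmax(x - xi[k], 0)^2 - 3 * pmax(x - xi[K], 0)^2) / (xi[K] - xi[k])
  }
  out <- matrix(0, length(x), K - 1L)
  if (deriv == 0L) {
    out[, 1L] <- x
    for (k in seq_len(K - 2L)) out[, k + 1L] <- dk(x, k) - dk(x, K - 1L)
  } else {
    out[, 1L] <- 1
    for (k in seq_len(K - 2L)) out[, k + 1L] <- dk1(x, k) - dk1(x, K - 1L)
  }
  colnames(out) <- paste0("ncs", seq_len(K - 1L))
  out
}

# Fixed-effect time columns (no intercept) and their time-derivative.
time_design <- function(t, spec, deriv = 0L) {
  if (spec$time_basis == "linear") {
    m <- matrix(if (deriv == 0L) t else rep(1, length(t)), ncol = 1L)
    colnames(m) <- "t"
    m
  } else {
    if (is.null(spec$knots)) stop("spec not prepared: knots unset", call. = FALSE)
    ncs_basis(t, spec$knots, spec$boundary, deriv)
  }
}

# Full fixed design for one block of rows: intercept, time basis, covariates.
# `baseline` is a one-row-per-patient table aligned by patient_id.
build_design <- function(t, spec, covar = NULL, deriv = 0L) {
  tb <- time_design(t, spec, deriv)
  icpt <- if (deriv == 0L) rep(1, length(t)) else rep(0, length(t))
  X <- cbind(`(Intercept)` = icpt, tb)
  if (length(spec$covariates)) {
    if (is.null(covar)) stop("covariate columns required by spec", call. = FALSE)
    cm <- as.matrix(covar[, spec$covariates, drop = FALSE])
    if (deriv != 0L) cm[] <- 0
    X <- cbind(X, cm)
  }
  X
}

# Random-effects design: intercept + linear time (and its derivative).
rand_design <- function(t, deriv = 0L) {
  if (deriv == 0L) cbind(b0 = rep(1, length(t)), b1 = t)
  else cbind(b0 = rep(0, length(t)), b1 = rep(1, length(t)))
}
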