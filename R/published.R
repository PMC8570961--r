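#' Published joint-model hazard-ratio multipliers
#'
#' The multipliers of the published registry fit of the MELD-Na joint
#' model, one per term of its log-linear hazard: current MELD-Na value
#' 1.15, current slope 1.02, age 1.38, female sex 0.75, cirrhosis 0.95,
#' ACLF grade indicators 1.06 / 1.98 / 5.90, bacterial peritonitis 1.18 and
#' life-support dependency 1.35. Stored verbatim and unit-agnostically (the
#' source does not state the slope or age scaling); used for worked
#' examples and the demo predictor, never as fitting targets.
#'
#' @return object of class `meldjm_published`: a named vector of hazard
#'   ratios with the association terms split out.
#' @examples
#' pub <- published_coefficients()
#' hazard_ratio(pub, value = 1)                    # 1.15
#' hazard_ratio(pub, covariates = list(aclf3 = 1)) # 5.90
#' @export
published_coefficients <- function() {
  structure(list(
    hr_value = 1.15, hr_slope = 1.02,
    hr = c(age = 1.38, female = 0.75, cirrhosis = 0.95,
           aclf1 = 1.06, aclf2 = 1.98, aclf3 = 5.90,
           sbp = 1.18, life_support = 1.35)),
    class = "meldjm_published")
}

#' @rdname hazard_ratio
#' @export
hazard_ratio.meldjm_published <- function(object, covariates = list(),
                                          value = 0, slope = 0,
                                          reference = list(), ...) {
  dw <- covariate_delta(names(object$hr), covariates, reference)
  ref_v <- reference$value %||% 0; ref_s <- reference$slope %||% 0
  object$hr_value^(value - ref_v) * object$hr_slope^(slope - ref_s) *
    prod(object$hr^dw)
}

#' Demo predictor preloaded with the published multipliers
#'
#' Convenience accessor used by the documentation walkthrough: returns the
#' published-coefficient hazard-ratio calculator.
#' @return a `meldjm_published` object.
#' @export
load_published_demo <- function() published_coefficients()

#' @export
print.meldjm_published <- function(x, ...) {
  cat("Published joint-model hazard-ratio multipliers\n")
  cat(sprintf("  MELD-Na value  %.2f   MELD-Na slope  %.2f\n",
              x$hr_value, x$hr_slope))
  for (nm in names(x$hr)) cat(sprintf("  %-13s %.2f\n", nm, x$hr[nm]))
  invisible(x)
}
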