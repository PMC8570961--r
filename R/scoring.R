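#' MELD and MELD-Na scores from a lab panel
#'
#' Computes the UNOS allocation scores from serum bilirubin, creatinine,
#' INR and sodium. The laboratory MELD is
#' \deqn{10 \times (0.957 \ln C_r + 0.378 \ln B + 1.120 \ln I + 0.643)}
#' with bilirubin, creatinine and INR floored at 1.0, creatinine capped at
#' 4.0 mg/dl (and set to 4.0 when the patient is on renal replacement
#' therapy), rounded to the nearest integer and bounded to \[6, 40\]. The
#' sodium adjustment applies when MELD > 11, with sodium clamped to
#' \[125, 137\] mmol/l:
#' \deqn{MELDNa = MELD + 1.32 (137 - Na) - 0.033 \, MELD (137 - Na)}
#' again rounded and bounded to \[6, 40\]. All clamp constants live in
#' [meld_constants()] so a different score dialect can be swapped in.
#'
#' @param bilirubin serum bilirubin, mg/dl; must be > 0.
#' @param creatinine serum creatinine, mg/dl; must be > 0.
#' @param inr international normalized ratio; must be > 0.
#' @param sodium serum sodium, mmol/l.
#' @param dialysis logical; renal replacement therapy in the scoring window.
#' @param constants list of clamp/cap constants, see [meld_constants()].
#'
#' @return A data.frame with integer columns `meld` and `meld_na` plus the
#'   clamped component values actually used (`bili_used`, `creat_used`,
#'   `inr_used`, `na_used`). Vectorised over the lab inputs.
#' @examples
#' compute_meld_na(1, 1, 1, 137)           # floor of the scale: 6 / 6
#' compute_meld_na(4.8, 1.2, 1.9, 129, dialysis = TRUE)
#' @export
compute_meld_na <- function(bilirubin, creatinine, inr, sodium,
                            dialysis = FALSE, constants = meld_constants()) {
  n <- max(length(bilirubin), length(creatinine), length(inr), length(sodium),
           length(dialysis))
  bilirubin <- rep_len(bilirubin, n); creatinine <- rep_len(creatinine, n)
  inr <- rep_len(inr, n); sodium <- rep_len(sodium, n)
  dialysis <- rep_len(as.logical(dialysis), n)
  for (nm in c("bilirubin", "creatinine", "inr", "sodium")) {
    v <- get(nm)
    if (anyNA(v)) stop("missing values in '", nm, "'", call. = FALSE)
  }
  if (anyNA(dialysis)) stop("missing values in 'dialysis'", call. = FALSE)
  if (any(bilirubin <= 0) || any(creatinine <= 0) || any(inr <= 0))
    stop("bilirubin, creatinine and INR must be strictly positive", call. = FALSE)

  k <- constants
  b <- pmax(bilirubin, k$lab_floor)
  cr <- pmax(creatinine, k$lab_floor)
  cr[dialysis] <- k$creat_cap
  cr <- pmin(cr, k$creat_cap)
  i <- pmax(inr, k$lab_floor)
  na <- pmin(pmax(sodium, k$na_lo), k$na_hi)

  meld_raw <- 10 * (0.957 * log(cr) + 0.378 * log(b) + 1.120 * log(i) + 0.643)
  meld <- pmin(pmax(round(meld_raw), k$score_lo), k$score_hi)

  dna <- k$na_hi - na
  adj <- meld + 1.32 * dna - 0.033 * meld * dna
  meld_na <- ifelse(meld > k$na_threshold,
                    pmin(pmax(round(adj), k$score_lo), k$score_hi),
                    meld)
  data.frame(meld = as.integer(meld), meld_na = as.integer(meld_na),
             bili_used = b, creat_used = cr, inr_used = i, na_used = na)
}

#' Constants of the UNOS MELD / MELD-Na score
#'
#' Isolated so the scoring dialect (floors, caps, sodium clamp, score bounds)
#' is auditable and replaceable in one place.
#' @return Named list of clamp constants.
#' @export
meld_constants <- function() {
  list(lab_floor = 1.0, creat_cap = 4.0, na_lo = 125, na_hi = 137,
       score_lo = 6L, score_hi = 40L, na_threshold = 11L)
}

#' EASL-CLIF organ-failure flags from a lab panel
#'
#' Applies the organ-failure definitions used for ACLF grading in registry
#' data: liver failure is bilirubin >= 12 mg/dl; kidney failure is creatinine
#' >= 2.0 mg/dl or renal replacement therapy; cerebral failure is hepatic
#' encephalopathy grade 3-4; coagulation failure is INR >= 2.5; mechanical
#' ventilation stands in for respiratory failure and life-support dependency
#' for circulatory failure (PaO2/FiO2 and vasopressor detail are not
#' recorded by the registry). Dysfunction bands follow the same criteria:
#' kidney dysfunction is creatinine 1.5-1.9 mg/dl without renal replacement,
#' cerebral dysfunction is encephalopathy grade 1-2. All thresholds are
#' inclusive.
#'
#' @inheritParams compute_meld_na
#' @param he_grade integer 0-4, West-Haven hepatic encephalopathy grade.
#' @param mech_vent logical, mechanical ventilation.
#' @param circ_support logical, life-support / circulatory-support surrogate.
#'
#' @return data.frame of logical failure flags (`liver_f`, `kidney_f`,
#'   `brain_f`, `coag_f`, `circ_f`, `resp_f`), dysfunction flags
#'   (`kidney_dysfunction`, `brain_dysfunction`), the failure count
#'   `n_failures` and the `aclf_grade` (0-3).
#' @examples
#' flag_organ_failures(12, 1.0, 1.1, he_grade = 0)   # liver failure only
#' flag_organ_failures(2, 1.4, 1.2, dialysis = TRUE) # kidney failure via RRT
#' @export
flag_organ_failures <- function(bilirubin, creatinine, inr, dialysis = FALSE,
                                he_grade = 0L, mech_vent = FALSE,
                                circ_support = FALSE) {
  n <- max(length(bilirubin), length(creatinine), length(inr), length(dialysis),
           length(he_grade), length(mech_vent), length(circ_support))
  bilirubin <- rep_len(bilirubin, n); creatinine <- rep_len(creatinine, n)
  inr <- rep_len(inr, n); dialysis <- rep_len(as.logical(dialysis), n)
  he_grade <- rep_len(as.integer(he_grade), n)
  mech_vent <- rep_len(as.logical(mech_vent), n)
  circ_support <- rep_len(as.logical(circ_support), n)
  if (any(bilirubin <= 0) || any(creatinine <= 0) || any(inr <= 0))
    stop("bilirubin, creatinine and INR must be strictly positive", call. = FALSE)
  if (any(!he_grade %in% 0:4))
    stop("he_grade must be an integer in 0..4", call. = FALSE)

  out <- data.frame(
    liver_f  = bilirubin >= 12,
    kidney_f = creatinine >= 2.0 | dialysis,
    brain_f  = he_grade >= 3,
    coag_f   = inr >= 2.5,
    circ_f   = circ_support,
    resp_f   = mech_vent,
    kidney_dysfunction = !dialysis & creatinine >= 1.5 & creatinine < 2.0,
    brain_dysfunction  = he_grade %in% 1:2
  )
  out$n_failures <- as.integer(out$liver_f + out$kidney_f + out$brain_f +
                               out$coag_f + out$circ_f + out$resp_f)
  out$aclf_grade <- grade_aclf(out)
  out
}

#' ACLF grade from an organ-failure profile
#'
#' EASL-CLIF grading: grade 0 when no qualifying pattern; grade 1 for a
#' single kidney failure, a single cerebral failure with kidney dysfunction,
#' or a single other organ failure accompanied by kidney and/or cerebral
#' dysfunction; grade 2 for exactly two organ failures; grade 3 for three or
#' more.
#'
#' @param profile data.frame as returned by [flag_organ_failures()] (the
#'   `n_failures`/`aclf_grade` columns may be absent; flags are required).
#' @return integer vector of grades 0-3.
#' @export
grade_aclf <- function(profile) {
  req <- c("liver_f", "kidney_f", "brain_f", "coag_f", "circ_f", "resp_f",
           "kidney_dysfunction", "brain_dysfunction")
  if (!all(req %in% names(profile)))
    stop("profile must contain columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  nf <- as.integer(profile$liver_f + profile$kidney_f + profile$brain_f +
                   profile$coag_f + profile$circ_f + profile$resp_f)
  if (!is.null(profile$n_failures) && any(profile$n_failures != nf))
    stop("inconsistent profile: n_failures does not match the failure flags",
         call. = FALSE)
  grade <- integer(length(nf))
  one <- nf == 1L
  grade[one & profile$kidney_f] <- 1L
  grade[one & profile$brain_f & profile$kidney_dysfunction] <- 1L
  other <- one & !profile$kidney_f & !profile$brain_f &
    (profile$kidney_dysfunction | profile$brain_dysfunction)
  grade[other] <- 1L
  grade[nf == 2L] <- 2L
  grade[nf >= 3L] <- 3L
  grade
}

#' Score a longitudinal lab table
#'
#' Appends MELD, MELD-Na, the six organ-failure flags and the ACLF grade to
#' a longitudinal table of raw lab panels (one row per measurement).
#'
#' @param labs data.frame with columns `patient_id`, `t`, `bilirubin`,
#'   `creatinine`, `inr`, `sodium`, `dialysis`, `he_grade`, `mech_vent`,
#'   `circ_support`. Missing `dialysis`/`mech_vent`/`circ_support` columns
#'   default to `FALSE`, mirroring registry conventions for absent
#'   life-support flags.
#' @return the input with scoring columns appended.
#' @export
score_lab_table <- function(labs) {
  need <- c("patient_id", "t", "bilirubin", "creatinine", "inr", "sodium")
  miss <- setdiff(need, names(labs))
  if (length(miss))
    stop("lab table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (nm in c("dialysis", "mech_vent", "circ_support"))
    if (is.null(labs[[nm]])) labs[[nm]] <- FALSE
  if (is.null(labs$he_grade)) labs$he_grade <- 0L
  if (any(labs$t < 0)) stop("measurement times must be non-negative", call. = FALSE)
  sc <- compute_meld_na(labs$bilirubin, labs$creatinine, labs$inr, labs$sodium,
                        labs$dialysis)
  fl <- flag_organ_failures(labs$bilirubin, labs$creatinine, labs$inr,
                            labs$dialysis, labs$he_grade, labs$mech_vent,
                            labs$circ_support)
  cbind(labs, sc[c("meld", "meld_na")], fl)
}

#' Read / write longitudinal lab CSVs
#'
#' Thin wrappers around [utils::read.csv()] that validate the expected
#' column set. `read_lab_csv` accepts either a numeric `t` column (days
#' since listing) or an ISO `date` column together with a `listing_date`,
#' which it converts to day offsets.
#'
#' @param path file path.
#' @param x scored table to write.
#' @return `read_lab_csv`: validated data.frame; `write_scored_csv`:
#'   invisibly, the path.
#' @export
read_lab_csv <- function(path) {
  labs <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(labs$t)) {
    if (!is.null(labs$date) && !is.null(labs$listing_date)) {
      labs$t <- as.numeric(as.Date(labs$date) - as.Date(labs$listing_date))
      labs$date <- labs$listing_date <- NULL
    } else {
      stop("need a 't' column (days since listing) or 'date' + 'listing_date'",
           call. = FALSE)
    }
  }
  need <- c("patient_id", "t", "bilirubin", "creatinine", "inr", "sodium")
  miss <- setdiff(need, names(labs))
  if (length(miss))
    stop("lab CSV is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  labs
}

#' @rdname read_lab_csv
#' @export
write_scored_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
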