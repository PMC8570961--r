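# MELD/MELD-Na scoring and EASL-CLIF organ-failure grading.

test_that("MELD-Na matches the closed-form score at the clamp floor and caps", {
  # all log terms vanish at the lower clamps: 10 * 0.643 = 6.43 -> 6
  sc <- compute_meld_na(1.0, 1.0, 1.0, 137)
  expect_identical(sc$meld, 6L)
  expect_identical(sc$meld_na, 6L)

  # dialysis forces creatinine to 4.0, strictly raising the score
  with_dial <- compute_meld_na(3, 1.2, 1.5, 133, dialysis = TRUE)
  without <- compute_meld_na(3, 1.2, 1.5, 133, dialysis = FALSE)
  expect_identical(with_dial$creat_used, 4.0)
  expect_gt(with_dial$meld_na, without$meld_na)

  # extreme labs cap at 40
  expect_identical(compute_meld_na(50, 9, 9, 120)$meld_na, 40L)

  # sodium at/above the upper clamp leaves MELD unchanged
  hi_na <- compute_meld_na(6, 2, 2, 142)
  expect_identical(hi_na$meld_na, hi_na$meld)
})

test_that("MELD-Na agrees with an independent re-evaluation on random panels", {
  set.seed(101)
  n <- 10000
  b <- exp(stats::runif(n, log(0.3), log(40)))
  cr <- exp(stats::runif(n, log(0.4), log(8)))
  inr <- exp(stats::runif(n, log(0.8), log(6)))
  na <- stats::runif(n, 115, 150)
  dia <- stats::runif(n) < 0.1
  got <- compute_meld_na(b, cr, inr, na, dia)

  # independent scalar-by-scalar re-implementation of the formula
  oracle <- function(b, cr, inr, na, dia) {
    cr <- if (dia) 4 else min(max(cr, 1), 4)
    m <- round(10 * (0.957 * log(cr) + 0.378 * log(max(b, 1)) +
                       1.120 * log(max(inr, 1)) + 0.643))
    m <- min(max(m, 6), 40)
    na <- min(max(na, 125), 137)
    if (m > 11) {
      mn <- round(m + 1.32 * (137 - na) - 0.033 * m * (137 - na))
      min(max(mn, 6), 40)
    } else m
  }
  exp_mn <- mapply(oracle, b, cr, inr, na, dia)
  expect_identical(got$meld_na, as.integer(exp_mn))
})

test_that("scoring rejects invalid labs and missing fields", {
  expect_error(compute_meld_na(-1, 1, 1, 137), "strictly positive")
  expect_error(compute_meld_na(NA, 1, 1, 137), "missing")
  expect_error(score_lab_table(data.frame(patient_id = 1, t = 0)), "missing columns")
})

test_that("organ-failure flags follow the inclusive thresholds", {
  p <- flag_organ_failures(12.0, 1.0, 1.1)
  expect_true(p$liver_f)
  expect_identical(p$n_failures, 1L)

  expect_true(flag_organ_failures(2, 1.4, 1.2, dialysis = TRUE)$kidney_f)

  p2 <- flag_organ_failures(2, 1.0, 1.2, he_grade = 2)
  expect_identical(p2$n_failures, 0L)
  expect_true(p2$brain_dysfunction)

  # inclusive boundary cases
  expect_true(flag_organ_failures(1, 2.0, 1)$kidney_f)
  expect_true(flag_organ_failures(1, 1, 2.5)$coag_f)
  expect_true(flag_organ_failures(1, 1, 1, he_grade = 3)$brain_f)
  # kidney dysfunction band is 1.5-1.9, not on dialysis
  expect_true(flag_organ_failures(1, 1.5, 1)$kidney_dysfunction)
  expect_false(flag_organ_failures(1, 2.0, 1)$kidney_dysfunction)
})

test_that("ACLF grading follows the EF-Clif patterns", {
  base <- flag_organ_failures(1, 1, 1)
  expect_identical(grade_aclf(base), 0L)

  expect_identical(flag_organ_failures(1, 2.2, 1)$aclf_grade, 1L)  # kidney only
  # single liver failure alone: grade 0; with kidney dysfunction: grade 1
  expect_identical(flag_organ_failures(13, 1.0, 1)$aclf_grade, 0L)
  expect_identical(flag_organ_failures(13, 1.6, 1)$aclf_grade, 1L)
  expect_identical(flag_organ_failures(13, 1.0, 1, he_grade = 1)$aclf_grade, 1L)
  # single cerebral failure needs kidney dysfunction
  expect_identical(flag_organ_failures(1, 1.0, 1, he_grade = 4)$aclf_grade, 0L)
  expect_identical(flag_organ_failures(1, 1.7, 1, he_grade = 4)$aclf_grade, 1L)
  # two failures -> 2; three -> 3
  expect_identical(flag_organ_failures(13, 2.5, 1)$aclf_grade, 2L)
  expect_identical(flag_organ_failures(13, 1, 2.6, he_grade = 3)$aclf_grade, 3L)

  expect_error(grade_aclf(transform(base, n_failures = 5L)), "inconsistent")
})

test_that("raising a lab toward its threshold never clears flags and never lowers the grade", {
  set.seed(7)
  for (k in 1:200) {
    b <- exp(stats::runif(1, log(0.5), log(30)))
    cr <- exp(stats::runif(1, log(0.5), log(6)))
    inr <- exp(stats::runif(1, log(0.8), log(5)))
    he <- sample(0:4, 1)
    p1 <- flag_organ_failures(b, cr, inr, he_grade = he)
    p2 <- flag_organ_failures(b * 1.5, cr * 1.5, inr * 1.5, he_grade = min(he + 1, 4))
    flags <- c("liver_f", "kidney_f", "brain_f", "coag_f")
    expect_true(all(!unlist(p1[flags]) | unlist(p2[flags])))
    # adding failures never lowers the grade
    if (p2$n_failures >= p1$n_failures && all(!unlist(p1[flags]) | unlist(p2[flags])))
      expect_gte(p2$aclf_grade, p1$aclf_grade)
  }
})

test_that("scored tables round-trip through CSV with appended columns", {
  labs <- data.frame(patient_id = c("a", "a", "b"), t = c(0, 3, 0),
                     bilirubin = c(2, 14, 1), creatinine = c(1, 2.4, 0.9),
                     inr = c(1.2, 2.8, 1.0), sodium = c(133, 128, 140),
                     he_grade = c(0, 3, 0))
  sc <- score_lab_table(labs)
  expect_true(all(c("meld_na", "aclf_grade", "liver_f") %in% names(sc)))
  expect_identical(sc$aclf_grade[2], 3L)
  tmp <- tempfile(fileext = ".csv")
  write_scored_csv(sc, tmp)
  back <- read_lab_csv(tmp)
  expect_equal(back$meld_na, sc$meld_na)
  unlink(tmp)
})
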