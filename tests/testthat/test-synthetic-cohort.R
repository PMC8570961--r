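# Synthetic waitlist generator: determinism, conservation, null-hazard
# calibration, filters and the patient-level split.

test_that("simulation is reproducible and conserves patients", {
  cfg <- sim_config(n_patients = 80)
  a <- simulate_cohort(cfg, seed = 5)
  b <- simulate_cohort(cfg, seed = 5)
  expect_identical(a$longitudinal, b$longitudinal)
  expect_identical(a$outcomes, b$outcomes)
  expect_identical(a$baseline, b$baseline)

  # one outcome per patient; measurements precede the event
  expect_setequal(a$outcomes$patient_id, a$baseline$patient_id)
  expect_identical(anyDuplicated(a$outcomes$patient_id), 0L)
  mrg <- merge(a$longitudinal, a$outcomes)
  expect_true(all(mrg$t < mrg$event_time))
  expect_true(all(a$longitudinal$t >= 0))
  # registry mode: integer scores within the allocation bounds
  expect_true(all(a$longitudinal$meld_na >= 6 & a$longitudinal$meld_na <= 40))
})

test_that("with no covariate or trajectory effects event times follow the baseline hazard", {
  lam <- 0.004
  cfg <- sim_config(n_patients = 5000, alpha_value = 0, alpha_slope = 0,
                    gamma = c(female = 0), h0 = lam, transplant_rate = 0,
                    removal_rate = 0, horizon = 2500, grid_step = 1,
                    gap_meanlog = log(60))
  co <- simulate_cohort(cfg, seed = 31)
  tt <- co$outcomes$event_time[co$outcomes$event_type == "death"]
  expect_gt(length(tt), 4900)
  ks <- suppressWarnings(stats::ks.test(tt, "pexp", rate = lam))
  expect_gt(ks$p.value, 0.01)
})

test_that("steeper true slopes shorten survival when the slope association is positive", {
  cfg <- sim_config(n_patients = 2000, alpha_value = 0, alpha_slope = 3,
                    gamma = c(female = 0), aclf_shift = c(0, 0, 0),
                    h0 = 2e-3, transplant_rate = 0, removal_rate = 0,
                    horizon = 1500, grid_step = 1, gap_meanlog = log(30))
  co <- simulate_cohort(cfg, seed = 13)
  d <- merge(co$outcomes, co$truth)
  d <- d[d$event_type == "death", ]
  # rank correlation between the true slope and the death time is negative
  expect_lt(stats::cor(d$true_slope, d$event_time, method = "spearman"), -0.2)
})

test_that("the marginal event rate rises with the value association", {
  rates <- sapply(c(0, 0.07, 0.14), function(av) {
    cfg <- sim_config(n_patients = 700, alpha_value = av, alpha_slope = 0,
                      gamma = c(female = 0), transplant_rate = 0,
                      removal_rate = 0, horizon = 90)
    co <- simulate_cohort(cfg, seed = 99)
    mean(co$outcomes$event_type == "death")
  })
  expect_true(all(diff(rates) > 0))
})

test_that("study filters drop flagged patients and censor at exception dates", {
  co <- simulate_cohort(sim_config(n_patients = 10), seed = 2)
  tb <- co[c("baseline", "longitudinal", "outcomes")]
  tb$baseline$hcc <- c(TRUE, TRUE, rep(FALSE, 8))
  f <- apply_study_filters(tb)
  expect_identical(nrow(f$tables$baseline), 8L)
  expect_identical(f$report$hcc, 2L)
  expect_false(any(f$tables$outcomes$patient_id %in% tb$baseline$patient_id[1:2]))

  # no flags: identity
  tb2 <- co[c("baseline", "longitudinal", "outcomes")]
  f2 <- apply_study_filters(tb2)
  expect_identical(f2$tables$outcomes, tb2$outcomes)

  # exception date censors a later death
  tb3 <- co[c("baseline", "longitudinal", "outcomes")]
  tb3$outcomes$event_time[1] <- 45
  tb3$outcomes$event_type[1] <- "death"
  tb3$baseline$exception_day <- c(30, rep(NA, 9))
  f3 <- apply_study_filters(tb3)
  oc1 <- f3$tables$outcomes[f3$tables$outcomes$patient_id ==
                              tb3$baseline$patient_id[1], ]
  expect_identical(oc1$event_time, 30)
  expect_identical(oc1$event_type, "censored")
  lg1 <- f3$tables$longitudinal[f3$tables$longitudinal$patient_id ==
                                  tb3$baseline$patient_id[1], ]
  expect_true(all(lg1$t <= 30))
})

test_that("the train/test split is patient-level, exhaustive and seeded", {
  co <- simulate_cohort(sim_config(n_patients = 100), seed = 8)
  tb <- co[c("baseline", "longitudinal", "outcomes")]
  sp <- split_train_test(tb, 0.67, seed = 1)
  expect_identical(nrow(sp$train$baseline), 67L)
  expect_identical(nrow(sp$test$baseline), 33L)
  expect_length(intersect(sp$train$baseline$patient_id,
                          sp$test$baseline$patient_id), 0)
  expect_setequal(c(sp$train$baseline$patient_id, sp$test$baseline$patient_id),
                  tb$baseline$patient_id)
  # all of a patient's rows land on one side
  expect_true(all(sp$train$longitudinal$patient_id %in%
                    sp$train$baseline$patient_id))
  sp2 <- split_train_test(tb, 0.67, seed = 1)
  expect_identical(sp$train$baseline$patient_id, sp2$train$baseline$patient_id)
  sp3 <- split_train_test(tb, 0.67, seed = 2)
  expect_false(identical(sort(sp$train$baseline$patient_id),
                         sort(sp3$train$baseline$patient_id)))
  expect_error(split_train_test(tb, 1.2), "between 0 and 1")
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(cor_re = 1.5), "positive semi-definite")
  expect_error(sim_config(sigma = -1), "sigma")
  expect_error(sim_config(gamma = c(bogus = 1)), "unknown gamma names")
})
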