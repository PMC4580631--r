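# Deterministic person-time blocks: n subjects followed one year each, the
# first `events` of them with an event (at mid-year, irrelevant to the rate).
py_block <- function(arm, age, sex, n, events, annualization = 365) {
  data.frame(arm = arm, age = age, sex = sex,
             time = annualization,
             event = rep(c(1L, 0L), c(events, n - events)))
}

test_that("one stratum reduces the adjusted rate to the crude rate", {
  rows <- rbind(py_block("fibrate", 65, "male", 100, 12),
                py_block("statin", 66, "male", 300, 24))
  mh <- mh_adjusted_rates(rows)
  expect_equal(mh$rates$rate[mh$rates$arm == "fibrate"], 12, tolerance = 1e-12)
  expect_equal(mh$rates$rate[mh$rates$arm == "statin"], 8, tolerance = 1e-12)
})

test_that("two-stratum adjustment matches the closed-form hand computation", {
  rows <- rbind(py_block("fibrate", 55, "male", 100, 10),
                py_block("fibrate", 65, "male", 200, 5),
                py_block("statin", 55, "male", 100, 8),
                py_block("statin", 65, "male", 200, 4))
  mh <- mh_adjusted_rates(rows)
  # weights Y1*Y0/(Y1+Y0): 50 and 100; rates per 100 py
  w <- c(50, 100)
  r1 <- sum(w * c(10 / 100, 5 / 200)) / sum(w) * 100
  r0 <- sum(w * c(8 / 100, 4 / 200)) / sum(w) * 100
  expect_equal(mh$rates$rate, c(r1, r0), tolerance = 1e-10)
  expect_true(all(mh$rates$lower95 < mh$rates$rate),
              all(mh$rates$upper95 > mh$rates$rate))
})

test_that("adjustment removes confounding by the stratum mix", {
  # identical within-stratum rates, very different age mixes
  rows <- rbind(py_block("fibrate", 55, "male", 400, 40),  # 10 per 100 py
                py_block("fibrate", 85, "male", 50, 1),    # 2 per 100 py
                py_block("statin", 55, "male", 50, 5),
                py_block("statin", 85, "male", 400, 8))
  mh <- mh_adjusted_rates(rows)
  expect_equal(mh$rates$rate[1], mh$rates$rate[2], tolerance = 1e-10)
  crude1 <- 41 / 450 * 100
  crude0 <- 13 / 450 * 100
  expect_gt(abs(crude1 - crude0), 5)  # crude rates are far apart
  expect_gt(mh$p_value, 0.9)
})

test_that("empty strata in one arm are dropped with a warning", {
  rows <- rbind(py_block("fibrate", 55, "male", 50, 5),
                py_block("statin", 55, "male", 50, 4),
                py_block("statin", 85, "female", 30, 3))
  expect_warning(mh <- mh_adjusted_rates(rows), "zero person-time")
  expect_identical(nrow(mh$strata), 1L)
})

test_that("screening keeps strong complete predictors and drops incomplete ones", {
  a <- simulate_cohort(generator_config(n_subjects = 20000, seed = 201))$analysis
  sc <- screen_covariates(a)
  sel <- attr(sc, "selected")
  expect_true("insulin" %in% sel)
  # deprivation quintile has missing values: never selected
  expect_false("dep_quintile" %in% sel)
  expect_false("dm_duration" %in% sel)
  expect_false(any(sc$selected[sc$candidate == "dep_quintile"]))
  # the report covers every candidate
  expect_true(all(c("metformin", "aspirin", "dep_quintile") %in% sc$candidate))
})

test_that("screening power and size behave as a 5%-level Wald test", {
  hits <- 0
  for (r in 1:8) {
    a <- simulate_cohort(generator_config(n_subjects = 20000,
                                          seed = 300 + r))$analysis
    sc <- screen_covariates(a, candidates = "insulin")
    hits <- hits + ("insulin" %in% attr(sc, "selected"))
  }
  expect_gte(hits, 7)  # log HR 0.5, ~90 exposed events: near-full power
  null_hits <- 0
  for (r in 1:30) {
    a <- simulate_cohort(generator_config(n_subjects = 4000,
                                          seed = 400 + r))$analysis
    sc <- screen_covariates(a, candidates = "sulfa")  # not in the hazard model
    null_hits <- null_hits + ("sulfa" %in% attr(sc, "selected"))
  }
  expect_lte(null_hits / 30, 0.17)  # ~5% nominal
})

test_that("final models nest and degenerate gracefully", {
  a <- simulate_cohort(generator_config(n_subjects = 8000, seed = 205))$analysis
  m <- fit_final_models(a, 540, c("insulin", "depression"))
  expect_gte(m$agesex$loglik, m$crude$loglik)
  expect_gte(m$adjusted$loglik, m$agesex$loglik)
  hr <- m$adjusted$hr
  expect_true(all(c("fibrate_p1", "fibrate_p2") %in% names(hr)))
  # zero selected covariates: model 3 equals model 2 exactly
  m0 <- fit_final_models(a, 540, character(0))
  expect_identical(m0$adjusted$coefficients, m0$agesex$coefficients)
  expect_identical(m0$adjusted$loglik, m0$agesex$loglik)
})

test_that("uniform weights reproduce the unweighted fit exactly", {
  d <- simple_cohort(600, hr = 1.5, seed = 211)
  f1 <- cox_fit(d, "fibrate")
  f2 <- cox_fit(d, "fibrate", weights = rep(2, nrow(d)))
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
})

test_that("without confounding, weighting leaves the hazard ratio unchanged", {
  cfg <- generator_config(n_subjects = 15000, seed = 215,
                          propensity_coefficients = c())
  a <- simulate_cohort(cfg)$analysis
  crude <- cox_fit(a, "fibrate")
  ipw <- ipw_cox(a, c("metformin", "insulin", "depression"))
  expect_lt(abs(ipw$fit$coefficients[1] - crude$coefficients[1]), 0.03)
})

test_that("IPW removes strong measured confounding and balances covariates", {
  cfg <- generator_config(n_subjects = 20000, seed = 217,
    propensity_coefficients = c(metformin = 1.2, ccb = 1.0, insulin = 1.5),
    covariate_log_hazards = c(metformin = 0.8, ccb = 0.8, insulin = 1.0),
    treatment_log_hr_schedule = data.frame(start = 0, end = Inf,
                                           loghr = log(1.5)))
  a <- simulate_cohort(cfg)$analysis
  crude <- cox_fit(a, "fibrate")
  ipw <- ipw_cox(a, c("metformin", "ccb", "insulin"))
  expect_lt(abs(ipw$fit$coefficients[1] - log(1.5)),
            abs(crude$coefficients[1] - log(1.5)))
  expect_gt(max(abs(ipw$balance$smd_unweighted)), 0.2)
  expect_lt(max(abs(ipw$balance$smd_weighted)), 0.1)
  # two-period weighted fit runs and reports both periods
  ipw2 <- ipw_cox(a, c("metformin", "ccb", "insulin"), cutoff_day = 540)
  expect_true(all(c("fibrate_p1", "fibrate_p2") %in%
                    names(ipw2$fit$coefficients)))
})

test_that("extreme propensities are flagged and truncation caps weights", {
  set.seed(219)
  n <- 4000
  z <- rbinom(n, 1, 0.5)
  d <- data.frame(subject_id = 1:n, z = z,
                  fibrate = rbinom(n, 1, stats::plogis(-6 + 8 * z)),
                  time = pmax(1, rpois(n, 300)), event = rbinom(n, 1, 0.2))
  ipw <- ipw_cox(d, "z", stabilized = FALSE)
  expect_gt(length(ipw$flagged), 0)
  ipw_t <- ipw_cox(d, "z", stabilized = FALSE, truncate_at = 0.95)
  expect_lt(max(ipw_t$weights), max(ipw$weights))
})
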