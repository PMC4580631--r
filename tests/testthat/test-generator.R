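test_that("config validation rejects malformed generating schedules", {
  expect_error(generator_config(fibrate_share_target = 1.2), "inside")
  expect_error(generator_config(baseline_hazard = 0), "positive")
  expect_error(generator_config(treatment_log_hr_schedule =
    data.frame(start = c(0, 500), end = c(400, Inf), loghr = c(0, 0))),
    "contiguous")
  expect_error(generator_config(treatment_log_hr_schedule =
    data.frame(start = 0, end = 900, loghr = 0)), "Inf")
  expect_error(generator_config(treatment_log_hr_schedule =
    data.frame(start = 100, end = Inf, loghr = 0)), "start at 0")
})

test_that("single-subject generation yields exactly one row of each table", {
  cfg <- generator_config(n_subjects = 1, seed = 42)
  pop <- generate_population(cfg)
  expect_identical(nrow(pop$demographics), 1L)
  expect_identical(nrow(pop$truth), 1L)
})

test_that("generation is reproducible by seed and varies across seeds", {
  cfg <- generator_config(n_subjects = 200, seed = 9)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  c3 <- simulate_cohort(generator_config(n_subjects = 200, seed = 10))
  expect_false(identical(a$analysis$time, c3$analysis$time))
  cl1 <- generate_claims(generate_population(cfg), a$truth, cfg)
  cl2 <- generate_claims(generate_population(cfg), b$truth, cfg)
  expect_identical(cl1, cl2)
})

test_that("propensity intercept calibration hits the fibrate share target", {
  cfg <- generator_config(n_subjects = 31652, seed = 3,
                          propensity_coefficients = c(),
                          fibrate_share_target = 0.128)
  pop <- generate_population(cfg)
  share <- mean(pop$truth$arm == "fibrate")
  se <- sqrt(0.128 * 0.872 / 31652)
  expect_lt(abs(share - 0.128), 3 * se)
  # with confounded assignment the calibration must still hold
  cfg2 <- generator_config(n_subjects = 31652, seed = 4)
  share2 <- mean(generate_population(cfg2)$truth$arm == "fibrate")
  expect_lt(abs(share2 - 0.128), 3 * se)
})

test_that("an unattainable share target raises a calibration error", {
  cfg <- generator_config(n_subjects = 500, seed = 1,
                          propensity_coefficients = c(metformin = 60),
                          fibrate_share_target = 0.128)
  expect_error(generate_population(cfg), "calibration")
})

test_that("a +1 log-odds propensity effect reproduces an odds ratio of e", {
  cfg <- generator_config(n_subjects = 50000, seed = 21,
                          propensity_coefficients = c(depression = 1.0))
  tr <- generate_population(cfg)$truth
  tab <- table(tr$depression, tr$arm == "fibrate")
  or <- tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1])
  se_log_or <- sqrt(sum(1 / tab))
  expect_lt(abs(log(or) - 1.0), 3 * se_log_or)
})

test_that("piecewise-exponential sampler matches the exponential closed form", {
  set.seed(5)
  n <- 10000
  h <- matrix(0.01, n, 1)
  t1 <- coxcpt:::rpiecewise_exp(h, c(0, Inf))
  ks <- stats::ks.test(t1, stats::pexp, rate = 0.01)
  expect_gt(ks$p.value, 0.01)
  # doubling the hazard halves the median
  t2 <- coxcpt:::rpiecewise_exp(matrix(0.02, n, 1), c(0, Inf))
  expect_lt(abs(stats::median(t2) / stats::median(t1) - 0.5), 0.05)
})

test_that("two-interval sampler reproduces the interval hazard ratio", {
  set.seed(8)
  n <- 50000
  d <- 200
  h <- cbind(rep(0.002, n), rep(0.004, n))  # log 2 jump at day d
  t1 <- coxcpt:::rpiecewise_exp(h, c(0, d, Inf))
  # occurrence/exposure oracle per interval against a constant-rate arm
  h0 <- matrix(0.002, n, 2)
  t0 <- coxcpt:::rpiecewise_exp(h0, c(0, d, Inf))
  rate <- function(t, lo, hi) {
    ev <- sum(t > lo & t <= hi)
    py <- sum(pmax(0, pmin(t, hi) - lo))
    c(ev = ev, rate = ev / py)
  }
  r1a <- rate(t1, 0, d); r0a <- rate(t0, 0, d)
  r1b <- rate(t1, d, 2000); r0b <- rate(t0, d, 2000)
  se_ratio <- function(ra, rb) sqrt(1 / ra[["ev"]] + 1 / rb[["ev"]])
  expect_lt(abs(log(r1a[["rate"]] / r0a[["rate"]]) - 0), 3 * se_ratio(r1a, r0a))
  expect_lt(abs(log(r1b[["rate"]] / r0b[["rate"]]) - log(2)),
            3 * se_ratio(r1b, r0b))
})

test_that("cumulative hazard at an uncensored event time is unit exponential", {
  cfg <- generator_config(n_subjects = 10000, seed = 13,
                          study_window = c(0L, 0L),
                          baseline_hazard = 0.001,
                          covariate_log_hazards = c(),
                          censor_admin_day = 1000000L)
  sim <- simulate_cohort(cfg)
  expect_true(all(sim$analysis$event == 1))
  ch <- sim$truth$cumhaz_at_exit
  expect_lt(abs(mean(ch) - 1), 3 / sqrt(length(ch)))
})

test_that("claims streams satisfy the entry rules by construction", {
  cfg <- generator_config(n_subjects = 80, seed = 17)
  pop <- generate_population(cfg)
  out <- simulate_outcomes(pop$truth, cfg)
  cl <- generate_claims(pop, out, cfg)
  for (i in seq_len(nrow(out))) {
    d <- cl[cl$subject_id == out$subject_id[i], ]
    idx <- out$index_day[i]
    own <- if (out$arm[i] == "fibrate") "fibrate" else "statin"
    ind <- d[d$code_class == own & d$record_type == "drug", ]
    expect_gte(nrow(ind), 2)
    expect_true(all(ind$prescriber == "gp"))
    oad <- d$day[d$record_type == "drug" & startsWith(d$code_class, "oad_") &
                   d$day >= idx - 913 & d$day < idx]
    aht <- d$day[d$record_type == "drug" &
                   startsWith(d$code_class, "antihypertensive_") &
                   d$day >= idx - 913 & d$day < idx]
    expect_true(brute_rolling(oad, 3, 365))
    expect_true(brute_rolling(aht, 3, 365))
  }
  # designed violations show up in the stream
  des <- c(`1` = "prior_lipid", `2` = "single_reimb", `3` = "non_gp",
           `4` = "prior_cv")
  cl2 <- generate_claims(pop, out, cfg, exclusion_design = des)
  d1 <- cl2[cl2$subject_id == 1, ]
  other <- setdiff(c("statin", "fibrate"),
                   if (out$arm[1] == "fibrate") "fibrate" else "statin")
  expect_true(any(d1$code_class == other & d1$day < out$index_day[1] &
                    d1$day >= out$index_day[1] - 913))
  d4 <- cl2[cl2$subject_id == 4, ]
  expect_true(any(startsWith(d4$code_class, "cv_event_") &
                    d4$day < out$index_day[4]))
})
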