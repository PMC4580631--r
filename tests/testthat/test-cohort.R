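test_that("minimal qualifying pattern defines an initiator", {
  cl <- rbind(drug3(1, "statin", c(10, 40)))
  out <- identify_initiators(cl)
  expect_identical(out$arm, "statin")
  expect_identical(out$index_day, 10L)
})

test_that("a single reimbursement is not an initiation", {
  expect_identical(nrow(identify_initiators(drug3(1, "fibrate", 10))), 0L)
})

test_that("simultaneous statin and fibrate at index is not monotherapy", {
  cl <- rbind(drug3(1, "statin", c(10, 40)), drug3(1, "fibrate", 10))
  expect_identical(nrow(identify_initiators(cl)), 0L)
  # other class intervening between the two reimbursements also disqualifies
  cl2 <- rbind(drug3(2, "statin", 10), drug3(2, "fibrate", 25),
               drug3(2, "statin", 40))
  expect_identical(nrow(identify_initiators(cl2)), 0L)
})

test_that("empty claims give an empty result, not an error", {
  out <- identify_initiators(drug3(1, "statin", c(10, 40))[0, ])
  expect_identical(nrow(out), 0L)
})

test_that("the hand-enumerated fixture yields exactly the designed cohort", {
  fx <- fixture10()
  cand <- identify_initiators(fx$claims)
  expect_setequal(cand$subject_id, c(1L, 2L, 6L, 7L, 8L, 9L, 10L))
  coh <- build_cohort(fx$claims, fx$demographics)
  expect_setequal(coh$subject_id, fx$included)
  expect_identical(as.character(coh$arm[match(fx$included, coh$subject_id)]),
                   unname(fx$arms))
  att <- attr(coh, "attrition")
  expect_identical(att$remaining, c(7L, 6L, 5L, 5L, 4L))
  # designed covariates and outcome of subject 1
  s1 <- coh[coh$subject_id == 1, ]
  expect_identical(s1$metformin, 1L)
  expect_identical(s1$event, 1L)
  expect_identical(s1$event_type, "stroke")
  expect_identical(s1$time, 100L)
})

test_that("age/sex thresholds are inclusive at 50 (men) and exclude younger women", {
  fx <- fixture10()
  coh <- build_cohort(fx$claims, fx$demographics)
  expect_true(7L %in% coh$subject_id)   # male aged exactly 50
  expect_false(6L %in% coh$subject_id)  # female aged 59
})

test_that("missing demographics raise an error naming the subject", {
  fx <- fixture10()
  cand <- identify_initiators(fx$claims)
  expect_error(apply_inclusion(cand, fx$claims, fx$demographics[-1, ]), "1")
})

test_that("comedication flags require three reimbursements in the prior year", {
  rows <- data.frame(subject_id = 1:2, arm = c("statin", "statin"),
                     index_day = c(0L, 0L), sex = "male", age = 60L,
                     dep_quintile = 1L)
  cl <- rbind(drug3(1, "oad_metformin", c(-300, -200, -100)),
              drug3(2, "oad_metformin", c(-300, -200)))
  out <- derive_covariates(rows, cl, NULL)
  expect_identical(out$metformin, c(1L, 0L))
  # no claims in the prior year leaves every flag at zero
  rows3 <- rows[1, ]; rows3$subject_id <- 3L
  out3 <- derive_covariates(rows3, cl, NULL)
  expect_true(all(out3[, c("metformin", "insulin", "aspirin", "hosp_any")] == 0))
})

test_that("rolling-window disease counts agree with a brute-force scan", {
  set.seed(31)
  for (r in 1:200) {
    days <- sort(sample(-913:-1, sample(1:8, 1)))
    k <- sample(2:4, 1)
    expect_identical(coxcpt:::has_rolling_count(days, k, 365),
                     brute_rolling(days, k, 365))
  }
})

test_that("only the first outcome occurrence counts", {
  rows <- data.frame(subject_id = 1L, arm = "statin", index_day = 0L,
                     sex = "male", age = 60L, dep_quintile = 1L)
  cl <- rbind(claim_row(1, 100, "hospital", "cv_event_stroke"),
              claim_row(1, 200, "death", "death"))
  out <- derive_outcome(rows, cl, admin_end_day = 913L)
  expect_identical(out$event, 1L)
  expect_identical(out$event_type, "stroke")
  expect_identical(out$time, 100L)
  # permuting claim order leaves the outcome unchanged
  out2 <- derive_outcome(rows, cl[2:1, ], admin_end_day = 913L)
  expect_identical(out, out2)
  # no events: administrative censoring
  out3 <- derive_outcome(rows, cl[0, ], admin_end_day = 913L)
  expect_identical(out3$event, 0L)
  expect_identical(out3$time, 913L)
  # excluding amputations recomputes the first occurrence
  cl4 <- rbind(claim_row(1, 50, "hospital", "cv_event_amputation"),
               claim_row(1, 200, "death", "death"))
  out4 <- derive_outcome(rows, cl4, 913L, include_amputation = FALSE)
  expect_identical(out4$event_type, "death")
  expect_identical(out4$time, 200L)
})

test_that("persistence and switch censoring follow the six-month gap rule", {
  fx <- fixture10()
  itt <- build_cohort(fx$claims, fx$demographics, rule = "itt")
  per <- build_cohort(fx$claims, fx$demographics, rule = "persistence")
  sw <- build_cohort(fx$claims, fx$demographics, rule = "switch")
  g <- function(d, id, col) d[d$subject_id == id, col]
  # refills at 0 and 30 then none; event at 350 -> truncated at 30+183
  expect_identical(g(per, 10, "time"), 213L)
  expect_identical(g(per, 10, "event"), 0L)
  # switch to statin at day 100 -> truncated at 100+183, event at 350 dropped
  expect_identical(g(sw, 10, "time"), 283L)
  expect_identical(g(sw, 10, "event"), 0L)
  # subject 1 persists past the event: untouched under both rules
  expect_identical(g(per, 1, "time"), 100L)
  expect_identical(g(per, 1, "event"), 1L)
  expect_identical(g(sw, 1, "time"), 100L)
  # itt is the identity rule
  expect_identical(itt, build_cohort(fx$claims, fx$demographics))
})

test_that("censoring rules never extend follow-up or add events", {
  cfg <- generator_config(n_subjects = 150, seed = 23)
  pop <- generate_population(cfg)
  out <- simulate_outcomes(pop$truth, cfg)
  cl <- generate_claims(pop, out, cfg)
  itt <- build_cohort(cl, pop$demographics, rule = "itt")
  for (rule in c("persistence", "switch")) {
    alt <- build_cohort(cl, pop$demographics, rule = rule)
    expect_identical(alt$subject_id, itt$subject_id)
    expect_true(all(alt$time <= itt$time))
    expect_true(all(alt$event <= itt$event))
  }
})

test_that("relaxing a single criterion never shrinks the included set", {
  cfg <- generator_config(n_subjects = 120, seed = 29)
  pop <- generate_population(cfg)
  out <- simulate_outcomes(pop$truth, cfg)
  des <- stats::setNames(rep(c("prior_lipid", "prior_cv", "single_reimb",
                               "non_gp"), each = 5), 1:20)
  cl <- generate_claims(pop, out, cfg, exclusion_design = des)
  base <- build_cohort(cl, pop$demographics)$subject_id
  relaxed <- list(
    eligibility_criteria(min_disease_reimbursements = 2L),
    eligibility_criteria(min_age_male = 40L, min_age_female = 40L),
    eligibility_criteria(require_gp_prescriber = FALSE),
    eligibility_criteria(max_refill_gap_days = 400L))
  for (cr in relaxed) {
    ids <- build_cohort(cl, pop$demographics, criteria = cr)$subject_id
    expect_true(all(base %in% ids))
  }
})

test_that("flow-chart counts sum from candidates to the included set", {
  cfg <- generator_config(n_subjects = 100, seed = 37)
  pop <- generate_population(cfg)
  out <- simulate_outcomes(pop$truth, cfg)
  des <- stats::setNames(rep("prior_cv", 8), 3:10)
  cl <- generate_claims(pop, out, cfg, exclusion_design = des)
  coh <- build_cohort(cl, pop$demographics)
  att <- attr(coh, "attrition")
  n_cand <- att$remaining[1]
  expect_identical(n_cand - sum(att$excluded[-1]),
                   att$remaining[nrow(att)])
  expect_identical(att$remaining[nrow(att)], nrow(coh))
})
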