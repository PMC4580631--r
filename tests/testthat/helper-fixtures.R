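# Shared fixtures and independent oracles, built in code at test time.

claim_row <- function(id, day, type, class, presc = "na") {
  data.frame(subject_id = id, day = as.integer(day), record_type = type,
             code_class = class, prescriber = presc, stringsAsFactors = FALSE)
}

drug3 <- function(id, class, days, presc = "gp")
  do.call(rbind, lapply(days, claim_row, id = id, type = "drug",
                        class = class, presc = presc))

# Ten-subject hand-enumerated claims fixture. Designed outcomes:
#   included: 1 (statin), 2 (fibrate), 7 (statin, male aged exactly 50),
#             10 (fibrate; persistence/switch truncation case)
#   excluded: 3 (prior statin in washout), 4 (single reimbursement),
#             5 (non-GP prescriber), 6 (female aged 59),
#             8 (cardiovascular event in washout), 9 (only 2 OAD records)
fixture10 <- function() {
  cl <- rbind(
    # 1: statin initiator, index 10, stroke at day 110 (follow-up 100)
    drug3(1, "statin", c(10, 40)),
    drug3(1, "oad_metformin", c(-290, -190, -90)),
    drug3(1, "antihypertensive_other", c(-280, -180, -80)),
    claim_row(1, 110, "hospital", "cv_event_stroke"),
    # 2: fibrate initiator, index 20, no event
    drug3(2, "fibrate", c(20, 50)),
    drug3(2, "oad_sulfa", c(-180, -130, -80)),
    drug3(2, "antihypertensive_acei", c(-170, -120, -70)),
    # 3: prior statin 100 days before an otherwise valid initiation
    drug3(3, "statin", c(-100, 15, 45)),
    drug3(3, "oad_metformin", c(-200, -150, -100)),
    drug3(3, "antihypertensive_other", c(-190, -140, -90)),
    # 4: one reimbursement only
    drug3(4, "statin", 30),
    drug3(4, "oad_metformin", c(-200, -150, -100)),
    drug3(4, "antihypertensive_other", c(-190, -140, -90)),
    # 5: prescriber is not a GP
    drug3(5, "statin", c(12, 42), presc = "other"),
    drug3(5, "oad_metformin", c(-200, -150, -100)),
    drug3(5, "antihypertensive_other", c(-190, -140, -90)),
    # 6: valid claims, female aged 59
    drug3(6, "statin", c(8, 38)),
    drug3(6, "oad_metformin", c(-200, -150, -100)),
    drug3(6, "antihypertensive_other", c(-190, -140, -90)),
    # 7: male aged exactly 50 (inclusive boundary)
    drug3(7, "statin", c(5, 35)),
    drug3(7, "oad_metformin", c(-295, -195, -95)),
    drug3(7, "antihypertensive_ccb", c(-285, -185, -85)),
    # 8: stroke hospitalisation 200 days before index
    drug3(8, "fibrate", c(25, 55)),
    drug3(8, "oad_metformin", c(-200, -150, -100)),
    drug3(8, "antihypertensive_other", c(-190, -140, -90)),
    claim_row(8, -175, "hospital", "cv_event_stroke"),
    # 9: only two oral-antidiabetic reimbursements
    drug3(9, "statin", c(18, 48)),
    drug3(9, "oad_metformin", c(-100, -50)),
    drug3(9, "antihypertensive_other", c(-190, -140, -90)),
    # 10: fibrate initiator, index 0, refills at 0 and 30 then none,
    #     switch to statin at day 100, myocardial infarction at day 350
    drug3(10, "fibrate", c(0, 30)),
    drug3(10, "statin", 100),
    drug3(10, "oad_glitazone", c(-200, -150, -100)),
    drug3(10, "antihypertensive_arb", c(-190, -140, -90)),
    claim_row(10, 350, "hospital", "cv_event_mi"))
  demo <- data.frame(
    subject_id = 1:10,
    sex = c("male", "female", "male", "male", "male",
            "female", "male", "female", "male", "female"),
    birth_year = 2008L - c(60L, 65L, 62L, 63L, 64L, 59L, 50L, 66L, 61L, 67L),
    dep_quintile = c(1L, 2L, 3L, 4L, 5L, 1L, 2L, 3L, 4L, 5L),
    stringsAsFactors = FALSE)
  list(claims = cl, demographics = demo,
       included = c(1L, 2L, 7L, 10L),
       arms = c(`1` = "statin", `2` = "fibrate", `7` = "statin",
                `10` = "fibrate"))
}

# Exhaustive grid maximiser of the Breslow log partial likelihood for a
# single binary covariate: the independent oracle for the Newton fitters.
breslow_loglik <- function(time, event, x, beta) {
  ed <- sort(unique(time[event == 1]))
  sapply(beta, function(b) {
    s <- 0
    for (d in ed) {
      r1 <- sum(x == 1 & time >= d); r0 <- sum(x == 0 & time >= d)
      e1 <- sum(time == d & event == 1 & x == 1)
      e0 <- sum(time == d & event == 1 & x == 0)
      s <- s + e1 * b - (e0 + e1) * log(r0 + r1 * exp(b))
    }
    s
  })
}

grid_max_breslow <- function(time, event, x, lo = -4, hi = 4, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  ll <- breslow_loglik(time, event, x, grid)
  grid[which.max(ll)]
}

# Brute-force check: k reimbursements within some `window`-day span
brute_rolling <- function(days, k, window) {
  days <- sort(days)
  if (length(days) < k) return(FALSE)
  for (start in days)
    if (sum(days >= start & days <= start + window - 1) >= k) return(TRUE)
  FALSE
}

toy6 <- function()
  utils::read.csv(system.file("extdata", "toy6.csv", package = "coxcpt"))

published_counts <- function()
  utils::read.csv(system.file("extdata", "published_counts.csv",
                              package = "coxcpt"))

# Small single-period cohort simulated outside the claims machinery; used
# where a test needs survival data but not the generator under test.
simple_cohort <- function(n, hr = 1, p_treat = 0.5, h0 = 0.002, cens = 900,
                          seed = 1) {
  set.seed(seed)
  x <- stats::rbinom(n, 1, p_treat)
  t_cont <- stats::rexp(n, h0 * hr^x)
  time <- pmax(1L, as.integer(ceiling(pmin(t_cont, cens))))
  data.frame(subject_id = seq_len(n), time = time,
             event = as.integer(t_cont <= cens), fibrate = x)
}
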