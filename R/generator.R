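#' Configuration for the synthetic claims generator
#'
#' Builds and validates the configuration object consumed by
#' [generate_population()], [simulate_outcomes()], [generate_claims()] and the
#' one-call wrapper [simulate_cohort()]. Defaults emulate a French-style
#' new-user cohort of high-cardiovascular-risk diabetic patients initiating
#' statin or fibrate monotherapy: entry staggered over an 18-month inclusion
#' window, administrative end of follow-up 913 days after the study epoch,
#' a 12.8\% fibrate share, and a piecewise-constant treatment hazard ratio
#' that is null early in follow-up and harmful late (0.95 before day 540,
#' 1.73 after).
#'
#' All times are integer day offsets from the study epoch (day 0 = opening of
#' the inclusion window). "30 months" of drug history corresponds to 913 days.
#'
#' @param n_subjects number of subjects to simulate.
#' @param study_window integer length-2 vector, first and last day on which a
#'   subject may enter (index window).
#' @param fibrate_share_target expected proportion of fibrate initiators,
#'   strictly inside (0, 1). The propensity-model intercept is calibrated so
#'   the population share matches this value.
#' @param propensity_coefficients named numeric vector of log-odds effects of
#'   covariates on receiving fibrate (names must be covariate columns, or
#'   `"age_c"` for age centred at 68, `"male"` for the sex indicator).
#' @param baseline_hazard baseline event hazard per person-day (> 0) for a
#'   female statin user aged 68 with no comorbidity flags.
#' @param covariate_log_hazards named numeric vector of log-hazard effects.
#' @param treatment_log_hr_schedule data frame with columns `start`, `end`,
#'   `loghr`: contiguous intervals starting at 0, last `end` must be `Inf`.
#'   The log hazard ratio applies to the fibrate arm (statin reference).
#' @param censor_admin_day administrative end of follow-up (day offset).
#' @param random_censor_rate optional rate (per person-day) of uninformative
#'   loss to follow-up; 0 disables it.
#' @param dep_missing_rate fraction of subjects with missing deprivation
#'   quintile (missing completely at random).
#' @param duration_unknown_rate fraction of subjects whose diabetes onset
#'   predates the observable claims history (duration band "unknown").
#' @param covariate_marginals named list of marginal prevalences for the
#'   binary covariates; see `coxcpt_default_marginals()`.
#' @param seed integer seed driving all randomness of the generator.
#' @return an object of class `coxcpt_config` (a validated list).
#' @export
generator_config <- function(n_subjects = 10000,
                             study_window = c(0L, 549L),
                             fibrate_share_target = 0.128,
                             propensity_coefficients = coxcpt_default_propensity(),
                             baseline_hazard = 2.7e-5,
                             covariate_log_hazards = coxcpt_default_log_hazards(),
                             treatment_log_hr_schedule = default_hr_schedule(),
                             censor_admin_day = 913L,
                             random_censor_rate = 0,
                             dep_missing_rate = 0.09,
                             duration_unknown_rate = 0.30,
                             covariate_marginals = coxcpt_default_marginals(),
                             seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    study_window = as.integer(study_window),
    fibrate_share_target = fibrate_share_target,
    propensity_coefficients = propensity_coefficients,
    baseline_hazard = baseline_hazard,
    covariate_log_hazards = covariate_log_hazards,
    treatment_log_hr_schedule = treatment_log_hr_schedule,
    censor_admin_day = as.integer(censor_admin_day),
    random_censor_rate = random_censor_rate,
    dep_missing_rate = dep_missing_rate,
    duration_unknown_rate = duration_unknown_rate,
    covariate_marginals = covariate_marginals,
    seed = as.integer(seed)
  )
  class(cfg) <- "coxcpt_config"
  validate_config(cfg)
  cfg
}

#' @rdname generator_config
#' @param x a `coxcpt_config` object.
#' @export
validate_config <- function(x) {
  stopifnot(inherits(x, "coxcpt_config"))
  if (x$n_subjects < 1L) stop("n_subjects must be a positive count")
  if (length(x$study_window) != 2L || x$study_window[2] < x$study_window[1])
    stop("study_window must be (start_day, end_day) with end >= start")
  if (!(x$fibrate_share_target > 0 && x$fibrate_share_target < 1))
    stop("fibrate_share_target must be strictly inside (0, 1)")
  if (x$baseline_hazard <= 0) stop("baseline_hazard must be strictly positive")
  if (x$random_censor_rate < 0) stop("random_censor_rate must be >= 0")
  sch <- x$treatment_log_hr_schedule
  if (!is.data.frame(sch) || !all(c("start", "end", "loghr") %in% names(sch)))
    stop("treatment_log_hr_schedule needs columns start, end, loghr")
  sch <- sch[order(sch$start), , drop = FALSE]
  if (sch$start[1] != 0)
    stop("treatment_log_hr_schedule intervals must start at 0")
  if (nrow(sch) > 1 && any(sch$start[-1] != sch$end[-nrow(sch)]))
    stop("treatment_log_hr_schedule intervals must be contiguous and non-overlapping")
  if (!is.infinite(sch$end[nrow(sch)]))
    stop("last treatment_log_hr_schedule interval must extend to Inf")
  if (any(sch$end <= sch$start)) stop("schedule intervals must have positive length")
  if (x$censor_admin_day <= x$study_window[2])
    stop("censor_admin_day must lie after the study window")
  invisible(x)
}

#' @rdname generator_config
#' @export
default_hr_schedule <- function() {
  data.frame(start = c(0, 540), end = c(540, Inf),
             loghr = c(log(0.95), log(1.73)))
}

#' Default generating parameters
#'
#' Marginal covariate prevalences, treatment-propensity log-odds and outcome
#' log-hazards used by [generator_config()]. Prevalences follow the published
#' baseline table of a nationwide fibrate-vs-statin initiator cohort
#' (31,652 subjects); propensity effects reproduce the direction and rough
#' size of the observed arm imbalances (fibrate users younger, more often
#' women and depressed, less often on metformin, insulin, antiplatelets or
#' ACE inhibitors); log-hazards follow the age- and sex-adjusted univariate
#' hazard ratios of the same study.
#'
#' @return a named list / named numeric vector of defaults.
#' @export
coxcpt_default_marginals <- function() {
  list(
    p_female = 0.476,
    # age bands 50-59 (men only), 60-69, 70-79, 80+
    age_band_probs = c(0.158, 0.434, 0.305, 0.103),
    metformin = 0.641, sulfa = 0.420, glitazone = 0.073, oad_other = 0.177,
    insulin = 0.077,
    alzheimer = 0.0085, cancer = 0.013, depression = 0.108, parkinson = 0.005,
    betablocker = 0.217, arb = 0.219, acei = 0.183, diuretic = 0.052,
    ccb = 0.266, antihtn_other = 0.530,
    aspirin = 0.160, clopidogrel = 0.031,
    hosp_any = 0.176,
    # diabetes duration bands <2, 2-5, 5-10, 10+ among subjects with a known band
    duration_band_probs = c(0.289, 0.237, 0.253, 0.221)
  )
}

#' @rdname coxcpt_default_marginals
#' @export
coxcpt_default_propensity <- function() {
  c(male = -0.10, age_c = -0.012,
    metformin = -0.25, oad_other = -0.20, insulin = -0.35,
    depression = 0.27, aspirin = -0.28, clopidogrel = -0.35,
    acei = -0.25, ccb = -0.18, arb = -0.13, betablocker = 0.13)
}

#' @rdname coxcpt_default_marginals
#' @export
coxcpt_default_log_hazards <- function() {
  c(male = log(1.61), age_c = log(1.07),
    insulin = log(1.65), alzheimer = log(2.46), cancer = log(2.29),
    depression = log(1.42), parkinson = log(2.67), clopidogrel = log(1.44),
    ccb = log(1.14), hosp_any = log(1.17))
}

binary_covariate_names <- function() {
  c("metformin", "sulfa", "glitazone", "oad_other", "insulin",
    "alzheimer", "cancer", "depression", "parkinson",
    "betablocker", "arb", "acei", "diuretic", "ccb", "antihtn_other",
    "aspirin", "clopidogrel", "hosp_any")
}

# Design matrix used by both the propensity and the hazard linear predictors.
covariate_design <- function(cov) {
  cbind(male = as.numeric(cov$sex == "male"),
        age_c = cov$age - 68,
        as.matrix(cov[, binary_covariate_names(), drop = FALSE]))
}

linear_predictor <- function(design, coefs) {
  if (length(coefs) == 0) return(rep(0, nrow(design)))
  missing <- setdiff(names(coefs), colnames(design))
  if (length(missing))
    stop("unknown covariate(s) in coefficient vector: ",
         paste(missing, collapse = ", "))
  drop(design[, names(coefs), drop = FALSE] %*% coefs)
}

#' Generate a synthetic study population
#'
#' Draws demographics, baseline covariates and a confounded treatment arm for
#' each subject. The treatment arm follows a logistic model on the configured
#' covariates whose intercept is calibrated numerically so that the expected
#' fibrate share equals `fibrate_share_target`.
#'
#' @param config a [generator_config()] object.
#' @return a list with elements `demographics` (subject_id, sex, birth_year,
#'   dep_quintile) and `truth` (one row per subject: arm, index day, all
#'   covariate values, diabetes-duration band, propensity linear predictor).
#' @export
generate_population <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  n <- config$n_subjects
  m <- config$covariate_marginals

  sex <- ifelse(stats::runif(n) < m$p_female, "female", "male")
  # band 1 (50-59) is male-only; females get bands 2-4 renormalised
  bp <- m$age_band_probs
  band <- integer(n)
  is_f <- sex == "female"
  band[!is_f] <- sample.int(4L, sum(!is_f), replace = TRUE, prob = bp)
  band[is_f] <- 1L + sample.int(3L, sum(is_f), replace = TRUE, prob = bp[2:4])
  lo <- c(50, 60, 70, 80)[band]
  hi <- c(59, 69, 79, 92)[band]
  age <- lo + floor(stats::runif(n) * (hi - lo + 1))

  dep <- sample.int(5L, n, replace = TRUE)
  dep[stats::runif(n) < config$dep_missing_rate] <- NA_integer_

  cov <- data.frame(subject_id = seq_len(n), sex = sex, age = age,
                    dep_quintile = dep, stringsAsFactors = FALSE)
  for (nm in binary_covariate_names())
    cov[[nm]] <- as.integer(stats::runif(n) < m[[nm]])

  dur_known <- stats::runif(n) >= config$duration_unknown_rate
  dur_band <- rep("unknown", n)
  dur_band[dur_known] <- c("<2", "2-5", "5-10", "10+")[
    sample.int(4L, sum(dur_known), replace = TRUE, prob = m$duration_band_probs)]
  cov$dm_duration <- dur_band

  design <- covariate_design(cov)
  lp <- linear_predictor(design, config$propensity_coefficients)
  f <- function(a) mean(stats::plogis(a + lp)) - config$fibrate_share_target
  if (f(-25) > 0 || f(25) < 0)
    stop("propensity calibration failed: fibrate_share_target unattainable ",
         "with the given propensity_coefficients")
  a0 <- stats::uniroot(f, c(-25, 25), tol = 1e-10)$root
  arm <- ifelse(stats::runif(n) < stats::plogis(a0 + lp), "fibrate", "statin")

  index_day <- config$study_window[1] +
    floor(stats::runif(n) * (diff(config$study_window) + 1))

  truth <- cov
  truth$arm <- arm
  truth$index_day <- as.integer(index_day)
  truth$propensity_lp <- a0 + lp

  demographics <- data.frame(
    subject_id = cov$subject_id,
    sex = cov$sex,
    birth_year = 2008L - cov$age,
    dep_quintile = cov$dep_quintile,
    stringsAsFactors = FALSE)

  list(demographics = demographics, truth = truth)
}

# Exact piecewise-exponential sampler: inverts the cumulative hazard
# Lambda(t) = sum_k h_k * overlap(t, interval k) in closed form.
# h is an n x K matrix of per-interval hazards, bounds the K+1 interval
# boundaries (first 0, last Inf). Returns continuous event times.
rpiecewise_exp <- function(h, bounds, u = NULL) {
  n <- nrow(h); K <- ncol(h)
  if (is.null(u)) u <- stats::runif(n)
  target <- -log(u)
  t_out <- rep(NA_real_, n)
  acc <- rep(0, n)               # cumulative hazard at interval start
  for (k in seq_len(K)) {
    len <- bounds[k + 1] - bounds[k]
    need <- is.na(t_out)
    inc <- h[, k] * len          # Inf * Inf-safe: last interval len = Inf
    hit <- need & (target <= acc + inc)
    t_out[hit] <- bounds[k] + (target[hit] - acc[hit]) / h[hit, k]
    acc <- acc + ifelse(is.finite(inc), inc, 0)
  }
  t_out
}

#' Simulate outcome times under a piecewise-constant treatment effect
#'
#' Event times are drawn from a piecewise-exponential distribution with
#' subject hazard `baseline_hazard * exp(covariate effects + treatment log HR
#' in force at t)`; the inversion of the cumulative hazard is exact. Times are
#' measured from each subject's index day and rounded up to whole days (claims
#' data carry day granularity). Censoring occurs at the administrative end of
#' follow-up and, optionally, at an exponential loss-to-follow-up time.
#'
#' @param truth the `truth` table from [generate_population()].
#' @param config a [generator_config()] object.
#' @return `truth` with columns `true_event_day` (NA when censored before the
#'   event), `true_censor_day`, `time` (follow-up in days), `event` (0/1),
#'   `event_type` and `cumhaz_at_exit` (the realised cumulative hazard, kept
#'   for calibration checks).
#' @export
simulate_outcomes <- function(truth, config) {
  validate_config(config)
  set.seed(config$seed + 1L)
  n <- nrow(truth)
  sch <- config$treatment_log_hr_schedule[
    order(config$treatment_log_hr_schedule$start), , drop = FALSE]
  bounds <- c(sch$start, Inf)
  design <- covariate_design(truth)
  lp <- linear_predictor(design, config$covariate_log_hazards)
  base <- config$baseline_hazard * exp(lp)
  fib <- truth$arm == "fibrate"
  mult <- outer(fib, exp(sch$loghr), function(f, m) ifelse(f, m, 1))
  h <- base * mult
  t_cont <- rpiecewise_exp(h, bounds)
  event_day <- pmax(1L, as.integer(ceiling(t_cont)))

  cens <- config$censor_admin_day - truth$index_day
  if (config$random_censor_rate > 0) {
    ltfu <- pmax(1L, as.integer(ceiling(stats::rexp(n, config$random_censor_rate))))
    cens <- pmin(cens, ltfu)
  }
  event <- as.integer(event_day <= cens)
  time <- ifelse(event == 1L, event_day, cens)

  out <- truth
  out$true_event_day <- ifelse(event == 1L, event_day, NA_integer_)
  out$true_censor_day <- as.integer(cens)
  out$time <- as.integer(time)
  out$event <- event
  out$event_type <- ifelse(event == 1L,
                           sample(c("death", "stroke", "mi", "amputation"), n,
                                  replace = TRUE,
                                  prob = c(0.55, 0.25, 0.19, 0.012)),
                           "none")
  # cumulative hazard actually accrued at exit (exact, piecewise)
  ch <- numeric(n)
  for (k in seq_len(nrow(sch))) {
    overlap <- pmax(0, pmin(time, bounds[k + 1]) - bounds[k])
    ch <- ch + h[, k] * overlap
  }
  out$cumhaz_at_exit <- ch
  out
}

#' One-call synthetic analysis cohort
#'
#' Convenience wrapper producing a ready-to-analyse table (one row per
#' subject with arm, follow-up, event and baseline covariates) together with
#' the generating truth, bypassing the claims stream and cohort builder. This
#' is the path used for validating the statistical machinery; the claims path
#' ([generate_claims()] + [build_cohort()]) validates the cohort construction.
#'
#' @inheritParams generate_population
#' @return list with `analysis` (an analysis table, see [build_cohort()]) and
#'   `truth`.
#' @export
simulate_cohort <- function(config) {
  pop <- generate_population(config)
  tr <- simulate_outcomes(pop$truth, config)
  keep <- c("subject_id", "arm", "index_day", "time", "event", "event_type",
            "sex", "age", "dep_quintile", "dm_duration",
            binary_covariate_names())
  analysis <- tr[, keep]
  analysis$arm <- factor(analysis$arm, levels = c("statin", "fibrate"))
  analysis$fibrate <- as.integer(analysis$arm == "fibrate")
  analysis$male <- as.integer(analysis$sex == "male")
  list(analysis = analysis, truth = tr)
}
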