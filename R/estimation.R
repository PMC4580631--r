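#' Mantel-Haenszel age- and sex-adjusted annual event rates
#'
#' Per-stratum (age band x sex) incidence rates (events per person-year of
#' first-event follow-up) are combined across strata with Mantel-Haenszel
#' person-time weights `w_s = Y_s0 Y_s1 / (Y_s0 + Y_s1)`, yielding one
#' adjusted annual rate per arm, reported per 100 person-years. Confidence
#' intervals use the normal approximation on the log rate; the two-arm
#' comparison p-value comes from the MH-weighted rate difference.
#'
#' @param rows analysis table with `arm`, `age`, `sex`, `time`, `event`.
#' @param age_breaks lower bounds of the age bands (default the 50-59,
#'   60-69, 70-79, 80+ bands).
#' @param annualization days per person-year.
#' @param scale rates reported per `scale` person-years (100 by default, so
#'   a rate of 2.42 reads "2.42\% per year").
#' @return object of class `mh_rates`: per-arm adjusted rate with 95\% CI,
#'   per-stratum detail, p-value.
#' @export
mh_adjusted_rates <- function(rows, age_breaks = c(50, 60, 70, 80),
                              annualization = 365, scale = 100) {
  band <- cut(rows$age, breaks = c(age_breaks, Inf), right = FALSE,
              labels = paste0(age_breaks, "+"))
  if (any(is.na(band))) stop("mh_adjusted_rates: ages below the first band")
  stratum <- interaction(band, rows$sex, drop = TRUE)
  fib <- rows$arm == "fibrate"
  py <- rows$time / annualization
  agg <- function(sel) {
    data.frame(stratum = levels(stratum),
               events = as.vector(tapply(rows$event[sel], stratum[sel], sum,
                                         default = 0)),
               py = as.vector(tapply(py[sel], stratum[sel], sum, default = 0)))
  }
  a1 <- agg(fib); a0 <- agg(!fib)
  a1$events[is.na(a1$events)] <- 0; a0$events[is.na(a0$events)] <- 0
  a1$py[is.na(a1$py)] <- 0; a0$py[is.na(a0$py)] <- 0
  drop <- a1$py == 0 | a0$py == 0
  if (any(drop)) {
    warning("dropping stratum with zero person-time in one arm: ",
            paste(a1$stratum[drop], collapse = ", "))
    a1 <- a1[!drop, ]; a0 <- a0[!drop, ]
  }
  w <- a1$py * a0$py / (a1$py + a0$py)
  r1 <- a1$events / a1$py
  r0 <- a0$events / a0$py
  rate <- function(r) sum(w * r) / sum(w)
  var_rate <- function(ev, pyr) sum(w^2 * ev / pyr^2) / sum(w)^2
  R1 <- rate(r1); R0 <- rate(r0)
  v1 <- var_rate(a1$events, a1$py); v0 <- var_rate(a0$events, a0$py)
  se_log1 <- sqrt(v1) / R1
  se_log0 <- sqrt(v0) / R0
  rd <- R1 - R0
  z <- rd / sqrt(v1 + v0)
  out <- list(
    rates = data.frame(
      arm = c("fibrate", "statin"),
      rate = scale * c(R1, R0),
      lower95 = scale * c(R1 * exp(-1.96 * se_log1), R0 * exp(-1.96 * se_log0)),
      upper95 = scale * c(R1 * exp(1.96 * se_log1), R0 * exp(1.96 * se_log0))),
    strata = data.frame(stratum = a1$stratum, weight = w,
                        events_fibrate = a1$events, py_fibrate = a1$py,
                        events_statin = a0$events, py_statin = a0$py),
    rate_difference = scale * rd,
    p_value = 2 * stats::pnorm(-abs(z)),
    scale = scale, annualization = annualization)
  class(out) <- "mh_rates"
  out
}

#' @export
print.mh_rates <- function(x, ...) {
  cat("Mantel-Haenszel age/sex-adjusted event rates (per", x$scale,
      "person-years)\n")
  print(round_df(x$rates, 2))
  cat("Rate difference:", round(x$rate_difference, 3),
      " p =", format.pval(x$p_value, digits = 3), "\n")
  invisible(x)
}

#' Univariate covariate screening for the final model
#'
#' Each candidate covariate is tested in a Cox model containing age
#' (continuous), sex and the candidate; candidates with a significant hazard
#' ratio (p < `alpha`) that are free of missing data and on the configured
#' clinically-eligible allow-list are selected for the fully adjusted model.
#' The report covers every candidate (a Table-2-style listing).
#'
#' @param rows analysis table.
#' @param candidates covariate names to screen.
#' @param alpha significance threshold (0.05).
#' @param allow_list clinically justifiable covariates (clinical judgment is
#'   not computable, so this is a configured list; the default mirrors the
#'   covariates retained in the published final model).
#' @return screening report data frame with attribute `selected`.
#' @export
screen_covariates <- function(rows,
                              candidates = c("dep_quintile", "dm_duration",
                                             "metformin", "sulfa", "glitazone",
                                             "oad_other", "insulin",
                                             "alzheimer", "cancer", "depression",
                                             "parkinson", "betablocker", "arb",
                                             "acei", "diuretic", "ccb",
                                             "antihtn_other", "aspirin",
                                             "clopidogrel", "hosp_any"),
                              alpha = 0.05,
                              allow_list = c("insulin", "clopidogrel",
                                             "alzheimer", "cancer",
                                             "depression", "parkinson",
                                             "hosp_any", "metformin", "sulfa",
                                             "glitazone", "oad_other",
                                             "betablocker", "arb", "acei",
                                             "diuretic", "ccb",
                                             "antihtn_other", "aspirin")) {
  rep_rows <- list()
  selected <- character(0)
  for (cand in candidates) {
    v <- rows[[cand]]
    complete <- !anyNA(v) && !any(v == "unknown")
    term <- if (is.character(v) || is.factor(v)) paste0("factor(", cand, ")") else cand
    res <- tryCatch({
      d <- rows[!is.na(v), , drop = FALSE]
      fit <- cox_fit(d, c("age", "male", term))
      i <- grep(cand, names(fit$coefficients), fixed = TRUE)
      data.frame(candidate = cand, level = names(fit$coefficients)[i],
                 HR = fit$hr[i], lower95 = fit$ci_lower[i],
                 upper95 = fit$ci_upper[i], p = fit$p[i],
                 stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(candidate = cand, level = cand, HR = NA_real_,
                 lower95 = NA_real_, upper95 = NA_real_, p = NA_real_,
                 stringsAsFactors = FALSE))
    screenable <- !all(is.na(res$p))
    sig <- screenable && any(res$p < alpha, na.rm = TRUE)
    res$complete <- complete
    res$selected <- sig && complete && cand %in% allow_list
    rep_rows[[cand]] <- res
    if (res$selected[1]) selected <- c(selected, cand)
  }
  out <- do.call(rbind, rep_rows)
  rownames(out) <- NULL
  attr(out, "selected") <- selected
  attr(out, "alpha") <- alpha
  out
}

#' Fit the three nested final Cox models
#'
#' All three models contain the treatment variable split at `cutoff_day`
#' (one coefficient, hence one hazard ratio, per period) while any other
#' covariate enters with a constant coefficient: (1) crude, (2) adjusted on
#' age and sex, (3) model 2 plus the screened covariates.
#'
#' @param rows analysis table.
#' @param cutoff_day change-point day(s) of the treatment effect.
#' @param selected covariates for the fully adjusted model (possibly empty,
#'   in which case model 3 equals model 2).
#' @param variable treatment indicator column.
#' @param ties passed to [cox_fit()].
#' @return named list of `cox_fit` objects: `crude`, `agesex`, `adjusted`.
#' @export
fit_final_models <- function(rows, cutoff_day, selected = character(0),
                             variable = "fibrate", ties = "efron") {
  cp <- expand_time_split(rows, variable, cutoff_day)
  xk <- paste0(variable, "_p", seq_len(length(cutoff_day) + 1L))
  sel_terms <- vapply(selected, function(s) {
    v <- rows[[s]]
    if (is.character(v) || is.factor(v)) paste0("factor(", s, ")") else s
  }, character(1))
  list(
    crude = cox_fit(cp, xk, ties = ties),
    agesex = cox_fit(cp, c(xk, "age", "male"), ties = ties),
    adjusted = cox_fit(cp, c(xk, "age", "male", sel_terms), ties = ties))
}

standardized_mean_diff <- function(v, g, w = NULL) {
  if (is.null(w)) w <- rep(1, length(v))
  wm <- function(x, wt) sum(wt * x) / sum(wt)
  wv <- function(x, wt) {
    mu <- wm(x, wt)
    sum(wt * (x - mu)^2) / sum(wt)
  }
  m1 <- wm(v[g == 1], w[g == 1]); m0 <- wm(v[g == 0], w[g == 0])
  s <- sqrt((wv(v[g == 1], w[g == 1]) + wv(v[g == 0], w[g == 0])) / 2)
  if (s == 0) return(0)
  (m1 - m0) / s
}

#' Inverse-probability-of-treatment-weighted Cox analysis
#'
#' Propensity-score sensitivity analysis: a logistic model of the treatment
#' arm on the covariates gives each subject's probability of the treatment
#' actually received; its inverse (optionally stabilised by the marginal arm
#' probability) is applied as a case weight in the (optionally time-split)
#' Cox model, with a robust sandwich variance. Covariate balance is
#' summarised by standardized mean differences before and after weighting.
#'
#' @param rows analysis table.
#' @param covariates propensity-model covariates (complete columns).
#' @param cutoff_day optional change point for a two-period weighted fit;
#'   `NULL` fits a single-period weighted model.
#' @param stabilized multiply weights by the marginal arm probability.
#' @param truncate_at optional quantile (e.g. 0.99) at which weights are
#'   symmetrically truncated.
#' @param variable treatment indicator column.
#' @return object of class `ipw_cox`: weighted `cox_fit`, propensity scores,
#'   weights, balance table, ids of subjects with extreme (< 0.01 or > 0.99)
#'   estimated probabilities.
#' @export
ipw_cox <- function(rows, covariates, cutoff_day = NULL, stabilized = TRUE,
                    truncate_at = NULL, variable = "fibrate") {
  if (length(covariates) && anyNA(rows[, covariates]))
    stop("ipw_cox: covariates must be complete")
  rhs <- if (length(covariates)) paste(covariates, collapse = "+") else "1"
  fml <- stats::as.formula(paste(variable, "~", rhs))
  ps_fit <- stats::glm(fml, data = rows, family = stats::binomial())
  ps <- stats::fitted(ps_fit)
  z <- rows[[variable]]
  p_received <- ifelse(z == 1, ps, 1 - ps)
  flagged <- rows$subject_id[ps < 0.01 | ps > 0.99]
  marg <- mean(z)
  w <- if (stabilized) ifelse(z == 1, marg, 1 - marg) / p_received
       else 1 / p_received
  if (!is.null(truncate_at)) {
    hi <- stats::quantile(w, truncate_at)
    lo <- stats::quantile(w, 1 - truncate_at)
    w <- pmin(pmax(w, lo), hi)
  }
  balance <- data.frame(
    covariate = covariates,
    smd_unweighted = vapply(covariates, function(s)
      standardized_mean_diff(as.numeric(rows[[s]]), z), numeric(1)),
    smd_weighted = vapply(covariates, function(s)
      standardized_mean_diff(as.numeric(rows[[s]]), z, w), numeric(1)),
    row.names = NULL)
  if (is.null(cutoff_day)) {
    fit <- cox_fit(rows, variable, weights = w, robust = TRUE)
  } else {
    rows$.w_ipw <- w
    cp <- expand_time_split(rows, variable, cutoff_day)
    xk <- paste0(variable, "_p", seq_len(length(cutoff_day) + 1L))
    fit <- cox_fit(cp, xk, weights = cp$.w_ipw, robust = TRUE)
  }
  structure(list(fit = fit, ps = ps, weights = w, balance = balance,
                 flagged = flagged, stabilized = stabilized),
            class = "ipw_cox")
}

#' @export
print.ipw_cox <- function(x, ...) {
  cat("IPW-weighted Cox model (", if (x$stabilized) "stabilized " else "",
      "weights, robust variance)\n", sep = "")
  print(x$fit)
  cat("max |SMD| after weighting:",
      round(max(abs(x$balance$smd_weighted)), 3), "\n")
  invisible(x)
}
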