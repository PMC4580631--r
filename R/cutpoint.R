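#' Candidate cut-off grid for the change-point search
#'
#' Candidates are placed at monthly marks (multiples of `month_days`) below
#' the maximum follow-up: every single mark for a 2-interval split, every
#' ordered pair of marks for a 3-interval split. Candidates are later flagged
#' infeasible when any interval holds fewer than `min_events_per_arm` events
#' in either arm, since such interval coefficients are unidentifiable or
#' wildly unstable.
#'
#' @param max_followup_day largest follow-up time in the cohort.
#' @param month_days length of a "month" in days (30 by default; calendar
#'   months are ill-defined relative to subject-level index dates).
#' @param n_intervals number of intervals (2 or 3).
#' @return list of strictly increasing integer cut-off vectors.
#' @export
build_grid <- function(max_followup_day, month_days = 30L, n_intervals = 2L) {
  if (max_followup_day <= 2L * month_days)
    stop("build_grid: follow-up window too short for a split")
  marks <- seq(month_days, max_followup_day - 1L, by = month_days)
  marks <- marks[marks < max_followup_day]
  if (n_intervals == 2L) return(lapply(marks, identity))
  if (n_intervals == 3L) {
    out <- list()
    for (i in seq_along(marks)) for (j in seq_along(marks)) if (j > i)
      out[[length(out) + 1L]] <- c(marks[i], marks[j])
    return(out)
  }
  stop("n_intervals must be 2 or 3")
}

candidate_label <- function(cutoffs) paste(cutoffs, collapse = "+")

# With-replacement resample preserving the exact per-arm sample sizes
# (hence the fibrate/statin proportion) of the original cohort.
stratified_resample <- function(i1, i0) {
  c(i1[sample.int(length(i1), length(i1), replace = TRUE)],
    i0[sample.int(length(i0), length(i0), replace = TRUE)])
}

# Observed profile over candidates given a risk table; feasibility screen on
# per-interval per-arm event counts from the original data.
profile_from_rt <- function(rt, candidates, min_events_per_arm = 5L) {
  res <- lapply(candidates, function(cut) {
    f <- split_arm_fit(rt, cut)
    feasible <- all(f$events_arm1 >= min_events_per_arm) &&
      all(f$events_arm0 >= min_events_per_arm)
    list(cutoffs = cut, loglik = if (feasible) f$loglik else NA_real_,
         beta = f$beta, feasible = feasible,
         reason = if (feasible) "" else "too few events in an interval/arm")
  })
  res
}

#' Profile log-likelihood over candidate cut-off times
#'
#' For each feasible candidate, splits the treatment variable at the
#' candidate's cut-offs, fits the univariate Cox model with one coefficient
#' per interval (Breslow partial likelihood) and records the maximised log
#' partial likelihood. The best cut-off corresponds to the maximum.
#'
#' @param rows analysis table with `time`, `event` and a 0/1 `fibrate`
#'   column (or another treatment indicator named by `variable`).
#' @param candidates list of cut-off vectors from [build_grid()].
#' @param variable name of the treatment indicator column.
#' @param min_events_per_arm feasibility screen threshold.
#' @return data frame: candidate label, cut-offs (list column), log
#'   partial likelihood, interval coefficients (list column), feasibility.
#' @export
profile_likelihood <- function(rows, candidates, variable = "fibrate",
                               min_events_per_arm = 5L) {
  x <- rows[[variable]]
  if (is.null(x)) stop("profile_likelihood: no column '", variable, "'")
  rt <- risk_table(rows$time, rows$event, x)
  res <- profile_from_rt(rt, candidates, min_events_per_arm)
  if (all(!vapply(res, `[[`, logical(1), "feasible")))
    stop("profile_likelihood: all candidates infeasible")
  data.frame(
    candidate = vapply(res, function(r) candidate_label(r$cutoffs), character(1)),
    cutoff1 = vapply(res, function(r) r$cutoffs[1], numeric(1)),
    cutoff2 = vapply(res, function(r)
      if (length(r$cutoffs) > 1) r$cutoffs[2] else NA_real_, numeric(1)),
    loglik = vapply(res, `[[`, numeric(1), "loglik"),
    feasible = vapply(res, `[[`, logical(1), "feasible"),
    stringsAsFactors = FALSE)
}

# Per-interval proportional-hazards verdicts for one candidate on the
# original data: within each interval, fit the treatment-only Cox model on
# the counting-process rows of that interval and run the Schoenfeld score
# test against time.
interval_ph_verdicts <- function(rows, cutoffs, variable = "fibrate",
                                 alpha = 0.05) {
  cp <- expand_time_split(rows, variable, cutoffs)
  b <- c(0, cutoffs, Inf)
  K <- length(b) - 1L
  out <- data.frame(interval = seq_len(K), p = NA_real_,
                    verdict = NA_character_, stringsAsFactors = FALSE)
  for (k in seq_len(K)) {
    d <- cp[cp$interval == k, , drop = FALSE]
    p <- tryCatch({
      fit <- survival::coxph(
        stats::as.formula(paste("survival::Surv(start, stop, event) ~", variable)),
        data = d, ties = "breslow")
      survival::cox.zph(fit, transform = "identity")$table[variable, "p"]
    }, error = function(e) NA_real_)
    out$p[k] <- p
    out$verdict[k] <- if (is.na(p)) "untestable" else if (p < alpha) "violated" else "ok"
  }
  out
}

#' Select the change point by bootstrap-maximised median likelihood
#'
#' Implements the cut-off selection procedure: `B` resamples are drawn with
#' replacement, stratified by arm so that every resample has the same sample
#' size and the same fibrate/statin proportion as the original cohort. For
#' every resample and every feasible candidate cut-off, the univariate
#' time-split Cox log partial likelihood is recorded; the selected cut-off
#' maximises the median of the `B` likelihoods among candidates whose split
#' satisfies the proportional-hazards assumption within each interval on the
#' original data. When no 2-interval candidate passes, the search widens to
#' 3-interval candidates; when none passes at all, the best-by-median
#' candidate is returned with verdict `"no PH-satisfying candidate"`.
#'
#' @inheritParams profile_likelihood
#' @param B number of bootstrap resamples (500 by default).
#' @param seed integer seed; the full result is reproducible bit-for-bit.
#' @param month_days monthly grid step in days.
#' @param identity_resample if `TRUE`, every "resample" is the original
#'   cohort (degenerate bootstrap, used to check that selection then equals
#'   the observed-likelihood argmax).
#' @param ph_check re-check proportional hazards per interval on the
#'   original data and restrict selection to passing candidates.
#' @param try_three_intervals widen to 3-interval candidates when no
#'   2-interval candidate passes the PH screen.
#' @param min_events_per_arm feasibility screen threshold.
#' @param alpha significance level of the per-interval PH verdicts.
#' @return object of class `cutoff_search`: candidate table (observed and
#'   median bootstrap log-likelihoods), bootstrap matrix, selected cut-offs,
#'   PH verdicts for the selected candidate, `B`, `seed`, status.
#' @export
bootstrap_select <- function(rows, B = 500L, seed = 1L, month_days = 30L,
                             variable = "fibrate",
                             identity_resample = FALSE, ph_check = TRUE,
                             try_three_intervals = TRUE,
                             min_events_per_arm = 5L, alpha = 0.05) {
  stopifnot(B >= 1L)
  set.seed(seed)
  x <- rows[[variable]]
  time <- as.integer(rows$time)
  event <- as.integer(rows$event)
  maxf <- max(time)

  run_level <- function(candidates) {
    rt0 <- risk_table(time, event, x)
    prof <- profile_from_rt(rt0, candidates, min_events_per_arm)
    feas <- vapply(prof, `[[`, logical(1), "feasible")
    if (!any(feas)) return(NULL)
    i1 <- which(x == 1L); i0 <- which(x == 0L)
    n1 <- length(i1); n0 <- length(i0)
    boot <- matrix(NA_real_, nrow = B, ncol = length(candidates))
    for (b in seq_len(B)) {
      if (identity_resample) {
        rtb <- rt0
      } else {
        idx <- stratified_resample(i1, i0)
        rtb <- risk_table(time[idx], event[idx], x[idx])
      }
      for (j in which(feas))
        boot[b, j] <- split_arm_fit(rtb, prof[[j]]$cutoffs)$loglik
    }
    med <- apply(boot, 2, stats::median)
    list(prof = prof, feas = feas, boot = boot, median = med)
  }

  select_from <- function(lvl, candidates) {
    ord <- order(-lvl$median,
                 vapply(candidates, `[[`, numeric(1), 1))  # ties -> earliest
    ord <- ord[lvl$feas[ord]]
    ph_sel <- NULL
    chosen <- NA_integer_
    status <- "ok"
    if (ph_check) {
      for (j in ord) {
        ph <- interval_ph_verdicts(rows, candidates[[j]], variable, alpha)
        if (all(ph$verdict == "ok")) { chosen <- j; ph_sel <- ph; break }
      }
      if (is.na(chosen)) status <- "no PH-satisfying candidate"
    }
    if (is.na(chosen)) {
      chosen <- ord[1]
      if (is.null(ph_sel))
        ph_sel <- interval_ph_verdicts(rows, candidates[[chosen]], variable, alpha)
    }
    list(chosen = chosen, ph = ph_sel, status = status)
  }

  candidates <- build_grid(maxf, month_days, n_intervals = 2L)
  lvl <- run_level(candidates)
  if (is.null(lvl)) stop("bootstrap_select: all 2-interval candidates infeasible")
  sel <- select_from(lvl, candidates)

  if (sel$status == "no PH-satisfying candidate" && try_three_intervals &&
      maxf > 3L * month_days) {
    cand3 <- build_grid(maxf, month_days, n_intervals = 3L)
    lvl3 <- run_level(cand3)
    if (!is.null(lvl3)) {
      sel3 <- select_from(lvl3, cand3)
      if (sel3$status == "ok") {
        candidates <- cand3; lvl <- lvl3; sel <- sel3
      }
    }
  }

  tab <- data.frame(
    candidate = vapply(candidates, candidate_label, character(1)),
    loglik_observed = vapply(lvl$prof, `[[`, numeric(1), "loglik"),
    loglik_boot_median = lvl$median,
    feasible = lvl$feas,
    stringsAsFactors = FALSE)
  structure(list(
    candidates = candidates,
    table = tab,
    boot_loglik = lvl$boot,
    selected = candidates[[sel$chosen]],
    selected_index = sel$chosen,
    ph_verdicts = sel$ph,
    status = sel$status,
    B = B, seed = seed, month_days = month_days
  ), class = "cutoff_search")
}

#' @export
print.cutoff_search <- function(x, ...) {
  cat("Change-point search over", length(x$candidates), "candidates,",
      "B =", x$B, "stratified bootstrap resamples\n")
  cat("Selected cut-off:", candidate_label(x$selected), "days",
      if (x$status != "ok") paste0("(", x$status, ")"), "\n")
  invisible(x)
}

#' Two-period Cox model with a bootstrap-selected change point
#'
#' The package's headline estimator. Given an analysis cohort (one row per
#' subject with arm, follow-up and baseline covariates), it (1) selects the
#' hazard-ratio change point of the treatment variable by the
#' bootstrap-median profile-likelihood search ([bootstrap_select()]), then
#' (2) fits the three nested Cox models of the primary analysis — crude,
#' age/sex-adjusted and fully adjusted — in which the treatment variable is
#' split at the selected cut-off (one hazard ratio per period) while every
#' other covariate keeps a constant coefficient.
#'
#' @param data analysis table (from [build_cohort()] or
#'   [simulate_cohort()]).
#' @param covariates character vector of adjustment covariates for the full
#'   model (columns of `data`); `NULL` selects them by univariate screening
#'   through [screen_covariates()].
#' @param cutoff_day fix the change point instead of searching.
#' @param B,seed,month_days passed to [bootstrap_select()].
#' @param variable treatment indicator column.
#' @param ... further arguments to [bootstrap_select()].
#' @return object of class `cutpoint_cox` with components `cutoff`,
#'   `search` (a `cutoff_search`, when run), `models` (named list of
#'   `cox_fit`: crude, agesex, adjusted), `screen` (when screening ran),
#'   `n`, `n_events`, `call`. Methods: `print`, `summary`, `coef`,
#'   `logLik`, `plot`, `predict`, `residuals`.
#' @export
cutpoint_cox <- function(data, covariates = NULL, cutoff_day = NULL,
                         B = 500L, seed = 1L, month_days = 30L,
                         variable = "fibrate", ...) {
  cl <- match.call()
  search <- NULL
  if (is.null(cutoff_day)) {
    search <- bootstrap_select(data, B = B, seed = seed,
                               month_days = month_days, variable = variable, ...)
    cutoff_day <- search$selected
  }
  screen <- NULL
  if (is.null(covariates)) {
    screen <- screen_covariates(data)
    covariates <- attr(screen, "selected")
  }
  models <- fit_final_models(data, cutoff_day, covariates, variable = variable)
  structure(list(
    cutoff = cutoff_day,
    search = search,
    models = models,
    screen = screen,
    covariates = covariates,
    variable = variable,
    n = nrow(data),
    n_events = sum(data$event),
    call = cl
  ), class = "cutpoint_cox")
}

period_hr_table <- function(fit, variable, cutoffs) {
  nm <- paste0(variable, "_p", seq_len(length(cutoffs) + 1L))
  i <- match(nm, names(fit$coefficients))
  b <- c(0, cutoffs, Inf)
  data.frame(period = sprintf("(%s, %s] days", b[-length(b)], b[-1]),
             HR = fit$hr[i], lower95 = fit$ci_lower[i],
             upper95 = fit$ci_upper[i], p = fit$p[i],
             row.names = NULL)
}

#' @export
print.cutpoint_cox <- function(x, ...) {
  cat("Two-period Cox model, change point at",
      candidate_label(x$cutoff), "days",
      if (!is.null(x$search)) sprintf("(selected from %d candidates, B = %d)",
                                      length(x$search$candidates), x$search$B),
      "\n")
  cat(x$n, "subjects,", x$n_events, "events\n\n")
  cat("Fully adjusted treatment hazard ratios:\n")
  print(round_df(period_hr_table(x$models$adjusted, x$variable, x$cutoff), 3))
  invisible(x)
}

round_df <- function(d, k) {
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], round, k)
  d
}

#' @export
summary.cutpoint_cox <- function(object, ...) {
  out <- list(cutoff = object$cutoff,
              status = if (is.null(object$search)) "fixed" else object$search$status,
              periods = lapply(object$models, period_hr_table,
                               variable = object$variable, cutoffs = object$cutoff),
              models = object$models,
              covariates = object$covariates)
  class(out) <- "summary.cutpoint_cox"
  out
}

#' @export
print.summary.cutpoint_cox <- function(x, ...) {
  cat("Change point:", candidate_label(x$cutoff), "days [", x$status, "]\n")
  for (nm in names(x$periods)) {
    cat("\n--", nm, "model (loglik",
        format(x$models[[nm]]$loglik, digits = 8), ")\n")
    print(round_df(x$periods[[nm]], 3))
  }
  if (length(x$covariates))
    cat("\nAdjustment covariates:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.cutpoint_cox <- function(object, model = "adjusted", ...)
  object$models[[model]]$coefficients

#' @export
logLik.cutpoint_cox <- function(object, model = "adjusted", ...)
  logLik(object$models[[model]])

#' @export
predict.cutpoint_cox <- function(object, model = "adjusted", ...)
  stats::predict(object$models[[model]]$model, ...)

#' @export
residuals.cutpoint_cox <- function(object, model = "adjusted",
                                   type = "martingale", ...)
  stats::residuals(object$models[[model]]$model, type = type, ...)

#' Plot method: bootstrap-median likelihood profile
#'
#' Mirrors the likelihood-profile figure of the selection procedure: the
#' median bootstrap log partial likelihood (and the observed profile) against
#' the candidate cut-off day, with the selected change point marked.
#'
#' @param x a `cutpoint_cox` object fitted with a search.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cutpoint_cox <- function(x, ...) {
  if (is.null(x$search)) stop("no search to plot: cutoff was fixed")
  tab <- x$search$table
  tab <- tab[!grepl("+", tab$candidate, fixed = TRUE) & tab$feasible, ]
  day <- as.numeric(tab$candidate)
  graphics::plot(day, tab$loglik_boot_median, type = "b", pch = 16,
                 xlab = "candidate cut-off (days)",
                 ylab = "log partial likelihood",
                 main = "Bootstrap-median likelihood profile", ...)
  graphics::lines(day, tab$loglik_observed, lty = 2, col = "grey40")
  graphics::abline(v = x$cutoff[1], col = "red3", lty = 3)
  graphics::legend("bottomright", bty = "n", lty = c(1, 2, 3),
                   col = c("black", "grey40", "red3"), pch = c(16, NA, NA),
                   legend = c("bootstrap median", "observed", "selected"))
  invisible(x)
}
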