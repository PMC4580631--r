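#' Kaplan-Meier curves for the analysis cohort
#'
#' Product-limit estimator, optionally per level of a grouping covariate.
#' Simultaneous events at a day are handled as ties; at-risk counts
#' decrement by events plus censorings.
#'
#' @param rows analysis table with `time` and `event`.
#' @param group_by name of a grouping column, or `NULL` for one curve.
#' @return data frame of class `km_curve` with columns `group`, `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`.
#' @export
km_estimate <- function(rows, group_by = NULL) {
  if (is.null(rows) || nrow(rows) == 0) stop("km_estimate: empty input")
  if (any(rows$time <= 0)) stop("km_estimate: follow-up times must be positive")
  if (is.null(group_by)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = rows)
    groups <- rep("all", length(fit$time))
  } else {
    fit <- survival::survfit(
      stats::as.formula(paste0("survival::Surv(time, event) ~ ", group_by)),
      data = rows)
    groups <- if (is.null(fit$strata)) rep("all", length(fit$time))
      else rep(sub("^[^=]*=", "", names(fit$strata)), fit$strata)
  }
  out <- data.frame(group = groups, time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv, stringsAsFactors = FALSE)
  class(out) <- c("km_curve", class(out))
  out
}

#' Fit a Cox proportional hazards model on counting-process rows
#'
#' Thin, contract-enforcing wrapper around [survival::coxph()]. Accepts
#' either single-record rows (`time`, `event`) or counting-process rows
#' (`start`, `stop`, `event`); maximises the Efron (default) or Breslow
#' partial likelihood by Newton-Raphson with step-halving; standard errors
#' come from the inverse observed information.
#'
#' @param data analysis or counting-process data frame.
#' @param covariates character vector of model terms (columns of `data`).
#' @param ties `"efron"` or `"breslow"`.
#' @param weights optional case weights.
#' @param robust request the robust sandwich variance (required with
#'   non-uniform weights).
#' @param tol convergence tolerance on the log-likelihood change.
#' @param max_iter maximum Newton iterations.
#' @return object of class `cox_fit`: coefficients, SEs, hazard ratios with
#'   95\% CIs, log partial likelihoods (null and at the optimum), number of
#'   events, iteration count, convergence flag, ties method and the
#'   underlying `coxph` fit.
#' @export
cox_fit <- function(data, covariates, ties = c("efron", "breslow"),
                    weights = NULL, robust = FALSE,
                    tol = 1e-9, max_iter = 100L) {
  ties <- match.arg(ties)
  if (!length(covariates)) stop("cox_fit: at least one covariate is required")
  cp <- all(c("start", "stop") %in% names(data))
  if (sum(data$event) < 1) stop("cox_fit: at least one event is required")
  mm <- stats::model.matrix(
    stats::as.formula(paste("~", paste(covariates, collapse = "+"))), data)
  const <- colnames(mm)[-1][apply(mm[, -1, drop = FALSE], 2,
                                  function(z) length(unique(z)) == 1L)]
  if (length(const))
    stop("cox_fit: constant covariate(s): ", paste(const, collapse = ", "))
  lhs <- if (cp) "survival::Surv(start, stop, event)"
         else "survival::Surv(time, event)"
  rhs <- paste(covariates, collapse = "+")
  dat <- data
  dat$.w <- if (is.null(weights)) rep(1, nrow(data)) else weights
  if (robust) {
    # sandwich variance clustered on subject (rows of one subject are not
    # independent in counting-process form)
    if (!"subject_id" %in% names(dat)) dat$subject_id <- seq_len(nrow(dat))
    rhs <- paste(rhs, "+ cluster(subject_id)")
  }
  fml <- stats::as.formula(paste(lhs, "~", rhs))
  fit <- survival::coxph(fml, data = dat, weights = .w, ties = ties,
                         robust = robust,
                         control = survival::coxph.control(eps = tol,
                                                           iter.max = max_iter))
  beta <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  converged <- is.null(fit$info) && fit$iter < max_iter &&
    all(is.finite(beta)) && all(abs(beta) < 15)
  structure(list(
    coefficients = beta,
    se = se,
    hr = exp(beta),
    ci_lower = exp(beta - 1.96 * se),
    ci_upper = exp(beta + 1.96 * se),
    p = 2 * stats::pnorm(-abs(beta / se)),
    loglik = fit$loglik[2],
    loglik_null = fit$loglik[1],
    n = fit$n,
    n_events = fit$nevent,
    iter = fit$iter,
    converged = converged,
    ties = ties,
    model = fit
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox model (", x$ties, " ties), ", x$n_events, " events, loglik ",
      format(x$loglik, digits = 8),
      if (!x$converged) "  [NOT CONVERGED]" else "", "\n", sep = "")
  tab <- data.frame(coef = x$coefficients, HR = x$hr,
                    lower95 = x$ci_lower, upper95 = x$ci_upper, p = x$p)
  print(round(tab, 4))
  invisible(x)
}

#' @export
coef.cox_fit <- function(object, ...) object$coefficients

#' @export
logLik.cox_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients), class = "logLik")
}

#' Expand an analysis table into time-split counting-process rows
#'
#' Decomposes a covariate X into interval-specific copies
#' X_k(t) = X for t in P_k and 0 elsewhere, where the intervals P_k partition
#' follow-up at the given cut-off days. Each subject contributes one
#' left-open/right-closed row `(start, stop]` per interval overlapped by
#' their follow-up; the event sits on the final row; all other columns are
#' copied unchanged. Total person-time and events are conserved exactly.
#'
#' @param rows analysis table with `time`, `event` and the split variable.
#' @param variable name of the (numeric) column to split.
#' @param cutoffs strictly increasing cut-off days, each inside
#'   `(0, max(time))`.
#' @return counting-process data frame with `start`, `stop`, `event`,
#'   `interval` and columns `<variable>_p1 ... <variable>_pK`.
#' @export
expand_time_split <- function(rows, variable, cutoffs) {
  if (!variable %in% names(rows)) stop("unknown variable: ", variable)
  if (!is.numeric(rows[[variable]]))
    stop("split variable must be numeric (an indicator)")
  cutoffs <- as.numeric(cutoffs)
  if (length(cutoffs) == 0) stop("at least one cutoff is required")
  if (is.unsorted(cutoffs, strictly = TRUE)) stop("cutoffs must be strictly increasing")
  if (any(cutoffs <= 0)) stop("cutoffs must be positive")
  if (any(cutoffs >= max(rows$time)))
    stop("cutoff at or beyond the maximum follow-up")
  if (!"subject_id" %in% names(rows)) rows$subject_id <- seq_len(nrow(rows))
  b <- c(0, cutoffs, Inf)
  K <- length(b) - 1L
  pieces <- vector("list", K)
  for (k in seq_len(K)) {
    sel <- rows$time > b[k]
    d <- rows[sel, , drop = FALSE]
    d$start <- b[k]
    d$stop <- pmin(d$time, b[k + 1])
    last <- d$stop == d$time
    d$event <- ifelse(last, d$event, 0L)
    d$interval <- k
    pieces[[k]] <- d
  }
  out <- do.call(rbind, pieces)
  out <- out[order(out$subject_id, out$start), , drop = FALSE]
  x <- out[[variable]]
  for (k in seq_len(K))
    out[[paste0(variable, "_p", k)]] <- x * (out$interval == k)
  rownames(out) <- NULL
  out
}

#' Quantitative proportional-hazards diagnostic
#'
#' Score test on the scaled Schoenfeld residuals against follow-up time
#' (identity transform), one test per covariate plus a global test; the
#' verdict is "violated" at p < 0.05. This is the quantitative surrogate for
#' the usual graphical assessment by survival curves, which remains
#' available through [km_estimate()].
#'
#' @param fit a `cox_fit` object.
#' @param transform time transform passed to [survival::cox.zph()].
#' @param alpha significance level for the verdict.
#' @return data frame of class `ph_diagnostic`: covariate, chisq, df,
#'   p-value, verdict.
#' @export
ph_diagnostic <- function(fit, transform = "identity", alpha = 0.05) {
  stopifnot(inherits(fit, "cox_fit"))
  if (fit$n_events < 2) stop("ph_diagnostic: fewer than 2 events, undefined")
  if (!fit$converged) warning("ph_diagnostic on a non-converged fit")
  z <- survival::cox.zph(fit$model, transform = transform)
  tab <- as.data.frame(z$table)
  out <- data.frame(covariate = rownames(tab), chisq = tab$chisq,
                    df = tab$df, p = tab$p,
                    verdict = ifelse(tab$p < alpha, "violated", "ok"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("ph_diagnostic", class(out))
  out
}
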