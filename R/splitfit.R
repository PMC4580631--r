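# Specialised partial-likelihood machinery for the cut-off search.
#
# The search fits, for every candidate cut-off vector and every bootstrap
# resample, a Cox model containing only the interval-specific copies of one
# binary covariate (the treatment arm). For that special case the Breslow
# partial likelihood factorises over event days,
#   l(beta) = sum_d [ e1(d) beta(d) - m(d) log(r0(d) + r1(d) exp(beta(d))) ],
# where r0/r1 are the at-risk counts per arm, e0/e1 the event counts per arm,
# m = e0 + e1, and beta(d) is the coefficient of the interval containing d.
# Because every subject enters at time 0, the risk sets depend only on the
# follow-up times, so the whole likelihood is a function of a small per-day
# aggregate ("risk table") that is computed once per (re)sample and shared by
# all candidates. Each interval coefficient then solves an independent
# one-dimensional concave maximisation (Newton with step-halving).

# Per-event-day aggregate: day, at-risk and event counts per arm.
risk_table <- function(time, event, x) {
  time <- as.integer(time)
  maxt <- max(time)
  t1 <- time[x == 1L]; t0 <- time[x == 0L]
  cnt1 <- tabulate(t1, nbins = maxt)
  cnt0 <- tabulate(t0, nbins = maxt)
  ed <- which(tabulate(time[event == 1L], nbins = maxt) > 0L)
  e1 <- tabulate(time[event == 1L & x == 1L], nbins = maxt)[ed]
  e0 <- tabulate(time[event == 1L & x == 0L], nbins = maxt)[ed]
  # number at risk at day d = count with time >= d (everyone enters at 0)
  r1 <- (length(t1) - cumsum(cnt1) + cnt1)[ed]
  r0 <- (length(t0) - cumsum(cnt0) + cnt0)[ed]
  list(day = ed, r0 = r0, r1 = r1, e0 = e0, e1 = e1)
}

# Maximise the one-interval Breslow log partial likelihood over the scalar
# coefficient. rt fields must already be restricted to the interval's days.
fit_one_interval <- function(rt, tol = 1e-10, max_iter = 50L) {
  m <- rt$e0 + rt$e1
  E1 <- sum(rt$e1)
  ll <- function(b) {
    eb <- exp(b)
    sum(rt$e1) * b - sum(m * log(rt$r0 + rt$r1 * eb))
  }
  if (length(rt$day) == 0)
    return(list(beta = 0, loglik = 0, converged = TRUE, n_events = 0L))
  b <- 0
  l <- ll(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eb <- exp(b)
    denom <- rt$r0 + rt$r1 * eb
    g <- E1 - sum(m * rt$r1 * eb / denom)
    h <- -sum(m * rt$r0 * rt$r1 * eb / denom^2)
    if (abs(h) < 1e-300) break
    step <- -g / h
    b_new <- b + step
    l_new <- ll(b_new)
    halvings <- 0L
    while ((!is.finite(l_new) || l_new < l) && halvings < 30L) {
      step <- step / 2
      b_new <- b + step
      l_new <- ll(b_new)
      halvings <- halvings + 1L
    }
    if (is.finite(l_new) && abs(l_new - l) < tol) {
      b <- b_new; l <- l_new; converged <- TRUE; break
    }
    b <- b_new; l <- l_new
    if (abs(b) > 15) break  # monotone likelihood
  }
  list(beta = b, loglik = l, converged = converged && abs(b) <= 15,
       n_events = sum(m))
}

# Fit the univariate time-split model for one candidate cut-off vector,
# reusing a precomputed risk table. cutoffs = NULL fits the unsplit model.
split_arm_fit <- function(rt, cutoffs = NULL) {
  b <- c(0, cutoffs, Inf)
  K <- length(b) - 1L
  beta <- numeric(K); ll <- 0; conv <- TRUE
  ev1 <- integer(K); ev0 <- integer(K)
  for (k in seq_len(K)) {
    sel <- rt$day > b[k] & rt$day <= b[k + 1]
    sub <- list(day = rt$day[sel], r0 = rt$r0[sel], r1 = rt$r1[sel],
                e0 = rt$e0[sel], e1 = rt$e1[sel])
    f <- fit_one_interval(sub)
    beta[k] <- f$beta
    ll <- ll + f$loglik
    conv <- conv && f$converged
    ev1[k] <- sum(sub$e1); ev0[k] <- sum(sub$e0)
  }
  list(beta = beta, loglik = ll, converged = conv,
       events_arm1 = ev1, events_arm0 = ev0)
}

# Breslow log partial likelihood at fixed coefficients (used by tests).
split_arm_loglik <- function(rt, cutoffs, beta) {
  b <- c(0, cutoffs, Inf)
  idx <- findInterval(rt$day, b, left.open = TRUE)
  bd <- beta[idx]
  sum(rt$e1 * bd - (rt$e0 + rt$e1) * log(rt$r0 + rt$r1 * exp(bd)))
}
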