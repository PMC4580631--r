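#' Eligibility criteria for the new-user cohort
#'
#' Parameter object for the cohort construction rules: a 913-day (30-month)
#' lipid-lowering washout, two consecutive same-class GP-prescribed
#' reimbursements to define initiation, at least three oral-antidiabetic and
#' three antihypertensive reimbursements within some 365-day span of the
#' washout (treated diabetes and hypertension), age over 50 (men) / 60
#' (women), and no cardiovascular hospitalisation during the washout.
#'
#' @param washout_days lipid-lowering-free lookback before index (days).
#' @param index_window first and last admissible index day.
#' @param min_consecutive_reimbursements reimbursements defining initiation.
#' @param max_refill_gap_days maximum spacing between the consecutive
#'   reimbursements (the dispensing interval); the definition of
#'   "consecutive" requires a bound, 120 days by default.
#' @param min_disease_reimbursements count defining a treated disease.
#' @param disease_window_days rolling window (days) for that count.
#' @param min_age_male,min_age_female inclusive age thresholds at entry.
#' @param require_gp_prescriber must the index prescription come from a GP?
#' @param extract_start earliest day covered by the claims extract; the
#'   diabetes-duration band is "unknown" when the first oral-antidiabetic
#'   record is left-truncated at this horizon.
#' @return an object of class `coxcpt_criteria`.
#' @export
eligibility_criteria <- function(washout_days = 913L,
                                 index_window = c(0L, 549L),
                                 min_consecutive_reimbursements = 2L,
                                 max_refill_gap_days = 120L,
                                 min_disease_reimbursements = 3L,
                                 disease_window_days = 365L,
                                 min_age_male = 50L,
                                 min_age_female = 60L,
                                 require_gp_prescriber = TRUE,
                                 extract_start = -913L) {
  cr <- list(washout_days = as.integer(washout_days),
             index_window = as.integer(index_window),
             min_consecutive_reimbursements = as.integer(min_consecutive_reimbursements),
             max_refill_gap_days = as.integer(max_refill_gap_days),
             min_disease_reimbursements = as.integer(min_disease_reimbursements),
             disease_window_days = as.integer(disease_window_days),
             min_age_male = as.integer(min_age_male),
             min_age_female = as.integer(min_age_female),
             require_gp_prescriber = isTRUE(require_gp_prescriber),
             extract_start = as.integer(extract_start))
  stopifnot(cr$min_consecutive_reimbursements >= 1L,
            cr$min_disease_reimbursements >= 1L,
            cr$washout_days >= cr$disease_window_days)
  class(cr) <- "coxcpt_criteria"
  cr
}

lipid_classes <- c("statin", "fibrate")

is_oad_class <- function(x) startsWith(x, "oad_")
is_antihtn_class <- function(x) startsWith(x, "antihypertensive_")
is_cv_event_class <- function(x) startsWith(x, "cv_event_")

#' Identify monotherapy initiators
#'
#' Finds, per subject, the first run of at least two reimbursements of the
#' same lipid-lowering class (statin or fibrate), prescribed by a GP, inside
#' the index window, with no lipid-lowering reimbursement of either class in
#' the washout before that day. Subjects whose initiation mixes the two
#' classes (simultaneous or interleaved reimbursements) are not monotherapy
#' initiators and are dropped.
#'
#' @param claims claims table (see [generate_claims()] for the layout).
#' @param criteria an [eligibility_criteria()] object.
#' @return data frame with columns `subject_id`, `arm`, `index_day`; empty
#'   when no subject qualifies.
#' @export
identify_initiators <- function(claims, criteria = eligibility_criteria()) {
  lip <- claims[claims$record_type == "drug" &
                claims$code_class %in% lipid_classes, , drop = FALSE]
  if (nrow(lip) == 0)
    return(data.frame(subject_id = integer(0), arm = character(0),
                      index_day = integer(0)))
  lip <- lip[order(lip$subject_id, lip$day), , drop = FALSE]
  res <- lapply(split(lip, lip$subject_id), function(d) {
    d0 <- d$day[1]
    # washout: any earlier lipid record would itself be the first record,
    # so the first record day is the only possible new-user index
    if (d0 < criteria$index_window[1] || d0 > criteria$index_window[2])
      return(NULL)
    first_class <- d$code_class[1]
    if (any(d$day == d0 & d$code_class != first_class)) return(NULL) # combo at index
    if (criteria$require_gp_prescriber && d$prescriber[1] != "gp") return(NULL)
    k <- criteria$min_consecutive_reimbursements
    if (nrow(d) < k) return(NULL)
    run <- d[seq_len(k), , drop = FALSE]
    if (any(run$code_class != first_class)) return(NULL)  # other class intervenes
    if (any(diff(run$day) > criteria$max_refill_gap_days)) return(NULL)
    data.frame(subject_id = d$subject_id[1], arm = first_class,
               index_day = d0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(subject_id = integer(0), arm = character(0),
                      index_day = integer(0))
  rownames(out) <- NULL
  out
}

# at least k reimbursements of the class set within some rolling window of
# `window` days, all inside [index - washout, index)
has_rolling_count <- function(days, k, window) {
  days <- sort(unique(days))
  if (length(days) < k) return(FALSE)
  any(days[seq_len(length(days) - k + 1) + k - 1] -
        days[seq_len(length(days) - k + 1)] <= window - 1L)
}

#' Apply the inclusion and exclusion rules
#'
#' Retains initiators who, at index, are old enough (over 50 for men, 60 for
#' women), have treated type-2 diabetes and treated hypertension (at least
#' three reimbursements of the respective class within some 365-day span of
#' the washout) and no cardiovascular hospitalisation during the washout.
#' Rules are applied in that order and an attrition table (flow-chart counts)
#' is attached.
#'
#' @param candidates output of [identify_initiators()].
#' @param claims the claims table.
#' @param demographics demographics table (`subject_id`, `sex`, `birth_year`,
#'   `dep_quintile`).
#' @param criteria an [eligibility_criteria()] object.
#' @return data frame of included subjects (id, arm, index day, sex, age,
#'   deprivation quintile) with attribute `attrition`.
#' @export
apply_inclusion <- function(candidates, claims, demographics,
                            criteria = eligibility_criteria()) {
  if (nrow(candidates) == 0) {
    out <- cbind(candidates, sex = character(0), age = integer(0),
                 dep_quintile = integer(0))
    attr(out, "attrition") <- data.frame(rule = character(0), excluded = integer(0),
                                         remaining = integer(0))
    return(out)
  }
  miss <- setdiff(candidates$subject_id, demographics$subject_id)
  if (length(miss))
    stop("demographics missing for subject(s): ", paste(miss, collapse = ", "))
  dd <- demographics[match(candidates$subject_id, demographics$subject_id), ]
  x <- candidates
  x$sex <- dd$sex
  x$age <- 2008L - dd$birth_year
  x$dep_quintile <- dd$dep_quintile

  cl <- claims[claims$subject_id %in% x$subject_id, , drop = FALSE]
  cl_by <- split(cl, factor(cl$subject_id, levels = x$subject_id))

  attrition <- list()
  note <- function(rule, keep) {
    attrition[[length(attrition) + 1L]] <<- data.frame(
      rule = rule, excluded = sum(!keep), remaining = sum(keep))
    keep
  }

  keep <- ifelse(x$sex == "male", x$age >= criteria$min_age_male,
                 x$age >= criteria$min_age_female)
  x <- x[note("age_sex_threshold", keep), , drop = FALSE]

  check_disease <- function(pred) {
    vapply(seq_len(nrow(x)), function(i) {
      d <- cl_by[[as.character(x$subject_id[i])]]
      idx <- x$index_day[i]
      sel <- d$record_type == "drug" & pred(d$code_class) &
        d$day >= idx - criteria$washout_days & d$day < idx
      has_rolling_count(d$day[sel], criteria$min_disease_reimbursements,
                        criteria$disease_window_days)
    }, logical(1))
  }
  cl_by <- cl_by[as.character(x$subject_id)]
  x <- x[note("treated_diabetes", check_disease(is_oad_class)), , drop = FALSE]
  cl_by <- cl_by[as.character(x$subject_id)]
  x <- x[note("treated_hypertension", check_disease(is_antihtn_class)), , drop = FALSE]
  cl_by <- cl_by[as.character(x$subject_id)]

  keep <- vapply(seq_len(nrow(x)), function(i) {
    d <- cl_by[[as.character(x$subject_id[i])]]
    idx <- x$index_day[i]
    !any(d$record_type == "hospital" & is_cv_event_class(d$code_class) &
           d$day >= idx - criteria$washout_days & d$day < idx)
  }, logical(1))
  x <- x[note("no_prior_cv_event", keep), , drop = FALSE]

  rownames(x) <- NULL
  attr(x, "attrition") <- do.call(rbind, attrition)
  x
}

#' Derive baseline covariates from the claims history
#'
#' Each binary comedication/comorbidity covariate equals 1 iff at least three
#' reimbursements of its class occurred in the year before index
#' (`[index - 365, index)`); prior hospitalisation requires a single
#' `hospital_any` record in the same window; the diabetes-duration band is
#' mapped from the first-ever oral-antidiabetic record and set to "unknown"
#' when that record is left-truncated at the extract horizon.
#'
#' @param rows output of [apply_inclusion()].
#' @inheritParams apply_inclusion
#' @return `rows` completed with all covariate columns.
#' @export
derive_covariates <- function(rows, claims, demographics,
                              criteria = eligibility_criteria()) {
  class_map <- c(oad_metformin = "metformin", oad_sulfa = "sulfa",
                 oad_glitazone = "glitazone", oad_other = "oad_other",
                 insulin = "insulin",
                 antihypertensive_betablocker = "betablocker",
                 antihypertensive_arb = "arb", antihypertensive_acei = "acei",
                 antihypertensive_diuretic = "diuretic",
                 antihypertensive_ccb = "ccb",
                 antihypertensive_other = "antihtn_other",
                 aspirin = "aspirin", clopidogrel = "clopidogrel",
                 comorbidity_alzheimer = "alzheimer",
                 comorbidity_cancer = "cancer",
                 antidepressant = "depression",
                 comorbidity_parkinson = "parkinson")
  for (nm in unique(class_map)) rows[[nm]] <- 0L
  rows$hosp_any <- 0L
  rows$dm_duration <- "unknown"

  cl <- claims[claims$subject_id %in% rows$subject_id, , drop = FALSE]
  cl_by <- split(cl, factor(cl$subject_id, levels = rows$subject_id))
  for (i in seq_len(nrow(rows))) {
    d <- cl_by[[i]]
    idx <- rows$index_day[i]
    if (is.null(d) || nrow(d) == 0) next
    yr <- d[d$day >= idx - 365L & d$day < idx, , drop = FALSE]
    drug <- yr[yr$record_type == "drug", , drop = FALSE]
    counts <- table(drug$code_class)
    for (cc in names(counts)) {
      nm <- class_map[cc]
      if (!is.na(nm) && counts[[cc]] >= criteria$min_disease_reimbursements)
        rows[[nm]][i] <- 1L
    }
    if (any(yr$record_type == "hospital" & yr$code_class == "hospital_any"))
      rows$hosp_any[i] <- 1L
    oad_days <- d$day[d$record_type == "drug" &
                        (is_oad_class(d$code_class) | d$code_class == "insulin")]
    if (length(oad_days)) {
      first <- min(oad_days)
      dur <- idx - first
      rows$dm_duration[i] <-
        if (first <= criteria$extract_start) "unknown"
        else if (dur >= 3650) "10+"
        else if (dur >= 1825) "5-10"
        else if (dur >= 730) "2-5"
        else "<2"
    }
  }
  rows
}

#' Attach the composite outcome and follow-up
#'
#' The composite endpoint is the first occurrence of all-cause death,
#' ischemic stroke, myocardial infarction or above-the-ankle amputation
#' after index; follow-up runs to the first event or to the administrative
#' end of the study. A same-day event is given one day of risk time so every
#' subject contributes positive follow-up.
#'
#' @param rows covariate-complete rows from [derive_covariates()].
#' @param claims the claims table.
#' @param admin_end_day administrative end of follow-up (day offset).
#' @param include_amputation keep amputations in the composite? Setting
#'   `FALSE` recomputes the first occurrence over death/stroke/MI only.
#' @return `rows` with `time` (days), `event` (0/1) and `event_type`.
#' @export
derive_outcome <- function(rows, claims, admin_end_day = 913L,
                           include_amputation = TRUE) {
  types <- c(death = "death", cv_event_stroke = "stroke", cv_event_mi = "mi",
             cv_event_amputation = "amputation")
  if (!include_amputation) types <- types[names(types) != "cv_event_amputation"]
  ev <- claims[(claims$record_type == "death" & claims$code_class == "death") |
                 (claims$record_type == "hospital" &
                    claims$code_class %in% names(types)), , drop = FALSE]
  rows$time <- as.integer(admin_end_day - rows$index_day)
  rows$event <- 0L
  rows$event_type <- "none"
  if (nrow(ev)) {
    ev <- ev[order(ev$subject_id, ev$day), , drop = FALSE]
    ev_by <- split(ev, factor(ev$subject_id, levels = rows$subject_id))
    for (i in seq_len(nrow(rows))) {
      d <- ev_by[[i]]
      if (is.null(d) || nrow(d) == 0) next
      d <- d[d$day >= rows$index_day[i] & d$day <= admin_end_day, , drop = FALSE]
      if (nrow(d) == 0) next
      first <- d[1L, ]
      rows$event[i] <- 1L
      rows$event_type[i] <- unname(types[first$code_class])
      rows$time[i] <- max(1L, as.integer(first$day - rows$index_day[i]))
    }
  }
  rows
}

#' Apply a follow-up censoring rule
#'
#' `"itt"` leaves follow-up untouched (intention-to-treat). `"persistence"`
#' truncates follow-up at (last index-drug reimbursement + `gap_days`) when a
#' reimbursement-free gap of at least `gap_days` opens before the end of
#' follow-up, discarding any event past the truncation. `"switch"` truncates
#' `gap_days` after the first reimbursement of the other lipid-lowering
#' class, with the same convention.
#'
#' @param rows analysis rows with `time`/`event` (from [derive_outcome()]).
#' @param claims the claims table.
#' @param rule one of `"itt"`, `"persistence"`, `"switch"`.
#' @param gap_days the six-month gap, 183 days by default.
#' @return `rows` with possibly shortened `time` and zeroed `event`.
#' @export
apply_censoring <- function(rows, claims, rule = c("itt", "persistence", "switch"),
                            gap_days = 183L) {
  rule <- match.arg(rule)
  if (rule == "itt") return(rows)
  drug <- claims[claims$record_type == "drug" &
                   claims$code_class %in% lipid_classes &
                   claims$subject_id %in% rows$subject_id, , drop = FALSE]
  drug <- drug[order(drug$subject_id, drug$day), , drop = FALSE]
  by <- split(drug, factor(drug$subject_id, levels = rows$subject_id))
  for (i in seq_len(nrow(rows))) {
    d <- by[[i]]
    idx <- rows$index_day[i]
    end <- idx + rows$time[i]
    trunc_day <- NA_integer_
    if (rule == "persistence") {
      own <- d$day[d$code_class == rows$arm[i] & d$day >= idx & d$day <= end]
      pts <- sort(unique(c(idx, own)))
      gaps <- diff(c(pts, end))
      j <- which(gaps >= gap_days)
      if (length(j)) trunc_day <- pts[j[1]] + gap_days
    } else {
      other <- setdiff(lipid_classes, rows$arm[i])
      sw <- d$day[d$code_class == other & d$day > idx & d$day <= end]
      if (length(sw)) trunc_day <- min(sw) + gap_days
    }
    if (!is.na(trunc_day) && trunc_day < end) {
      if (rows$event[i] == 1L && idx + rows$time[i] > trunc_day) {
        rows$event[i] <- 0L
        rows$event_type[i] <- "none"
      }
      rows$time[i] <- max(1L, as.integer(trunc_day - idx))
    }
  }
  rows
}

#' Build the analysis cohort from claims and demographics
#'
#' One-call wrapper: [identify_initiators()], [apply_inclusion()],
#' [derive_covariates()], [derive_outcome()], [apply_censoring()]. The result
#' is the analysis table consumed by the estimation functions, with an
#' `attrition` attribute holding the flow-chart counts.
#'
#' @inheritParams apply_inclusion
#' @inheritParams derive_outcome
#' @inheritParams apply_censoring
#' @return analysis data frame (arm as a statin/fibrate factor, `fibrate` and
#'   `male` indicator columns, covariates, `time`, `event`).
#' @export
build_cohort <- function(claims, demographics,
                         criteria = eligibility_criteria(),
                         admin_end_day = 913L,
                         rule = "itt", gap_days = 183L,
                         include_amputation = TRUE) {
  cand <- identify_initiators(claims, criteria)
  inc <- apply_inclusion(cand, claims, demographics, criteria)
  att <- attr(inc, "attrition")
  rows <- derive_covariates(inc, claims, demographics, criteria)
  rows <- derive_outcome(rows, claims, admin_end_day, include_amputation)
  rows <- apply_censoring(rows, claims, rule, gap_days)
  rows$arm <- factor(rows$arm, levels = c("statin", "fibrate"))
  rows$fibrate <- as.integer(rows$arm == "fibrate")
  rows$male <- as.integer(rows$sex == "male")
  attr(rows, "attrition") <- rbind(
    data.frame(rule = "initiators", excluded = NA_integer_,
               remaining = nrow(cand)), att)
  rows
}
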