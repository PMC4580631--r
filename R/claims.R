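#' Generate a synthetic claims stream
#'
#' Turns the generated population and outcome truth into a claims-like event
#' table (drug reimbursements, hospital discharges, deaths) consistent with
#' the cohort-entry rules: every included-by-design subject carries at least
#' two consecutive GP-prescribed reimbursements of the index drug inside the
#' study window, at least three oral-antidiabetic and three antihypertensive
#' reimbursements within a one-year span of the 913-day lookback, and claim
#' records realising each baseline covariate flag. Designed exclusions
#' violate exactly one rule each.
#'
#' @param population output of [generate_population()].
#' @param outcomes output of [simulate_outcomes()] (the truth table with
#'   follow-up and events).
#' @param config a [generator_config()] object.
#' @param exclusion_design optional named character vector mapping
#'   `subject_id` to one violation among `"prior_lipid"`, `"prior_cv"`,
#'   `"single_reimb"`, `"non_gp"`. (Age/sex exclusions live in the
#'   demographics table, not the claims stream.)
#' @param extract_start earliest day covered by the simulated data extract;
#'   no claim is emitted before it.
#' @return a claims data frame with columns `subject_id`, `day`,
#'   `record_type` (`drug`/`hospital`/`death`), `code_class`, `prescriber`
#'   (`gp`/`other`/`na`), sorted by subject and day.
#' @export
generate_claims <- function(population, outcomes, config,
                            exclusion_design = NULL,
                            extract_start = -913L) {
  validate_config(config)
  set.seed(config$seed + 2L)
  tr <- outcomes
  n <- nrow(tr)
  rows <- vector("list", n)

  antihtn_classes <- c(betablocker = "antihypertensive_betablocker",
                       arb = "antihypertensive_arb",
                       acei = "antihypertensive_acei",
                       diuretic = "antihypertensive_diuretic",
                       ccb = "antihypertensive_ccb",
                       antihtn_other = "antihypertensive_other")
  oad_classes <- c(metformin = "oad_metformin", sulfa = "oad_sulfa",
                   glitazone = "oad_glitazone", oad_other = "oad_other")
  comorb_classes <- c(alzheimer = "comorbidity_alzheimer",
                      cancer = "comorbidity_cancer",
                      depression = "antidepressant",
                      parkinson = "comorbidity_parkinson")
  dur_lo <- c("<2" = 30, "2-5" = 730, "5-10" = 1825, "10+" = 3650)
  dur_hi <- c("<2" = 729, "2-5" = 1824, "5-10" = 3649, "10+" = 5475)

  refill_days <- function(from, to, k) {
    # k reimbursement days spread over [from, to]
    if (to < from) to <- from
    sort(from + sample.int(max(1L, to - from + 1L), k, replace = TRUE) - 1L)
  }

  for (i in seq_len(n)) {
    s <- tr$subject_id[i]
    idx <- tr$index_day[i]
    viol <- if (!is.null(exclusion_design) && as.character(s) %in% names(exclusion_design))
      exclusion_design[[as.character(s)]] else "none"
    d <- list()
    add <- function(day, type, class, presc = "na")
      d[[length(d) + 1L]] <<- list(day = as.integer(day),
                                   record_type = rep_len(type, length(day)),
                                   code_class = rep_len(class, length(day)),
                                   prescriber = rep_len(presc, length(day)))

    ## -- index drug reimbursements ------------------------------------------
    own <- if (tr$arm[i] == "fibrate") "fibrate" else "statin"
    presc <- if (viol == "non_gp") "other" else "gp"
    add(idx, "drug", own, presc)
    if (viol != "single_reimb") {
      add(idx + 30L, "drug", own, presc)
      # refills every ~30 days for a geometric number of months, capped at exit
      extra <- stats::rgeom(1, 0.12)
      if (extra > 0) {
        last <- idx + 30L
        for (r in seq_len(extra)) {
          nxt <- last + 25L + sample.int(15L, 1L)
          if (nxt - idx >= tr$time[i]) break
          add(nxt, "drug", own, presc)
          last <- nxt
        }
      }
    }
    if (viol == "prior_lipid")
      add(idx - 100L, "drug", if (own == "statin") "fibrate" else "statin", "gp")
    if (viol == "prior_cv")
      add(idx - 200L, "hospital", "cv_event_stroke")

    ## -- oral antidiabetics (T2D criterion + covariates + duration) --------
    any_oad <- FALSE
    for (nm in names(oad_classes)) if (tr[[nm]][i] == 1L) {
      any_oad <- TRUE
      add(refill_days(idx - 360L, idx - 5L, 3L + stats::rpois(1, 2)),
          "drug", oad_classes[[nm]], "gp")
    }
    if (!any_oad) {
      # diabetic by design even when no single class reaches the covariate
      # threshold in the final year: 3 reimbursements earlier in the washout
      add(c(idx - 500L, idx - 450L, idx - 400L), "drug", "oad_other", "gp")
    }
    if (tr$insulin[i] == 1L)
      add(refill_days(idx - 360L, idx - 5L, 4L), "drug", "insulin", "gp")
    # first-ever oral antidiabetic record, truncated at the extract horizon
    onset <- if (tr$dm_duration[i] == "unknown") extract_start
      else max(extract_start,
               idx - (dur_lo[[tr$dm_duration[i]]] +
                      sample.int(dur_hi[[tr$dm_duration[i]]] -
                                 dur_lo[[tr$dm_duration[i]]] + 1L, 1L) - 1L))
    add(onset, "drug", "oad_metformin", "gp")

    ## -- antihypertensives (hypertension criterion + covariates) -----------
    any_ah <- FALSE
    for (nm in names(antihtn_classes)) if (tr[[nm]][i] == 1L) {
      any_ah <- TRUE
      add(refill_days(idx - 360L, idx - 5L, 3L + stats::rpois(1, 2)),
          "drug", antihtn_classes[[nm]], "gp")
    }
    if (!any_ah)
      add(c(idx - 500L, idx - 450L, idx - 400L), "drug",
          "antihypertensive_other", "gp")

    ## -- antiplatelets, comorbidity proxies, hospitalisations --------------
    if (tr$aspirin[i] == 1L)
      add(refill_days(idx - 360L, idx - 5L, 4L), "drug", "aspirin", "gp")
    if (tr$clopidogrel[i] == 1L)
      add(refill_days(idx - 360L, idx - 5L, 4L), "drug", "clopidogrel", "gp")
    for (nm in names(comorb_classes)) if (tr[[nm]][i] == 1L)
      add(refill_days(idx - 360L, idx - 5L, 3L), "drug",
          comorb_classes[[nm]], "gp")
    if (tr$hosp_any[i] == 1L)
      add(idx - sample.int(360L, 1L), "hospital", "hospital_any")

    ## -- outcome ------------------------------------------------------------
    if (tr$event[i] == 1L) {
      ed <- idx + tr$time[i]
      if (tr$event_type[i] == "death") add(ed, "death", "death")
      else add(ed, "hospital", paste0("cv_event_", tr$event_type[i]))
    }
    rows[[i]] <- list(
      n = sum(vapply(d, function(p) length(p$day), integer(1))),
      day = unlist(lapply(d, `[[`, "day")),
      record_type = unlist(lapply(d, `[[`, "record_type")),
      code_class = unlist(lapply(d, `[[`, "code_class")),
      prescriber = unlist(lapply(d, `[[`, "prescriber")))
  }

  out <- data.frame(
    subject_id = rep(tr$subject_id, vapply(rows, `[[`, integer(1), "n")),
    day = unlist(lapply(rows, `[[`, "day")),
    record_type = unlist(lapply(rows, `[[`, "record_type")),
    code_class = unlist(lapply(rows, `[[`, "code_class")),
    prescriber = unlist(lapply(rows, `[[`, "prescriber")),
    stringsAsFactors = FALSE)
  out <- out[out$day >= extract_start, , drop = FALSE]
  out <- out[order(out$subject_id, out$day), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write or read generator outputs as delimited text
#'
#' Plain comma-separated UTF-8 tables with a fixed header. The truth table is
#' written with a `truth__test_only.csv` suffix to flag that it must never
#' feed an analysis.
#'
#' @param x data frame to write.
#' @param path file path.
#' @export
write_claims_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_claims_table
#' @export
read_claims_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
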