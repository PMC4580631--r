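#' Read and validate a pipeline configuration file
#'
#' The configuration is a nested YAML file with two blocks: `generator`
#' (fields of [generator_config()]) and `analysis` (fields: `rules`, a
#' subset of itt/persistence/switch; `endpoints`, subset of
#' full/no_amputation; `B`; `month_days`; `seed`). Missing required keys are
#' reported by name.
#'
#' @param path YAML file path, or a list with the same structure.
#' @return validated list with `generator` (a `coxcpt_config`) and
#'   `analysis`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (is.list(path)) path else yaml::read_yaml(path)
  for (key in c("generator", "analysis"))
    if (is.null(raw[[key]])) stop("config: missing required key '", key, "'")
  for (key in c("n_subjects", "seed"))
    if (is.null(raw$generator[[key]]))
      stop("config: missing required key 'generator.", key, "'")
  gen_args <- raw$generator
  if (!is.null(gen_args$treatment_log_hr_schedule))
    gen_args$treatment_log_hr_schedule <-
      as.data.frame(lapply(gen_args$treatment_log_hr_schedule, unlist))
  gen <- do.call(generator_config, gen_args)
  an <- raw$analysis
  an$rules <- if (is.null(an$rules)) "itt" else unlist(an$rules)
  bad <- setdiff(an$rules, c("itt", "persistence", "switch"))
  if (length(bad)) stop("config: unknown censoring rule(s): ",
                        paste(bad, collapse = ", "))
  an$endpoints <- if (is.null(an$endpoints)) "full" else unlist(an$endpoints)
  bad <- setdiff(an$endpoints, c("full", "no_amputation"))
  if (length(bad)) stop("config: unknown endpoint(s): ",
                        paste(bad, collapse = ", "))
  if (is.null(an$B)) an$B <- 500L
  if (is.null(an$month_days)) an$month_days <- 30L
  if (is.null(an$seed)) an$seed <- gen$seed
  list(generator = gen, analysis = an)
}

write_table <- function(x, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  path
}

#' Run the full analysis pipeline
#'
#' Orchestrates generate -> build cohort -> find cut-off -> estimate for each
#' requested censoring rule and endpoint variant, writing delimited report
#' tables and a run manifest (config snapshot, seeds, stage timings, file
#' digests, versions) into `out_dir`. The cut-off search runs once, on the
#' intention-to-treat cohort with the full endpoint, and the selected cut-off
#' is carried into every variant (the sensitivity analyses of the study keep
#' the primary cut-off).
#'
#' @param config path to a YAML config, or a config list
#'   (see [read_pipeline_config()]).
#' @param out_dir output directory, created if needed.
#' @return the run manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  clock <- function(stage, expr) {
    s <- proc.time()[["elapsed"]]
    v <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - s, 2)
    v
  }
  files <- character(0)

  ## stage 1: simulate
  pop <- clock("simulate", {
    p <- generate_population(cfg$generator)
    o <- simulate_outcomes(p$truth, cfg$generator)
    cl <- generate_claims(p, o, cfg$generator)
    list(pop = p, out = o, claims = cl)
  })
  files <- c(files,
             write_table(pop$claims, out_dir, "claims.csv"),
             write_table(pop$pop$demographics, out_dir, "demographics.csv"),
             write_table(pop$out, out_dir, "truth__test_only.csv"))

  ## stage 2: cohorts per rule
  criteria <- eligibility_criteria(index_window = cfg$generator$study_window)
  cohorts <- clock("build_cohort", {
    lapply(stats::setNames(cfg$analysis$rules, cfg$analysis$rules), function(r)
      build_cohort(pop$claims, pop$pop$demographics, criteria,
                   admin_end_day = cfg$generator$censor_admin_day, rule = r))
  })
  for (r in names(cohorts))
    files <- c(files, write_table(cohorts[[r]], out_dir,
                                  paste0("analysis_", r, ".csv")))
  primary <- cohorts[["itt"]]
  if (is.null(primary)) primary <- cohorts[[1]]
  files <- c(files, write_table(attr(primary, "attrition"), out_dir,
                                "attrition.csv"))

  ## stage 3: cut-off search on the primary cohort
  search <- clock("cutoff_search",
    bootstrap_select(primary, B = cfg$analysis$B, seed = cfg$analysis$seed,
                     month_days = cfg$analysis$month_days))
  files <- c(files, write_table(search$table, out_dir, "cutoff_profile.csv"))

  ## stage 4: estimation per rule x endpoint
  est_tables <- clock("estimate", {
    screen <- screen_covariates(primary)
    files <<- c(files, write_table(screen, out_dir, "covariate_screen.csv"))
    mh <- mh_adjusted_rates(primary)
    files <<- c(files, write_table(mh$rates, out_dir, "mh_rates.csv"))
    km <- km_estimate(primary, group_by = "arm")
    files <<- c(files, write_table(km, out_dir, "km_curves.csv"))
    sel <- attr(screen, "selected")
    out <- list()
    for (r in names(cohorts)) for (ep in cfg$analysis$endpoints) {
      rows <- cohorts[[r]]
      if (ep == "no_amputation") {
        amput <- rows$event_type == "amputation"
        rows$event[amput] <- 0L
        rows$event_type[amput] <- "none"
        rows$time[amput] <- cfg$generator$censor_admin_day - rows$index_day[amput]
      }
      models <- fit_final_models(rows, search$selected, sel)
      tab <- do.call(rbind, lapply(names(models), function(nm) {
        pt <- period_hr_table(models[[nm]], "fibrate", search$selected)
        cbind(model = nm, pt)
      }))
      nm <- paste0("table3_", r, "_", ep)
      files <<- c(files, write_table(tab, out_dir, paste0(nm, ".csv")))
      out[[nm]] <- tab
    }
    ipw <- ipw_cox(primary, covariates = intersect(sel, names(primary)),
                   cutoff_day = search$selected)
    ipw_tab <- cbind(model = "ipw",
                     period_hr_table(ipw$fit, "fibrate", search$selected))
    files <<- c(files, write_table(ipw_tab, out_dir, "table3_ipw.csv"),
                write_table(ipw$balance, out_dir, "ipw_balance.csv"))
    out
  })

  manifest <- list(
    package = "coxcpt",
    versions = list(coxcpt = as.character(utils::packageVersion("coxcpt")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    seeds = list(generator = cfg$generator$seed, analysis = cfg$analysis$seed),
    config = list(generator = cfg$generator[setdiff(names(cfg$generator),
                    c("propensity_coefficients", "covariate_log_hazards",
                      "covariate_marginals", "treatment_log_hr_schedule"))],
                  analysis = cfg$analysis),
    selected_cutoff = search$selected,
    stage_timings_sec = timings,
    total_sec = round(proc.time()[["elapsed"]] - t0, 2),
    outputs = lapply(stats::setNames(files, basename(files)),
                     function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Render a human-readable run report
#'
#' Assembles the flow-chart counts, the adjusted event rates, the
#' likelihood-profile table of the cut-off search and the three-model
#' hazard-ratio tables from a completed [run_pipeline()] output directory
#' into one plain-text report. Sensitivity variants that were not run are
#' marked "not run".
#'
#' @param out_dir the pipeline output directory.
#' @param file report path (default `report.txt` inside `out_dir`).
#' @return the report path, invisibly.
#' @export
render_report <- function(out_dir, file = file.path(out_dir, "report.txt")) {
  need <- c("attrition.csv", "mh_rates.csv", "cutoff_profile.csv")
  for (f in need)
    if (!file.exists(file.path(out_dir, f)))
      stop("render_report: missing stage output '", f, "'")
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  dump <- function(f) {
    tab <- utils::read.csv(file.path(out_dir, f))
    w(paste(utils::capture.output(print(round_df(tab, 3))), collapse = "\n"), "")
  }
  w("== Cohort flow chart ==", "")
  dump("attrition.csv")
  w("== Age/sex-adjusted annual event rates (per 100 person-years) ==", "")
  dump("mh_rates.csv")
  w("== Cut-off search (log partial likelihoods) ==", "")
  dump("cutoff_profile.csv")
  w("== Two-period hazard-ratio models ==", "")
  for (r in c("itt", "persistence", "switch"))
    for (ep in c("full", "no_amputation")) {
      f <- paste0("table3_", r, "_", ep, ".csv")
      w(paste0("-- ", r, " / ", ep, " --"))
      if (file.exists(file.path(out_dir, f))) dump(f) else w("not run", "")
    }
  w("-- IPW sensitivity --")
  if (file.exists(file.path(out_dir, "table3_ipw.csv"))) dump("table3_ipw.csv")
  else w("not run", "")
  invisible(file)
}
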