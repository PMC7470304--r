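#' Validate a pipeline run configuration
#'
#' Reads a JSON run configuration and checks it against the schema: a
#' `seed`, an optional `input_dir` (when absent, a cohort is simulated from
#' the `cohort` section, whose fields override [default_config()]), a
#' `criteria` section overriding [match_criteria()], and an `analysis`
#' section (`horizons`, `welch`, `mode`, `censor_day`, `plots`). All
#' problems are collected and reported together.
#'
#' @param path path to a JSON file, or an already-parsed list.
#' @return List of class `run_config`; errors with the full problem list
#'   otherwise.
#' @export
validate_config <- function(path) {
  raw <- if (is.character(path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else path
  errs <- character()
  note <- function(msg) errs <<- c(errs, msg)
  known <- c("seed", "input_dir", "out_dir", "cohort", "criteria", "analysis",
             "log_level")
  for (k in setdiff(names(raw), known)) note(paste0("unknown field: ", k))
  seed <- raw$seed
  if (is.null(seed) || !is.numeric(seed)) note("seed: required integer")
  cohort_cfg <- default_config(seed = if (is.numeric(seed)) seed else 1L)
  for (k in names(raw$cohort)) {
    if (!k %in% names(cohort_cfg)) { note(paste0("cohort.", k, ": unknown field")); next }
    if (is.list(cohort_cfg[[k]])) {
      for (k2 in names(raw$cohort[[k]])) {
        if (!k2 %in% names(cohort_cfg[[k]]))
          note(paste0("cohort.", k, ".", k2, ": unknown field"))
        else cohort_cfg[[k]][[k2]] <- raw$cohort[[k]][[k2]]
      }
    } else if (k == "comorbidity_prevalences") {
      bad <- setdiff(names(raw$cohort[[k]]), names(cohort_cfg[[k]]))
      if (length(bad)) note(paste0("cohort.comorbidity_prevalences: unknown: ",
                                   paste(bad, collapse = ", ")))
      else cohort_cfg[[k]][names(raw$cohort[[k]])] <- unlist(raw$cohort[[k]])
    } else cohort_cfg[[k]] <- raw$cohort[[k]]
  }
  tryCatch(.validate_config(cohort_cfg), error = function(e) note(conditionMessage(e)))
  crit_args <- if (is.null(raw$criteria)) list() else raw$criteria
  if (!is.null(crit_args$age_window) &&
      (!is.numeric(crit_args$age_window) || crit_args$age_window < 0))
    note("criteria.age_window: must be a non-negative number")
  valid_classes <- c(.drugs, "corticosteroids")
  if (!is.null(crit_args$cotreatment_drugs)) {
    bad <- setdiff(crit_args$cotreatment_drugs, valid_classes)
    if (length(bad)) note(paste0("criteria.cotreatment_drugs: unknown drug: ",
                                 paste(bad, collapse = ", ")))
  }
  criteria <- tryCatch(
    do.call(match_criteria,
            crit_args[intersect(names(crit_args),
                                names(formals(match_criteria)))]),
    error = function(e) { note(paste0("criteria: ", conditionMessage(e))); NULL })
  ana <- list(horizons = c(48, 72, 96), welch = FALSE, mode = "greedy",
              censor_day = 30L, plots = TRUE)
  for (k in names(raw$analysis)) {
    if (!k %in% names(ana)) note(paste0("analysis.", k, ": unknown field"))
    else ana[[k]] <- raw$analysis[[k]]
  }
  if (!all(ana$horizons %in% c(48, 72, 96)))
    note("analysis.horizons: must be a subset of 48/72/96")
  if (!ana$mode %in% c("greedy", "optimal"))
    note("analysis.mode: must be greedy or optimal")
  if (!is.null(raw$input_dir) && !dir.exists(raw$input_dir))
    note(paste0("input_dir does not exist: ", raw$input_dir))
  if (length(errs))
    stop("invalid run config:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  structure(list(seed = as.integer(seed), input_dir = raw$input_dir,
                 out_dir = raw$out_dir, cohort = cohort_cfg,
                 criteria = criteria, analysis = ana),
            class = "run_config")
}

.config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, force = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or read) -> derive -> match -> balance -> outcome
#' analyses, writing a reproducible report bundle to `out_dir`: the matched
#' pairs (`pairs.csv`), balance diagnostics (`balance.csv`), horizon change
#' tables (`safi_changes.csv`), Kaplan-Meier curves (`km.csv`, and `km.png`
#' when a graphics device is available), the adjusted Cox summary
#' (`cox_summary.csv`), the mortality comparison (inside `manifest.json`),
#' and a manifest carrying the seed, package version and a config hash so
#' identical configs yield identical manifests. When matching yields no
#' pairs the matched analyses are skipped with a warning.
#'
#' @param run_config a [validate_config()] result (or a path to one).
#' @param out_dir overrides `run_config$out_dir`.
#' @return The bundle as a list (pairs, balance, changes, discharge, cox,
#'   mortality, manifest), invisibly.
#' @export
run_pipeline <- function(run_config, out_dir = NULL) {
  if (is.character(run_config)) run_config <- validate_config(run_config)
  stopifnot(inherits(run_config, "run_config"))
  out_dir <- if (!is.null(out_dir)) out_dir else run_config$out_dir
  if (is.null(out_dir)) stop("no out_dir configured")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))

  x <- stage("input", if (!is.null(run_config$input_dir))
    read_cohort(run_config$input_dir)
    else simulate_cohort(run_config$cohort, seed = run_config$seed))
  derived <- stage("prepare", derive_days(x))
  pairs <- stage("match", match_cohort(x, run_config$criteria, derived,
                                       mode = run_config$analysis$mode))
  bundle <- list(pairs = pairs)
  ana <- run_config$analysis
  if (nrow(pairs)) {
    bundle$balance <- stage("balance", balance_table(pairs, x, derived))
    bundle$changes <- lapply(ana$horizons, function(h)
      stage("safi_change", safi_change(pairs, x, h, derived,
                                       welch = ana$welch)))
    names(bundle$changes) <- paste0("h", ana$horizons)
    bundle$discharge <- stage("discharge",
      discharge_analysis_matched(pairs, x, censor_day = ana$censor_day))
  } else {
    warning("no matched pairs; matched analyses skipped")
  }
  bundle$subcohorts <- stage("subcohorts", select_unmatched_subcohorts(x))
  bundle$cox <- stage("cox",
    discharge_cox_unmatched(x, bundle$subcohorts,
                            censor_day = ana$censor_day))
  bundle$mortality <- stage("mortality",
    mortality_comparison(x, bundle$subcohorts))

  # ---- write the bundle -------------------------------------------------
  hash <- .config_hash(unclass(run_config)[c("seed", "cohort", "criteria",
                                             "analysis")])
  hdr <- sprintf("# tvmatch %s seed=%d config=%s",
                 as.character(utils::packageVersion("tvmatch")),
                 run_config$seed, hash)
  wout <- function(df, file) {
    path <- file.path(out_dir, file)
    writeLines(hdr, path)
    suppressWarnings(utils::write.table(df, path, append = TRUE, sep = ",",
                                        row.names = FALSE, quote = FALSE))
    path
  }
  wout(pairs[, list(treated_id, index_day, control_id, start_day,
                    ps_distance)], "pairs.csv")
  if (!is.null(bundle$balance)) wout(bundle$balance, "balance.csv")
  if (!is.null(bundle$changes)) {
    ch <- rbindlist(lapply(bundle$changes, function(r)
      rbindlist(lapply(c("saturation", "fio2", "safi"), function(m)
        data.table(horizon = r$horizon, measure = m,
                   mean_treated = r[[m]]$mean_treated,
                   n_treated = r[[m]]$n_treated,
                   mean_control = r[[m]]$mean_control,
                   n_control = r[[m]]$n_control,
                   mean_difference = r[[m]]$mean_difference,
                   ci_low = r[[m]]$ci[1], ci_high = r[[m]]$ci[2],
                   p = r[[m]]$p)))))
    wout(ch, "safi_changes.csv")
  }
  if (!is.null(bundle$discharge)) {
    km <- bundle$discharge$km
    kmdf <- data.table(group = rep(sub("group=", "", names(km$strata)),
                                   km$strata),
                       time = km$time, n_risk = km$n.risk,
                       n_event = km$n.event, surv = km$surv)
    wout(kmdf, "km.csv")
    if (isTRUE(ana$plots)) .km_plot(km, bundle$discharge,
                                    file.path(out_dir, "km.png"))
  }
  cx <- bundle$cox
  wout(data.table(term = rownames(cx$coefficients),
                  round(as.data.table(cx$coefficients), 5)),
       "cox_summary.csv")
  manifest <- list(
    package_version = as.character(utils::packageVersion("tvmatch")),
    seed = run_config$seed, config_hash = hash,
    n_patients = nrow(x$statics),
    n_treated = attr(pairs, "n_treated"), n_pairs = nrow(pairs),
    n_unmatched = length(attr(pairs, "unmatched")),
    ps_method = attr(pairs, "ps_method"),
    logrank_p = if (!is.null(bundle$discharge)) bundle$discharge$p else NA,
    cox_hr = cx$hr, cox_ci = cx$ci, cox_p = cx$p,
    mortality = bundle$mortality[c("deaths", "n", "p",
                                   "insufficient_events")])
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = 10, force = TRUE),
             file.path(out_dir, "manifest.json"))
  bundle$manifest <- manifest
  invisible(bundle)
}

# KM plot; silently skipped when no file device can be opened (headless
# builds without cairo).
.km_plot <- function(km, discharge, path) {
  ok <- tryCatch({ grDevices::png(path, 800, 600, type = "cairo"); TRUE },
                 error = function(e) FALSE)
  if (!ok) return(invisible(NULL))
  on.exit(grDevices::dev.off())
  graphics::plot(km, col = c("steelblue", "firebrick"), lwd = 2,
                 xlab = "Days from follow-up start",
                 ylab = "Proportion still in hospital",
                 main = sprintf("Time to discharge (log-rank p = %.3f)",
                                discharge$p))
  graphics::legend("topright", legend = names(discharge$n),
                   col = c("steelblue", "firebrick"), lwd = 2, bty = "n")
  invisible(path)
}

#' Command-line entry point
#'
#' Dispatches the `tvmatch` subcommands: `simulate` (write the three cohort
#' CSVs), `prepare` (derived-day table), `match` (pairs CSV), `balance`
#' (balance table for an existing pairs file), `analyze` and `run` (full
#' pipeline bundle). Install target: `inst/cli/tvmatch`.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return Exit status, invisibly.
#' @export
tvmatch_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: tvmatch <simulate|prepare|match|analyze|run> --config FILE --out DIR [--seed N] [--in DIR]"
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opts <- list(config = NULL, out = NULL, seed = NULL, `in` = NULL)
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opts)) stop("unknown option: ", args[i])
    opts[[key]] <- args[i + 1]
    i <- i + 2
  }
  cfg <- if (!is.null(opts$config)) validate_config(opts$config)
         else validate_config(list(seed = 1L))
  if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
  if (!is.null(opts$`in`)) cfg$input_dir <- opts$`in`
  if (!is.null(opts$out)) cfg$out_dir <- opts$out
  if (is.null(cfg$out_dir)) stop("--out is required")
  get_cohort <- function() if (!is.null(cfg$input_dir)) read_cohort(cfg$input_dir)
    else simulate_cohort(cfg$cohort, seed = cfg$seed)
  switch(cmd,
    simulate = {
      write_cohort(get_cohort(), cfg$out_dir)
      message("wrote cohort CSVs to ", cfg$out_dir)
    },
    prepare = {
      x <- get_cohort()
      if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
      fwrite(derive_days(x), file.path(cfg$out_dir, "derived.csv"), na = "")
      message("wrote derived.csv to ", cfg$out_dir)
    },
    match = {
      x <- get_cohort()
      pairs <- match_cohort(x, cfg$criteria, mode = cfg$analysis$mode)
      if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
      fwrite(pairs[, list(treated_id, index_day, control_id, start_day,
                          ps_distance)],
             file.path(cfg$out_dir, "pairs.csv"))
      message(nrow(pairs), " pairs written (",
              length(attr(pairs, "unmatched")), " treated unmatched)")
    },
    analyze = ,
    run = {
      run_pipeline(cfg)
      message("report bundle written to ", cfg$out_dir)
    },
    stop(usage))
  invisible(0L)
}
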