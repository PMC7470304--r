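#' @importFrom data.table data.table as.data.table setorder := .N .SD rbindlist fread fwrite setDF setnames
#' @importFrom stats rnorm rbinom runif plogis qlogis sd quantile median
NULL

# Column contracts for the three tables. Day 0 is the day of admission; all
# day fields are integer offsets from it.
.static_cols <- c("patient_id", "sex", "age", "obesity", "chf", "crf", "sahs",
                  "tobacco", "hypertension", "diabetes", "copd",
                  "other_cardiopathy", "admission_day", "death_day",
                  "discharge_day", "palliative_sedation")
.obs_cols <- c("patient_id", "day", "spo2", "fio2", "sbp", "dbp", "hr",
               "temperature", "crp", "xray_quadrants", "oxygen_device")
.treat_cols <- c("patient_id", "drug", "day", "dose_mg")

.comorbidities <- c("obesity", "chf", "crf", "sahs", "tobacco", "hypertension",
                    "diabetes", "copd", "other_cardiopathy")
.devices <- c("room_air", "nasal_prongs", "venturi", "reservoir", "niv", "imv")
.drugs <- c("azithromycin", "hydroxychloroquine", "lopinavir_ritonavir",
            "interferon", "tocilizumab", "methylprednisolone", "dexamethasone",
            "heparin")

#' Construct a longitudinal admission cohort
#'
#' A `cohort` bundles the three tables of a hospitalized-patient data set:
#' one row per patient of static covariates and admission outcomes
#' (`statics`), one row per patient-day of vitals, oxygenation, C-reactive
#' protein and chest-radiograph quadrants (`observations`), and one row per
#' administered dose of any recorded drug (`treatments`). Day 0 is the day of
#' admission; `death_day` / `discharge_day` are day offsets, `NA` while the
#' patient is still in hospital at the end of follow-up (follow-up is
#' truncated 30 days after admission).
#'
#' @param statics data.frame with columns `patient_id`, `sex`
#'   (`"male"`/`"female"`), `age`, the nine comorbidity flags (`obesity`,
#'   `chf`, `crf`, `sahs`, `tobacco`, `hypertension`, `diabetes`, `copd`,
#'   `other_cardiopathy`), `admission_day`, `death_day`, `discharge_day`,
#'   `palliative_sedation`.
#' @param observations data.frame with columns `patient_id`, `day`, `spo2`
#'   (percent), `fio2` (percent, 21--100), `sbp`, `dbp`, `hr`, `temperature`,
#'   `crp` (mg/dL, may be `NA`), `xray_quadrants` (0--4, `NA` on days without
#'   a radiograph), `oxygen_device` (one of `room_air`, `nasal_prongs`,
#'   `venturi`, `reservoir`, `niv`, `imv`).
#' @param treatments data.frame with columns `patient_id`, `drug`, `day`,
#'   `dose_mg`.
#' @param validate run [validate_cohort()] on the result (default `TRUE`).
#' @return An object of class `cohort`.
#' @seealso [read_cohort()], [write_cohort()], [simulate_cohort()]
#' @export
cohort <- function(statics, observations, treatments, validate = TRUE) {
  # copy defensively: data.table inputs would otherwise be reordered in
  # place, aliasing the caller's tables
  obj <- structure(
    list(statics = data.table::copy(as.data.table(statics)),
         observations = data.table::copy(as.data.table(observations)),
         treatments = data.table::copy(as.data.table(treatments))),
    class = "cohort")
  setorder(obj$statics, patient_id)
  if (nrow(obj$observations)) setorder(obj$observations, patient_id, day)
  if (nrow(obj$treatments)) setorder(obj$treatments, patient_id, drug, day)
  if (validate) validate_cohort(obj)
  obj
}

#' @exportS3Method base::print
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d patients, %d patient-days, %d treatment events\n",
              nrow(x$statics), nrow(x$observations), nrow(x$treatments)))
  deaths <- sum(!is.na(x$statics$death_day))
  disch <- sum(!is.na(x$statics$discharge_day))
  cat(sprintf("  deaths: %d, discharges: %d, in hospital at censoring: %d\n",
              deaths, disch, nrow(x$statics) - deaths - disch))
  invisible(x)
}

.fail_rows <- function(bad, table, msg) {
  if (any(bad)) {
    rows <- which(bad)
    stop(sprintf("%s: %s (rows %s)", table, msg,
                 paste(utils::head(rows, 5), collapse = ", ")),
         call. = FALSE)
  }
}

#' Validate cohort invariants
#'
#' Checks the referential and range invariants of a [cohort()]: known column
#' sets, patient ids in the daily and treatment tables present in the static
#' table, unique days per patient, FiO2 within 21--100 with FiO2 = 21 on room
#' air, radiograph quadrants in 0--4, at most one of death/discharge set,
#' event days not before admission. Errors name the offending table and rows.
#'
#' @param x a `cohort`.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "cohort"))
  s <- x$statics; o <- x$observations; tr <- x$treatments
  miss <- setdiff(.static_cols, names(s))
  if (length(miss)) stop("statics: missing columns: ", paste(miss, collapse = ", "))
  miss <- setdiff(.obs_cols, names(o))
  if (length(miss)) stop("observations: missing columns: ", paste(miss, collapse = ", "))
  miss <- setdiff(.treat_cols, names(tr))
  if (length(miss)) stop("treatments: missing columns: ", paste(miss, collapse = ", "))

  .fail_rows(duplicated(s$patient_id), "statics", "duplicate patient_id")
  .fail_rows(!s$sex %in% c("male", "female"), "statics", "sex must be male/female")
  .fail_rows(!is.na(s$age) & s$age < 0, "statics", "negative age")
  both <- !is.na(s$death_day) & !is.na(s$discharge_day)
  .fail_rows(both, "statics", "both death_day and discharge_day set")
  ev <- pmin(s$death_day, s$discharge_day, na.rm = TRUE)
  ev[is.na(s$death_day) & is.na(s$discharge_day)] <- NA
  .fail_rows(!is.na(ev) & ev < s$admission_day, "statics",
             "event day precedes admission")

  if (nrow(o)) {
    unknown <- !o$patient_id %in% s$patient_id
    .fail_rows(unknown, "observations", "unknown patient_id")
    .fail_rows(duplicated(o[, c("patient_id", "day")]), "observations",
               "duplicate patient-day")
    .fail_rows(!is.na(o$fio2) & (o$fio2 < 21 | o$fio2 > 100), "observations",
               "fio2 outside [21, 100]")
    .fail_rows(!is.na(o$spo2) & (o$spo2 <= 0 | o$spo2 > 100), "observations",
               "spo2 outside (0, 100]")
    .fail_rows(!o$oxygen_device %in% .devices, "observations",
               "unknown oxygen_device")
    .fail_rows(o$oxygen_device == "room_air" & !is.na(o$fio2) & o$fio2 != 21,
               "observations", "fio2 must be 21 on room air")
    .fail_rows(!is.na(o$xray_quadrants) &
                 !o$xray_quadrants %in% 0:4, "observations",
               "xray_quadrants outside 0-4")
  }
  if (nrow(tr)) {
    .fail_rows(!tr$patient_id %in% s$patient_id, "treatments",
               "unknown patient_id")
    .fail_rows(!tr$drug %in% .drugs, "treatments", "unknown drug")
    .fail_rows(duplicated(tr[, c("patient_id", "drug", "day")]), "treatments",
               "duplicate dose on same day")
  }
  invisible(x)
}

.bool_to_chr <- function(x) ifelse(is.na(x), "", ifelse(x, "true", "false"))
.chr_to_bool <- function(x) {
  out <- rep(NA, length(x))
  out[tolower(x) %in% c("true", "1")] <- TRUE
  out[tolower(x) %in% c("false", "0")] <- FALSE
  out
}

#' Read a cohort from its three delimited-text tables
#'
#' Reads `patients.csv`, `observations.csv` and `treatments.csv` (UTF-8 CSV,
#' booleans encoded `true`/`false`, missing values as empty fields) and
#' validates all cohort invariants; a row violating a range or
#' referential-integrity constraint raises an error naming the table and row.
#'
#' @param static_path,obs_path,treat_path paths to the three CSV files, or a
#'   single directory for `static_path` containing the three default names.
#' @return A validated [cohort()].
#' @export
read_cohort <- function(static_path, obs_path = NULL, treat_path = NULL) {
  if (is.null(obs_path) && dir.exists(static_path)) {
    obs_path <- file.path(static_path, "observations.csv")
    treat_path <- file.path(static_path, "treatments.csv")
    static_path <- file.path(static_path, "patients.csv")
  }
  s <- fread(static_path, colClasses = list(character = "patient_id"),
             na.strings = "")
  o <- fread(obs_path, colClasses = list(character = "patient_id"),
             na.strings = "")
  tr <- fread(treat_path, colClasses = list(character = "patient_id"),
              na.strings = "")
  for (col in c(.comorbidities, "palliative_sedation")) {
    if (is.character(s[[col]])) s[, (col) := .chr_to_bool(get(col))]
    if (is.numeric(s[[col]])) s[, (col) := as.logical(get(col))]
  }
  if (nrow(tr) == 0 && ncol(tr) == 0)
    tr <- data.table(patient_id = character(), drug = character(),
                     day = integer(), dose_mg = numeric())
  cohort(s, o, tr)
}

#' Write a cohort to three CSV files
#'
#' Inverse of [read_cohort()]: writes `patients.csv`, `observations.csv` and
#' `treatments.csv` under `dir`. `read_cohort(write_cohort(x))` reproduces an
#' equal cohort.
#'
#' @param x a `cohort`.
#' @param dir output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  s <- data.table::copy(x$statics)
  for (col in c(.comorbidities, "palliative_sedation"))
    s[, (col) := .bool_to_chr(get(col))]
  paths <- c(patients = file.path(dir, "patients.csv"),
             observations = file.path(dir, "observations.csv"),
             treatments = file.path(dir, "treatments.csv"))
  fwrite(s, paths["patients"], na = "", quote = FALSE)
  fwrite(x$observations, paths["observations"], na = "", quote = FALSE)
  fwrite(x$treatments, paths["treatments"], na = "", quote = FALSE)
  invisible(paths)
}

# Day of exit from hospital (death or discharge), NA if censored in hospital.
.exit_day <- function(statics) {
  ev <- pmin(statics$death_day, statics$discharge_day, na.rm = TRUE)
  ev[is.na(statics$death_day) & is.na(statics$discharge_day)] <- NA
  ev
}
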