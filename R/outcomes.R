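#' Change in respiratory parameters at a fixed horizon, matched subcohorts
#'
#' For every member of every matched pair, computes the change in SAFI,
#' saturation and FiO2 between follow-up day 1 (the aligned index/start day)
#' and `horizon` hours later, then compares treated vs control changes with
#' a two-sample t-test (equal-variance by default, the classical Student
#' form). Patients under palliative sedation are excluded (their saturation
#' no longer tracks disease severity), as are members without an observation
#' at the horizon day; exclusions are counted per group.
#'
#' @param pairs output of [match_cohort()].
#' @param x the `cohort`.
#' @param horizon 48, 72 or 96 (hours).
#' @param derived optional [derive_days()] table.
#' @param welch use the Welch (unequal-variance) t-test instead.
#' @return List of class `safi_change_result`: one element per measure
#'   (`safi`, `saturation`, `fio2`), each with per-group mean change, the
#'   control-minus-treated mean difference with 95% CI, `p`, and per-group
#'   `n`; plus `horizon` and `n_excluded`.
#' @export
safi_change <- function(pairs, x, horizon = 48, derived = NULL,
                        welch = FALSE) {
  stopifnot(horizon %in% c(48, 72, 96), nrow(pairs) >= 1)
  if (is.null(derived)) derived <- derive_days(x)
  hdays <- as.integer(horizon / 24)
  obs <- x$observations
  okey <- paste(obs$patient_id, obs$day)
  dkey <- paste(derived$patient_id, derived$day)
  st <- x$statics
  palliative <- st$patient_id[st$palliative_sedation]
  value_at <- function(ids, days, col, tab, key)
    tab[[col]][match(paste(ids, days), key)]
  member_changes <- function(ids, day1) {
    keep <- !ids %in% palliative
    data.table(
      keep = keep,
      safi = value_at(ids, day1 + hdays, "safi", derived, dkey) -
        value_at(ids, day1, "safi", derived, dkey),
      saturation = value_at(ids, day1 + hdays, "spo2", obs, okey) -
        value_at(ids, day1, "spo2", obs, okey),
      fio2 = value_at(ids, day1 + hdays, "fio2", obs, okey) -
        value_at(ids, day1, "fio2", obs, okey))
  }
  ch_t <- member_changes(pairs$treated_id, pairs$index_day)
  ch_c <- member_changes(pairs$control_id, pairs$start_day)
  out <- list(horizon = horizon,
              n_excluded = sum(!ch_t$keep) + sum(!ch_c$keep))
  for (m in c("safi", "saturation", "fio2")) {
    a <- ch_t[[m]][ch_t$keep]; a <- a[!is.na(a)]  # treated
    b <- ch_c[[m]][ch_c$keep]; b <- b[!is.na(b)]  # control
    if (length(a) < 2 || length(b) < 2)
      stop("fewer than 2 patients per group after exclusions (", m, ")")
    diff <- mean(b) - mean(a)
    if (sd(a) == 0 && sd(b) == 0) {   # degenerate: identical flat changes
      ci <- c(diff, diff)
      p <- if (isTRUE(all.equal(diff, 0))) 1 else NA_real_
    } else {
      tt <- stats::t.test(b, a, var.equal = !welch)
      ci <- unname(tt$conf.int); p <- tt$p.value
    }
    out[[m]] <- list(mean_treated = mean(a), mean_control = mean(b),
                     mean_difference = diff, ci = ci, p = p,
                     n_treated = length(a), n_control = length(b))
  }
  class(out) <- "safi_change_result"
  out
}

#' @exportS3Method base::print
print.safi_change_result <- function(x, ...) {
  cat(sprintf("Change from follow-up day 1 at %d hours (matched subcohorts)\n",
              x$horizon))
  for (m in c("saturation", "fio2", "safi")) {
    r <- x[[m]]
    cat(sprintf(
      "  %-10s treated %6.2f (n%d)  control %6.2f (n%d)  diff %6.2f (%.2f; %.2f)  p=%.3f\n",
      m, r$mean_treated, r$n_treated, r$mean_control, r$n_control,
      r$mean_difference, r$ci[1], r$ci[2], r$p))
  }
  invisible(x)
}

#' Time to discharge in the matched subcohorts
#'
#' Kaplan-Meier curves and log-rank test of time to discharge, measured from
#' each member's follow-up day 1 (the aligned index/start day). Deceased
#' patients are excluded; patients still in hospital are right-censored at
#' `censor_day` days after admission.
#'
#' @param pairs output of [match_cohort()].
#' @param x the `cohort`.
#' @param censor_day administrative censoring day (days from admission).
#' @return List of class `tte_result`: per-group `n`, `events`, `censored`,
#'   median and mean stay, the `survival::survfit` object (`km`), log-rank
#'   `chisq` and `p`, and `n_deceased_excluded`.
#' @export
discharge_analysis_matched <- function(pairs, x, censor_day = 30L) {
  stopifnot(nrow(pairs) >= 1)
  st <- as.data.frame(x$statics)
  rownames(st) <- st$patient_id
  build <- function(ids, day1, group) {
    dd <- st[ids, "discharge_day"]
    dead <- !is.na(st[ids, "death_day"])
    time <- ifelse(!is.na(dd), dd - day1, censor_day - day1)
    data.frame(id = ids, group = group, time = time,
               event = as.integer(!is.na(dd)), dead = dead)
  }
  df <- rbind(build(pairs$treated_id, pairs$index_day, "treated"),
              build(pairs$control_id, pairs$start_day, "control"))
  n_dead <- sum(df$dead)
  df <- df[!df$dead & df$time > 0, ]
  if (sum(df$event) == 0) stop("no discharge events after exclusions")
  df$group <- factor(df$group, c("control", "treated"))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  lr <- if (all(table(df$group) > 0)) {
    # a fully degenerate comparison (zero log-rank variance, e.g. all events
    # tied at one time) makes survdiff's internal solve() singular; the
    # statistic is 0 there by definition
    tryCatch(survival::survdiff(survival::Surv(time, event) ~ group,
                                data = df),
             error = function(e) list(chisq = 0))
  } else NULL
  sm <- summary(fit)$table
  med <- if (is.matrix(sm)) sm[, "median"] else sm[["median"]]
  if (!is.null(names(med))) names(med) <- sub("^group=", "", names(med))
  res <- list(
    n = table(df$group), events = tapply(df$event, df$group, sum),
    median_stay = med, mean_stay = tapply(df$time, df$group, mean),
    km = fit,
    logrank_chisq = if (!is.null(lr)) lr$chisq else NA_real_,
    p = if (!is.null(lr)) 1 - stats::pchisq(lr$chisq, 1) else NA_real_,
    n_deceased_excluded = n_dead)
  class(res) <- "tte_result"
  res
}

#' @exportS3Method base::print
print.tte_result <- function(x, ...) {
  cat("Time to discharge (deceased excluded)\n")
  for (g in names(x$n))
    cat(sprintf("  %-8s n=%d events=%d mean stay %.1f d, median %.1f d\n",
                g, x$n[[g]], x$events[[g]], x$mean_stay[[g]],
                x$median_stay[[g]]))
  cat(sprintf("  log-rank chisq %.3f, p = %.3f (%d deceased excluded)\n",
              x$logrank_chisq, x$p, x$n_deceased_excluded))
  invisible(x)
}

#' Select the unmatched comparison subcohorts
#'
#' Builds the second-strategy comparison groups: patients treated with both
#' hydroxychloroquine and lopinavir/ritonavir, with corticosteroid users
#' removed, and users of any remaining drug distributed significantly
#' asymmetrically between exposure groups (Fisher p < `alpha`) removed
#' iteratively. Exposure is at least `min_doses` doses of azithromycin at
#' any time; patients with an intermediate dose count (1 to `min_doses`-1)
#' are excluded from both groups.
#'
#' @param x a `cohort`.
#' @param alpha asymmetry threshold.
#' @param min_doses azithromycin exposure threshold.
#' @return List: `exposed_ids`, `control_ids`, `dropped` (named list of id
#'   vectors by reason), `asymmetric_drugs`.
#' @export
select_unmatched_subcohorts <- function(x, alpha = 0.05, min_doses = 3L) {
  tr <- x$treatments
  users <- function(drug, min_n = 1L) {
    tab <- table(tr$patient_id[tr$drug == drug])
    names(tab)[tab >= min_n]
  }
  base <- intersect(users("hydroxychloroquine"), users("lopinavir_ritonavir"))
  if (!length(base)) stop("no patients on both hydroxychloroquine and lopinavir/ritonavir")
  cortico <- union(users("methylprednisolone"), users("dexamethasone"))
  dropped <- list(corticosteroids = intersect(base, cortico))
  base <- setdiff(base, cortico)
  az <- exposure_table(x, min_doses = min_doses)
  partial <- az$patient_id[!az$exposed & !az$control]
  dropped$partial_exposure <- intersect(base, partial)
  base <- setdiff(base, partial)
  exposed <- intersect(base, az$patient_id[az$exposed])
  ctrl <- intersect(base, az$patient_id[az$control])
  other <- setdiff(unique(tr$drug),
                   c("azithromycin", "hydroxychloroquine",
                     "lopinavir_ritonavir", "methylprednisolone",
                     "dexamethasone"))
  asym <- character()
  repeat {
    worst <- NULL; worst_p <- alpha
    for (d in other) {
      u <- users(d)
      tab <- rbind(c(sum(exposed %in% u), sum(!exposed %in% u)),
                   c(sum(ctrl %in% u), sum(!ctrl %in% u)))
      if (sum(tab[, 1]) == 0) next
      p <- stats::fisher.test(tab)$p.value
      if (p < worst_p) { worst <- d; worst_p <- p }
    }
    if (is.null(worst)) break
    asym <- c(asym, worst)
    u <- users(worst)
    dropped[[worst]] <- c(intersect(exposed, u), intersect(ctrl, u))
    exposed <- setdiff(exposed, u); ctrl <- setdiff(ctrl, u)
    other <- setdiff(other, worst)
  }
  if (!length(exposed) || !length(ctrl))
    stop("empty subcohort after exclusions")
  list(exposed_ids = sort(exposed), control_ids = sort(ctrl),
       dropped = dropped, asymmetric_drugs = asym)
}

.default_cox_covariates <- c("sex", "age", "obesity", "chf", "crf", "sahs",
                             "baseline_saturation", "baseline_crp",
                             "baseline_quadrants")

# Per-patient analysis frame for the unmatched Cox models: baseline values
# are the emergency-room (day 0) observations.
.cox_frame <- function(x, ids) {
  st <- as.data.frame(x$statics)
  rownames(st) <- st$patient_id
  o0 <- x$observations[x$observations$day == 0, ]
  key <- o0$patient_id
  df <- st[ids, c("patient_id", "sex", "age", "obesity", "chf", "crf", "sahs",
                  "death_day", "discharge_day")]
  df$baseline_saturation <- o0$spo2[match(ids, key)]
  df$baseline_crp <- o0$crp[match(ids, key)]
  df$baseline_quadrants <- o0$xray_quadrants[match(ids, key)]
  df
}

#' Adjusted Cox model of time to discharge, unmatched subcohorts
#'
#' Fits a Cox proportional-hazards model (Efron ties) of time to discharge,
#' counted from admission, on exposure plus the prespecified prognostic
#' covariates: sex, age, obesity, heart failure, chronic renal failure,
#' SAHS, emergency-room saturation, emergency-room CRP and emergency-room
#' radiograph quadrants. Deceased patients are excluded; the rest are
#' right-censored at `censor_day`. Complete-case on the model covariates.
#'
#' @param x a `cohort`.
#' @param subcohorts output of [select_unmatched_subcohorts()].
#' @param covariates adjustment covariate names (defaults to the nine above).
#' @param censor_day administrative censoring day.
#' @return List of class `cox_result`: `hr`, `ci`, `p` for exposure, the
#'   full coefficient table (`coefficients`), `n`, `events`,
#'   `n_deceased_excluded`.
#' @export
discharge_cox_unmatched <- function(x, subcohorts,
                                    covariates = .default_cox_covariates,
                                    censor_day = 30L) {
  ids <- c(subcohorts$exposed_ids, subcohorts$control_ids)
  df <- .cox_frame(x, ids)
  df$exposed <- df$patient_id %in% subcohorts$exposed_ids
  n_dead <- sum(!is.na(df$death_day))
  df <- df[is.na(df$death_day), ]
  df$time <- ifelse(!is.na(df$discharge_day), df$discharge_day, censor_day)
  df$event <- as.integer(!is.na(df$discharge_day))
  df <- df[df$time > 0, c("time", "event", "exposed", covariates)]
  df <- df[stats::complete.cases(df), ]
  if (sum(df$event) == 0) stop("no discharge events")
  # constant covariates carry no information and break the model matrix
  keep <- covariates[vapply(covariates, function(v)
    length(unique(df[[v]])) > 1, logical(1))]
  form <- stats::as.formula(paste(
    "survival::Surv(time, event) ~ exposed",
    if (length(keep)) paste("+", paste(keep, collapse = " + ")) else ""))
  fit <- survival::coxph(form, data = df, ties = "efron", x = TRUE, y = TRUE)
  if (!is.null(fit$info) || any(is.na(stats::coef(fit)[1])))
    stop("Cox model did not converge")
  sm <- summary(fit)
  res <- list(hr = unname(sm$conf.int["exposedTRUE", "exp(coef)"]),
              ci = unname(sm$conf.int["exposedTRUE",
                                      c("lower .95", "upper .95")]),
              p = unname(sm$coefficients["exposedTRUE", "Pr(>|z|)"]),
              coefficients = sm$coefficients,
              n = nrow(df), events = sum(df$event),
              n_deceased_excluded = n_dead, fit = fit)
  class(res) <- "cox_result"
  res
}

#' @exportS3Method base::print
print.cox_result <- function(x, ...) {
  cat(sprintf(
    "Adjusted Cox (discharge): exposure HR %.2f (95%% CI %.2f-%.2f; p = %.3f), n=%d, %d events\n",
    x$hr, x$ci[1], x$ci[2], x$p, x$n, x$events))
  invisible(x)
}

#' Mortality comparison in the unmatched subcohorts
#'
#' 30-day death counts per exposure group with Fisher's exact test. When the
#' total number of deaths is below `caveat_threshold` the result carries a
#' caveat flag: too few events to draw conclusions.
#'
#' @param x a `cohort`.
#' @param subcohorts output of [select_unmatched_subcohorts()].
#' @param caveat_threshold minimum events for an interpretable comparison.
#' @return List: per-group `deaths`, `n`, `percent`, Fisher `p`,
#'   `insufficient_events` flag.
#' @export
mortality_comparison <- function(x, subcohorts, caveat_threshold = 10L) {
  st <- x$statics
  dead <- st$patient_id[!is.na(st$death_day)]
  grp <- list(exposed = subcohorts$exposed_ids,
              control = subcohorts$control_ids)
  stopifnot(all(lengths(grp) > 0))
  d <- sapply(grp, function(ids) sum(ids %in% dead))
  n <- lengths(grp)
  tab <- rbind(d, n - d)
  p <- stats::fisher.test(tab)$p.value
  list(deaths = d, n = n, percent = 100 * d / n, p = p,
       insufficient_events = sum(d) < caveat_threshold)
}
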