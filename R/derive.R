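#' Oxygen saturation / FiO2 ratio (SAFI)
#'
#' SAFI is the non-invasive oxygenation index saturation(%) / FiO2(%). Its
#' maximum is 100/21 = 4.76 (2 dp), corresponding to 100% saturation on room
#' air. Monotone increasing in saturation and decreasing in FiO2.
#'
#' @param spo2_percent oxygen saturation in percent, in (0, 100].
#' @param fio2_percent inspired oxygen fraction in percent, in [21, 100].
#' @return The ratio, vectorized over both arguments.
#' @examples
#' compute_safi(100, 21)  # 4.76, the physical ceiling
#' compute_safi(96, 40)
#' @export
compute_safi <- function(spo2_percent, fio2_percent) {
  if (any(!is.na(fio2_percent) & (fio2_percent < 21 | fio2_percent > 100)))
    stop("fio2_percent must be in [21, 100]")
  if (any(!is.na(spo2_percent) & (spo2_percent <= 0 | spo2_percent > 100)))
    stop("spo2_percent must be in (0, 100]")
  spo2_percent / fio2_percent
}

#' Exposure status from a treatment log
#'
#' A patient counts as exposed to a drug when they received at least
#' `min_doses` doses of it (default 3, the study definition for
#' azithromycin).
#'
#' @param treatments treatment-event table for one patient (columns `drug`,
#'   `day`), or a full cohort treatment table already filtered to one
#'   patient.
#' @param drug drug name.
#' @param min_doses exposure threshold in doses.
#' @return List with `exposed` (logical), `n_doses`, `first_dose_day` (`NA`
#'   if never dosed).
#' @export
exposure_status <- function(treatments, drug = "azithromycin", min_doses = 3L) {
  days <- treatments$day[treatments$drug == drug]
  list(exposed = length(days) >= min_doses,
       n_doses = length(days),
       first_dose_day = if (length(days)) min(days) else NA_integer_)
}

#' Impute radiograph quadrants between equal radiographs
#'
#' Fills the days between two consecutive radiographs that show the same
#' number of affected quadrants, provided the gap between them is at most
#' `max_gap` days (default 6); all other unobserved days stay missing and
#' observed days are never altered. The operation is idempotent.
#'
#' @param days strictly increasing integer days with an observed radiograph.
#' @param quadrants affected quadrants (0--4) on those days.
#' @param max_gap maximum day gap across which equal radiographs are bridged.
#' @param full_days days for which to return a value (default
#'   `min(days):max(days)`).
#' @return data.table with columns `day`, `quadrants`, `provenance`
#'   (`"observed"`, `"imputed"`, or `NA` when still missing).
#' @export
impute_radiology <- function(days, quadrants, max_gap = 6L, full_days = NULL) {
  if (anyDuplicated(days)) stop("duplicate radiograph days")
  o <- order(days); days <- days[o]; quadrants <- quadrants[o]
  keep <- !is.na(quadrants)
  days <- days[keep]; quadrants <- quadrants[keep]
  if (is.null(full_days))
    full_days <- if (length(days)) seq(min(days), max(days)) else integer()
  out <- data.table(day = as.integer(full_days),
                    quadrants = NA_integer_, provenance = NA_character_)
  if (!length(days)) return(out)
  idx <- match(days, out$day)
  ok <- !is.na(idx)
  out$quadrants[idx[ok]] <- as.integer(quadrants[ok])
  out$provenance[idx[ok]] <- "observed"
  if (length(days) >= 2) {
    for (k in seq_len(length(days) - 1L)) {
      if (quadrants[k] == quadrants[k + 1L] &&
          (days[k + 1L] - days[k]) <= max_gap) {
        between <- out$day > days[k] & out$day < days[k + 1L]
        fill <- between & is.na(out$provenance)
        out$quadrants[fill] <- as.integer(quadrants[k])
        out$provenance[fill] <- "imputed"
      }
    }
  }
  out
}

#' Reference CRP at an index day
#'
#' The reference C-reactive protein for a follow-up start is the value on the
#' index day itself or, failing that, on the day before; otherwise missing.
#'
#' @param obs observation table for one patient (columns `day`, `crp`).
#' @param index_day day of follow-up start.
#' @return CRP in mg/dL, or `NA`.
#' @export
reference_crp <- function(obs, index_day) {
  for (d in c(index_day, index_day - 1L)) {
    v <- obs$crp[obs$day == d]
    if (length(v) && !is.na(v[1])) return(v[1])
  }
  NA_real_
}

#' Reference radiograph quadrants at an index day
#'
#' The most recent (possibly imputed) quadrant count in the window
#' `[index_day - 2, index_day]`; missing if no value falls in the window.
#'
#' @param imputed output of [impute_radiology()] for one patient (columns
#'   `day`, `quadrants`).
#' @param index_day day of follow-up start.
#' @return Integer quadrants 0--4, or `NA`.
#' @export
reference_xray <- function(imputed, index_day) {
  w <- imputed[!is.na(imputed$quadrants) &
                 imputed$day >= index_day - 2L & imputed$day <= index_day, ]
  if (!nrow(w)) return(NA_integer_)
  as.integer(w$quadrants[which.max(w$day)])
}

#' Derive per-day analysis quantities for a whole cohort
#'
#' Computes the derived-day table used by matching and outcome analyses:
#' SAFI for every patient-day plus the radiology series after
#' [impute_radiology()] with provenance flags.
#'
#' @param x a `cohort`.
#' @return data.table with columns `patient_id`, `day`, `safi`, `crp`,
#'   `xray_quadrants`, `xray_provenance`.
#' @export
derive_days <- function(x) {
  stopifnot(inherits(x, "cohort"))
  o <- x$observations
  out <- o[, list(patient_id, day, safi = compute_safi(spo2, fio2), crp,
                  xray_quadrants,
                  xray_provenance = ifelse(is.na(xray_quadrants),
                                           NA_character_, "observed"))]
  # vectorized equivalent of per-patient impute_radiology() (cross-checked
  # against it in the test suite): consecutive equal radiographs <= max_gap
  # apart have their intervening days filled
  xo <- o[!is.na(xray_quadrants),
          list(patient_id, day, q = xray_quadrants)]
  if (nrow(xo)) {
    setorder(xo, patient_id, day)
    xo[, `:=`(nday = data.table::shift(day, -1),
              nq = data.table::shift(q, -1)), by = patient_id]
    fill <- xo[!is.na(nday) & q == nq & nday - day >= 2 & nday - day <= 6]
    if (nrow(fill)) {
      len <- fill$nday - fill$day - 1L
      filled <- data.table(
        patient_id = rep(fill$patient_id, len),
        day = rep(fill$day, len) + sequence(len),
        fq = rep(fill$q, len))
      out[filled, on = c("patient_id", "day"),
          `:=`(xray_quadrants = ifelse(is.na(xray_quadrants), i.fq,
                                       xray_quadrants),
               xray_provenance = ifelse(is.na(xray_provenance), "imputed",
                                        xray_provenance))]
    }
  }
  setorder(out, patient_id, day)
  out[]
}

#' Data-driven selection of matching covariates
#'
#' Reproduces the covariate-selection cascade used to pick prognostic
#' matching markers from the pathological antecedents: for each outcome
#' (severe disease, defined as any day on a non-rebreathing reservoir mask or
#' mechanical ventilation, and 30-day death) the antecedents are screened
#' bivariately (chi-square, or Fisher's exact test when any expected cell is
#' below 5; keep p < 0.05), the survivors enter an L1-penalized logistic
#' model with the penalty chosen by 5-fold cross-validated deviance, and the
#' covariates retained at that penalty are refit in an unpenalized
#' multivariate logistic model, keeping those significant at p < 0.05. The
#' union over outcomes is returned. Deterministic given `seed` (which drives
#' the cross-validation folds).
#'
#' @param x a `cohort`.
#' @param outcomes subset of `c("severe_disease", "death")`.
#' @param seed integer seed for the cross-validation fold assignment.
#' @param alpha screening and refit significance level.
#' @return Character vector of selected antecedent names (possibly empty).
#' @export
select_matching_covariates <- function(x, outcomes = c("severe_disease", "death"),
                                       seed = 1L, alpha = 0.05) {
  stopifnot(inherits(x, "cohort"))
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  s <- x$statics
  severe_ids <- unique(x$observations$patient_id[
    x$observations$oxygen_device %in% c("reservoir", "niv", "imv")])
  ymap <- list(severe_disease = s$patient_id %in% severe_ids,
               death = !is.na(s$death_day))
  selected <- character()
  for (oc in outcomes) {
    y <- ymap[[oc]]
    if (length(unique(y)) < 2)
      stop("degenerate outcome '", oc, "': all patients identical")
    # bivariate screen
    screened <- character()
    for (v in .comorbidities) {
      tab <- table(factor(s[[v]], c(FALSE, TRUE)), factor(y, c(FALSE, TRUE)))
      if (any(tab == 0) && (sum(tab[2, ]) == 0 || sum(tab[, 2]) == 0)) next
      exp_cells <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      p <- if (any(exp_cells < 5)) stats::fisher.test(tab)$p.value
           else suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
      if (!is.na(p) && p < alpha) screened <- c(screened, v)
    }
    if (!length(screened)) next
    kept <- screened
    if (length(screened) >= 2) {
      X <- as.matrix(s[, screened, with = FALSE]) * 1
      set.seed(seed)
      cv <- glmnet::cv.glmnet(X, y, family = "binomial", nfolds = 5)
      b <- as.matrix(stats::coef(cv, s = "lambda.min"))[-1, 1]
      kept <- names(b)[b != 0]
    }
    if (!length(kept)) next
    # unpenalized multivariate refit
    df <- data.frame(y = y, s[, kept, with = FALSE])
    fit <- stats::glm(y ~ ., data = df, family = stats::binomial())
    co <- summary(fit)$coefficients
    sig <- rownames(co)[-1][co[-1, 4] < alpha]
    sig <- sub("TRUE$", "", sig)
    selected <- union(selected, sig)
  }
  selected
}
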