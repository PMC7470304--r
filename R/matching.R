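#' Matching criteria for time-varying risk-set matching
#'
#' Hard constraints a (control, start-day) candidate must satisfy relative to
#' a treated patient at their first-dose day: identical sex and obesity
#' status, age difference at most `age_window` years, identical reference
#' radiograph quadrants, control SAFI within `safi_window` of the treated
#' SAFI (control minus treated), reference CRP within `crp_window` mg/dL,
#' and identical co-treatment sets among `cotreatment_drugs` with each
#' relative start-day difference at most `cotreatment_lag` days. Defaults are
#' the published windows: age 15 y, SAFI [-1.1, +2], CRP [-6, +4] mg/dL,
#' lag 3 d, 1:1 ratio. Corticosteroids (methylprednisolone, dexamethasone)
#' are matched as a pooled class by default; heparin is deliberately not a
#' criterion.
#'
#' @param exact_binary static covariates matched exactly.
#' @param age_window maximum absolute age difference, years.
#' @param safi_window,crp_window allowed control-minus-treated range.
#' @param cotreatment_drugs drug classes whose presence must agree.
#' @param cotreatment_lag tolerated relative start lag, days.
#' @param pool_corticosteroids treat methylprednisolone and dexamethasone as
#'   one class (`corticosteroids`); set `FALSE` to match them per-drug.
#' @param min_doses doses defining exposure (controls have zero doses;
#'   patients with 1 to `min_doses - 1` doses are excluded from both arms).
#' @param min_start_day earliest allowed control start day (default 1, the
#'   first day after admission).
#' @return List of class `match_criteria`.
#' @export
match_criteria <- function(exact_binary = c("sex", "obesity"),
                           age_window = 15,
                           safi_window = c(-1.1, 2.0),
                           crp_window = c(-6, 4),
                           cotreatment_drugs = c("hydroxychloroquine",
                                                 "lopinavir_ritonavir",
                                                 "interferon",
                                                 "corticosteroids",
                                                 "tocilizumab"),
                           cotreatment_lag = 3L,
                           pool_corticosteroids = TRUE,
                           min_doses = 3L,
                           min_start_day = 1L) {
  stopifnot(age_window >= 0, cotreatment_lag >= 0,
            safi_window[1] <= safi_window[2], crp_window[1] <= crp_window[2])
  structure(list(exact_binary = exact_binary, age_window = age_window,
                 safi_window = safi_window, crp_window = crp_window,
                 cotreatment_drugs = cotreatment_drugs,
                 cotreatment_lag = as.integer(cotreatment_lag),
                 pool_corticosteroids = pool_corticosteroids,
                 min_doses = as.integer(min_doses),
                 min_start_day = as.integer(min_start_day),
                 ratio = 1L),
            class = "match_criteria")
}

#' Exposure classification for every patient
#'
#' @param x a `cohort`.
#' @param drug exposure drug.
#' @param min_doses dose threshold for exposure.
#' @return data.table with `patient_id`, `n_doses`, `first_dose_day`,
#'   `exposed` (>= min_doses), `control` (zero doses ever). Patients with an
#'   intermediate dose count are neither.
#' @export
exposure_table <- function(x, drug = "azithromycin", min_doses = 3L) {
  sel <- x$treatments[["drug"]] == drug   # plain vector, not the column
  tr <- x$treatments[sel, list(n_doses = .N, first_dose_day = min(day)),
                     by = patient_id]
  out <- merge(x$statics[, list(patient_id)], tr, by = "patient_id",
               all.x = TRUE)
  out[is.na(n_doses), n_doses := 0L]
  out[, exposed := n_doses >= min_doses]
  out[, control := n_doses == 0L]
  out[]
}

# Per patient x criteria-class first dose day (wide, NA when never given).
.cotreat_wide <- function(x, criteria) {
  tr <- data.table::copy(x$treatments)
  if (criteria$pool_corticosteroids)
    tr[drug %in% c("methylprednisolone", "dexamethasone"),
       drug := "corticosteroids"]
  tr <- tr[drug %in% criteria$cotreatment_drugs,
           list(first = min(day)), by = list(patient_id, drug)]
  wide <- data.table::dcast(tr, patient_id ~ drug, value.var = "first")
  missing_cols <- setdiff(criteria$cotreatment_drugs, names(wide))
  for (m in missing_cols) wide[, (m) := NA_integer_]
  out <- merge(x$statics[, list(patient_id)], wide, by = "patient_id",
               all.x = TRUE)
  out[]
}

# Snapshot table: one row per patient-day with SAFI, vitals, reference CRP
# (day or day-1) and reference radiograph quadrants (last imputed value
# within 2 days), computed with day-value windows so gaps in the daily grid
# are handled correctly.
.snapshots <- function(x, derived) {
  o <- x$observations[, list(patient_id, day, sbp, dbp, hr)]
  snap <- merge(derived, o, by = c("patient_id", "day"), sort = TRUE)
  last_within <- function(day, val, window) {
    obs <- !is.na(val)
    if (!any(obs)) return(rep(val[NA_integer_], length(day)))
    od <- day[obs]; ov <- val[obs]
    idx <- findInterval(day, od)
    out <- ifelse(idx >= 1 & day - od[pmax(idx, 1L)] <= window,
                  ov[pmax(idx, 1L)], val[NA_integer_])
    out
  }
  snap[, crp_ref := last_within(day, crp, 1L), by = patient_id]
  snap[, xray_ref := last_within(day, as.numeric(xray_quadrants), 2L),
       by = patient_id]
  snap
}

#' Enumerate all feasible (control, start-day) candidates
#'
#' The brute-force first stage of the matching algorithm: for every exposed
#' treated patient, taken at the day of their first dose, every combination
#' of never-exposed control and hospital day is tested against all hard
#' constraints of `criteria`. Controls must still be in hospital and
#' event-free on the candidate start day; candidates with a missing
#' reference CRP or reference radiograph on either side are infeasible.
#'
#' @param x a `cohort`.
#' @param criteria a [match_criteria()].
#' @param derived optional precomputed [derive_days()] table.
#' @return data.table of candidates: `treated_id`, `index_day`,
#'   `control_id`, `start_day`, the aligned-day covariate snapshots of both
#'   members (`safi_t`, `safi_c`, `crp_t`, `crp_c`, `xray`, `sbp_t`,
#'   `sbp_c`, `dbp_t`, `dbp_c`, `hr_t`, `hr_c`).
#' @export
enumerate_candidates <- function(x, criteria = match_criteria(),
                                 derived = NULL) {
  stopifnot(inherits(x, "cohort"), inherits(criteria, "match_criteria"))
  if (is.null(derived)) derived <- derive_days(x)
  expo <- exposure_table(x, min_doses = criteria$min_doses)
  if (!any(expo$exposed))
    return(.empty_candidates())
  snap <- .snapshots(x, derived)
  ct <- .cotreat_wide(x, criteria)
  ct_cols <- criteria$cotreatment_drugs

  st <- x$statics
  exit <- .exit_day(st)
  pinfo <- data.table(patient_id = st$patient_id, sex = st$sex,
                      obesity = st$obesity, age = st$age, exit = exit)

  treated <- expo[expo$exposed == TRUE]
  tt <- merge(treated[, list(patient_id, index_day = first_dose_day)],
              pinfo, by = "patient_id")
  tt <- merge(tt, snap, by.x = c("patient_id", "index_day"),
              by.y = c("patient_id", "day"))
  tt <- merge(tt, ct, by = "patient_id")
  setnames(tt, c("patient_id", "safi", "crp_ref", "xray_ref", "sbp", "dbp", "hr"),
           c("treated_id", "safi_t", "crp_t", "xray_t", "sbp_t", "dbp_t", "hr_t"))
  setnames(tt, ct_cols, paste0("ct_t_", ct_cols))

  controls <- expo[expo$control == TRUE]
  cdays <- merge(controls[, list(patient_id)], snap, by = "patient_id")
  cdays <- merge(cdays, pinfo, by = "patient_id")
  cdays <- cdays[day >= criteria$min_start_day &
                   (is.na(exit) | day < exit) & !is.na(safi)]
  cdays <- merge(cdays, ct, by = "patient_id")
  setnames(cdays,
           c("patient_id", "day", "safi", "crp_ref", "xray_ref", "sbp", "dbp", "hr"),
           c("control_id", "start_day", "safi_c", "crp_c", "xray_c",
             "sbp_c", "dbp_c", "hr_c"))
  setnames(cdays, ct_cols, paste0("ct_c_", ct_cols))

  if (!nrow(tt) || !nrow(cdays)) return(.empty_candidates())

  # exact binary + age window at person level, then expand over control days
  keys <- criteria$exact_binary
  tt_k <- tt; cd_k <- cdays
  cand <- merge(tt_k, cd_k, by = keys, allow.cartesian = TRUE,
                suffixes = c(".t", ".c"))
  cand <- cand[abs(age.t - age.c) <= criteria$age_window]
  cand <- cand[!is.na(safi_t) &
                 safi_c - safi_t >= criteria$safi_window[1] &
                 safi_c - safi_t <= criteria$safi_window[2]]
  cand <- cand[!is.na(crp_t) & !is.na(crp_c) &
                 crp_c - crp_t >= criteria$crp_window[1] &
                 crp_c - crp_t <= criteria$crp_window[2]]
  cand <- cand[!is.na(xray_t) & !is.na(xray_c) & xray_t == xray_c]
  for (dcl in ct_cols) {
    t_first <- cand[[paste0("ct_t_", dcl)]]
    c_first <- cand[[paste0("ct_c_", dcl)]]
    ok <- (is.na(t_first) & is.na(c_first)) |
      (!is.na(t_first) & !is.na(c_first) &
         abs((c_first - cand$start_day) - (t_first - cand$index_day)) <=
           criteria$cotreatment_lag)
    cand <- cand[ok]
  }
  if (!nrow(cand)) return(.empty_candidates())
  out <- cand[, list(treated_id, index_day, control_id, start_day,
                     safi_t, safi_c, crp_t, crp_c, xray = as.integer(xray_t),
                     sbp_t, sbp_c, dbp_t, dbp_c, hr_t, hr_c)]
  setorder(out, treated_id, control_id, start_day)
  out[]
}

.empty_candidates <- function() {
  data.table(treated_id = character(), index_day = integer(),
             control_id = character(), start_day = integer(),
             safi_t = numeric(), safi_c = numeric(),
             crp_t = numeric(), crp_c = numeric(), xray = integer(),
             sbp_t = numeric(), sbp_c = numeric(),
             dbp_t = numeric(), dbp_c = numeric(),
             hr_t = numeric(), hr_c = numeric())
}

#' Propensity-score refinement of feasible candidates
#'
#' Fits a logistic propensity model of treated status on the aligned-day
#' snapshot covariates (SAFI, systolic and diastolic blood pressure, heart
#' rate, CRP) across all treated patients and all candidate control-days,
#' then scores every candidate by the absolute propensity difference from
#' its treated patient. When the fit degenerates (separation or
#' non-convergence) the distance falls back to standardized Euclidean
#' distance on the five covariates; the method used is recorded in the
#' `"ps_method"` attribute. Missing vitals are mean-imputed within the fit.
#'
#' @param candidates output of [enumerate_candidates()].
#' @return `candidates` with an added `ps_distance` column; attribute
#'   `ps_method` is `"logistic"` or `"euclidean"`.
#' @export
propensity_refine <- function(candidates) {
  cand <- data.table::copy(candidates)
  if (!nrow(cand)) {
    cand[, ps_distance := numeric()]
    attr(cand, "ps_method") <- "logistic"
    return(cand)
  }
  tt <- unique(cand[, list(id = treated_id, safi = safi_t, sbp = sbp_t,
                           dbp = dbp_t, hr = hr_t, crp = crp_t)])
  cc <- unique(cand[, list(id = paste(control_id, start_day, sep = "@"),
                           safi = safi_c, sbp = sbp_c, dbp = dbp_c,
                           hr = hr_c, crp = crp_c)])
  df <- rbind(cbind(tt, treated = 1L), cbind(cc, treated = 0L))
  for (v in c("safi", "sbp", "dbp", "hr", "crp")) {
    m <- mean(df[[v]], na.rm = TRUE)
    df[is.na(get(v)), (v) := m]
  }
  method <- "logistic"
  fit <- withCallingHandlers(
    stats::glm(treated ~ safi + sbp + dbp + hr + crp, data = df,
               family = stats::binomial()),
    warning = function(w) {
      method <<- "euclidean"
      invokeRestart("muffleWarning")
    })
  if (method == "logistic" && !fit$converged) method <- "euclidean"
  if (method == "logistic") {
    ps <- stats::predict(fit, type = "response")
    ps_map <- stats::setNames(ps, df$id)
    cand[, ps_distance := abs(ps_map[paste(control_id, start_day, sep = "@")] -
                                ps_map[treated_id])]
  } else {
    covs <- c("safi", "sbp", "dbp", "hr", "crp")
    sds <- sapply(covs, function(v) max(sd(df[[v]]), 1e-8))
    z <- as.matrix(df[, covs, with = FALSE]) %*% diag(1 / sds)
    rownames(z) <- df$id
    zt <- z[cand$treated_id, , drop = FALSE]
    zc <- z[paste(cand$control_id, cand$start_day, sep = "@"), , drop = FALSE]
    cand[, ps_distance := sqrt(rowSums((zt - zc)^2))]
  }
  attr(cand, "ps_method") <- method
  cand[]
}

# O(n^3) Hungarian algorithm on a square cost matrix; returns the column
# assigned to each row. Classic potentials formulation; arrays are 0..n
# shifted by one for R's 1-based indexing (index 0 is the dummy row/column).
.hungarian <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i; j0 <- 0
    minv <- rep(Inf, n + 1); used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- Inf; j1 <- 0
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else minv[j + 1] <- minv[j + 1] - delta
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0) assign[p[j + 1]] <- j
  assign
}

#' Match a cohort 1:1 without replacement
#'
#' Runs the full matching pipeline: [enumerate_candidates()] under the hard
#' constraints, [propensity_refine()], then pairing. The default `greedy`
#' mode walks treated patients in ascending `patient_id` order, each taking
#' its propensity-closest candidate among still-unused controls (ties broken
#' by control id, then start day); `optimal` mode instead minimizes the
#' total propensity distance over all 1:1 assignments (Hungarian algorithm)
#' as a sensitivity analysis. Both are deterministic. Unmatched treated
#' patients are reported, not fatal.
#'
#' @param x a `cohort`.
#' @param criteria a [match_criteria()].
#' @param derived optional precomputed [derive_days()] table.
#' @param mode `"greedy"` (default) or `"optimal"`.
#' @return data.table of matched pairs (`treated_id`, `index_day`,
#'   `control_id`, `start_day`, `ps_distance`, and the covariate snapshot
#'   columns), with attributes `unmatched` (treated ids left unmatched),
#'   `ps_method`, and `n_treated`.
#' @export
match_cohort <- function(x, criteria = match_criteria(), derived = NULL,
                         mode = c("greedy", "optimal")) {
  mode <- match.arg(mode)
  if (is.null(derived)) derived <- derive_days(x)
  cand <- propensity_refine(enumerate_candidates(x, criteria, derived))
  expo <- exposure_table(x, min_doses = criteria$min_doses)
  treated_ids <- sort(expo$patient_id[expo$exposed])
  if (!nrow(cand)) {
    out <- cbind(.empty_candidates(), data.table(ps_distance = numeric()))
    attr(out, "unmatched") <- treated_ids
    attr(out, "ps_method") <- attr(cand, "ps_method")
    attr(out, "n_treated") <- length(treated_ids)
    return(out)
  }
  setorder(cand, treated_id, ps_distance, control_id, start_day)
  if (mode == "greedy") {
    used <- character()
    rows <- list()
    for (tid in treated_ids) {
      ci <- cand[treated_id == tid & !control_id %in% used]
      if (nrow(ci)) {
        rows[[tid]] <- ci[1]
        used <- c(used, ci$control_id[1])
      }
    }
    pairs <- rbindlist(rows)
  } else {
    # per (treated, control) best day, then square-padded assignment
    best <- cand[, .SD[which.min(ps_distance)],
                 by = list(treated_id, control_id)]
    tids <- sort(unique(best$treated_id))
    cids <- sort(unique(best$control_id))
    n <- max(length(tids), length(cids))
    big <- 1e6
    cost <- matrix(big, n, n)
    cost[cbind(match(best$treated_id, tids), match(best$control_id, cids))] <-
      best$ps_distance
    asg <- .hungarian(cost)
    sel <- data.table(treated_id = tids,
                      control_id = cids[asg[seq_along(tids)]])
    sel <- sel[!is.na(control_id)]
    pairs <- merge(best, sel, by = c("treated_id", "control_id"))
    pairs <- pairs[ps_distance < big]
  }
  if (is.null(pairs) || !nrow(pairs)) {
    pairs <- cbind(.empty_candidates(), data.table(ps_distance = numeric()))
  }
  setorder(pairs, treated_id)
  attr(pairs, "unmatched") <- setdiff(treated_ids, pairs$treated_id)
  attr(pairs, "ps_method") <- attr(cand, "ps_method")
  attr(pairs, "n_treated") <- length(treated_ids)
  pairs[]
}

.fisher_or_na <- function(a, b) {
  tab <- rbind(c(sum(a), length(a) - sum(a)), c(sum(b), length(b) - sum(b)))
  if (any(rowSums(tab) == 0)) return(NA_real_)
  stats::fisher.test(tab)$p.value
}
.t_or_na <- function(a, b, var.equal = TRUE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) return(NA_real_)
  if (sd(a) == 0 && sd(b) == 0)
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  stats::t.test(a, b, var.equal = var.equal)$p.value
}

#' Balance diagnostics for matched pairs
#'
#' Compares the two arms of a matched set on every baseline covariate:
#' continuous covariates (age, aligned-day saturation/vitals/temperature,
#' SAFI, reference CRP, radiograph quadrants, hospital stay from follow-up
#' start among discharged patients) by equal-variance t-test, binary
#' covariates (sex, comorbidities, co-treatment use) by Fisher's exact test.
#'
#' @param pairs output of [match_cohort()].
#' @param x the `cohort` the pairs came from.
#' @param derived optional [derive_days()] table.
#' @return data.table with columns `covariate`, `type`, `treated`,
#'   `control`, `p` (group means for continuous rows, counts for binary
#'   rows).
#' @export
balance_table <- function(pairs, x, derived = NULL) {
  stopifnot(nrow(pairs) >= 1)
  if (is.null(derived)) derived <- derive_days(x)
  st <- as.data.frame(x$statics)
  rownames(st) <- st$patient_id
  ts <- st[pairs$treated_id, ]; cs <- st[pairs$control_id, ]
  obs <- x$observations
  oat <- function(ids, days, col) {
    key <- paste(ids, days)
    v <- obs[[col]][match(key, paste(obs$patient_id, obs$day))]
    v
  }
  rows <- list()
  add_cont <- function(name, a, b)
    rows[[name]] <<- data.table(covariate = name, type = "continuous",
                                treated = mean(a, na.rm = TRUE),
                                control = mean(b, na.rm = TRUE),
                                p = .t_or_na(a, b))
  add_bin <- function(name, a, b)
    rows[[name]] <<- data.table(covariate = name, type = "binary",
                                treated = sum(a), control = sum(b),
                                p = .fisher_or_na(a, b))
  add_cont("age", ts$age, cs$age)
  add_bin("male", ts$sex == "male", cs$sex == "male")
  for (v in .comorbidities) add_bin(v, ts[[v]], cs[[v]])
  add_cont("saturation", oat(pairs$treated_id, pairs$index_day, "spo2"),
           oat(pairs$control_id, pairs$start_day, "spo2"))
  add_cont("sbp", pairs$sbp_t, pairs$sbp_c)
  add_cont("dbp", pairs$dbp_t, pairs$dbp_c)
  add_cont("hr", pairs$hr_t, pairs$hr_c)
  add_cont("temperature",
           oat(pairs$treated_id, pairs$index_day, "temperature"),
           oat(pairs$control_id, pairs$start_day, "temperature"))
  add_cont("safi", pairs$safi_t, pairs$safi_c)
  tr <- safi_trend_check(pairs, derived)
  rows[["safi_trend"]] <- data.table(covariate = "safi_trend",
                                     type = "continuous",
                                     treated = tr$mean_treated,
                                     control = tr$mean_control, p = tr$p)
  add_cont("xray_quadrants", as.numeric(pairs$xray), as.numeric(pairs$xray))
  add_cont("crp", pairs$crp_t, pairs$crp_c)
  expo_t <- .cotreat_wide(x, match_criteria())
  et <- as.data.frame(expo_t); rownames(et) <- et$patient_id
  for (dcl in c("hydroxychloroquine", "lopinavir_ritonavir", "interferon",
                "corticosteroids", "tocilizumab"))
    add_bin(dcl, !is.na(et[pairs$treated_id, dcl]),
            !is.na(et[pairs$control_id, dcl]))
  exit <- .exit_day(x$statics)
  names(exit) <- x$statics$patient_id
  stay_t <- exit[pairs$treated_id] - pairs$index_day
  stay_c <- exit[pairs$control_id] - pairs$start_day
  dead <- !is.na(st[pairs$treated_id, "death_day"])
  dead_c <- !is.na(st[pairs$control_id, "death_day"])
  add_cont("hospital_stay", stay_t[!dead & !is.na(stay_t)],
           stay_c[!dead_c & !is.na(stay_c)])
  rbindlist(rows)
}

#' Pre-index SAFI trend comparability check
#'
#' For each member of each pair, the change in SAFI between follow-up day 1
#' (the index/start day) and the day before it; the per-group means are
#' compared by t-test to verify neither group was systematically improving
#' or worsening on entry. Pairs in which either member lacks a prior-day
#' SAFI (e.g. treated on the day of admission) are excluded and counted.
#'
#' @param pairs output of [match_cohort()].
#' @param derived a [derive_days()] table.
#' @return List: `mean_treated`, `mean_control`, `p`, `n_pairs_used`,
#'   `n_pairs_excluded`.
#' @export
safi_trend_check <- function(pairs, derived) {
  key <- paste(derived$patient_id, derived$day)
  safi_at <- function(ids, days)
    derived$safi[match(paste(ids, days), key)]
  d_t <- safi_at(pairs$treated_id, pairs$index_day) -
    safi_at(pairs$treated_id, pairs$index_day - 1L)
  d_c <- safi_at(pairs$control_id, pairs$start_day) -
    safi_at(pairs$control_id, pairs$start_day - 1L)
  ok <- !is.na(d_t) & !is.na(d_c)
  list(mean_treated = mean(d_t[ok]), mean_control = mean(d_c[ok]),
       p = .t_or_na(d_t[ok], d_c[ok]),
       n_pairs_used = sum(ok), n_pairs_excluded = sum(!ok))
}
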