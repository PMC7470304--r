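# Independent oracles. These deliberately re-derive everything with plain
# loops and scalar logic; they never call the package's vectorized paths.

# Radiology imputation by explicit day-walk (equal radiographs <= 6 d apart).
oracle_impute <- function(days, quads, max_gap = 6) {
  full <- if (length(days)) min(days):max(days) else integer()
  val <- setNames(rep(NA_integer_, length(full)), full)
  val[as.character(days)] <- quads
  if (length(days) >= 2) {
    for (k in 1:(length(days) - 1)) {
      if (!is.na(quads[k]) && !is.na(quads[k + 1]) &&
          quads[k] == quads[k + 1] && days[k + 1] - days[k] <= max_gap &&
          days[k + 1] - days[k] >= 2) {
        for (d in (days[k] + 1):(days[k + 1] - 1))
          val[as.character(d)] <- quads[k]
      }
    }
  }
  val
}

# Reference lookups, scalar.
oracle_ref_crp <- function(obs, day) {
  for (d in c(day, day - 1)) {
    v <- obs$crp[obs$day == d]
    if (length(v) == 1 && !is.na(v)) return(v)
  }
  NA_real_
}
oracle_ref_xray <- function(obs, day, max_gap = 6) {
  xobs <- obs[!is.na(obs$xray_quadrants), ]
  imp <- oracle_impute(xobs$day, xobs$xray_quadrants, max_gap)
  best <- NA_integer_
  for (d in (day - 2):day) {
    v <- imp[as.character(d)]
    if (length(v) == 1 && !is.na(v)) best <- as.integer(v)
  }
  best
}

# Brute-force triple loop over (treated, control, day): the independent
# reference for the candidate-set comparison. Returns "tid|cid|day" keys.
oracle_candidates <- function(x, criteria = match_criteria()) {
  st <- as.data.frame(x$statics)
  tr <- as.data.frame(x$treatments)
  ob <- as.data.frame(x$observations)
  az <- tr[tr$drug == "azithromycin", ]
  ndose <- table(az$patient_id)
  treated <- names(ndose)[ndose >= criteria$min_doses]
  controls <- setdiff(st$patient_id, names(ndose))
  classes <- criteria$cotreatment_drugs
  first_day <- function(id, cls) {
    drugs <- if (cls == "corticosteroids" && criteria$pool_corticosteroids)
      c("methylprednisolone", "dexamethasone") else cls
    d <- tr$day[tr$patient_id == id & tr$drug %in% drugs]
    if (length(d)) min(d) else NA
  }
  keys <- character()
  for (tid in sort(treated)) {
    it <- min(az$day[az$patient_id == tid])
    ts <- st[st$patient_id == tid, ]
    tob <- ob[ob$patient_id == tid, ]
    row_t <- tob[tob$day == it, ]
    if (nrow(row_t) != 1) next
    safi_t <- row_t$spo2 / row_t$fio2
    crp_t <- oracle_ref_crp(tob, it)
    xr_t <- oracle_ref_xray(tob, it)
    for (cid in sort(controls)) {
      cs <- st[st$patient_id == cid, ]
      if (cs$sex != ts$sex) next
      if (cs$obesity != ts$obesity) next
      if (abs(cs$age - ts$age) > criteria$age_window) next
      cob <- ob[ob$patient_id == cid, ]
      exit <- if (!is.na(cs$death_day)) cs$death_day
              else if (!is.na(cs$discharge_day)) cs$discharge_day else Inf
      for (d in cob$day) {
        if (d < criteria$min_start_day) next
        if (d >= exit) next
        row_c <- cob[cob$day == d, ]
        safi_c <- row_c$spo2 / row_c$fio2
        if (is.na(safi_c)) next
        if (safi_c - safi_t < criteria$safi_window[1] ||
            safi_c - safi_t > criteria$safi_window[2]) next
        crp_c <- oracle_ref_crp(cob, d)
        if (is.na(crp_t) || is.na(crp_c)) next
        if (crp_c - crp_t < criteria$crp_window[1] ||
            crp_c - crp_t > criteria$crp_window[2]) next
        xr_c <- oracle_ref_xray(cob, d)
        if (is.na(xr_t) || is.na(xr_c) || xr_t != xr_c) next
        ok <- TRUE
        for (cls in classes) {
          ft <- first_day(tid, cls); fc <- first_day(cid, cls)
          if (is.na(ft) != is.na(fc)) { ok <- FALSE; break }
          if (!is.na(ft) && abs((fc - d) - (ft - it)) > criteria$cotreatment_lag) {
            ok <- FALSE; break
          }
        }
        if (!ok) next
        keys <- c(keys, paste(tid, cid, d, sep = "|"))
      }
    }
  }
  keys
}

# Maximum bipartite matching size via augmenting paths (Kuhn's algorithm)
# on the treated-control feasibility graph.
oracle_max_matching <- function(edges) {
  if (!nrow(edges)) return(0L)
  tids <- unique(edges$treated_id)
  cids <- unique(edges$control_id)
  adj <- lapply(tids, function(t)
    match(unique(edges$control_id[edges$treated_id == t]), cids))
  match_of <- rep(0L, length(cids))
  try_kuhn <- function(u, seen) {
    for (v in adj[[u]]) {
      if (!seen[v]) {
        seen[v] <<- TRUE
        if (match_of[v] == 0L || try_kuhn(match_of[v], seen)) {
          match_of[v] <<- u
          return(TRUE)
        }
      }
    }
    FALSE
  }
  size <- 0L
  for (u in seq_along(tids)) {
    seen <- rep(FALSE, length(cids))
    if (try_kuhn(u, seen)) size <- size + 1L
  }
  size
}

# Two-sample log-rank statistic computed from the O-E / variance sums by
# hand, plus a label-permutation p-value.
oracle_logrank_chisq <- function(time, event, group) {
  g1 <- group == group[1]
  o_minus_e <- 0; varsum <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1)
      varsum <- varsum + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (varsum == 0) return(0)
  o_minus_e^2 / varsum
}
oracle_logrank_perm_p <- function(time, event, group, n_perm, seed = 1) {
  set.seed(seed)
  obs <- oracle_logrank_chisq(time, event, group)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    if (oracle_logrank_chisq(time, event, sample(group)) >= obs - 1e-12)
      hits <- hits + 1L
  }
  hits / n_perm
}

# Two-sided Fisher p as the hypergeometric sum over tables at least as
# extreme (probability at most that of the observed table).
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Efron-ties Cox log partial likelihood for a single binary covariate setup
# generalized to a covariate matrix; used for the score check at coxph's
# estimate.
oracle_efron_loglik <- function(beta, time, event, X) {
  eta <- as.vector(X %*% beta)
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(event == 1 & time == t)
    R <- which(time >= t)
    d <- length(D)
    sumD <- sum(exp(eta[D]))
    sumR <- sum(exp(eta[R]))
    ll <- ll + sum(eta[D])
    for (l in 0:(d - 1))
      ll <- ll - log(sumR - (l / d) * sumD)
  }
  ll
}
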