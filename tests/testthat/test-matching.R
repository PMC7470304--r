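test_that("each published hard window is enforced at its boundary", {
  # baseline: all windows satisfied -> feasible
  ok <- enumerate_candidates(window_cohort())
  expect_gt(nrow(ok), 0)
  # age difference 20 > 15
  expect_equal(nrow(enumerate_candidates(window_cohort(control_age = 80))), 0)
  # control SAFI 1.8 vs treated 3.0: delta -1.2 below -1.1
  expect_equal(nrow(enumerate_candidates(window_cohort(control_safi = 1.8))), 0)
  # delta exactly -1.1 is allowed, +2.0 allowed, +2.1 not
  expect_gt(nrow(enumerate_candidates(window_cohort(control_safi = 1.9))), 0)
  expect_gt(nrow(enumerate_candidates(window_cohort(control_safi = 4.76,
                                                    treated_safi = 2.76))), 0)
  expect_equal(nrow(enumerate_candidates(
    window_cohort(control_safi = 4.2, treated_safi = 2.0))), 0)
  # CRP: control - treated must lie in [-6, +4]
  expect_equal(nrow(enumerate_candidates(window_cohort(control_crp = 1.5))), 0)
  expect_gt(nrow(enumerate_candidates(window_cohort(control_crp = 2))), 0)
  expect_equal(nrow(enumerate_candidates(window_cohort(control_crp = 12.5))), 0)
  # sex, obesity, radiograph quadrants must agree exactly
  expect_equal(nrow(enumerate_candidates(window_cohort(control_sex = "female"))), 0)
  expect_equal(nrow(enumerate_candidates(window_cohort(control_obese = TRUE))), 0)
  expect_equal(nrow(enumerate_candidates(window_cohort(control_quad = 3L))), 0)
  # co-treatment sets must agree
  expect_equal(nrow(enumerate_candidates(
    window_cohort(control_cotreat = FALSE))), 0)
})

test_that("feasible sets equal the brute-force oracle on mini-cohorts", {
  for (seed in 1:40) {
    x <- make_mini_cohort(seed)
    cand <- enumerate_candidates(x)
    got <- sort(paste(cand$treated_id, cand$control_id, cand$start_day,
                      sep = "|"))
    expect_equal(got, sort(oracle_candidates(x)), info = paste("seed", seed))
  }
})

test_that("emitted pairs re-validate every hard constraint independently", {
  checked <- 0L
  for (seed in 41:90) {
    x <- make_mini_cohort(seed, n_treated = 4, n_control = 10, rich = TRUE)
    pairs <- match_cohort(x)
    if (!nrow(pairs)) next
    feas <- oracle_candidates(x)
    keys <- paste(pairs$treated_id, pairs$control_id, pairs$start_day,
                  sep = "|")
    expect_true(all(keys %in% feas), info = paste("seed", seed))
    expect_false(any(duplicated(pairs$control_id)))
    expect_false(any(duplicated(pairs$treated_id)))
    checked <- checked + nrow(pairs)
  }
  expect_gt(checked, 20)  # the fuzz actually exercised pairs
})

test_that("greedy pair count is bounded by maximum bipartite matching", {
  for (seed in 81:110) {
    x <- make_mini_cohort(seed)
    cand <- enumerate_candidates(x)
    pairs <- match_cohort(x)
    expect_lte(nrow(pairs), oracle_max_matching(cand))
  }
})

test_that("tightening any window never adds candidates", {
  for (seed in c(3, 7, 12)) {
    x <- make_mini_cohort(seed, n_treated = 4, n_control = 8)
    base <- nrow(enumerate_candidates(x))
    tighter <- list(
      match_criteria(age_window = 8),
      match_criteria(safi_window = c(-0.5, 1.0)),
      match_criteria(crp_window = c(-3, 2)),
      match_criteria(cotreatment_lag = 1L))
    for (cr in tighter)
      expect_lte(nrow(enumerate_candidates(x, cr)), base)
  }
})

test_that("propensity refinement prefers the closest candidate", {
  # two controls: one identical to the treated on all five covariates,
  # one displaced on all of them -> identical one selected, distance ~0
  x <- window_cohort()
  st <- data.table::copy(x$statics)
  extra <- st[st$patient_id == "C1"]
  extra$patient_id <- "C2"
  ob <- data.table::copy(x$observations)
  eo <- ob[ob$patient_id == "C1"]
  eo$patient_id <- "C2"
  # C1 becomes identical to T1's snapshot; C2 stays displaced
  ob[ob$patient_id == "C1", c("spo2", "fio2", "crp") := list(63, 21, 8)]
  ob[ob$patient_id == "C1", c("sbp", "dbp", "hr") := list(120, 70, 80)]
  eo[, c("sbp", "dbp", "hr") := list(150, 90, 110)]
  tr <- data.table::copy(x$treatments)
  etr <- tr[tr$patient_id == "C1"]
  etr$patient_id <- "C2"
  x2 <- cohort(rbind(st, extra), rbind(ob, eo), rbind(tr, etr))
  pairs <- match_cohort(x2)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$control_id, "C1")
  expect_lt(pairs$ps_distance,
            min(propensity_refine(enumerate_candidates(x2))[
              control_id == "C2", ps_distance]))
})

test_that("single candidate is selected regardless of distance", {
  pairs <- match_cohort(window_cohort(control_safi = 4.7, control_crp = 11))
  expect_equal(nrow(pairs), 1L)
})

test_that("competition for one control leaves one treated unmatched", {
  # duplicate the treated patient of the window cohort: two treated, one
  # feasible control
  x <- window_cohort()
  st <- data.table::copy(x$statics)
  t2 <- st[st$patient_id == "T1"]; t2$patient_id <- "T2"
  ob <- data.table::copy(x$observations)
  o2 <- ob[ob$patient_id == "T1"]; o2$patient_id <- "T2"
  tr <- data.table::copy(x$treatments)
  r2 <- tr[tr$patient_id == "T1"]; r2$patient_id <- "T2"
  x2 <- cohort(rbind(st, t2), rbind(ob, o2), rbind(tr, r2))
  pairs <- match_cohort(x2)
  expect_equal(nrow(pairs), 1L)
  expect_length(attr(pairs, "unmatched"), 1L)
  expect_equal(attr(pairs, "n_treated"), 2L)
})

test_that("an infeasible cohort yields zero pairs, not an error", {
  x <- window_cohort(control_sex = "female")
  pairs <- match_cohort(x)
  expect_equal(nrow(pairs), 0L)
  expect_equal(attr(pairs, "unmatched"), "T1")
})

test_that("the Hungarian solver matches exhaustive assignment on small costs", {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(3:5, 1)
    cost <- matrix(round(runif(n * n), 3), n)
    best <- min(sapply(perms(seq_len(n)), function(p)
      sum(cost[cbind(seq_len(n), p)])))
    asg <- tvmatch:::.hungarian(cost)
    expect_equal(sum(cost[cbind(seq_len(n), asg)]), best)
  }
})

test_that("optimal mode never exceeds greedy total distance", {
  for (seed in c(2, 9, 23)) {
    x <- make_mini_cohort(seed, n_treated = 5, n_control = 9, rich = TRUE)
    g <- match_cohort(x, mode = "greedy")
    o <- match_cohort(x, mode = "optimal")
    if (nrow(g) && nrow(o) && nrow(g) == nrow(o))
      expect_lte(sum(o$ps_distance), sum(g$ps_distance) + 1e-9)
    expect_gte(nrow(o), nrow(g))  # optimal finds at least as many pairs
  }
})

test_that("balance table covers the baseline covariates with sane p-values", {
  x <- simulate_cohort(default_config(seed = 2))
  pairs <- match_cohort(x)
  bal <- balance_table(pairs, x)
  expect_true(all(c("age", "male", "obesity", "safi", "safi_trend", "crp",
                    "xray_quadrants", "hospital_stay", "hydroxychloroquine")
                  %in% bal$covariate))
  expect_true(all(is.na(bal$p) | (bal$p >= 0 & bal$p <= 1)))
  # exact-matched covariates are perfectly balanced
  expect_equal(bal[bal$covariate == "male", ]$treated,
               bal[bal$covariate == "male", ]$control)
  expect_equal(bal[bal$covariate == "obesity", ]$treated,
               bal[bal$covariate == "obesity", ]$control)
  expect_equal(bal[bal$covariate == "xray_quadrants", ]$p, 1)
})

test_that("matched groups differing only by a constant age shift flag age", {
  x <- window_cohort()
  pairs <- match_cohort(x)
  # synthetic 29-pair set: identical covariates except age shifted 20 y
  many <- pairs[rep(1, 29)]
  many$control_id <- sprintf("C%02d", 1:29)
  st <- x$statics
  a <- tvmatch:::.t_or_na(rep(60, 29), rep(80, 29))
  expect_lt(a, 0.05)
  b <- tvmatch:::.t_or_na(rep(60, 29), rep(60, 29))
  expect_equal(b, 1)
})

test_that("SAFI trend check reports flat trajectories as comparable", {
  x <- window_cohort()          # constant SAFI by construction
  pairs <- match_cohort(x)
  d <- derive_days(x)
  tr <- safi_trend_check(pairs, d)
  if (tr$n_pairs_used > 0) {
    expect_equal(tr$mean_treated, 0)
    expect_equal(tr$mean_control, 0)
  }
  expect_equal(tr$n_pairs_used + tr$n_pairs_excluded, nrow(pairs))
})
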