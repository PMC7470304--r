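# Shared medium-size matched cohort for the outcome analyses.
outcome_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      x <- simulate_cohort(default_config(n_patients = 500, seed = 42))
      pairs <- match_cohort(x)
      cache <<- list(x = x, pairs = pairs, derived = derive_days(x))
    }
    cache
  }
})

test_that("identical trajectories give zero difference and p near 1", {
  x <- window_cohort()
  pairs <- match_cohort(x)
  many <- pairs[rep(1, 10)]  # replicate the pair to satisfy group sizes
  many$control_id <- "C1"; many$treated_id <- "T1"
  r <- safi_change(many, x, 48)
  expect_equal(r$safi$mean_difference, 0)
  expect_equal(r$safi$mean_treated, 0)     # flat trajectory
  expect_true(is.na(r$safi$p) || r$safi$p > 0.99)
})

test_that("safi_change drops palliative-sedation patients and counts them", {
  f <- outcome_fixture()
  r0 <- safi_change(f$pairs, f$x, 48, f$derived)
  x2 <- clone_cohort(f$x)
  # flag one matched treated patient as palliative
  tid <- f$pairs$treated_id[1]
  x2$statics[x2$statics$patient_id == tid, "palliative_sedation"] <- TRUE
  r1 <- safi_change(f$pairs, x2, 48, f$derived)
  expect_equal(r1$n_excluded, r0$n_excluded + 1L)
  expect_lte(r1$safi$n_treated, r0$safi$n_treated)
})

test_that("horizon changes are recovered when a drift is injected", {
  # exposure worsens SAFI by 0.3/day: the 48-h difference (control - treated)
  # should come out positive across the matched groups
  cfg <- default_config(n_patients = 800, seed = 13)
  cfg$true_effect$safi_drift <- -0.3
  x <- simulate_cohort(cfg)
  pairs <- match_cohort(x)
  r <- safi_change(pairs, x, 48)
  expect_gt(r$safi$mean_difference, 0)
})

test_that("matched discharge analysis excludes the dead and censors at 30 d", {
  f <- outcome_fixture()
  res <- discharge_analysis_matched(f$pairs, f$x)
  st <- as.data.frame(f$x$statics); rownames(st) <- st$patient_id
  dead <- sum(!is.na(st[c(f$pairs$treated_id, f$pairs$control_id),
                        "death_day"]))
  expect_equal(res$n_deceased_excluded, dead)
  expect_lte(sum(res$n), 2 * nrow(f$pairs) - dead)
  # survival curves are proper step functions
  expect_true(all(res$km$surv >= 0 & res$km$surv <= 1))
  expect_true(all(diff(res$km$surv[seq_len(res$km$strata[1])]) <= 0))
})

test_that("log-rank agrees with the hand-rolled statistic and permutations", {
  time <- c(4, 6, 8, 2, 3, 4); event <- rep(1, 6)
  group <- rep(c("treated", "control"), each = 3)
  chisq <- oracle_logrank_chisq(time, event, group)
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  expect_equal(sd_fit$chisq, chisq, tolerance = 1e-8)
  p_perm <- oracle_logrank_perm_p(time, event, group, n_perm = 4000, seed = 2)
  # exhaustive enumeration of all C(6,3) label assignments
  idx <- combn(6, 3)
  stats <- apply(idx, 2, function(k) {
    g <- rep("b", 6); g[k] <- "a"
    oracle_logrank_chisq(time, event, g)
  })
  p_exact <- mean(stats >= chisq - 1e-12)
  se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(p_perm - p_exact), 3 * se)
})

test_that("identical event times in both groups give log-rank chisq 0", {
  x <- window_cohort()
  pairs <- match_cohort(x)
  many <- pairs[rep(1, 6)]
  res <- discharge_analysis_matched(many, x)
  expect_equal(unname(res$logrank_chisq), 0, tolerance = 1e-12)
  expect_equal(unname(res$p), 1, tolerance = 1e-12)
})

test_that("unmatched subcohort selection mirrors the exclusion cascade", {
  f <- outcome_fixture()
  sub <- select_unmatched_subcohorts(f$x)
  tr <- f$x$treatments
  users <- function(d) unique(tr$patient_id[tr$drug == d])
  keep <- c(sub$exposed_ids, sub$control_ids)
  # all kept patients on HCQ + LPV/r, none on corticosteroids
  expect_true(all(keep %in% intersect(users("hydroxychloroquine"),
                                      users("lopinavir_ritonavir"))))
  expect_length(intersect(keep, union(users("methylprednisolone"),
                                      users("dexamethasone"))), 0)
  et <- exposure_table(f$x)
  expect_true(all(sub$exposed_ids %in% et$patient_id[et$exposed]))
  expect_true(all(sub$control_ids %in% et$patient_id[et$control]))
})

test_that("a perfectly exposure-confounded drug is dropped as asymmetric", {
  x <- outcome_fixture()$x
  et <- exposure_table(x)
  tr <- data.table::copy(x$treatments)
  tr <- tr[tr$drug != "interferon"]
  # give interferon to exposed patients only
  ifn <- data.table::data.table(
    patient_id = head(et$patient_id[et$exposed], 40),
    drug = "interferon", day = 1L, dose_mg = 250)
  x2 <- cohort(x$statics, x$observations, rbind(tr, ifn))
  sub <- select_unmatched_subcohorts(x2)
  expect_true("interferon" %in% sub$asymmetric_drugs)
  expect_length(intersect(c(sub$exposed_ids, sub$control_ids),
                          ifn$patient_id), 0)
})

test_that("subcohort selection errors without an HCQ+LPV/r base", {
  x <- window_cohort()  # nobody on lopinavir/ritonavir
  expect_error(select_unmatched_subcohorts(x), "hydroxychloroquine")
})

test_that("adjusted Cox recovers the exposure effect structure", {
  f <- outcome_fixture()
  sub <- select_unmatched_subcohorts(f$x)
  res <- discharge_cox_unmatched(f$x, sub)
  expect_true(res$hr > res$ci[1] && res$hr < res$ci[2])
  expect_true(all(res$ci > 0))
  expect_equal(res$n_deceased_excluded,
               sum(!is.na(f$x$statics$death_day[
                 f$x$statics$patient_id %in%
                   c(sub$exposed_ids, sub$control_ids)])))
  # Efron partial-likelihood score is ~0 at the fitted estimate
  fit <- res$fit
  y <- fit$y
  X <- fit$x
  beta <- stats::coef(fit)
  eps <- 1e-5
  for (j in c(1, 2)) {
    bp <- beta; bm <- beta
    bp[j] <- bp[j] + eps; bm[j] <- bm[j] - eps
    grad <- (oracle_efron_loglik(bp, y[, 1], y[, 2], X) -
               oracle_efron_loglik(bm, y[, 1], y[, 2], X)) / (2 * eps)
    expect_lt(abs(grad), 1e-2)
  }
})

test_that("with degenerate covariates the Cox HR equals the unadjusted one", {
  f <- outcome_fixture()
  sub <- select_unmatched_subcohorts(f$x)
  x2 <- clone_cohort(f$x)
  # flatten every adjustment covariate
  x2$statics[, c("sex", "age", "obesity", "chf", "crf", "sahs") :=
               list("male", 70L, FALSE, FALSE, FALSE, FALSE)]
  x2$observations[x2$observations$day == 0,
                  c("spo2", "crp", "xray_quadrants") := list(92, 10, 2L)]
  x2$observations[x2$observations$day == 0 &
                    x2$observations$oxygen_device == "room_air",
                  "fio2"] <- 21  # keep invariant intact
  adj <- discharge_cox_unmatched(x2, sub)
  ids <- c(sub$exposed_ids, sub$control_ids)
  st <- as.data.frame(x2$statics); rownames(st) <- st$patient_id
  df <- data.frame(
    exposed = ids %in% sub$exposed_ids,
    dd = st[ids, "discharge_day"], dead = !is.na(st[ids, "death_day"]))
  df <- df[!df$dead, ]
  df$time <- ifelse(is.na(df$dd), 30, df$dd)
  df$event <- as.integer(!is.na(df$dd))
  unadj <- survival::coxph(survival::Surv(time, event) ~ exposed, data = df,
                           ties = "efron")
  expect_equal(adj$hr, unname(exp(coef(unadj))), tolerance = 1e-6)
})

test_that("mortality comparison matches the exact hypergeometric oracle", {
  f <- outcome_fixture()
  sub <- select_unmatched_subcohorts(f$x)
  m <- mortality_comparison(f$x, sub)
  a <- m$deaths[["exposed"]]; na <- m$n[["exposed"]]
  b <- m$deaths[["control"]]; nb <- m$n[["control"]]
  expect_equal(m$p, oracle_fisher_p(a, na - a, b, nb - b), tolerance = 1e-9)
  # the published 6/74 vs 7/132 split reproduces its Fisher p
  expect_equal(stats::fisher.test(rbind(c(6, 68), c(7, 125)))$p.value,
               oracle_fisher_p(6, 68, 7, 125), tolerance = 1e-9)
})

test_that("mortality caveat flag follows the event count", {
  f <- outcome_fixture()
  sub <- select_unmatched_subcohorts(f$x)
  x2 <- clone_cohort(f$x)
  keep_dead <- x2$statics$patient_id[!is.na(x2$statics$death_day)][1:3]
  x2$statics[!(x2$statics$patient_id %in% keep_dead) &
               !is.na(x2$statics$death_day),
             c("death_day", "discharge_day") := list(NA_integer_, 28L)]
  m <- mortality_comparison(x2, sub)
  expect_lte(sum(m$deaths), 3)
  expect_true(m$insufficient_events)
  x3 <- clone_cohort(f$x)
  x3$statics[, c("death_day", "discharge_day") := list(NA_integer_, 10L)]
  m0 <- mortality_comparison(x3, sub)
  expect_equal(unname(m0$p), 1)
  expect_equal(sum(m0$deaths), 0)
})
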