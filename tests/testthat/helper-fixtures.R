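# Fixtures are generated in code; nothing binary ships with the package.

# Hand-written 3-patient cohort exercising every column type.
tiny_cohort <- function() {
  statics <- data.frame(
    patient_id = c("A01", "A02", "A03"),
    sex = c("male", "female", "male"),
    age = c(70L, 55L, 80L),
    obesity = c(FALSE, TRUE, FALSE), chf = c(FALSE, FALSE, TRUE),
    crf = c(FALSE, FALSE, FALSE), sahs = c(FALSE, FALSE, FALSE),
    tobacco = c(TRUE, FALSE, FALSE), hypertension = c(TRUE, FALSE, TRUE),
    diabetes = c(FALSE, FALSE, TRUE), copd = c(FALSE, FALSE, FALSE),
    other_cardiopathy = c(FALSE, FALSE, FALSE),
    admission_day = 0L,
    death_day = c(NA, NA, 4L), discharge_day = c(5L, 3L, NA),
    palliative_sedation = c(FALSE, FALSE, TRUE))
  observations <- data.frame(
    patient_id = rep(c("A01", "A02", "A03"), times = c(6, 4, 5)),
    day = c(0:5, 0:3, 0:4),
    spo2 = c(95, 94, 96, 97, 98, 98, 99, 98, 99, 99, 88, 86, 84, 80, 75),
    fio2 = c(28, 28, 21, 21, 21, 21, 21, 21, 21, 21, 40, 40, 85, 85, 100),
    sbp = 120, dbp = 70, hr = 80, temperature = 36.8,
    crp = c(8, NA, 6, NA, NA, 3, 2, NA, NA, NA, 20, NA, 25, NA, 30),
    xray_quadrants = c(2L, NA, NA, 2L, NA, NA, 0L, NA, NA, NA,
                       3L, NA, NA, 4L, NA),
    oxygen_device = c(rep("nasal_prongs", 2), rep("room_air", 4),
                      rep("room_air", 4),
                      "venturi", "venturi", "reservoir", "reservoir", "imv"))
  treatments <- data.frame(
    patient_id = c(rep("A01", 5), rep("A03", 2)),
    drug = c(rep("azithromycin", 3), rep("hydroxychloroquine", 2),
             "azithromycin", "heparin"),
    day = c(1L, 2L, 3L, 0L, 1L, 1L, 0L),
    dose_mg = c(500, 250, 250, 800, 400, 500, 40))
  cohort(statics, observations, treatments)
}

# Random structured mini-cohort for fuzzing the matcher against the oracle:
# a handful of treated and controls, short stays, sparse CRP/radiographs,
# random co-treatments. Independent of simulate_cohort() on purpose.
make_mini_cohort <- function(seed, n_treated = NULL, n_control = NULL,
                             rich = FALSE) {
  set.seed(seed)
  if (is.null(n_treated)) n_treated <- sample(1:6, 1)
  if (is.null(n_control)) n_control <- sample(2:10, 1)
  crp_miss <- if (rich) 0.1 else 0.4
  quad_miss <- if (rich) 0.15 else 0.5
  ages <- if (rich) 55:75 else 40:90
  cot <- if (rich)
    c(hydroxychloroquine = .85, lopinavir_ritonavir = .85, interferon = 0,
      tocilizumab = 0, dexamethasone = 0, heparin = .5)
  else
    c(hydroxychloroquine = .7, lopinavir_ritonavir = .7, interferon = .15,
      tocilizumab = .1, dexamethasone = .15, heparin = .5)
  n <- n_treated + n_control
  ids <- sprintf("M%02d", seq_len(n))
  stay <- sample(3:9, n, replace = TRUE)
  dies <- runif(n) < 0.1
  statics <- data.frame(
    patient_id = ids,
    sex = sample(c("male", "female"), n, replace = TRUE, prob = c(.6, .4)),
    age = sample(ages, n, replace = TRUE),
    obesity = runif(n) < 0.3, chf = runif(n) < 0.1, crf = runif(n) < 0.15,
    sahs = runif(n) < 0.1, tobacco = runif(n) < 0.1,
    hypertension = runif(n) < 0.5, diabetes = runif(n) < 0.25,
    copd = runif(n) < 0.1, other_cardiopathy = runif(n) < 0.15,
    admission_day = 0L,
    death_day = ifelse(dies, stay, NA_integer_),
    discharge_day = ifelse(dies, NA_integer_, stay),
    palliative_sedation = FALSE)
  obs <- do.call(rbind, lapply(seq_len(n), function(i) {
    days <- 0:stay[i]
    nd <- length(days)
    dev <- sample(c("room_air", "nasal_prongs", "venturi"), nd,
                  replace = TRUE)
    fio2 <- c(room_air = 21, nasal_prongs = 28, venturi = 40)[dev]
    crp <- round(runif(nd, 1, 20), 1)
    crp[runif(nd) < crp_miss] <- NA
    quad <- sample(0:4, nd, replace = TRUE)
    quad[runif(nd) < quad_miss] <- NA
    data.frame(patient_id = ids[i], day = days,
               spo2 = sample(85:100, nd, replace = TRUE),
               fio2 = unname(fio2),
               sbp = sample(100:150, nd, replace = TRUE),
               dbp = sample(55:90, nd, replace = TRUE),
               hr = sample(60:110, nd, replace = TRUE),
               temperature = 36.5, crp = crp, xray_quadrants = quad,
               oxygen_device = dev)
  }))
  treat_rows <- list()
  for (i in seq_len(n_treated)) {
    start <- sample(0:min(2, stay[i] - 1), 1)
    dd <- start:min(start + 4, stay[i])
    if (length(dd) < 3) dd <- start:min(start + 2, stay[i])  # may stay partial
    treat_rows[[length(treat_rows) + 1]] <- data.frame(
      patient_id = ids[i], drug = "azithromycin", day = dd,
      dose_mg = c(500, rep(250, length(dd) - 1)))
  }
  for (i in seq_len(n)) {
    for (d in c("hydroxychloroquine", "lopinavir_ritonavir", "interferon",
                "tocilizumab", "dexamethasone", "heparin")) {
      if (runif(1) < cot[[d]]) {
        start <- sample(0:min(3, stay[i]), 1)
        dd <- start:min(start + 4, stay[i])
        treat_rows[[length(treat_rows) + 1]] <- data.frame(
          patient_id = ids[i], drug = d, day = dd, dose_mg = 100)
      }
    }
  }
  cohort(statics, obs, do.call(rbind, treat_rows))
}

# Minimal hand-built two-arm cohort for targeted window checks: one treated
# patient (index day 1) and one control, with every covariate settable.
window_cohort <- function(control_age = 70, control_sex = "male",
                          control_obese = FALSE, control_safi = 3.5,
                          control_crp = 6, control_quad = 2L,
                          treated_safi = 3.0, treated_crp = 8,
                          treated_quad = 2L, control_cotreat = TRUE) {
  mk_obs <- function(id, safi, crp, quad) {
    # encode a wanted SAFI exactly: fio2 = 21 is not always possible for
    # safi > 100/21, so use spo2 = safi * fio2 with fio2 chosen to keep
    # spo2 <= 100.
    fio2 <- if (21 * safi <= 100) 21 else 28
    dev <- if (fio2 == 21) "room_air" else "nasal_prongs"
    data.frame(patient_id = id, day = 0:4, spo2 = safi * fio2, fio2 = fio2,
               sbp = 120, dbp = 70, hr = 80, temperature = 36.8,
               crp = crp, xray_quadrants = c(quad, NA, NA, NA, NA),
               oxygen_device = dev)
  }
  statics <- data.frame(
    patient_id = c("T1", "C1"), sex = c("male", control_sex),
    age = c(60L, as.integer(control_age)),
    obesity = c(FALSE, control_obese), chf = FALSE, crf = FALSE,
    sahs = FALSE, tobacco = FALSE, hypertension = FALSE, diabetes = FALSE,
    copd = FALSE, other_cardiopathy = FALSE, admission_day = 0L,
    death_day = NA_integer_, discharge_day = c(4L, 4L),
    palliative_sedation = FALSE)
  obs <- rbind(mk_obs("T1", treated_safi, 8, treated_quad),
               mk_obs("C1", control_safi, control_crp, control_quad))
  obs$crp[obs$patient_id == "T1"] <- treated_crp
  obs$crp[obs$patient_id == "C1"] <- control_crp
  treats <- data.frame(patient_id = "T1", drug = "azithromycin", day = 1:3,
                       dose_mg = c(500, 250, 250))
  if (control_cotreat) {
    treats <- rbind(treats,
                    data.frame(patient_id = c("T1", "C1"),
                               drug = "hydroxychloroquine", day = c(1L, 1L),
                               dose_mg = 400))
  } else {
    treats <- rbind(treats,
                    data.frame(patient_id = "T1",
                               drug = "hydroxychloroquine", day = 1L,
                               dose_mg = 400))
  }
  cohort(statics, obs, treats)
}

# Deep copy: the tables inside a cohort are data.tables, so := in a test
# would otherwise mutate a shared fixture.
clone_cohort <- function(x) {
  cohort(data.table::copy(x$statics), data.table::copy(x$observations),
         data.table::copy(x$treatments))
}
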