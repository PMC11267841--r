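# builders for small hand-made cohorts, plus an independent random-stay
# generator and a naive day-loop scoring oracle used to cross-check the
# vectorised implementation

make_days <- function(patient_id, day_index,
                      weight_kg = NA_real_, intake_ml = 2000,
                      diuretics_given = FALSE, ultrafiltration_ml = 0,
                      serum_na_mmol_l = 140, serum_k_mmol_l = 4,
                      rifle_level = "none", hypotension = FALSE,
                      icu_id = "X", period = "control") {
  tibble::tibble(
    patient_id = patient_id, icu_id = icu_id, period = period,
    day_index = as.integer(day_index), weight_kg = weight_kg,
    intake_ml = intake_ml, diuretics_given = diuretics_given,
    ultrafiltration_ml = ultrafiltration_ml,
    serum_na_mmol_l = serum_na_mmol_l, serum_k_mmol_l = serum_k_mmol_l,
    rifle_level = rifle_level, hypotension = hypotension
  )
}

make_stay <- function(patient_id, admission_weight_kg = 70,
                      discharge_weight_kg = NA_real_, los_days = 5,
                      icu_id = "X", period = "control") {
  tibble::tibble(
    patient_id = patient_id, icu_id = icu_id, period = period,
    admission_weight_kg = admission_weight_kg,
    discharge_weight_kg = discharge_weight_kg,
    los_days = as.integer(los_days)
  )
}

# random stay generator independent of the package's simulator: mixed
# missingness, labs in and out of contraindication ranges, short stays
random_test_stay <- function(id, seed) {
  set.seed(seed)
  los <- sample(1:16, 1)
  adm <- runif(1, 50, 100)
  days <- make_days(
    patient_id = id,
    day_index = 1:los,
    weight_kg = ifelse(runif(los) < 0.7, runif(los, adm - 5, adm + 6),
                       NA_real_),
    intake_ml = round(runif(los, 0, 3000)),
    diuretics_given = runif(los) < 0.2,
    ultrafiltration_ml = ifelse(runif(los) < 0.1, runif(los, 200, 2000), 0),
    serum_na_mmol_l = ifelse(runif(los) < 0.1, NA_real_,
                             runif(los, 130, 160)),
    serum_k_mmol_l = ifelse(runif(los) < 0.1, NA_real_,
                            runif(los, 2.2, 5.2)),
    rifle_level = sample(rifle_levels(), los, replace = TRUE,
                         prob = c(0.6, 0.15, 0.1, 0.08, 0.04, 0.03)),
    hypotension = runif(los) < 0.2
  )
  stay <- make_stay(id, admission_weight_kg = adm, los_days = los)
  fb_cohort(stay, days)
}

# naive day-by-day oracle for the exposure score; deliberately re-derives
# thresholds, contraindications and compliance with its own if/else logic
oracle_score_stay <- function(cohort) {
  stay <- cohort$stays
  days <- cohort$days
  adm <- stay$admission_weight_kg
  los <- stay$los_days
  last <- min(los, 14)
  nwin <- if (los >= 2) last - 2 + 1 else 0
  ndev <- nover <- nweighed <- 0
  if (nwin > 0) {
    for (d in 2:last) {
      rec <- days[days$day_index == d, ]
      if (nrow(rec) == 0) next
      thr <- if (d == 2) adm + 2 else if (d <= 7) adm else adm - 2
      w <- rec$weight_kg
      if (!is.na(w)) nweighed <- nweighed + 1
      overloaded <- !is.na(w) && w > thr
      if (overloaded) nover <- nover + 1
      contra <- isTRUE(rec$hypotension) ||
        (!is.na(rec$serum_na_mmol_l) && rec$serum_na_mmol_l > 155) ||
        (!is.na(rec$serum_k_mmol_l) && rec$serum_k_mmol_l < 2.8) ||
        rec$rifle_level %in% c("risk", "injury", "failure", "loss", "eskd")
      prev_rec <- days[days$day_index == d - 1, ]
      prev <- if (nrow(prev_rec) == 1) prev_rec$intake_ml else NA_real_
      responded <- isTRUE(rec$diuretics_given) ||
        rec$ultrafiltration_ml > 0 ||
        (!is.na(prev) && prev > 0 && rec$intake_ml <= 0.7 * prev + 1e-9)
      if (overloaded && !contra && !responded) ndev <- ndev + 1
    }
  }
  if (nwin > 0) {
    raw <- 100 * (1 - ndev / nwin)
    prop <- nweighed / nwin
    final <- raw * prop
  } else {
    raw <- prop <- final <- NA_real_
  }
  list(n_deviations = ndev, n_overload_days = nover, n_window_days = nwin,
       n_weighed_window = nweighed, raw_score = raw,
       weigh_proportion = prop, final_score = final)
}
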