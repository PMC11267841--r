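group_columns <- function() {
  c("icu_id", "period", "n_patients", "n_expected", "p_weigh", "p_adhere",
    "p_contra", "p_hypo_day", "los_mean", "los_dispersion",
    "admission_weight_mean_kg", "admission_weight_sd_kg",
    "baseline_intake_ml", "overload_drift_kg_per_day", "weight_noise_sd_kg")
}

#' Default per-(ICU, period) simulation settings
#'
#' Twelve ICUs (lettered A-L) observed in a control and an intervention
#' period. Weighing and adherence propensities vary across ICUs to emulate
#' the between-unit spread seen in multicentre stepped-wedge trials:
#' control-period daily weighing probabilities span 0.30-0.72 (weekly
#' weigh-in averages of roughly 2-5) and adherence 0.25-0.65 (standard of
#' care plus contamination), while intervention-period weighing spans
#' 0.67-0.85 and adherence 0.60-0.95 (suboptimal but much higher
#' fidelity). Other settings are shared: ~10-day mean stay (negative
#' binomial truncated at 3 days), 75 (12) kg admission weight, 2500 mL
#' baseline daily intake, 0.5 kg/day fluid drift and 0.3 kg weighing
#' noise, 10% daily lab/renal contraindication probability and 20% daily
#' hypotension probability.
#'
#' @param n_patients Patients simulated per (ICU, period).
#' @param n_expected Planned enrolment per (ICU, period), used for reach.
#' @return A tibble with one row per (ICU, period).
#' @export
default_cohort_groups <- function(n_patients = 50L, n_expected = 60L) {
  icu <- LETTERS[1:12]
  ctrl <- tibble::tibble(
    icu_id = icu,
    period = "control",
    n_patients = as.integer(n_patients),
    n_expected = as.integer(n_expected),
    p_weigh = seq(0.30, 0.72, length.out = 12),
    p_adhere = seq(0.25, 0.65, length.out = 12),
    p_contra = 0.10,
    p_hypo_day = 0.20,
    los_mean = 10,
    los_dispersion = 4,
    admission_weight_mean_kg = 75,
    admission_weight_sd_kg = 12,
    baseline_intake_ml = 2500,
    overload_drift_kg_per_day = 0.5,
    weight_noise_sd_kg = 0.3
  )
  intv <- ctrl |>
    mutate(period = "intervention",
           p_weigh = seq(0.67, 0.85, length.out = 12),
           p_adhere = seq(0.60, 0.95, length.out = 12))
  bind_rows(ctrl, intv) |> arrange(.data$icu_id, .data$period)
}

#' Configuration of the synthetic cohort generator
#'
#' @param groups One row per (ICU, period); see [default_cohort_groups()]
#'   for the required columns and the default calibration.
#' @param response_mix Named weights for the compliant response drawn on
#'   adherent overload days: intake restriction, diuretics,
#'   ultrafiltration. Normalised to sum to one.
#' @param seed Master seed; every stay derives its own reproducible
#'   substream from it, so adding patients or groups never perturbs
#'   previously generated stays.
#' @param force_overload Degenerate mode for calibration checks: every
#'   patient stays exactly 1 kg above the overload threshold on every
#'   window day (no weighing noise, stay fixed at the full window length).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(groups = default_cohort_groups(),
                          response_mix = c(restriction = 0.6,
                                           diuretics = 0.3,
                                           ultrafiltration = 0.1),
                          seed = 1L,
                          force_overload = FALSE) {
  groups <- tibble::as_tibble(groups)
  missing <- setdiff(group_columns(), names(groups))
  if (length(missing) > 0) {
    stop("Config error: group table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("p_weigh", "p_adhere", "p_contra", "p_hypo_day")) {
    v <- groups[[col]]
    if (any(is.na(v) | v < 0 | v > 1)) {
      stop(sprintf("Config error: %s must lie in [0, 1]", col),
           call. = FALSE)
    }
  }
  if (any(groups$los_mean <= 0)) {
    stop("Config error: los_mean must be positive", call. = FALSE)
  }
  if (any(groups$n_patients < 1)) {
    stop("Config error: n_patients must be >= 1", call. = FALSE)
  }
  if (anyDuplicated(paste(groups$icu_id, groups$period, sep = "\r")) > 0) {
    stop("Config error: duplicated (icu_id, period) in group table",
         call. = FALSE)
  }
  stopifnot(setequal(names(response_mix),
                     c("restriction", "diuretics", "ultrafiltration")),
            all(response_mix >= 0), sum(response_mix) > 0)
  structure(
    list(groups = groups,
         response_mix = response_mix / sum(response_mix),
         seed = as.integer(seed),
         force_overload = isTRUE(force_overload)),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config> %d groups, %d patients total, seed %d%s\n",
              nrow(x$groups), sum(x$groups$n_patients), x$seed,
              if (x$force_overload) " (degenerate force-overload mode)" else ""))
  invisible(x)
}

# evaluate code under a seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# deterministic per-stay substream seed: 31-ary string hash of the key,
# reduced modulo a Mersenne prime so it fits a 32-bit integer
derive_seed <- function(master, ...) {
  key <- paste(master, ..., sep = "\r")
  h <- 0
  for (cp in utf8ToInt(key)) h <- (h * 31 + cp) %% 2147483629
  as.integer(h) + 1L
}

# one stay as plain vectors (fast path shared by simulate_stay/simulate_cohort)
simulate_stay_raw <- function(p, seed, rules, mix, force_overload,
                              patient_id) {
  with_seed(seed, {
    w1 <- rules$window_start_day
    w2 <- rules$window_end_day
    if (force_overload) {
      los <- w2
    } else {
      repeat {
        los <- rnbinom(1L, size = p$los_dispersion, mu = p$los_mean)
        if (los >= 3) break
      }
    }
    los <- as.integer(los)
    repeat {
      adm <- rnorm(1L, p$admission_weight_mean_kg, p$admission_weight_sd_kg)
      if (adm >= 35) break
    }

    weight <- rep(NA_real_, los)
    intake <- numeric(los)
    diur <- logical(los)
    uf <- numeric(los)
    na_v <- numeric(los)
    k_v <- numeric(los)
    rifle <- rep("none", los)
    hypo <- logical(los)

    tw <- adm # true (unobserved) weight on the current day
    rifle_pool <- c("risk", "injury", "failure")
    for (d in seq_len(los)) {
      if (force_overload && d >= w1) {
        tw <- day_threshold(min(d, w2), adm, rules) + 1
      }
      weighed <- d == 1L || runif(1L) < p$p_weigh
      if (weighed) {
        noise <- if (force_overload) 0 else rnorm(1L, 0, p$weight_noise_sd_kg)
        weight[d] <- tw + noise
      }
      hypo[d] <- runif(1L) < p$p_hypo_day
      if (runif(1L) < p$p_contra) {
        type <- sample(c("sodium", "potassium", "rifle"), 1L)
        na_v[d] <- if (type == "sodium") runif(1L, 156, 165) else runif(1L, 135, 148)
        k_v[d] <- if (type == "potassium") runif(1L, 2.0, 2.7) else runif(1L, 3.3, 4.8)
        rifle[d] <- if (type == "rifle") {
          sample(rifle_pool, 1L, prob = c(0.6, 0.3, 0.1))
        } else "none"
      } else {
        na_v[d] <- runif(1L, 135, 148)
        k_v[d] <- runif(1L, 3.3, 4.8)
      }

      thr <- if (d >= w1) day_threshold(min(d, w2), adm, rules) else Inf
      overload_true <- tw > thr
      overload_obs <- weighed && !is.na(weight[d]) && weight[d] > thr
      contra_d <- is_contraindicated(hypo[d], na_v[d], k_v[d], rifle[d], rules)
      respond <- overload_obs && !contra_d && runif(1L) < p$p_adhere

      if (respond) {
        type <- sample(names(mix), 1L, prob = mix)
        if (type == "restriction" && d > 1L) {
          # 5 points beyond the rule fraction so the restriction is clear
          intake[d] <- max(0, (1 - rules$restriction_fraction - 0.05)) *
            intake[d - 1L]
        } else {
          intake[d] <- p$baseline_intake_ml
          if (type == "diuretics") diur[d] <- TRUE
          if (type == "ultrafiltration") uf[d] <- runif(1L, 500, 2500)
        }
      } else {
        intake[d] <- p$baseline_intake_ml
      }

      if (!force_overload) {
        # fluid accumulates after admission and whenever overload goes
        # untreated; a compliant response removes fluid
        drift <- if (respond) -p$overload_drift_kg_per_day
        else if (d == 1L || overload_true) p$overload_drift_kg_per_day
        else 0
        tw <- tw + drift
      }
    }

    list(
      stay = list(patient_id = patient_id, icu_id = p$icu_id,
                  period = p$period, admission_weight_kg = adm,
                  discharge_weight_kg = tw, los_days = los),
      days = list(patient_id = rep(patient_id, los),
                  icu_id = rep(p$icu_id, los),
                  period = rep(p$period, los),
                  day_index = seq_len(los),
                  weight_kg = weight, intake_ml = intake,
                  diuretics_given = diur, ultrafiltration_ml = uf,
                  serum_na_mmol_l = na_v, serum_k_mmol_l = k_v,
                  rifle_level = rifle, hypotension = hypo)
    )
  })
}

#' Simulate a single ICU stay
#'
#' Draws one patient stay under the settings of a single (ICU, period)
#' group. Length of stay is negative-binomial truncated at 3 days (so the
#' stay enters the scoring window). The true weight starts at admission
#' weight and accumulates the configured daily fluid drift whenever
#' overload goes untreated; a compliant response (drawn with probability
#' `p_adhere` on days where overload is *observed*, i.e. the patient was
#' weighed above threshold and not contraindicated) reverses the drift.
#' Response type is drawn from `response_mix`; an intake-restriction
#' response cuts intake clearly below the rule boundary relative to the
#' previous day. Day 1 is always weighed; later days with probability
#' `p_weigh`, recorded with Gaussian measurement noise. Labs and RIFLE
#' level are drawn inside contraindication ranges with daily probability
#' `p_contra`, hypotension with `p_hypo_day`. Discharge weight is the last
#' simulated true weight.
#'
#' @param params A one-row data frame or named list with the columns of
#'   [default_cohort_groups()].
#' @param seed Integer seed for this stay's private RNG substream.
#' @param rules A [scoring_rules()] object.
#' @param response_mix See [cohort_config()].
#' @param force_overload See [cohort_config()].
#' @param patient_id Identifier for the simulated patient.
#' @return A single-patient [fb_cohort()].
#' @export
#' @examples
#' g <- default_cohort_groups()[1, ]
#' simulate_stay(g, seed = 42)
simulate_stay <- function(params, seed,
                          rules = scoring_rules(),
                          response_mix = c(restriction = 0.6,
                                           diuretics = 0.3,
                                           ultrafiltration = 0.1),
                          force_overload = FALSE,
                          patient_id = "pt-001") {
  p <- as.list(params)
  for (col in c("p_weigh", "p_adhere", "p_contra", "p_hypo_day")) {
    if (is.na(p[[col]]) || p[[col]] < 0 || p[[col]] > 1) {
      stop(sprintf("Config error: %s must lie in [0, 1]", col),
           call. = FALSE)
    }
  }
  response_mix <- response_mix / sum(response_mix)
  raw <- simulate_stay_raw(p, seed, rules, response_mix, force_overload,
                           patient_id)
  fb_cohort(tibble::as_tibble(raw$stay), tibble::as_tibble(raw$days))
}

#' Simulate a full multi-ICU cohort
#'
#' Generates `n_patients` stays for every (ICU, period) group of the
#' configuration. Each stay runs on its own RNG substream derived from the
#' master seed and the (ICU, period, patient index) key, so the output is
#' byte-reproducible and insensitive to the order or number of other
#' groups.
#'
#' @param config A [cohort_config()].
#' @param rules A [scoring_rules()] object (the generator uses the same
#'   thresholds the scorer will apply).
#' @return An [fb_cohort()] with unique patient ids across the cohort.
#' @export
#' @examples
#' cfg <- cohort_config(default_cohort_groups(n_patients = 2), seed = 7)
#' simulate_cohort(cfg)
simulate_cohort <- function(config = cohort_config(),
                            rules = scoring_rules()) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- config$groups
  total <- sum(groups$n_patients)
  stays_list <- vector("list", total)
  days_list <- vector("list", total)
  k <- 0L
  for (i in seq_len(nrow(groups))) {
    g <- as.list(groups[i, ])
    for (j in seq_len(g$n_patients)) {
      pid <- sprintf("%s-%s-%04d", g$icu_id, substr(g$period, 1, 3), j)
      s <- derive_seed(config$seed, g$icu_id, g$period, j)
      k <- k + 1L
      raw <- simulate_stay_raw(g, s, rules, config$response_mix,
                               config$force_overload, pid)
      stays_list[[k]] <- raw$stay
      days_list[[k]] <- raw$days
    }
  }
  col <- function(lst, name) unlist(lapply(lst, `[[`, name), use.names = FALSE)
  stays <- tibble::tibble(
    patient_id = col(stays_list, "patient_id"),
    icu_id = col(stays_list, "icu_id"),
    period = col(stays_list, "period"),
    admission_weight_kg = col(stays_list, "admission_weight_kg"),
    discharge_weight_kg = col(stays_list, "discharge_weight_kg"),
    los_days = col(stays_list, "los_days")
  )
  days <- tibble::tibble(
    patient_id = col(days_list, "patient_id"),
    icu_id = col(days_list, "icu_id"),
    period = col(days_list, "period"),
    day_index = col(days_list, "day_index"),
    weight_kg = col(days_list, "weight_kg"),
    intake_ml = col(days_list, "intake_ml"),
    diuretics_given = col(days_list, "diuretics_given"),
    ultrafiltration_ml = col(days_list, "ultrafiltration_ml"),
    serum_na_mmol_l = col(days_list, "serum_na_mmol_l"),
    serum_k_mmol_l = col(days_list, "serum_k_mmol_l"),
    rifle_level = col(days_list, "rifle_level"),
    hypotension = col(days_list, "hypotension")
  )
  fb_cohort(stays, days)
}
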