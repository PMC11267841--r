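#' Daily fluid-overload threshold
#'
#' The weight above which a patient counts as fluid-overloaded on a given
#' ICU day: admission weight + 2 kg on Day 2, admission weight on Days 3-7,
#' admission weight - 2 kg on Days 8-14 (under default rules).
#'
#' @param day_index Integer day(s) since admission; must lie inside the
#'   scoring window.
#' @param admission_weight_kg Admission weight(s) in kg.
#' @param rules A [scoring_rules()] object.
#' @return Numeric threshold(s) in kg.
#' @export
#' @examples
#' day_threshold(c(2, 5, 10), 70)
day_threshold <- function(day_index, admission_weight_kg,
                          rules = scoring_rules()) {
  if (any(day_index < rules$window_start_day |
          day_index > rules$window_end_day)) {
    stop(sprintf("day_index outside the scoring window (Day %d-%d)",
                 rules$window_start_day, rules$window_end_day),
         call. = FALSE)
  }
  offset <- ifelse(
    day_index < rules$mid_band[1], rules$early_offset_kg,
    ifelse(day_index <= rules$mid_band[2], rules$mid_offset_kg,
           rules$late_offset_kg)
  )
  admission_weight_kg + offset
}

#' Tri-state daily overload status
#'
#' `"unknown"` when the patient was not weighed that day, `"overloaded"`
#' when the measured weight strictly exceeds [day_threshold()],
#' `"not_overloaded"` otherwise. A weight exactly at the threshold is not
#' overloaded.
#'
#' @param weight_kg Measured weight(s), `NA` when not weighed.
#' @inheritParams day_threshold
#' @return Character vector in `{"overloaded", "not_overloaded", "unknown"}`.
#' @export
overload_state <- function(weight_kg, day_index, admission_weight_kg,
                           rules = scoring_rules()) {
  thr <- day_threshold(day_index, admission_weight_kg, rules)
  dplyr::case_when(
    is.na(weight_kg) ~ "unknown",
    weight_kg > thr ~ "overloaded",
    TRUE ~ "not_overloaded"
  )
}

#' Daily contraindication to the fluid-restriction strategy
#'
#' A day is contraindicated when any of: arterial hypotension, serum
#' sodium strictly above the cut-off (155 mmol/L by default), serum
#' potassium strictly below the cut-off (2.8 mmol/L), or renal dysfunction
#' at or above the RIFLE contraindication level ("risk"). Missing labs
#' contribute no contraindication.
#'
#' @param hypotension Logical vector.
#' @param serum_na_mmol_l,serum_k_mmol_l Numeric vectors, `NA` allowed.
#' @param rifle_level Character vector of [rifle_levels()].
#' @param rules A [scoring_rules()] object.
#' @return Logical vector.
#' @export
is_contraindicated <- function(hypotension, serum_na_mmol_l,
                               serum_k_mmol_l, rifle_level,
                               rules = scoring_rules()) {
  rifle_min <- rifle_rank(rules$rifle_contraindication_min)
  (hypotension %in% TRUE) |
    (!is.na(serum_na_mmol_l) & serum_na_mmol_l > rules$na_max_mmol_l) |
    (!is.na(serum_k_mmol_l) & serum_k_mmol_l < rules$k_min_mmol_l) |
    (!is.na(rifle_rank(rifle_level)) & rifle_rank(rifle_level) >= rifle_min)
}

#' Daily compliant response to fluid overload
#'
#' A day carries a compliant response when diuretics were prescribed,
#' ultrafiltration was performed, or intake was restricted by at least the
#' rule fraction (30%) relative to the previous day's intake. The
#' restriction branch is unevaluable (false) when the previous day's
#' intake is absent or zero; an intake exactly at the 30% boundary counts
#' as compliant (a 1e-9 ml tolerance absorbs binary rounding of the
#' fraction).
#'
#' @param diuretics_given Logical vector.
#' @param ultrafiltration_ml Non-negative numeric vector.
#' @param intake_ml Intake on the day under scrutiny.
#' @param previous_intake_ml Intake on the previous calendar day; `NA`
#'   when that day is unrecorded.
#' @param rules A [scoring_rules()] object.
#' @return Logical vector.
#' @export
is_compliant_response <- function(diuretics_given, ultrafiltration_ml,
                                  intake_ml, previous_intake_ml,
                                  rules = scoring_rules()) {
  restricted <- !is.na(previous_intake_ml) & previous_intake_ml > 0 &
    intake_ml <= (1 - rules$restriction_fraction) * previous_intake_ml + 1e-9
  (diuretics_given %in% TRUE) | (ultrafiltration_ml > 0) | restricted
}

# per-day scored table for every window day of every patient
scored_days <- function(cohort, rules) {
  w1 <- rules$window_start_day
  w2 <- rules$window_end_day
  prev <- cohort$days |>
    select("patient_id", "day_index", prev_intake_ml = "intake_ml") |>
    mutate(day_index = .data$day_index + 1L)
  cohort$days |>
    inner_join(cohort$stays |> select("patient_id", "admission_weight_kg"),
               by = "patient_id") |>
    filter(.data$day_index >= w1, .data$day_index <= w2) |>
    left_join(prev, by = c("patient_id", "day_index")) |>
    mutate(
      overload = overload_state(.data$weight_kg, .data$day_index,
                                .data$admission_weight_kg, rules),
      contraindicated = is_contraindicated(
        .data$hypotension, .data$serum_na_mmol_l, .data$serum_k_mmol_l,
        .data$rifle_level, rules),
      compliant = is_compliant_response(
        .data$diuretics_given, .data$ultrafiltration_ml, .data$intake_ml,
        .data$prev_intake_ml, rules),
      deviation = .data$overload == "overloaded" &
        !.data$contraindicated & !.data$compliant
    )
}

#' Count protocol deviations per patient
#'
#' A deviation is an overloaded, non-contraindicated window day on which
#' no compliant response (restriction, diuretics, ultrafiltration) was
#' applied. Days without a weigh-in have unknown overload status and can
#' never contribute a deviation. Patients whose stay ends before the
#' scoring window opens return all-zero counters.
#'
#' @param cohort An [fb_cohort()].
#' @param rules A [scoring_rules()] object.
#' @return A tibble with one row per patient: `patient_id`,
#'   `n_deviations`, `n_overload_days`, `n_window_days`,
#'   `n_weighed_window`.
#' @export
#' @examples
#' count_deviations(example_stay())
count_deviations <- function(cohort, rules = scoring_rules()) {
  w1 <- rules$window_start_day
  w2 <- rules$window_end_day
  counts <- scored_days(cohort, rules) |>
    group_by(.data$patient_id) |>
    summarise(
      n_deviations = sum(.data$deviation),
      n_overload_days = sum(.data$overload == "overloaded"),
      n_weighed_window = sum(!is.na(.data$weight_kg)),
      .groups = "drop"
    )
  cohort$stays |>
    select("patient_id", "los_days") |>
    left_join(counts, by = "patient_id") |>
    mutate(
      n_window_days = pmax(0L, pmin(.data$los_days, w2) - w1 + 1L),
      dplyr::across(c("n_deviations", "n_overload_days", "n_weighed_window"),
                    ~ as.integer(ifelse(is.na(.x), 0L, .x)))
    ) |>
    select("patient_id", "n_deviations", "n_overload_days",
           "n_window_days", "n_weighed_window")
}

#' Per-patient score of actual exposure to the strategy
#'
#' For each patient: `raw_score = 100 * (1 - n_deviations / n_window_days)`
#' (the deviation-free rate over the days of the stay inside the Day 2-14
#' scoring window), `weigh_proportion = n_weighed_window / n_window_days`,
#' and `final_score = raw_score * weigh_proportion`, ranging from 0
#' (minimal exposure) to 100 (maximal exposure). Patients whose stay never
#' enters the window get `NA` scores and are excluded from aggregation
#' with a warning downstream.
#'
#' @param cohort An [fb_cohort()].
#' @param rules A [scoring_rules()] object. With
#'   `denominator = "full_los"`, the deviation rate is computed over all
#'   ICU days instead of window days only.
#' @return A tibble with one row per patient: identifiers, the four
#'   deviation counters, `weigh_proportion`, `raw_score`, `final_score`.
#' @export
#' @examples
#' score_exposure(example_stay())$final_score
score_exposure <- function(cohort, rules = scoring_rules()) {
  counts <- count_deviations(cohort, rules)
  cohort$stays |>
    select("patient_id", "icu_id", "period", "los_days") |>
    left_join(counts, by = "patient_id") |>
    mutate(
      denom = if (rules$denominator == "full_los") .data$los_days
              else .data$n_window_days,
      raw_score = ifelse(.data$n_window_days > 0,
                         100 * (1 - .data$n_deviations / .data$denom),
                         NA_real_),
      weigh_proportion = ifelse(.data$n_window_days > 0,
                                .data$n_weighed_window / .data$n_window_days,
                                NA_real_),
      final_score = .data$raw_score * .data$weigh_proportion
    ) |>
    select("patient_id", "icu_id", "period",
           "n_window_days", "n_weighed_window", "n_overload_days",
           "n_deviations", "weigh_proportion", "raw_score", "final_score")
}

#' Exposure score for a single stay
#'
#' Convenience wrapper around [score_exposure()] for a cohort holding
#' exactly one patient.
#'
#' @inheritParams score_exposure
#' @return A one-row tibble.
#' @export
patient_score <- function(cohort, rules = scoring_rules()) {
  if (nrow(cohort$stays) != 1) {
    stop("`patient_score()` expects a cohort with exactly one patient; ",
         "use `score_exposure()` for many.", call. = FALSE)
  }
  score_exposure(cohort, rules)
}

#' Mean exposure score per ICU and period
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of
#' the final exposure score in each (ICU, period) group. Patients with an
#' undefined score (stay ending before the scoring window) are dropped
#' with a warning; groups of size one get `NA` standard deviation.
#'
#' @param exposure Output of [score_exposure()].
#' @return A tibble: `icu_id`, `period`, `n`, `score_mean`, `score_sd`.
#' @export
icu_period_score <- function(exposure) {
  undefined <- is.na(exposure$final_score)
  if (any(undefined)) {
    warning(sprintf("%d patient(s) with undefined exposure score excluded from aggregation",
                    sum(undefined)), call. = FALSE)
  }
  exposure |>
    filter(!is.na(.data$final_score)) |>
    group_by(.data$icu_id, .data$period) |>
    summarise(
      n = dplyr::n(),
      score_mean = mean(.data$final_score),
      score_sd = sd(.data$final_score),
      .groups = "drop"
    )
}
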