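#' Strategy reach
#'
#' Included patients as a percentage of expected enrolment.
#'
#' @param n_included,n_expected Non-negative counts; `n_expected` must be
#'   at least 1. Vectorised.
#' @return `100 * n_included / n_expected`.
#' @export
#' @examples
#' reach(43, 30)
reach <- function(n_included, n_expected) {
  if (any(n_expected < 1)) {
    stop("`n_expected` must be >= 1", call. = FALSE)
  }
  100 * n_included / n_expected
}

#' Weekly weigh-ins per patient
#'
#' Number of days with a recorded weight, rescaled to a 7-day week over
#' the full ICU stay.
#'
#' @param cohort An [fb_cohort()].
#' @return A tibble: `patient_id`, `icu_id`, `period`, `n_weighed`,
#'   `weekly_weighins`.
#' @export
weekly_weighins <- function(cohort) {
  weighed <- cohort$days |>
    group_by(.data$patient_id) |>
    summarise(n_weighed = sum(!is.na(.data$weight_kg)), .groups = "drop")
  cohort$stays |>
    select("patient_id", "icu_id", "period", "los_days") |>
    left_join(weighed, by = "patient_id") |>
    mutate(n_weighed = ifelse(is.na(.data$n_weighed), 0L, .data$n_weighed),
           weekly_weighins = 7 * .data$n_weighed / .data$los_days) |>
    select("patient_id", "icu_id", "period", "n_weighed", "weekly_weighins")
}

#' Achieved over expected weighing, per patient
#'
#' Percentage of performed weigh-ins relative to the number the period's
#' protocol calls for. In the intervention period daily weighing is
#' expected on every day of the stay inside the Day 2-14 scoring window,
#' and achieved weigh-ins are counted over those days. In the control
#' period the standard of care is weekly weighing: one weigh-in is
#' expected per started 7-day block of the stay and all weigh-ins of the
#' stay count, so values far above 100% indicate weighing beyond the
#' standard of care. Patients with zero expected weigh-ins (an
#' intervention stay ending before the window opens) get `NA` and a
#' warning.
#'
#' @param cohort An [fb_cohort()].
#' @param rules A [scoring_rules()] object (defines the window).
#' @return A tibble: `patient_id`, `icu_id`, `period`, `achieved`,
#'   `expected`, `achieved_expected_pct`.
#' @export
weighing_achieved_expected <- function(cohort, rules = scoring_rules()) {
  w1 <- rules$window_start_day
  w2 <- rules$window_end_day
  counts <- cohort$days |>
    group_by(.data$patient_id) |>
    summarise(
      n_weighed_stay = sum(!is.na(.data$weight_kg)),
      n_weighed_window = sum(!is.na(.data$weight_kg) &
                               .data$day_index >= w1 & .data$day_index <= w2),
      .groups = "drop"
    )
  out <- cohort$stays |>
    select("patient_id", "icu_id", "period", "los_days") |>
    left_join(counts, by = "patient_id") |>
    mutate(
      dplyr::across(c("n_weighed_stay", "n_weighed_window"),
                    ~ ifelse(is.na(.x), 0L, .x)),
      n_window_days = pmax(0L, pmin(.data$los_days, w2) - w1 + 1L),
      expected = ifelse(.data$period == "intervention",
                        .data$n_window_days,
                        ceiling(.data$los_days / 7)),
      achieved = ifelse(.data$period == "intervention",
                        .data$n_weighed_window, .data$n_weighed_stay),
      achieved_expected_pct = ifelse(.data$expected > 0,
                                     100 * .data$achieved / .data$expected,
                                     NA_real_)
    ) |>
    select("patient_id", "icu_id", "period", "achieved", "expected",
           "achieved_expected_pct")
  if (any(is.na(out$achieved_expected_pct))) {
    warning(sprintf("%d patient(s) with zero expected weigh-ins excluded (NA)",
                    sum(is.na(out$achieved_expected_pct))), call. = FALSE)
  }
  out
}

#' Proportion of patients with at least one hypotension episode
#'
#' At-least-one semantics over the whole ICU stay: a patient with several
#' hypotensive days counts once.
#'
#' @param cohort An [fb_cohort()].
#' @return A tibble per (ICU, period): `hypotension_pct`,
#'   `hypotension_n`, group size `n`.
#' @export
hypotension_proportion <- function(cohort) {
  any_hypo <- cohort$days |>
    group_by(.data$patient_id) |>
    summarise(any_hypotension = any(.data$hypotension), .groups = "drop")
  cohort$stays |>
    select("patient_id", "icu_id", "period") |>
    left_join(any_hypo, by = "patient_id") |>
    mutate(any_hypotension = .data$any_hypotension %in% TRUE) |>
    group_by(.data$icu_id, .data$period) |>
    summarise(
      n = dplyr::n(),
      hypotension_n = sum(.data$any_hypotension),
      hypotension_pct = 100 * .data$hypotension_n / .data$n,
      .groups = "drop"
    )
}

#' Weight change between ICU admission and discharge
#'
#' `discharge_weight_kg - admission_weight_kg`, `NA` (excluded from
#' aggregation) when the discharge weight is missing.
#'
#' @param cohort An [fb_cohort()].
#' @return A tibble: `patient_id`, `icu_id`, `period`,
#'   `weight_change_kg`.
#' @export
weight_change <- function(cohort) {
  cohort$stays |>
    mutate(weight_change_kg =
             .data$discharge_weight_kg - .data$admission_weight_kg) |>
    select("patient_id", "icu_id", "period", "weight_change_kg")
}

#' Per-ICU, per-period process-evaluation summary
#'
#' Assembles one row per (ICU, period): group size, reach, weekly
#' weigh-ins (mean, SD over patients), achieved/expected weighing (mean
#' over patients), exposure score (mean, SD), proportion and count of
#' patients with at least one hypotension episode, and admission-discharge
#' weight change (mean, SD). SDs are sample SDs and `NA` for single-patient
#' groups.
#'
#' @param cohort An [fb_cohort()].
#' @param enrolment A data frame `icu_id`, `period`, `n_expected` giving
#'   planned enrolment per group; its groups must match the cohort's
#'   exactly.
#' @param rules A [scoring_rules()] object.
#' @param exposure Optional precomputed [score_exposure()] output.
#' @return A tibble with one row per (ICU, period).
#' @export
summarize_cohort <- function(cohort, enrolment,
                             rules = scoring_rules(),
                             exposure = NULL) {
  if (is.null(exposure)) exposure <- score_exposure(cohort, rules)

  gkey <- function(df) sort(unique(paste(df$icu_id, df$period, sep = "/")))
  only_stays <- setdiff(gkey(cohort$stays), gkey(enrolment))
  only_enrol <- setdiff(gkey(enrolment), gkey(cohort$stays))
  if (length(only_stays) > 0 || length(only_enrol) > 0) {
    stop("Integrity error: (icu_id, period) groups differ between cohort and enrolment: ",
         paste(c(only_stays, only_enrol), collapse = ", "), call. = FALSE)
  }

  ww <- weekly_weighins(cohort) |>
    group_by(.data$icu_id, .data$period) |>
    summarise(weekly_weighins_mean = mean(.data$weekly_weighins),
              weekly_weighins_sd = sd(.data$weekly_weighins),
              .groups = "drop")
  ae <- weighing_achieved_expected(cohort, rules) |>
    group_by(.data$icu_id, .data$period) |>
    summarise(weighing_achieved_expected_pct =
                mean(.data$achieved_expected_pct, na.rm = TRUE),
              .groups = "drop")
  sc <- icu_period_score(exposure) |>
    select("icu_id", "period", "score_mean", "score_sd")
  hp <- hypotension_proportion(cohort)
  wc <- weight_change(cohort) |>
    group_by(.data$icu_id, .data$period) |>
    summarise(weight_change_mean_kg =
                mean(.data$weight_change_kg, na.rm = TRUE),
              weight_change_sd_kg = sd_narm(.data$weight_change_kg),
              .groups = "drop")

  hp |>
    left_join(tibble::as_tibble(enrolment), by = c("icu_id", "period")) |>
    mutate(reach_pct = reach(.data$n, .data$n_expected)) |>
    left_join(ww, by = c("icu_id", "period")) |>
    left_join(ae, by = c("icu_id", "period")) |>
    left_join(sc, by = c("icu_id", "period")) |>
    left_join(wc, by = c("icu_id", "period")) |>
    select("icu_id", "period", "n", "n_expected", "reach_pct",
           "weekly_weighins_mean", "weekly_weighins_sd",
           "weighing_achieved_expected_pct", "score_mean", "score_sd",
           "hypotension_pct", "hypotension_n",
           "weight_change_mean_kg", "weight_change_sd_kg") |>
    arrange(.data$icu_id, .data$period)
}

# sample sd ignoring NAs; NA when fewer than two observations remain
sd_narm <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) NA_real_ else sd(x)
}
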