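#' Ordered RIFLE renal-dysfunction levels
#'
#' Severity staging of acute kidney injury used by the contraindication
#' rule of the exposure score, ordered from no dysfunction to end-stage
#' kidney disease.
#'
#' @return Character vector `c("none", "risk", "injury", "failure",
#'   "loss", "eskd")`, in increasing severity order.
#' @export
#' @examples
#' rifle_levels()
rifle_levels <- function() {
  c("none", "risk", "injury", "failure", "loss", "eskd")
}

# integer severity rank; NA for unknown strings
rifle_rank <- function(x) {
  match(x, rifle_levels())
}

#' Scoring rules for the exposure-to-strategy score
#'
#' Bundles every numeric constant of the exposure score: the scoring window
#' (Day 2 to Day 14 after ICU admission, Day 1 = admission day), the
#' day-banded overload thresholds relative to admission weight (+2 kg on
#' Day 2, +0 kg on Days 3-7, -2 kg on Days 8-14), the minimum intake
#' restriction counting as a compliant response (30% relative to the
#' previous day), and the contraindication cut-offs (serum sodium
#' > 155 mmol/L, serum potassium < 2.8 mmol/L, renal dysfunction at or
#' above the RIFLE "risk" level, or arterial hypotension).
#'
#' @param window_start_day,window_end_day Inclusive integer bounds of the
#'   scoring window in days since admission.
#' @param early_offset_kg Offset added to admission weight on the first
#'   window day (Day 2).
#' @param mid_offset_kg,late_offset_kg Offsets for the middle and late
#'   day bands.
#' @param mid_band,late_band Length-2 integer vectors giving the inclusive
#'   day ranges of the middle and late bands. Together with the first
#'   window day they must tile the window contiguously.
#' @param restriction_fraction Minimum fractional reduction of intake
#'   relative to the previous day that counts as a compliant restriction
#'   response; strictly between 0 and 1.
#' @param na_max_mmol_l Serum sodium above which restriction is
#'   contraindicated (strict inequality).
#' @param k_min_mmol_l Serum potassium below which restriction is
#'   contraindicated (strict inequality).
#' @param rifle_contraindication_min Minimum RIFLE level (inclusive) that
#'   contraindicates the strategy; one of [rifle_levels()].
#' @param denominator Denominator for the deviation rate: `"window"`
#'   (days of the stay inside the scoring window, the default) or
#'   `"full_los"` (all days of the ICU stay).
#'
#' @return An object of class `scoring_rules` (a named list).
#' @export
#' @examples
#' rules <- scoring_rules()
#' rules$restriction_fraction
scoring_rules <- function(window_start_day = 2L,
                          window_end_day = 14L,
                          early_offset_kg = 2,
                          mid_offset_kg = 0,
                          late_offset_kg = -2,
                          mid_band = c(3L, 7L),
                          late_band = c(8L, 14L),
                          restriction_fraction = 0.30,
                          na_max_mmol_l = 155,
                          k_min_mmol_l = 2.8,
                          rifle_contraindication_min = "risk",
                          denominator = c("window", "full_los")) {
  denominator <- match.arg(denominator)
  window_start_day <- as.integer(window_start_day)
  window_end_day <- as.integer(window_end_day)
  mid_band <- as.integer(mid_band)
  late_band <- as.integer(late_band)
  if (window_start_day >= window_end_day) {
    stop("`window_start_day` must be smaller than `window_end_day`.",
         call. = FALSE)
  }
  if (!(restriction_fraction > 0 && restriction_fraction < 1)) {
    stop("`restriction_fraction` must lie strictly between 0 and 1.",
         call. = FALSE)
  }
  if (!rifle_contraindication_min %in% rifle_levels()) {
    stop("`rifle_contraindication_min` must be one of: ",
         paste(rifle_levels(), collapse = ", "), call. = FALSE)
  }
  # the early day plus the two bands must tile the window contiguously
  if (mid_band[1] != window_start_day + 1L ||
      late_band[1] != mid_band[2] + 1L ||
      late_band[2] != window_end_day) {
    stop("Day bands must partition the scoring window: ",
         "first window day, then `mid_band`, then `late_band`.",
         call. = FALSE)
  }
  structure(
    list(
      window_start_day = window_start_day,
      window_end_day = window_end_day,
      early_offset_kg = early_offset_kg,
      mid_offset_kg = mid_offset_kg,
      late_offset_kg = late_offset_kg,
      mid_band = mid_band,
      late_band = late_band,
      restriction_fraction = restriction_fraction,
      na_max_mmol_l = na_max_mmol_l,
      k_min_mmol_l = k_min_mmol_l,
      rifle_contraindication_min = rifle_contraindication_min,
      denominator = denominator
    ),
    class = "scoring_rules"
  )
}

#' @export
print.scoring_rules <- function(x, ...) {
  cat("<scoring_rules>\n")
  cat(sprintf("  window: Day %d-%d (Day 1 = admission)\n",
              x$window_start_day, x$window_end_day))
  cat(sprintf("  overload thresholds: admission %+g kg (Day %d), %+g kg (Days %d-%d), %+g kg (Days %d-%d)\n",
              x$early_offset_kg, x$window_start_day,
              x$mid_offset_kg, x$mid_band[1], x$mid_band[2],
              x$late_offset_kg, x$late_band[1], x$late_band[2]))
  cat(sprintf("  compliant restriction: >= %d%% intake reduction vs previous day\n",
              round(100 * x$restriction_fraction)))
  cat(sprintf("  contraindications: hypotension, Na > %g mmol/L, K < %g mmol/L, RIFLE >= %s\n",
              x$na_max_mmol_l, x$k_min_mmol_l, x$rifle_contraindication_min))
  cat(sprintf("  deviation-rate denominator: %s\n", x$denominator))
  invisible(x)
}
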