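#' @importFrom rlang %||% .data
#' @importFrom dplyr
#'   arrange bind_rows case_when filter group_by inner_join left_join mutate
#'   n rename select summarise ungroup
#' @importFrom stats rnbinom rnorm runif sd
NULL

day_columns <- function() {
  c("patient_id", "icu_id", "period", "day_index", "weight_kg",
    "intake_ml", "diuretics_given", "ultrafiltration_ml",
    "serum_na_mmol_l", "serum_k_mmol_l", "rifle_level", "hypotension")
}

stay_columns <- function() {
  c("patient_id", "icu_id", "period", "admission_weight_kg",
    "discharge_weight_kg", "los_days")
}

periods <- function() c("control", "intervention")

#' Assemble a validated patient-day cohort
#'
#' A cohort holds two linked tables: `stays` (one row per patient:
#' admission/discharge weight, length of stay, ICU and trial period) and
#' `days` (one row per patient per ICU day: measured weight, intake volume,
#' treatments, labs, RIFLE level, hypotension flag). An absent weight means
#' the patient was not weighed that day; absent labs mean not measured.
#'
#' @param stays Data frame with columns `patient_id`, `icu_id`, `period`
#'   (`"control"` or `"intervention"`), `admission_weight_kg`,
#'   `discharge_weight_kg` (may be `NA`), `los_days`.
#' @param days Data frame with columns `patient_id`, `icu_id`, `period`,
#'   `day_index` (1-based, Day 1 = admission day), `weight_kg` (`NA` if not
#'   weighed), `intake_ml` (oral + parenteral volume excluding vascular
#'   filling), `diuretics_given`, `ultrafiltration_ml`, `serum_na_mmol_l`,
#'   `serum_k_mmol_l`, `rifle_level` (one of [rifle_levels()]),
#'   `hypotension`.
#' @param validate Run [validate_cohort()] (default `TRUE`).
#'
#' @return An object of class `fb_cohort`: a list with elements `stays`
#'   and `days`, days sorted by patient and day index.
#' @export
fb_cohort <- function(stays, days, validate = TRUE) {
  stays <- tibble::as_tibble(stays)
  days <- tibble::as_tibble(days) |> arrange(.data$patient_id, .data$day_index)
  out <- structure(list(stays = stays, days = days), class = "fb_cohort")
  if (validate) validate_cohort(out)
  out
}

#' @export
print.fb_cohort <- function(x, ...) {
  cat(sprintf("<fb_cohort> %d patients, %d patient-days, %d ICU(s)\n",
              nrow(x$stays), nrow(x$days), length(unique(x$stays$icu_id))))
  invisible(x)
}

#' Validate a patient-day cohort against the data-model invariants
#'
#' Checks column presence, value domains (non-negative volumes, positive
#' admission weight, RIFLE membership, period membership), uniqueness of
#' `(patient_id, day_index)`, `day_index <= los_days`, and agreement of
#' `icu_id`/`period` between the day and stay tables. Errors name the
#' offending column or the first offending row.
#'
#' @param cohort An [fb_cohort()] or a list with `stays` and `days`.
#' @return Invisibly `TRUE`; otherwise an error.
#' @export
validate_cohort <- function(cohort) {
  stays <- cohort$stays
  days <- cohort$days

  missing_s <- setdiff(stay_columns(), names(stays))
  if (length(missing_s) > 0) {
    stop("Schema error: stay table is missing column(s): ",
         paste(missing_s, collapse = ", "), call. = FALSE)
  }
  missing_d <- setdiff(day_columns(), names(days))
  if (length(missing_d) > 0) {
    stop("Schema error: day table is missing column(s): ",
         paste(missing_d, collapse = ", "), call. = FALSE)
  }

  first_bad <- function(bad) which(bad)[1]

  if (any(bad <- !stays$period %in% periods())) {
    stop(sprintf("Validation error: stay row %d has period '%s'; must be one of: %s",
                 first_bad(bad), stays$period[first_bad(bad)],
                 paste(periods(), collapse = ", ")), call. = FALSE)
  }
  if (any(bad <- !days$period %in% periods())) {
    stop(sprintf("Validation error: day row %d has an invalid period",
                 first_bad(bad)), call. = FALSE)
  }
  if (any(bad <- is.na(stays$admission_weight_kg) | stays$admission_weight_kg <= 0)) {
    stop(sprintf("Validation error: stay row %d has non-positive admission weight",
                 first_bad(bad)), call. = FALSE)
  }
  if (any(bad <- is.na(stays$los_days) | stays$los_days < 1)) {
    stop(sprintf("Validation error: stay row %d has los_days < 1",
                 first_bad(bad)), call. = FALSE)
  }
  if (anyDuplicated(stays$patient_id) > 0) {
    stop(sprintf("Integrity error: duplicated patient_id '%s' in stay table",
                 stays$patient_id[anyDuplicated(stays$patient_id)]),
         call. = FALSE)
  }

  if (any(bad <- is.na(days$day_index) | days$day_index < 1)) {
    stop(sprintf("Validation error: day row %d has day_index < 1",
                 first_bad(bad)), call. = FALSE)
  }
  key <- paste(days$patient_id, days$day_index, sep = "\r")
  if (anyDuplicated(key) > 0) {
    i <- anyDuplicated(key)
    stop(sprintf("Integrity error: duplicate (patient_id, day_index) = ('%s', %d)",
                 days$patient_id[i], days$day_index[i]), call. = FALSE)
  }
  for (col in c("intake_ml", "ultrafiltration_ml")) {
    v <- days[[col]]
    if (any(bad <- is.na(v) | v < 0)) {
      stop(sprintf("Validation error: day row %d has negative or missing %s",
                   first_bad(bad), col), call. = FALSE)
    }
  }
  if (any(bad <- !is.na(days$weight_kg) & days$weight_kg < 0)) {
    stop(sprintf("Validation error: day row %d has negative weight_kg",
                 first_bad(bad)), call. = FALSE)
  }
  if (any(bad <- !is.na(days$serum_na_mmol_l) & days$serum_na_mmol_l <= 0)) {
    stop(sprintf("Validation error: day row %d has non-positive serum sodium",
                 first_bad(bad)), call. = FALSE)
  }
  if (any(bad <- !is.na(days$serum_k_mmol_l) & days$serum_k_mmol_l <= 0)) {
    stop(sprintf("Validation error: day row %d has non-positive serum potassium",
                 first_bad(bad)), call. = FALSE)
  }
  if (any(bad <- !days$rifle_level %in% rifle_levels())) {
    stop(sprintf("Validation error: day row %d has rifle_level '%s'; must be one of: %s",
                 first_bad(bad), days$rifle_level[first_bad(bad)],
                 paste(rifle_levels(), collapse = ", ")), call. = FALSE)
  }

  # cross-table agreement
  chk <- days |>
    left_join(
      stays |> select("patient_id",
                      stay_icu = "icu_id", stay_period = "period",
                      "los_days"),
      by = "patient_id"
    )
  if (any(bad <- is.na(chk$los_days))) {
    stop(sprintf("Integrity error: day row %d refers to patient_id '%s' absent from the stay table",
                 first_bad(bad), chk$patient_id[first_bad(bad)]), call. = FALSE)
  }
  if (any(bad <- chk$icu_id != chk$stay_icu | chk$period != chk$stay_period)) {
    stop(sprintf("Integrity error: day row %d disagrees with the stay table on icu_id/period",
                 first_bad(bad)), call. = FALSE)
  }
  if (any(bad <- chk$day_index > chk$los_days)) {
    stop(sprintf("Integrity error: day row %d has day_index beyond los_days",
                 first_bad(bad)), call. = FALSE)
  }
  invisible(TRUE)
}

# coerce freshly read columns to canonical types
canonicalize_days <- function(days) {
  days |> mutate(
    patient_id = as.character(.data$patient_id),
    icu_id = as.character(.data$icu_id),
    period = as.character(.data$period),
    day_index = as.integer(.data$day_index),
    weight_kg = as.numeric(.data$weight_kg),
    intake_ml = as.numeric(.data$intake_ml),
    diuretics_given = as.logical(.data$diuretics_given),
    ultrafiltration_ml = as.numeric(.data$ultrafiltration_ml),
    serum_na_mmol_l = as.numeric(.data$serum_na_mmol_l),
    serum_k_mmol_l = as.numeric(.data$serum_k_mmol_l),
    rifle_level = as.character(.data$rifle_level),
    hypotension = as.logical(.data$hypotension)
  )
}

canonicalize_stays <- function(stays) {
  stays |> mutate(
    patient_id = as.character(.data$patient_id),
    icu_id = as.character(.data$icu_id),
    period = as.character(.data$period),
    admission_weight_kg = as.numeric(.data$admission_weight_kg),
    discharge_weight_kg = as.numeric(.data$discharge_weight_kg),
    los_days = as.integer(.data$los_days)
  )
}

apply_schema <- function(df, schema, required, what) {
  if (!is.null(schema)) {
    # schema maps canonical name -> file column name
    for (canon in names(schema)) {
      file_col <- schema[[canon]]
      if (!file_col %in% names(df)) {
        stop(sprintf("Schema error: %s file has no column '%s' (mapped to '%s')",
                     what, file_col, canon), call. = FALSE)
      }
      names(df)[names(df) == file_col] <- canon
    }
  }
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("Schema error: %s file is missing mandatory column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read a patient-day cohort from delimited text
#'
#' Reads the stay-level and day-level CSV files (comma separated, UTF-8,
#' period decimal mark; lines starting with `#` are treated as provenance
#' comments and skipped), applies an optional column-name mapping, and
#' returns a validated cohort. Empty weight or lab cells become missing
#' values, never zero.
#'
#' @param stays_path,days_path Paths to the two CSV files.
#' @param stays_schema,days_schema Optional named character vectors mapping
#'   canonical column names to the names used in the file, e.g.
#'   `c(weight_kg = "poids")`.
#' @return A validated [fb_cohort()].
#' @export
read_cohort <- function(stays_path, days_path,
                        stays_schema = NULL, days_schema = NULL) {
  stays <- readr::read_csv(stays_path, comment = "#",
                           show_col_types = FALSE, progress = FALSE)
  days <- readr::read_csv(days_path, comment = "#",
                          show_col_types = FALSE, progress = FALSE)
  stays <- apply_schema(stays, stays_schema, stay_columns(), "stay") |>
    canonicalize_stays()
  days <- apply_schema(days, days_schema, day_columns(), "day") |>
    canonicalize_days()
  fb_cohort(stays, days)
}

write_csv_provenance <- function(df, path, provenance = NULL) {
  if (!is.null(provenance)) {
    writeLines(paste0("# ", provenance), path)
    readr::write_csv(df, path, append = TRUE, col_names = TRUE,
                     progress = FALSE)
  } else {
    readr::write_csv(df, path, progress = FALSE)
  }
  invisible(path)
}

#' Write a cohort to a pair of CSV files
#'
#' Inverse of [read_cohort()]: values round-trip losslessly (doubles are
#' written with full precision).
#'
#' @param cohort An [fb_cohort()].
#' @param stays_path,days_path Output paths.
#' @param provenance Optional single string written as a leading `#`
#'   comment line on both files (e.g. seed and configuration hash).
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, stays_path, days_path, provenance = NULL) {
  write_csv_provenance(cohort$stays, stays_path, provenance)
  write_csv_provenance(cohort$days, days_path, provenance)
  invisible(c(stays_path, days_path))
}

#' Write the per-ICU, per-period summary table
#'
#' One row per (ICU, period) with the reach, weighing, exposure-score,
#' hypotension and weight-change statistics. Refuses empty input and
#' duplicated (ICU, period) keys.
#'
#' @param rows Data frame as produced by [summarize_cohort()].
#' @param path Output CSV path.
#' @param provenance Optional `#` comment line content.
#' @return Invisibly, `path`.
#' @export
write_summary_table <- function(rows, path, provenance = NULL) {
  if (is.null(rows) || nrow(rows) == 0) {
    stop("Integrity error: summary table is empty.", call. = FALSE)
  }
  key <- paste(rows$icu_id, rows$period, sep = "\r")
  if (anyDuplicated(key) > 0) {
    i <- anyDuplicated(key)
    stop(sprintf("Integrity error: duplicate (icu_id, period) = ('%s', '%s')",
                 rows$icu_id[i], rows$period[i]), call. = FALSE)
  }
  write_csv_provenance(rows, path, provenance)
}

#' Read a summary table written by [write_summary_table()]
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_summary_table <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' A small fully worked example stay
#'
#' One patient admitted at 70 kg with a five-day stay: overloaded without
#' any protocol response on Day 2 (one deviation), overloaded but treated
#' with diuretics on Day 3, below threshold on Day 4, and overloaded but
#' hypotensive (contraindicated) on Day 5. Weighed on every window day.
#' Its exposure score decomposes to 1 deviation over 4 window days, a
#' weigh-in proportion of 1, and a final score of 75.
#'
#' @return An [fb_cohort()] with a single stay.
#' @export
#' @examples
#' score_exposure(example_stay())
example_stay <- function() {
  stays <- tibble::tibble(
    patient_id = "pt-01", icu_id = "A", period = "intervention",
    admission_weight_kg = 70, discharge_weight_kg = 71, los_days = 5L
  )
  days <- tibble::tibble(
    patient_id = "pt-01", icu_id = "A", period = "intervention",
    day_index = 1:5,
    weight_kg = c(70, 73, 71, 69.5, 71),
    intake_ml = c(2000, 1500, 2200, 2000, 1800),
    diuretics_given = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    ultrafiltration_ml = 0,
    serum_na_mmol_l = 140,
    serum_k_mmol_l = 4.0,
    rifle_level = "none",
    hypotension = c(FALSE, FALSE, FALSE, FALSE, TRUE)
  )
  fb_cohort(stays, days)
}
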