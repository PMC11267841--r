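test_that("reach is included over expected, as a percentage", {
  expect_equal(round(reach(43, 30), 1), 143.3)
  expect_equal(reach(30, 30), 100)
  expect_equal(reach(0, 30), 0)
  expect_error(reach(10, 0), "n_expected")
})

test_that("weekly weigh-ins rescale weighing counts to a 7-day week", {
  co <- fb_cohort(
    dplyr::bind_rows(
      make_stay("daily", los_days = 14),
      make_stay("sparse", los_days = 14),
      make_stay("weekly", los_days = 7)
    ),
    dplyr::bind_rows(
      make_days("daily", 1:14, weight_kg = 70),
      make_days("sparse", 1:14,
                weight_kg = c(70, 70, NA, NA, 70, NA, NA, 70,
                              rep(NA_real_, 6))),
      make_days("weekly", 1:7, weight_kg = c(70, rep(NA_real_, 6)))
    )
  )
  ww <- weekly_weighins(co)
  expect_equal(ww$weekly_weighins[ww$patient_id == "daily"], 7)
  expect_equal(ww$weekly_weighins[ww$patient_id == "sparse"], 2)
  expect_equal(ww$weekly_weighins[ww$patient_id == "weekly"], 1)
})

test_that("achieved/expected weighing uses period-specific expectations", {
  co <- fb_cohort(
    dplyr::bind_rows(
      make_stay("iv", los_days = 10, period = "intervention"),
      make_stay("ct", los_days = 14, period = "control"),
      make_stay("none", los_days = 14, period = "control")
    ),
    dplyr::bind_rows(
      # intervention: weighed on every window day of a 10-day stay
      make_days("iv", 1:10, period = "intervention",
                weight_kg = c(NA, rep(70, 9))),
      # control: 8 weigh-ins over 14 days, weekly expectation of 2
      make_days("ct", 1:14,
                weight_kg = c(rep(70, 8), rep(NA_real_, 6))),
      make_days("none", 1:14, weight_kg = NA_real_)
    )
  )
  ae <- weighing_achieved_expected(co)
  expect_equal(ae$achieved_expected_pct[ae$patient_id == "iv"], 100)
  expect_equal(ae$expected[ae$patient_id == "ct"], 2)
  expect_equal(ae$achieved_expected_pct[ae$patient_id == "ct"], 400)
  expect_equal(ae$achieved_expected_pct[ae$patient_id == "none"], 0)

  # intervention stay ending before the window opens has no expectation
  co1 <- fb_cohort(
    make_stay("short", los_days = 1, period = "intervention"),
    make_days("short", 1, weight_kg = 70, period = "intervention")
  )
  expect_warning(ae1 <- weighing_achieved_expected(co1), "zero expected")
  expect_true(is.na(ae1$achieved_expected_pct))
})

test_that("hypotension proportion uses at-least-one semantics", {
  co <- fb_cohort(
    dplyr::bind_rows(lapply(1:4, function(i) {
      make_stay(paste0("p", i), los_days = 5)
    })),
    dplyr::bind_rows(
      make_days("p1", 1:5, hypotension = TRUE),   # 5 episodes count once
      make_days("p2", 1:5, hypotension = c(FALSE, TRUE, rep(FALSE, 3))),
      make_days("p3", 1:5),
      make_days("p4", 1:5)
    )
  )
  hp <- hypotension_proportion(co)
  expect_equal(hp$hypotension_pct, 50)
  expect_equal(hp$hypotension_n, 2L)
})

test_that("weight change is discharge minus admission, NA-safe", {
  co <- fb_cohort(
    dplyr::bind_rows(
      make_stay("down", 70, discharge_weight_kg = 68, los_days = 3),
      make_stay("flat", 70, discharge_weight_kg = 70, los_days = 3),
      make_stay("unknown", 70, los_days = 3)
    ),
    dplyr::bind_rows(lapply(c("down", "flat", "unknown"), function(id) {
      make_days(id, 1:3, weight_kg = 70)
    }))
  )
  wc <- weight_change(co)
  expect_equal(wc$weight_change_kg[wc$patient_id == "down"], -2)
  expect_equal(wc$weight_change_kg[wc$patient_id == "flat"], 0)
  expect_true(is.na(wc$weight_change_kg[wc$patient_id == "unknown"]))
})

test_that("Cohen's kappa matches the closed form and its symmetries", {
  a <- rep(c("x", "y"), c(50, 50))
  b <- rep(c("x", "y", "x", "y"), c(45, 5, 15, 35))
  # agreement table (45, 5; 15, 35): p_o = 0.8, p_e = 0.5, kappa = 0.6
  expect_equal(cohens_kappa(a, b), 0.6, tolerance = 1e-12)

  expect_identical(cohens_kappa(a, a), 1)
  expect_equal(cohens_kappa(a, b), cohens_kappa(b, a))

  set.seed(4)
  perm <- sample(length(a))
  expect_equal(cohens_kappa(a[perm], b[perm]), cohens_kappa(a, b))

  # one coder constant, the other independent 50/50: chance-level agreement
  set.seed(7)
  flips <- sample(c("x", "y"), 2000, replace = TRUE)
  expect_lt(abs(cohens_kappa(rep("x", 2000), flips)), 0.05)

  expect_error(cohens_kappa(a, b[-1]), "same length")
  expect_error(cohens_kappa(character(0), character(0)), "non-empty")
})

test_that("a hand-built two-patient group reproduces spreadsheet statistics", {
  co <- fb_cohort(
    dplyr::bind_rows(
      make_stay("h1", 70, discharge_weight_kg = 67, los_days = 7,
                icu_id = "Z", period = "intervention"),
      make_stay("h2", 80, discharge_weight_kg = 81, los_days = 14,
                icu_id = "Z", period = "intervention")
    ),
    dplyr::bind_rows(
      # h1: weighed daily, overloaded on days 2-3 only, treated on day 3
      make_days("h1", 1:7, icu_id = "Z", period = "intervention",
                weight_kg = c(70, 73, 71, 69, 69, 68, 67),
                diuretics_given = c(rep(FALSE, 2), TRUE, rep(FALSE, 4))),
      # h2: weighed on 7 of 13 window days, one hypotensive day,
      # overloaded-untreated on days 8 and 10
      make_days("h2", 1:14, icu_id = "Z", period = "intervention",
                weight_kg = c(80, 81, NA, 80, NA, 80, NA, 79.5, NA, 79,
                              NA, NA, 77, 81),
                hypotension = c(rep(FALSE, 13), TRUE))
    )
  )
  enrol <- tibble::tibble(icu_id = "Z", period = "intervention",
                          n_expected = 4L)
  sm <- summarize_cohort(co, enrol)

  # hand-computed: h1 score 100*(1-1/6)*1,  h2 score 100*(1-2/13)*(7/13)
  s1 <- 100 * (1 - 1 / 6)
  s2 <- 100 * (1 - 2 / 13) * (7 / 13)
  expect_equal(sm$score_mean, mean(c(s1, s2)))
  expect_equal(sm$score_sd, sd(c(s1, s2)))
  expect_equal(sm$reach_pct, 50)
  expect_equal(sm$weekly_weighins_mean, mean(c(7, 7 * 8 / 14)))
  expect_equal(sm$weighing_achieved_expected_pct,
               mean(c(100, 100 * 7 / 13)))
  expect_equal(sm$hypotension_pct, 50)
  expect_equal(sm$hypotension_n, 1L)
  expect_equal(sm$weight_change_mean_kg, mean(c(-3, 1)))
  expect_equal(sm$weight_change_sd_kg, sd(c(-3, 1)))

  # single-patient groups flag SDs as NA
  co1 <- fb_cohort(co$stays[1, ], dplyr::filter(co$days, patient_id == "h1"))
  sm1 <- summarize_cohort(co1, dplyr::mutate(enrol, n_expected = 2L))
  expect_true(is.na(sm1$score_sd))
  expect_true(is.na(sm1$weekly_weighins_sd))

  # mismatched groups are an integrity error naming the group
  expect_error(
    summarize_cohort(co, tibble::tibble(icu_id = "Q", period = "control",
                                        n_expected = 4L)),
    "Q/control|Z/intervention"
  )
})

test_that("summary statistics match a naive two-pass oracle", {
  co <- simulate_cohort(
    cohort_config(default_cohort_groups(n_patients = 8), seed = 77)
  )
  enrol <- default_cohort_groups(n_patients = 8)[, c("icu_id", "period", "n_expected")]
  sm <- summarize_cohort(co, enrol)

  # naive recomputation for one group, straight from the raw tables
  pick <- sm[sm$icu_id == "E" & sm$period == "control", ]
  ids <- co$stays$patient_id[co$stays$icu_id == "E" &
                               co$stays$period == "control"]
  ww <- vapply(ids, function(id) {
    d <- co$days[co$days$patient_id == id, ]
    los <- co$stays$los_days[co$stays$patient_id == id]
    7 * sum(!is.na(d$weight_kg)) / los
  }, numeric(1))
  expect_equal(pick$weekly_weighins_mean, mean(ww), tolerance = 1e-9)
  expect_equal(pick$weekly_weighins_sd, sd(ww), tolerance = 1e-9)

  hyp <- vapply(ids, function(id) {
    any(co$days$hypotension[co$days$patient_id == id])
  }, logical(1))
  expect_equal(pick$hypotension_n, sum(hyp))
  expect_equal(pick$hypotension_pct, 100 * mean(hyp), tolerance = 1e-9)

  scores <- vapply(ids, function(id) {
    oracle_score_stay(fb_cohort(
      co$stays[co$stays$patient_id == id, ],
      co$days[co$days$patient_id == id, ],
      validate = FALSE
    ))$final_score
  }, numeric(1))
  expect_equal(pick$score_mean, mean(scores), tolerance = 1e-9)
})
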