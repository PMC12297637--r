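visit_series <- function(n, worsen_at = integer(), dates = NULL, ...) {
  # identical normal visits, optionally worsened (motor MRC 0 everywhere,
  # +24 points) at the given indices
  if (is.null(dates)) dates <- as.Date("2024-01-01") + 180 * (seq_len(n) - 1)
  lapply(seq_len(n), function(i) {
    a <- normal_assessment(patient_id = "p1", visit_date = dates[i])
    if (i %in% worsen_at) a$motor <- normal_motor(rep(0, 4))
    a
  })
}

test_that("trajectory tabulates totals and deltas vs baseline and previous", {
  tr <- trajectory(visit_series(3, worsen_at = 3))
  expect_equal(tr$total, c(0, 0, 24))
  expect_equal(tr$delta_baseline, c(NA, 0, 24))
  expect_equal(tr$delta_previous, c(NA, 0, 24))
  expect_false(any(tr$incomplete))

  # a single visit has no deltas
  tr1 <- trajectory(visit_series(1))
  expect_true(is.na(tr1$delta_baseline) && is.na(tr1$delta_previous))

  # identical repeated visits: all deltas zero
  tr2 <- trajectory(visit_series(2))
  expect_equal(tr2$delta_baseline[2], 0)
})

test_that("trajectory rejects mixed patients and unordered dates", {
  vs <- visit_series(2)
  vs[[2]]$patient_id <- "p2"
  expect_error(trajectory(vs), "mix patient ids")
  vs <- visit_series(2, dates = as.Date(c("2024-06-01", "2024-01-01")))
  expect_error(trajectory(vs), "strictly increasing")
})

test_that("the score criterion needs >4 points together with deterioration", {
  mk <- function(delta, subj) {
    vs <- visit_series(2)
    # bump the second visit by `delta` points via sensory findings
    vs[[2]]$sensory <- switch(as.character(delta),
      `5` = list(sensory_finding("cold", "lower_limb", "thigh"),
                 sensory_finding("pinprick", "lower_limb", "lower_leg")),
      `4.5` = list(sensory_finding("cold", "lower_limb", "thigh"),
                   sensory_finding("pinprick", "lower_limb", "foot")),
      `4` = list(sensory_finding("cold", "lower_limb", "lower_leg"),
                 sensory_finding("pinprick", "lower_limb", "lower_leg")))
    vs[[2]]$subjective_deterioration <- subj
    evaluate_progression(trajectory(vs))
  }
  v <- mk(5, TRUE)
  expect_true(v$progression[2])
  expect_equal(v$triggered[2], "score")
  # exactly 4 points: strict inequality, not progression
  v <- mk(4, TRUE)
  expect_false(v$progression[2])
  # a 4.5-point revised delta satisfies the strict >4 rule
  v <- mk(4.5, TRUE)
  expect_true(v$progression[2])
  # without subjective deterioration the score criterion does not fire
  v <- mk(5, FALSE)
  expect_false(v$progression[2])
  # ... unless the conjunction is switched off
  vs <- visit_series(2, worsen_at = 2)
  v <- evaluate_progression(trajectory(vs),
    criteria = progression_criteria(require_subjective_deterioration = FALSE))
  expect_true(v$score_criterion[2])
})

test_that("weight loss of at least 5% flags progression on its own", {
  vs <- visit_series(3)
  v <- evaluate_progression(trajectory(vs), weights = c(80, 77, 76))
  expect_false(v$progression[2])  # 3.75% loss
  expect_true(v$progression[3])   # exactly 5.0% loss
  expect_equal(v$triggered[3], "weight")

  # missing weights disable only the weight criterion, with a note
  v <- evaluate_progression(trajectory(vs))
  expect_false(any(v$progression))
  expect_match(v$notes[2], "missing weight")
})

test_that("new organ involvement flags progression on its own", {
  vs <- visit_series(2)
  vs[[2]]$new_organ_involvement <- TRUE
  v <- evaluate_progression(trajectory(vs))
  expect_true(v$progression[2])
  expect_equal(v$triggered[2], "new_organ")
  expect_match(paste(attr(v, "notes"), collapse = " "), "exclude the eyes")
})

test_that("stable repeated visits are never flagged", {
  vs <- visit_series(4)
  v <- evaluate_progression(trajectory(vs), weights = rep(70, 4))
  expect_false(any(v$progression))
})

test_that("verdicts are monotone when criteria are loosened", {
  vs <- visit_series(3, worsen_at = 2:3)
  for (i in 2:3) vs[[i]]$subjective_deterioration <- TRUE
  tr <- trajectory(vs)
  w <- c(80, 78, 75)
  strict <- evaluate_progression(tr, weights = w,
    criteria = progression_criteria(score_increase_threshold = 30,
                                    weight_loss_fraction = 0.2))
  loose <- evaluate_progression(tr, weights = w,
    criteria = progression_criteria(score_increase_threshold = 4,
                                    weight_loss_fraction = 0.05))
  expect_true(all(loose$progression >= strict$progression))
})

test_that("deltas can be taken against the previous visit instead", {
  vs <- visit_series(3, worsen_at = 2:3)
  for (i in 2:3) vs[[i]]$subjective_deterioration <- TRUE
  v <- evaluate_progression(trajectory(vs),
    criteria = progression_criteria(baseline = "previous"))
  expect_equal(v$score_delta, c(NA, 24, 0))
  expect_true(v$progression[2])
  expect_false(v$progression[3])
})

test_that("mBMI is BMI times albumin, refusing non-positive input", {
  expect_equal(mbmi(72, 1.8, 40), 72 / 1.8^2 * 40)
  expect_equal(mbmi(80, 2.0, 35), 700)
  expect_error(mbmi(72, 1.8, 0), "positive")
  expect_error(mbmi(-1, 1.8, 40), "positive")
})
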