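test_that("original limb sensory score is the floor of the revised score, exhaustively", {
  for (region in c("lower_limb", "upper_limb")) {
    ladder <- kumamotoscale:::.limb_ladders[[region]]
    expect_equal(limb_sensory_score_original(region, ladder),
                 floor(limb_sensory_score(region, ladder)))
  }
  # spot values from the coarsened three-level ladder
  expect_equal(limb_sensory_score_original("lower_limb",
                                           c("normal", "toes", "foot",
                                             "lower_leg", "knee", "thigh")),
               c(0, 1, 1, 2, 2, 3))
  # floor refinement also holds item-wise across all modalities in a scored
  # assessment (trunk items are shared)
  for (level in kumamotoscale:::.limb_ladders$lower_limb) {
    for (mod in c("cold", "pinprick", "light_touch")) {
      f <- list(sensory_finding(mod, "lower_limb", level))
      expect_equal(as.numeric(sensory_subscore(f, "original")),
                   floor(as.numeric(sensory_subscore(f, "revised"))))
    }
  }
})

test_that("original orthostasis scores any positive drop up to 20 as 2", {
  drop <- function(d, ...) autonomic_findings(sbp_supine = 120,
                                              sbp_standing_3min = 120 - d, ...)
  expect_equal(as.numeric(orthostasis_score_original(drop(0))), 0)
  expect_equal(as.numeric(orthostasis_score_original(drop(5))), 2)
  expect_equal(as.numeric(orthostasis_score_original(drop(15))), 2)
  expect_equal(as.numeric(orthostasis_score_original(drop(20))), 2)
  expect_equal(as.numeric(orthostasis_score_original(drop(21))), 4)
  expect_equal(as.numeric(orthostasis_score_original(
    drop(5, orthostatic_syncope = TRUE))), 6)
})

test_that("original GI scoring has no constipation point", {
  expect_equal(as.numeric(gi_score_original(
    autonomic_findings(stools_per_week = 2, stools_hard = TRUE))), 0)
  expect_equal(as.numeric(gi_score_original(au_normal())), 0)
  expect_equal(as.numeric(gi_score_original(
    autonomic_findings(gi_level_code = 2))), 2)
  # a pre-coded revised constipation point is dropped with a note
  g <- gi_score_original(autonomic_findings(gi_level_code = 1))
  expect_equal(as.numeric(g), 0)
  expect_match(attr(g, "notes"), "original")
})

test_that("motor, urination, sicca, heart and kidney items agree across engines", {
  set.seed(101)
  for (k in 1:25) {
    a <- assessment_from_scores(random_item_scores(), patient_id = "shared")
    orig <- score_assessment(a, "original")
    rev <- score_assessment(a, "revised")
    shared <- c(paste0("motor_", all_movements), "auto_urination",
                "auto_dry_eyes", "auto_dry_mouth", "visc_heart", "visc_kidney")
    expect_identical(orig$item_scores[shared], rev$item_scores[shared])
  }
})

test_that("both engines keep subscores in [0, 24] and totals in [0, 96]", {
  set.seed(202)
  for (k in 1:25) {
    a <- assessment_from_scores(random_item_scores())
    for (scale in c("revised", "original")) {
      b <- score_assessment(a, scale)
      expect_true(all(b$subscores >= 0 & b$subscores <= 24))
      expect_true(b$total >= 0 && b$total <= 96)
      expect_equal(b$total, sum(b$subscores))
    }
  }
})

test_that("compare_scales reports paired breakdowns and deltas", {
  cp <- compare_scales(example_assessment())
  expect_equal(cp$original$total, 17)
  expect_equal(cp$revised$total, 16.5)
  expect_equal(cp$total_delta, -0.5)
  expect_equal(cp$subscores$delta, c(0.5, 0, -1, 0))

  # all-normal: every delta zero
  cp <- compare_scales(normal_assessment())
  expect_true(all(cp$items$delta == 0))
  expect_equal(cp$total_delta, 0)

  # sensory loss at the knee only: the finer ladder adds half a point
  a <- normal_assessment()
  a$sensory <- list(sensory_finding("cold", "lower_limb", "knee"))
  cp <- compare_scales(a)
  expect_equal(cp$subscores$delta[cp$subscores$domain == "sensory"], 0.5)
})
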