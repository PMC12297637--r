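test_that("limb sensory levels map to the six revised sub-scores", {
  lower <- c(normal = 0, toes = 1, foot = 1.5, lower_leg = 2, knee = 2.5,
             thigh = 3)
  upper <- c(normal = 0, fingers = 1, hand = 1.5, forearm = 2, upper_arm = 2.5,
             shoulder = 3)
  expect_equal(limb_sensory_score("lower_limb", names(lower)), unname(lower))
  expect_equal(limb_sensory_score("upper_limb", names(upper)), unname(upper))
  expect_error(limb_sensory_score("lower_limb", "hand"), "ladder")
})

test_that("trunk/head sensory scoring is 0-3 and accepts original labels", {
  expect_equal(trunk_sensory_score(c("none", "midline_trunk",
                                     "midclavicular_line", "neck_and_face")),
               0:3)
  expect_equal(trunk_sensory_score(c("umbilical", "clavicular")), 1:2)
  expect_error(trunk_sensory_score("thigh"), "ladder")
})

test_that("MRC and NIS-LL grades map to the Kumamoto motor ladder", {
  expect_equal(mrc_to_kumamoto(5:0), c(0, 2, 3, 4, 5, 6))
  expect_equal(nisll_to_kumamoto(c(0, 2, 3.25, 3.50, 3.75, 4)),
               c(0, 2, 3, 4, 5, 6))
  expect_error(mrc_to_kumamoto(2.5), "integer")
  expect_error(mrc_to_kumamoto(6), "0-5")
  expect_error(nisll_to_kumamoto(3), "NIS-LL|one of")
})

test_that("sensory subscore sums items with worse-side merging", {
  # left worse than right: item takes the left (maximum) score
  f <- list(sensory_finding("cold", "lower_limb", "knee", side = "left"),
            sensory_finding("cold", "lower_limb", "toes", side = "right"))
  s <- sensory_subscore(f)
  expect_equal(as.numeric(s), 2.5)
  expect_equal(unname(attr(s, "items")["sens_cold_lower_limb"]), 2.5)
  # no findings means intact sensation
  expect_equal(as.numeric(sensory_subscore(list())), 0)
})

test_that("trunk/head light touch is recorded but never scored", {
  f <- list(sensory_finding("light_touch", "trunk_head", "midline_trunk"))
  s <- sensory_subscore(f)
  expect_equal(as.numeric(s), 0)
  expect_match(attr(s, "notes"), "not a scored item")
})

test_that("motor subscore sums the four movements and flags untested ones", {
  expect_equal(as.numeric(motor_subscore(normal_motor())), 0)
  expect_equal(as.numeric(motor_subscore(normal_motor(c(3, 5, 5, 5)))), 3)
  expect_equal(as.numeric(motor_subscore(normal_motor(rep(0, 4)))), 24)
  # NIS-LL grade alone works too
  f <- normal_motor()
  f[[1]] <- motor_finding("ankle_dorsiflexion", mrc_grade = NA,
                          nis_ll_grade = 3.25)
  expect_equal(as.numeric(motor_subscore(f)), 3)
  # untested movement -> incomplete
  s <- motor_subscore(normal_motor()[1:3])
  expect_true(is.na(s))
  expect_equal(attr(s, "missing"), "motor_wrist_dorsiflexion")
})

test_that("GI scoring separates constipation from diarrhoea tiers", {
  expect_equal(as.numeric(gi_score(au_normal())), 0)
  # constipation: fewer than three hard stools per week
  expect_equal(as.numeric(gi_score(autonomic_findings(stools_per_week = 2,
                                                      stools_hard = TRUE))), 1)
  expect_equal(as.numeric(gi_score(autonomic_findings(stools_per_week = 3,
                                                      stools_hard = TRUE))), 0)
  # diarrhoea needs at least three loose stools per day
  expect_equal(as.numeric(gi_score(autonomic_findings(loose_stools_per_day = 2))), 0)
  expect_equal(as.numeric(gi_score(autonomic_findings(loose_stools_per_day = 3))), 2)
  expect_equal(as.numeric(gi_score(autonomic_findings(loose_stools_per_day = 6))), 4)
  expect_equal(as.numeric(gi_score(autonomic_findings(loose_stools_per_day = 12))), 6)
  # pre-coded tier accepted; raw wins on conflict with a note
  expect_equal(as.numeric(gi_score(autonomic_findings(gi_level_code = 4))), 4)
  g <- gi_score(autonomic_findings(gi_level_code = 6, loose_stools_per_day = 3))
  expect_equal(as.numeric(g), 2)
  expect_match(attr(g, "notes"), "raw wins")
  # nothing recorded -> missing
  expect_true(is.na(gi_score(autonomic_findings())))
})

test_that("orthostasis bands classify the worst standing systolic drop", {
  drop <- function(d, ...) autonomic_findings(sbp_supine = 120,
                                              sbp_standing_1min = 120 - d / 2,
                                              sbp_standing_3min = 120 - d, ...)
  expect_equal(as.numeric(orthostasis_score(drop(0))), 0)
  expect_equal(as.numeric(orthostasis_score(drop(5))), 0)
  expect_equal(as.numeric(orthostasis_score(drop(9))), 0)
  expect_equal(as.numeric(orthostasis_score(drop(10))), 2)
  expect_equal(as.numeric(orthostasis_score(drop(15))), 2)
  expect_equal(as.numeric(orthostasis_score(drop(20))), 2)
  expect_equal(as.numeric(orthostasis_score(drop(21))), 4)
  # syncope requiring countermeasures dominates
  expect_equal(as.numeric(orthostasis_score(drop(5, orthostatic_syncope = TRUE))), 6)
  # supine hypertension moves the 2-point onset to 30 mm Hg, width preserved
  expect_equal(as.numeric(orthostasis_score(drop(25, supine_hypertension = TRUE))), 0)
  expect_equal(as.numeric(orthostasis_score(drop(30, supine_hypertension = TRUE))), 2)
  expect_equal(as.numeric(orthostasis_score(drop(41, supine_hypertension = TRUE))), 4)
  # only the 1-min measurement available still scores
  one <- autonomic_findings(sbp_supine = 130, sbp_standing_1min = 115)
  expect_equal(as.numeric(orthostasis_score(one)), 2)
  # missing supine pressure -> missing item
  expect_true(is.na(orthostasis_score(autonomic_findings(sbp_standing_3min = 110))))
  # confounder and diastolic notes
  o <- orthostasis_score(autonomic_findings(
    sbp_supine = 120, sbp_standing_3min = 115, dbp_supine = 80,
    dbp_standing = 68, on_antihypertensives = TRUE))
  expect_equal(as.numeric(o), 0)
  expect_length(attr(o, "notes"), 2)
})

test_that("urination bands follow the residual-urine definitions", {
  res <- function(r, ...) autonomic_findings(residual_urine_ml = r, ...)
  expect_equal(as.numeric(urination_score(res(100))), 0)
  expect_equal(as.numeric(urination_score(res(200))), 2)
  expect_equal(as.numeric(urination_score(res(400,
    prostate_hyperplasia_excluded = TRUE))), 4)
  expect_equal(as.numeric(urination_score(res(600,
    prostate_hyperplasia_excluded = TRUE))), 6)
  expect_equal(as.numeric(urination_score(res(100, sporadic_incontinence = TRUE))), 2)
  expect_equal(as.numeric(urination_score(autonomic_findings(catheterized = TRUE))), 6)
  expect_true(is.na(urination_score(autonomic_findings())))
  # retention without prostate exclusion carries a caution note
  u <- urination_score(res(200))
  expect_match(attr(u, "notes"), "prostate")
})

test_that("sicca grades pass through with the drug-induced exclusion", {
  s <- sicca_scores(autonomic_findings(dry_eyes_grade = 1, dry_mouth_grade = 3))
  expect_equal(unname(s[c("dry_eyes", "dry_mouth")]), c(1, 3))
  s <- sicca_scores(autonomic_findings(dry_eyes_grade = 0, dry_mouth_grade = 3,
                                       dry_mouth_drug_induced = TRUE))
  expect_equal(unname(s["dry_mouth"]), 0)
  expect_match(attr(s, "notes"), "drug-induced")
})

test_that("heart and kidney ladders score their four categories", {
  hs <- vapply(c("normal", "conduction_disturbance", "advanced_conduction",
                 "device_or_chf"),
               function(c) heart_score(visceral_findings(cardiac_level_code = c)),
               numeric(1))
  expect_equal(unname(hs), c(0, 4, 8, 12))
  expect_true(is.na(heart_score(visceral_findings())))

  expect_equal(kidney_score(visceral_findings(cardiac_level_code = "normal")), 0)
  expect_equal(kidney_score(visceral_findings(dipstick_proteinuria = TRUE)), 4)
  expect_equal(kidney_score(visceral_findings(proteinuria_g_per_24h = 2)), 4)
  # nephrotic syndrome needs all three components
  expect_equal(kidney_score(visceral_findings(proteinuria_g_per_24h = 4,
                                              hypoalbuminemia = TRUE,
                                              oedema = TRUE)), 8)
  expect_equal(kidney_score(visceral_findings(proteinuria_g_per_24h = 4,
                                              hypoalbuminemia = TRUE)), 4)
  expect_equal(kidney_score(visceral_findings(proteinuria_g_per_24h = 3.5,
                                              hypoalbuminemia = TRUE,
                                              oedema = TRUE)), 4)
  expect_equal(kidney_score(visceral_findings(on_dialysis = TRUE)), 12)
})

test_that("score_assessment assembles subscores, notes and missing items", {
  b <- score_assessment(example_assessment())
  expect_s3_class(b, "kumamoto_breakdown")
  expect_equal(unname(b$subscores), c(4.5, 0, 4, 8))
  expect_equal(b$total, sum(b$subscores))
  expect_false(b$incomplete)

  # missing motor item propagates to an incomplete total
  a <- example_assessment()
  a$motor <- a$motor[1:3]
  b <- score_assessment(a)
  expect_true(b$incomplete)
  expect_true(is.na(b$total))
  expect_equal(b$missing_items, "motor_wrist_dorsiflexion")

  # invalid assessments are refused
  bad <- assessment("p", "2024-01-01",
                    motor = list(motor_finding("ankle_dorsiflexion", 9)))
  expect_error(score_assessment(bad), "invalid assessment")
})

test_that("item scores are monotone in their raw findings", {
  # sensory ladders
  for (region in c("lower_limb", "upper_limb")) {
    ladder <- kumamotoscale:::.limb_ladders[[region]]
    for (fun in list(limb_sensory_score, limb_sensory_score_original)) {
      expect_true(all(diff(fun(region, ladder)) >= 0))
    }
  }
  expect_true(all(diff(trunk_sensory_score(
    c("none", "midline_trunk", "midclavicular_line", "neck_and_face"))) >= 0))
  # lower MRC grade never lowers the score
  expect_true(all(diff(mrc_to_kumamoto(5:0)) >= 0))
  expect_true(all(diff(nisll_to_kumamoto(c(0, 2, 3.25, 3.5, 3.75, 4))) >= 0))
  # larger BP drop, both scales and with supine hypertension
  drops <- 0:45
  for (scale in c("revised", "original")) {
    for (sh in c(FALSE, TRUE)) {
      sc <- vapply(drops, function(d) {
        as.numeric(orthostasis_score(autonomic_findings(
          sbp_supine = 160, sbp_standing_3min = 160 - d,
          supine_hypertension = sh), scale = scale))
      }, numeric(1))
      expect_true(all(diff(sc) >= 0))
    }
  }
  # larger residual volume
  sc <- vapply(seq(0, 700, by = 10), function(r) {
    as.numeric(urination_score(autonomic_findings(
      residual_urine_ml = r, prostate_hyperplasia_excluded = TRUE)))
  }, numeric(1))
  expect_true(all(diff(sc) >= 0))
  # more loose stools
  sc <- vapply(3:15, function(n) {
    as.numeric(gi_score(autonomic_findings(loose_stools_per_day = n)))
  }, numeric(1))
  expect_true(all(diff(sc) >= 0))
  # worse cardiac category and renal stage
  expect_true(all(diff(vapply(
    c("normal", "conduction_disturbance", "advanced_conduction",
      "device_or_chf"),
    function(c) heart_score(visceral_findings(cardiac_level_code = c)),
    numeric(1))) >= 0))
  renal <- list(visceral_findings(),
                visceral_findings(dipstick_proteinuria = TRUE),
                visceral_findings(proteinuria_g_per_24h = 4,
                                  hypoalbuminemia = TRUE, oedema = TRUE),
                visceral_findings(on_dialysis = TRUE))
  expect_true(all(diff(vapply(renal, kidney_score, numeric(1))) >= 0))
})

test_that("scoring is deterministic and independent of finding order", {
  a <- worst_assessment()
  set.seed(42)
  for (scale in c("revised", "original")) {
    ref <- score_assessment(a, scale)
    for (k in 1:5) {
      b <- a
      b$sensory <- sample(b$sensory)
      b$motor <- sample(b$motor)
      sh <- score_assessment(b, scale)
      expect_identical(sh$item_scores, ref$item_scores)
      expect_identical(sh$subscores, ref$subscores)
      expect_identical(sh$total, ref$total)
    }
    expect_identical(score_assessment(a, scale), score_assessment(a, scale))
  }
})
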