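# Fixtures built in code: canonical assessments and small builders used
# across the suite.

normal_assessment <- function(...) kumamotoscale:::.normal_assessment(...)
worst_assessment <- function(...) kumamotoscale:::.worst_assessment(...)

all_movements <- c("ankle_dorsiflexion", "knee_extension", "elbow_flexion",
                   "wrist_dorsiflexion")

normal_motor <- function(grades = rep(5, 4)) {
  Map(function(m, g) motor_finding(m, mrc_grade = g), all_movements, grades)
}

# Minimal complete assessment with an overridable autonomic block.
assessment_with_autonomic <- function(au) {
  assessment("p", "2024-01-01", motor = normal_motor(), autonomic = au,
             visceral = visceral_findings(cardiac_level_code = "normal"))
}

au_normal <- function(...) {
  defaults <- list(stools_per_week = 7, stools_hard = FALSE,
                   loose_stools_per_day = 0, sbp_supine = 120,
                   sbp_standing_1min = 120, sbp_standing_3min = 120,
                   residual_urine_ml = 0, dry_eyes_grade = 0,
                   dry_mouth_grade = 0)
  args <- utils::modifyList(defaults, list(...))
  do.call(autonomic_findings, args)
}

# Build an assessment realising given per-item revised-scale scores (the
# synthetic module's inverse-ladder construction).
assessment_from_scores <- function(items, patient_id = "p",
                                   visit_date = "2024-01-01") {
  kumamotoscale:::.assessment_from_item_scores(items, patient_id, visit_date,
                                               weight_kg = 70)
}

# Independent oracle for pre-coded assessments: plain table-lookup sums over
# the item registry, no scoring-engine code involved.
oracle_totals <- function(items, scale) {
  reg <- item_registry(scale)
  sens_limb <- reg$item_code[reg$domain == "sensory"][1:6]
  it <- items
  if (scale == "original") it[sens_limb] <- floor(it[sens_limb])
  if (scale == "original" && it[["auto_gi"]] == 1) it[["auto_gi"]] <- 0
  # orthostasis: the canonical raw constructions (drops 0/15/25, syncope)
  # score identically under both versions, so no adjustment is needed
  subs <- c(tapply(it[reg$item_code], reg$domain, sum))
  list(subscores = subs[c("sensory", "motor", "autonomic", "visceral")],
       total = sum(it))
}

random_item_scores <- function() {
  reg <- item_registry("revised")
  vapply(stats::setNames(reg$grid, reg$item_code),
         function(g) sample(g, 1), numeric(1))
}
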