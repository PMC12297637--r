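# Domain types, item registry and validation shared by both scoring engines.

# Anatomical ladders, ordered distal -> proximal. Sensory findings record the
# most proximal level of LOST (not reduced) sensation.
.limb_ladders <- list(
  lower_limb = c("normal", "toes", "foot", "lower_leg", "knee", "thigh"),
  upper_limb = c("normal", "fingers", "hand", "forearm", "upper_arm", "shoulder")
)
.trunk_ladder <- c("none", "midline_trunk", "midclavicular_line", "neck_and_face")
# The 1997 sheet labelled the trunk levels differently; ranks map 1:1.
.trunk_ladder_original <- c("none", "umbilical", "clavicular", "neck_and_face")

.modalities <- c("cold", "pinprick", "light_touch")
.regions <- c("lower_limb", "upper_limb", "trunk_head")
.sides <- c("left", "right", "unspecified")
.movements <- c("ankle_dorsiflexion", "knee_extension", "elbow_flexion",
                "wrist_dorsiflexion")
.cardiac_levels <- c("normal", "conduction_disturbance", "advanced_conduction",
                     "device_or_chf")
.nisll_grades <- c(0, 2, 3.25, 3.50, 3.75, 4)

#' Item registry for the Kumamoto scale
#'
#' The scale is a closed registry of 19 items in four subdomains: 8 sensory
#' (3 modalities x 2 limb regions, plus cold and pinprick on trunk/head),
#' 4 motor movements, 5 autonomic items and 2 visceral items. Each subdomain
#' has a maximum of 24 points; the total ranges 0-96.
#'
#' @param scale `"revised"` or `"original"`; the two versions share the item
#'   registry but differ in the attainable score grid for the limb sensory and
#'   gastrointestinal items.
#' @return A tibble with columns `item_code`, `domain`, `max_score` and `grid`
#'   (a list-column of attainable item scores, ascending).
#' @examples
#' item_registry("revised")
#' @export
item_registry <- function(scale = c("revised", "original")) {
  scale <- match.arg(scale)
  limb_grid <- if (scale == "revised") c(0, 1, 1.5, 2, 2.5, 3) else 0:3
  gi_grid <- if (scale == "revised") c(0, 1, 2, 4, 6) else c(0, 2, 4, 6)
  sens_codes <- c(
    "sens_cold_lower_limb", "sens_pinprick_lower_limb", "sens_touch_lower_limb",
    "sens_cold_upper_limb", "sens_pinprick_upper_limb", "sens_touch_upper_limb",
    "sens_cold_trunk_head", "sens_pinprick_trunk_head"
  )
  tibble::tibble(
    item_code = c(
      sens_codes,
      paste0("motor_", .movements),
      "auto_gi", "auto_orthostasis", "auto_urination",
      "auto_dry_eyes", "auto_dry_mouth",
      "visc_heart", "visc_kidney"
    ),
    domain = rep(c("sensory", "motor", "autonomic", "visceral"),
                 times = c(8L, 4L, 5L, 2L)),
    grid = c(
      rep(list(limb_grid), 6), rep(list(0:3), 2),
      rep(list(c(0, 2, 3, 4, 5, 6)), 4),
      list(gi_grid), rep(list(c(0, 2, 4, 6)), 2), rep(list(0:3), 2),
      rep(list(c(0, 4, 8, 12)), 2)
    ),
    max_score = vapply(grid, max, numeric(1))
  )
}

#' Record a sensory finding
#'
#' One finding per modality, region and (optionally) side, giving the most
#' proximal anatomical level at which sensation is lost. Limb ladders run
#' `normal, toes/fingers, foot/hand, lower_leg/forearm, knee/upper_arm,
#' thigh/shoulder`; the trunk/head ladder runs `none, midline_trunk,
#' midclavicular_line, neck_and_face` (the original labels `umbilical` and
#' `clavicular` are accepted as rank-equivalent aliases).
#'
#' @param modality `"cold"`, `"pinprick"` or `"light_touch"`.
#' @param region `"lower_limb"`, `"upper_limb"` or `"trunk_head"`.
#' @param level Anatomical level on the region's ladder.
#' @param side `"left"`, `"right"`, or `"unspecified"` for a combined judgement.
#' @param instrument Optional free text naming the bedside instrument used.
#' @return An object of class `sensory_finding`.
#' @examples
#' sensory_finding("cold", "lower_limb", "lower_leg")
#' @export
sensory_finding <- function(modality, region, level, side = "unspecified",
                            instrument = NULL) {
  structure(
    list(modality = as.character(modality), region = as.character(region),
         level = as.character(level), side = as.character(side),
         instrument = instrument),
    class = "sensory_finding"
  )
}

#' Record a motor finding
#'
#' MRC muscle-power grade (0 = no visible contraction, 5 = normal power) for
#' one of the four tested movements. An NIS-LL grade (`0, 2, 3.25, 3.50, 3.75,
#' 4`) may be given instead of, or alongside, the MRC grade; both ladders map
#' onto the same Kumamoto item score.
#'
#' @param movement One of `"ankle_dorsiflexion"`, `"knee_extension"`,
#'   `"elbow_flexion"`, `"wrist_dorsiflexion"`.
#' @param mrc_grade Integer 0-5, or `NA` if only an NIS-LL grade was recorded.
#' @param side `"left"`, `"right"` or `"unspecified"`.
#' @param nis_ll_grade Optional NIS-LL grade.
#' @return An object of class `motor_finding`.
#' @examples
#' motor_finding("ankle_dorsiflexion", 5)
#' @export
motor_finding <- function(movement, mrc_grade = NA, side = "unspecified",
                          nis_ll_grade = NA) {
  structure(
    list(movement = as.character(movement),
         mrc_grade = suppressWarnings(as.numeric(mrc_grade)),
         side = as.character(side),
         nis_ll_grade = suppressWarnings(as.numeric(nis_ll_grade))),
    class = "motor_finding"
  )
}

#' Record autonomic findings for one visit
#'
#' Raw measurements and categorical findings feeding the five autonomic items
#' (GI symptoms, orthostasis, urination, dry eyes, dry mouth). Fields left `NA`
#' mark the corresponding item as not assessed; scoring then reports it as a
#' missing item rather than imputing.
#'
#' @param stools_per_week Stool count per week (constipation is fewer than
#'   three hard stools per week).
#' @param stools_hard Flag: stools are hard.
#' @param loose_stools_per_day Loose stool count per day (diarrhoea requires at
#'   least three loose stools per day).
#' @param gi_level_code Optional pre-coded GI item score (revised grid
#'   `0,1,2,4,6`); raw stool fields win over the code on conflict.
#' @param sbp_supine,sbp_standing_1min,sbp_standing_3min Systolic blood
#'   pressure (mm Hg) after 5 min supine rest and after 1 and 3 min standing.
#' @param dbp_supine,dbp_standing Optional diastolic pressures (mm Hg).
#' @param supine_hypertension Flag; when set, the 2-point orthostatic band
#'   onset moves from 10 to 30 mm Hg.
#' @param orthostatic_syncope Flag: syncope/presyncope on standing requiring
#'   countermeasures (scores 6).
#' @param on_antihypertensives Confounder flag; noted, not scored.
#' @param residual_urine_ml Post-void residual urine volume (ml), by bladder
#'   scan after double voiding.
#' @param sporadic_incontinence Flag.
#' @param catheterized Flag (scores 6).
#' @param prostate_hyperplasia_excluded Optional flag; a caution note is
#'   emitted when urinary retention is scored without it.
#' @param dry_eyes_grade,dry_mouth_grade Ordinal severity 0 none / 1 mild /
#'   2 moderate / 3 severe.
#' @param dry_mouth_drug_induced Flag; a drug-induced dry mouth is excluded
#'   (scored 0) with a note.
#' @return An object of class `autonomic_findings`.
#' @export
autonomic_findings <- function(stools_per_week = NA, stools_hard = NA,
                               loose_stools_per_day = NA, gi_level_code = NA,
                               sbp_supine = NA, sbp_standing_1min = NA,
                               sbp_standing_3min = NA, dbp_supine = NA,
                               dbp_standing = NA, supine_hypertension = FALSE,
                               orthostatic_syncope = FALSE,
                               on_antihypertensives = FALSE,
                               residual_urine_ml = NA,
                               sporadic_incontinence = FALSE,
                               catheterized = FALSE,
                               prostate_hyperplasia_excluded = NA,
                               dry_eyes_grade = NA, dry_mouth_grade = NA,
                               dry_mouth_drug_induced = FALSE) {
  num <- function(x) suppressWarnings(as.numeric(x))
  lgl <- function(x) as.logical(x)
  structure(
    list(stools_per_week = num(stools_per_week), stools_hard = lgl(stools_hard),
         loose_stools_per_day = num(loose_stools_per_day),
         gi_level_code = num(gi_level_code),
         sbp_supine = num(sbp_supine),
         sbp_standing_1min = num(sbp_standing_1min),
         sbp_standing_3min = num(sbp_standing_3min),
         dbp_supine = num(dbp_supine), dbp_standing = num(dbp_standing),
         supine_hypertension = lgl(supine_hypertension),
         orthostatic_syncope = lgl(orthostatic_syncope),
         on_antihypertensives = lgl(on_antihypertensives),
         residual_urine_ml = num(residual_urine_ml),
         sporadic_incontinence = lgl(sporadic_incontinence),
         catheterized = lgl(catheterized),
         prostate_hyperplasia_excluded = lgl(prostate_hyperplasia_excluded),
         dry_eyes_grade = num(dry_eyes_grade),
         dry_mouth_grade = num(dry_mouth_grade),
         dry_mouth_drug_induced = lgl(dry_mouth_drug_induced)),
    class = "autonomic_findings"
  )
}

#' Record visceral findings for one visit
#'
#' Cardiac and renal findings feeding the two visceral items (each scored
#' `0, 4, 8, 12`). Nephrotic syndrome is derived, never asserted: it requires
#' proteinuria above 3.5 g/24 h, hypoalbuminemia and oedema together.
#'
#' @param cardiac_level_code `"normal"`, `"conduction_disturbance"` (e.g.
#'   first-degree AV block), `"advanced_conduction"`, or `"device_or_chf"`
#'   (third-degree AV block or pacemaker, with heart failure counted only in
#'   this category). `NA` marks the heart item as not assessed.
#' @param cardiac_finding_text Optional free text (e.g. the ECG finding).
#' @param dipstick_proteinuria Flag: proteinuria on urine dipsticks.
#' @param proteinuria_g_per_24h Optional quantified proteinuria (g/24 h).
#' @param hypoalbuminemia,oedema Flags; with proteinuria > 3.5 g/24 h they
#'   establish nephrotic syndrome.
#' @param on_dialysis Flag (scores 12).
#' @return An object of class `visceral_findings`.
#' @export
visceral_findings <- function(cardiac_level_code = NA,
                              cardiac_finding_text = NULL,
                              dipstick_proteinuria = FALSE,
                              proteinuria_g_per_24h = NA,
                              hypoalbuminemia = FALSE, oedema = FALSE,
                              on_dialysis = FALSE) {
  structure(
    list(cardiac_level_code = as.character(cardiac_level_code),
         cardiac_finding_text = cardiac_finding_text,
         dipstick_proteinuria = as.logical(dipstick_proteinuria),
         proteinuria_g_per_24h = suppressWarnings(as.numeric(proteinuria_g_per_24h)),
         hypoalbuminemia = as.logical(hypoalbuminemia),
         oedema = as.logical(oedema),
         on_dialysis = as.logical(on_dialysis)),
    class = "visceral_findings"
  )
}

#' Bundle one patient-visit assessment
#'
#' @param patient_id Opaque patient identifier.
#' @param visit_date Visit date (coerced with [as.Date()]; ISO 8601 strings
#'   are accepted).
#' @param sensory List of [sensory_finding()] objects (absent items are scored
#'   as intact sensation).
#' @param motor List of [motor_finding()] objects (an untested movement is a
#'   missing item).
#' @param autonomic An [autonomic_findings()] object.
#' @param visceral A [visceral_findings()] object.
#' @param weight_kg,height_m,serum_albumin_g_per_L Optional anthropometrics
#'   and albumin for progression evaluation and [mbmi()].
#' @param subjective_deterioration Optional flag recorded at the visit, used
#'   by the progression rule.
#' @param new_organ_involvement Optional flag: onset of symptoms or signs of
#'   further organ involvement (the eyes excluded).
#' @return An object of class `kumamoto_assessment`.
#' @seealso [score_assessment()], [validate_assessment()]
#' @examples
#' a <- assessment("p1", "2024-01-15",
#'   sensory = list(sensory_finding("cold", "lower_limb", "foot")),
#'   motor = lapply(
#'     c("ankle_dorsiflexion", "knee_extension", "elbow_flexion",
#'       "wrist_dorsiflexion"),
#'     motor_finding, mrc_grade = 5),
#'   autonomic = autonomic_findings(
#'     stools_per_week = 7, loose_stools_per_day = 0,
#'     sbp_supine = 120, sbp_standing_3min = 118,
#'     residual_urine_ml = 20, dry_eyes_grade = 0, dry_mouth_grade = 0),
#'   visceral = visceral_findings(cardiac_level_code = "normal"))
#' score_assessment(a)
#' @export
assessment <- function(patient_id, visit_date, sensory = list(),
                       motor = list(), autonomic = autonomic_findings(),
                       visceral = visceral_findings(), weight_kg = NA,
                       height_m = NA, serum_albumin_g_per_L = NA,
                       subjective_deterioration = NA,
                       new_organ_involvement = NA) {
  structure(
    list(patient_id = as.character(patient_id),
         visit_date = as.Date(visit_date),
         sensory = sensory, motor = motor,
         autonomic = autonomic, visceral = visceral,
         weight_kg = suppressWarnings(as.numeric(weight_kg)),
         height_m = suppressWarnings(as.numeric(height_m)),
         serum_albumin_g_per_L = suppressWarnings(as.numeric(serum_albumin_g_per_L)),
         subjective_deterioration = as.logical(subjective_deterioration),
         new_organ_involvement = as.logical(new_organ_involvement)),
    class = "kumamoto_assessment"
  )
}

#' @export
print.kumamoto_assessment <- function(x, ...) {
  cat("<kumamoto_assessment> patient", x$patient_id, "visit",
      format(x$visit_date), "\n")
  cat("  sensory findings:", length(x$sensory),
      "| motor findings:", length(x$motor), "\n")
  invisible(x)
}

.finding_row <- function(field, rule, message) {
  tibble::tibble(field = field, rule = rule, message = message)
}

#' Validate an assessment
#'
#' Checks every type invariant and returns all violations as data, not
#' exceptions: unknown categories, out-of-range grades and measurements,
#' duplicate findings for the same item and side, and MRC/NIS-LL grade pairs
#' that map to different Kumamoto scores.
#'
#' @param a A [assessment()] object.
#' @return A tibble with columns `field`, `rule`, `message`; zero rows iff the
#'   assessment is well formed.
#' @examples
#' validate_assessment(example_assessment())  # zero rows
#' @export
validate_assessment <- function(a) {
  out <- list()
  add <- function(...) out[[length(out) + 1L]] <<- .finding_row(...)
  if (!inherits(a, "kumamoto_assessment")) {
    return(.finding_row("assessment", "type", "not a kumamoto_assessment"))
  }
  if (is.na(a$visit_date)) add("visit_date", "date", "visit_date is not a valid date")

  seen_sens <- character()
  for (i in seq_along(a$sensory)) {
    f <- a$sensory[[i]]
    pre <- sprintf("sensory[%d].", i)
    if (!f$modality %in% .modalities) {
      add(paste0(pre, "modality"), "category",
          sprintf("unknown modality '%s'", f$modality))
      next
    }
    if (!f$region %in% .regions) {
      add(paste0(pre, "region"), "category",
          sprintf("unknown region '%s'", f$region))
      next
    }
    if (!f$side %in% .sides) {
      add(paste0(pre, "side"), "category", sprintf("unknown side '%s'", f$side))
    }
    ladder <- if (f$region == "trunk_head") {
      c(.trunk_ladder, .trunk_ladder_original)
    } else .limb_ladders[[f$region]]
    if (!f$level %in% ladder) {
      add(paste0(pre, "level"), "ladder",
          sprintf("level '%s' is not on the %s ladder", f$level, f$region))
    }
    key <- paste(f$modality, f$region, f$side, sep = "/")
    if (key %in% seen_sens) {
      add(paste0(pre, "item"), "duplicate",
          sprintf("duplicate sensory finding for %s", key))
    }
    seen_sens <- c(seen_sens, key)
  }

  seen_mot <- character()
  for (i in seq_along(a$motor)) {
    f <- a$motor[[i]]
    pre <- sprintf("motor[%d].", i)
    if (!f$movement %in% .movements) {
      add(paste0(pre, "movement"), "category",
          sprintf("unknown movement '%s'", f$movement))
      next
    }
    if (!f$side %in% .sides) {
      add(paste0(pre, "side"), "category", sprintf("unknown side '%s'", f$side))
    }
    has_mrc <- !is.na(f$mrc_grade)
    has_nis <- !is.na(f$nis_ll_grade)
    if (has_mrc && (f$mrc_grade != round(f$mrc_grade) ||
                    f$mrc_grade < 0 || f$mrc_grade > 5)) {
      add(paste0(pre, "mrc_grade"), "range",
          sprintf("mrc_grade %s is not an integer in 0-5", f$mrc_grade))
      has_mrc <- FALSE
    }
    if (has_nis && !f$nis_ll_grade %in% .nisll_grades) {
      add(paste0(pre, "nis_ll_grade"), "range",
          sprintf("nis_ll_grade %s is not on the NIS-LL ladder", f$nis_ll_grade))
      has_nis <- FALSE
    }
    if (has_mrc && has_nis &&
        mrc_to_kumamoto(f$mrc_grade) != nisll_to_kumamoto(f$nis_ll_grade)) {
      add(paste0(pre, "grades"), "consistency",
          sprintf("MRC %s and NIS-LL %s map to different Kumamoto scores",
                  f$mrc_grade, f$nis_ll_grade))
    }
    key <- paste(f$movement, f$side, sep = "/")
    if (key %in% seen_mot) {
      add(paste0(pre, "item"), "duplicate",
          sprintf("duplicate motor finding for %s", key))
    }
    seen_mot <- c(seen_mot, key)
  }

  au <- a$autonomic
  nonneg <- function(field, value) {
    if (!is.na(value) && value < 0) {
      add(paste0("autonomic.", field), "range",
          sprintf("%s must be non-negative, got %s", field, value))
    }
  }
  for (fld in c("stools_per_week", "loose_stools_per_day", "sbp_supine",
                "sbp_standing_1min", "sbp_standing_3min", "dbp_supine",
                "dbp_standing", "residual_urine_ml")) {
    nonneg(fld, au[[fld]])
  }
  for (fld in c("dry_eyes_grade", "dry_mouth_grade")) {
    g <- au[[fld]]
    if (!is.na(g) && !g %in% 0:3) {
      add(paste0("autonomic.", fld), "range",
          sprintf("%s must be in 0-3, got %s", fld, g))
    }
  }
  if (!is.na(au$gi_level_code) && !au$gi_level_code %in% c(0, 1, 2, 4, 6)) {
    add("autonomic.gi_level_code", "range",
        sprintf("gi_level_code must be one of 0,1,2,4,6, got %s",
                au$gi_level_code))
  }

  vi <- a$visceral
  if (!is.na(vi$cardiac_level_code) &&
      !vi$cardiac_level_code %in% .cardiac_levels) {
    add("visceral.cardiac_level_code", "category",
        sprintf("unknown cardiac level '%s'", vi$cardiac_level_code))
  }
  if (!is.na(vi$proteinuria_g_per_24h) && vi$proteinuria_g_per_24h < 0) {
    add("visceral.proteinuria_g_per_24h", "range",
        "proteinuria must be non-negative")
  }
  if (!is.na(a$weight_kg) && a$weight_kg <= 0) {
    add("weight_kg", "range", "weight_kg must be positive")
  }
  if (!is.na(a$height_m) && a$height_m <= 0) {
    add("height_m", "range", "height_m must be positive")
  }
  if (length(out) == 0) {
    return(tibble::tibble(field = character(), rule = character(),
                          message = character()))
  }
  do.call(rbind, out)
}

.stop_if_invalid <- function(a) {
  v <- validate_assessment(a)
  if (nrow(v) > 0) {
    stop("invalid assessment: ",
         paste(sprintf("%s [%s]: %s", v$field, v$rule, v$message),
               collapse = "; "), call. = FALSE)
  }
  invisible(a)
}

#' The published worked-example patient
#'
#' A typical ATTRv amyloidosis patient with moderate sensory polyneuropathy:
#' loss of cold sensation in the fingers, feet and lower legs, loss of
#' pinprick sensation in the feet, normal motor function, a 5 mm Hg systolic
#' blood pressure drop after 3 min standing, chronic constipation (two hard
#' stools per week), severe dry mouth, proteinuria on urine dipsticks, and a
#' first-degree AV block on ECG. Scores 16.5 points on the revised scale and
#' 17 on the original.
#'
#' @param patient_id,visit_date Metadata for the returned assessment.
#' @return A `kumamoto_assessment`.
#' @examples
#' compare_scales(example_assessment())
#' @export
example_assessment <- function(patient_id = "example", visit_date = "2024-01-15") {
  assessment(
    patient_id, visit_date,
    sensory = list(
      sensory_finding("cold", "lower_limb", "lower_leg",
                      instrument = "Rolltemp II"),
      sensory_finding("pinprick", "lower_limb", "foot",
                      instrument = "Neuropen"),
      sensory_finding("cold", "upper_limb", "fingers",
                      instrument = "Rolltemp II")
    ),
    motor = lapply(.movements, motor_finding, mrc_grade = 5),
    autonomic = autonomic_findings(
      stools_per_week = 2, stools_hard = TRUE, loose_stools_per_day = 0,
      sbp_supine = 120, sbp_standing_1min = 118, sbp_standing_3min = 115,
      residual_urine_ml = 50,
      dry_eyes_grade = 0, dry_mouth_grade = 3, dry_mouth_drug_induced = FALSE
    ),
    visceral = visceral_findings(
      cardiac_level_code = "conduction_disturbance",
      cardiac_finding_text = "first-degree AV block on ECG",
      dipstick_proteinuria = TRUE
    )
  )
}

# A fully normal assessment: every item explicitly examined and unremarkable.
.normal_assessment <- function(patient_id = "normal", visit_date = "2024-01-15") {
  assessment(
    patient_id, visit_date,
    sensory = list(),
    motor = lapply(.movements, motor_finding, mrc_grade = 5),
    autonomic = autonomic_findings(
      stools_per_week = 7, stools_hard = FALSE, loose_stools_per_day = 0,
      sbp_supine = 120, sbp_standing_1min = 120, sbp_standing_3min = 120,
      residual_urine_ml = 0, dry_eyes_grade = 0, dry_mouth_grade = 0
    ),
    visceral = visceral_findings(cardiac_level_code = "normal")
  )
}

# Worst category on every item of every subdomain.
.worst_assessment <- function(patient_id = "worst", visit_date = "2024-01-15") {
  sens <- c(
    lapply(.modalities, sensory_finding, region = "lower_limb", level = "thigh"),
    lapply(.modalities, sensory_finding, region = "upper_limb", level = "shoulder"),
    lapply(c("cold", "pinprick"), sensory_finding, region = "trunk_head",
           level = "neck_and_face")
  )
  assessment(
    patient_id, visit_date,
    sensory = sens,
    motor = lapply(.movements, motor_finding, mrc_grade = 0),
    autonomic = autonomic_findings(
      loose_stools_per_day = 10,
      sbp_supine = 140, sbp_standing_1min = 100, sbp_standing_3min = 90,
      orthostatic_syncope = TRUE,
      catheterized = TRUE, residual_urine_ml = 600,
      dry_eyes_grade = 3, dry_mouth_grade = 3
    ),
    visceral = visceral_findings(cardiac_level_code = "device_or_chf",
                                 on_dialysis = TRUE)
  )
}
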