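# Item-level and subdomain scoring under the revised scale, plus the
# breakdown container shared with the original-scale engine.

.revised_limb_scores <- c(normal = 0, distal1 = 1, distal2 = 1.5,
                          mid = 2, proximal1 = 2.5, proximal2 = 3)

#' Orthostasis scoring configuration
#'
#' Thresholds for classifying the systolic blood pressure drop on standing.
#' Defaults follow the revised scale: a drop inside `two_point_drop_range`
#' (closed, 10-20 mm Hg) scores 2; a drop above `four_point_drop_threshold`
#' (exclusive, 20 mm Hg) scores 4; syncope/presyncope requiring
#' countermeasures scores 6 regardless of the drop. With supine hypertension
#' the 2-point band onset moves to `supine_hypertension_drop_threshold`
#' (30 mm Hg, the consensus orthostatic-hypotension rule) with the band width
#' preserved. A diastolic drop of at least `diastolic_drop_threshold`
#' (10 mm Hg) is noted but does not change the score, which is systolic-based.
#'
#' @param two_point_drop_range Length-2 numeric, closed band (mm Hg).
#' @param four_point_drop_threshold Numeric (mm Hg), exclusive.
#' @param supine_hypertension_drop_threshold Numeric (mm Hg).
#' @param diastolic_drop_threshold Numeric (mm Hg).
#' @return An object of class `orthostasis_config`.
#' @export
orthostasis_config <- function(two_point_drop_range = c(10, 20),
                               four_point_drop_threshold = 20,
                               supine_hypertension_drop_threshold = 30,
                               diastolic_drop_threshold = 10) {
  stopifnot(length(two_point_drop_range) == 2,
            all(two_point_drop_range > 0),
            diff(two_point_drop_range) > 0,
            four_point_drop_threshold >= two_point_drop_range[2],
            supine_hypertension_drop_threshold > two_point_drop_range[1],
            diastolic_drop_threshold > 0)
  structure(
    list(two_point_drop_range = as.numeric(two_point_drop_range),
         four_point_drop_threshold = as.numeric(four_point_drop_threshold),
         supine_hypertension_drop_threshold =
           as.numeric(supine_hypertension_drop_threshold),
         diastolic_drop_threshold = as.numeric(diastolic_drop_threshold)),
    class = "orthostasis_config"
  )
}

#' Revised limb sensory item score
#'
#' Maps the most proximal level of lost sensation on a limb to the revised
#' six-step grid `0, 1, 1.5, 2, 2.5, 3`: normal 0; toes/fingers 1; foot/hand
#' 1.5; lower leg/forearm 2; knee/upper arm 2.5; thigh/shoulder 3. The
#' half-point levels (foot, knee, hand, upper arm) are the granularity added
#' by the revision.
#'
#' @param region `"lower_limb"` or `"upper_limb"`.
#' @param level Anatomical level on the region's ladder.
#' @return Item score in `{0, 1, 1.5, 2, 2.5, 3}` (vectorised over `level`).
#' @examples
#' limb_sensory_score("lower_limb", "foot")  # 1.5
#' @export
limb_sensory_score <- function(region, level) {
  region <- match.arg(region, c("lower_limb", "upper_limb"))
  ladder <- .limb_ladders[[region]]
  idx <- match(level, ladder)
  if (anyNA(idx)) {
    stop(sprintf("level(s) %s not on the %s ladder (%s)",
                 paste(sQuote(level[is.na(idx)]), collapse = ", "),
                 region, paste(ladder, collapse = ", ")), call. = FALSE)
  }
  unname(.revised_limb_scores[idx])
}

#' Trunk and head sensory item score
#'
#' Identical under both scale versions: no loss 0, loss to the midline of the
#' trunk 1, to the midclavicular line 2, to the neck and face 3. The original
#' labels (`umbilical`, `clavicular`) are accepted as rank-equivalent.
#'
#' @param level Level on the trunk/head ladder.
#' @return Item score in `{0, 1, 2, 3}` (vectorised).
#' @examples
#' trunk_sensory_score("midline_trunk")  # 1
#' @export
trunk_sensory_score <- function(level) {
  idx <- match(level, .trunk_ladder)
  alt <- match(level, .trunk_ladder_original)
  idx[is.na(idx)] <- alt[is.na(idx)]
  if (anyNA(idx)) {
    stop(sprintf("level(s) %s not on the trunk/head ladder (%s)",
                 paste(sQuote(level[is.na(idx)]), collapse = ", "),
                 paste(.trunk_ladder, collapse = ", ")), call. = FALSE)
  }
  idx - 1
}

#' MRC grade to Kumamoto motor item score
#'
#' The modified MRC mapping: normal power (5) scores 0; 50% weak (4) scores 2;
#' movement against gravity (3) scores 3; movement with gravity eliminated (2)
#' scores 4; visible contraction without movement (1) scores 5; no visible
#' contraction (0) scores 6. Score 1 is unreachable by design.
#'
#' @param mrc_grade Integer grade(s) 0-5.
#' @return Item score in `{0, 2, 3, 4, 5, 6}` (vectorised).
#' @examples
#' mrc_to_kumamoto(4)  # 2
#' @export
mrc_to_kumamoto <- function(mrc_grade) {
  if (any(is.na(mrc_grade)) || any(mrc_grade != round(mrc_grade)) ||
      any(mrc_grade < 0 | mrc_grade > 5)) {
    stop("mrc_grade must be an integer in 0-5", call. = FALSE)
  }
  c(6, 5, 4, 3, 2, 0)[mrc_grade + 1]
}

#' NIS-LL grade to Kumamoto motor item score
#'
#' Alternate motor mapping from the Neuropathy Impairment Score ladder:
#' 0 -> 0, 2 -> 2, 3.25 -> 3, 3.50 -> 4, 3.75 -> 5, 4 -> 6.
#'
#' @param nis_grade Grade(s) in `{0, 2, 3.25, 3.50, 3.75, 4}`.
#' @return Item score in `{0, 2, 3, 4, 5, 6}` (vectorised).
#' @examples
#' nisll_to_kumamoto(3.25)  # 3
#' @export
nisll_to_kumamoto <- function(nis_grade) {
  idx <- match(nis_grade, .nisll_grades)
  if (anyNA(idx)) {
    stop("nis_grade must be one of 0, 2, 3.25, 3.50, 3.75, 4", call. = FALSE)
  }
  c(0, 2, 3, 4, 5, 6)[idx]
}

# --- internal per-domain scorers ------------------------------------------
# Each returns list(items = named numeric (NA = missing), notes = character(),
# missing = character()).

.score_sensory <- function(findings, scale = "revised") {
  items <- stats::setNames(numeric(8), item_registry(scale)$item_code[1:8])
  notes <- character()
  limb_fun <- if (scale == "revised") limb_sensory_score else
    limb_sensory_score_original
  mod_tag <- c(cold = "cold", pinprick = "pinprick", light_touch = "touch")
  for (f in findings) {
    if (f$region == "trunk_head") {
      if (f$modality == "light_touch") {
        notes <- c(notes, paste(
          "trunk/head light touch is not a scored item;",
          "finding recorded but excluded from scoring"))
        next
      }
      code <- paste0("sens_", mod_tag[[f$modality]], "_trunk_head")
      sc <- trunk_sensory_score(f$level)
    } else {
      code <- paste0("sens_", mod_tag[[f$modality]], "_", f$region)
      sc <- limb_fun(f$region, f$level)
    }
    # worse-side merging: the item scores the maximum across sides
    items[[code]] <- max(items[[code]], sc)
  }
  list(items = items, notes = notes, missing = character())
}

.score_motor <- function(findings) {
  codes <- paste0("motor_", .movements)
  items <- stats::setNames(rep(NA_real_, 4), codes)
  notes <- character()
  for (f in findings) {
    code <- paste0("motor_", f$movement)
    sc <- if (!is.na(f$mrc_grade)) mrc_to_kumamoto(f$mrc_grade)
          else if (!is.na(f$nis_ll_grade)) nisll_to_kumamoto(f$nis_ll_grade)
          else NA_real_
    if (is.na(sc)) next
    items[[code]] <- max(items[[code]], sc, na.rm = TRUE)
  }
  list(items = items, notes = notes, missing = codes[is.na(items)])
}

#' GI symptoms item score
#'
#' Revised grid `0, 1, 2, 4, 6`: no lower-GI symptoms 0; constipation (fewer
#' than three hard stools per week) 1; diarrhoea (at least three loose stools
#' per day) 2, 4 or 6 by severity tier. Tiers may be supplied pre-coded via
#' `gi_level_code`; raw stool counts are mapped through `tier_bands` and win
#' over the code on conflict (with a note). Under the original scale
#' (`scale = "original"`) constipation is not a symptom and scores 0.
#'
#' @param findings An [autonomic_findings()] object.
#' @param scale `"revised"` or `"original"`.
#' @param tier_bands Ascending loose-stools/day onsets for the 2-, 4- and
#'   6-point diarrhoea tiers (default 3, 6, 10; the first is the diarrhoea
#'   definition, the rest an artifact convention).
#' @return Item score, or `NA` when no GI field was recorded. Notes are
#'   attached as attribute `"notes"`.
#' @examples
#' gi_score(autonomic_findings(stools_per_week = 2, stools_hard = TRUE))  # 1
#' @export
gi_score <- function(findings, scale = c("revised", "original"),
                     tier_bands = c(3, 6, 10)) {
  scale <- match.arg(scale)
  stopifnot(length(tier_bands) == 3, all(diff(tier_bands) > 0))
  au <- findings
  notes <- character()
  raw_avail <- !is.na(au$stools_per_week) || !is.na(au$loose_stools_per_day)
  raw_score <- NA_real_
  if (raw_avail) {
    if (!is.na(au$loose_stools_per_day) &&
        au$loose_stools_per_day >= tier_bands[1]) {
      raw_score <- c(2, 4, 6)[findInterval(au$loose_stools_per_day, tier_bands)]
    } else if (!is.na(au$stools_per_week) && au$stools_per_week < 3) {
      raw_score <- if (scale == "revised") 1 else 0
      if (scale == "original") {
        notes <- c(notes,
                   "constipation is not a scored symptom on the original scale")
      }
    } else {
      raw_score <- 0
    }
  }
  code_score <- au$gi_level_code
  if (!is.na(code_score) && scale == "original" && code_score == 1) {
    notes <- c(notes,
               "constipation is not a scored symptom on the original scale")
    code_score <- 0
  }
  score <- if (!is.na(raw_score)) {
    if (!is.na(code_score) && code_score != raw_score) {
      notes <- c(notes, sprintf(
        "gi_level_code %s disagrees with raw stool pattern (scores %s); raw wins",
        au$gi_level_code, raw_score))
    }
    raw_score
  } else {
    code_score
  }
  structure(score, notes = notes)
}

#' Orthostasis item score
#'
#' The systolic drop is the supine pressure minus the worst (lowest) standing
#' pressure measured after 1 and 3 min. Revised bands: drop below 10 mm Hg
#' scores 0; 10-20 scores 2; above 20 scores 4; syncope/presyncope requiring
#' countermeasures scores 6. With supine hypertension the 2-point onset moves
#' to 30 mm Hg (band width preserved). Original bands (`scale = "original"`):
#' any measured drop up to 20 mm Hg scores 2 (a drop of exactly 0 scores 0);
#' above 20 scores 4; the syncope flag scores 6.
#'
#' @param findings An [autonomic_findings()] object.
#' @param cfg An [orthostasis_config()].
#' @param scale `"revised"` or `"original"`.
#' @return Item score in `{0, 2, 4, 6}`, or `NA` when the supine or all
#'   standing pressures are missing. Notes attached as attribute `"notes"`.
#' @examples
#' orthostasis_score(autonomic_findings(sbp_supine = 120,
#'                                      sbp_standing_3min = 105))  # 2
#' @export
orthostasis_score <- function(findings, cfg = orthostasis_config(),
                              scale = c("revised", "original")) {
  scale <- match.arg(scale)
  au <- findings
  notes <- character()
  standing <- c(au$sbp_standing_1min, au$sbp_standing_3min)
  if (is.na(au$sbp_supine) || all(is.na(standing))) {
    return(structure(NA_real_, notes = notes))
  }
  drop <- au$sbp_supine - min(standing, na.rm = TRUE)
  if (isTRUE(au$on_antihypertensives)) {
    notes <- c(notes, paste(
      "patient on antihypertensives: consider other causes of hypotension",
      "when interpreting the orthostasis score"))
  }
  if (!is.na(au$dbp_supine) && !is.na(au$dbp_standing) &&
      au$dbp_supine - au$dbp_standing >= cfg$diastolic_drop_threshold) {
    notes <- c(notes, sprintf(
      "diastolic drop of at least %g mm Hg meets the consensus orthostatic-hypotension criterion (not scored)",
      cfg$diastolic_drop_threshold))
  }
  if (isTRUE(au$orthostatic_syncope)) {
    return(structure(6, notes = notes))
  }
  score <- if (scale == "original") {
    if (drop > 20) 4 else if (drop > 0) 2 else 0
  } else {
    lo <- cfg$two_point_drop_range[1]
    hi <- cfg$four_point_drop_threshold
    if (isTRUE(au$supine_hypertension)) {
      width <- hi - lo
      lo <- cfg$supine_hypertension_drop_threshold
      hi <- lo + width
      notes <- c(notes, sprintf(
        "supine hypertension: 2-point band onset moved to %g mm Hg", lo))
    }
    if (drop > hi) 4 else if (drop >= lo) 2 else 0
  }
  structure(score, notes = notes)
}

#' Urination item score
#'
#' Post-void residual urine (bladder scan after double voiding) and
#' incontinence/catheter status: below 150 ml with no incontinence scores 0;
#' sporadic incontinence or 150-300 ml scores 2; retention with 300-500 ml
#' scores 4; catheterisation or above 500 ml scores 6. Bands are taken
#' low-inclusive (`[150, 300)`, `[300, 500]`, `> 500`). A caution note is
#' emitted when retention is scored without benign prostate hyperplasia
#' having been excluded.
#'
#' @param findings An [autonomic_findings()] object.
#' @return Item score in `{0, 2, 4, 6}`, or `NA` when neither a residual
#'   volume nor the catheter flag is available. Notes attached as `"notes"`.
#' @examples
#' urination_score(autonomic_findings(residual_urine_ml = 200))  # 2
#' @export
urination_score <- function(findings) {
  au <- findings
  notes <- character()
  if (isTRUE(au$catheterized)) {
    return(structure(6, notes = notes))
  }
  if (is.na(au$residual_urine_ml)) {
    if (isTRUE(au$sporadic_incontinence)) {
      notes <- c(notes,
                 "sporadic incontinence recorded but no bladder scan: item not scored")
    }
    return(structure(NA_real_, notes = notes))
  }
  r <- au$residual_urine_ml
  score <- if (r > 500) 6
    else if (r >= 300) 4
    else if (r >= 150 || isTRUE(au$sporadic_incontinence)) 2
    else 0
  if (r >= 150 && !isTRUE(au$prostate_hyperplasia_excluded)) {
    notes <- c(notes, paste(
      "urinary retention scored without benign prostate hyperplasia excluded;",
      "exclude it as a cause in elderly males"))
  }
  structure(score, notes = notes)
}

#' Dry eyes and dry mouth item scores
#'
#' Pass-through of the coded 0-3 severity grades (0 none, 1 mild, 2 moderate,
#' 3 severe). A dry mouth judged to be a side effect of the patient's
#' medications is excluded: scored 0 with a note.
#'
#' @param findings An [autonomic_findings()] object.
#' @return Named numeric `c(dry_eyes = , dry_mouth = )` (`NA` for ungraded
#'   items), with notes attached as attribute `"notes"`.
#' @examples
#' sicca_scores(autonomic_findings(dry_eyes_grade = 0, dry_mouth_grade = 3))
#' @export
sicca_scores <- function(findings) {
  au <- findings
  notes <- character()
  for (fld in c("dry_eyes_grade", "dry_mouth_grade")) {
    if (!is.na(au[[fld]]) && !au[[fld]] %in% 0:3) {
      stop(fld, " must be in 0-3", call. = FALSE)
    }
  }
  mouth <- au$dry_mouth_grade
  if (!is.na(mouth) && mouth > 0 && isTRUE(au$dry_mouth_drug_induced)) {
    notes <- c(notes,
               "dry mouth judged drug-induced: excluded from scoring (0 points)")
    mouth <- 0
  }
  structure(c(dry_eyes = au$dry_eyes_grade, dry_mouth = mouth), notes = notes)
}

.score_autonomic <- function(au, scale = "revised", cfg = orthostasis_config()) {
  gi <- gi_score(au, scale = scale)
  ort <- orthostasis_score(au, cfg = cfg, scale = scale)
  uri <- urination_score(au)
  sic <- sicca_scores(au)
  items <- c(auto_gi = as.numeric(gi), auto_orthostasis = as.numeric(ort),
             auto_urination = as.numeric(uri),
             auto_dry_eyes = unname(sic["dry_eyes"]),
             auto_dry_mouth = unname(sic["dry_mouth"]))
  notes <- c(attr(gi, "notes"), attr(ort, "notes"), attr(uri, "notes"),
             attr(sic, "notes"))
  list(items = items, notes = notes, missing = names(items)[is.na(items)])
}

#' Heart item score
#'
#' The cardiac ladder `0, 4, 8, 12`: normal 0; conduction disturbance (e.g.
#' first-degree AV block) 4; advanced conduction disturbance 8; pacemaker or
#' third-degree AV block, with heart failure counted only in this category,
#' 12.
#'
#' @param findings A [visceral_findings()] object.
#' @return Item score in `{0, 4, 8, 12}`, or `NA` when no cardiac level code
#'   is recorded.
#' @examples
#' heart_score(visceral_findings(cardiac_level_code = "conduction_disturbance"))
#' @export
heart_score <- function(findings) {
  code <- findings$cardiac_level_code
  if (is.na(code)) return(NA_real_)
  idx <- match(code, .cardiac_levels)
  if (is.na(idx)) {
    stop(sprintf("unknown cardiac level '%s' (expected one of %s)", code,
                 paste(.cardiac_levels, collapse = ", ")), call. = FALSE)
  }
  c(0, 4, 8, 12)[idx]
}

#' Kidney item score
#'
#' The renal ladder `0, 4, 8, 12`: no renal findings 0; proteinuria (dipstick
#' or quantified) 4; nephrotic syndrome — proteinuria above 3.5 g/24 h plus
#' hypoalbuminemia plus oedema, all derived from the raw components — 8; on
#' dialysis 12.
#'
#' @param findings A [visceral_findings()] object.
#' @return Item score in `{0, 4, 8, 12}`.
#' @examples
#' kidney_score(visceral_findings(dipstick_proteinuria = TRUE))  # 4
#' @export
kidney_score <- function(findings) {
  vi <- findings
  if (isTRUE(vi$on_dialysis)) return(12)
  prot_q <- !is.na(vi$proteinuria_g_per_24h) && vi$proteinuria_g_per_24h > 0
  nephrotic <- !is.na(vi$proteinuria_g_per_24h) &&
    vi$proteinuria_g_per_24h > 3.5 &&
    isTRUE(vi$hypoalbuminemia) && isTRUE(vi$oedema)
  if (nephrotic) return(8)
  if (isTRUE(vi$dipstick_proteinuria) || prot_q) return(4)
  0
}

.score_visceral <- function(vi) {
  items <- c(visc_heart = heart_score(vi), visc_kidney = kidney_score(vi))
  list(items = items, notes = character(), missing = names(items)[is.na(items)])
}

#' Sensory subdomain subscore
#'
#' Sum over the six limb items (cold, pinprick and light touch per limb
#' region, worse side per item) and the two trunk/head items (cold and
#' pinprick). Items without a finding count as intact sensation (0). Range
#' 0-24; half-point steps under the revised scale.
#'
#' @param findings List of [sensory_finding()] objects.
#' @param scale `"revised"` or `"original"`.
#' @return The subscore, with per-item contributions as attribute `"items"`
#'   and any exclusion notes as `"notes"`.
#' @export
sensory_subscore <- function(findings, scale = c("revised", "original")) {
  scale <- match.arg(scale)
  s <- .score_sensory(findings, scale)
  structure(sum(s$items), items = s$items, notes = s$notes)
}

#' Motor subdomain subscore
#'
#' Sum of the MRC-mapped (or NIS-LL-mapped) item scores over the four tested
#' movements, worse side per movement; identical under both scale versions.
#' Range 0-24. Untested movements make the subscore incomplete (`NA`).
#'
#' @param findings List of [motor_finding()] objects.
#' @return The subscore (`NA` if any movement is untested), with per-item
#'   contributions as attribute `"items"` and untested movements as
#'   `"missing"`.
#' @export
motor_subscore <- function(findings) {
  s <- .score_motor(findings)
  structure(if (length(s$missing)) NA_real_ else sum(s$items),
            items = s$items, missing = s$missing)
}

#' Autonomic subdomain subscore
#'
#' GI + orthostasis + urination + dry eyes + dry mouth; range 0-24.
#'
#' @param findings An [autonomic_findings()] object.
#' @param scale `"revised"` or `"original"`.
#' @param cfg An [orthostasis_config()].
#' @return The subscore (`NA` if any component item is not assessable), with
#'   per-item contributions as attribute `"items"`, applied-rule notes as
#'   `"notes"` and missing items as `"missing"`.
#' @export
autonomic_subscore <- function(findings, scale = c("revised", "original"),
                               cfg = orthostasis_config()) {
  scale <- match.arg(scale)
  s <- .score_autonomic(findings, scale, cfg)
  structure(if (length(s$missing)) NA_real_ else sum(s$items),
            items = s$items, notes = s$notes, missing = s$missing)
}

.new_breakdown <- function(scale_version, parts) {
  items <- unlist(lapply(parts, `[[`, "items"))
  notes <- unlist(lapply(parts, `[[`, "notes"))
  missing <- unlist(lapply(parts, `[[`, "missing"))
  subs <- vapply(parts, function(p) {
    if (anyNA(p$items)) NA_real_ else sum(p$items)
  }, numeric(1))
  names(subs) <- c("sensory", "motor", "autonomic", "visceral")
  structure(
    list(scale_version = scale_version,
         item_scores = items,
         subscores = subs,
         total = if (anyNA(subs)) NA_real_ else sum(subs),
         missing_items = as.character(missing),
         notes = as.character(notes),
         incomplete = length(missing) > 0),
    class = "kumamoto_breakdown"
  )
}

#' Score one assessment
#'
#' Runs the full scoring engine: item scores, the four 0-24 subdomain
#' subscores (sensory, motor, autonomic, visceral) and the 0-96 total, under
#' the revised or the original scale version. Scoring is deterministic and
#' independent of finding order. Items that cannot be assessed are reported
#' in `missing_items` and make the affected subscore and the total `NA`
#' (incomplete) — no imputation or proration is performed. Every non-obvious
#' rule applied (side-effect exclusions, code/raw conflicts, band shifts) is
#' recorded in `notes`.
#'
#' @param a A validated [assessment()].
#' @param scale `"revised"` (default) or `"original"`.
#' @param cfg An [orthostasis_config()].
#' @return An object of class `kumamoto_breakdown`: a list with
#'   `scale_version`, `item_scores` (named numeric, `NA` = missing),
#'   `subscores`, `total`, `missing_items`, `notes` and `incomplete`.
#' @examples
#' score_assessment(example_assessment())            # total 16.5
#' score_assessment(example_assessment(), "original") # total 17
#' @export
score_assessment <- function(a, scale = c("revised", "original"),
                             cfg = orthostasis_config()) {
  scale <- match.arg(scale)
  .stop_if_invalid(a)
  .new_breakdown(scale, list(
    .score_sensory(a$sensory, scale),
    .score_motor(a$motor),
    .score_autonomic(a$autonomic, scale, cfg),
    .score_visceral(a$visceral)
  ))
}

#' @export
print.kumamoto_breakdown <- function(x, ...) {
  cat(sprintf("<kumamoto_breakdown> %s scale\n", x$scale_version))
  cat(sprintf("  sensory %g | motor %g | autonomic %g | visceral %g\n",
              x$subscores["sensory"], x$subscores["motor"],
              x$subscores["autonomic"], x$subscores["visceral"]))
  cat(sprintf("  total: %g / 96%s\n", x$total,
              if (x$incomplete) " (INCOMPLETE)" else ""))
  if (length(x$missing_items)) {
    cat("  missing:", paste(x$missing_items, collapse = ", "), "\n")
  }
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Tidy a score breakdown
#'
#' @param x A `kumamoto_breakdown`.
#' @return A tibble with one row per item: `item_code`, `domain`, `score`.
#' @export
breakdown_items <- function(x) {
  stopifnot(inherits(x, "kumamoto_breakdown"))
  reg <- item_registry(x$scale_version)
  tibble::tibble(item_code = reg$item_code, domain = reg$domain,
                 score = unname(x$item_scores[reg$item_code]))
}
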