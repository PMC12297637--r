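# Multi-visit score trajectories and progression evaluation per the Swedish
# guideline rule.

#' Progression criteria
#'
#' The Swedish-guideline definition of significant disease progression:
#' subjective deterioration together with a more-than-4-point increase on the
#' Kumamoto score, unintentional weight loss of at least 5% of the body
#' weight, and/or onset of new symptoms or signs of further organ involvement
#' (the eyes excluded). The score threshold is a strict inequality, so a
#' delta of exactly 4 points does not qualify while a half-point revised
#' delta of 4.5 does.
#'
#' @param score_increase_threshold Points; the score criterion requires a
#'   delta strictly greater than this (default 4).
#' @param weight_loss_fraction Fraction of baseline body weight (default
#'   0.05) whose loss alone flags progression.
#' @param require_subjective_deterioration If `TRUE` (default) the score
#'   criterion additionally requires the subjective-deterioration flag; the
#'   weight and organ criteria stand alone.
#' @param exclude_eye_involvement Documentation flag (default `TRUE`): the
#'   `new_organ_involvement` flag must already exclude the eyes; a reminder
#'   note is emitted.
#' @param baseline `"first"` (default) compares each visit with the first
#'   visit; `"previous"` with the preceding visit.
#' @return An object of class `progression_criteria`.
#' @export
progression_criteria <- function(score_increase_threshold = 4,
                                 weight_loss_fraction = 0.05,
                                 require_subjective_deterioration = TRUE,
                                 exclude_eye_involvement = TRUE,
                                 baseline = c("first", "previous")) {
  stopifnot(score_increase_threshold > 0,
            weight_loss_fraction > 0, weight_loss_fraction < 1)
  structure(
    list(score_increase_threshold = score_increase_threshold,
         weight_loss_fraction = weight_loss_fraction,
         require_subjective_deterioration = require_subjective_deterioration,
         exclude_eye_involvement = exclude_eye_involvement,
         baseline = match.arg(baseline)),
    class = "progression_criteria"
  )
}

#' Score a visit series
#'
#' Scores an ordered series of assessments for one patient and tabulates
#' per-visit totals, subscores and deltas versus the baseline (first) visit
#' and versus the previous visit. Incomplete visits (missing items) are
#' flagged; their deltas are `NA`.
#'
#' @param assessments List of [assessment()] objects for one patient, in
#'   strictly increasing date order.
#' @param scale `"revised"` or `"original"`.
#' @param cfg An [orthostasis_config()].
#' @return A tibble of class `kumamoto_trajectory` with one row per visit:
#'   `patient_id`, `visit`, `visit_date`, the four subscores, `total`,
#'   `incomplete`, `delta_baseline`, `delta_previous`, `weight_kg`,
#'   `subjective_deterioration`, `new_organ_involvement`. The full
#'   breakdowns are attached as attribute `"breakdowns"`.
#' @export
trajectory <- function(assessments, scale = c("revised", "original"),
                       cfg = orthostasis_config()) {
  scale <- match.arg(scale)
  stopifnot(length(assessments) >= 1)
  ids <- vapply(assessments, `[[`, character(1), "patient_id")
  if (length(unique(ids)) != 1) {
    stop("assessments mix patient ids: ",
         paste(unique(ids), collapse = ", "), call. = FALSE)
  }
  dates <- as.Date(vapply(assessments, function(a) format(a$visit_date),
                          character(1)))
  if (length(dates) > 1 && any(diff(dates) <= 0)) {
    stop("visit dates must be strictly increasing", call. = FALSE)
  }
  br <- lapply(assessments, score_assessment, scale = scale, cfg = cfg)
  totals <- vapply(br, `[[`, numeric(1), "total")
  subs <- t(vapply(br, `[[`, numeric(4), "subscores"))
  out <- tibble::tibble(
    patient_id = ids,
    visit = seq_along(assessments),
    visit_date = dates,
    sensory = subs[, "sensory"], motor = subs[, "motor"],
    autonomic = subs[, "autonomic"], visceral = subs[, "visceral"],
    total = totals,
    incomplete = vapply(br, `[[`, logical(1), "incomplete"),
    delta_baseline = totals - totals[1],
    delta_previous = c(NA_real_, diff(totals)),
    weight_kg = vapply(assessments, `[[`, numeric(1), "weight_kg"),
    subjective_deterioration = vapply(assessments, `[[`, logical(1),
                                      "subjective_deterioration"),
    new_organ_involvement = vapply(assessments, `[[`, logical(1),
                                   "new_organ_involvement")
  )
  out$delta_baseline[1] <- NA_real_
  attr(out, "breakdowns") <- br
  attr(out, "scale") <- scale
  class(out) <- c("kumamoto_trajectory", class(out))
  out
}

#' Evaluate disease progression along a trajectory
#'
#' Applies the progression rule visit by visit: the score criterion fires
#' when the total-score delta exceeds the threshold (strictly) and — by
#' default — subjective deterioration is recorded; the weight criterion fires
#' on loss of at least the configured fraction of baseline body weight; the
#' organ criterion fires on the `new_organ_involvement` flag. A visit is
#' flagged as progression when any criterion fires. Missing weights disable
#' only the weight criterion, with a note.
#'
#' @param traj A [trajectory()] result.
#' @param weights Optional numeric per-visit weights (kg) overriding those
#'   recorded on the assessments.
#' @param criteria A [progression_criteria()].
#' @return A tibble with one row per visit: `visit`, `visit_date`,
#'   `score_delta`, `score_criterion`, `weight_criterion`, `organ_criterion`,
#'   `progression`, `triggered` (comma-separated criteria that fired), and
#'   `notes`.
#' @examples
#' # see the package vignette for a worked multi-visit example
#' @export
evaluate_progression <- function(traj, weights = NULL,
                                 criteria = progression_criteria()) {
  stopifnot(inherits(traj, "kumamoto_trajectory"))
  n <- nrow(traj)
  w <- if (is.null(weights)) traj$weight_kg else as.numeric(weights)
  stopifnot(length(w) == n)
  totals <- traj$total
  ref <- function(i) {
    if (criteria$baseline == "first") totals[1] else totals[i - 1]
  }
  notes <- rep("", n)
  global_notes <- character()
  if (criteria$exclude_eye_involvement) {
    global_notes <- c(global_notes,
      "organ criterion: new_organ_involvement must exclude the eyes")
  }
  global_notes <- c(global_notes, sprintf(
    "score criterion read as: subjective deterioration together with >%g-point increase (deltas vs %s visit); weight and organ criteria stand alone",
    criteria$score_increase_threshold, criteria$baseline))
  score_crit <- weight_crit <- organ_crit <- rep(FALSE, n)
  score_delta <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i == 1) next
    if (!is.na(totals[i]) && !is.na(ref(i))) {
      score_delta[i] <- totals[i] - ref(i)
      subj_ok <- !criteria$require_subjective_deterioration ||
        isTRUE(traj$subjective_deterioration[i])
      score_crit[i] <- score_delta[i] > criteria$score_increase_threshold &&
        subj_ok
    } else {
      notes[i] <- paste0(notes[i], "incomplete scores: score criterion not evaluable; ")
    }
    if (!is.na(w[1]) && !is.na(w[i])) {
      weight_crit[i] <- (w[1] - w[i]) >= criteria$weight_loss_fraction * w[1]
    } else {
      notes[i] <- paste0(notes[i], "missing weight: weight criterion disabled; ")
    }
    organ_crit[i] <- isTRUE(traj$new_organ_involvement[i])
  }
  triggered <- vapply(seq_len(n), function(i) {
    paste(c("score", "weight", "new_organ")[c(score_crit[i], weight_crit[i],
                                              organ_crit[i])],
          collapse = ",")
  }, character(1))
  out <- tibble::tibble(
    visit = traj$visit, visit_date = traj$visit_date,
    score_delta = score_delta,
    score_criterion = score_crit, weight_criterion = weight_crit,
    organ_criterion = organ_crit,
    progression = score_crit | weight_crit | organ_crit,
    triggered = triggered, notes = trimws(notes)
  )
  attr(out, "notes") <- global_notes
  out
}

#' Modified body mass index
#'
#' mBMI = BMI (kg/m^2) times serum albumin (g/L), the standard nutritional
#' marker in ATTRv amyloidosis follow-up; it corrects the BMI for
#' oedema-inflated body weight.
#'
#' @param weight_kg Body weight in kg.
#' @param height_m Height in metres.
#' @param serum_albumin_g_per_L Serum albumin in g/L.
#' @return mBMI in kg/m^2 * g/L (vectorised).
#' @examples
#' mbmi(72, 1.8, 40)  # 888.9
#' @export
mbmi <- function(weight_kg, height_m, serum_albumin_g_per_L) {
  if (any(is.na(weight_kg)) || any(is.na(height_m)) ||
      any(is.na(serum_albumin_g_per_L)) ||
      any(weight_kg <= 0) || any(height_m <= 0) ||
      any(serum_albumin_g_per_L <= 0)) {
    stop("weight, height and albumin must all be positive", call. = FALSE)
  }
  weight_kg / height_m^2 * serum_albumin_g_per_L
}
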