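# Readers and writers: JSON assessment documents (versioned schema) and the
# long CSV interchange format, plus score-breakdown serialisation. Units are
# fixed (mm Hg, ml, kg, g/L, g/24 h); dates are ISO 8601. Readers report
# every problem they find, with line/record locations, not just the first.

.schema_version <- "1.0"

.json_assessment_fields <- c(
  "patient_id", "visit_date", "sensory", "motor", "autonomic", "visceral",
  "weight_kg", "height_m", "serum_albumin_g_per_L",
  "subjective_deterioration", "new_organ_involvement")
.json_sensory_fields <- c("modality", "region", "level", "side", "instrument")
.json_motor_fields <- c("movement", "mrc_grade", "side", "nis_ll_grade")
.autonomic_fields <- function() names(formals(autonomic_findings))
.visceral_fields <- function() names(formals(visceral_findings))

.csv_fields <- list(
  motor = c("mrc", "mrc_left", "mrc_right", "nis_ll", "nis_ll_left",
            "nis_ll_right"),
  sensory = c("level", "level_left", "level_right", "instrument"),
  auto_gi = c("stools_per_week", "stools_hard", "loose_stools_per_day",
              "gi_level_code"),
  auto_orthostasis = c("sbp_supine", "sbp_standing_1min", "sbp_standing_3min",
                       "dbp_supine", "dbp_standing", "supine_hypertension",
                       "orthostatic_syncope", "on_antihypertensives"),
  auto_urination = c("residual_urine_ml", "sporadic_incontinence",
                     "catheterized", "prostate_hyperplasia_excluded"),
  auto_dry_eyes = "grade",
  auto_dry_mouth = c("grade", "drug_induced"),
  visc_heart = c("level_code", "finding_text"),
  visc_kidney = c("dipstick_proteinuria", "proteinuria_g_per_24h",
                  "hypoalbuminemia", "oedema", "on_dialysis"),
  meta = c("weight_kg", "height_m", "serum_albumin_g_per_L",
           "subjective_deterioration", "new_organ_involvement")
)

.as_flag <- function(x) {
  if (is.logical(x)) return(x)
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

#' Read assessments from JSON or CSV
#'
#' JSON documents carry a versioned `schema_version` field and an
#' `assessments` array mirroring the [assessment()] structure. The long CSV
#' format has columns `patient_id, visit_date, item_code, field, value`, one
#' row per recorded field; rows are grouped into one assessment per
#' patient-visit. All schema violations — unknown fields, unknown item codes,
#' malformed values — are collected and reported together with their record
#' or line numbers. Each parsed assessment is then validated with
#' [validate_assessment()]; any validation finding is also an error.
#'
#' @param path File to read.
#' @param format `"auto"` (by extension), `"json"` or `"csv"`.
#' @param lenient If `TRUE`, unknown fields are tolerated (and dropped with a
#'   warning) instead of rejected.
#' @return A list of validated `kumamoto_assessment` objects.
#' @export
read_assessments <- function(path, format = c("auto", "json", "csv"),
                             lenient = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  assessments <- if (format == "json") {
    .read_assessments_json(path, lenient)
  } else {
    .read_assessments_csv(path, lenient)
  }
  problems <- character()
  for (i in seq_along(assessments)) {
    v <- validate_assessment(assessments[[i]])
    if (nrow(v) > 0) {
      problems <- c(problems, sprintf(
        "assessment %d (%s @ %s): %s [%s] %s", i,
        assessments[[i]]$patient_id, format(assessments[[i]]$visit_date),
        v$field, v$rule, v$message))
    }
  }
  if (length(problems)) {
    stop("invalid assessment data in ", path, ":\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  assessments
}

.check_unknown <- function(given, known, where, problems, lenient) {
  extra <- setdiff(given, known)
  if (length(extra)) {
    msg <- sprintf("%s: unknown field(s) %s", where,
                   paste(sQuote(extra), collapse = ", "))
    if (lenient) warning(msg, call. = FALSE) else problems <- c(problems, msg)
  }
  problems
}

.read_assessments_json <- function(path, lenient) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  problems <- character()
  if (is.null(doc$schema_version)) {
    problems <- c(problems, "missing schema_version")
  } else if (!identical(as.character(doc$schema_version), .schema_version)) {
    problems <- c(problems, sprintf(
      "unsupported schema_version '%s' (expected '%s')",
      doc$schema_version, .schema_version))
  }
  problems <- .check_unknown(names(doc), c("schema_version", "assessments"),
                             "document", problems, lenient)
  recs <- doc$assessments
  if (is.null(recs)) {
    problems <- c(problems, "missing 'assessments' array")
    recs <- list()
  }
  out <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    where <- sprintf("assessments[%d]", i)
    problems <- .check_unknown(names(r), .json_assessment_fields, where,
                               problems, lenient)
    sens <- lapply(seq_along(r$sensory), function(j) {
      f <- r$sensory[[j]]
      problems <<- .check_unknown(names(f), .json_sensory_fields,
                                  sprintf("%s.sensory[%d]", where, j),
                                  problems, lenient)
      sensory_finding(f$modality %||% NA, f$region %||% NA, f$level %||% NA,
                      f$side %||% "unspecified", f$instrument)
    })
    mot <- lapply(seq_along(r$motor), function(j) {
      f <- r$motor[[j]]
      problems <<- .check_unknown(names(f), .json_motor_fields,
                                  sprintf("%s.motor[%d]", where, j),
                                  problems, lenient)
      motor_finding(f$movement %||% NA, f$mrc_grade %||% NA,
                    f$side %||% "unspecified", f$nis_ll_grade %||% NA)
    })
    problems <- .check_unknown(names(r$autonomic), .autonomic_fields(),
                               paste0(where, ".autonomic"), problems, lenient)
    problems <- .check_unknown(names(r$visceral), .visceral_fields(),
                               paste0(where, ".visceral"), problems, lenient)
    au <- do.call(autonomic_findings,
                  r$autonomic[intersect(names(r$autonomic), .autonomic_fields())])
    vi <- do.call(visceral_findings,
                  r$visceral[intersect(names(r$visceral), .visceral_fields())])
    out[[i]] <- assessment(
      r$patient_id %||% NA, r$visit_date %||% NA,
      sensory = sens, motor = mot, autonomic = au, visceral = vi,
      weight_kg = r$weight_kg %||% NA, height_m = r$height_m %||% NA,
      serum_albumin_g_per_L = r$serum_albumin_g_per_L %||% NA,
      subjective_deterioration = r$subjective_deterioration %||% NA,
      new_organ_involvement = r$new_organ_involvement %||% NA)
  }
  if (length(problems)) {
    stop("schema violations in ", path, ":\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.sens_code_parts <- function(code) {
  # sens_<tag>_<region>; tag 'touch' encodes light_touch
  m <- regmatches(code, regexec(
    "^sens_(cold|pinprick|touch)_(lower_limb|upper_limb|trunk_head)$", code))[[1]]
  if (length(m) == 0) return(NULL)
  list(modality = c(cold = "cold", pinprick = "pinprick",
                    touch = "light_touch")[[m[2]]],
       region = m[3])
}

.read_assessments_csv <- function(path, lenient) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("patient_id", "visit_date", "item_code", "field", "value")
  if (!all(required %in% names(df))) {
    stop("CSV must have columns ", paste(required, collapse = ", "),
         "; found ", paste(names(df), collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) return(list())
  df$line <- seq_len(nrow(df)) + 1L  # header is line 1
  problems <- character()
  motor_codes <- paste0("motor_", .movements)
  keys <- unique(df[, c("patient_id", "visit_date")])
  keys <- keys[order(keys$patient_id, keys$visit_date), , drop = FALSE]
  out <- list()
  for (k in seq_len(nrow(keys))) {
    rows <- df[df$patient_id == keys$patient_id[k] &
                 df$visit_date == keys$visit_date[k], , drop = FALSE]
    sens <- list(); mot_raw <- list()
    au_args <- list(); vi_args <- list(); meta_args <- list()
    for (j in seq_len(nrow(rows))) {
      code <- rows$item_code[j]; fld <- rows$field[j]
      val <- rows$value[j]; line <- rows$line[j]
      sp <- .sens_code_parts(code)
      if (!is.null(sp)) {
        if (!fld %in% .csv_fields$sensory) {
          problems <- c(problems, sprintf(
            "line %d: unknown field '%s' for item '%s'", line, fld, code))
          next
        }
        if (fld == "instrument") next  # attached below via level rows only
        side <- switch(fld, level = "unspecified", level_left = "left",
                       level_right = "right")
        sens[[length(sens) + 1L]] <-
          sensory_finding(sp$modality, sp$region, val, side)
      } else if (code %in% motor_codes) {
        if (!fld %in% .csv_fields$motor) {
          problems <- c(problems, sprintf(
            "line %d: unknown field '%s' for item '%s'", line, fld, code))
          next
        }
        side <- if (grepl("_left$", fld)) "left"
                else if (grepl("_right$", fld)) "right" else "unspecified"
        grade_kind <- if (grepl("^mrc", fld)) "mrc" else "nis_ll"
        mot_raw[[length(mot_raw) + 1L]] <- list(
          movement = sub("^motor_", "", code), side = side,
          kind = grade_kind, value = val)
      } else if (code %in% c("auto_gi", "auto_orthostasis", "auto_urination",
                             "auto_dry_eyes", "auto_dry_mouth")) {
        if (!fld %in% .csv_fields[[code]]) {
          problems <- c(problems, sprintf(
            "line %d: unknown field '%s' for item '%s'", line, fld, code))
          next
        }
        target <- switch(paste(code, fld),
                         "auto_dry_eyes grade" = "dry_eyes_grade",
                         "auto_dry_mouth grade" = "dry_mouth_grade",
                         "auto_dry_mouth drug_induced" = "dry_mouth_drug_induced",
                         fld)
        au_args[[target]] <- val
      } else if (code %in% c("visc_heart", "visc_kidney")) {
        if (!fld %in% .csv_fields[[code]]) {
          problems <- c(problems, sprintf(
            "line %d: unknown field '%s' for item '%s'", line, fld, code))
          next
        }
        target <- switch(paste(code, fld),
                         "visc_heart level_code" = "cardiac_level_code",
                         "visc_heart finding_text" = "cardiac_finding_text",
                         fld)
        vi_args[[target]] <- val
      } else if (code == "meta") {
        if (!fld %in% .csv_fields$meta) {
          problems <- c(problems, sprintf(
            "line %d: unknown field '%s' for item 'meta'", line, fld))
          next
        }
        meta_args[[fld]] <- val
      } else {
        problems <- c(problems, sprintf(
          "line %d: unknown item_code '%s'", line, code))
      }
    }
    # merge per (movement, side) motor grade rows
    mot <- list()
    if (length(mot_raw)) {
      key <- vapply(mot_raw, function(m) paste(m$movement, m$side), "")
      for (kk in unique(key)) {
        grp <- mot_raw[key == kk]
        mrc <- NA; nis <- NA
        for (g in grp) {
          if (g$kind == "mrc") mrc <- g$value else nis <- g$value
        }
        mot[[length(mot) + 1L]] <-
          motor_finding(grp[[1]]$movement, mrc, grp[[1]]$side, nis)
      }
    }
    flag_fields <- c("stools_hard", "supine_hypertension", "orthostatic_syncope",
                     "on_antihypertensives", "sporadic_incontinence",
                     "catheterized", "prostate_hyperplasia_excluded",
                     "dry_mouth_drug_induced", "dipstick_proteinuria",
                     "hypoalbuminemia", "oedema", "on_dialysis",
                     "subjective_deterioration", "new_organ_involvement")
    for (f in intersect(names(au_args), flag_fields)) {
      au_args[[f]] <- .as_flag(au_args[[f]])
    }
    for (f in intersect(names(vi_args), flag_fields)) {
      vi_args[[f]] <- .as_flag(vi_args[[f]])
    }
    for (f in intersect(names(meta_args), flag_fields)) {
      meta_args[[f]] <- .as_flag(meta_args[[f]])
    }
    out[[length(out) + 1L]] <- assessment(
      keys$patient_id[k], keys$visit_date[k],
      sensory = sens, motor = mot,
      autonomic = do.call(autonomic_findings, au_args),
      visceral = do.call(visceral_findings, vi_args),
      weight_kg = meta_args$weight_kg %||% NA,
      height_m = meta_args$height_m %||% NA,
      serum_albumin_g_per_L = meta_args$serum_albumin_g_per_L %||% NA,
      subjective_deterioration = meta_args$subjective_deterioration %||% NA,
      new_organ_involvement = meta_args$new_organ_involvement %||% NA)
  }
  if (length(problems)) {
    stop("schema violations in ", path, ":\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  out
}

.assessment_to_list <- function(a) {
  drop_na <- function(x) x[!vapply(x, function(v) {
    is.null(v) || (length(v) == 1 && is.na(v))
  }, logical(1))]
  list(
    patient_id = a$patient_id, visit_date = format(a$visit_date),
    sensory = lapply(a$sensory, function(f) drop_na(unclass(f))),
    motor = lapply(a$motor, function(f) drop_na(unclass(f))),
    autonomic = drop_na(unclass(a$autonomic)),
    visceral = drop_na(unclass(a$visceral)),
    weight_kg = a$weight_kg, height_m = a$height_m,
    serum_albumin_g_per_L = a$serum_albumin_g_per_L,
    subjective_deterioration = a$subjective_deterioration,
    new_organ_involvement = a$new_organ_involvement
  )
}

#' Write assessments to a JSON document
#'
#' @param assessments A list of `kumamoto_assessment` objects (or one).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_assessments <- function(assessments, path) {
  if (inherits(assessments, "kumamoto_assessment")) {
    assessments <- list(assessments)
  }
  doc <- list(schema_version = .schema_version,
              assessments = lapply(assessments, .assessment_to_list))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write a score breakdown (or scale comparison) to file
#'
#' JSON output mirrors the `kumamoto_breakdown` structure (items in score
#' sheet order, subscores, total, missing items, notes) under the versioned
#' schema; CSV output is a long `section,key,value` table. Both round-trip
#' through [read_breakdown()].
#'
#' @param b A `kumamoto_breakdown` or `kumamoto_comparison`.
#' @param path Output file.
#' @param format `"auto"` (by extension), `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_breakdown <- function(b, path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  if (inherits(b, "kumamoto_comparison")) {
    if (format != "json") {
      utils::write.csv(b$items, path, row.names = FALSE)
      return(invisible(path))
    }
    doc <- list(schema_version = .schema_version, type = "comparison",
                original = .breakdown_to_list(b$original),
                revised = .breakdown_to_list(b$revised),
                total_delta = b$total_delta)
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  stopifnot(inherits(b, "kumamoto_breakdown"))
  if (format == "json") {
    doc <- c(list(schema_version = .schema_version, type = "breakdown"),
             .breakdown_to_list(b))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else {
    long <- rbind(
      data.frame(section = "meta", key = "scale_version",
                 value = b$scale_version),
      data.frame(section = "item", key = names(b$item_scores),
                 value = as.character(b$item_scores)),
      data.frame(section = "subscore", key = names(b$subscores),
                 value = as.character(b$subscores)),
      data.frame(section = "total", key = "total",
                 value = as.character(b$total)),
      if (length(b$missing_items)) {
        data.frame(section = "missing", key = b$missing_items, value = "")
      },
      if (length(b$notes)) {
        data.frame(section = "note", key = seq_along(b$notes),
                   value = b$notes)
      }
    )
    utils::write.csv(long, path, row.names = FALSE)
  }
  invisible(path)
}

.breakdown_to_list <- function(b) {
  reg_order <- item_registry(b$scale_version)$item_code
  list(scale_version = b$scale_version,
       item_scores = as.list(b$item_scores[reg_order]),
       subscores = as.list(b$subscores),
       total = b$total,
       missing_items = b$missing_items,
       notes = b$notes,
       incomplete = b$incomplete)
}

#' Read a score breakdown written by [write_breakdown()]
#'
#' @param path File to read.
#' @param format `"auto"`, `"json"` or `"csv"`.
#' @return A `kumamoto_breakdown`.
#' @export
read_breakdown <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  if (format == "json") {
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    items <- vapply(doc$item_scores, function(x) {
      if (is.null(x)) NA_real_ else as.numeric(x)
    }, numeric(1))
    subs <- vapply(doc$subscores, function(x) {
      if (is.null(x)) NA_real_ else as.numeric(x)
    }, numeric(1))
    structure(
      list(scale_version = doc$scale_version, item_scores = items,
           subscores = subs,
           total = if (is.null(doc$total)) NA_real_ else as.numeric(doc$total),
           missing_items = as.character(unlist(doc$missing_items)),
           notes = as.character(unlist(doc$notes)),
           incomplete = isTRUE(doc$incomplete)),
      class = "kumamoto_breakdown")
  } else {
    long <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    pick <- function(section) long[long$section == section, , drop = FALSE]
    it <- pick("item"); su <- pick("subscore")
    missing <- pick("missing")$key
    structure(
      list(scale_version = pick("meta")$value[1],
           item_scores = stats::setNames(suppressWarnings(as.numeric(it$value)),
                                         it$key),
           subscores = stats::setNames(suppressWarnings(as.numeric(su$value)),
                                       su$key),
           total = suppressWarnings(as.numeric(pick("total")$value[1])),
           missing_items = as.character(missing),
           notes = as.character(pick("note")$value),
           incomplete = length(missing) > 0),
      class = "kumamoto_breakdown")
  }
}
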