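# Original 1997 scale scoring and side-by-side comparison with the revision.
# Motor, urination, sicca, heart and kidney items are scored identically to
# the revised engine; the limb sensory ladder, GI symptoms and orthostasis
# differ.

#' Original limb sensory item score
#'
#' The 1997 scale used three limb levels (toe/leg/thigh, finger/elbow/
#' shoulder) with scores `0, 1, 2, 3`. Findings recorded on the revised
#' five-level ladder are coarsened: toes/foot 1, lower leg/knee 2, thigh 3
#' (upper limb: fingers/hand 1, forearm/upper arm 2, shoulder 3). This is
#' exactly the floor of the revised score.
#'
#' @inheritParams limb_sensory_score
#' @return Item score in `{0, 1, 2, 3}` (vectorised over `level`).
#' @examples
#' limb_sensory_score_original("lower_limb", "foot")  # 1
#' @export
limb_sensory_score_original <- function(region, level) {
  floor(limb_sensory_score(region, level))
}

#' @rdname gi_score
#' @export
gi_score_original <- function(findings, tier_bands = c(3, 6, 10)) {
  gi_score(findings, scale = "original", tier_bands = tier_bands)
}

#' @rdname orthostasis_score
#' @export
orthostasis_score_original <- function(findings, cfg = orthostasis_config()) {
  orthostasis_score(findings, cfg = cfg, scale = "original")
}

#' @rdname score_assessment
#' @export
score_assessment_original <- function(a, cfg = orthostasis_config()) {
  score_assessment(a, scale = "original", cfg = cfg)
}

#' Compare the original and revised scales on one assessment
#'
#' Scores the assessment under both scale versions and tabulates item-wise,
#' subdomain-wise and total differences (revised minus original). The revised
#' scale's finer sensory grid and its constipation and orthostasis changes
#' are the only sources of disagreement.
#'
#' @param a A validated [assessment()].
#' @param cfg An [orthostasis_config()].
#' @return An object of class `kumamoto_comparison`: list with `original` and
#'   `revised` breakdowns, an `items` tibble (`item_code`, `domain`,
#'   `original`, `revised`, `delta`), a `subscores` tibble, and `total_delta`.
#' @examples
#' compare_scales(example_assessment())  # total delta -0.5
#' @export
compare_scales <- function(a, cfg = orthostasis_config()) {
  orig <- score_assessment(a, "original", cfg)
  rev <- score_assessment(a, "revised", cfg)
  it <- breakdown_items(orig)
  items <- tibble::tibble(
    item_code = it$item_code, domain = it$domain,
    original = it$score,
    revised = unname(rev$item_scores[it$item_code])
  )
  items$delta <- items$revised - items$original
  subs <- tibble::tibble(
    domain = names(orig$subscores),
    original = unname(orig$subscores),
    revised = unname(rev$subscores)
  )
  subs$delta <- subs$revised - subs$original
  structure(
    list(original = orig, revised = rev, items = items, subscores = subs,
         total_delta = rev$total - orig$total),
    class = "kumamoto_comparison"
  )
}

#' @export
print.kumamoto_comparison <- function(x, ...) {
  cat("<kumamoto_comparison> original vs revised\n")
  su <- x$subscores
  for (i in seq_len(nrow(su))) {
    cat(sprintf("  %-9s original %4g | revised %4g | delta %+g\n",
                su$domain[i], su$original[i], su$revised[i], su$delta[i]))
  }
  cat(sprintf("  total     original %4g | revised %4g | delta %+g\n",
              x$original$total, x$revised$total, x$total_delta))
  invisible(x)
}
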