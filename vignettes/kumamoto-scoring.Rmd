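---
title: "Scoring ATTRv amyloidosis with the Kumamoto scale: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring ATTRv amyloidosis with the Kumamoto scale: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kumamotoscale)
```

## The instrument

Hereditary transthyretin (ATTRv) amyloidosis is a progressive multisystem
disease: sensorimotor and autonomic polyneuropathy together with cardiac,
gastrointestinal and renal involvement. The Kumamoto scale is a bedside
clinimetric instrument for following that whole picture. It has four
subdomains — sensory abnormalities, motor function, autonomic dysfunction and
visceral organ involvement — each scored 0–24 points from a closed registry
of items, summing to a 0–96 total. This package implements two versions of
the scale as deterministic scoring engines over structured clinical findings:

* the **revised** scale, whose main changes are a five-level anatomical
  ladder for limb sensory loss (half-point steps 0, 1, 1.5, 2, 2.5, 3),
  constipation as a separate 1-point GI symptom, a 10–20 mm Hg 2-point
  orthostasis band, MRC-based motor grading, and explicit definitions for
  residual urine bands and nephrotic syndrome; and
* the **original** 1997 scale, kept for retrospective comparability: a
  three-level limb sensory ladder (integer scores), no constipation point,
  and a 0–20 mm Hg 2-point orthostasis band.

Both engines share one input model (`assessment()` with sensory, motor,
autonomic and visceral findings), so one examination can be scored under
both versions side by side with `compare_scales()`.

## Item scoring rules

**Sensory.** A finding records the most proximal level of *lost* (not
reduced) sensation per modality (cold, pinprick, light touch) and region.
Limb levels map to 0/1/1.5/2/2.5/3 on the revised scale; the original scale
is exactly the floor of the revised score (toes and foot collapse to 1, lower
leg and knee to 2). Trunk/head levels (midline trunk, midclavicular line,
neck and face) score 1/2/3 under both versions and exist only for cold and
pinprick: the sensory maximum 24 = 9 (lower limb) + 9 (upper limb) + 6
(trunk/head), which leaves no room for a trunk light-touch item. A supplied
trunk light-touch finding is therefore recorded but excluded, with a note.

**Motor.** Four single-joint movements (ankle dorsiflexion, knee extension,
elbow flexion, wrist dorsiflexion), graded on the MRC scale and mapped
5→0, 4→2, 3→3, 2→4, 1→5, 0→6 (score 1 is unreachable by design); the NIS-LL
ladder 0/2/3.25/3.50/3.75/4 maps onto the same scores and may be supplied
instead or alongside (disagreement is a validation finding).

**Autonomic.** GI symptoms: constipation is fewer than three hard stools per
week (1 point, revised only); diarrhoea requires at least three loose stools
per day and occupies tiers 2/4/6. Orthostasis uses the worst systolic drop
after 1 and 3 min standing. Urination uses post-void residual urine by
bladder scan: <150 ml → 0, sporadic incontinence or 150–300 ml → 2,
300–500 ml → 4, catheterisation or >500 ml → 6. Dry eyes and dry mouth are
0–3 ordinal grades; a drug-induced dry mouth is excluded (scored 0 with a
note).

**Visceral.** Heart and kidney each on 0/4/8/12. Kidney: proteinuria → 4,
nephrotic syndrome (proteinuria >3.5 g/24 h *and* hypoalbuminemia *and*
oedema, always derived from the components) → 8, on dialysis → 12.

## Design choices where the instrument is silent

The published scale sheets leave several operational details open; this
package fixes them explicitly and records every applied rule in the
breakdown's `notes`:

* **Laterality.** Side handling is not specified. We accept per-side
  findings and score each item from the worse side (most proximal sensory
  level, lowest MRC grade); `side = "unspecified"` is a combined judgement.
  This follows the worst-deficit convention of impairment scales and
  preserves the 24-point subdomain maxima.
* **Missing items.** No imputation or proration: affected subscores and the
  total are reported as incomplete (`NA`) together with the list of missing
  items. Silent proration would corrupt longitudinal deltas. Absent sensory
  findings, by contrast, denote intact sensation — the sheet records
  deficits, not normals. Motor, autonomic and visceral items must be
  positively assessed.
* **Interval boundaries.** The printed band endpoints overlap (150/300/500 ml,
  10/20 mm Hg). We use low-inclusive half-open residual-urine bands
  ([150, 300), [300, 500], >500) and a closed [10, 20] systolic 2-point band;
  all boundary cases are pinned by tests.
* **Orthostasis upper categories.** Only the 2-point interval is printed.
  A drop above 20 mm Hg scores 4; 6 points require an explicit
  syncope/presyncope flag. With supine hypertension the 2-point onset moves
  to 30 mm Hg (the consensus orthostatic-hypotension threshold), band width
  preserved. All thresholds are configurable via `orthostasis_config()`.
  The diastolic criterion (10 mm Hg) is noted but never scored, since the
  printed bands are systolic. On the original scale we take the printed
  0–20 mm Hg band literally — any measured positive drop scores 2 — but a
  drop of exactly 0 scores 0 so that a fully normal examination totals 0.
* **Diarrhoea tiers.** The original tier wordings exist only as an image, so
  tiers 2/4/6 are accepted pre-coded (`gi_level_code`) or derived from
  configurable loose-stool bands (defaults 3–5, 6–9, ≥10 per day — an
  artifact convention, documented as such). When raw counts and a code
  disagree, raw wins with a conflict note. Constipation and diarrhoea do not
  co-occur in the score: the single worst applicable tier is used.
* **Heart 8-point category.** Not printed; reachable only through the
  explicit `advanced_conduction` code, sitting between first-degree block (4)
  and device/CHF (12).
* **Sicca grades 1–2.** Not described; the 0–3 codebook (none/mild/
  moderate/severe) is an artifact convention.

## Longitudinal use and the progression rule

`trajectory()` scores an ordered visit series and reports deltas versus the
baseline visit and versus the previous visit (the guideline does not say
which; baseline is the default and both are reported).
`evaluate_progression()` implements the Swedish-guideline definition of
significant progression: subjective deterioration together with a
more-than-4-point score increase, unintentional weight loss of at least 5% of
body weight, and/or new organ involvement (eyes excluded). The guideline
text mixes "together with" and "and/or"; we read the conjunction as binding
subjective deterioration to the score criterion only, with the weight and
organ criteria standing alone — this parsing is flagged in the output notes
and both the conjunction and the thresholds are configurable. The score
threshold is a strict inequality: a 4-point delta does not qualify, a
half-point revised delta of 4.5 does. `mbmi()` provides the modified body
mass index (BMI × serum albumin, kg/m² · g/L), the conventional nutritional
marker in ATTRv follow-up.

## The synthetic cohort generator

No patient-level dataset accompanies the instrument, so the package ships a
seeded simulator used throughout the test suite. Each patient carries one
latent severity per subdomain on the subscore scale [0, 24], drawn from a
truncated normal baseline and advancing linearly (points/year), clamped to
the range. A latent value is realised as findings by a greedy distal-first
fill: items are visited in a fixed order (lower limb before upper limb before
trunk; the revised score grids `0,1,1.5,2,2.5,3`, `0,2,3,4,5,6`, etc.) and
each item takes the largest grid score not exceeding the remaining latent
mass. The per-item scores are then inverted through the ladders into raw
findings — anatomical levels, MRC grades, a supine/standing blood-pressure
pair, residual urine volumes, stool counts, cardiac and renal categories.
"Quantised to the scale's step grid" means exactly the sum this greedy fill
attains; with zero rater noise, scoring a generated assessment recovers the
per-item targets and hence the quantised latent — a round-trip the tests
assert exactly. Rater noise miscodes each item to an adjacent grid level
with a configured probability, mimicking inter-rater disagreement on
neighbouring anatomical levels; no long-range errors are modelled.

Defaults emulate a moderate-stage, predominantly neuropathic cohort under
six-monthly follow-up: 25 patients, 6 visits, baseline latent means
(sensory 4, motor 2, autonomic 3, visceral 0, SDs 2/1/1.5/2), progression
1.5/1/1/0.5 points/year, 5% adjacent-level miscoding, body weight
N(75, 10) kg and stable unless a loss fraction is set. These are simulation
conventions chosen to exercise every scoring band within a typical follow-up
horizon, not natural-history estimates; the simulator makes no attempt to
calibrate against published survival. Consequently, passing tests show the
engines are faithful to the printed rules and internally consistent — they
say nothing about inter-rater reliability or clinical validity on real
patients, which the instrument's authors themselves list as future work.

`granularity_experiment()` quantifies the revision's stated motivation — a
more granular sensory ladder captures subtler progression — by recording,
per simulated patient, the first visit at which each scale's sensory
subscore departs from baseline. Because the original limb score is the floor
of the revised score, with zero noise the revised scale can never detect
change later; the experiment reports the mean lead time (visits and months)
and the proportion of patients where the revised scale was no later.

## Numerical and testing notes

Scoring is pure table arithmetic on half-point grids — exactly representable
in binary floating point, so equality comparisons are exact and breakdowns
are bit-for-bit reproducible and independent of finding order. The test
suite verifies the published worked example to the half point under both
scales, the complete MRC/NIS-LL mapping table, all band boundaries
(149/150/299/300/500/501 ml; 2 vs 3 stools/week; 9/10/20/21 mm Hg), an
exhaustive floor-refinement check over all limb levels, monotonicity of every
item in its raw finding, and oracle equivalence of the full engine against a
plain table-lookup sum on 1,000 randomly pre-coded assessments. Simulation
checks use 200 progressing patients over 6 visits under a fixed seed; sizes
were chosen to exercise all score bands while keeping the suite fast.

## A worked example

```{r}
a <- example_assessment()
compare_scales(a)
```

The finer revised sensory ladder scores the pinprick loss in the feet 1.5
instead of 1 (+0.5); constipation earns 1 point the original scale lacks,
while the 5 mm Hg orthostatic drop — scored 2 under the original 0–20 mm Hg
band — falls below the revised 10 mm Hg onset (net −1 autonomic); heart and
kidneys agree. Revised total 16.5 versus original 17.

## Limitations

The engines score what the sheet defines; they do not interpret ECGs, judge
drug causality of sicca symptoms, or handle ancillary investigations (nerve
conduction, echocardiography, scintigraphy). The original-scale GI and
sicca tier wordings survive only as coded categories. The simulator's
equal-width latent bands and symmetric noise are conveniences, not disease
models.
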