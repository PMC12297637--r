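# kumamotoscale

Deterministic scoring of the **Kumamoto scale** — revised and original 1997
versions — for monitoring hereditary transthyretin (ATTRv) amyloidosis.

ATTRv amyloidosis is a progressive multisystem disease: sensorimotor and
autonomic polyneuropathy plus cardiac, gastrointestinal and renal
involvement. The Kumamoto scale is the bedside instrument used for routine
follow-up in the Nordic countries: four subdomains — sensory, motor,
autonomic, visceral — each scored 0–24 points from ordinal clinical items,
summing to a 0–96 total. This package is for clinicians, trialists and
registry data managers who need reproducible, auditable scale scores from
structured examination findings.

The engines turn raw findings into item scores through the published
ladders:

* **Sensory** (0–24): most proximal level of *lost* sensation per modality
  (cold, pinprick, light touch) and region; revised limb grid
  {0, 1, 1.5, 2, 2.5, 3} (toes, foot, lower leg, knee, thigh / fingers,
  hand, forearm, upper arm, shoulder), original grid = floor(revised);
  trunk/head {0, 1, 2, 3} for cold and pinprick.
* **Motor** (0–24): MRC grades for ankle dorsiflexion, knee extension,
  elbow flexion, wrist dorsiflexion, mapped 5→0, 4→2, 3→3, 2→4, 1→5, 0→6
  (NIS-LL grades 0/2/3.25/3.50/3.75/4 map to the same scores).
* **Autonomic** (0–24): GI symptoms (constipation <3 hard stools/week = 1
  point, revised only; diarrhoea ≥3 loose stools/day in tiers 2/4/6),
  orthostasis (worst standing systolic drop: revised 10–20 mm Hg → 2,
  >20 → 4, syncope → 6; original counts any positive drop ≤20 as 2),
  urination (residual urine <150 ml → 0, incontinence or 150–300 → 2,
  300–500 → 4, catheter or >500 → 6), dry eyes and dry mouth (0–3, with a
  drug-induced exclusion).
* **Visceral** (0–24): heart and kidney each {0, 4, 8, 12}; nephrotic
  syndrome (proteinuria >3.5 g/24 h + hypoalbuminemia + oedema) → 8,
  dialysis → 12.

On top of the engines: side-by-side scale comparison, multi-visit
trajectories with the Swedish-guideline progression rule (subjective
deterioration together with a >4-point increase, ≥5% weight loss, and/or
new organ involvement excluding the eyes), a modified-BMI helper
(BMI × serum albumin), JSON/CSV readers with exhaustive validation, and a
seeded synthetic-cohort simulator that also quantifies the revised sensory
ladder's detection lead time over the original.

## Worked example

`example_assessment()` encodes the published comparison patient: loss of
cold sensation in fingers, feet and lower legs, loss of pinprick sensation
in the feet, normal motor function, a 5 mm Hg orthostatic systolic drop,
constipation (two hard stools per week), severe dry mouth, dipstick
proteinuria, and a first-degree AV block.

```r
library(kumamotoscale)
compare_scales(example_assessment())
#> <kumamoto_comparison> original vs revised
#>   sensory   original    4 | revised  4.5 | delta +0.5
#>   motor     original    0 | revised    0 | delta +0
#>   autonomic original    5 | revised    4 | delta -1
#>   visceral  original    8 | revised    8 | delta +0
#>   total     original   17 | revised 16.5 | delta -0.5
```

The revised scale's half-point limb levels score the pinprick loss in the
feet 1.5 instead of 1; constipation adds the new 1-point GI symptom; the
5 mm Hg drop no longer reaches the revised 10 mm Hg orthostasis onset
(it scored 2 under the original 0–20 mm Hg band). Heart (first-degree AV
block, 4) and kidneys (dipstick proteinuria, 4) are unchanged.

A command-line wrapper with `score`, `compare`, `validate`, `progression`
and `simulate` subcommands is installed at

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","kumamoto.R",package="kumamotoscale"))')" \
    score --in visits.json --scale both
```

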