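---
title: "Normative classification of visuospatial neglect from VR visual search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative classification of visuospatial neglect from VR visual search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neglectvr)
```

## The problem and the model

Unilateral visuospatial neglect leaves one half of space under-attended after
brain injury despite intact vision. Conventional pen-and-paper screens (clock
drawing, letter cancellation, line crossing) give a single binary call and
miss milder or right-sided presentations. An immersive-VR visual-search game
records far richer behaviour: per-trial accuracy and reaction time for
targets in the left or right hemispace at set sizes of 8, 16 and 24 elements,
plus per-level mean lateral orientation of the headset and gaze raycasts on a
2 m sphere centred on the calibrated head position.

`neglectvr` turns those recordings into an explainable three-class decision.
Eight raw metrics are computed per player:

| metric | family | definition | units |
|---|---|---|---|
| `accuracy_subtract` | orientation | accuracy(right targets) − accuracy(left targets), pooled over set sizes | pp |
| `rt_subtract` | orientation | mean RT(left) − mean RT(right), correct trials, outlier-filtered | s |
| `headset_mean`, `gaze_mean` | orientation | mean lateral raycast angle per set size | ° |
| `headset_slope`, `gaze_slope` | orientation | OLS slope of those means against set size | °/item |
| `accuracy_slope` | challenge | OLS slope of per-set-size accuracy | %/item |
| `rt_slope` | challenge | OLS slope of per-set-size mean RT | s/item |

Both subtraction terms are signed so that positive always means a rightward
behavioural orientation (worse performance on the left). Midline targets
(lateral angle exactly 0) belong to neither hemispace and are excluded from
the contrasts. The two repetitions of each set size are pooled into one
per-set-size summary.

RT outliers are removed per player with Tukey fences on the RTs themselves:
a trial is dropped when its RT falls strictly below `Q1 − 1.5·IQR` or
strictly above `Q3 + 1.5·IQR`. The filter is applied once, pooled over all
correct analysis trials for the subtraction contrast, and separately within
each game level for the per-set-size means that feed the RT slope. Quartiles
use linear interpolation between order statistics (R's default type-7
convention) everywhere; fences — and therefore every downstream label —
depend on this choice, so it is fixed and documented rather than left to the
caller.

## The normative model

Each metric value $M$ is flagged atypical by a conjunction of two
distribution-free outlier tests:

$$B = \big[(M < Q1_c - 1.5\,IQR_c) \lor (M > Q3_c + 1.5\,IQR_c)\big]
\;\land\;
\big[(M < Q1_p - 1.5\,IQR_p) \lor (M > Q3_p + 1.5\,IQR_p)\big],$$

with quartiles computed once in the control cohort ($c$) and once in the
patient cohort ($p$). A behaviour only counts as pathological when it is
unusual relative to healthy players *and* unusual even among patients — the
conjunction can only lower the false-positive rate relative to a
single-cohort Tukey rule, which the acceptance checks verify by simulation
(null patients drawn from the control distribution flag at well under the
single-cohort rate). Inequalities are strict: a value sitting exactly on a
fence is typical. A tiny relative epsilon (`1e-9` of the fence scale)
protects that boundary rule against floating-point representation of the
fence itself.

Flag coding follows the feature family. Orientation contrasts and slopes
become `sign(value)` when atypical (−1 leftward, +1 rightward), else 0. The
per-set-size mean metrics are flagged when atypical at one or more set sizes;
the direction is taken from the atypical mean with the largest fence
exceedance, measured against the nearer (binding) fence, and an exact
directional tie yields 0 with a warning. Challenge flags are one-sided:
`accuracy_slope` counts only when atypically *below* the lower fences and
`rt_slope` only when atypically *above* the upper fences — a player whose
accuracy rises or whose RT falls with set size is unusual but not challenged.
Missing metrics are flagged 0 with a warning; treating missingness as
atypical would fabricate pathology. Fences require at least 4 players per
cohort per metric (configurable) and can be frozen to JSON and reapplied, so
a normative model derived from one cohort can score new players.

## Summary scores and the neglect rule

* **atypicality** — number of non-zero flags, 0–8;
* **orientation** — algebraic sum of the six directional flags, −6..+6, so
  opposite effects cancel;
* **challenge** — sum of the two challenge flags, 0–2;
* **severity** — proportion of detection errors in the worse hemispace,
  `1 − min(acc_left, acc_right)/100`; descriptive only. Defined on the error
  scale so an unimpaired player scores ≈ 0.

A player is labelled **neglect** when `|orientation| > 1`, or when
`|orientation| > 0` and `challenge > 0`; **minor_atypicality** when flags are
present but the rule is unmet; **non_neglect** when atypicality is 0. The
rule uses the absolute orientation because right-neglect presents as a
*negative* orientation sum; the verbal form of the rule only makes sense for
both sides when read on the magnitude. Either path implies atypicality ≥ 2 —
converging evidence across features. Bands (`minor` ≤ 2, `moderate` ≤ 4,
`comprehensive` > 4) are descriptive metadata, distinct from the three-way
label.

Neglect cases receive a category code crossing side (`L`/`R`) with `O` for
high orientation and `C` for high challenge, where "high" means *at or
above* the median over all neglect players (both sides pooled in the
orientation median). The at-or-above convention is deliberate: challenge
takes small integer values, so a strict majority split would put a cut-off
of 1.0 *above* players scoring exactly 1; `≥` lets the cut-off sit on an
attained value. Explicit cut-offs can be supplied to score new cohorts
against frozen category boundaries.

## Diagnostic validation statistics

`confusion_analysis()` treats the VR label as ground truth and a binary
reference test as predictor, in two layouts: Model 1 keeps all three truth
classes (the binary predictor's minor-atypicality row exists with zero
counts); Model 2 pools minor atypicality into non-neglect. Reported per
class: sensitivity, specificity, balanced accuracy, PPV and NPV (through the
prevalence formulas, algebraically identical to the direct cell forms), F1
(β = 1), prevalence, detection rate and detection prevalence; undefined
ratios (zero denominators) propagate as `NA`, never as 0. Overall accuracy
carries an exact Clopper–Pearson 95% interval, and the comparison against
the no-information rate (always guessing the most prevalent class) is the
exact one-sided binomial tail `P(X ≥ correct)` — the standard
no-information-rate test. Agreement beyond chance is Cohen's
`κ = (P_o − P_c)/(1 − P_c)`.

Risk modelling is univariable Poisson regression of the atypicality count on
one covariate at a time (`stats::glm`, log link), reported as incidence rate
ratios with Wald 95% intervals. Categorical predictors are releveled so the
least frequent category (optionally the two least frequent combined) is the
reference; continuous predictors are never discretised. Patients with
atypicality 0 are retained in the fit — dropping them would discard most of
a typical cohort and bias the rates upward.

## The synthetic cohort generator

No gameplay recordings are distributable, so the package ships a seeded
generator that emulates the game design: eight levels, two repetitions of
set sizes 2/8/16/24 (reverse-ordered second half, set size 2 a tutorial),
40 trials per level balanced 20 left / 20 right on a spherical grid of four
eccentricities and three elevations. Correctness is Bernoulli with
probability `base + slope·set_size − hemispace deficit`, scaled by a lapse
rate; RT is log-normal around `rt_base + rt_slope·set_size + hemispace
penalty` (positive, right-skewed — the generative family is not prescribed
by the domain, so log-normal is fixed for reproducibility); per-set-size
orientation means are normal around `bias + bias_slope·set_size`. Per-player
seeds derive from the master seed by a documented multiplicative hash, so
cohorts reproduce independent of iteration order.

Preset effect sizes are fixed at values a clinician would recognise as
realistic and are not revisited: strong-orientation presets (`loc`, `lo`,
`ro`) use ±30° raycast bias, ~30-percentage-point contralesional accuracy
deficits and 0.6–0.7 s RT penalties; challenge presets steepen the accuracy
slope to about −1.2 pp/item and the RT slope to 0.09 s/item; `minor` applies
one mild anomaly (11° gaze bias, 12 pp deficit, 0.3 s penalty or a steepened
accuracy slope) on a single seed-chosen dimension, mirroring the clinical
picture of isolated sub-threshold signs. The default patient mix (29
typical, 9 minor, 5 LOC, 1 LO, 2 LC, 1 L, 1 RO, 3 RC of 51) reflects an
inpatient rehabilitation cohort in which most patients search normally and
left neglect outnumbers right.

The generator is deliberately simple where realism does not affect the
classifier: no serial-search process model, no correlation between headset
and gaze beyond shared means, no fatigue or learning across levels, and
covariates (age, sex, FIM, diagnosis, injury fields, the pen-and-paper
flag) are drawn from plausible marginals conditioned on the preset rather
than from a joint clinical model. Passing tests therefore demonstrate that
the pipeline recovers *known* effects injected in this idealised world; they
do not certify sensitivity or specificity on real gameplay.

## Numerical and design choices

* Quartiles: type-7 linear interpolation, everywhere.
* Fences: strict inequalities, ties typical, `1e-9` relative epsilon.
* Mean-metric direction tie-break: largest fence exceedance; exact ties → 0
  with a warning.
* Minimum cohort size per fence: 4.
* Set-size slopes are fitted to the three per-set-size means; with balanced
  repetitions this equals the per-level fit, and for equally spaced set
  sizes the OLS slope reduces to `(v24 − v8)/16`.
* Controls are scored and labelled exactly like patients, but category codes
  and the category medians are restricted to neglect-labelled patients.
* The RT outlier filter is a single pass, as the outlier definition
  specifies. It is not idempotent in general — removing tail values shrinks
  the quartiles, which can expose new values — and no second pass is taken.

## Problem sizes used by the checks

The test-suite and acceptance script work at sizes chosen to make the
stochastic properties sharp while staying quick to run: preset recovery uses
100 seeded cohorts of 10 controls + 16 patients (a mix of one player per
strong preset plus typical/minor fillers); the null-cohort conjunction check
uses 400 replicates at the study's 30/51 cohort sizes; Wald-interval
coverage uses 200 simulated 51-patient cohorts with a true rate ratio of
2.0; and the end-to-end run reproduces a full 81-player study.

## Known limitations

The conjunction rule makes patient fences sensitive to cohort composition:
when any one behavioural phenotype exceeds roughly a quarter of the patient
cohort, the patient quartiles absorb it and its members stop being outliers
among patients. This is a property of the method, not of the
implementation — it argues for heterogeneous normative cohorts. Likewise,
mild single-feature anomalies frequently fall inside the patient fences and
are labelled non-neglect rather than minor atypicality; the minor class is
intrinsically conservative under the conjunction. Finally, all empirical
performance figures produced here are conditional on the simulator's
assumptions above.
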