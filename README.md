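# cystscore

Automated segmentation and scoring of pulmonary cysts in thoracic CT.

In diffuse cystic lung diseases such as lymphangioleiomyomatosis (LAM),
the **cyst score** — the percentage of lung volume occupied by air-filled
cysts —

```
score = 100 × V_cyst / (V_lung − V_airway)
```

is a standard quantitative index of disease burden, tracked across
patient visits alongside pulmonary-function tests. The established
semi-automatic procedure segments cysts at a fixed global threshold of
−940 HU and relies on a trained operator to adjust that threshold by eye,
which makes the score vulnerable to operator variability and scanner
calibration drift — precisely the errors that matter when measuring a
slow rate of change.

`cystscore` implements a fully automatic, calibration-adaptive pipeline
for R users working with quantitative CT densitometry:

* **Adaptive thresholding.** Each scan's air reference `A` (median HU of
  the exterior air and the airway lumen) and a local parenchyma field
  `P(x)` (windowed 75th percentile of lung HU, 15 mm half-width) define a
  location-specific cyst threshold

  `T(x) = A + f · (P(x) − A)`, `f = 0.4`,

  calibrated so nominal anatomy (`A = −1000`, `P = −850`) reproduces the
  standard −940 HU. A uniform calibration shift moves `A`, `P` and `T`
  identically, so the segmentation is drift-invariant by construction.
* **Anatomy segmentation**: exterior air, lung fields (connected
  components + closing) and large airways (seeded region growing with
  leak control) from the HU volume alone.
* **Fixed-threshold baseline**: the semi-automatic core with the
  operator's visual adjustment exposed as a numeric offset.
* **Synthetic thoracic phantom** with exact ground-truth masks (body,
  lungs, trachea, power-law-sized spherical cysts, PSF blur, noise,
  calibration drift) so every stage is testable without clinical data.
* **Longitudinal tools**: per-patient cyst-score rate of change (%/year)
  from consecutive visits.
* **Validation statistics**: Bland–Altman limits of agreement,
  absolute-difference summaries, Welch's t, the two-sample F test,
  Pearson correlation with pulmonary-function values, Williams' test for
  two dependent correlations sharing one variable, and range truncation
  for comparisons over a common score range.

I/O: DICOM series (read; per-slice rescale to HU) and NIfTI
(read/write) via RNifti; CSV visit tables.

## A worked example

```r
library(cystscore)

ph <- generate_phantom(phantom_spec(seed = 7))
ph$true_fraction_pct
#> [1] 10.08301

auto  <- run_automatic(ph$volume)   # adaptive thresholds
fixed <- run_semiauto(ph$volume)    # fixed -940 HU baseline
auto$score_pct
#> [1] 9.711892
fixed$score_pct
#> [1] 8.808177

# a +30 HU calibration drift: the adaptive score barely moves,
# the fixed-threshold score loses ~3 points
drifted <- apply_calibration_shift(ph$volume, 30)
run_automatic(drifted)$score_pct - auto$score_pct
#> [1] -0.01347733
run_semiauto(drifted)$score_pct - fixed$score_pct
#> [1] -2.872887
```

The automatic score lands within 0.4 points of the geometric truth
(10.08%), and under a ±30 HU drift it moves by ~0.01 points while the
fixed threshold moves by ~3 — the adaptivity the method exists for.

A thin command-line front end is installed with the package
(`exec/cystscore`): `phantom`, `segment-anatomy`, `score`, `rates` and
`validate` subcommands over the same functions.

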