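# vncamarrow

Automated estimation of bone-marrow infiltration in plasma-cell disorders
(multiple myeloma and MGUS) from dual-energy CT.

Biopsy grades marrow infiltration from ~0.003 cm³ of tissue; this package
analyzes the whole thoracolumbar marrow space instead. After virtual
non-calcium (VNCa) post-processing removes the calcium signal, residual
marrow attenuation reflects cellular composition, because plasma-cell
infiltration displaces fatty marrow (HU ≪ 0) with soft-tissue-like cells
(HU > 0). The package is written for imaging scientists and
radiology/hematology researchers who want a transparent, fully testable
re-implementation of that workflow.

The core statistic is the **non-fatty portion of bone marrow**

    non-fatty portion = 100 · |{VNCa > 0 HU}| / |{VNCa > −1000 HU}|  (%)

computed over a marrow volume of interest built from the 17 most caudal
vertebrae with a 3 mm cortical erosion. Around it sit:

- a three-compartment (fat / soft tissue / mineral) forward model and a
  two-basis calcium-suppression transform (suppression index 25 = full
  removal; dense calcifications sink to the −1024 HU scale floor),
- rule-based vertebra labeling for phantoms plus an import path for
  external (e.g. CNN) label maps; 3 mm ball erosion honoring anisotropic
  voxel spacing,
- attenuation histograms (5 HU bins over [−1024, 3071] HU, standardized
  to 336.0 cm³ for group overlays),
- phantom-less BMD: two-point in-body calibration on subcutaneous fat and
  erector-spinae muscle, measured on L1–L3 with caudal fallback past
  lesioned vertebrae,
- the inference layer: logit-compressed bounded-response regression with
  White-type robust errors, Breusch–Pagan and VIF diagnostics, ROC with
  Youden thresholds, DeLong CIs and Obuchowski post-hoc power,
  noncentral-F sample-size planning, ICC(2,1) reader agreement, majority
  voting,
- a synthetic dual-energy spine-phantom and cohort generator with known
  composition, infiltration, BMD and lesion truth, so the whole pipeline
  is testable without clinical data.

## Worked example

Simulate the default 35-patient cohort (21 myeloma / 14 MGUS) and run the
full pipeline:

```r
library(vncamarrow)

report <- run_pipeline(run_config(seed = 1))
print(report)
#> vnca_report: 35 patients quantified (0 failed)
#> Infiltration model (n = 35), White-type (HC3) robust inference
#>                term estimate robust_se statistic  p_value
#> 1       (Intercept)  -3.6312   0.94020     -3.86 5.15e-04
#> 2 non_fatty_percent   0.1502   0.00994     15.12 4.00e-16
#> 3         bmd_mg_ml  -0.0188   0.00996     -1.88 6.86e-02
#> partial r (non-fatty | BMD) = 0.92; Breusch-Pagan p = 0.153; max VIF = 1.82
#> lesion outcome:    AUC 0.93 [0.84-1.00]; Youden threshold 25.6 (sens 0.86, spec 0.95); power 1.00
#> diagnosis outcome: AUC 0.99 [0.96-1.00]; Youden threshold 17.1 (sens 0.90, spec 1.00); power 1.00
```

Reading the output: each patient's phantom is rendered, calcium-
suppressed, segmented (17 vertebrae, 3 mm erosion) and reduced to its
non-fatty portion; the regression then shows that the statistic predicts
logit-transformed biopsy infiltration (robust p = 4e-16) after adjusting
for BMD, and the ROC blocks quantify how well it separates
lesion-positive reads and the myeloma diagnosis. On synthetic cohorts the
association is much stronger than in patients — VNCa noise puts the
phantom baseline near 12% rather than the clinical ~1% — so thresholds
here do not transfer to clinical data; the phantoms validate mechanics,
not clinical effect sizes (see the methods vignette).

Per-patient numbers and group histograms are tibbles throughout:

```r
report$quantification
#> # A tibble: 35 × 10  (patient_id, voi_volume_cm3, n_marrow, n_above_zero,
#> #   non_fatty_percent, bmd_mg_ml, vertebrae_used, bmd_fallback, reader_bmd_1, reader_bmd_2)
tidy(report$inference$regression)    # term-level estimates, robust and classical
glance(report$inference$regression)  # n, R², partial/semipartial/model r, BP, VIF
autoplot(report$inference$roc_lesions)
plot_group_histograms(report)        # myeloma vs MGUS standardized histograms
```

Deterministic single functions work standalone, e.g.
`roc_power(0.70, 13, 22)` → 0.5294, `regression_sample_size(f2 = 0.32)`
→ n = 27, `logit_bounded(0, 35)` → −4.2341.

A thin command-line front end is included at
`inst/scripts/vnca-marrow.R` (`run`, `simulate`, `quantify` on NIfTI
volumes).

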