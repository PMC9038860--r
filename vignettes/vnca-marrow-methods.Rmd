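---
title: "Quantifying bone-marrow infiltration from virtual non-calcium dual-energy CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bone-marrow infiltration from virtual non-calcium dual-energy CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Bone-marrow biopsy is the reference standard for grading plasma-cell
infiltration in multiple myeloma (MM) and its precursors (smoldering
myeloma, MGUS), but it samples a fraction of a cubic centimeter of a
patchy disease. Dual-energy CT (DECT) offers a whole-spine alternative:
after virtually removing the calcium signal from the vertebrae, the
residual marrow attenuation reflects its cellular composition, because
plasma-cell infiltrates displace fatty (strongly negative HU) marrow with
soft-tissue-like (positive HU) cells. `vncamarrow` implements that
pipeline end to end — calcium suppression, marrow segmentation, the
*non-fatty portion of bone marrow* statistic, in-body calibrated bone
mineral density (BMD), and the inference layer — together with a
synthetic dual-energy spine phantom generator that gives every stage a
known ground truth.

## The three-compartment model and calcium suppression

A marrow voxel is modeled as a volume mixture of fat, soft tissue and
bone mineral with fractions $f + s + m = 1$. Its attenuation at energy
$e$ is linear:

$$\mathrm{HU}_e = f\,H^{\mathrm{fat}}_e + s\,H^{\mathrm{soft}}_e + m\,H^{\mathrm{min}}_e .$$

Given co-registered low/high-energy grids, the pair of equations is
solved per voxel (a closed-form 2×2 inverse) for the soft excess $s$ and
the mineral content $m$, expressed in units of a reference mineral
density (400 mg/ml by default, so $m$ may exceed 1 inside cortical
bone). The virtual non-calcium (VNCa) value removes a fraction
$\sigma = \min(\mathrm{index}/25,\,1)$ of the mineral and renormalizes
the remaining sub-voxel to full volume:

$$\mathrm{VNCa} = \frac{\mathrm{HU}_{\mathrm{conv}} - \sigma\,\hat m\,H^{\mathrm{min}}_{\mathrm{conv}}}{1 - \sigma\,\hat m}.$$

At full suppression this returns exactly the attenuation of the fat/soft
mixture occupying the voxel, which is what makes the transform testable:
forward-model a composition, suppress, and the mineral term vanishes to
machine precision. Voxels whose estimated non-mineral volume vanishes
(dense calcification) have nothing to renormalize; they are mapped to
the HU floor of −1024, which reproduces the characteristic spike at the
far-left end of clinical VNCa marrow histograms. Output is clamped to
the CT scale [−1024, 3071].

Two numerical notes. First, the suppression-index semantics
($\sigma = \mathrm{index}/25$, clipped) are a declared convention: the
vendor mapping behind the "index 25" setting is unpublished, and only
full suppression is exercised by default. Second, the 2×2 solve
amplifies image noise considerably (with the default basis, 15 HU of
independent noise per energy becomes roughly 80 HU of VNCa noise in
marrow). This is a real property of two-material decomposition, and it
is why the synthetic phantoms show a noise-driven baseline of the marrow
statistic rather than the near-zero clinical baseline.

## Marrow segmentation

Clinical deployments segment vertebrae with a pre-trained CNN; that
model is external to this package. Two interchangeable paths produce the
label map instead: an imported integer label map (`labeled_spine()`),
or a rule-based labeler for phantom-like data (`label_vertebrae()`)
that thresholds the conventional image at +200 HU, fills each
cross-section, finds vertebral bodies as contiguous runs of bone-bearing
axial slices, and splits merged bodies at bone-profile minima below 20%
of the run maximum (a genuine fusion bridge carries far less bone than a
body section). Labels are ordered caudal to cranial by centroid;
segmentations are never silently corrected — a miscount surfaces as an
error, e.g. `found 16 < 17`.

The marrow VOI is the union of the 17 most caudal vertebrae (the
thoracolumbar stack), eroded by a 3 mm ball to exclude the bordering
cortical bone, which holds no marrow. The erosion honors anisotropic
voxel spacing: a voxel survives if and only if every voxel center within
3 mm physical distance belongs to the mask, so at 1×1×2 mm spacing the
structuring element has semi-axes of 3, 3 and 1.5 voxels. Erosion runs
on the union mask (equivalent to per-vertebra erosion for separated
bodies). Lesion voxels marked in an imported label map (label −1) are
excluded from the VOI, mirroring how CNN segmentations spare osteolytic
lesions.

## The non-fatty portion of bone marrow

The headline statistic is the percentage of marrow-VOI VNCa voxels with
attenuation strictly above 0 HU among voxels strictly above −1000 HU:

$$\text{non-fatty portion} = 100 \cdot \frac{|\{ \mathrm{VNCa} > 0 \}|}{|\{ \mathrm{VNCa} > -1000 \}|}\,\%.$$

Both inequalities are strict: 0 HU is not non-fatty and −1000 HU is not
marrow. The denominator rule exists because the VOI retains calcium-
removed dense-bone voxels at the scale floor; they are not marrow and
must not dilute the ratio. The statistic is computed from the raw voxel
sample, never from binned counts, to avoid 5-HU quantization bias; the
histogram (5 HU bins, left-closed right-open, anchored at −1024 HU over
[−1024, 3071]) is for reporting and display. For group overlays each
histogram is standardized to a common VOI volume of 336.0 cm³ so the
curves cover the same area.

## Phantom-less bone mineral density

BMD is measured without an external calibration phantom: ROI means in
subcutaneous fat and paravertebral (erector spinae) muscle anchor an
affine HU → mg/ml map, which is applied to the mean conventional HU of
the 3-mm-eroded trabecular interiors of the target vertebrae. Because
both anchors come from the same image, constant scanner drift cancels
exactly. Targets default to the 3rd–5th labels counting from the bottom
— L1–L3 of a thoracolumbar stack whose lowest labels are L5 and L4 — and
a target that intersects the lesion/fracture mask is replaced by the
next measurable vertebra of the *lower* spine, flagged as a fallback.

The hydroxyapatite-equivalent densities assigned to the two reference
tissues are not published for the clinical software. The package derives
its defaults from the material basis so that the two-point line inverts
the marrow mixing line — mineral displacing fat over a baseline of 95%
fat / 5% soft tissue — giving ≈ −2.6 mg/ml for fat and ≈ +50.1 mg/ml for
muscle with the default basis. This convention is validated purely by
phantom-truth recovery: noiseless phantoms recover their true BMD
exactly, and the median absolute error over noisy phantoms stays well
under 5 mg/ml. Its known limitation is composition confounding: diffuse
infiltration replaces fat with soft tissue and raises conventional-HU
BMD estimates above truth (tens of mg/ml at high infiltration). This
mirrors the fat-content sensitivity of clinical quantitative CT and is
one reason BMD enters the infiltration regression as a covariate.
Inter-reader variability is emulated by re-measuring with per-reader
subsampled ROIs; since phantom marrow is homogeneous, reader agreement
is nearly perfect (ICC(2,1) ≈ 1), which demonstrates the machinery, not
a realistic inter-reader spread.

## Statistical inference

Biopsy infiltration is a fraction that reaches both boundaries, so the
response is compressed before the logit, uniformly for all observations:
$y' = (y(n-1) + 0.5)/n$, then $\mathrm{logit}(y')$. The model is ordinary
least squares of the transformed infiltration on the non-fatty portion
with BMD as a control covariate. Heteroskedasticity is assessed with the
studentized Breusch–Pagan test (the $nR^2$ statistic of the auxiliary
regression of squared residuals on the design, $\chi^2_k$ reference) and
collinearity with variance inflation factors.

Robust inference is White-type. The reported standard errors use the
leverage-adjusted HC3 weights rather than White's original HC0: at
cohort sizes in the dozens, HC0 p-values reject a true null at roughly
8–9% instead of 5%, while HC3 — the standard small-sample recommendation
(Long & Ervin 2000) and the default in R's `sandwich` — holds the
nominal size. The HC0 matrix is still computed and exposed
(`fit$vcov_hc0`) and is verified against the textbook sandwich formula
in the tests; classical standard errors and p-values are reported
alongside. Because "the correlation" of a predictor with a response in a
two-predictor model is ambiguous, the fit reports all three flavours:
the partial correlation given BMD (headline), the semipartial
correlation, and the whole-model multiple correlation.

ROC analysis uses the empirical (Mann–Whitney) AUC with a DeLong 95%
interval (via pROC, the standard implementation). The operating
threshold maximizes Youden's J over midpoints between adjacent observed
scores (with sentinels beyond the range); a positive call is a score
strictly above the threshold, and ties in J are broken toward higher
specificity, then toward the higher threshold. Post-hoc power of the
two-sided AUC-vs-0.5 test uses the binormal model with Obuchowski's
variance function for continuous ratings, with the null variance at AUC
0.5 and the alternative variance at the observed AUC; two-sided is
assumed. The a-priori sample size for the regression iterates n upward
until the noncentral-F power of the 1-df main-predictor test (ncp
$f^2 n$, denominator df $n - k - 1$) reaches the target. A point worth
stating explicitly: noncentral-F theory describes the *classical* test,
so the package's power function is validated against classical p-values
under a fixed-noncentrality design; the robust HC3 test trades a little
power for its correct size. Reader agreement is ICC(2,1) from the
two-way ANOVA mean squares, and the radiologist lesion call is the
majority vote of three binary reads.

## The synthetic cohort

The phantom generator defines the study conditions. Geometry: 18
stacked cylindrical vertebral bodies (radius 12 mm, height 14 mm, 4 mm
gaps, 3 mm cortical shell of pure mineral) on a 48×48×216 grid at
1×1×1.5 mm — flat endplates and no posterior elements, because the
analyzed quantity is marrow-interior attenuation, not anatomy. Marrow
composition follows the affine displacement map
$s = 0.05 + 0.6\,i$ at infiltration $i$, with the mineral fraction set
by the true BMD; the coupling strength is a convention chosen to satisfy
monotonicity and recovery, not to reproduce clinical effect sizes.
Osteolytic lesions are mineral-free, soft-dominant spheres with radii
sampled from 4–12 mm; pure-fat and pure-muscle reference rods flank the
spine for the BMD calibration. Attenuation is the forward mixture model
plus additive Gaussian noise (sd 15 HU, independent across energies);
correlated noise, beam hardening, scatter and motion are out of scope.

Cohorts mirror a first-presentation plasma-cell-disorder population: 21
MM and 14 MGUS patients, MM biopsy infiltration drawn from a
Beta(0.63, 0.84) fitted once to the reported quartiles (median 40%, IQR
12.5–70%), MGUS infiltration a point mass at zero, true BMD normal
(96.8, 15) mg/ml, lesions in MM with probability 13/21, and three
simulated readers (sensitivity 0.9, specificity 0.95) whose majority
vote is the lesion outcome. Biopsy reports state 5%-wide ranges, so the
clinical record carries band midpoints (exact zeros stay zero). All
randomness flows from one top-level seed through per-patient derived
seeds; a rerun with the same configuration is byte-identical, and single
patients can be regenerated independently of the batch.

What passing tests do and do not show: the phantoms validate the
*mechanics* — exact mineral removal, geometry-faithful erosion,
truth-recovering segmentation and BMD, monotone infiltration response,
calibrated inference — under idealized physics. They do not certify
clinical effect sizes: the VNCa noise baseline puts the phantom
statistic in the tens of percent rather than the low single percents of
patients, thresholds learned on phantoms do not transfer, and the
homogeneous marrow makes reader agreement unrealistically perfect.

## Problem sizes and determinism

Default analyses use the full 35-patient cohort on the grid above
(≈ 0.5 M voxels per patient; a complete batch run takes well under ten
minutes on one CPU). Calibration simulations use 2,000 replicates at
n = 35 (size) and 20 seeds at n = 200 (slope recovery); oracle suites
run 200 random ROC fixtures. Erosion includes boundary offsets at
exactly the radius (tolerance 1e-9 mm); the degenerate VNCa
renormalization cutoff is a non-mineral volume of 1e-3; Youden and
ordering ties are broken deterministically as described, so every
reported number is reproducible bit for bit under a fixed seed.
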