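---
title: "Methods: outcome classification from MALDI-MSI peptide profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: outcome classification from MALDI-MSI peptide profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msiclass)
```

`msiclass` turns per-pixel MALDI mass spectrometry imaging (MSI) spectra of
tryptic peptides into a patient-level classifier of chemoradiotherapy
outcome in head and neck squamous cell carcinoma (HNSCC). This vignette is
the package's own account of the method: the model and its assumptions, the
parameters that matter, what the synthetic data generator does and does not
emulate, the numerical choices, and the known limitations.

## Data model

An `msi_dataset` holds one spectrum per tissue pixel (rows), an m/z axis in
Da (columns), pixel metadata (patient, slide, integer x/y grid position at a
nominal 50 µm pitch, and a tumor-ROI flag), and a patient table with the
outcome label: `NED` (no evidence of disease at two years, the positive
class) or `RecPro` (recurrence/progression). All modelling is restricted to
tumor-ROI pixels; non-tumor pixels are kept because they serve as each
patient's internal reference during standardization (see below).

## Preprocessing

The chain is fixed — top-hat baseline removal, then TIC normalization, then
peak detection/alignment — and is recorded in the feature matrix's
provenance attribute.

* **Top-hat baseline removal** subtracts the morphological opening of each
  spectrum (erosion then dilation with a flat structuring element). Peaks
  narrower than the element survive; slowly varying chemical baseline is
  removed. The default width is 201 axis points, an odd-width rendition of
  the conventional "peak width 200" vendor setting; whether that vendor
  parameter means points or mDa is not documented, so the width is exposed
  as `structure_width`. The implementation is the van Herk/Gil–Werman
  two-pass sliding extremum, vectorized over spectra, with partial windows
  at the edges; unit tests pin it to a brute-force erosion/dilation oracle.
* **TIC normalization** divides each spectrum by its intensity sum. In MSI
  the dominant nuisance is a smooth per-pixel multiplicative factor (matrix
  deposition, sampling efficiency, per-slide gain); TIC normalization
  removes anything shared by all features of a pixel. Spectra with
  non-positive total ion count are flagged and excluded.
* **Peak detection and alignment.** The vendor segmentation pipeline is
  proprietary, so the package uses the simplest reproducible surrogate that
  yields an aligned matrix of the expected shape: local maxima of the mean
  tumor spectrum above `min_prominence` become feature centroids; maxima
  closer than twice the alignment tolerance (default ±0.2 Da) are merged
  into the more intense one; each spectrum's feature value is the maximum
  intensity inside the window (windowed sum available via `agg = "sum"`).
  An optional 5-point moving-average smoothing before detection stands in
  for the vendor's undocumented "medium denoising" and is off by default.
* **2× down-sampling** for the full-feature model averages consecutive
  feature pairs (new centroid at the pair midpoint); an unpaired trailing
  column is kept unchanged, which preserves information and keeps the
  711 → 356 column arithmetic exact.

## Univariate screening

Per feature, the ROC-AUC of RecPro-vs-NED spectrum intensities is the
Mann–Whitney statistic divided by $n_1 n_2$ (ties count one half), so
AUC < 0.5 means lower intensity in RecPro tumors. To neutralize unequal
tissue areas, the larger group is randomly subsampled to the smaller group's
spectrum count (seeded; `n_draws > 1` reports selection stability across
draws, since a single undisclosed subsample is otherwise unauditable). A
feature is *discriminatory* when AUC > 0.7 or AUC < 0.3 — the lower branch
capturing inverse association — **and** its multiplicity-adjusted two-sided
Wilcoxon rank-sum p-value is below 0.001 (strict inequalities). The
correction method is Benjamini–Hochberg by default (the field's default for
per-feature screening; the correction used in the original analyses is
unnamed), with Bonferroni selectable. The rank-sum test uses the exact null
distribution when $n_1+n_2 \le 12$ without ties, otherwise a normal
approximation with tie-corrected variance and continuity correction.

With hundreds of spectra per patient, spectra are pseudo-replicates: the
rank-sum p-values are anti-conservative with respect to patients, which is
why selection leans on the AUC thresholds and the p-value acts as a filter.

## Classification model

The classifier is an L1-penalized, class-weighted logistic regression on
standardized feature intensities:

$$\min_{\beta, b}\; \frac{\sum_i w_i\,\mathrm{NLL}(y_i, x_i^\top\beta + b)}{\sum_i w_i} + \lambda \lVert \beta \rVert_1,$$

with $w_i$ inversely proportional to class frequency and the intercept
unpenalized. The solver is glmnet's coordinate descent (convergence
threshold 1e-10 on its internal criterion, up to 1e5 passes); a grid-search
oracle test verifies that the returned solution minimizes exactly this
objective. Two feature modes mirror the study design: `all_mz` (the
2×-down-sampled full matrix) and `restricted` (the screened subset).

**Per-patient standardization and its pitfall.** Each patient's features
are centred and scaled by that patient's own mean and SD, removing
systematic between-patient offsets; test patients use only their own
statistics, so no information crosses the train/test boundary. Taken
literally over exactly the analyzed spectra, however, this step is
degenerate: every patient's — hence every class's — feature means become
exactly zero, and with exact inverse-frequency weights the gradient of the
convex penalized likelihood at $\beta = 0$ vanishes, making the null model
the global optimum. Any non-trivial published result implies the
standardization statistics were computed on a wider spectrum set than the
modelled one. The package therefore computes each patient's statistics over
*all* of that patient's spectra — tumor ROI plus adjacent non-tumor tissue —
while fitting and evaluating on ROI spectra only. The non-tumor band acts as
an internal reference, and tumor-specific class differences survive
standardization.

**Cross-validation.** Folds are assigned to whole patients (never spectra),
stratified by outcome: within each class, patients are shuffled (seeded)
and dealt round-robin from a random starting fold, so fold sizes and class
mixes are balanced within one patient (31 patients give fold sizes
7/6/6/6/6, each fold with at least two NED patients). Stratification
granularity at the patient level is a deliberate reading of the ambiguous
"class-stratified sampling". A leakage guard asserts disjoint train/test
patient sets in every split.

**Evaluation.** Metrics are reported per split and as the arithmetic mean
over splits, at two levels. Spectra level: each test spectrum is called NED
when $P(\mathrm{NED}) > 0.5$. Patient level: class probabilities are summed
over the patient's spectra and the larger sum wins; an exactly tied sum is
called RecPro (the conservative call toward flagging risk; ties have measure
zero). Sensitivity is NED recall, specificity RecPro recall, balanced
accuracy their mean; ROC-AUC uses $P(\mathrm{NED})$ (patient level: the
summed probability) with NED positive. Majority voting counts a patient as
correctly classified only when *strictly* more than half of their spectra
are correct. Coefficient stability reports features with nonzero
coefficients in at least two splits and whether their signs agree across
splits.

**Regularization strength.** Published "strength" values for other
implementations are not portable across objective parameterizations (penalty
weight versus its inverse, and differing loss normalizations), so the
package's defaults were tuned once on the synthetic study conditions:
λ = 0.02 for `all_mz` (≈ 10–15 nonzero coefficients per split) and λ = 0.05
for `restricted`. Sparsity is monotone non-increasing in λ, which is tested.

**Transfer.** `cross_cohort_evaluate` quantifies a second cohort at the
training centroids, standardizes its patients on their own spectra, and
applies every split's model to all of its tumor spectra.

## The synthetic generator

`generate_cohort` emulates the study conditions so that every stage has a
measurable ground truth. Defaults (desk scale): 31 patients (20 RecPro / 11
NED) for the training-like cohort and 29 (15/14) for the transfer-like one;
200 tumor pixels per patient plus a 50% band of adjacent non-tumor pixels;
700 peptide peaks interleaved with gap points on a 1401-point axis over m/z
600–3200; 30 planted outcome-associated features; patients distributed over
9 slides. A `full_scale` flag raises the per-patient pixel count to 3500,
approximating the ~100k-spectra scale of a real cohort; the desk scale keeps
the full acceptance suite within minutes on one CPU.

On the log scale, a pixel's intensity at feature $f$ sums: a per-feature
abundance (SD 0.4); a per-patient, per-feature offset (SD 0.2); a per-slide,
per-feature batch offset (SD 0.1 — feature-specific, because purely
multiplicative slide gains would be removed by TIC normalization and have no
downstream consequence); a smooth spatial field common to all features of a
pixel (SD 0.6, correlation length 5 pixels — the dominant, TIC-removable
matrix/sampling variation); a latent spatial "program" shared by the planted
features only (SD 0.35), modelling co-expression of peptides from the same
proteins and giving the annotation module genuinely co-localized feature
pairs (calibrated once so that planted pairs exceed the default validation
correlation of 0.4 while unrelated pairs stay near zero); and white noise
(SD 0.35). Intensities are exponentiated, an additive slowly varying
baseline (amplitude 0.2 relative to a median peak of 1) is laid along the
raw axis so top-hat removal has real work to do, and gap points carry only
baseline plus a small positive noise floor.

The planted class shift is `effect_size` times the total log-scale SD of
all noise components, applied as a *decrease* in RecPro tumor pixels
(matching the observed inverse association, AUC < 0.3). With no subclones
the empirical standardized group difference therefore equals `effect_size`,
which a moment-estimation oracle test verifies. Intratumoral heterogeneity
is realized as contiguous subclone patches — a smoothed Gaussian field
thresholded at each patient's own (1 − fraction) quantile, so the realized
subclone fraction is exactly the nominal 20% — in which the *opposite*
class profile is expressed. Subclones are what keep the task non-trivial
after per-patient standardization, deflate per-feature AUCs toward the
selection threshold, and bound per-patient spectrum accuracy away from 1.

What the generator does **not** emulate: raw profile peak shapes and
isotope envelopes, matrix cluster ions, mass-calibration drift, ROI
annotation error, or patient-level clinical covariates. Passing tests
therefore demonstrate that the pipeline's statistics and machine learning
behave correctly under a realistic noise budget — not that the biological
effect sizes of real cohorts are recoverable.

The transfer-like cohort draws an independent planted feature set by
default, reproducing the qualitative finding that a model trained on one
treatment cohort does not transfer to another (patient-level balanced
accuracy near 0.5); passing the training cohort's planted features instead
(`signal_features =`) creates the shared-signal positive control, which
transfers to within 0.15 of the within-cohort performance.

`generate_peptide_library` writes a bottom-up LC-MS/MS-style library on the
same feature grid: multi-peptide proteins draw their peptides from planted
(co-expressed) features, singleton proteins from null features; masses are
stored as neutral monoisotopic values (feature m/z − 1.00728 Da) plus
measurement jitter.

## Annotation

Observed MALDI m/z values are treated as [M+H]⁺ ions of tryptic peptides
(the +1.00728 Da proton offset can be disabled). Candidates within ±0.2 Da —
mirroring the alignment interval; the original matching tolerance is not
documented — are ranked by smallest absolute mass deviation, then highest
−logP score, then sequence, making the result independent of library row
order. Protein validation implements the two-peptide rule quantitatively:
a protein is validated when ≥ 2 of its matched features have pairwise
Pearson correlations (Spearman selectable) of their ROI intensity vectors of
at least 0.4. "Similar tissue distribution" is not quantified anywhere
authoritative; 0.4 is a deliberately permissive default that cleanly
separates co-expressed planted pairs (≳ 0.45) from unrelated pairs (≲ 0.2)
under the default noise budget.

## Numerical choices and degenerate inputs

* Zero-SD features standardize to 0 rather than NaN; single-spectrum
  patients are an error.
* An all-zero spectrum cannot be TIC-normalized and is flagged and excluded.
* Tied aggregated patient probabilities → RecPro; exactly 50% correct
  spectra → not majority-correct.
* `tophat_baseline` requires an odd structuring element shorter than the
  axis; the pipeline wrapper caps the width below short demo axes.
* Feature matching ties (equal deviation, equal score) resolve
  alphabetically by sequence.
* All stochastic steps (generator, subsampling, fold assignment) draw from
  named seeds through an RNG-state-preserving wrapper, so identical configs
  are bit-identical and callers' random streams are untouched.
* Problem sizes in the test and acceptance runs are the desk-scale defaults
  above (31 + 29 patients × 300 pixels × 700 features; 5 seeds; 20 null
  replicates), chosen so the complete suite runs in a few minutes.

## Limitations

* The per-patient standardization degeneracy above means the package's
  account necessarily deviates from the literal published recipe; the
  chosen repair (whole-section statistics, ROI-only modelling) is one of
  several defensible readings.
* Printed regularization strengths from other software cannot be mapped
  onto λ without the original data; absolute coefficient scales are
  therefore not comparable.
* Patient-level metrics on ~30 patients have wide split-to-split
  variability; mean-over-splits values should be read as rough indicators,
  and the same caution applies to the synthetic analogues.
* The peak-detection surrogate reproduces the *shape* of a vendor-aligned
  feature matrix, not its exact centroid list; real-data feature counts
  will differ from any fixed target.
```{r session}
sessionInfo()
```
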