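---
title: "Methods: multi-site REIMS tissue classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-site REIMS tissue classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures the package
implements, the parameters that matter and their defaults, what the
synthetic cohort generator does and does not emulate, and the numerical
and design choices made where more than one reasonable option existed.

## The analysis problem

REIMS produces one lipid profile per second of electrosurgical cutting.
In negative mode, normal breast adipose yields spectra dominated by
triglyceride chloride adducts around m/z 850–1000, while invasive
carcinoma yields abundant glycerophospholipids around m/z 600–900. A
classifier built on these profiles can type tissue in near real time,
but multi-centre deployment exposes it to site effects: different
instruments, noise floors, analysts and pathology workflows. The
package's pipeline quantifies (a) how well tissue classification
transfers across sites and patients, (b) how large inter-site spectral
variability is relative to intra-site variability, and (c) whether a
molecular subtype (PIK3CA mutation) is readable from fatty-acid
profiles.

## Preprocessing

Each scan passes through four steps, in order:

1. **Background subtraction.** A per-scan scalar baseline is subtracted
   from every peak and intensities are clipped at zero. The default
   estimator is the scan's lower-quartile peak intensity — in a
   centroided REIMS peak list the large majority of entries are
   low-level chemical noise, so a low quantile of the intensity
   distribution estimates the chemical-background level without touching
   the (orders-of-magnitude larger) lipid peaks. A user-supplied scalar
   or per-peak background (e.g. a pre-burn solvent spectrum) can be
   passed instead.
2. **Lockmass correction.** The most intense peak within ±0.5 Da of the
   deprotonated leucine-enkephalin reference (m/z 554.2615) anchors a
   *uniform additive* m/z shift that places it exactly on the reference.
   A single-point additive correction (rather than a ppm-proportional
   one) is appropriate for a one-point calibrant and a 400 Da analysis
   window; after correction the reference sits on 554.2615 to within
   1e-9 Da. Scans with no peak in the window are flagged and excluded
   from modeling by the QC filter.
3. **Binning.** Intensities are summed into 0.1 Da bins over m/z
   600–1000 (the phospholipid/triglyceride region). Bins are half-open
   and left-closed, anchored at the grid start: m/z 600.0 falls in the
   first bin, 1000.0 outside the grid. In-range intensity is conserved
   exactly.
4. **TIC normalization.** Bin vectors are divided by their sum, making
   profiles comparable across scans of very different absolute
   intensity. The operation is idempotent and scale invariant.

Two filters sit around these steps. The **QC filter** excludes scans
whose raw (pre-normalization) TIC is *strictly below* 2×10⁴ counts, and
scans whose lockmass correction failed, recording machine-readable
reasons. **Label assignment** works per sampling point and propagates to
all of the point's scans: at least 30% tumor cells labels `tumor`
(inclusive threshold), exactly 0% with 100% normal adipose histology
labels `normal`, and anything else — including 0% points whose
surroundings are not pure adipose — is `excluded`. Points without an
annotation stay `unassigned` with a warning. The 30% rule is applied per
point, not per scan, because the histology label is extrapolated from
the tissue surrounding the ablated area.

Parameter defaults (all in `preprocess_config()`): lockmass reference
554.2615 Da, tolerance ±0.5 Da, bin width 0.1 Da, grid 600–1000 Da, QC
floor 2×10⁴ counts, tumor threshold 30%.

## PCA/LDA classification

`reims_pcalda()` fits PCA with at most 25 components (fewer when limited
by feature count or `n − 1`), then LDA in PCA space. The phrase "LDA
with n−1 dimensions" is read with *n = number of classes* — one
discriminant for the two-class problem — since linear discriminant
analysis cannot produce more than `n_classes − 1` directions; the
alternative reading (number of input variables) is not realizable.

Numerical conventions, chosen for exact reproducibility across runs and
platforms:

* PCA operates on TIC-normalized intensities *without* per-feature
  standardization — standardizing 0.1 Da bins would inflate the very
  chemical-noise bins the variability analysis identifies as a nuisance.
* Every PCA loading and LDA direction is oriented so its
  largest-magnitude coefficient is positive.
* The pooled within-class scatter is ridge-regularized with
  `epsilon = 1e-8 × trace/dim` only when numerically singular; the
  epsilon is recorded on the fitted object.
* LDA directions are scaled to unit pooled within-class variance, so
  Euclidean distance to a class centroid in discriminant space is
  already in within-class standard deviations.

Classification assigns the nearest centroid in that standardized space;
a spectrum farther than **5 SD** from its *nearest* centroid is flagged
an outlier. Outliers are retained in the default rate denominators, and
an option recomputes rates with them excluded — both readings are
reported because published confusion tables are reconcilable with their
printed rates only under the outlier-excluded denominator. Exact
distance ties break to the lexicographically first class label and are
recorded.

Three cross-validation schemes mirror the multi-centre questions:
`single_site` (train on one site, test on the others), `leave_site_out`
and `leave_patient_out`. Fold construction guarantees the held-out
site/patient never contributes training spectra; folds whose training
set loses a class are skipped with a warning; pooled confusion matrices
are the exact sum of fold matrices.

## Variability metrics

Cosine similarity (inner product over norm product; in [0, 1] for
non-negative spectra) is summarized within and between groups by median
and IQR. KNN site identification is leave-one-out with cosine distance,
majority vote among `k = 5` neighbours (k is not dictated by any
external constraint; 5 is a common default and exposed as a parameter),
vote ties broken toward the single nearest neighbour. The volcano table
computes per-bin two-sample t statistics — Welch's unequal-variance form
by default — with two-tailed p-values and log2 fold changes using a
pseudocount of half the smallest positive bin value in the contrast.
No multiple-testing correction is applied by default (raw p < 0.05
flags significance, matching common practice in this literature);
Benjamini–Hochberg is available behind a flag.

## Sparse feature selection and targeted models

`l1_feature_select()` fits an l1-penalized linear separator and returns
the bins with non-zero weight ranked by |weight|. The solver is
lasso-penalized logistic regression (`glmnet`) at the single penalty
`lambda = 1/(n × cost)`, reached by a warm-started path from the null
model — coordinate descent dropped directly onto a small lambda is
unreliable. The `cost` parameter (default 500) plays the role of the
inverse-regularization constant of margin-based sparse classifiers:
larger cost, weaker penalty, larger selected set; the selected-set size
is non-decreasing in cost. Because the l1 optimum is non-unique over
exactly identical columns, duplicate columns among the selection are
reported once, with combined weight, on the lowest bin index. The test
surface deliberately depends only on selected-set membership, never on
the weights themselves. `targeted_model()` refits the PCA/LDA classifier
on a selected subset (e.g. 11 ions) under the identical contract as the
full-range model.

## Fatty-acid profiles and the channel classifier

Six deprotonated ω6 fatty acids are read directly from the
lockmass-corrected peak list (not from the 600–1000 grid): FA(18:2)
279.23, FA(20:2) 307.26, FA(20:3) 305.25, FA(20:4) 303.23, FA(22:4)
331.26, FA(22:5) 329.25. Each channel is the maximum intensity within
±0.1 Da (matching the binning resolution) of its reference, and the
profile is normalized to the channel sum. Ratio analysis reports the
arachidonic-acid elongation products FA(22:4)/FA(20:4) and
FA(22:5)/FA(20:4), the direct elongation FA(20:2)/FA(18:2), and the
overall pathway flux (sum of the five products)/FA(18:2); all ratios are
homogeneous of degree zero in the profile.

The channel classifier stores, per class and channel, the **median** and
**standard deviation** of training profiles. How the six channel
likelihoods combine is an open choice; the package assumes independence
and sums per-channel Gaussian log-densities, the simplest reading of
"each channel's distribution" — and the one an explicit density oracle
verifies in the tests. SDs are floored at 1e-6 of the class-channel
median (1e-9 absolute when the median is zero) so degenerate classes
keep finite densities. Cross-validation is stratified k-fold (default
5), shuffled reproducibly from a seed; sensitivity is the positive-class
(default `Mut`) recall, specificity the recall of the remaining class.
Tukey box statistics use linear-interpolation quartiles (R quantile
type 7 — fences are sensitive to the quantile rule, so it is fixed and
documented) with whiskers at the most extreme points within 1.5 IQR of
the quartiles.

## The synthetic cohort generator

No clinical spectra are distributed with this package, so all end-to-end
validation runs on synthetic cohorts whose generative assumptions are
explicit:

* **Class templates** place the marker species of the reference ion
  table with class-appropriate intensities: TG/DG/FA(18:1) high in
  adipose, PE/PA/PI with FA(18:2)/FA(20:4) high in tumor. Absolute
  scales put a typical scan TIC near 10⁶ counts, so the 2×10⁴ QC floor
  is meaningful. Peak intensities are lognormal with cv 0.25,
  mean-corrected so expectations equal template means.
* **Partial tumors blend into stroma, not adipose.** A sampling point
  with tumor-cell percentage w mixes the tumor template (weight w/100)
  with a benign *stroma* template — phospholipid-leaning, low-TG —
  because the non-tumor fraction of a carcinoma-bearing region is
  fibrous stroma; pure adipose is its own class by the 100%-adipose
  labeling rule. This is why sub-threshold (excluded) points are mostly
  classified as cancer rather than normal, as observed clinically.
* **Hierarchical biological variability.** Per-patient and per-point
  lognormal perturbations (cv 0.35 and 0.20) of all template peaks give
  correlated within-class spread, so leave-patient-out folds face
  genuinely new patients and the discriminant cannot collapse onto
  directions with near-zero training variance.
* **Site effects**: overall intensity scale, constant mass drift
  (≤ 0.05 Da, removed by lockmass correction), chemical-noise floor
  scale, coagulation-mode TG attenuation, a mass-dependent
  instrument-response tilt `exp(slope × (mz − 800)/200)`, and ~40
  *consistent* site background ions at site-specific m/z positions —
  the reproducible low-abundance contaminants that make spectra
  site-identifiable. Within a site, acquisition drifts per sampling
  point (noise floor cv 0.5, slope jitter sd 0.08), so site differences
  shift distributions that already vary within a site instead of
  creating directions no training fold has seen. The defaults (three
  sites spanning a 4× intensity range, 0.7–1.6× noise range, ±0.15
  response tilt) are this package's choices of realistic magnitudes;
  no quantitative site-effect values are available to match.
* **Cautery modes** mix cut and coagulation per point (default 60% cut);
  coagulation attenuates TG peaks by a site-specific factor.
* **Subtypes.** Tumor-bearing patients are PIK3CA-mutant with default
  probability 0.66; mutant tumor templates scale the FA channels by
  (FA(18:2) 0.6, FA(20:2) 1.4, FA(20:3) 1.5, FA(20:4) 1.0, FA(22:4)
  1.6, FA(22:5) 1.6) — decreased precursor, increased downstream
  products, arachidonic acid itself unchanged. `scale_fa_effects()`
  interpolates these multipliers toward identity on the log scale for
  effect-size sweeps.
* **Tumor-cell percentages** default to a mixture (80% U(30, 95), 20%
  U(1, 29)) so the exclusion rule is exercised; the `table1_like`
  preset reproduces the published cohort shape exactly (3 sites × 7
  patients × 10 points, one scan each, 82/57/39/32
  normal-cut/normal-coag/tumor-cut/tumor-coag, all tumor points ≥ 30%).
* One global seed drives everything; identical seeds give bitwise
  identical cohorts. Consistent background-ion *positions* derive from
  the site identifier, independent of the stream.

**What the generator does not emulate** — and therefore what passing
tests do *not* establish about clinical data: isotope envelopes and
adduct chemistry; the physics of aerosol generation and transport;
pathologist labeling error and inter-observer variability;
tissue-heterogeneity structure beyond a two-template blend; real
lipidomic diversity beyond the 15 marker species plus noise; and any
site effect not in the list above. Recovery results on synthetic
cohorts demonstrate that the pipeline is correct and well-calibrated
under its own assumptions, not that clinical accuracy would reach the
same numbers.

## Problem sizes and runtime choices

The default synthetic cohort used by the test suite and the acceptance
script is 3 sites × 6 patients × 6 points × 2 scans = 216 spectra on a
4000-bin grid — large enough that leave-site-out folds retain ~140
training spectra per class pair while a full test run stays fast. The
channel-classifier effect-size sweep uses 30 patients × 4 points (120
profiles), comparable to the scale at which such subtype analyses are
reported. These sizes are the package's validation choices; all
generators accept larger designs.

## Degenerate inputs and edge rules

Empty spectra error in lockmass correction; all-zero spectra are flagged
by background subtraction and rejected by TIC normalization; zero
vectors are a domain error for cosine similarity; classes with fewer
than 2 (PCA/LDA) or 3 (channel model) samples are fit errors; a fold
that loses a class is skipped with a warning rather than silently
dropped; zero-variance bins yield `NA` p-values; zero FA denominators
yield `NA` ratios with a recorded reason; missing tumor-cell percentages
serialize as explicit missing values and never collapse to 0%, which
means a confirmed pure-normal point.

## Known limitations

* The lockmass search takes the most intense in-window peak; a massive
  interferent within ±0.5 Da of LeuEnk would mis-anchor the shift.
* LDA on ≤ 25 PCA components can still overfit when within-class
  variance is tiny along some direction; the ridge guard handles exact
  singularity, not near-singularity.
* The l1 selector's `cost` is mapped to `lambda = 1/(n × cost)`;
  selected sets for intermediate costs depend on the solver's penalty
  normalization and should be read as rankings, not as an exactly
  reproducible set under other solvers.
* The channel classifier mixes a robust location (median) with a
  non-robust scale (SD), as specified; heavy-tailed channels inflate
  the scale and flatten likelihood contrasts.
* mzML input is out of scope; the package reads its own documented CSV
  and JSONL peak-list dialects.
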