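# reims — multi-site REIMS lipidomic classification of breast tissue

Rapid evaporative ionization mass spectrometry (REIMS, the "iKnife")
analyses the aerosol produced by electrosurgical dissection in real time:
each one-second scan is a lipid profile of the tissue just cauterized.
Negative-mode spectra of normal breast adipose are dominated by
triglyceride chloride adducts (m/z 865.71, 893.74, 919.75), while
invasive breast cancer shows abundant glycerophospholipids (m/z 699.50,
744.55, 885.55) — a contrast strong enough to type tissue during surgery.
The hard question for clinical deployment is *transferability*: does a
classifier trained at one hospital still work on spectra acquired by a
different instrument, analyst and pathology workflow at another?

This package implements the complete multi-centre analysis workflow for
that question, for mass-spectrometrists and biostatisticians working with
REIMS (or comparable ambient-MS) tissue data:

* **Preprocessing** — background subtraction; per-scan lockmass
  recalibration against continuously infused leucine-enkephalin
  ([M−H]⁻ at m/z 554.2615); binning to 0.1 Da over m/z 600–1000; total
  ion count (TIC) normalization; QC exclusion of scans with raw TIC
  below 2×10⁴; histology-driven labeling (≥ 30% tumor cells → tumor,
  100% normal adipose → normal, anything between → excluded).
* **Classification** — PCA (≤ 25 components) followed by LDA
  (`n_classes − 1` discriminants), nearest-centroid assignment in
  standardized discriminant space with a 5×SD outlier rule, and three
  cross-validation schemes: single-site models, leave-one-site-out and
  leave-one-patient-out.
* **Variability** — intra/inter-site cosine-similarity summaries,
  leave-one-out KNN site identification (cosine distance), and per-bin
  Welch-t volcano tables.
* **Feature selection & fatty acids** — sparse (l1) linear feature
  selection (cost parameter C, default 500); targeted models on the
  selected bins; six-channel ω6 fatty-acid profiles
  (FA(18:2) 279.23, FA(20:2) 307.26, FA(20:3) 305.25, FA(20:4) 303.23,
  FA(22:4) 331.26, FA(22:5) 329.25, normalized to their sum); metabolic
  ratio analysis; and a Gaussian *channel classifier* (per class and
  channel, a normal distribution parameterized by median and SD; a
  sample joins the class with the highest summed log-likelihood) with
  stratified 5-fold cross-validation — used to probe PIK3CA-mutation
  subtypes from FA profiles.
* **Synthetic cohorts** — a generator that emulates the multi-centre
  study design (sites × patients × sampling points × scans, cut vs
  coagulation cautery, tumor-cell percentages, site intensity/noise/
  drift/response effects, hierarchical patient- and point-level
  biological variability, planted PIK3CA FA effects) with full ground
  truth, so every pipeline stage is testable end to end.

The core model objects follow the classic R idiom: `reims_pcalda()` and
`channel_fit()` return classed S3 objects with `print()`, `summary()`,
`predict()` and `plot()` methods.

## Worked example

```r
library(reims)
rep <- run_pipeline(list(seed = 1, cohort = list(seed = 1)))
print(rep)
```

```
simulate: 216 scans from 3 site(s)
preprocess: 216 scans kept, 0 excluded by QC
crossval: leave-site-out CCR 100.00%, leave-patient-out CCR 100.00%
variability: KNN site accuracy 54.1%
fa: channel-classifier CV accuracy 72.4%
REIMS pipeline report (seed 1)
  scans modeled: 196 of 216 simulated
  single_site        CCR  98.72%  FN  4.31%  FP  0.00%
  leave_site_out     CCR 100.00%  FN  0.00%  FP  0.00%
  leave_patient_out  CCR 100.00%  FN  0.00%  FP  0.00%
  KNN site accuracy: 54.1%
  selected features: 4 bins
  PIK3CA channel CV: acc 72.4%, sens 66.7%, spec 78.6%
  outputs: /tmp/.../reims_report_...
```

Reading the numbers: 216 scans are simulated from the default three-site
cohort; 196 carry a tumor or normal label (the rest are sub-threshold
tumor points, excluded by the 30% rule exactly as annotated clinical
points would be). Tissue classification transfers across sites and
patients essentially perfectly at the planted effect size (CCR = correct
classification rate; FN/FP = false negative/positive rates on the tumor
class). KNN site identification at 54% (chance 33%) says the tissue
signal dominates the residual site fingerprint after preprocessing,
while the PIK3CA channel classifier reaches 72% five-fold CV accuracy on
tumor FA profiles — the planted mutant effect (FA(18:2) down; FA(20:2),
FA(20:3), FA(22:4), FA(22:5) up) is real but, as in clinical data,
partially masked by patient-level variability. Every table is also
written as CSV under `rep$out_dir`, with a manifest recording the seed
and configuration hash.

Smaller pieces work standalone:

```r
d <- read_peaklist(system.file("extdata", "example_cohort_synthetic.csv",
                               package = "reims"))
prep <- preprocess_dataset(d)                  # lockmass, QC, bin, TIC
fit  <- reims_pcalda(prep$x, prep$meta$tissue_label)
ppm_error_mag(279.234, 279.2329)               # 3.9 ppm, FA(18:2) [M-H]-
```

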