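---
title: "Stabilized serum metabolic diagnosis: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stabilized serum metabolic diagnosis: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Label-free LDI-MS metabolic fingerprinting can classify serum samples in
seconds, but a single low-shot acquisition is noisy: the same sample measured
twice can move a classifier's predicted disease probability enough to flip
the diagnostic label. Averaging many laser shots (or many technical
replicates) restores reproducibility at the price of acquisition time.
`smpdx` implements the full analysis loop for studying and fixing this
trade-off on simulated cohorts: a shot-resolved spectrum simulator with
ground-truth biomarkers, serum-metabolic-profile (SMP) extraction, a
GAN-based *deep stabilizer* that maps one low-shot acquisition to a
high-shot-equivalent spectrum, sparse-learning diagnosis with biomarker
screening, and the diagnosis-variation-characteristic (MK) surface that
quantifies diagnostic reproducibility jointly with sensitivity and
specificity.

```{r}
library(smpdx)
run <- run_pipeline(pipeline_config(seed = 1), mode = "both")
run
```

# The acquisition model

`simulate_spectrum()` draws the mean of `n_shots` independent single-shot
spectra. Each single shot consists of

* Gaussian peaks (width `peak_sigma`, default 0.2 Da on the default
  9001-point, 0.1 Da grid) at the panel's m/z centres, with heights
  `2^log2_abundance`;
* a **global per-shot gain** (unit-mean lognormal, CV `gain_cv = 3.3`)
  multiplying every peak, the flat baseline and the chemical noise —
  the laser-fluence / sweet-spot component of shot-to-shot variability;
* an independent **per-peak ionization factor** (unit-mean lognormal,
  per-shot CV `shot_cv = 0.25`, modulated by a per-feature multiplier);
* Poisson-placed chemical-noise peaks (`chemical_noise_density` per Da)
  with heights below the planted-feature regime, re-drawn per acquisition;
* additive detector noise with per-shot standard deviation `detector_sd`.

Because all noise terms have unit mean (or zero mean), the expectation of a
spectrum is independent of `n_shots` and equals `analytic_spectrum()`, and
every apex variance scales exactly as `1/n_shots` — the averaging law the
whole study design rests on. Intensities are truncated at zero, a negligible
bias except in near-zero-signal regions at very low shot counts.

## Why this noise budget

The two CV parameters were fixed from the documented behaviour of the
measurement process, not from any internal test: a native 1000-shot
replicate should show apex CVs around 10–13% (the unstable regime that
motivates stabilization), while high-shot aggregates and stabilized spectra
reach 3–5%. The variance algebra ties these numbers together: for gain CV
$c_g$ and per-peak CV $c_f$ per shot, a peak factor has per-shot variance
$c_g^2 + c_f^2 + c_g^2 c_f^2$, of which only $c_g^2$ is shared across peaks
and therefore removable by any spectrum-level correction. With
$c_g = 3.3$ and $c_f = 0.25$ the 1000-shot apex CV is ≈ 10.8% and the
irreducible floor is ≈ 2.7%, so a perfect stabilizer lands exactly in the
documented 3–5% band. (An earlier draft with a larger per-peak share made
the floor ≈ 8.5%, i.e. a world in which *no* algorithm could reproduce the
documented stabilized CVs; that decomposition misrepresents the system being
emulated and was discarded.)

What the generator deliberately does **not** model: isotope envelopes,
adduct chemistry beyond optional fixed-offset satellites (off by default),
mass-calibration drift, baseline wander, detector saturation, or any
ionization physics. Tests passing on these simulations therefore demonstrate
algorithmic correctness and the direction of the stabilization effect under
a controlled noise budget — not instrument-grade performance on real serum
spectra.

# SMP extraction

`extract_smp()` chains four steps, each exposed separately:

* `detect_peaks()` — strict local maxima of a centred `window_points`
  window (default 5 grid points) that exceed the spectrum median. The
  implementation is vectorized but agrees point-for-point with an
  exhaustive window scan (tested).
* `estimate_snr()` — S/N = (apex − local baseline) / noise scale. The noise
  scale is `1.4826 × MAD` of the peak-free region (apexes masked with a
  `snr_exclude` half-width); the local baseline is the median of peak-free
  points within `snr_local` points. A noise-free spectrum reports a capped
  sentinel (1e6). Both half-widths scale with the grid: the defaults suit
  the 0.1 Da grid, and the pipeline shrinks them for coarse binned grids.
* `filter_by_snr()` — retains S/N **strictly above** 3; a peak at exactly
  the threshold is background by definition.
* `align_features()` — peaks pooled over all spectra, sorted by m/z, and
  greedily clustered with total cluster width ≤ `mz_tolerance` (default
  0.1 Da, chosen to equal the default grid spacing so quantization can
  never split a feature). Consensus m/z is the intensity-weighted mean.
  Missing cells are imputed as 0 — absence of a peak is information the
  sparse classifier may use — and a feature must be present in at least
  `min_fraction` (default 0.5) of spectra, which is what actually removes
  the randomly-placed chemical noise at high shot counts, where the S/N
  criterion saturates.

The filter is applied per spectrum and the presence requirement across
spectra; whether the original procedure pooled S/N across a cohort is not
determinable, so both knobs are exposed.

# The deep stabilizer

`train_stabilizer()` fits a generative-adversarial mapping from one binned
low-shot spectrum to its high-shot-equivalent reference (by construction:
the mean of the sample's replicates). The generator has two dense-block
convolutional branches fused by element-wise product and addition:

```
out = relu( coarse(u) + mask(u) ⊙ refinement(u) )
```

with `mask` a sigmoid (bounded in [0, 1] by construction). Three
representation choices matter much more than network size at CPU scale:

* **Log-intensity domain.** The network sees `u = log1p(x / c)` (with `c`
  the median reference intensity). This compresses the dynamic range and
  turns the dominant multiplicative gain into an additive offset.
* **Background context channel.** Alongside `u`, the network receives the
  spectrum's lower-decile intensity as a constant channel. Peaks and
  chemical noise only ever add intensity, so a low quantile tracks the
  per-acquisition gain while staying blind to peak content; a running
  median, by contrast, is visibly contaminated by chemical-noise spillover.
* **Normalization prior in the coarse branch.** The coarse branch computes
  `u − γ·(bg(u) − m₀) + c(trunk(u))` with `γ` learnable (initialized at 1)
  and `m₀` the reference background level of the training set. At
  initialization the model already performs approximate gain correction;
  training refines `γ` and learns the residual structure (chemical-noise
  suppression, detector-noise smoothing) instead of spending its step
  budget rediscovering division.

The loss is mean absolute error in the log-intensity representation plus a
non-saturating adversarial term (weight 0.01; weight 0 reduces training to
pure paired regression and skips the discriminator entirely). The
discriminator is unconditional — it scores spectra, not (input, output)
pairs — and the attention mask is learned end-to-end without peak
supervision; both points were genuinely open and the simpler variant was
chosen. Inference is fully deterministic; seeds control initialization and
batch order only.

All sizes (2 dense blocks of 2 layers, growth 8, kernel 9, 512 bins) are
desk-scale defaults: one epoch on 160 pairs takes a few seconds on one CPU,
and the directional results below are insensitive to moderate changes.
Training diverging to non-finite loss raises an error naming the epoch.

# Diagnosis

`fit_elastic_net()` wraps a logistic elastic net (glmnet) with the mixing
parameter selected over {0.1, …, 1.0} and the penalty over the automatic
path by inner cross-validation (AUC where fold sizes allow, deviance
otherwise). Supplying both `alpha` and `lambda` skips selection — the fast
path used for the 100-model replicate ensembles, so that ensemble spread
reflects acquisition variation rather than tuning noise.
`fit_oplsda()` is the conventional baseline: NIPALS orthogonal signal
correction (orthogonal scores have exactly zero training correlation with
the class) followed by a single predictive PLS component mapped to a
probability by univariate logistic regression.

`compute_metrics()` reports the trapezoidal ROC AUC (equal to the
Mann-Whitney statistic with half-credit for ties), step-integrated AUPRC,
and the operating point nearest the upper-left ROC corner — the phrase is
geometric, so minimal Euclidean distance to (0, 1) is the default and
Youden's J is a flag. AUC confidence intervals are stratified-bootstrap
percentiles (2000 resamples by default; method unstated in the source
convention, percentile bootstrap chosen as the assumption-light default).

`permutation_test()` re-runs the *entire* cross-validated pipeline per
label permutation and uses the add-one estimator
`p = (1 + #{null ≥ observed}) / (n_perm + 1)`, which is exact under
exchangeability and never returns 0.

`screen_biomarkers()` applies the three-way restriction with strict
inequalities: Welch t-test p < 0.001 (unadjusted; multiplicity adjustment
was left as a flagged option rather than guessed), enriched-class mean raw
intensity > 25 (intensities are deliberately un-normalized throughout), and
hit frequency > 60 out of the 100 replicate fits (the only natural
denominator in the replication design; configurable).

# The MK surface

For each percentile n = 1…100, every replicate model thresholds at its own
nth control percentile (linear-interpolation convention; an exclusive-rank
variant sits behind a flag), patients strictly above threshold are positive,
and the surface records threshold, specificity, mean sensitivity and a
diagnostic CV. Two CV semantics exist in the source material; both are
implemented:

* `cv_mode = "sensitivity"` (**default**): CV of the 100 per-model
  sensitivities — the clinical-assay convention (a CV < 10% at the chosen
  threshold), bounded for any data.
* `cv_mode = "labels"`: mean over patients of the CV of each patient's 100
  binary labels. This statistic equals √((1−p)/p) for a patient called
  positive with rate p, so it diverges for rarely-positive patients;
  empirically a *noisier* classifier can then show a *smaller* VUS because
  noise pushes hard patients to all-negative (CV 0 by the all-zero
  convention). That pathology is why it is not the default.

`vus()` integrates cv(n)·sensitivity(n) against specificity by the
trapezoidal rule, closing the segment below the smallest observed
specificity at the first row's integrand, so a constant-CV,
full-sensitivity surface over specificity [0, 1] integrates to exactly that
constant and cv ≡ 0 gives exactly 0. The raw (specificity, sensitivity, cv)
rows are kept in the object so any other integration convention can be
applied. `select_threshold()` returns the largest percentile with CV
strictly below `cv_max` (default 10%); when nothing qualifies it says so
rather than inventing a row. No VUS value here is comparable in absolute
terms to values computed on other cohorts with an unknown integration
convention — only orderings (stabilized vs native) carry meaning.

All-zero vectors have CV 0 by convention; a zero mean with nonzero spread
is an error, not a number.

# The end-to-end comparison

`run_pipeline()` simulates discovery and validation cohorts with technical
replicates, optionally trains and applies the stabilizer (training pairs:
one replicate in, the sample's replicate mean out, from the discovery
cohort only), re-extracts SMPs from the same binned representation in both
modes, cross-validates both classifiers, fits the 100-model replicate
ensemble (each model trained on one random replicate-to-individual
assignment at frozen hyperparameters), screens biomarkers, and builds the
MK surface on the validation cohort with per-model thresholds. The report
prints a native (N) vs deep-stabilized (D) table of CV/metric pairs, VUS,
and the CV < 10% threshold percentile.

## Problem sizes

Defaults are a deliberate desk-scale study: 35 features (6 biomarkers, 5 up
/ 1 down, log2 fold change 0.6, between-subject CV 0.4 — a realistic serum
metabolomics effect size), 30/30 discovery and 15/15 validation subjects,
10 technical replicates at 1000 shots, 1024-point spectra binned to 512,
100 ensemble models. A full two-mode run takes about three minutes on one
CPU. The test suite uses further-scaled variants of the same configuration
(down to 15/15 + 12/12 subjects, 256 bins, 200-shot natives — the noisy
end of the regime the stabilizer is meant for) so that twenty-seed
direction checks stay fast; these sizes are choices of the package, stated
here so results can be reproduced exactly.

# Known limitations

* The simulator's noise budget is a surrogate calibrated to documented CV
  behaviour; real instruments add drift and structure it does not contain.
* The stabilizer is trained per study; no pretrained weights are shipped
  and no transfer across acquisition settings is claimed.
* VUS magnitudes are convention-dependent (see above).
* OPLS-DA is implemented with one predictive component only, as used for
  binary discrimination; multi-class subtyping is out of scope (run
  separate binary tasks).
* The backprop engine is plain R + BLAS and single-threaded; it is sized
  for hundreds of epochs on 512-bin spectra, not for instrument-resolution
  (80,000-point) inputs.
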