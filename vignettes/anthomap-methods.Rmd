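---
title: "Hyperspectral estimation and mapping of mulberry anthocyanin: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyperspectral estimation and mapping of mulberry anthocyanin: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`anthomap` implements a complete visible/near-infrared hyperspectral
chemometrics pipeline for estimating total anthocyanin content (mg/g
fresh weight, cyanidin-3-glucoside equivalents) in mulberry fruit, and
for rendering per-pixel anthocyanin distribution maps. Because no public
mulberry hyperspectral dataset with wet-chemistry labels exists, the
package ships a synthetic scene generator that emulates the statistical
structure of such a study — two varieties, three maturity stages, 180
samples — so every stage of the pipeline can be validated end to end
against a known ground truth. This vignette explains the models, the
defaults, and what the synthetic validation does and does not show.

## The measurement chain

**Reflectance calibration.** Raw sensor counts are converted to relative
reflectance band by band as

$$R_\lambda = \frac{I_\lambda - D_\lambda}{W_\lambda - D_\lambda},$$

where $I$ is the raw image, $W$ a white-reference scan and $D$ a
dark-current scan. This cancels the illumination gradient and the dark
offset. Cells where $W - D \le 10^{-6}$ carry no signal and are zeroed
with a warning; output is clipped to $[0, 1.5]$ so that mild
super-unity noise excursions survive but gross ones do not.

**ROI segmentation.** Fruit tissue is NIR-bright against the black
cardboard background, so a pixel is fruit iff $R(800\,\mathrm{nm}) \ge
0.2$ — the threshold is read as the *minimum fruit reflectance*, with
the comparison direction configurable. Chlorophyll-rich stalk tissue is
then removed by the signed green/red contrast rule: a pixel is retained
iff $R(550) - R(670) \le 0.04$. Stalks reflect more at 550 nm than at
the chlorophyll absorption around 670 nm, while anthocyanin-rich flesh
absorbs strongly at 550 nm, making the signed difference discriminative.
An absolute-difference variant is available (`absolute = TRUE`); the
signed rule is the default because anthocyanin-rich flesh can legally
have a *large negative* difference. Wavelength lookups use the nearest
band center, ties resolving toward the lower wavelength. No
morphological cleanup is applied — the segmentation is pure
thresholding.

**Spectral extraction.** The modeling path uses the arithmetic mean ROI
spectrum of each sample; the deep-feature path uses 400 ROI pixels per
sample drawn uniformly without replacement (seed-controlled). With the
default 180-sample study this stacks a 72,000-row pixel matrix. Sampling
uniformly over the mask (rather than a contiguous 20 × 20 window) treats
the per-sample pixel budget as a random sample of the ROI; a contiguous
window would correlate the draws with position on the fruit.

**Wet-chemistry reference.** The pH-differential assay gives

$$A = (A_{520} - A_{700})_{\mathrm{pH}\,1.0} -
      (A_{520} - A_{700})_{\mathrm{pH}\,4.5}, \qquad
\mathrm{content} = \frac{A \cdot MW \cdot DF \cdot V}
                        {\varepsilon \cdot \ell \cdot M},$$

with the cyanidin-3-glucoside constants $MW = 449.2$ g/mol, $DF = 25$,
$V = 10$ ml, $\varepsilon = 26900$, path length $\ell = 1$ cm and sample
mass $M = 0.5$ g by default. All constants are arguments because other
anthocyanin references use different $MW/\varepsilon$ conventions. A
negative $A$ (possible under measurement noise near zero pigment) is
propagated with a warning, not clamped, so the noise statistics of
synthetic references stay honest.

## Preprocessing

Spectra are cropped to the 450–1050 nm analysis window (closed interval;
379 bands on the default grid) and transformed by the standard normal
variate (SNV): each spectrum is centered by its own mean and divided by
its own standard deviation. The sample (n−1) denominator is the default
(the population variant is a flag); the choice only rescales every row
by the same constant and is immaterial downstream. SNV is applied
identically to mean ROI spectra (modeling) and to single-pixel spectra
(mapping), so the mapping path replays the training transform exactly.

## Variable reduction

**SPA.** The successive projections algorithm grows, from every
candidate start band, a chain of minimally collinear bands: at each step
all remaining bands are projected onto the orthogonal complement of the
chosen set and the band with the largest projection norm is appended.
Each (start, k) prefix is scored by the validation RMSE of an ordinary
least-squares fit on a held-out third of the samples — the spec of the
algorithm leaves the evaluator open; OLS on a holdout is the standard
choice — and the minimum-RMSE subset wins. The RMSE-versus-k path of the
winning start typically falls in a ladder shape and levels off.

**CARS.** Competitive adaptive reweighted sampling couples Monte-Carlo
resampling with PLS regression coefficients. Each of 50 runs draws an
80% calibration subset, fits PLS1 (SIMPLS; components ≤ 10 chosen by
5-fold CV within the run), keeps the top fraction of bands by
\|coefficient\| following the exponentially decreasing schedule
$r_i = e^{-k(i-1)}$ calibrated so $r_1 = 1$ and $r_{50} = 2/p$, then
competitively resamples among the survivors with weights proportional
to \|coefficient\|. Each run's surviving set is scored by 10-fold
RMSECV on the full data, and the minimum-RMSECV run is returned. The
retained-count path is non-increasing from $p$; the returned band count
is a data-dependent output, not a constant.

**SAE.** The stacked auto-encoder compresses each SNV spectrum to 13
deep features through the mirror-symmetric stack
379–300–150–13–150–300–379, all units sigmoid. Training is greedy
layer-wise pretraining of the three constituent auto-encoders followed
by end-to-end fine-tuning under mean-squared reconstruction loss, 40
epochs each, batch 200, constant learning rate 0.001. The optimizer is
minibatch SGD with classical momentum 0.9: with a constant 0.001 rate
and no momentum the stack converges far too slowly to reach the
near-perfect reconstructions the architecture is capable of, and
momentum is the minimal, standard addition that fixes this without
introducing a schedule. Because sigmoid outputs live in (0, 1) while
SNV spectra are unbounded, inputs are affinely squashed per band to
[0.05, 0.95] using training-set ranges; the squash is stored in the
model and replayed at encoding time. Training is deterministic given
the seed: all shuffles are drawn from R's RNG and the C++ inner loop is
single-threaded. Whether the reference procedure fine-tuned end to end
is not documented; fine-tuning is enabled here because purely
layer-wise training cannot reach reconstruction correlations ≥ 0.99,
which the architecture plainly attains. "40 iterations" is read as 40
epochs. Features for the regression models are the encodings of each
sample's mean SNV spectrum; per-pixel encodings are used only in the
mapping path. The SAE itself is trained on pixel spectra, which carry
sensor noise — this doubles as denoising and is why SAE features
transfer well from clean mean spectra to noisy pixels.

## Regression models and optimization

**ELM.** The extreme learning machine is a single-hidden-layer network
(90 sigmoid neurons by default) whose input weights and offsets are
*fixed* and whose output weights are solved in closed form as the
minimum-norm least-squares solution $\beta = H^{+}(y - \bar y)$ with
$H = \sigma(XW + b)$; predictions add $\bar y$ back. The response
centering is equivalent to an output bias frozen at $\bar y$: without
it the hidden layer must spend capacity representing the constant
offset of the content scale, and small ELMs can fit worse than the mean
predictor. Inputs are min-max scaled per column to $[-1, 1]$ so the
sigmoid operates in its active region; the scaling is stored in the
model.

A 90-neuron $H$ built from 126 training samples on a low-dimensional
feature manifold is severely ill-conditioned: the exact pseudoinverse
then carries output weights with norms up to $10^6$, and while
sample-level fit and cross-validation look superb, applying such a
model to *individual pixels* — slightly off the training manifold, with
sensor noise — makes predictions explode. Sample-level CV cannot see
this failure mode. `fit_elm` therefore accepts a ridge penalty on the
output weights (default 0, the exact pseudoinverse), and the pipeline
selects the penalty by a *pixel-consistency criterion*: per-pixel
predictions on training scenes are scored against those scenes'
wet-chemistry references, and the penalty minimizing that RMSE wins.
Only training scenes participate; no ground-truth concentration maps
are used.

**LS-SVM.** Least-squares SVM regression with the RBF kernel
$k(u, v) = e^{-\gamma\|u-v\|^2}$ solves the saddle system
$\bigl[\begin{smallmatrix}0 & 1^{\top}\\ 1 & K + I/C\end{smallmatrix}\bigr]
\bigl[\begin{smallmatrix}b\\ \alpha\end{smallmatrix}\bigr] =
\bigl[\begin{smallmatrix}0\\ y\end{smallmatrix}\bigr]$ directly —
no quadratic program. $\gamma$ is interpreted as the RBF width
parameter (conventions differ; some toolboxes use $\sigma^2$ with
$k = e^{-\|u-v\|^2/\sigma^2}$). A singular system receives one 1e-10
diagonal jitter before erroring.

**GA.** Both models are tuned by a real-coded genetic algorithm:
population 20, tournament selection of size 2, arithmetic crossover
(rate 0.9), per-gene Gaussian mutation (rate 0.05, sd = 10% of the gene
range) clipped to bounds, elitism of one. For LS-SVM the genome is
$(C, \gamma) \in [0.01, 100]^2$ over 200 generations; for the ELM it is
the full weight/offset vector in $[-1, 1]^{d \cdot 90 + 90}$ over 300
generations. The GA *fitness is the 5-fold cross-validated RMSE on the
training set*, not the training RMSE: an interpolating ELM has zero
training error by construction, so training-RMSE fitness would reward
exactly the overfitting the random-weight ELM is prone to. The operator
rates are standard values, fixed here and configurable.

**Evaluation.** $R^2 = 1 - SS_{res}/SS_{tot}$ about the evaluated set's
own mean (squared Pearson correlation is exported alongside, since some
reports use it); RMSE in mg/g. The split is 7:3, stratified by variety
× stage so each of the six cells splits 21/9.

## The synthetic study generator

The generator stands in for an unreleased laboratory dataset; its
defaults *are* the study conditions and are not tuned against test
outcomes.

* **Design.** 2 varieties × 3 stages × 30 samples = 180 scenes. Stage
  mean contents (mg/g): variety A 1.0 / 2.5 / 4.5, variety B 0.7 / 1.9
  / 3.6 — ripe mulberry measures a few mg/g fresh weight, contents rise
  steeply with maturity, and the darker variety is offset upward at
  every stage. Individual samples scatter around their stage mean with
  a lognormal CV of 0.15, the order of between-fruit biological
  variation in pigment assays.
* **Spectra.** Per-pixel reflectance is a smooth sigmoidal baseline
  minus Gaussian absorbers: a broad anthocyanin band at 535 nm (sd
  70 nm, spanning roughly 500–700 nm) whose depth saturates with
  concentration as $0.55\,c/(c + 1.5)$; a chlorophyll band at 680 nm
  (sd 12 nm) scaled by a stage-dependent level (0.8 / 0.4 / 0.15 for
  S1/S2/S3 — the chlorophyll trough is visible at red maturity and
  fades); water/sugar bands at 840 and 970 nm. Reflectance is clipped
  to [0.01, 0.99] and decreases strictly with anthocyanin at 600 nm.
* **Geometry.** Six elliptical fruits on a jittered grid, each with a
  short green stalk patch whose spectrum (chlorophyll-rich plus a green
  reflectance bump at 550 nm) yields $R(550)-R(670) \approx +0.08$,
  against flesh values ≤ 0.02 — the 0.04 stalk threshold separates the
  two cleanly. The background is dark cardboard with $R(800) < 0.1$.
* **Within-fruit heterogeneity.** The concentration field is smooth
  lognormal (Gaussian-filtered white noise, sd 3 px, exponentiated)
  with a stage-dependent within-fruit CV — 0.20 at red maturity, 0.15
  at red-to-purple, 0.10 at full maturity, reflecting that pigment
  distribution is most uneven early in ripening — rescaled so the
  fruit-mask mean equals the sample's design content exactly; the wet-chemistry reference can then
  be emitted without materializing the cube, and the reference noise
  budget is purely the configured absorbance noise (sd 0.005 absorbance
  units ≈ 0.04 mg/g). Real within-fruit pigment statistics are unknown;
  the random field is a stand-in, not a validated model.
* **Acquisition.** White scan = dark level + per-band gain × a
  separable quadratic illumination gradient (±10%) + noise; raw scan =
  the same with the true reflectance multiplied in. Sensor noise sd is
  0.005 reflectance units on the raw scan, 0.002 on the white (panels
  are brighter and usually averaged) and 0.001 on the dark. Scenes are
  120 × 120 px over 379 evenly spaced bands (450–1050 nm) by default;
  the full 305–1090 nm grid is available for exercising the crop. Each
  scene regenerates bit-identically from its stored seed, so the
  180-cube study (≈ 23 GB if held at once) is materialized lazily, one
  scene at a time.

**What passing the synthetic study shows — and what it does not.** The
generator's spectra are low-dimensional and its noise is white and
Gaussian; a real spectrograph adds wavelength-correlated noise,
specular highlights, fruit-surface curvature and touching fruit, none
of which are modeled. End-to-end recovery on this study therefore
demonstrates that the pipeline's *mechanics* are correct (calibration,
masking, transform replay, selector behavior, optimizer convergence,
map assembly) and that the model class can recover a known
concentration–spectrum relationship through realistic amounts of shot
noise — it does not certify accuracy on real fruit.

## Mapping choices

The mapping stage uses the SAE + GA-ELM bundle rather than whichever
grid cell happened to minimize test RMSE. The reason is robustness at
pixel granularity: the SAE is trained on the noisy pixel spectra
themselves, so its 13 features transfer cleanly from mean spectra to
pixels (empirically, the encoding of a scene's mean spectrum coincides
with the mean of its pixel encodings to three decimals), and the ELM's
ridge is calibrated on pixel data. RBF-kernel models fed raw bands
degrade badly per pixel: independent noise across 379 bands moves every
pixel far from every training point in kernel distance, collapsing
predictions toward the bias term.

Rendered maps (and their reported statistics) are smoothed within the
mask by a 1-pixel Gaussian. Per-pixel predictions carry independent
sensor noise, while real pigment fields — and the generator's — vary
smoothly on a scale of several pixels; a narrow mask-aware smoother
therefore removes mostly noise. The bare per-pixel chain
(`smooth_sigma = 0`) remains the `predict_map` default.

## Numerical choices and degenerate inputs

* Nearest-band ties resolve toward the lower wavelength; bundle/cube
  alignment tolerates ±2 nm.
* SNV flags rows with sd < 1e-12 and returns them as zeros.
* The ELM pseudoinverse truncates singular values below
  1e-10 × max(d); LS-SVM adds a single 1e-10 jitter on singularity.
* SPA chains truncate with a warning when the residual norms collapse
  (collinear sets); CARS caps the retained count at the current
  surviving set and reduces PLS components when the set is smaller.
* Empty segmentation masks return as-is with a warning; sampling more
  pixels than the mask holds returns the whole mask with a warning.
* The prediction-map color scale defaults to the map's own range; a
  shared scale across scenes is used for cross-stage comparisons.

## Problem sizes used in the shipped runs

The package defaults follow the study design (180 samples, 400
pixels/sample, SAE 40 epochs, GA 300/200 generations). The shipped
analysis scripts, the test suite and `scripts/acceptance.R` run the
same design with two reductions chosen once as desk-scale working
sizes: the SAE trains on a 16,000-row subsample of the 72,000 pixel
rows (reconstruction correlation is ≥ 0.99 there, and the downstream
usefulness of the 13 features — the regression error they support —
stabilizes at that size), and the GA runs 150 generations for the ELM
weight search and 50 for the LS-SVM hyperparameters (the CV-RMSE
fitness plateaus within a few tens of generations at these problem
sizes). All other parameters are the defaults.

## Known limitations

* ENVI (BIL) is the only cube file format; the in-memory axis order is
  fixed at (row, col, band).
* The LS-SVM stores its full training set; it is O(n³) in training and
  O(n) per prediction — fine at n = 126, not for thousands of samples.
* The GA-ELM genome grows with the feature count (d × 90 + 90); for
  all-band inputs the search space is far larger than 20 × 300
  evaluations can cover, and the GA there acts closer to a seeded
  random restart with elitism. Selected-variable inputs are where the
  optimization is meaningful.
* `reflectance_model` is phenomenological: plausible shapes and
  contrasts, not radiative transfer.
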