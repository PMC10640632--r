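---
title: "Multivariate spectral calibration with specal: models, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate spectral calibration with specal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specal)
```

## The problem

Naphazoline HCl (NZ) and pheniramine maleate (PN) are co-formulated in eye
drops; pharmacopoeial monographs additionally name three related impurities
(NZ impurity B, PN impurities A and B) that a purity assay must quantify.
All five compounds absorb in the same UV region and their spectra overlap
severely, so no single wavelength is selective for any of them.
Multivariate calibration resolves the overlap by regressing whole spectra
on known concentrations: `specal` implements the two calibrators used in
this assay family — PLS2 regression fitted by NIPALS, and a linear
("purelin") feed-forward network — plus the experimental design that
generates the calibration mixtures and the figures of merit that validate
the result.

Because no spectral data are deposited for this assay, the package includes
a synthetic-spectrum module that emulates the statistical structure the
analysis assumes. Everything downstream of spectrum acquisition is the real
method, exercised end to end on simulated measurements.

## The calibration design

Twenty-five mixtures follow a five-level, five-factor multilevel design:
each analyte takes the coded levels $-2,\dots,+2$, each exactly five times,
and every ordered pair of factors runs through all $5\times 5 = 25$ level
combinations exactly once. Pairwise, the concentration profiles form a
complete factorial, so no analyte's concentration is confounded with any
other's — the property that makes 25 runs sufficient for five components.

`generate_design()` constructs the table by indexing runs over a
$5\times5$ grid $(a,b)$ and assigning factor $k$ the level
$(a + c_k b) \bmod 5$ with distinct multipliers $c_k$. For any two factors
the map $(a,b)\mapsto(\mathrm{lev}_i,\mathrm{lev}_j)$ is a bijection of the
25 cells, which yields the pair-orthogonality property by construction and
supports up to six factors. Published listings of such designs differ by
row/level permutations; the package treats the combinatorial invariants —
not any particular listing — as the contract, and the tests verify them
exhaustively.

Coded levels map affinely onto working ranges
(`realize_concentrations()`): 5.0–13.0 µg/mL for NZ, 10.0–60.0 for PN,
1.0–5.0 for NZ impurity B, 2.0–14.0 for both PN impurities, giving level
sets such as $\{5,7,9,11,13\}$ and $\{10,22.5,35,47.5,60\}$.

Fifteen runs calibrate and ten validate. Which runs form the calibration
set is not part of the published design, so `split_runs()` draws the split
from a seeded RNG under one constraint: every level of every factor must
appear in the calibration subset, so the models never extrapolate in coded
space. Infeasible constraints error out after a bounded number of redraws.

## The synthetic spectra

Pure-component spectra are sums of Gaussian bands,
$s_j(\lambda) = \sum_k p_k \exp\{-(\lambda-\mu_k)^2/2\sigma_k^2\}$,
a standard smooth surrogate for UV absorption envelopes. Mixtures obey
Beer–Lambert superposition with a 1 cm path folded into the absorptivities
$p_k$ (AU·mL·µg⁻¹), plus Gaussian photometric noise.

The default library (`default_library()`) encodes the features the
analysis depends on:

* every component has at least one band inside the 250–300 nm working
  window, and neighbouring components overlap severely there (several
  pairwise cosine similarities above 0.9);
* strong secondary bands sit below 250 nm, where the noise model's SD rises
  from 0.001 AU (`sigma_base`) to 0.008 AU (`sigma_below_250`) — the noisy
  region the window selection discards;
* all envelopes decay to under 5 % of their maximum above 300 nm, the
  near-zero region the window also discards;
* peak absorptivities put design-level mixtures at roughly 0.1–1.5 AU, the
  photometric range where absorbance measurement is reliable.

Within those constraints the band positions and widths were chosen so that
the simulated study reproduces the error structure reported for the real
assay: pooled validation RMSEP of a few hundredths of a µg/mL at the
default noise, per-component recovery SDs of roughly 0.1–2 %, and a
leave-one-out latent-variable choice of 5–6. An early draft library with
nearly proportional envelopes was close to rank-deficient in the window
(noise amplification of ~900 µg/mL per AU of noise for some components);
no five-analyte assay achieving ~100 ± 2 % recoveries could look like
that, so the library was given modest vibronic structure (doublets,
shoulders, a red satellite) that brings the amplification of the
pseudoinverse rows to 7–29 µg/mL per AU. The generator seed jitters band
centres by ±1 nm and intensities by a few percent, mimicking day-to-day
standard preparation; all stochastic steps are reproducible under their
seeds.

What the generator does **not** emulate: stray light, scatter, baseline
artefacts beyond an optional smooth sinusoidal drift, pH/solvent shifts,
wavelength miscalibration, and any quantitative resemblance to the real
compounds' band shapes (only a printed figure of those exists). Passing
tests therefore demonstrate the correctness and statistical behaviour of
the calibration machinery under the stated noise model — not performance
on real instrument data.

## Preprocessing

The working window is 250.0–300.0 nm: on the instrument's 0.2 nm grid that
is exactly 251 points, which is also the network's input width.
`select_window()` only slices existing grid points (matched with a 1e-9 nm
tolerance, endpoints inclusive); it never interpolates.

Both spectra and concentrations are mean-centered with calibration-set
means (`fit_centering()`); validation data reuse those means, and
concentration means are added back after prediction. Centering the
response as well as the spectra is the convention of the classical PLS
toolboxes this workflow descends from; it is harmless (the two models are
affine either way) and makes the centering transform a self-contained,
invertible object stored inside every fitted model.

## PLS by NIPALS

`fit_pls()` implements PLS2 NIPALS from scratch: latent variables are
extracted one at a time by the alternating iteration
$w \propto X^\top u$, $t = Xw$, $q \propto Y^\top t$, $u \propto Yq$,
followed by deflation of both blocks with the X-loading
$p = X^\top t/t^\top t$. Regression coefficients for centered data are
$B = W(P^\top W)^{-1}Q^\top$.

Numerical choices, all fixed for determinism:

* the Y-score starts from the Y column of maximal variance;
* the inner loop stops at a relative weight change of 1e-12 (max 500
  iterations);
* each weight vector's largest-magnitude element is forced positive,
  removing NIPALS' sign indeterminacy so serialized models are
  reproducible;
* extraction stops with an informative error if the residual X block falls
  below 1e-12 of its initial energy (rank deficiency), naming the
  achievable number of components.

At full rank the fit coincides with minimum-norm least squares, and on
random fixtures predictions agree with an independent PLS implementation
(mixOmics) to ~1e-13; both checks are in the test suite.

Model complexity is chosen by leave-one-out cross-validation
(`loo_curve()`): each calibration sample is predicted from a model fitted
on the other fourteen. One NIPALS fit at the largest candidate count per
fold provides the whole nested model sequence via truncation of the
score/loading expansion; the tests verify this equals a naive
refit-per-component loop exactly. RMSECV is reported on the original
concentration scale, pooled across the five components (one curve, as the
assay's practice) and per component. `select_n_lv()` then applies a
parsimony rule: the smallest count whose pooled RMSECV is within 2 %
(`threshold_ratio = 0.02`) of the curve minimum. The published account of
this assay selected six latent variables by inspecting the error curve;
the fixed rule makes that qualitative judgement reproducible and testable,
and lands on 5–6 for the synthetic study depending on the noise
realization.

## The linear network

The second calibrator is a three-layer feed-forward network with linear
transfer functions throughout: 251 inputs (the window), a small hidden
layer, 5 outputs. Historically it was trained with 4 hidden neurons,
learning rate 0.1 and 50 epochs of gradient descent; `specal` keeps that
configuration as `preset = "reference"`.

Because every layer is linear, the network is exactly an affine map
$y = W_2(W_1x + b_1) + b_2$ of rank at most the hidden width
(`ann_as_affine()` collapses it; the tests confirm equality to machine
precision). That has a hard consequence: the design's five concentration
columns are mutually orthogonal, so the exact inverse map has rank five,
and **no** 4-hidden-neuron purelin network can recover all five analytes
accurately — the best rank-4 approximation must sacrifice one direction
entirely. The package therefore also ships `preset = "accurate"`
(`n_hidden = 5`, `lr = 0.05`, 20000 epochs), which converges to the exact
solution on noiseless design data (mean validation recoveries within
0.01 % of 100 %). The reference preset remains available for fidelity, and
on this generator it typically underfits at 50 epochs exactly as the rank
argument predicts for its dropped direction.

Training is full-batch gradient descent on the mean squared error of
scaled variables — inputs mean-centered and divided by one global SD of
the calibration absorbances, targets scaled per component to $[-1,1]$ —
because raw AU × µg/mL scales make a 0.1 learning rate diverge
immediately. Divergence (non-finite loss) raises an error that points at
the scaling. The analytic gradient is verified against central finite
differences to 1e-5, and a step-for-step comparison against a hand-rolled
descent loop is in the tests. Initialization is uniform in a fan-in-scaled
symmetric interval with zero biases, reproducible under a seed.

## Figures of merit

For each component of the validation set, `merit_report()` assembles:

* per-sample recoveries $100\,\hat c/c$ with mean and SD ($n-1$);
* RMSEP $=\sqrt{\sum e^2/n}$ and SEP $=\sqrt{\sum e^2/(n-2)}$ on the same
  residuals, so SEP/RMSEP $=\sqrt{n/(n-2)}$ identically. The $n-2$
  denominator without bias subtraction is the convention uniquely
  consistent with all ten published (SEP, RMSEP) pairs this package checks
  against; the common bias-corrected $n-1$ form is not, and is therefore
  not offered as a default;
* ordinary least squares of predicted on actual (slope, intercept, Pearson
  r, residual SD with $n-2$ df);
* LOD $=3.3\,s/\mathrm{slope}$ and LOQ $=10\,s/\mathrm{slope}$ with $s$
  the regression residual SD — the ICH pattern forced by the universal
  LOQ/LOD ratio of 10/3.3 in the published table. The absolute published
  LOD values depend on the original residuals and cannot be recomputed
  from printed data; only the internal ratios are reproducible, and only
  those are asserted.

`standard_addition()` evaluates spike recoveries on the added amount only,
and `compare_methods()` performs the pooled-variance two-sided t test and
the variance-ratio F test (larger variance in the numerator, one-tailed
upper critical value) from summary statistics. One published critical
value — F at p = 0.05 for df (9,4), printed as 5.60 — does not correspond
to any standard convention (`qf(0.95, 9, 4)` = 6.00); the package computes
the principled value and the discrepancy is simply reported, not imitated.

## Problem sizes and reproducibility

The shipped study uses the design's own dimensions: 25 spectra of 1001
points, window of 251 points, 15/10 split, LOO over 15 samples, up to 10
latent variables, and 20 replicates per noise level in the noise-response
checks. `run_pipeline()` executes the whole sequence from one seeded
configuration and writes every artifact (design and spectra CSVs, model
JSONs with provenance, a JSON merit report); two runs from the same
configuration are identical.

## Known limitations

* Synthetic spectra only; see above for what the generator omits.
* The published per-mixture recoveries are reproduced arithmetically
  (summaries from printed values), but the original instrument data are
  unavailable, so absolute agreement of LODs or RMSEPs with the published
  table is out of reach by construction.
* PLS1-per-component, SIMPLS/kernel PLS, nonlinear transfer functions,
  momentum/adaptive optimizers and derivative/scatter preprocessing are
  out of scope.
* The t/F comparison assumes summary statistics of an external reference
  method; raw reference-method replicates are not modelled.
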