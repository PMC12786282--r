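---
title: "Nanoplasmonic biosensing simulation and KAN classification: models and methods"
author: "plasmoKAN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nanoplasmonic biosensing simulation and KAN classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmoKAN)
```

plasmoKAN models a serum liquid-biopsy assay built on a gold nanohole
metasurface: small extracellular vesicles (sEV) carrying the tumor markers
GPC1 or EphA2 bind antibodies on the chip, and the reflectance spectrum of
the chip changes. The package provides (i) a closed-form physical model of
the chip's optical modes and of the binding response, (ii) a synthetic
cohort generator that stands in for the clinical serum data, (iii) the three
conventional biosensing readouts, and (iv) a full-spectrum
Kolmogorov-Arnold network (KAN) classifier with attention-based
interpretability. This vignette documents the models, the tunable
parameters, the numerical choices, and what the synthetic data can and
cannot show.

## Resonance physics

The chip is a square lattice of nanoholes (period $P = 500$ nm, hole
diameter 200 nm, depth 200 nm) in a gold film. Two families of optical
modes appear in the 500-800 nm band:

* surface plasmon polaritons (SPP), at
  $\lambda_{\mathrm{SPP}} = \frac{P}{\sqrt{i^2+j^2}}
  \sqrt{\frac{\varepsilon_d\,\varepsilon_{\mathrm{Au}}}
  {\varepsilon_d+\varepsilon_{\mathrm{Au}}}}$,
* Wood-Rayleigh anomalies (WA), at
  $\lambda_{\mathrm{WA}} = \frac{P}{\sqrt{i^2+j^2}}\sqrt{\varepsilon_d}$,

with $(i,j)$ the diffraction order and $\varepsilon_d = n_{\mathrm{medium}}^2$.
In water the first-order anomaly sits at $500 \times 1.33 = 665$ nm:

```{r wa}
woodAnomalyWavelength(chipGeometry(period_nm = 500), c(1, 0),
                      materialModel(n_medium = 1.33))
```

`sppWavelength()` accepts either a constant gold permittivity (closed form,
exact) or a function of wavelength, in which case the implicit condition
$\lambda = f(\varepsilon_{\mathrm{Au}}(\lambda))$ is solved by damped
fixed-point iteration (damping 0.5, tolerance $10^{-6}$ nm, at most 100
iterations). The permittivity table behind the measured 580/728 nm mode
positions is not derivable from first principles here, so the four working
modes are *configured*, not derived: P1 (580 nm, SPP at the gold-water
interface), P2 (665 nm, WA), P3 (680 nm, attributed to the gold-silicon
substrate interface; the closed form with silicon permittivities does not
reproduce it, so it is treated as a configured mode), and P4 (728 nm, SPP,
the most surface-sensitive mode).

## Lineshape model

Measured reflectance spectra are replaced by a phenomenological lineshape: a
flat baseline (default 0.95) minus one inverted Lorentzian dip per mode,
clipped to $[0,1]$. Fano asymmetry is deliberately omitted: symmetric dips
make trough positions well-defined and the synthesis/detection round trip
exactly testable. Linewidths (FWHM 22/10/16/14 nm), dip depths
(0.30/0.22/0.28/0.45) and refractometric sensitivities (30/0/10/60 nm per
RIU) are model parameters chosen once so that (a) saturated binding shifts
stay inside the default mode windows, (b) the shift-vs-intensity crossover
described below occurs within the swept concentration range, and (c) the
downstream classifiers operate in the intended accuracy regime. The
sensitivities are *surface* response coefficients: they multiply the
effective-index change of the bound layer, which spans the full
$n_{\mathrm{water}}\!=\!1.33$ to $n_{\mathrm{sEV}}\!=\!1.60$ range at
monolayer saturation, so values far below bulk-RIU sensitivities keep shifts
on the nanometre scale that the band accommodates.

## Binding response

Binding follows a Langmuir isotherm, $\theta = Kx/(1+Kx)$, with $K$ the
equilibrium constant and $x$ the marker concentration (all concentrations in
the package are expressed in units of $1/K$). Three effects act on each SPP
mode (`applyBinding()`):

1. **Refractometric effect (RE).** The interfacial index becomes
   $n = \theta n_{\mathrm{sEV}} + (1-\theta) n_{\mathrm{water}}$ and the
   mode shifts by $\Delta\lambda = S \, \Delta n$.
2. **Spectroscopic effect (SE).** Bound particles absorb and scatter;
   following Beer-Lambert, $A = \varepsilon c l$ with fixed near-field path
   length $l$, and the dip contrast is multiplied by $10^{-A}$. The
   absorbing load $c = c_{\max}\,\theta_{\mathrm{abs}}$ uses its own
   Langmuir scale $\theta_{\mathrm{abs}} = (K/\gamma)x / (1 + (K/\gamma)x)$
   with $\gamma = 5$: absorbance reflects the *accumulated* particle load in
   the sensing volume (multilayer pile-up), which keeps growing after the
   first antibody monolayer saturates. With $c$ tied to the same $\theta$ as
   the wavelength channel, the two normalized response curves are ratios of
   identical Langmuir forms and can be shown never to cross in the interior
   of a sweep — contradicting the observed shift-first/intensity-later
   behavior — so the slower absorbance scale is a structural requirement of
   the model, not a tuning convenience.
3. **Loading (NLE).** The mode broadens as
   $\mathrm{FWHM}' = \mathrm{FWHM}\,(1 + \beta\theta)$, $\beta = 0.2$;
   loading is described only qualitatively in the literature, so a linear
   first-order broadening is used.

Wood-anomaly modes are left untouched by binding: their condition involves
only the period and the bulk index, which is what makes P2 a useful on-chip
reference.

`modeResponseSweep()` exposes the concentration response of one mode. The
crossover diagnostic interrogates reflectance at the *fixed* pre-binding
resonance wavelength: there the dip walking off-wavelength contributes
quadratically at small coverage while the shift itself is first-order, so
the normalized wavelength response leads at low concentration and the
normalized intensity response overtakes it exactly once along a logarithmic
sweep. The trough-minimum change (the SE *feature*) is kept separate from
this diagnostic; it is monotone and saturates on the $\gamma$-delayed scale.

## Synthetic cohort

No clinical data are available, so `cohortDesign()` encodes the study
structure: 600 PDAC subjects and 1200 controls (900 healthy, 100
pancreatitis, 100 cholangiocarcinoma, 100 hepatocellular carcinoma), two
markers per subject, five replicate spectrum pairs per marker (10 spectra
per subject, 18,000 in total), and a 0.6/0.2/0.2 subject-level
train/test/external split. Optional EphA2-positive breast and colorectal
classes are available for dual-marker specificity experiments.

Serum marker concentrations are log-normal per class and marker. The
defaults place the PDAC medians roughly an order of magnitude above control
medians for both markers (GPC1 near-exclusive to PDAC; EphA2 also mildly
elevated in the other cancer classes), with log-s.d. 0.8 (PDAC) and 0.7
(others). No distributions are reported for the real cohort; these values
are calibrated so that the full-spectrum classifier reaches the intended
high-AUC regime at default noise while the single-readout pathways remain
clearly below it.

Two per-subject *channel couplings* (log-normal, $\sigma_{\log} = 0.8$)
model biological heterogeneity of the vesicles themselves: one scales the
refractive-index contrast of the bound layer (the RE channel), the other the
vesicle absorptivity (the SE channel). They are drawn independently, so each
single-channel readout carries an irreducible subject-level nuisance that
the other channel does not share — the mechanism by which combining
channels (NLE, and a fortiori the full spectrum, which also sees the
coupling-free linewidth broadening) genuinely outperforms any single
readout, rather than doing so by training luck.

Measurement noise has six seeded components per acquisition: additive
Gaussian reflectance noise (s.d. 0.004), a linear baseline tilt (±0.002), a
rigid wavelength-calibration jitter (s.d. 0.15 nm), a multiplicative
intensity gain (s.d. 1%), and — on the post-detection spectrum only — a
residual bulk refractive-index change of the medium (s.d. 0.002 RIU, moving
every bulk-sensitive mode through its bulk-shift coefficient) and a
non-specific adsorption depth scaling (log-s.d. 0.06). The first four mimic
spectrometer behavior; the last two mimic serum-matrix effects. Replicates
additionally jitter the effective concentration (log-s.d. 0.05,
assay repeatability).

What the generator does *not* emulate: serum matrix interference and
free-protein competition chemistry, antibody affinity variation between chip
batches, Fano lineshapes, wavelength-dependent instrument response, and any
distributional detail of the real cohort. Passing tests on these data
demonstrate that the pipeline recovers structure *of the kind the model
encodes*; they are not evidence about clinical performance, and the
clinical AUC/accuracy values of the original study are deliberately not
reproduced.

## Conventional readouts

`detectModeTroughs()` splits a spectrum into four half-open windows
([560,610), [650,672), [672,700), [700,760) nm), takes the window minimum
and refines it by three-point parabolic interpolation (ties toward the lower
wavelength; windows whose minimum sits on an edge are flagged, not fatal).
For a symmetric dip the parabola through the three bracketing samples
recovers an off-grid center essentially exactly; sub-0.05 nm accuracy on a
0.5 nm grid is verified in the tests. RE features are per-mode wavelength
shifts (post − pre), SE features per-mode trough-reflectance changes, and
NLE their concatenation — no joint statistic is defined for the loading
effect in the source material, so the concatenation (which dominates both
margins) is used. Four-mode fusion concatenates the per-mode values.

## The KAN classifier

KAN layers place a learnable univariate function on every edge: a cubic
B-spline (order $k=3$) on a uniform grid of $G=5$ points spanning
$[-3, 3]$ ($G+k-1 = 7$ basis functions per edge, inputs clamped to the
range) plus a silu base activation with a learnable weight; node outputs are
sums over incoming edges. Spline coefficients initialize as
$\mathcal N(0, 0.1)$; base weights initialize at $1/p_{\mathrm{in}}$ so node
sums are $O(1)$ at any width — a unit base weight summed over 64 edges
saturates the downstream clamp and sigmoid and stalls training. The
vectorized forward pass is verified against a naive per-edge triple loop to
$10^{-10}$, and all gradients against finite differences.

The feature-table classifier stacks KAN layers (default widths
$[K, 16, 8, 1]$) with a terminal sigmoid. A plain ReLU multilayer
perceptron (`buildMLPModel()`, widths $[K, 64, 32, 1]$) serves as the
matched reference; the KAN needs fewer parameters at comparable capacity.

The full-spectrum model tiles the z-scored pre/post channel pair into
contiguous patches (per-wavelength normalization statistics computed on the
training partition only and frozen), embeds each patch linearly into
$d_{\mathrm{model}} = 64$, adds the standard sinusoidal positional encoding
(rate $pos / 10000^{2i/d_{\mathrm{model}}}$, sin in even and cos in odd
dimensions — the usual interleaving, adopted because only the rate is
specified in the source), and applies $L = 2$ pre-norm multi-head
self-attention layers with $H = 4$ heads and residual connections. Every
head's attention weight matrix is exportable (`attentionMaps()`,
`exportAttentionHeatmaps()`). Pooling over patches is *gated*: a learned
per-patch, per-dimension gain multiplies the residual stream before the
mean. Plain mean pooling ties readout weights across patch positions and
therefore cannot represent a general linear functional of the spectrum; the
gated form composed with the linear embedding spans all of them (a rank
argument: the $P \times c$ readout matrix factorizes over the $d$ embedding
dimensions). A layer norm and a KAN head ($[64, 16, 1]$) follow — KAN
layers sit only in the head, not inside the attention blocks — and a
zero-initialized global linear shortcut from the flattened normalized
spectra feeds the logit directly. The shortcut matters: a plain logistic
regression on the same inputs is a strong classifier on these data, and
without the shortcut the embed-attend-pool pipeline demonstrably fails to
recover that linear readout at desk-scale sample sizes; with it the model
is a strict superset of the linear classifier and the attention + KAN path
learns the nonlinear residual structure. The default patch length is 16
grid points (8 nm per patch).

Training minimizes the clipped binary cross-entropy
($\hat y$ clipped to $[10^{-7}, 1-10^{-7}]$) with Adam (learning rate
$10^{-3}$, batch 64), decoupled weight decay on weight and coefficient
arrays, optionally a half-cosine learning-rate schedule, a light Gaussian
input-noise augmentation and exponential moving-average (EMA) weight
averaging (the full-spectrum recipe uses $1.5\times10^{-3}$, decay
$3\times10^{-4}$, cosine, augmentation s.d. 0.15, EMA 0.995).
The best checkpoint is chosen by validation AUC (validation BCE as
tiebreak, plain BCE when only one class is present), with early stopping
after 10-15 stale epochs; all shuffling and augmentation derive from one
seed, so runs are bit-reproducible. Subject-level scores are the mean of
the subject's replicate record probabilities; the replicate-aggregation rule
is not specified in the source material.

## Evaluation

`rocAuc()` uses midranks (exactly the Mann-Whitney pairwise probability
with ties counted one half; verified against brute-force pair counting and
against pROC), `prAuc()` step-wise interpolation, and
`confusionAndRates()` either a fixed threshold or the Youden-optimal
threshold chosen on a designated validation set — the operating rule is not
stated in the source, and Youden's J is the conventional choice. Evaluation
is subject-level throughout. Dual-marker fusion trains a small KAN head
($[2, 4, 1]$) on paired per-marker subject scores (mean fusion as the
no-training fallback), and `relativeImportance()` reports seeded
permutation importances normalized to sum to one — "relative importance" has
no stated mechanism in the source, and permutation importance is the
standard model-agnostic reading.

## Problem sizes and determinism

The test suite runs the physics and oracle checks at full precision, the
counting checks on the complete 1800-subject design, and the
classifier-ordering benchmark on a 600-subject scaled design (one third of
the study, proportional class counts, one marker), with the null
calibration summarized as the median held-out AUC over three seed-derived
replicates — a single 240-subject null AUC draw has a standard deviation
near 0.04, so the median is what the ±0.05 calibration band meaningfully
constrains. Every stochastic stage draws its stream from
`deriveSeed(global_seed, stage_name)`; nothing uses the global RNG state.

## Known limitations

The lineshape is symmetric-Lorentzian on a flat baseline; real nanohole
spectra show Fano asymmetry and curved baselines. The substrate-interface
mode P3 is configured, not derived. Gold dispersion enters only through the
optional tabulated-permittivity solver; the default per-mode constant
permittivity cannot reproduce mode-position temperature drifts or
higher-order modes. The cohort generator's effect sizes are calibrated, not
estimated from data, so absolute AUC values on synthetic cohorts carry no
clinical meaning — only orderings and calibration properties are
interpreted. Training runs on a single CPU; the architectures are sized for
desk-scale experiments, not GPU-scale hyperparameter searches.
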