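---
title: "Methods: differential microwave imaging and CNN classification for hyperthermia monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential microwave imaging and CNN classification for hyperthermia monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`thermowave` simulates, images, and classifies the heating state of a neck
tumor and of the spinal cord during hyperthermia treatment, using microwave
scattering data. This vignette is the package's account of the underlying
model, of the choices that were genuinely open, and of what the synthetic
study does and does not show.

## 1. Dielectric model

Biological tissues are non-magnetic and dispersive. Each tissue is
described by a two-pole Cole–Cole model,

$$\varepsilon_r(\omega, T) = \varepsilon_\infty +
\frac{\Delta\varepsilon_1}{1 + (j\omega\tau_1)^{1-\alpha_1}} +
\frac{\Delta\varepsilon_2}{1 + (j\omega\tau_2)^{1-\alpha_2}} +
\frac{\sigma}{j\omega\varepsilon_0},$$

under the $e^{j\omega t}$ convention, so $\varepsilon_r = \varepsilon' -
j\varepsilon''$ with $\varepsilon'' \ge 0$. The $(1-\alpha)$ power of a
complex quantity uses the principal branch. $\varepsilon_0$ defaults to the
CODATA value $8.8541878128\times10^{-12}$ F/m and is exposed as an argument
because some printed tables round it differently.

Temperature enters through a linear relative-rate model about the 37 °C
reference: parameter $p$ becomes $p\,(1 + c_p\,(T-37))$. The bundled
defaults are $c_\sigma = +2\,\%/°C$ and $c_{\Delta\varepsilon_1} =
-0.5\,\%/°C$ with all other rates zero — the commonly reported dominant
sensitivities of tissue conductivity and permittivity in the low-GHz band.
The exact per-tissue rates in this temperature range are not settled in the
literature; they are configuration (columns of the tissue table), not
physics baked into the code, and only the two heated tissues (tumor, spinal
cord) are evaluated away from 37 °C. The validity window is [37, 46] °C for
the tumor and [37, 40] °C for the cord.

The bundled tissue table
(`inst/extdata/tissue_params_synthetic.csv`) carries *synthetic* stand-in
Cole–Cole parameters for skin, fat, muscle, cortical bone, spinal cord,
thyroid, and a nodular tumor (modelled as elevated-permittivity thyroid).
The values are authored in the style of the published tissue-dielectric
compilations and give realistic permittivities (e.g. muscle
$\approx 54 - 12j$ at 1.35 GHz), but they are fixture data: no claim is
made that they reproduce any database row.

## 2. Phantom and study conditions

The imaging domain is a square of side 24 cm discretized into $128\times128$
cells (1.875 mm). The stylized neck cross-section is an ellipse with
semi-axes 5.5 cm × 5.0 cm: a 4 mm skin shell, a 4 mm fat shell, a muscle
bulk, an 18 mm-radius vertebral disc enclosing a 4.5 mm-radius spinal cord
posteriorly, two 10 mm thyroid lobes anteriorly, and a 4.5 mm-radius
circular tumor concentric with one lobe. The domain side was chosen so that
the 5×5-pixel tumor ROI window (9.375 mm at full resolution) just encloses
the 9 mm tumor disc; an 18 cm domain (1.4 mm cells) would leave the tumor
larger than its prescribed window. Pixel (i, j) has its center at
$((i-0.5)h - L/2, (j-0.5)h - L/2)$; this convention is defined once in
`phantom_config()` and used everywhere.

Per-sample variability follows the study conditions: every tissue's
frequency-evaluated complex permittivity receives an additive complex
offset with $N(0, 0.1^2)$ real and imaginary parts, drawn once per sample
and held constant across the band and across the baseline/heated
measurement pair (the same patient measured twice). The offsets are
untruncated by default; a ±0.2 truncation is available because the
"±0.2-wide interval" phrasing of such protocols can also be read as a
bound. ROI temperatures are drawn uniformly from the discrete 1 °C grids
[37..46] °C (tumor) and [37..40] °C (cord), independently, so one
simulation feeds both datasets.

Structures smaller than a cell never vanish from the raster: a disc that
captures no pixel center labels the pixel containing its center.

## 3. Forward solver

The 2D TM scattering problem is the pair of state and data equations with
the scalar Green's function $g(r,r') = -\tfrac{j}{4}H_0^{(2)}(k_b|r-r'|)$,
outgoing and decaying for the lossy background ($\mathrm{Im}\,k_b < 0$).
The background is a non-dispersive water-mixture matching medium,
$\varepsilon_{rb}' = 23$, $\sigma_b = 1.0$ S/m by default. Among matching
media from $\varepsilon_{rb}' = 23$ to 78 this choice also maximizes the
differential signal-to-noise ratio of the heated-tissue signature, so the
default was kept.

Discretization is pulse-basis, point-matching method of moments on the
raster: the self cell is integrated analytically over the equal-area circle
($a = h/\sqrt{\pi}$, giving the diagonal term
$-\tfrac{j\pi k_b a}{2}H_1^{(2)}(k_b a) - 1$), off-diagonal interactions
use the midpoint rule. Systems up to 4096 unknowns are solved by dense LU;
larger ones by conjugate gradients on the normal equations with
FFT-accelerated operator application (relative-residual tolerance
$10^{-6}$). The two paths agree to $10^{-6}$ on shared cases, and the dense
path reproduces the analytic Bessel/Hankel series for a homogeneous
dielectric cylinder to below 2 % relative RMS at the default
discretization. The discrete co-located multistatic matrix is reciprocal to
machine precision. Solves warn when fewer than 10 cells per background
wavelength are available.

Because base R's Bessel functions are real-only, the package carries its
own complex-argument kernels: power series for $|z|\le 11$, Hankel
asymptotic expansions with optimal truncation beyond, Miller's downward
recurrence for $J_n$ and stable upward recurrence for $H_n^{(2)}$. They are
validated against base R on the real axis and by the Wronskian identity off
it.

Antennas are 12 co-located point (line) sources on a 9 cm-radius circle:
two groups of three flanking the anterior gap (where the heating applicator
sits) at ±35/45/55°, and six evenly spaced over the posterior arc
[120°, 240°]. Measurement noise is complex circular AWGN scaled per
frequency so that the block signal-to-noise ratio is 30 dB, applied
*independently* to the baseline and heated acquisitions — two measurement
sessions — so the differential data carries both draws.

## 4. Differential imaging

With treatment-planning knowledge of the segmented anatomy, the unheated
total field $E_{tot}^{[0]}$ is computable, and for the small
heating-induced perturbation $\delta\chi$ the distorted-wave Born
approximation gives the linear model
$\Delta E_S = k_b^2\int E_{tot}^{[0]}(r',r_m)E_{tot}^{[0]}(r',r_v)\,
\delta\chi(r')\,dr'$. Matrix entries use the source-excited total fields at
receiver positions via reciprocity. Per-frequency blocks are stacked
row-wise into one system before a single SVD — the standard
frequency-diversity reading when $\delta\chi$ is treated as
frequency-independent over the band; no per-frequency weighting is applied
(none is implied by the protocol, and the blocks have comparable norms).

The operator is restricted to the two ROI windows and inverted by TSVD with
$P_{cut} = 1$. The SVD is computed once per baseline phantom (offline); the
online step is a $P_{cut}$-term projection, i.e. real-time. By default the
operator uses each sample's own randomized baseline (perfect planning
knowledge); a `"nominal"` switch builds it from the unrandomized phantom to
study model mismatch.

## 5. Classifiers and training protocol

The two ROI images are split into Re/Im channels
($5\times5\times2$ tumor, $6\times6\times2$ cord). Each CNN is
conv(3×3, 16, same, ReLU) → conv(3×3, 32, same, ReLU) → dense(64, ReLU) →
dense($N_c$, softmax); with $P_{cut}=1$ images the informative content is a
single complex coefficient, so network capacity is not the bottleneck, and
the compact stack keeps the parameter count ($\approx5\times10^4$) well
below the dataset sizes. Inputs are not standardized: the $\delta\chi$
magnitudes are physically meaningful. Labels follow the temperature rise:
tumor class 0/1/2 split at ΔT = 3 and 7 °C, cord class 0/1 split at 2 °C.

The loss is the categorical cross-entropy normalised by both the batch size
and the class count, $-\tfrac{1}{N N_c}\sum_n\sum_c C\log\hat C$; a flag
restores the conventional $1/N$ form (the gradients differ by the constant
$N_c$ only). Training: Adam, learning rate $10^{-4}$, batch 16, at most 300
epochs, early stopping after 10 epochs without validation improvement with
best-weights restoration (standard practice where the protocol is silent).
10-fold cross-validation with fold-indexed re-initialization seeds; every
random stage (fold assignment, init, shuffling) derives a child seed from
the master seed, so runs are bit-reproducible. Convolutions are evaluated
as matrix products on gathered 3×3 patches; the analytic gradients are
verified against finite differences in the test suite.

Metrics are computed on each fold's validation split and averaged across
folds: per class (one-vs-rest for the 3-class tumor case, the only
consistent reading of the binary DSC/MCC formulas), DSC
$= 2TP/(2TP+FP+FN)$ and MCC $= (TP\cdot TN - FP\cdot FN)/\sqrt{DM}$, with
MCC = 0 by convention for a degenerate denominator. Confusion matrices are
summed over folds.

## 6. Scale presets and problem sizes

Two presets share all physics and protocol constants (12 antennas, 30 dB
SNR, sd 0.1 randomization, $P_{cut}=1$, 10 folds, Adam/1e-4/16/300/10):

* **full** — 128×128 grid over 24 cm (1.875 mm cells), 10 frequencies,
  3000 tumor / 2000 cord samples. Hours on one CPU.
* **reduced** — 32×32 grid over 12 cm (3.75 mm cells), 3 frequencies
  (0.9, 1.35, 1.8 GHz), 400 tumor / 300 cord samples. Minutes on one CPU;
  this is the scale the acceptance script and the test suite run.

The reduced preset shrinks the *domain* together with the grid rather than
coarsening the cells: the cell size controls how many pixels the 4.5 mm
tumor occupies inside its fixed 5×5 window, and that fraction shapes the
$P_{cut}=1$ inverse problem (the leading singular vector is a smooth window
mode; a sub-pixel tumor projects poorly onto it). 3.75 mm is the closest a
32² grid that still contains the neck can get to the full-scale
resolution. At 3.75 mm the solver operates below 10 cells per background
wavelength at the top of the band and warns accordingly; baseline and
heated states share the discretization, so the differential images remain
consistent.

## 7. What the synthetic study shows — and what it does not

The generator emulates the study conditions: per-tissue dispersion,
temperature-dependent heated tissues, per-sample Gaussian tissue
variability, two-session 30 dB measurement noise. It does not emulate real
anatomy (the raster is stylized, not an anatomical model), realistic
antennas (point sources, no mutual coupling), 3D propagation, thermal
physics (temperatures are imposed, not computed from a bio-heat equation),
or motion.

Passing tests therefore demonstrate the correctness and stability of the
chain — forward solver against an independent analytic oracle, DWBA
linearization error shrinking with the perturbation, TSVD against a
pseudo-inverse oracle, exact label/metric arithmetic, calibrated noise, and
near-perfect end-to-end classification in the noise-free extreme-ΔT
regime — not clinical performance.

A known limitation follows from the stand-in physics: with the synthetic
tissue table and the default ±2 %/−0.5 % per-°C temperature rates, the
differential scattered field at therapeutic heating sits near the 30 dB
measurement-noise floor after the $P_{cut}=1$ projection, so classes
adjacent in temperature overlap substantially and the achievable
noisy-data accuracy is far below the noise-free ceiling. The acceptance
script reports exactly what the pipeline achieves under these conditions;
closing the gap to a clinical-grade result would require the true
temperature-coefficient model and anatomy rather than stand-ins, which is
out of scope here. The per-°C dielectric response and the ROI-to-antenna
geometry are the sensitivity levers a user should explore first (all are
configuration).

## 8. Numerical details worth knowing

* Degenerate inputs: zero contrast short-circuits the solver (exact zero
  scattered field); a zero tumor radius is rejected at configuration;
  singular values below $10^{-12}\lambda_1$ are excluded from TSVD with a
  warning; a predicted probability below $10^{-12}$ at a true class is
  clipped with a warning.
* Tie-breaks: class prediction is the argmax of the softmax; `max.col`
  ties are broken by the first maximum for reproducibility.
* The child-seed derivation uses small multipliers so the arithmetic stays
  exact in doubles and below $2^{31}$.
* Fold counts must divide the dataset size exactly; the error message
  lists the valid alternatives.
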