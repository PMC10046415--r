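# thermowave

Physics-assisted deep-learning microwave thermometry for hyperthermia
treatment monitoring, assessed in silico on a synthetic 2D neck phantom.

## The problem

Hyperthermia treatment (HT) heats a tumor to 40–43 °C to sensitize it to
radio- or chemotherapy. The therapy needs non-invasive feedback: did the
tumor reach the therapeutic band, and is nearby heat-sensitive healthy
tissue (here, the spinal cord) staying cool? Tissue dielectric properties
depend on temperature, so a microwave imaging (MWI) array around the neck
can in principle sense the heating — but the underlying inverse scattering
problem is nonlinear and ill-posed.

`thermowave` implements a full simulated pipeline that turns this into a
tractable classification problem:

1. **Tissue dielectrics.** Each tissue follows a two-pole Cole–Cole model
   εr(ω,T) = ε∞ + Δε₁/(1+(jωτ₁)^(1−α₁)) + Δε₂/(1+(jωτ₂)^(1−α₂)) + σ/(jωε₀),
   with a linear temperature model p(T) = p·(1 + c_p (T−37)) applied to the
   heated tissues.
2. **Forward scattering.** The 2D TM state and data equations are solved by
   a pulse-basis, point-matching method of moments (dense LU on small grids,
   CG-FFT above), for 12 point antennas on a circle and multiple frequencies
   in [0.9, 1.8] GHz; measurements get 30 dB additive white Gaussian noise.
3. **Differential imaging.** For small heating-induced perturbations the
   distorted-wave Born approximation linearizes the problem:
   ΔES = kb² ∫ Etot⁰(r′,rm) Etot⁰(r′,rv) δχ(r′) dr′, with the unheated total
   field playing the role of the Green's function. The operator is
   restricted to two square regions of interest (5×5 px tumor, 6×6 px
   spinal cord) and inverted by truncated SVD,
   δχ = Σ_{p≤Pcut} λp⁻¹ νp (upᴴ ΔES), with Pcut = 1.
4. **Classification.** Two compact CNNs (two 3×3 conv layers, a dense
   layer, softmax) map the two-channel Re/Im ROI images to temperature
   classes — tumor: {unheated, therapeutic, hot} split at ΔT = 3 and 7 °C;
   cord: {unheated, hot} split at ΔT = 2 °C — trained with Adam
   (lr 1e-4, batch 16, ≤300 epochs, early stopping) under 10-fold
   cross-validation and scored with class-wise Dice (DSC) and Matthews
   (MCC) coefficients.

Everything is generated internally: no external data. The bundled tissue
table (`inst/extdata/tissue_params_synthetic.csv`) contains synthetic
stand-in Cole–Cole parameters in the style of the published tissue
compilations.

## Worked example

One simulated measurement pair on the desk-scale phantom, imaged at Pcut=1:

```r
library(thermowave)

ph    <- build_neck_phantom(phantom_config(n = 32L, domain_size = 0.12))
lay   <- antenna_layout()
freqs <- frequency_set(3L)

baseline <- lapply(freqs, function(f) solve_total_field(ph, lay, f))
op <- build_roi_operator(baseline, ph$rois$tumor)

heated <- set_roi_temperatures(ph, T_tumor = 42, T_cord = 37)
hot <- lapply(freqs, function(f) solve_total_field(heated, lay, f))

es0 <- simplify2array(lapply(baseline, `[[`, "es"))
es1 <- simplify2array(lapply(hot, `[[`, "es"))
img <- tsvd_invert(op, differential_data(es1, es0), pcut = 1)
max(Mod(img$delta_chi))          # 0.00915
assign_tumor_label(42 - 37)      # 1 (therapeutic)
```

The phantom raster places 4 tumor and 4 spinal-cord pixels among
skin/fat/muscle/bone/thyroid on a 32×32 grid of 3.75 mm cells; the tumor
ROI operator is 432×25 (12 Tx × 12 Rx × 3 frequencies by 25 window pixels)
with full rank 25. Heating the tumor from 37 to 42 °C changes its complex
permittivity by a few percent, which appears as a differential-contrast
image with peak |δχ| ≈ 0.009 in the tumor window; the ground-truth label
for ΔT = 5 °C is class 1 (therapeutic).

The full experiment — dataset generation, 10-fold training of both CNNs,
metric tables and confusion matrices — is one call:

```r
res <- run_experiment(run_config("reduced", seed = 1), out_dir = "run1")
report(res)
```

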