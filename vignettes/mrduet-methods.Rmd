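---
title: "Methods: simulating interleaved 23Na/1H radial MRI with pTx excitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating interleaved 23Na/1H radial MRI with pTx excitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mrduet` is a desk-scale re-creation of a dual-nuclear cardiac MRI
examination at ultrahigh field: a sodium (²³Na) acquisition whose idle time
carries an interleaved proton (¹H) acquisition, with parallel-transmit
(pTx) pulses homogenizing the ¹H excitation. This vignette records the
models, the numerical choices, and what the synthetic data can and cannot
show.

## The acquisition model

**Projection ordering.** Both nuclei use 3D radial readouts whose
directions follow the two-dimensional golden means,

$$z_n = 2\,\mathrm{frac}(n\lambda_1) - 1,\qquad
  \phi_n = 2\pi\,\mathrm{frac}(n\lambda_2),$$

with $\lambda_2 \approx 0.6823$ the real root of $x^3 + x = 1$ and
$\lambda_1 = \lambda_2^2 \approx 0.4656$. We deliberately use the
full-precision irrational roots rather than the four-decimal values these
constants are usually quoted at: 0.4656 and 0.6823 are rational with joint
period 10 000, so a 60 000-projection series built from them would repeat
each direction exactly four times. With the exact roots, equidistribution
holds at any length (the test suite checks 60 000 directions for
duplicates and spherical-cap uniformity at 15 000).

Centre-out ("half") projections must cover the whole sphere
($z \in [-1, 1]$). Centre-through ("full") projections sample the
antipodal direction implicitly, so their polar coordinate only covers a
hemisphere ($z_n = \mathrm{frac}(n\lambda_1)$). The hemisphere convention
for full projections is our choice — only the two constants are commonly
printed, not the full-sphere/hemisphere mapping — and is stated here as an
assumption.

**Density-adapted readout.** Along each spoke, $|k|(t)$ rises linearly
(constant gradient) to $k_0 = $ `k0_fraction` $\cdot\, k_{max}$ and then
follows $k(t) = (k_0^3 + 3k_0^2 g_0 (t - t_0))^{1/3}$, i.e.
$k^2\,dk/dt = \text{const}$, which makes the acquired sampling density per
unit k-space volume uniform beyond $k_0$. `k0_fraction` defaults to 0.2;
the published protocols delegate the readout shape to their own
references, so the onset is exposed as configuration. Gradient hardware
limits (slew rate, amplitude) are not modelled; the readout is specified
directly as k(t).

**Density compensation and readout oversampling.** Density-compensation
factors are analytic: each sample is weighted by the volume of its radial
Voronoi shell divided by the number of projections, giving
$\mathrm{dcf} \propto k^2\,dk$ exactly ($\propto k^2$ in the linear
region, constant per unit time beyond $k_0$), with a finite positive
weight for the centre sample. A practical subtlety we found and encode in
`recommended_n_samples()`: the quadrature accuracy of this analytic DCF
for structures *away from the iso-centre* is governed by the radial
sampling rate at the centre of k-space, where the density-adapted gradient
is fastest. Sampling at the bare FOV Nyquist rate leaves percent-level
shading; the standard 2× readout oversampling reduces the error of a
two-compartment concentration ratio to ~2 % (the acceptance suite measures
this). All shipped configurations use 2× readout oversampling.

**Interleave schedule.** Each sodium TR (60 ms by default) opens with one
²³Na excitation/readout; `n_h_per_tr` = 4 ¹H projections fill the idle
time. The ¹H repetition intervals follow the pattern
$(a, a, a, b)$ with $3\,TR_a + TR_b = TR_{Na}$ (13.08 / 20.76 / 60 ms
defaults); $TR_b$ absorbs the sodium block. Whether the long interval
comes last (`"aab"`) or first (`"baa"`) within a period is not fixed by
the timing identity; both orders are implemented and the default is
`"aab"`. The ¹H pulse train is centred in the idle time after the sodium
readout. The schedule builder validates the identity to 1 µs and derives
$TR_b$ when only $TR_a$ is given.

**Signal model.** Neither nucleus's steady state is prescribed in the
protocol tables we mirror, so we assume an ideally spoiled gradient-echo
steady state,

$$S = M_0 \sin\alpha\,\frac{1 - E_1}{1 - E_1\cos\alpha}\,
      e^{-TE/T_2^*},\quad E_1 = e^{-TR/T_1},$$

with the ¹H steady state evaluated at the mean of its TR pattern.
Relaxation during the readout is collapsed into the single $e^{-TE/T_2^*}$
factor at the echo time; per-sample decay (and the bi-exponential ²³Na
$T_2^*$ of tissue) is not modelled. The simulator is exactly linear in
$M_0$, and the two nuclei are simulated independently — there is no
cross-talk mechanism, so per-nucleus raw data are *bit-identical* whether
events were scheduled interleaved or single-nuclear. The
interleaved-versus-single comparison in the test suite therefore verifies
the scheduling/simulation plumbing, not RF physics: on a real system this
equivalence is an empirical finding, here it holds by construction.

## The nonuniform Fourier engine

Reconstruction and forward simulation share a Kaiser–Bessel gridding
implementation (type-1 adjoint and type-2 forward nonuniform DFT): spread
onto a 2× oversampled grid with a width-$W$ Kaiser–Bessel window (shape
parameter per Beatty–Nishimura–Pauly), FFT, and analytic deapodization by
the window's Fourier transform $\propto \sinh(\sqrt{\beta^2 -
(\pi W s)^2})/\sqrt{\cdot}$. At the default $W = 10$ the transforms agree
with brute-force DFT summation to ~$10^{-9}$ relative error (tested
against an independent DFT oracle on 16³ grids); $W = 6$ (~$10^{-5}$) is
used inside the demonstration pipeline where throughput matters more than
oracle-grade accuracy. Image convention: the k-space centre maps to the
voxel with 0-based index $\lfloor N/2\rfloor$; forward phase
$e^{-2\pi i k\cdot x}$.

Reconstruction applies DCF and, by default, a radial Hamming window
$w(k) = 0.54 + 0.46\cos(\pi|k|/k_{max})$ to the samples before gridding
(pre-gridding radial apodization — the parameterization point is our
assumption, the test suite verifies the first PSF sidelobe shrinks).
Channels are combined by root-sum-of-squares; magnitude imaging without
sensitivity estimates makes RSS the standard choice. Cross-nucleus
comparison uses trilinear `resample_to`; grids are exactly aligned by
construction, so only a rigid-translation utility is provided, no
deformable registration.

## Flip-angle and field mapping

- **Double angle**: $FA = \arccos(S_{2\alpha}/2S_\alpha)$; valid in the
  long-TR regime (the 250 ms ²³Na protocol), the $T_1$ bias is ignored.
- **AFI**: two interleaved delays; with $n = TR_{long}/TR_{short}$ and $r$
  the ratio of the signal excited after the short delay to that after the
  long delay, $\cos FA = (rn - 1)/(n - r)$. Protocol tables sometimes
  list the long interval first, so the implementation keys on
  `(tr_long, tr_short)` by name. The first-order inversion was checked
  against a Bloch steady-state simulation of the two-TR cycle: at
  $T_1 = 1000$ ms and TR 75/15 ms the error stays below 0.5° across
  10–85° (largest near 90°).
- **Receive profile**: in a homogeneous-concentration sample,
  $B_1^-(x) \propto S(x)/\sin FA(x)$. The proportionality constant is not
  observable, so maps are normalized to mean 1 over the valid mask; voxels
  with $FA \notin [5°, 175°]$ are masked to avoid the $\sin$ blow-up.
- **Transmit efficiency**: $\eta(x) = FA(x)/(2\pi\gamma\,T_{pulse}
  U_{applied})$, reported in nT/V ($\gamma$: 42.577 MHz/T for ¹H, 11.262
  for ²³Na).
- **Relative channel maps** divide each complex channel image by the
  voxelwise sum of channel magnitudes (so relative magnitudes sum to 1);
  the absolute transmit scale is not recoverable from relative maps. The
  sum-of-magnitudes reference is our documented assumption.

## pTx pulse design

The design cost is the **coefficient of variation (population std/mean)
of the combined transmit magnitude over the heart ROI** — equivalently of
the normalized flip-angle map, since the small-tip FA is proportional to
the field. Published pulse-design pipelines do not always print their
exact cost; CV is the homogeneity metric they report, so we optimize it
directly and state that as an assumption.

- **DPS** (default phase shim) stands in for a vendor-fixed phase setting:
  unit weights on synthetic array fields whose default phases alternate by
  π between neighbouring channels, producing the characteristic central
  destructive dropout.
- **IPS** minimizes the subject's ROI CV over per-channel phases (first
  phase gauged to 0). Optimizer: multi-start local search — Nelder–Mead
  polished by BFGS for ≥ 3 channels; for 2 channels a 2° coarse scan
  seeds local refinement (the CV can be multimodal in one phase).
  Deterministic given the seed; on 2-channel/≤ 4-voxel instances the
  result matches an exhaustive 1° grid oracle. A single-voxel ROI makes
  CV degenerate (identically zero wherever defined); that case returns
  the constructive alignment of all channels.
- **UPS** minimizes the mean over a subject library of each subject's ROI
  CV, with the same gauge and determinism rules.
- **4kT** (kT-points): K = 4 rectangular sub-pulses with complex
  per-channel weights and gradient blips (candidate offsets ±1 cycle/FOV
  per axis plus zero, selected greedily), weights fitted by regularized
  magnitude least squares (variable exchange) toward a uniform target FA.
  The search is initialized from the IPS solution with zero blips and the
  best-CV iterate is returned, so CV(4kT) ≤ CV(IPS) by construction, and
  nesting the candidate set makes the cost monotone in K. The field
  matrix is normalized to unit RMS before optimization, which makes the
  whole design — including the discrete blip selection — exactly
  homogeneous in the map amplitude (weights scale as $1/c$ when maps
  scale by $c$); greedy comparisons use a $10^{-12}$ tolerance so
  floating-point ties cannot flip the selection. Tikhonov weight:
  $10^{-6}$ relative to the mean squared field, small enough not to bias
  the CV, large enough to keep the normal equations well conditioned.

**Reference voltage.** A linear calibration $U_{ref} = a\cdot\text{weight}
+ b$ is fitted by ordinary least squares; the synthetic calibration
generator draws weights from 55–105 kg around a 9.4 V/kg, 542.5 V line
with 115 V Gaussian scatter, sized to give a weight–voltage correlation
near 0.76 as observed for torso arrays at 7 T. The per-channel RF power
check models rectangular pulses into a matched 50 Ω load,
$P_c = D_c U_c^2 / 2Z$ with $D_c$ the per-channel duty cycle, against the
1.195 W per-channel limit of the ¹H array; the demonstration pipeline
converts the reference voltage (convention: 180° with a 1 ms hard pulse)
to per-channel amplitudes by scaling with the flip-angle fraction and
dividing across channels — vendor conventions differ, and this one is
stated rather than claimed.

## What the synthetic data emulate — and what they do not

The phantom module produces ellipsoidal compartments (a ~300 mM torso
analogue; illustrative 140 mM blood / 43 mM myocardium values for the
two-compartment heart, documented as placeholders, not measurements).
Coil fields are phenomenological: a birdcage analogue with a smooth
linear+quadratic corner taper whose `asymmetry` parameter dials the
central-ROI CV (1.0 ≈ 0.15, emulating the loaded/combined condition;
0.7 ≈ 0.09), and loop-array fields with exponential magnitude decay and
smooth phase ramps. There is no electromagnetic simulation, no noise
correlation between channels, no $B_0$ inhomogeneity, no motion, no
bi-exponential sodium relaxation, and no SAR field model beyond the
time-averaged power check. Passing tests therefore demonstrate that the
processing and optimization mathematics are correct on fields with
realistic smoothness and interference structure — not that the pipeline
is validated on real coils or subjects; in vivo CV values, efficiency
losses and noise levels cannot be reproduced at the desk, only the
orderings and formula identities that do not depend on hardware.

## Problem sizes and determinism

The demonstration pipeline (`run_demo`) uses a 16³ sodium grid at
(6 mm)³ and a 24³ proton grid at (4 mm)³ over a 96 mm field of view, with
400 sodium and 1600 proton projections and 2× oversampled readouts
(136/256 samples) — sizes chosen so the full pipeline, including two
acquisitions per nucleus and all four pulse designs, completes in about
two minutes on one CPU while keeping the proton array at its full 8
channels. Protocol *timing* quantities are always computed from the full
protocol configuration (15 000/60 000 projections), which is pure
arithmetic. The concentration-recovery check runs at 32³ with 2200
projections. Every stochastic element — simulated noise, the synthetic
subject library, optimizer restarts, calibration scatter — is derived
from a single integer seed, and generators save/restore the global RNG
state so they do not disturb the caller's stream. Degenerate inputs
(empty ROIs, zero phantoms, zero-signal voxels, mode/scheme mismatches,
non-filling TR patterns) raise errors or mask voxels rather than
propagating NaNs; division-by-zero voxels in relative-difference maps are
excluded and counted.

## Known limitations

- The adjoint-gridding reconstruction with analytic DCF is a direct (not
  iterative) reconstruction; no compressed sensing, no per-sample decay
  modelling, no off-resonance.
- The spoiled-GRE steady state is an assumption for both nuclei; sodium's
  multi-compartment relaxation is reduced to one mono-exponential $T_2^*$.
- Phase-only shims and kT-points are designed in the small-tip regime;
  large-tip (Bloch-accurate) design and SAR-constrained optimization via
  virtual observation points are out of scope.
- The interleaved/single-nuclear equivalence is structural in this
  simulator (see above), so it validates code paths, not physics.
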