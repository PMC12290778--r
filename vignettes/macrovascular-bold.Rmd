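---
title: "Simulating macrovascular resting-state BOLD: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating macrovascular resting-state BOLD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The physical model and its assumptions

Deoxygenated blood is paramagnetic relative to tissue. A vessel carrying
blood at oxygenation $Y$ inside tissue at reference oxygenation
$Y_{tissue}$ has volume susceptibility contrast
$\chi = \Delta\chi \cdot Hct \cdot (Y_{tissue} - Y)$, positive for veins
and negative for arteries under the defaults. The induced relative field
offset is computed two ways:

* **numerically**, as the inverse Fourier transform of the
  susceptibility spectrum multiplied by the k-space dipole kernel
  $1/3 - k_z^2/k^2$ (`field_offset_volume`), valid for arbitrary vessel
  geometry; and
* **analytically**, for an infinite cylinder
  (`cylinder_field_offset`): the dipolar
  $\sin^2\theta\,(a/r)^2\cos 2\phi$ pattern outside the vessel and the
  constant $(3\cos^2\theta - 1)/3$ offset inside.

Signal formation assumes the **static dephasing regime**: spins
accumulate phase $\gamma B_0 (\Delta B_z/B_0) T_E$ without diffusion
averaging, a good approximation for macrovessels whose field
perturbations extend far beyond a diffusion length. The voxel signal is
the magnitude of the weighted complex mean over sub-voxels
(`voxel_signal`); weights are the steady-state gradient-echo amplitudes
of each compartment (blood vs. tissue $T_1$, $T_2$). Inflow and
diffusion effects are out of scope by assumption.

Resting-state dynamics are deliberately minimal: a 0.1 Hz sinusoid
drives venous oxygenation and arterial blood-volume fraction (fBV).
"±10% peak-to-peak" means the driven quantity swings between 95% and
105% of baseline — the total swing, not the amplitude, is 10%. Real
vasomotion is broadband and non-sinusoidal; the sinusoid isolates the
geometry- and oxygenation-dependence of the response, which is what
these simulations are for.

## Parameters

All physical and sequence parameters live in one `sim_params()` object
(SI units): $\Delta\chi = 4\pi \times 0.27 \times 10^{-6}$
(dimensionless SI), $Hct = 0.4$, $B_0 = 3$ T, $T_E = 27$ ms,
$T_R = 2.2$ s, flip angle $90^\circ$, $Y_a/Y_v/Y_{tissue} =
0.98/0.6/0.85$, $T_{1,blood} = 1.649$ s, $T_{1,tissue} = 1.465$ s,
818 frames (30 min at $T_R = 2.2$ s). A YAML/JSON config with the same
key names (plus `_ms` and `alpha_deg` convenience keys) can override any
of them.

Two modelling choices deserve explanation:

* **Steady-state form.** The default expression places
  $\exp(-T_E/T_2)$ inside the steady-state denominator,
  $\sin\alpha\,(1 - E_1)/(1 - \cos\alpha\,E_1 E_2)$. At the default
  $90^\circ$ flip angle $\cos\alpha = 0$ and the $T_2$ factor drops out
  entirely, so compartment weights differ only through $T_1$. The
  textbook spoiled-gradient-echo form with a multiplicative
  $E_2$ decay is available via `signal_form = "spgr"` for users who
  want explicit $T_2$ weighting.
* **Blood $T_2(Y)$.** Relaxometry at 3 T is summarized by the quadratic
  law $1/T_2 = A + B(1-Y) + C(1-Y)^2$ with defaults
  $A = 4$, $B = 35$, $C = 300\ \mathrm{s^{-1}}$, fully exposed in
  `t2_blood_coef` so alternative calibrations can be swapped in. Under
  the default flip angle this choice only matters in `"spgr"` mode.

## The three simulators

**2D cylinder voxel** (`build_2d_voxel`): one analytic cylinder
cross-section centred in a 4 mm voxel of $n \times n$ sub-voxels
(default $4000^2$, i.e. 1 µm). The disc radius follows
$a = L\sqrt{fBV/\pi}$; above $fBV = \pi/4$ a centred disc no longer
fits the square voxel, so the radius is solved such that the *clipped*
disc area still equals the requested fBV (at $fBV \to 1$ the disc
circumscribes the voxel). This keeps the realized blood fraction honest
across the full sweep range instead of refusing fBV > 0.785. Results
change by less than 0.5% between $1000^2$ and $4000^2$ grids; sweeps in
the tests use $1000^2$.

**3D cylinder voxel** (`build_3d_voxel`): an oriented cylinder through
the voxel centre, voxelized at 40 µm (default $100^3$ sub-voxels), field
via the dipole kernel. The infinite cylinder is emulated by drawing it
across an extended grid (3 voxels per side by default) and convolving
cyclically, so the periodic images sit far from the voxel of interest;
for axis-aligned cylinders the cyclic wrap is exact. Realized fBV grows
with obliquity — a thin vessel at $45^\circ$ runs a $\sqrt 2$-times
longer path through a cubic voxel. `oblique_cylinder_fbv` computes the
same quantity without lattice quantization by clipping axis-parallel
chords against the cube exactly; thick vessels fall short of 1.41
because the cube corners clip the tube.

**Whole-volume network** (`macro_van_scene`,
`simulate_van_timeseries`): centreline+diameter+label volumes are
rasterized into tubes at a 0.2 mm working resolution, a susceptibility
volume is built per frame (venous oxygenation and arterial radius at
their instantaneous values), the field is computed once per *distinct*
oscillation state — the 0.1 Hz drive sampled at $T_R = 2.2$ s repeats
every 50 frames, so long runs cost at most 50 field evaluations — and
the weighted complex magnetization is aggregated to fMRI voxels by
block-wise complex means. Arterial fBV oscillation is realized as a
continuous radius modulation ($a \propto \sqrt{fBV}$) before
rasterization at each frame rather than a one-voxel quantized
dilation; the rasterized swing then tracks the requested ±30%
peak-to-peak up to lattice quantization of the tube cross-section.

## Vascular geometry processing

Centreline volumes carry a diameter per centreline voxel and a label
(0/1/2 = none/artery/vein). Merging multiple segmentation sources takes
the union and, where estimates overlap, the *largest* diameter; label
conflicts resolve to vein (venous susceptibility dominates the BOLD
effect where the two overlap) with a warning.

**Local orientation** is estimated per centreline voxel from the pair of
centreline voxels in a $9^3$ window that are both connected to the
centre along the centreline (26-connectivity) and maximally separated —
a rule that stays stable through bends and near bifurcations, where
naive nearest-neighbour pairs degenerate. If no connected pair exists,
the principal axis of the window's centreline second-moment tensor is
used; isolated voxels are flagged undefined and excluded downstream.
Because a centreline has no preferred direction of travel and every
field formula depends on orientation only through $\sin^2\theta$,
$\cos^2\theta$ and $\cos 2\phi$, the zenith is folded to $[0, \pi/2]$
and the azimuth to $[0, \pi)$.

**Voxelization** resamples the centreline along the piecewise-linear
segments joining 26-adjacent centreline voxels at the target resolution
and marks every voxel whose centre lies within one radius of the path
(boundary inclusive). On a 0.2 mm grid a 0.8 mm vessel centred on a
voxel centre quantizes to a 13-voxel cross-section; the inclusive-disc
lattice count overshoots the analytic area by ~3.5% at that resolution
and converges as the grid refines. fBV maps then count occupied
sub-voxels per fMRI voxel, and perivascular shells are successive
one-voxel dilation differences (26-connected by default — "one voxel in
every direction including diagonals" — 6-connected available), pairwise
disjoint by construction.

## Metrics and evaluation

* **RSFA**: the series is normalized by its mean, frames beyond the
  Tukey fences ($1.5 \times IQR$ beyond the quartiles of the normalized
  series) are removed, and RSFA is the standard deviation of what
  remains. For a pure sinusoid of relative amplitude $A$,
  RSFA $= A/\sqrt 2$.
* **FC**: the signed extremum of the normalized cross-correlation over
  lags up to ±5 frames (11 s, covering a full 0.1 Hz period) — the
  maximum if the largest-magnitude extremum is positive, the minimum if
  negative, ties preferring the positive extremum. The lag tolerance
  lets simulated correlations be compared with measured ones without
  modelling transit delays.
* **Sigma-weighting**: noiseless simulations have effectively infinite
  SNR, so each correlation is multiplied by the simulated temporal
  standard deviation of the *target* voxel as an SNR surrogate; a
  geometric-mean variant ($\sqrt{\sigma_i \sigma_j}$) is available
  behind a flag, and tables record both sigmas so either can be
  reconstructed.
* **Binned regression**: pairs are sorted by the *simulated* value (the
  prediction is the independent axis), grouped into consecutive
  fixed-count bins (remainder dropped), and an ordinary least-squares
  line is fit through the bin means; its $R^2$ measures prediction
  quality. Bin sizes follow pair abundance (100 / 1,000 / 10,000 for
  AA / AV / VV in full-scale analyses; 100 in the desk-scale recovery
  experiment).

## The synthetic test bed and what it does (not) show

`make_synthetic_van` traces piecewise-linear vessels with bounded
curvature through a cubic field of view, with diameters at or above the
0.8 mm angiographic detectability floor, an artery/vein split, and a
random per-vessel phase offset of the 0.1 Hz drive so vessels are
mutually decorrelated. `make_pseudo_experimental` turns a noiseless run
into a surrogate measurement: frame-wise Gaussian noise scaled to the
voxel mean (AR(1) optionally), a shared 0.03 Hz nuisance sinusoid
emulating a global physiological drive, and a smooth multiplicative
scaling field emulating receive-coil sensitivity. All randomness flows
from explicit seeds and generators restore the caller's RNG state.

`recovery_experiment` closes the loop: synthetic network → whole-volume
simulation → venous–venous FC → pseudo-experimental FC at each noise
level → binned regression. The desk-scale defaults were fixed once: a
$64^3$ working grid (12.8 mm field of view at 0.2 mm), 1.6 mm fMRI
voxels (a 4 mm grid would leave only ~3³ voxels at this field of view),
160 frames, bin size 100, zero-padding of half a field of view for the
whole-volume field step (the default elsewhere is a full field of view;
with sources this compact, halving the pad changes the field at the
vessels by well under a percent), and the nuisance component off so the
sweep isolates the noise level. With no noise the measurement equals
the prediction and $R^2 = 1$ by construction; the informative content
is how fast recovery degrades as noise grows.

What passing these tests shows: the field models agree with their
analytic oracles, the signal machinery is internally consistent across
the three simulators, and the evaluation pipeline recovers a known
ground truth with the expected noise sensitivity. What it does not
show: fidelity to real angiographic anatomy (synthetic vessels are
smooth tubes without branching or partial-volume ambiguity), realistic
physiological dynamics (single-frequency sinusoids), or in-vivo
prediction accuracy, which depends on segmentation quality and
measurement confounds not modelled here.

## Numerical choices

* Dipole kernel value at $k = 0$ set to 0 (zero-mean field); makes the
  uniform-susceptibility case exact and fixes the arbitrary constant.
* Zero-padding by one full field of view per side before the FFT
  suppresses cyclic wraparound; `pad = 0` gives a purely cyclic
  convolution, used deliberately for the extended-grid infinite
  cylinder.
* The main field is fixed to the grid $+z$ axis; oblique acquisition
  is handled by rotating the *geometry* through the volume's direction
  cosines, not by oblique kernels.
* Voxel-centre coordinate convention, 0-based corner origin; boundary
  inclusion in tube tests is $\le$ with a $10^{-9}$ slack so exact
  lattice tangencies are stable.
* Frames whose oscillation state repeats are memoized by value, keyed
  at 10 significant digits.
* Extremum ties in FC (|max| = |min|) resolve to the positive extremum,
  deterministically.
* Degenerate inputs fail loudly: zero-variance series are flagged
  undefined rather than returning NaN correlations; empty centrelines
  produce empty masks; scenes exceeding the memory cap are refused with
  the required size.

## Known limitations

Single-voxel models place the vessel at the voxel centre — vessel
position within the voxel, known to modulate the signal, is not
represented. The 2D model cannot express the fBV–obliquity interaction.
Whole-volume runs at full-brain scale are outside the intended desk
scale of this implementation; fields of view beyond a few centimetres
at 0.2 mm require memory and time budgets this package deliberately
guards against. Arterial dynamics are simplified to radius modulation
of a static centreline; real arterial pulsation moves the vessel wall
and the surrounding tissue. The $T_2(Y)$ relaxometry law is a
calibrated approximation, and sigma-weighting uses the target voxel's
sigma by convention — both are configurable rather than settled.
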