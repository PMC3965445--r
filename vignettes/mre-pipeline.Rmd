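---
title: "Simulated mouse-brain MRE: forward model, reconstruction, and longitudinal statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated mouse-brain MRE: forward model, reconstruction, and longitudinal statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mretools)
```

## The problem

Magnetic resonance elastography (MRE) measures tissue mechanics in vivo: an
external transducer drives harmonic shear waves (here 900 Hz) through the
head, a motion-sensitizing gradient (MSG) encodes the tissue displacement
into the MR signal phase, and an inversion of the wave equation converts the
imaged wave field into maps of the complex shear modulus
`G* = G' + iG''` (storage and loss modulus, in kPa). ROI averages of these
maps tracked over days can reveal transient mechanical responses of the
hippocampus — e.g. a stiffening episode when a wave of newly generated
neurons matures in the dentate gyrus after a dopaminergic lesion.

`mretools` implements that computational chain end to end, with a simulator
standing in for the scanner: no animal data are required anywhere, and every
processing stage can be validated against closed forms or independent
oracles.

## Forward model

The through-plane displacement `u(x, y)` of a time-harmonic shear wave in a
2D heterogeneous viscoelastic medium satisfies

```
div( G*(x,y) grad u ) + rho * omega^2 * u = 0 ,
```

with `rho` the density and `omega = 2*pi*f` the angular drive frequency.
`solve_forward()` discretises this with the standard 5-point
finite-difference stencil (edge-midpoint arithmetic-mean moduli), prescribes
a harmonic Dirichlet drive on one grid edge, and closes the remaining edges
with an absorbing sponge: a quadratic ramp of mass damping,
`rho*omega^2*(1 - i*sigma)`, emulating outgoing waves. The sign of the
sponge term matters: with this package's phase convention a forward-decaying
plane wave is `u = A exp(-i k* x)` with `k* = omega*sqrt(rho/G*)` on the
principal branch, so absorption must enter with a *negative* imaginary part
(the positive sign amplifies instead — the 1D oracle test catches this).
The sparse complex system is solved directly via an equivalent real block
system (`Matrix`).

Two solver verifications are built into the test suite:

* **Exactness:** with zero-flux (Neumann) lateral walls the 2D solution of a
  homogeneous phantom collapses onto the 1D three-point scheme; a dense
  tridiagonal oracle reproduces it to machine precision.
* **Physical accuracy:** against the analytic damped plane wave, pointwise
  agreement within 2% over the non-sponge interior requires both low
  finite-difference dispersion (about 48 pixels per wavelength; the relative
  wavenumber error of the stencil is `(kh)^2/24`) and an effective sponge
  (width 48 px, `sigma_max = 1.5`). At the acquisition regime of 12 pixels
  per wavelength the dispersion alone accumulates a ~1% wavenumber error, so
  there the test compares local wavenumbers, not pointwise fields.

`analytic_plane_wave()` provides the closed form used by both checks and by
the inversion tests.

## Phase encoding

For dynamic `d` of `n` (default 8 per vibration period) and MSG polarity
`s = ±1`, the encoded image is

```
phi_d = wrap( s * xi * Re[ u * exp(-2i*pi*d/n) ] + phi_static + noise ),
```

with encoding efficiency `xi = gamma * A_msg * N_cycles / (2 f)` — at the
default 285 mT/m, 9 cycles, 900 Hz this is `3.81e5` rad per metre of
displacement, so tens of micrometres of motion wrap the phase several times.
The static background phase is a low-order 2D polynomial
(`static_phase_poly()`), present so that the polarity difference has
something real to cancel. Noise is additive Gaussian before wrapping, with a
mandatory seed.

**Drive amplitude.** The transducer vibrates with amplitudes of tens of
micrometres, but what matters numerically is the *in-tissue* encoded phase.
The acquisition-like simulations here use a 2–6 µm boundary drive: the
halved phase-difference series (below) is congruent modulo `pi`, so its
pixel-to-pixel steps must stay below `pi/2` for any path-following
unwrapper (the Itoh condition); at a 10 µm one-edge drive the first columns
violate that bound and the failure is an artifact of the idealised one-sided
phantom, not of the method. Amplitude is exposed as a parameter everywhere.

## Reconstruction

`reconstruct()` chains five stages, each exported and individually tested:

1. `phase_difference()` — per dynamic, `wrap(pos - neg)/2`. Static phase
   cancels exactly; the factor 1/2 restores the single-polarity scale but
   leaves the series congruent to the motion phase modulo `pi`.
2. `unwrap_phase()` — quality-guided 2D unwrapping (C++ flood fill from the
   highest-quality pixel, quality = negative local variance of wrapped
   differences), with a `period` argument (`pi` for halved difference
   series) and a row/column Itoh fallback. Any global `k*pi` offset is
   harmless: it is constant in time and vanishes in the temporal DFT.
3. `extract_harmonic()` — temporal DFT at the fundamental; normalised so a
   series `xi*A*cos(2*pi*d/n - theta)` returns `xi*A*exp(i*theta)`, then
   divided by `xi` to give displacement in metres.
4. `bandpass_filter()` — radial Butterworth band-pass in k-space (default
   order 3, cutoffs `0.3*k_ref` and `3*k_ref` with
   `k_ref = 2*pi*f*sqrt(rho/G_ref)`, `G_ref = 5` kPa). The high-pass side
   suppresses the near-DC compression-wave regime (>= 99% attenuation at
   k -> 0), the low-pass side suppresses noise. The image is mirror-extended
   before the FFT: the field is not periodic, and without reflection padding
   the edge discontinuity rings across the heavily attenuated far field.
5. `helmholtz_invert()` — algebraic Helmholtz inversion
   `G* = -rho*omega^2*u / lap(u)` with the same 5-point Laplacian as the
   forward solver. Pixels are masked invalid on the border ring, where
   `|lap(u)|` falls below 5% of its interior median (wave nodes), or where
   the recovered `G'` is non-positive / `G''` negative (logged, never
   clamped).

Because forward solver and inversion share the stencil, their discretisation
biases cancel: a noise-free homogeneous simulation inverts to the exact
ground truth on interior pixels, and the end-to-end residual error (a few
tenths of a percent) comes from filtering and unwrapping. Inverting the
*continuum* plane wave instead exposes the stencil bias
`(kh/2)^2 / sin^2(kh/2)` (about +2.3% at 12 px/wavelength, +0.6% at 24),
which is why the closed-form inversion test samples at 24 px/wavelength —
and why the convergence test can verify the expected second-order decay.

## ROI summaries and the averaging-order choice

`roi_average()` averages each derived map (`G'`, `G''`, `|G*|`,
`phi = atan(G''/G')`) independently over the valid ROI pixels. The
alternative — averaging complex `G*` first and deriving afterwards — is
exposed as `avg_order = "complex_first"`. The per-map default was chosen
because a tabulated loss tangent of ~0.55 alongside mean moduli of 4.6 and
1.4 kPa is only consistent with averaging per-pixel `phi` values (the
arctangent of the mean ratio would be ~0.29): in heterogeneous, noisy maps
the two orders genuinely differ, and the per-map order reproduces the
tabulated kind of summary.

## The longitudinal study generator

`simulate_longitudinal_study()` draws a balanced table: 2 treatment groups
(CTR, MPTP) × 5 animals × 6 time points (baseline, 3, 6, 10, 14, 18 days
post injection) × 2 ROIs × 4 parameters. The generative model per
(animal, parameter) is a shared random intercept (between-animal sd) plus an
independent residual per record (within-animal sd); MPTP cell means are the
control means times configurable multipliers. `|G*|` and `phi` are derived
per record from the sampled `G'`, `G''`. Defaults encode the stated world:

* control hippocampal means `G' = 4608` Pa, `G'' = 1388` Pa (whole brain
  5234 / 1447 Pa);
* the transient 6-dpi effect, multipliers 1.51 on `G'` and 1.27 on `G''`
  (equivalently +51% / +27%; `|G*|` then lands at ~+49%);
* between-animal sds equal to the tabulated SEMs times `sqrt(5)`
  (1.61 kPa for `G'`, 0.28 kPa for `G''`), and within-animal (scan–rescan)
  sds of 20% of that — repeat scans of the same animal are far more
  consistent than animals are with each other, and the split leaves the
  group SEM at its tabulated value.

What a green test on this generator establishes is calibration and
arithmetic, not biology: the generator has no spatial structure, no
inversion artifacts, and its variance components are homoscedastic and
Gaussian, which real ROI averages are not guaranteed to be.

## Statistics

`rm_two_way_anova()` fits the mixed design (Treatment between subjects,
Time and Treatment×Time within, no sphericity correction) with dfs
(1, 8), (5, 40), (5, 40) for the 2×5×6 design; `two_way_anova()` handles the
fully between-subjects histology design, dfs (1, 48) and (5, 48) at n = 5.
Both are checked against a direct-summation oracle to 1e-10 relative, and
the null-world Treatment rejection rate is verified to sit at the nominal
0.05 over 500 simulated studies.

`bonferroni_pairwise()` enumerates an explicit family — CTR vs MPTP at each
time point (m = 6), or all time-point pairs within each group (m = 15) —
and reports `p_adj = min(1, m * p)`. Error terms: the residual mean square
for the between design; for the mixed design, group contrasts at a single
time use the Satterthwaite-pooled combination
`(MS_subjects + (t-1) * MS_within) / t` of the two error strata, and time
contrasts within a group use the within stratum. Which error term the
original SPSS analysis used is not recoverable; this choice is documented
rather than asserted.

**A known limitation, kept deliberately.** With truly independent groups of
5 animals and a between-animal sd of `SEM*sqrt(5)`, the 51% 6-dpi effect has
a noncentrality of ~2.3 against a Bonferroni-corrected alpha of 0.0083 —
theoretical power ~0.17, and the package's own 200-seed experiment detects
the effect in ~19% of runs. A majority detection rate is unreachable in
that world; the acceptance suite states the expectation and fails it
openly. (A paired design — the same animals scanned under both treatments,
as in the actual experiment this emulates, where the saline course precedes
the toxin course in one cohort — removes the between-animal variance and
easily reaches significance; the generator keeps the independent-groups
reading of the design because the table schema and the between-subjects
ANOVA require it.)

## Stereology

Three estimators cover the cell-quantification arithmetic:

* `series_total(n, k)` — counts from a 1-in-k section series (default 12,
  sections 480 µm apart) scale by k;
* `double_label_absolute(d, n, N)` — a double-label proportion scored on a
  sample (50 BrdU+ cells) scales the total-marker estimate;
* `fractionator_estimate(sum_Q, spec)` — optical fractionator
  `N = sum_Q * ssf^-1 * asf^-1 * hsf^-1` with the default geometry 30×30 µm
  frames in a 120×100 µm grid, a 20 µm disector in 40 µm sections and a
  1-in-12 series: combined factor 320. The 5 µm guard zone positions the
  disector inside the section; it does not enter the height fraction
  (20/40 = 1/2), which the spec of the geometry only implies.

`simulate_counts()` draws integer counts around specified cell means:
rounded means at sd 0, Poisson when `sd^2 <= mean`, negative binomial
(`size = mean^2/(sd^2 - mean)`) otherwise — cell counts are overdispersed
in practice, and the dispersion is configurable per marker.

## Numerical choices, in one place

* Density is never tabulated for brain tissue here; 1000 kg/m^3 (soft
  tissue) is the default everywhere, configurable.
* Grid = acquisition matrix (128 px); at 4.6 kPa / 900 Hz the wavelength is
  ~2.4 mm = 12 px, satisfying the >= 6 px/wavelength precondition.
* Demo simulations propagate over 12.5 mm (the brain's own scale): over a
  25 mm one-sided path, lossy tissue attenuates the wave ~40 dB, leaving
  sub-noise signal that no processing recovers; in vivo the skull excites
  the boundary from all sides instead.
* Laplacian floor 0.05 × median; masked pixels are excluded from every
  downstream average.
* Negative recovered moduli are invalidated, never clamped; their fraction
  is attached to the elastogram.
* Internal unit is Pa throughout; kPa appears only at the report layer.
  (The tabulated 6-dpi values "6971 (1019) kPa" are treated as a Pa
  misprint; the ratio to the 4.608 kPa baseline fixes the scale.)
* All stochastic signatures take a seed; `noise_sd = 0` paths are bit-wise
  deterministic.

## Reproducing the headline numbers

`scripts/acceptance.R` re-runs the deterministic end-to-end recovery
(homogeneous phantom at the control hippocampal modulus, 128×128, 25 mm
FoV, zero noise) and writes the ROI-averaged `G'` and `G''` in kPa; the
analysis scripts under `analysis/` run the same chain as a narrative
workflow, including the noisy two-region demo, the longitudinal ANOVA and
the stereology tables, writing their outputs under `results/`.
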