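---
title: "Quantitative multi-parameter mapping with mrfmap: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative multi-parameter mapping with mrfmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mrfmap` simulates and analyzes a 3D magnetic resonance fingerprinting
(MRF) acquisition that quantifies proton density (PD), T1, T2, the
rotating-frame relaxation time T1rho, and the transmit-field scale B1+
in a single pulse train. This vignette is the package's account of the
underlying physics, the numerical choices, and what the synthetic
experiments do and do not establish.

## The signal model

Magnetization is propagated with the extended phase graph (EPG)
formalism: the state is a ladder of configuration states
$(\tilde F_k^+, \tilde F_k^-, \tilde Z_k)$ over integer dephasing orders
$k$, where $\tilde F^+_k$ and $\tilde F^-_k$ hold transverse
magnetization dephased by $+k$ and $-k$ gradient cycles and
$\tilde Z_k$ the longitudinal components. Four operators generate every
sequence:

* **RF rotation** `epg_rf(state, flip, phase)` — the standard $3\times3$
  complex rotation acting on each order. Convention (used everywhere,
  including the test oracle): $F \equiv M_x + i M_y$ and an RF pulse of
  phase $0$ rotates about $+x$, right-handed, so a $90^\circ$ pulse on
  equilibrium produces $F_0^+ = -i$. RF rotations conserve
  $\sum_k |F^+_k|^2 + |F^-_k|^2 + 2|Z_k|^2$, which the tests check on
  random states.
* **Gradient shift** `epg_grad_shift(state)` — the unbalanced gradient
  moment of one FISP repetition moves $F^+$ up and $F^-$ down one order
  with the $k = 0$ crossover conjugation; orders above `max_order` are
  truncated.
* **Relaxation** `epg_relax(state, dt, params)` — transverse orders decay
  with $e^{-dt/T_2}$, longitudinal with $e^{-dt/T_1}$, and $Z_0$ recovers
  as $Z_0 \leftarrow Z_0 E_1 + (1 - E_1)$.
* **Preparations** — adiabatic inversion (instantaneous, efficiency
  parameter, default 1.0, B1-insensitive) and the spin-lock module
  below.

### The spin-lock (T1rho) preparation

The physical preparation is a composite cluster: a hard $90_y$ tip-down,
four balanced alternating-phase spin-lock pulses at 500 Hz with paired
$180_{\pm x}$ refocusing, tip-up and crusher. Its balanced design exists
precisely to cancel B0 and B1 errors inside the preparation, so the
dictionary model treats it as ideal: every longitudinal order is scaled
by $e^{-\mathrm{TSL}/T_{1\rho}}$ and all transverse magnetization is
crushed. This mono-exponential model is also the only one a dictionary
with a single T1rho axis can express. The spin-lock amplitude (500 Hz)
is carried as metadata for provenance; it does not enter the decay. The
pulse-by-pulse internals of the cluster are deliberately out of scope.

## The acquisition schedule

`build_schedule(sequence_config())` produces the full train: a 10 ms
adiabatic inversion; two FISP segments of 250 excitations each (flip
ramps peaking at 20 deg and 60 deg) separated by a 50 ms recovery
delay; two ideally spoiled FLASH segments with the same flip patterns
(these disentangle B1+ from T1, since the spoiled signal depends on
$\sin(B_1\alpha)$ without the T2-weighted echo pathways); and a
T1rho module of six spin-lock preparations with durations log-spaced
over 2 to 45 ms, each followed by 125 excitations (ramp to 20 deg) and a
500 ms recovery. TR is 7.5 ms with the echo sampled at TE = 3.5 ms, so
relaxation splits each TR into 3.5 ms before and 4 ms after the readout.
Every excitation yields one readout: $4\times250 + 6\times125 = 1750$
samples per fingerprint.

Choices the sequence description leaves open, fixed here as package
defaults:

* **Flip-angle ramp shape.** Only the 0-to-peak range is stated. The
  default is the half-sine lobe $\alpha_i = \alpha_{\max}
  \sin(\pi i/(n-1))$, the common choice for FISP-MRF trains because it
  starts and ends near zero (smooth transient response); a linear ramp
  is available via `ramp_shape = "linear"`. The ramp shape enters the
  schedule hash, so dictionaries built under different shapes cannot be
  mixed silently.
* **The six TSL values** between 2 and 45 ms are not printed; the
  default is log-spacing, which samples the short-TSL region where the
  typical tissue T1rho (60-120 ms) changes fastest per millisecond.
* **Inter-segment delays.** The 50 ms FISP delay is stated; the same
  delay is used between the FLASH segments and before the T1rho module.
* **Inversion efficiency** defaults to 1.0 and is configurable.
* **One fingerprint models one excitation train** (one kz partition)
  starting from equilibrium; inter-partition steady-state carryover is
  not modeled.

FLASH spoiling is modeled as ideal (transverse zeroed each TR) rather
than RF-phase-cycled EPG. At the dictionary level the two agree, and the
ideal model is several times faster.

## Dictionary, truncation and SVD compression

The dictionary grid uses geometric (6% step) axes — T1 from 50 to
3000 ms (71 values), T2 and T1rho from 2 to 200 ms (80 values each) —
with unphysical atoms ($T_2 > T_1$, and by default $T_{1\rho} > T_1$)
filtered out. The B1+ axis is configurable and defaults to the single
value 1 at desk scale. Each atom's 1750-point complex fingerprint is
simulated in chunks and stored with unit L2 norm plus its original norm,
so matching amplitudes convert back to PD.

**EPG order truncation.** The ladder is truncated at `max_order` 250 by
default (the longest segment's excitation count). An order-$k$ pathway
must survive at least $2k$ repetition times of T2 decay before it can
refocus into the echo, so with TR = 7.5 ms and T2 at most 200 ms the
contribution of orders above $\sim$100 is below $10^{-4}$ of the peak
signal; the dictionary-scale computations in the tests and the
acceptance script therefore run at `max_order = 64`, which we measured
to differ from order 250 by less than $10^{-4}$ relative even at
T2 = 200 ms. The truncation order participates in the schedule hash.

**Compression.** The dictionary is compressed by projecting onto the top
right singular vectors of the fingerprint matrix; for tall dictionaries
the singular vectors are computed from the timepoints-by-timepoints Gram
matrix accumulated in chunks (mathematically identical to the direct
SVD, and verified against it in the tests). One empirical property of
this sequence deserves emphasis: the fingerprints are so strongly
correlated that *99.9% of the total energy lies in a rank-3 subspace*,
in which atoms are not distinguishable (matching agreement collapses to
a few percent). Energy captured is therefore a poor criterion for
choosing the matching rank. The package default is a strict target
(energy $1 - 10^{-6}$, about rank 10 for mid-range dictionaries), at
which compressed matching reproduced uncompressed matching on 100% of
500 noisy test fingerprints.

## Matching

`match_voxel`/`match_volume` maximize the modulus of the complex inner
product between the unit-norm dictionary rows and the signal, which
makes matching invariant to the global complex scale (PD and receive
phase). Ties break to the lowest atom index so that ports agree
bit-for-bit on noiseless input. Background voxels whose signal norm
falls below a configurable fraction (default 1%) of the volume's 99th
percentile norm are masked. The word "iterative" in dictionary pattern
matching is realized as a coarse argmax plus an optional second pass
(`refine = TRUE`) that fits a parabola through the match scores of the
$\pm1$-step neighbors along each relaxation axis in log-parameter space
and moves the estimate to the vertex, clamped to one grid step. The
default is off; all acceptance checks run on the pure argmax.

## Digital phantoms and simulated acquisitions

`make_nist_like_phantom()` arranges 14 disjoint spheres on a ring,
with T1 geometrically spaced over 200-2500 ms, T2 over 5-600 ms and
T1rho over 5-450 ms (range ends of 0 are clamped to 5 ms, the smallest
value the relaxation model can represent meaningfully). The digital
sphere values emulate the published *ranges*; they are not claimed to
equal any physical phantom's per-sphere values.
`make_brain_like_phantom()` builds elliptical CSF/GM/WM compartments
(WM: T1 850 / T2 70 / T1rho 80 ms; GM: 1400/95/100; CSF: 4000/1800/1500,
literature-plausible round numbers) with optional focal lesions inside
WM whose T1, T2 and T1rho are elevated by a configurable fraction
(default +30%) over WM, emulating the elevated relaxation times of
demyelinating lesions.

Direct-mode acquisition simulates one fingerprint per labeled region
(voxels sharing a label share the EPG simulation — this cache is what
makes end-to-end runs take seconds), broadcasts it scaled by PD, and
adds i.i.d. complex Gaussian noise per shot before complex-averaging
the shots; the averaged noise SD falls as $1/\sqrt{n}$, standing in for
the k-space coverage benefit that the k-space mode models. Shots are
drawn sequentially from one seeded stream, so shot $s$ is the same
realization whatever the total shot count — comparisons across shot
counts use common random numbers. All randomness flows from the single
seed in `acquisition_config()`.

K-space mode samples each readout frame along golden-angle radial
spokes (increment $180(\sqrt5-1)/2 \approx 111.246^\circ$; shot $s$ of
$n$ adds the offset $180 s/n$ degrees) with Cartesian encoding along kz
in center-out partition order. The transform is an explicit non-uniform
DFT — exact, linear, and exactly adjoint, which is the right tool at
the 16-32 pixel grids used here; no gridding approximation is involved.
Reconstruction is the density-compensated adjoint with ramp weights and
2x radial readout oversampling ($\Delta k = 1/2$), the standard radial
practice; without oversampling the ring discretization of the ramp
leaves ~10% error on a 32-pixel disk, with it the reconstruction is
within 4% of the dense-DFT band-limited truth. Note that *any*
disc-band-limited reconstruction differs from a sharp-edged object by
~9.5% (Gibbs), so reconstruction accuracy must be judged against the
band-limited reference, not the raw object. Coil sensitivities, B0
blurring and motion are not modeled.

## Statistics

The evaluation statistics mirror common repeatability practice:

* `roi_stats` — mean and *population* SD over a region.
* `icc` — intraclass correlation
  $\sigma_b^2 / (\sigma_b^2 + \sigma_w^2)$ from a one-way decomposition:
  $\sigma_w^2 = \overline{d^2}/2$ from paired scan differences, and
  $\sigma_b^2 = \mathrm{var}(\text{subject means}) - \sigma_w^2/2$
  floored at zero. Only the ratio formula is prescribed; this
  decomposition is the standard one-way reading and is invariant to
  shifting or positively rescaling all measurements.
* `bland_altman` — bias and limits of agreement $\pm1.96$ sample SD.
* `paired_ttest` — the paired t statistic with a two-tailed p-value from
  the t-distribution survival function; zero-variance differences are a
  defined error rather than $p = 0$.
* `snr_estimate` — mean(signal ROI)/SD(noise ROI) on magnitude images.
  This ignores the Rician bias of background magnitude noise, matching
  common practice; a Rayleigh-corrected variant is selectable. In-vivo
  SNR values from scanner data are not reproducible from simulation,
  so only the $\sqrt{n}$-shots trend is checked.

## Problem sizes, noise levels and what the tests show

The test and acceptance experiments run at desk scale, chosen once as
realistic for the properties they probe:

* Physics equivalence: 20 random tissues, full 1750-point fingerprints,
  EPG vs an independent 2000-isochromat Bloch simulation (agreement is
  at machine precision, far below the $10^{-3}$ bound checked).
* Matching experiments: a 4913-atom, 6%-step dictionary over
  T1 500-1280 / T2 40-102 / T1rho 40-102 ms — wide enough to contain
  500 random draws with full $\pm3$-step neighborhoods, small enough to
  build in under two minutes. Noise robustness uses per-sample SNR 30
  (noise SD = RMS signal magnitude / 30 per complex sample).
* The multi-shot sphere experiment uses per-sample SNR 5 and a
  dictionary of $\pm3$-step 6% neighborhoods around each sphere's truth
  (the full published grid would be ~450k atoms and adds nothing to the
  trend being tested). Per-sphere SDs are estimated from voxel
  deviations pooled over six replicate seeded acquisitions: a single
  49-voxel ROI estimates an SD with only ~10% precision, too coarse to
  resolve the 2-to-4-shot step reliably.
* The brain-lesion experiment also runs at per-sample SNR 5 —
  deliberately strong noise, because a paired test across an ROI needs
  within-ROI variance: at high SNR every voxel of a homogeneous region
  quantizes to the same dictionary atom and the paired t statistic is
  undefined. At SNR 5 the +30% lesions are still recovered within one
  6% grid step.

Passing these tests shows that the simulation, dictionary, matcher and
statistics are internally consistent and reproduce the qualitative
behaviors expected of the acquisition (multi-shot noise averaging,
lesion contrast, compression fidelity). It does not validate the model
against scanner data: slab excitation profiles, magnetization transfer,
B0/B1 imperfections inside the preparations, coil arrays and
reconstruction artifacts are all outside the model, and real phantom or
in-vivo values cannot be reproduced here.

## Known limitations

* The T1rho preparation is mono-exponential by construction; dispersion
  effects (T1rho dependence on spin-lock amplitude) are not modeled,
  and the 500 Hz amplitude is provenance metadata only.
* The k-space pipeline is exact but $O(\text{samples}\times\text{pixels})$
  per frame, intended for small digital phantoms, not production
  reconstruction.
* The dictionary archive is an RDS container with the hierarchical
  layout (fingerprints, grid axes, SVD blocks, schedule hash and
  version attributes) rather than HDF5; the schedule-hash guard against
  mixing dictionaries across schedules is enforced on load and match.
* CSF-like tissues fall outside the published dictionary ranges
  (T1 up to 3000 ms, T2/T1rho up to 200 ms) and clip to the grid
  boundary; ROI analyses here exclude CSF.
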