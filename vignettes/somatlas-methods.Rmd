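---
title: "Travelling-wave digit mapping and probabilistic atlases: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Travelling-wave digit mapping and probabilistic atlases: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somatlas)
```

## The model

Phase-encoded ("travelling-wave") somatotopic mapping stimulates the five
digits of one hand in a fixed cyclic order -- 4 s of vibrotactile
stimulation per digit, a 20 s cycle, repeated 8--12 times -- while sampling
BOLD volumes every `TR = 2` s. A cortical location driven preferentially by
digit $d$ responds periodically at the cycle frequency $f_0 = 1/20$ Hz, and
the *phase* of that response encodes which digit dominates it: with the
digit-$d$ stimulation window centred at $t_d = (d - \tfrac12)\cdot 4$ s, the
fundamental of the response is $\cos(2\pi f_0 t - \varphi_d)$ with
$\varphi_d = 2\pi f_0 (t_d + \delta)$, where $\delta$ is the haemodynamic
delay. Runs are acquired in both forward (digit 1 to 5) and backward
orderings; because the delay enters the two orderings with opposite sign
relative to the stimulus phase, combining them cancels $\delta$.

Per location the package computes, from the discrete Fourier transform of
the preprocessed series:

* **amplitude** and **phase** of the component at $f_0$ (phase is the lag of
  the best-fitting cosine, wrapped to $[0, 2\pi)$);
* **coherence** $C$: the magnitude at $f_0$ divided by the root sum of
  squares of all non-DC magnitudes up to Nyquist, harmonics included. This
  denominator convention is configurable in principle but is the one used
  throughout; bins removed by the high-pass filter are excluded, and the
  degrees of freedom lost that way are tracked.

Single-subject digit maps are produced by masking the combined phase map
(statistical mask intersected with an anatomical mask) and binning the
surviving phases into five equal half-open bins of width $2\pi/5$. Group
atlases follow: the **full probability map** (FPM) of digit $d$ is the
fraction of subjects assigning $d$ to each location; the **digit hand ROI**
is where the summed FPM probability exceeds 0.5 (strictly); the **maximal
probability map** (MPM) assigns each hand-ROI location to the digit of
highest probability, winner-takes-all.

Validation uses the blurring metric
$B = 100\,(|\bigcup_k S_k| - \overline{|S_k|})/\overline{|S_k|}$ for the
cohort's per-digit ROIs $S_k$, and the central tendency
$P_{ij} = F\langle f_i \circ d_j\rangle / F\langle f_i\rangle$ between atlas
map $f_i$ and a held-out subject's digit ROI $d_j$, with
$F\langle\cdot\rangle$ the mean of absolute non-zero values, evaluated with
leave-one-out cross-validation. Reproducibility across sessions is tested
with the Rayleigh V-test on wrapped inter-session phase differences against
a hypothesised mean direction of 0.

## Tunable parameters

| parameter | units | default | why |
|---|---|---|---|
| `TR` | s | 2 | standard travelling-wave protocol sampling |
| `cycle_s` | s | 20 | five digits at 4 s dwell per cycle |
| `n_cycles` | -- | 10 | mid-range of the 8--12 cycles used in practice |
| `cutoff_hz` | Hz | 0.01 | removes scanner drift, well below $f_0 = 0.05$ Hz |
| `alpha` | -- | 0.05 | uncorrected one-sided mask level |
| `hand_threshold` | probability | 0.5 | "any digit" probability above one half |
| `phase_offset` | rad | 0 | generator phases sit mid-bin at offset 0; real data may need a delay-dependent origin |
| `haemo_delay_s` | s | 4 | typical BOLD lag; not fixed by the protocol, so exposed |
| `response_amplitude` | % signal | 2 | typical 7 T fingertip response |
| `noise_sd` | signal units | 1 | tSNR of about 100 on a baseline of 100 |
| `jitter_sd` | mm | 2 | moderate inter-subject misalignment after normalisation |
| `digit_size_cv` | -- | 0.1 | per-digit band-width variability across subjects |

## What the synthetic generator emulates -- and what it does not

`make_cohort()` draws each subject's ground-truth digit map from a shared
template strip (40 x 10 mm on a 64 x 40 x 1 voxel, 1 mm slab) by a random
rigid translation plus isotropic scaling, with per-digit band widths
perturbed multiplicatively. The relative template widths
(1.15, 1.10, 0.95, 1.15, 0.50) encode the reported size ordering of real
digit ROIs: digit 5 much the smallest, digit 3 slightly smaller than its
neighbours. The scale-jitter SD is tied to the translation jitter
(`0.025 * jitter_sd`) so that `jitter_sd = 0` reproduces the template
bit-exactly. `make_runs()` synthesises the response as a *band-limited*
boxcar: each digit's 4 s window expanded in Fourier series and truncated
below the sampling Nyquist, so the fundamental's phase and amplitude survive
TR sampling exactly, with the haemodynamic delay applied as a circular time
shift. Drift is a sum of cosines at the run's discrete frequencies below
0.01 Hz; noise is white Gaussian. Two anatomical masks are emitted: a tight
"manual" analogue (strip dilated by one voxel) and a loose "automatic"
analogue (bounding box plus margin).

The generator deliberately does **not** model cortical geometry, folding,
surface meshes, physiological noise, motion, distortion, or registration
error; jitter is rigid-plus-scale only, with rotation fixed at 0. A green
end-to-end test therefore establishes that the analysis chain is correct and
self-consistent on data with the assumed statistical structure -- it says
nothing about registration quality, HRF misspecification, or non-white
noise in real acquisitions.

## Numerical choices

* **Bin edges** are half-open, lower edge inclusive:
  phase 0 is digit 1, $2\pi - \epsilon$ is digit 5. The generator places
  each digit mid-bin, so noiseless recovery is exact and never sits on an
  edge.
* **Forward/backward combination.** Aligning the backward map is pure phase
  negation here: the stimulus ordering is reversed about the cycle
  boundary, for which the reversal offset is zero (an offset of
  $2\pi f_0 \mathrm{TR}(n-1)$ would be correct for sample-wise reversal,
  and `combine_runs()` exposes it as an argument). A plain circular mean of
  the aligned phases would be degenerate at a quarter-cycle delay (the two
  phases become antipodal) and wrong by $\pi$ beyond it, so the combiner
  first estimates one global lag from the amplitude-weighted circular mean
  of the per-location phase differences, resolves it to a delay in
  $[0, \mathrm{cycle}/2)$, removes it from both maps, and then averages.
  Delays of at least half a cycle are inherently ambiguous from phases
  alone.
* **Coherence-to-t and p-values.** The t statistic is the correlation-style
  transform $t = C\sqrt{\nu/(1-C^2)}$ with $\nu = n_{\mathrm{vol}} - 3$ for
  an unfiltered run, reduced by two per filtered-out frequency bin. The
  mask's p-value is *not* taken from the t distribution (which would be
  badly anti-conservative here) but from the exact null of coherence under
  Gaussian noise, $p = (1 - C^2)^{\nu/2}$; the type-I error of the mask is
  then nominal by construction and is verified by simulation in the test
  suite. When the mask is applied to a *combined* (two-run averaged)
  coherence map, as the full pipeline does, the threshold is conservative.
* **Hand-ROI threshold** is strict (`> 0.5`), following the "higher than
  one half" reading; `rebinarise()` uses an inclusive `>= 0.5` edge so that
  exactly-half projections survive.
* **MPM ties** go to the lowest digit index -- deterministic and
  independent of subject order -- and tied locations are flagged.
* **Zero circular resultant** (antipodal phases) yields an infinite
  circular-SD sentinel; resultants below 1e-12 are treated as zero.
* **Degenerate central tendency** (no overlap, a 0/0 case) is defined as
  $P = 0$ and flagged when it arises from an empty atlas digit in a
  leave-one-out fold.

## Design choices where the design was open

* **Two central-tendency variants.** The literal non-zero-mean definition
  degenerates to values in $\{0\} \cup [1, \infty)$ on binary atlas maps,
  so MPM-mode validation defaults to the overlap-fraction reading
  $\sum f \circ d / \sum f$ (never above 1), while FPM mode uses the
  literal definition. The two are not comparable with each other.
* **Bonferroni correction** multiplies by the 10 digit pairs, capped at 1;
  tests are two-sample with pooled variance across hands (Welch optional).
* **Curvature variability** uses the sample ($n-1$) standard deviation and
  summarises each ROI by the median of the SD map.
* **Handedness** is the signed ratio $H = (R - L)/(R + L)$ of
  right/left-handed activity counts.
* The haemodynamic delay magnitude is a free parameter of the generator
  (default 4 s) rather than a fixed constant, since the protocol does not
  determine it.
* Spatial normalisation is represented only as an externally supplied
  coordinate transform plus nearest-neighbour resampling
  (`resample_nearest()`); registration itself is out of scope, and
  synthetic cohorts are generated directly in the common domain.

## Known limitations

* The analysis maps digit *dominance*: a location responding to several
  digits is assigned only to the phase-dominant one, and overlap structure
  is not recoverable from a single Fourier phase.
* The statistical mask's exact calibration assumes white Gaussian noise;
  coloured physiological noise would make it only approximate.
* Delays of half a cycle or more cannot be distinguished from a
  $\pi$-shifted map with a complementary delay.
* Surface-domain support is limited to per-vertex area weighting; no mesh
  topology is represented, so no geodesic operations are available.
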