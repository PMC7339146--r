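# somatlas

Travelling-wave digit mapping and probabilistic somatotopic atlases in R.

## The problem

High-field fMRI can resolve the cortical representation of individual hand
digits in primary somatosensory cortex (S1), but only subject by subject:
phase-encoded ("travelling-wave") stimulation sweeps the five fingertips
cyclically (4 s per digit, 20 s per cycle), and the Fourier phase of each
voxel's response at the cycle frequency f₀ = 1/20 Hz encodes which digit
dominates it. Building a *group* atlas from such maps requires a chain of
well-defined steps — per-run sinusoid fitting, forward/backward combination
to cancel the haemodynamic delay, coherence-based statistical masking,
phase binning into mutually exclusive digit ROIs, probabilistic aggregation
across subjects, and validation metrics — each easy to get subtly wrong.

`somatlas` implements that chain as a tested, reusable pipeline for
researchers who want to build or evaluate digit-dominance atlases, together
with a synthetic-cohort generator with known ground truth so every stage is
testable without any imaging data.

## The method in brief

Per location the package computes the amplitude/phase of the discrete
Fourier component at f₀ and the coherence C (magnitude at f₀ over the root
sum of squares of all non-DC magnitudes up to Nyquist). Forward and
backward runs are combined to cancel the haemodynamic delay δ, which enters
the two orderings with opposite sign. Masked phases are binned into five
half-open bins of width 2π/5 to give each subject's digit map. Across a
cohort of n subjects:

- **FPM** (full probability map), per digit d: fraction of subjects
  assigning d to each location (multiples of 1/n);
- **digit hand ROI**: locations where the summed FPM probability exceeds
  0.5 (strictly);
- **MPM** (maximal probability map): winner-takes-all digit inside the hand
  ROI.

Validation: the blurring metric
B = 100·(|∪ₖSₖ| − mean|Sₖ|)/mean|Sₖ| (0 for perfect overlap), the central
tendency P = F⟨f∘d⟩/F⟨f⟩ (F⟨·⟩ = mean of absolute non-zero values; P = 1
when the ROI covers the map's support, >1 when it sits on the peak) with
leave-one-out cross-validation, ROI-size comparisons with log₁₀
Bonferroni-corrected pairwise p-values (−1.3 marks p = 0.05), circular
statistics (Rayleigh V-test, circular mean/SD) for inter-session
reproducibility, and cross-subject curvature variability.

See `vignettes/somatlas-methods.Rmd` for the model, parameter table,
numerical conventions and limitations.

## Worked example

An end-to-end synthetic cohort: 8 subjects, 2 mm spatial jitter, noise at
1% of baseline (tSNR ≈ 100).

```r
library(somatlas)
cfg <- pipeline_config(n_subjects = 8, seed = 42, noise_sd = 1, jitter_sd = 2)
res <- run_pipeline(cfg)   # pass out_dir = "..." to also write NIfTI/CSV
res$metrics$blurring
#>   digit        B
#> 1     1 154.1844
#> 2     2 143.7768
#> 3     3 150.1767
#> 4     4 133.1492
#> 5     5 258.5366
```

Digit 5 — generated much the smallest, as in real cohorts — overlaps worst
across subjects (highest B). The leave-one-out central-tendency matrix
(rows = atlas FPM, columns = held-out subject digit):

```r
round(res$metrics$loo[, ], 2)
#>      subject
#> atlas   D1   D2   D3   D4   D5
#>    D1 1.61 0.52 0.00 0.04 0.09
#>    D2 0.49 1.57 0.75 0.04 0.00
#>    D3 0.00 0.67 1.48 0.65 0.04
#>    D4 0.04 0.04 0.65 1.41 0.74
#>    D5 0.13 0.00 0.06 0.88 1.13
```

Diagonal values above 1 mean a held-out subject's digit ROI lands on the
high-probability core of the matching atlas map. The diagonal dominates
every row, weakest for D5, whose largest confusion is with the neighbouring
D4 (0.88) — the same degradation pattern reported for real digit atlases.
Inter-session reproducibility on one subject pair of phase maps:

```r
vtest(phase_difference(res$phase_maps[[1]], res$phase_maps[[2]],
                       res$hand_roi$mask), mu0 = 0)
#> V-test: n = 362, rbar = 0.754, V = 266.47, u = 19.81, p = 1.31e-87
```

(phase differences concentrated at 0 ⇒ the uniform null is firmly
rejected).

There is also a command-line interface with the subcommands `simulate`,
`phasemap`, `bin`, `atlas`, `validate` and `reproducibility`
(`inst/cli/somatlas`, or `somatlas_cli()` from R).

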