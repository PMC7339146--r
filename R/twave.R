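#' Preprocess a run: percent-signal change and high-pass filtering
#'
#' Each location's series is converted to percent signal change,
#' `100 * (x - mean) / mean`, and slow confounds are removed by zeroing the
#' discrete Fourier components at frequencies strictly below `cutoff_hz`
#' (the mean is removed by the percent-signal-change step). Because the
#' design is periodic and the run holds whole cycles, this spectral high-pass
#' is exact and leaves the stimulation frequency untouched.
#'
#' @param run A `tw_run` (see [make_runs()]) or any object with fields
#'   `data` (locations x time), `acq` and `domain`.
#' @param cutoff_hz High-pass cut-off in Hz; must be below the stimulation
#'   frequency.
#' @return The run with filtered `data`, and `hp_cutoff` recording the
#'   cut-off (used downstream to account for the removed degrees of freedom).
#' @export
preprocess_run <- function(run, cutoff_hz = 0.01) {
  stopifnot(!is.null(run$data), inherits(run$acq, "acq_params"))
  if (cutoff_hz >= run$acq$stim_freq)
    stop("cutoff_hz must be below the stimulation frequency (it would delete the signal of interest)")
  m <- rowMeans(run$data)
  if (any(m <= 0))
    stop("preprocess_run() needs strictly positive mean signal at every location")
  x <- 100 * (run$data - m) / m
  n <- ncol(x)
  if (cutoff_hz > 0) {
    freqs <- (seq_len(n) - 1) / (n * run$acq$TR)
    # bins strictly below the cutoff (and their conjugate mirrors), DC excluded
    lo <- which(freqs > 0 & freqs < cutoff_hz & seq_len(n) - 1 <= n / 2)
    if (length(lo) > 0) {
      X <- t(stats::mvfft(t(x)))
      kill <- unique(c(lo, n + 2 - lo))
      kill <- kill[kill >= 2 & kill <= n]
      X[, kill] <- 0
      x <- Re(t(stats::mvfft(t(X), inverse = TRUE))) / n
    }
  }
  run$data <- x
  run$hp_cutoff <- cutoff_hz
  run$preprocessed <- TRUE
  run
}

#' Fourier analysis of a travelling-wave run
#'
#' Per location, the discrete Fourier component at the stimulation frequency
#' gives the amplitude and phase of the best-fitting sinusoid; phase is the
#' lag of the best-fitting cosine, wrapped to `[0, 2*pi)`. Coherence is the
#' component's magnitude divided by the root sum of squares of all non-DC
#' component magnitudes up to the Nyquist frequency (harmonics included),
#' omitting any bins removed by the high-pass filter. The number of
#' real degrees of freedom remaining in that denominator is recorded so that
#' the coherence-to-t conversion stays calibrated after filtering.
#'
#' @param run A (preferably preprocessed) run.
#' @return A `phase_map` with fields `phase`, `coherence`, `amplitude`
#'   (percent signal), `n_volumes`, `dof` (denominator dof minus the two
#'   consumed by the signal bin), `acq` and `domain`.
#' @export
fourier_analyze <- function(run) {
  stopifnot(!is.null(run$data), inherits(run$acq, "acq_params"))
  n <- ncol(run$data)
  k <- run$acq$stim_freq * n * run$acq$TR
  if (abs(k - round(k)) > 1e-8)
    stop("the stimulation frequency is not an exact frequency bin: the run must hold whole cycles")
  k <- as.integer(round(k))
  if (k < 1 || k > floor(n / 2))
    stop("stimulation frequency out of the resolvable range")
  X <- t(stats::mvfft(t(run$data)))     # locations x frequency bins
  denom_bins <- seq_len(floor(n / 2))
  if (!is.null(run$hp_cutoff) && run$hp_cutoff > 0) {
    f <- denom_bins / (n * run$acq$TR)
    denom_bins <- denom_bins[f >= run$hp_cutoff]
  }
  if (!k %in% denom_bins)
    stop("the stimulation bin was removed by filtering")
  mags <- Mod(X[, denom_bins + 1L, drop = FALSE])
  denom <- sqrt(rowSums(mags^2))
  sig <- X[, k + 1L]
  coherence <- ifelse(denom > 0, Mod(sig) / denom, 0)
  # real dof in the denominator: 2 per complex bin, 1 for a Nyquist bin
  dof_denom <- 2L * length(denom_bins) -
    as.integer(n %% 2 == 0 && (n / 2) %in% denom_bins)
  structure(
    list(phase = wrap_to_2pi(-Arg(sig)),
         coherence = pmin(coherence, 1),
         amplitude = 2 * Mod(sig) / n,
         n_volumes = n,
         dof = dof_denom - 2L,
         acq = run$acq, domain = run$domain,
         direction = run$direction, subject = run$subject),
    class = "phase_map"
  )
}

#' Combine forward and backward runs, cancelling the haemodynamic delay
#'
#' Backward-run phases are negated (and optionally shifted by
#' `reversal_offset`) so both runs share the stimulus phase convention; the
#' residual haemodynamic lag then enters the two aligned maps with opposite
#' signs. A single global lag is estimated from the amplitude-weighted
#' circular mean of the per-location phase differences, resolved to a delay
#' in `[0, cycle_s/2)`; after removing it from both maps the combined phase
#' is the amplitude-weighted circular mean of the two delay-corrected
#' phases, and combined coherence and amplitude are arithmetic means.
#'
#' The global-lag step (rather than a plain circular mean of the aligned
#' phases) is what makes the cancellation exact for any delay below half a
#' cycle: a plain circular mean is degenerate at a quarter-cycle delay and
#' flips by pi beyond it.
#'
#' @param fwd,bwd `phase_map`s of the forward and backward runs (same domain
#'   and acquisition).
#' @param reversal_offset Phase offset added when negating the backward
#'   phases. The generator in this package reverses the stimulus ordering
#'   about the cycle boundary, for which the correct offset is 0 (the
#'   default); data reversed sample-wise about volume `n - 1` would need
#'   `2*pi*f0*TR*(n_volumes - 1)`.
#' @return A combined `phase_map`; the estimated haemodynamic delay in
#'   seconds is stored as `delay_est_s`.
#' @export
combine_runs <- function(fwd, bwd, reversal_offset = 0) {
  stopifnot(inherits(fwd, "phase_map"), inherits(bwd, "phase_map"))
  if (!.same_acq(fwd$acq, bwd$acq) || fwd$n_volumes != bwd$n_volumes)
    stop("forward and backward maps must share the acquisition parameters")
  if (!same_domain(fwd$domain, bwd$domain))
    stop("forward and backward maps must share the domain")
  phi_f <- fwd$phase
  phi_b <- wrap_to_2pi(-bwd$phase + reversal_offset)
  w <- fwd$amplitude * bwd$amplitude
  if (!any(w > 0)) w <- rep(1, length(w))
  z <- sum(w * exp(1i * (phi_f - phi_b)))
  two_delta <- if (Mod(z) > 0) wrap_to_2pi(Arg(z)) else 0
  delta <- two_delta / 2                       # lag angle in [0, pi)
  wf <- fwd$amplitude
  wb <- bwd$amplitude
  both0 <- wf + wb == 0
  wf[both0] <- wb[both0] <- 1
  zc <- wf * exp(1i * (phi_f - delta)) + wb * exp(1i * (phi_b + delta))
  phase <- wrap_to_2pi(Arg(zc))
  # degenerate antipodal pairs: fall back to the delay-corrected forward phase
  bad <- Mod(zc) < 1e-12
  phase[bad] <- wrap_to_2pi(phi_f[bad] - delta)
  structure(
    list(phase = phase,
         coherence = (fwd$coherence + bwd$coherence) / 2,
         amplitude = (fwd$amplitude + bwd$amplitude) / 2,
         n_volumes = fwd$n_volumes,
         dof = min(fwd$dof, bwd$dof),
         acq = fwd$acq, domain = fwd$domain,
         direction = "combined", subject = fwd$subject,
         delay_est_s = delta / (2 * pi * fwd$acq$stim_freq)),
    class = "phase_map"
  )
}

#' Convert a coherence map to t-values
#'
#' The t statistic is the correlation-style transform
#' `t = C * sqrt(dof / (1 - C^2))`, with `dof = n_volumes - 3` for an
#' unfiltered run (amplitude, phase and mean estimated) reduced by two for
#' every frequency bin removed by the high-pass filter. A coherence of
#' exactly 1 maps to `+Inf`. One-sided p-values for this statistic (coherence
#' cannot be negative) are computed by [statistical_mask()] from the exact
#' null distribution of coherence under Gaussian noise,
#' `p = (1 - C^2)^(dof/2)`, which keeps the false-positive rate of the mask
#' at its nominal level.
#'
#' @param map A `phase_map`.
#' @return A `t_map` with fields `t`, `dof` and `domain`.
#' @export
coherence_to_t <- function(map) {
  stopifnot(inherits(map, "phase_map"))
  if (map$n_volumes < 4) stop("coherence_to_t() needs at least 4 volumes")
  C <- map$coherence
  t <- ifelse(C >= 1, Inf, C * sqrt(map$dof / (1 - C^2)))
  structure(list(t = t, dof = map$dof, domain = map$domain), class = "t_map")
}

#' Wrapped inter-session phase differences
#'
#' @param a,b `phase_map`s on a shared domain.
#' @param mask Logical vector selecting the locations to compare.
#' @return Differences `a - b` wrapped to `(-pi, pi]`, one per masked
#'   location.
#' @export
phase_difference <- function(a, b, mask) {
  stopifnot(inherits(a, "phase_map"), inherits(b, "phase_map"))
  if (!same_domain(a$domain, b$domain))
    stop("phase maps must share the domain")
  mask <- as.logical(mask)
  .check_map_length(mask, a$domain, "mask")
  if (!any(mask)) stop("empty mask: no locations to compare")
  wrap_to_pi(a$phase[mask] - b$phase[mask])
}
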