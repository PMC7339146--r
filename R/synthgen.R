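#' Default common domain for synthetic cohorts
#'
#' A thin 64 x 40 x 1 voxel slab at 1 mm isotropic resolution, standing in
#' for the flattened cortical patch around the central sulcus on which all
#' subjects of a cohort are sampled after spatial normalisation.
#'
#' @return A volumetric [sample_domain()].
#' @export
strip_domain <- function() {
  sample_domain(c(64L, 40L, 1L), spacing = c(1, 1, 1))
}

# per-subject truth labels on the domain grid.
# The somatotopic template is a rectangular strip whose digit bands progress
# 1 -> 5 along x (the lateral -> medial analogue); each subject's strip is a
# translated + isotropically scaled copy with per-digit width perturbations.
.strip_labels <- function(domain, widths, height, tx, ty, scale, id) {
  cc <- voxel_centers(domain)
  ext <- domain$dim * domain$spacing
  cx <- ext[1] / 2
  cy <- ext[2] / 2
  w <- widths * scale
  L <- sum(w)
  hh <- height * scale / 2
  x0 <- cx - L / 2 + tx
  yc <- cy + ty
  if (x0 < 0 || x0 + L > ext[1] || yc - hh < 0 || yc + hh > ext[2])
    stop(sprintf(
      "subject %s: jittered digit strip leaves the domain (x [%0.1f, %0.1f], y [%0.1f, %0.1f])",
      id, x0, x0 + L, yc - hh, yc + hh))
  labels <- integer(domain$n_loc)
  in_y <- cc[, 2] >= yc - hh & cc[, 2] <= yc + hh
  relx <- cc[, 1] - x0
  in_x <- relx >= 0 & relx < L
  sel <- in_x & in_y
  labels[sel] <- findInterval(relx[sel], cumsum(c(0, w)),
                              rightmost.closed = FALSE)
  labels[labels > 5L] <- 5L
  labels
}

# one-voxel 8-neighbourhood dilation in the xy plane
.dilate_xy <- function(mask, domain) {
  d <- domain$dim
  m <- array(mask, dim = d)
  out <- m
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    xs <- pmin(pmax(seq_len(d[1]) + dx, 1L), d[1])
    ys <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
    out <- out | m[xs, ys, , drop = FALSE]
  }
  as.vector(out)
}

.bbox_mask <- function(mask, domain, margin) {
  d <- domain$dim
  m <- array(mask, dim = d)
  idx <- which(m, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - c(margin, margin, 0L), 1L)
  hi <- pmin(apply(idx, 2, max) + c(margin, margin, 0L), d)
  out <- array(FALSE, dim = d)
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  as.vector(out)
}

#' Generate a synthetic somatotopic cohort with known ground truth
#'
#' Each subject's ground-truth digit map is derived from a shared template
#' strip (digits 1..5 in contiguous bands along x) by a random rigid
#' translation plus isotropic scaling, with per-digit band widths perturbed
#' multiplicatively. The default relative widths make digit 5 by far the
#' smallest band and digit 3 slightly smaller than its neighbours, emulating
#' the size ordering reported for real digit ROIs. Two anatomical masks are
#' emitted per subject: a tight "manual" mask (the strip dilated by one
#' voxel, the analogue of a hand-drawn region around the orderly phase
#' progression) and a loose "automatic" mask (the strip's bounding box plus a
#' margin, the analogue of a pooled somatosensory-area label).
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param domain Common [sample_domain()]; defaults to [strip_domain()].
#' @param jitter_sd Standard deviation in mm of the per-subject translation
#'   jitter (both in-plane axes); the isotropic scale jitter SD is tied to it
#'   as `scale_sd = 0.025 * jitter_sd` so that `jitter_sd = 0` reproduces the
#'   template exactly.
#' @param digit_size_cv Coefficient of variation of the per-digit band
#'   widths across subjects.
#' @param seed Integer seed; identical seeds and parameters give bit-identical
#'   cohorts.
#' @param strip_length,strip_height Template strip extent in mm.
#' @param digit_rel_widths Relative template band widths for digits 1..5
#'   (normalised to `strip_length`).
#' @param response_amplitude Response amplitude in percent signal change.
#' @param haemo_delay_s Haemodynamic delay in seconds (a pure phase lag of
#'   the response waveform). Must lie in `[0, cycle_s/2)` for the
#'   forward/backward combination to be unambiguous.
#' @param hand Which hand the cohort maps (`"left"` or `"right"`).
#' @param m1_patch,secondary_d2 Optional extra features: a smaller full digit
#'   strip offset from the main one (motor-cortex analogue) and a detached
#'   secondary digit-2 patch beside the digit-1 band. Both fall outside the
#'   manual/automatic masks of the main strip.
#'
#' @return A list of `synthetic_subject` objects, each with fields `id`,
#'   `truth_labels` (integer vector, 0 = non-responsive), `jitter`,
#'   `digit_widths`, `response_amplitude`, `haemo_delay_s`, `manual_mask`,
#'   `automatic_mask`, `hand` and `domain`.
#' @export
make_cohort <- function(n_subjects, domain = strip_domain(),
                        jitter_sd = 2, digit_size_cv = 0.1, seed = 1,
                        strip_length = 40, strip_height = 10,
                        digit_rel_widths = c(1.15, 1.10, 0.95, 1.15, 0.50),
                        response_amplitude = 2, haemo_delay_s = 4,
                        hand = c("left", "right"),
                        m1_patch = FALSE, secondary_d2 = FALSE) {
  hand <- match.arg(hand)
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  if (digit_size_cv < 0) stop("digit_size_cv must be >= 0")
  stopifnot(inherits(domain, "sample_domain"), domain$type == "volume")
  base_w <- strip_length * digit_rel_widths / sum(digit_rel_widths)
  scale_sd <- 0.025 * jitter_sd
  set.seed(seed)
  lapply(seq_len(n_subjects), function(i) {
    id <- sprintf("S%03d", i)
    tx <- stats::rnorm(1, 0, jitter_sd)
    ty <- stats::rnorm(1, 0, jitter_sd)
    sc <- max(0.5, stats::rnorm(1, 1, scale_sd))
    wmul <- pmax(0.2, 1 + digit_size_cv * stats::rnorm(5))
    widths <- base_w * wmul
    labels <- .strip_labels(domain, widths, strip_height, tx, ty, sc, id)
    if (any(labels > 0L)) {
      manual <- .dilate_xy(labels > 0L, domain)
      automatic <- .bbox_mask(labels > 0L, domain, margin = 3L)
    } else {
      stop(sprintf("subject %s: digit strip is empty on this domain", id))
    }
    truth <- labels
    if (m1_patch) {
      extra <- tryCatch(
        .strip_labels(domain, widths * 0.6, strip_height * 0.6,
                      tx, ty - (strip_height + 6), sc, id),
        error = function(e) integer(domain$n_loc))
      truth[truth == 0L & extra > 0L & !manual] <- extra[truth == 0L & extra > 0L & !manual]
    }
    if (secondary_d2) {
      cc <- voxel_centers(domain)
      ext <- domain$dim * domain$spacing
      x0 <- ext[1] / 2 - sum(widths * sc) / 2 + tx
      yc <- ext[2] / 2 + ty
      patch <- cc[, 1] >= x0 & cc[, 1] < x0 + 3 &
        cc[, 2] < yc - strip_height * sc / 2 - 2 &
        cc[, 2] >= yc - strip_height * sc / 2 - 5
      truth[truth == 0L & patch & !manual] <- 2L
    }
    structure(
      list(id = id, truth_labels = truth,
           jitter = list(tx = tx, ty = ty, scale = sc, rotation = 0),
           digit_widths = widths, response_amplitude = response_amplitude,
           haemo_delay_s = haemo_delay_s, manual_mask = manual,
           automatic_mask = automatic, hand = hand, domain = domain),
      class = "synthetic_subject"
    )
  })
}

# band-limited travelling-wave response waveform: the 4 s boxcar of digit d,
# circularly delayed by `delay`, truncated to harmonics below the sampling
# Nyquist so the fundamental's phase and amplitude survive sampling exactly.
.response_waveform <- function(d, times, acq, delay, direction) {
  dwell <- acq$digit_dwell_s
  t_c <- if (direction == "forward") (d - 0.5) * dwell else (5 - d + 0.5) * dwell
  t_c <- t_c + delay
  h_max <- max(1L, as.integer(floor(acq$cycle_s / (2 * acq$TR) - 1e-9)))
  w <- rep(1 / 5, length(times))
  for (h in seq_len(h_max)) {
    w <- w + (2 / (pi * h)) * sin(pi * h / 5) *
      cos(2 * pi * h * (times - t_c) / acq$cycle_s)
  }
  w
}

#' Simulate a forward/backward pair of travelling-wave runs
#'
#' A location with truth label `d` carries a periodic response whose
#' fundamental at the stimulation frequency has phase
#' `(d - 1/2) * 2*pi/5 + 2*pi*stim_freq*haemo_delay_s` in the forward run and
#' `-(d - 1/2) * 2*pi/5 + 2*pi*stim_freq*haemo_delay_s` in the backward run
#' (phases as the lag of the best-fitting cosine, wrapped to `[0, 2*pi)`).
#' The response is a band-limited boxcar: each digit's 4 s stimulation window
#' low-pass filtered below the sampling Nyquist, so the fundamental is exact
#' under TR sampling. Non-responsive locations contain baseline, drift and
#' noise only. Drift is a sum of cosines at the run's discrete frequencies
#' below 0.01 Hz with random phases per location, exercising the high-pass
#' filter specifically.
#'
#' @param subject A `synthetic_subject` from [make_cohort()].
#' @param acq [acq_params()].
#' @param noise_sd Gaussian noise SD in signal units (baseline is 100).
#' @param drift_amp Amplitude in signal units of each low-frequency drift
#'   component.
#' @param seed Integer seed; forward and backward runs use independent draws
#'   from the same stream.
#' @return A list with components `forward` and `backward`, each a `tw_run`
#'   with fields `data` (locations x time matrix), `direction`, `acq`,
#'   `noise_sd`, `drift_amp` and `domain`.
#' @export
make_runs <- function(subject, acq = acq_params(), noise_sd = 1,
                      drift_amp = 0.5, seed = 1) {
  stopifnot(inherits(subject, "synthetic_subject"), inherits(acq, "acq_params"))
  n_t <- acq$n_volumes
  n_loc <- subject$domain$n_loc
  times <- (seq_len(n_t) - 1) * acq$TR
  baseline <- 100
  amp <- baseline * subject$response_amplitude / 100
  set.seed(seed)
  drift_freqs <- {
    j <- seq_len(floor(n_t / 2))
    f <- j / (n_t * acq$TR)
    f[f < 0.01 & f > 0]
  }
  one_run <- function(direction) {
    data <- matrix(baseline, nrow = n_loc, ncol = n_t)
    for (d in 1:5) {
      sel <- subject$truth_labels == d
      if (!any(sel)) next
      w <- .response_waveform(d, times, acq, subject$haemo_delay_s, direction)
      data[sel, ] <- data[sel, ] + rep(amp * w, each = sum(sel))
    }
    if (drift_amp > 0 && length(drift_freqs) > 0) {
      for (f in drift_freqs) {
        th <- stats::runif(n_loc, 0, 2 * pi)
        data <- data + drift_amp * cos(outer(th, 2 * pi * f * times, `+`))
      }
    }
    if (noise_sd > 0)
      data <- data + matrix(stats::rnorm(n_loc * n_t, 0, noise_sd), n_loc, n_t)
    structure(
      list(data = data, direction = direction, acq = acq,
           noise_sd = noise_sd, drift_amp = drift_amp,
           domain = subject$domain, subject = subject$id, hp_cutoff = NULL),
      class = "tw_run"
    )
  }
  list(forward = one_run("forward"), backward = one_run("backward"))
}

#' Simulate two scan sessions of the same subject
#'
#' Both sessions share the subject's ground truth but use independent noise
#' draws; the acquisitions may differ (for example in cycle count) as long as
#' the stimulation frequency matches.
#'
#' @param subject A `synthetic_subject`.
#' @param acq1,acq2 [acq_params()] for the two sessions (must share
#'   `stim_freq`).
#' @param noise_sd,drift_amp Passed to [make_runs()].
#' @param seed Integer seed controlling both sessions.
#' @return A list with components `session1` and `session2`, each a
#'   forward/backward pair as returned by [make_runs()].
#' @export
make_session_pair <- function(subject, acq1 = acq_params(), acq2 = acq1,
                              noise_sd = 1, drift_amp = 0.5, seed = 1) {
  if (abs(acq1$stim_freq - acq2$stim_freq) > 1e-12)
    stop("the two sessions must share the stimulation frequency")
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 2L)
  list(
    session1 = make_runs(subject, acq1, noise_sd, drift_amp, seed = seeds[1]),
    session2 = make_runs(subject, acq2, noise_sd, drift_amp, seed = seeds[2])
  )
}

#' Edinburgh handedness indices of the 22-subject reference cohort
#'
#' The handedness index `H = (R - L) / (R + L)` summarises the Edinburgh
#' Handedness Inventory; `H = 1` is fully right-handed. These are the
#' inventory results, in subject order, for the 22 right-handed subjects of
#' the reference somatotopy cohort.
#'
#' @return A numeric vector of 22 handedness indices.
#' @export
reference_handedness <- function() {
  c(1, 1, 0.85, 1, 1, 0.2, 1, 1, 1, 1, 1,
    1, 1, 0.6, 0.71, 1, 1, 0.4, 1, 1, 1, 1)
}
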