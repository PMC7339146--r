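# Group-level atlas construction: full probability maps (FPM), the digit
# hand ROI, maximal probability maps (MPM), nearest-neighbour resampling and
# group circular phase summaries.

#' Build full probability maps from a cohort of digit maps
#'
#' The probability of digit `d` at a location is the number of subjects
#' assigning `d` there divided by the cohort size; probabilities are
#' therefore multiples of `1/n` and, because per-subject assignments are
#' mutually exclusive, sum to at most 1 across digits at every location.
#'
#' @param cohort A list of `digit_map`s on a shared domain, all of one hand.
#' @return An `fpm_atlas` with fields `prob` (`n_loc` x 5 matrix),
#'   `n_subjects`, `hand` and `domain`.
#' @export
build_fpm <- function(cohort) {
  if (length(cohort) < 2) stop("build_fpm() needs at least 2 subjects")
  stopifnot(all(vapply(cohort, inherits, logical(1), "digit_map")))
  domain <- cohort[[1]]$domain
  hands <- unique(vapply(cohort, `[[`, character(1), "hand"))
  if (length(hands) != 1)
    stop("all digit maps in a cohort must map the same hand")
  for (dm in cohort) {
    if (!same_domain(dm$domain, domain))
      stop("all digit maps in a cohort must share the domain")
  }
  n <- length(cohort)
  counts <- matrix(0L, nrow = domain$n_loc, ncol = 5)
  for (dm in cohort) {
    for (d in 1:5) counts[, d] <- counts[, d] + (dm$labels == d)
  }
  structure(
    list(prob = counts / n, n_subjects = n, hand = hands, domain = domain),
    class = "fpm_atlas"
  )
}

#' Digit hand ROI: where any digit is represented with high probability
#'
#' The five FPMs are summed and thresholded; a location is included when the
#' summed probability of any digit being assigned there is strictly greater
#' than the threshold.
#'
#' @param fpm An `fpm_atlas`.
#' @param threshold Probability threshold in `[0, 1)`; default 0.5.
#' @return A `hand_roi` with fields `mask` (logical) and `threshold`.
#' @export
hand_roi <- function(fpm, threshold = 0.5) {
  stopifnot(inherits(fpm, "fpm_atlas"))
  if (threshold < 0 || threshold >= 1) stop("threshold must lie in [0, 1)")
  structure(
    list(mask = rowSums(fpm$prob) > threshold, threshold = threshold,
         domain = fpm$domain),
    class = "hand_roi"
  )
}

#' Maximal probability map: winner-takes-all digit labels
#'
#' Inside the digit hand ROI each location is labelled with the digit of
#' highest probability across the five FPMs; ties are broken towards the
#' lowest digit index (deterministic and subject-order independent), and tied
#' locations are flagged in the result. Locations outside the ROI are 0.
#'
#' @param fpm An `fpm_atlas`.
#' @param roi A `hand_roi` built from the same FPM.
#' @return An `mpm_atlas` with fields `labels` (integer 0..5), `ties`
#'   (logical) and `domain`.
#' @export
build_mpm <- function(fpm, roi) {
  stopifnot(inherits(fpm, "fpm_atlas"), inherits(roi, "hand_roi"))
  if (!same_domain(fpm$domain, roi$domain))
    stop("ROI and FPM must share the domain")
  best <- max.col(fpm$prob, ties.method = "first")
  pmax_ <- fpm$prob[cbind(seq_len(nrow(fpm$prob)), best)]
  ties <- rowSums(fpm$prob == pmax_) > 1 & pmax_ > 0
  labels <- integer(fpm$domain$n_loc)
  labels[roi$mask] <- best[roi$mask]
  structure(
    list(labels = labels, ties = ties & roi$mask, hand = fpm$hand,
         n_subjects = fpm$n_subjects, domain = fpm$domain),
    class = "mpm_atlas"
  )
}

#' Nearest-neighbour resampling of a labelled or binary map
#'
#' Each target location takes the value of the nearest source voxel, so
#' binary and integer label values are preserved exactly and no new values
#' are invented -- the interpolation contract that keeps per-subject digit
#' assignments mutually exclusive across spatial normalisation. The
#' transform maps target voxel-centre coordinates (mm) into the source
#' coordinate space; it may be a function taking and returning an `n x 3`
#' matrix, a 4 x 4 affine matrix, or `NULL` for the identity.
#'
#' @param values Numeric/integer vector over the source domain.
#' @param from Source [sample_domain()] (volumetric).
#' @param to Target [sample_domain()] (volumetric).
#' @param transform `NULL`, a function, or a 4 x 4 affine matrix.
#' @param outside Value used for target locations falling outside the source
#'   grid (default 0). An error is raised when no target location maps
#'   inside the source grid at all.
#' @return A vector of resampled values over the target domain.
#' @export
resample_nearest <- function(values, from, to, transform = NULL, outside = 0) {
  stopifnot(inherits(from, "sample_domain"), inherits(to, "sample_domain"),
            from$type == "volume", to$type == "volume")
  .check_map_length(values, from, "source map")
  tc <- voxel_centers(to)
  sc <- if (is.null(transform)) {
    tc
  } else if (is.function(transform)) {
    transform(tc)
  } else if (is.matrix(transform) && all(dim(transform) == c(4, 4))) {
    h <- cbind(tc, 1) %*% t(transform)
    h[, 1:3, drop = FALSE]
  } else {
    stop("transform must be NULL, a function, or a 4x4 affine matrix")
  }
  idx3 <- sweep(sc, 2, from$spacing, `/`) + 0.5   # fractional 1-based index
  idx3 <- round(idx3)
  inside <- idx3[, 1] >= 1 & idx3[, 1] <= from$dim[1] &
    idx3[, 2] >= 1 & idx3[, 2] <= from$dim[2] &
    idx3[, 3] >= 1 & idx3[, 3] <= from$dim[3]
  if (!any(inside))
    stop("the target domain lies entirely outside the source support")
  lin <- (idx3[, 3] - 1) * from$dim[1] * from$dim[2] +
    (idx3[, 2] - 1) * from$dim[1] + idx3[, 1]
  out <- rep(outside, to$n_loc)
  out[inside] <- values[lin[inside]]
  out
}

#' Rebinarise a fractional map
#'
#' Used after projections that smear a binary map into fractions: a location
#' is set when its value is greater than or equal to the threshold (the
#' inclusive edge keeps exact-0.5 projections).
#'
#' @param values Numeric vector with values in `[0, 1]`.
#' @param threshold Threshold in `[0, 1]`; default 0.5.
#' @return A numeric 0/1 vector.
#' @export
rebinarise <- function(values, threshold = 0.5) {
  if (any(values < 0 | values > 1)) stop("values must lie in [0, 1]")
  as.numeric(values >= threshold)
}

#' Group circular phase summaries inside the MPM support
#'
#' Computes, across subjects, the per-location circular mean and circular SD
#' of the phase maps restricted to the MPM support, plus a per-subject,
#' per-MPM-digit-ROI table of circular mean phases.
#'
#' @param phase_maps A list of per-subject `phase_map`s on the MPM's domain.
#' @param mpm An `mpm_atlas`.
#' @return A list with `mean` and `sd` (numeric vectors, `NA` outside the
#'   MPM support) and `table`, a data frame with columns `subject`, `digit`,
#'   `mean_phase` and `n_locations` (`mean_phase` is `NA` for empty MPM
#'   digits, which are flagged via `n_locations == 0`).
#' @export
group_phase_maps <- function(phase_maps, mpm) {
  stopifnot(inherits(mpm, "mpm_atlas"), length(phase_maps) >= 1)
  for (pm in phase_maps) {
    if (!same_domain(pm$domain, mpm$domain))
      stop("all phase maps must share the MPM domain")
  }
  support <- mpm$labels > 0L
  ph <- vapply(phase_maps, function(pm) pm$phase, numeric(mpm$domain$n_loc))
  if (is.null(dim(ph))) ph <- matrix(ph, nrow = mpm$domain$n_loc)
  mean_map <- sd_map <- rep(NA_real_, mpm$domain$n_loc)
  if (any(support)) {
    z <- rowMeans(exp(1i * ph[support, , drop = FALSE]))
    mean_map[support] <- wrap_to_2pi(Arg(z))
    r <- Mod(z)
    sd_map[support] <- ifelse(r < 1e-12, Inf, sqrt(-2 * log(pmin(r, 1))))
  }
  subjects <- seq_along(phase_maps)
  names(subjects) <- vapply(seq_along(phase_maps), function(i) {
    s <- phase_maps[[i]]$subject
    if (is.null(s) || is.na(s)) sprintf("subject%02d", i) else s
  }, character(1))
  rows <- list()
  for (i in seq_along(phase_maps)) {
    for (d in 1:5) {
      sel <- mpm$labels == d
      mp <- if (any(sel))
        circular_summary(phase_maps[[i]]$phase[sel])$mean_direction
      else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        subject = names(subjects)[i], digit = d,
        mean_phase = mp, n_locations = sum(sel))
    }
  }
  list(mean = mean_map, sd = sd_map, table = do.call(rbind, rows))
}
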