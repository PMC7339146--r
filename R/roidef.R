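# Subject-level digit ROI definition: statistical + anatomical masking of a
# combined phase map, then equal-width phase binning into five mutually
# exclusive binary digit regions.

#' Coherence-based statistical mask
#'
#' A location is included when its one-sided p-value is strictly below
#' `alpha`. p is computed from the exact null distribution of the coherence
#' statistic under Gaussian noise: inverting `t = C*sqrt(dof/(1-C^2))` gives
#' `1 - C^2 = dof/(t^2 + dof)` and `p = (dof/(t^2 + dof))^(dof/2)`.
#'
#' @param tmap A `t_map` from [coherence_to_t()].
#' @param alpha Uncorrected significance level in (0, 1).
#' @return A logical vector over the domain.
#' @export
statistical_mask <- function(tmap, alpha = 0.05) {
  stopifnot(inherits(tmap, "t_map"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  p <- ifelse(is.infinite(tmap$t), 0,
              (tmap$dof / (tmap$t^2 + tmap$dof))^(tmap$dof / 2))
  p < alpha
}

#' Bundle the statistical and anatomical masks of one subject
#'
#' @param statistical Logical vector from [statistical_mask()].
#' @param anatomical Logical vector: a tight hand-drawn ("manual") region or
#'   a loose atlas-label union ("automatic").
#' @param mode `"manual"` or `"automatic"`, recorded for provenance.
#' @param domain The shared [sample_domain()].
#' @return A `mask_set` object.
#' @export
mask_set <- function(statistical, anatomical, mode = c("manual", "automatic"),
                     domain) {
  mode <- match.arg(mode)
  stopifnot(inherits(domain, "sample_domain"))
  statistical <- as.logical(statistical)
  anatomical <- as.logical(anatomical)
  .check_map_length(statistical, domain, "statistical mask")
  .check_map_length(anatomical, domain, "anatomical mask")
  structure(list(statistical = statistical, anatomical = anatomical,
                 mode = mode, domain = domain),
            class = "mask_set")
}

#' Intersect the statistical and anatomical masks
#'
#' @param masks A [mask_set()].
#' @return The element-wise intersection as a logical vector. An empty
#'   intersection is allowed but raises a warning.
#' @export
apply_masks <- function(masks) {
  stopifnot(inherits(masks, "mask_set"))
  out <- masks$statistical & masks$anatomical
  if (!any(out))
    warning("statistical and anatomical masks are disjoint: the final mask is empty")
  out
}

#' Bin a phase map into five mutually exclusive digit ROIs
#'
#' The phase axis `[0, 2*pi)` is divided into 5 equal half-open bins of
#' width `2*pi/5`; a masked location whose offset phase falls in
#' `[(d-1)*2*pi/5, d*2*pi/5)` is assigned digit `d` (lower edge inclusive).
#' Unmasked locations stay unassigned (label 0).
#'
#' @param map A combined `phase_map` with phases wrapped to `[0, 2*pi)`.
#' @param mask Logical vector of locations to assign (typically
#'   [apply_masks()] output).
#' @param phase_offset Phase origin in radians subtracted before binning;
#'   the synthetic generator places each digit mid-bin at offset 0, while
#'   real data may need a delay-dependent origin.
#' @param subject,hand Metadata recorded on the result.
#' @return A `digit_map` with fields `subject`, `hand`, `labels` (integer,
#'   0 = unassigned) and `domain`.
#' @export
bin_phases <- function(map, mask, phase_offset = 0,
                       subject = NA_character_, hand = c("left", "right")) {
  hand <- match.arg(hand)
  stopifnot(inherits(map, "phase_map"))
  mask <- as.logical(mask)
  .check_map_length(mask, map$domain, "mask")
  ph <- wrap_to_2pi(map$phase - phase_offset)
  d <- as.integer(floor(ph / (2 * pi / 5))) + 1L
  d[d > 5L] <- 5L   # guard the phase == 2*pi floating-point edge
  labels <- integer(map$domain$n_loc)
  labels[mask] <- d[mask]
  digit_map(labels, map$domain, subject = subject, hand = hand)
}

#' Construct a digit map from an integer label vector
#'
#' @param labels Integer vector over the domain with values in 0..5
#'   (0 = unassigned).
#' @param domain The [sample_domain()].
#' @param subject,hand Metadata.
#' @return A `digit_map`.
#' @export
digit_map <- function(labels, domain, subject = NA_character_,
                      hand = c("left", "right")) {
  hand <- match.arg(hand)
  stopifnot(inherits(domain, "sample_domain"))
  labels <- as.integer(labels)
  .check_map_length(labels, domain, "label map")
  if (any(is.na(labels)) || any(labels < 0L | labels > 5L))
    stop("digit labels must be integers in 0..5")
  structure(list(subject = subject, hand = hand, labels = labels,
                 domain = domain),
            class = "digit_map")
}

#' Extract one digit's binary ROI from a digit map
#'
#' @param dm A `digit_map`.
#' @param d Digit index 1..5.
#' @return A logical vector over the domain.
#' @export
digit_roi <- function(dm, d) {
  stopifnot(inherits(dm, "digit_map"), d %in% 1:5)
  dm$labels == as.integer(d)
}
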