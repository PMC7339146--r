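# Atlas characterisation and validation metrics.

#' Blurring metric of a digit's ROIs across a cohort
#'
#' Quantifies how well spatially normalised single-subject ROIs of one digit
#' overlap: `B = 100 * (|union of ROIs| - mean ROI size) / mean ROI size`,
#' sizes counted in locations. Identical nonempty ROIs give `B = 0`; `n`
#' pairwise-disjoint equal ROIs give `B = 100 * (n - 1)`.
#'
#' @param rois A list (length >= 2) of logical vectors, one per subject, on
#'   a common domain.
#' @return A `blurring_score` list with `B` (percent), `union_size`,
#'   `mean_size` and `n`.
#' @export
blurring_metric <- function(rois) {
  if (length(rois) < 2) stop("blurring_metric() needs at least 2 subjects")
  rois <- lapply(rois, as.logical)
  sizes <- vapply(rois, sum, numeric(1))
  if (all(sizes == 0)) stop("all ROIs are empty")
  union_size <- sum(Reduce(`|`, rois))
  mean_size <- mean(sizes)
  structure(
    list(B = 100 * (union_size - mean_size) / mean_size,
         union_size = union_size, mean_size = mean_size, n = length(rois)),
    class = "blurring_score"
  )
}

#' Central tendency of a candidate ROI over a probability map
#'
#' Measures how much a binary ROI `d` overlaps the high-probability regions
#' of a map `f`. Two variants are provided. The `"nonzero-mean"` variant is
#' the ratio of the mean of the absolute non-zero entries of the Hadamard
#' product `f * d` to the mean of the absolute non-zero entries of `f`:
#' values above 1 mean the ROI sits over the map's peak, exactly 1 means it
#' covers the map's support, and values below 1 indicate peripheral overlap.
#' The `"overlap-fraction"` variant, `sum(f * d) / sum(f)`, is the natural
#' reading for binary `f` (e.g. MPM digit ROIs), where the non-zero-mean
#' form degenerates to 0 or 1; it never exceeds 1. An empty overlap yields
#' `P = 0` in both variants.
#'
#' @param f Numeric map (probabilities or binary) with at least one nonzero
#'   value.
#' @param d Binary (logical or 0/1) candidate ROI of the same length.
#' @param variant `"nonzero-mean"` or `"overlap-fraction"`.
#' @return The central tendency `P` as a single number.
#' @export
central_tendency <- function(f, d, variant = c("nonzero-mean", "overlap-fraction")) {
  variant <- match.arg(variant)
  if (length(f) != length(d)) stop("f and d must have the same length")
  d <- as.numeric(as.logical(d))
  if (!any(f != 0)) stop("the probability map f has no nonzero values")
  fd <- f * d
  if (variant == "nonzero-mean") {
    if (!any(fd != 0)) return(0)
    mean(abs(fd[fd != 0])) / mean(abs(f[f != 0]))
  } else {
    sum(abs(fd)) / sum(abs(f))
  }
}

#' Leave-one-out central tendency matrices
#'
#' For each of the `n` folds the atlas is rebuilt from the remaining
#' `n - 1` subjects and compared with the held-out subject: entry `(i, j)`
#' is the central tendency between atlas digit map `i` (an FPM, or the
#' binary MPM digit ROI when `mode = "mpm"`) and the held-out subject's
#' digit `j` ROI, averaged over folds. A fold in which an atlas digit map is
#' empty contributes `P = 0` for that row and is flagged.
#'
#' @param cohort A list (length >= 3) of `digit_map`s on a shared domain.
#' @param mode `"fpm"` (atlas digit maps are probability maps) or `"mpm"`
#'   (binary winner-takes-all ROIs inside the digit hand ROI).
#' @param variant Central tendency variant; defaults to `"nonzero-mean"` for
#'   FPM mode and `"overlap-fraction"` for MPM mode.
#' @param hand_threshold Digit hand ROI threshold used in MPM mode.
#' @return A 5 x 5 matrix (rows = atlas digit, columns = held-out subject
#'   digit) of fold-averaged central tendencies, with attributes `folds`
#'   (number of folds) and `flagged` (logical matrix marking cells that met
#'   an empty atlas digit or empty subject ROI in some fold).
#' @export
loo_central_tendency <- function(cohort, mode = c("fpm", "mpm"),
                                 variant = NULL, hand_threshold = 0.5) {
  mode <- match.arg(mode)
  if (length(cohort) < 3) stop("leave-one-out needs at least 3 subjects")
  if (is.null(variant))
    variant <- if (mode == "fpm") "nonzero-mean" else "overlap-fraction"
  n <- length(cohort)
  acc <- matrix(0, 5, 5)
  flagged <- matrix(FALSE, 5, 5)
  for (k in seq_len(n)) {
    fpm <- build_fpm(cohort[-k])
    atlas_maps <- if (mode == "fpm") {
      lapply(1:5, function(i) fpm$prob[, i])
    } else {
      mpm <- build_mpm(fpm, hand_roi(fpm, hand_threshold))
      lapply(1:5, function(i) as.numeric(mpm$labels == i))
    }
    held <- cohort[[k]]
    for (i in 1:5) {
      f <- atlas_maps[[i]]
      for (j in 1:5) {
        d <- digit_roi(held, j)
        if (!any(f != 0)) {
          flagged[i, j] <- TRUE            # empty atlas digit: P = 0 rule
          next
        }
        p <- central_tendency(f, d, variant)
        if (p == 0) flagged[i, j] <- flagged[i, j] || !any(d)
        acc[i, j] <- acc[i, j] + p
      }
    }
  }
  out <- acc / n
  dimnames(out) <- list(atlas = paste0("D", 1:5), subject = paste0("D", 1:5))
  attr(out, "folds") <- n
  attr(out, "flagged") <- flagged
  attr(out, "mode") <- mode
  attr(out, "variant") <- variant
  out
}

#' Sizes of each subject's digit ROIs
#'
#' Size is the location count weighted by the domain's per-location measure
#' (voxel volume in mm^3 or vertex area in mm^2).
#'
#' @param cohort A list of `digit_map`s.
#' @param domain The shared [sample_domain()]; defaults to the first map's.
#' @return A data frame with columns `subject`, `hand`, `digit`,
#'   `n_locations` and `size`.
#' @export
roi_sizes <- function(cohort, domain = NULL) {
  stopifnot(length(cohort) >= 1)
  if (is.null(domain)) domain <- cohort[[1]]$domain
  mv <- .measure_vec(domain)
  rows <- lapply(seq_along(cohort), function(k) {
    dm <- cohort[[k]]
    if (!same_domain(dm$domain, domain))
      stop("all digit maps must share the domain")
    data.frame(
      subject = if (is.na(dm$subject)) sprintf("S%03d", k) else dm$subject,
      hand = dm$hand, digit = 1:5,
      n_locations = vapply(1:5, function(d) sum(dm$labels == d), numeric(1)),
      size = vapply(1:5, function(d) sum(mv[dm$labels == d]), numeric(1)))
  })
  do.call(rbind, rows)
}

.log10_bonferroni <- function(p, n_comparisons = 10L) {
  log10(pmin(1, p * n_comparisons))
}

#' Pairwise digit ROI size comparisons
#'
#' For each of the 10 digit pairs, a two-sample t-test compares ROI sizes
#' pooled across hands; p-values are Bonferroni-corrected by the 10
#' comparisons (capped at 1) and reported as `log10(p)`, so -1.3 marks the
#' 0.05 significance level. The diagonal is 0 (`log10(1)`).
#'
#' @param sizes A size table from [roi_sizes()].
#' @param welch Use the Welch (unequal-variance) t-test; default `FALSE`
#'   (pooled variance).
#' @return A symmetric 5 x 5 matrix of `log10` Bonferroni-corrected
#'   p-values with attribute `flagged` marking degenerate (zero-variance)
#'   comparisons.
#' @export
pairwise_size_tests <- function(sizes, welch = FALSE) {
  stopifnot(is.data.frame(sizes), all(c("digit", "size") %in% names(sizes)))
  groups <- split(sizes$size, sizes$digit)
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each digit needs at least 2 size observations")
  out <- matrix(0, 5, 5, dimnames = list(paste0("D", 1:5), paste0("D", 1:5)))
  flagged <- matrix(FALSE, 5, 5)
  for (i in 1:4) for (j in (i + 1):5) {
    x <- groups[[as.character(i)]]
    y <- groups[[as.character(j)]]
    p <- tryCatch(
      stats::t.test(x, y, var.equal = !welch)$p.value,
      error = function(e) {
        flagged[i, j] <<- flagged[j, i] <<- TRUE
        if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
      })
    out[i, j] <- out[j, i] <- .log10_bonferroni(p)
  }
  attr(out, "flagged") <- flagged
  out
}

#' Cross-subject curvature variability
#'
#' Per-location mean and sample standard deviation (n - 1 denominator) of
#' curvature maps across subjects, plus the median of the SD map inside each
#' named ROI -- the summary used to compare anatomical variability between
#' cortical regions.
#'
#' @param maps A list (length >= 2) of numeric curvature vectors, one per
#'   subject, on a common domain.
#' @param rois A named list of logical ROI vectors.
#' @return A list with `mean` and `sd` vectors and `roi_median_sd`, a named
#'   numeric vector of per-ROI medians of the SD map.
#' @export
curvature_variability <- function(maps, rois = list()) {
  if (length(maps) < 2) stop("curvature_variability() needs at least 2 subjects")
  m <- do.call(cbind, lapply(maps, as.numeric))
  mean_map <- rowMeans(m)
  sd_map <- sqrt(rowSums((m - mean_map)^2) / (ncol(m) - 1))
  med <- vapply(rois, function(r) stats::median(sd_map[as.logical(r)]),
                numeric(1))
  list(mean = mean_map, sd = sd_map, roi_median_sd = med)
}

#' Handedness index from inventory counts
#'
#' `H = (R - L) / (R + L)`, where `R` and `L` are the numbers of everyday
#' activities reported as performed with the right and left hand; `H = 1`
#' is fully right-handed and `H = -1` fully left-handed.
#'
#' @param R,L Non-negative activity counts with `R + L > 0`.
#' @return A `handedness_record` list with `R`, `L` and `H`.
#' @examples
#' handedness_index(10, 0)$H   # 1
#' @export
handedness_index <- function(R, L) {
  if (R < 0 || L < 0) stop("R and L must be non-negative counts")
  if (R + L == 0) stop("R + L must be positive")
  structure(list(R = R, L = L, H = (R - L) / (R + L)),
            class = "handedness_record")
}
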