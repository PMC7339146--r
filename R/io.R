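# Typed map I/O on top of the NIfTI-1 layer, cohort manifests, and the
# pipeline configuration object.
#
# Conventions: phases are stored in radians in [0, 2*pi); label 0 means
# "unassigned"; digit volumes are ordered D1..D5 in 4D files; the descrip
# header field carries provenance as "somatlas;kind=..;key=val;..".

.descrip <- function(kind, ...) {
  extra <- list(...)
  s <- paste0("somatlas;kind=", kind)
  if (length(extra))
    s <- paste0(s, ";", paste(names(extra), unlist(extra), sep = "=",
                              collapse = ";"))
  substr(s, 1, 79)
}

.parse_descrip <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  out <- list()
  for (p in kv) if (length(p) == 2) out[[p[1]]] <- p[2]
  out
}

.domain_from_nifti <- function(nii) {
  sample_domain(dim(nii$data)[1:3], spacing = nii$spacing)
}

#' Write a map object as NIfTI-1
#'
#' Dispatches on the object type: a `digit_map` is written as a 4D file of
#' five binary volumes (D1..D5) plus a companion `*_labels.nii` integer
#' volume; an `fpm_atlas` as a 4D probability volume; an `mpm_atlas` or
#' `hand_roi` as an integer volume; a plain numeric vector (with `domain`
#' and `kind` supplied) as a 3D volume.
#'
#' @param x The object to write.
#' @param path Output `.nii` path.
#' @param ... Method-specific arguments: for the default vector method,
#'   `domain` ([sample_domain()]) and `kind` (one of `"mask"`, `"label"`,
#'   `"prob"`, `"phase"`, `"curv"`, `"tmap"`), plus optional `descrip`
#'   key-value provenance fields.
#' @return The main output path, invisibly.
#' @export
write_map <- function(x, path, ...) UseMethod("write_map")

#' @export
write_map.digit_map <- function(x, path, ...) {
  d <- x$domain
  vols <- array(0L, dim = c(d$dim, 5L))
  for (k in 1:5) vols[, , , k] <- array(as.integer(x$labels == k), dim = d$dim)
  write_nifti(vols, path, spacing = d$spacing, datatype = 2L,
              descrip = .descrip("digit4d", hand = x$hand, subject = x$subject))
  lab_path <- sub("\\.nii$", "_labels.nii", path)
  write_nifti(array(x$labels, dim = d$dim), lab_path, spacing = d$spacing,
              datatype = 8L,
              descrip = .descrip("label", hand = x$hand, subject = x$subject))
  invisible(path)
}

#' @export
write_map.fpm_atlas <- function(x, path, ...) {
  d <- x$domain
  write_nifti(array(x$prob, dim = c(d$dim, 5L)), path, spacing = d$spacing,
              datatype = 64L,
              descrip = .descrip("fpm", hand = x$hand, n = x$n_subjects))
  invisible(path)
}

#' @export
write_map.mpm_atlas <- function(x, path, ...) {
  d <- x$domain
  write_nifti(array(x$labels, dim = d$dim), path, spacing = d$spacing,
              datatype = 8L,
              descrip = .descrip("mpm", hand = x$hand, n = x$n_subjects))
  invisible(path)
}

#' @export
write_map.hand_roi <- function(x, path, ...) {
  d <- x$domain
  write_nifti(array(as.integer(x$mask), dim = d$dim), path,
              spacing = d$spacing, datatype = 2L,
              descrip = .descrip("mask", thr = x$threshold))
  invisible(path)
}

#' @export
write_map.default <- function(x, path, domain, kind, tr = 0, ...) {
  stopifnot(inherits(domain, "sample_domain"))
  .check_map_length(x, domain, "map")
  datatype <- if (kind %in% c("mask", "label")) 8L else 64L
  write_nifti(array(as.numeric(x), dim = domain$dim), path,
              spacing = domain$spacing, tr = tr, datatype = datatype,
              descrip = .descrip(kind, ...))
  invisible(path)
}

#' Read a typed map from NIfTI-1
#'
#' The map kind is taken from the file's provenance field when present,
#' otherwise from `kind`. Label maps are validated to be integer-valued
#' (non-integer values raise an error naming the offending values);
#' probability maps are validated to lie in `[0, 1]`, with values overshooting
#' by no more than `tol` clipped with a warning (or rejected when
#' `on_invalid = "error"`). A 4D file of five binary volumes is validated for
#' mutual exclusivity and returned as a `digit_map`.
#'
#' @param path Path to a `.nii` file.
#' @param kind Expected kind; `"auto"` trusts the file header.
#' @param on_invalid For probability maps: `"clip"` (default, warn) or
#'   `"error"`.
#' @param tol Tolerance for probability clipping.
#' @return For 4D digit files, a `digit_map`; otherwise a list with
#'   `values`, `domain`, `kind` and `meta` (parsed provenance).
#' @export
read_map <- function(path, kind = "auto", on_invalid = c("clip", "error"),
                     tol = 1e-6) {
  on_invalid <- match.arg(on_invalid)
  nii <- read_nifti(path)
  meta <- .parse_descrip(nii$descrip)
  if (kind == "auto")
    kind <- if (!is.null(meta$kind)) meta$kind else
      if (length(dim(nii$data)) == 4L && dim(nii$data)[4] == 5L) "digit4d"
      else "value"
  domain <- .domain_from_nifti(nii)
  vals <- as.vector(nii$data)
  if (kind == "digit4d") {
    nd <- dim(nii$data)
    if (length(nd) != 4L || nd[4] != 5L)
      stop(sprintf("%s: a digit map file must hold five volumes", path))
    vols <- matrix(vals, ncol = 5L)
    if (!all(vols %in% c(0, 1)))
      stop(sprintf("%s: digit volumes must be binary", path))
    if (any(rowSums(vols) > 1))
      stop(sprintf("%s: overlapping digit volumes violate mutual exclusivity",
                   path))
    labels <- as.integer(vols %*% (1:5))
    hand <- if (!is.null(meta$hand)) meta$hand else "left"
    return(digit_map(labels, domain,
                     subject = if (is.null(meta$subject)) NA_character_
                               else meta$subject,
                     hand = hand))
  }
  if (kind == "label") {
    bad <- vals[vals != round(vals)]
    if (length(bad))
      stop(sprintf("%s: label file contains non-integer values (e.g. %s)",
                   path, paste(utils::head(signif(unique(bad), 6), 3),
                               collapse = ", ")))
    vals <- as.integer(round(vals))
  }
  if (kind %in% c("prob", "fpm")) {
    over <- vals > 1 | vals < 0
    if (any(over)) {
      worst <- max(abs(pmax(vals - 1, 0)), abs(pmin(vals, 0)))
      if (on_invalid == "error" || worst > tol)
        stop(sprintf("%s: probability values outside [0, 1] (worst overshoot %g)",
                     path, worst))
      warning(sprintf("%s: clipping %d probability value(s) overshooting [0, 1] by <= %g",
                      path, sum(over), tol))
      vals <- pmin(pmax(vals, 0), 1)
    }
  }
  if (kind == "mask") vals <- vals != 0
  list(values = vals, domain = domain, kind = kind, meta = meta,
       dim4 = if (length(dim(nii$data)) == 4L) dim(nii$data)[4] else NULL)
}

#' Write and read a cohort manifest
#'
#' A manifest is a CSV table with one row per subject listing the file paths
#' of that subject's runs and maps plus the acquisition parameters and
#' generator seeds. Subject ids must be unique and a manifest holds one hand
#' only.
#'
#' @param manifest A data frame with at least `subject` and `hand` columns.
#' @param path CSV path.
#' @return `write_manifest()` returns the path invisibly; `read_manifest()`
#'   the validated data frame.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(is.data.frame(manifest),
            all(c("subject", "hand") %in% names(manifest)))
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @param check_paths Verify that all `path_*` columns point at existing
#'   files (resolved relative to the manifest's directory when not
#'   absolute).
#' @export
read_manifest <- function(path, check_paths = FALSE) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject", "hand") %in% names(m)))
    stop("a manifest needs `subject` and `hand` columns")
  if (anyDuplicated(m$subject))
    stop("subject ids in a manifest must be unique")
  if (length(unique(m$hand)) != 1)
    stop("a manifest holds one hand only")
  if (check_paths) {
    base <- dirname(path)
    for (col in grep("^path_", names(m), value = TRUE)) {
      p <- m[[col]]
      p <- ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
      missing <- p[!file.exists(p)]
      if (length(missing))
        stop(sprintf("manifest column %s: missing file(s): %s",
                     col, paste(utils::head(missing, 3), collapse = ", ")))
      m[[col]] <- p
    }
  }
  m
}

#' Pipeline configuration
#'
#' Collects every tunable parameter of the end-to-end analysis, validated
#' against the preconditions of the operations they feed.
#'
#' @param n_subjects Cohort size for the simulation stage.
#' @param seed Master integer seed; every random draw in the pipeline is
#'   derived from it.
#' @param noise_seed Optional separate seed for the run noise/drift draws;
#'   `NULL` (default) derives it from `seed`. Changing only `noise_seed`
#'   keeps the cohort's ground-truth maps identical while redrawing the
#'   time-series noise.
#' @param TR,cycle_s,n_cycles Acquisition parameters (see [acq_params()]).
#' @param cutoff_hz High-pass cut-off (must be below `1/cycle_s`).
#' @param alpha Statistical mask level.
#' @param hand_threshold Digit hand ROI probability threshold.
#' @param phase_offset Phase origin for binning.
#' @param mask_mode `"manual"` or `"automatic"` anatomical masking.
#' @param ct_variant Central tendency variant for FPM-mode validation.
#' @param noise_sd,drift_amp,jitter_sd,digit_size_cv Generator parameters.
#' @param hand Which hand the cohort maps.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(n_subjects = 6, seed = 1, noise_seed = NULL,
                            TR = 2, cycle_s = 20,
                            n_cycles = 10, cutoff_hz = 0.01, alpha = 0.05,
                            hand_threshold = 0.5, phase_offset = 0,
                            mask_mode = c("manual", "automatic"),
                            ct_variant = c("nonzero-mean", "overlap-fraction"),
                            noise_sd = 1, drift_amp = 0.5, jitter_sd = 2,
                            digit_size_cv = 0.1, hand = c("left", "right")) {
  mask_mode <- match.arg(mask_mode)
  ct_variant <- match.arg(ct_variant)
  hand <- match.arg(hand)
  acq <- acq_params(TR = TR, cycle_s = cycle_s, n_cycles = n_cycles)
  if (cutoff_hz >= acq$stim_freq)
    stop("cutoff_hz must be below the stimulation frequency")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (hand_threshold < 0 || hand_threshold >= 1)
    stop("hand_threshold must lie in [0, 1)")
  if (noise_sd < 0 || drift_amp < 0 || jitter_sd < 0 || digit_size_cv < 0)
    stop("noise_sd, drift_amp, jitter_sd and digit_size_cv must be >= 0")
  structure(
    list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
         noise_seed = if (is.null(noise_seed)) NULL else as.integer(noise_seed),
         TR = TR, cycle_s = cycle_s, n_cycles = as.integer(n_cycles),
         cutoff_hz = cutoff_hz, alpha = alpha,
         hand_threshold = hand_threshold, phase_offset = phase_offset,
         mask_mode = mask_mode, ct_variant = ct_variant,
         noise_sd = noise_sd, drift_amp = drift_amp, jitter_sd = jitter_sd,
         digit_size_cv = digit_size_cv, hand = hand, acq = acq),
    class = "pipeline_config"
  )
}

# stable polynomial hash of the serialised configuration, for provenance
.config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(
    config[setdiff(names(config), "acq")])), collapse = "\n")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}
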