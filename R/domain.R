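#' Define a common sampling domain
#'
#' Every map in a cohort analysis lives on one shared, ordered set of spatial
#' locations: either the voxels of a regular grid (volumetric analysis) or a
#' list of vertices carrying a per-vertex area (surface-style analysis).
#' Downstream objects (phase maps, digit maps, probability atlases) store
#' their values as plain numeric vectors in this domain's location order,
#' which for volumetric domains is R's column-major order over `dim`.
#'
#' @param dim For `type = "volume"`, an integer vector of length 3 giving the
#'   grid extent in voxels. For `type = "surface"`, the number of vertices.
#' @param spacing Voxel spacing in mm (length 3, volumetric domains only).
#' @param measure Per-location measure: voxel volume in mm^3 (scalar, derived
#'   from `spacing` when omitted) or per-vertex area in mm^2 (required for
#'   surface domains; scalar or one value per vertex).
#' @param type `"volume"` or `"surface"`.
#'
#' @return A `sample_domain` object with fields `dim`, `spacing`, `measure`,
#'   `type` and `n_loc`.
#' @examples
#' dom <- sample_domain(c(10, 8, 1), spacing = c(2, 2, 2))
#' dom$n_loc
#' @export
sample_domain <- function(dim, spacing = c(1, 1, 1),
                          measure = NULL, type = c("volume", "surface")) {
  type <- match.arg(type)
  if (type == "volume") {
    dim <- as.integer(dim)
    if (length(dim) != 3L || any(dim < 1L))
      stop("volumetric domains need a length-3 positive `dim`")
    if (length(spacing) != 3L || any(spacing <= 0))
      stop("`spacing` must be 3 positive voxel sizes in mm")
    n_loc <- prod(dim)
    if (is.null(measure)) measure <- prod(spacing)
  } else {
    if (length(dim) != 1L || dim < 1)
      stop("surface domains need a scalar vertex count")
    n_loc <- as.integer(dim)
    dim <- n_loc
    spacing <- NULL
    if (is.null(measure))
      stop("surface domains need a per-vertex area `measure` (mm^2)")
  }
  measure <- as.numeric(measure)
  if (!length(measure) %in% c(1L, n_loc))
    stop("`measure` must be scalar or one value per location")
  if (any(measure <= 0)) stop("all location measures must be > 0")
  structure(
    list(dim = dim, spacing = spacing, measure = measure,
         type = type, n_loc = as.integer(n_loc)),
    class = "sample_domain"
  )
}

#' @export
print.sample_domain <- function(x, ...) {
  if (x$type == "volume") {
    cat(sprintf("<sample_domain> volume %s @ %s mm (%d locations)\n",
                paste(x$dim, collapse = "x"),
                paste(signif(x$spacing, 3), collapse = "x"), x$n_loc))
  } else {
    cat(sprintf("<sample_domain> surface, %d vertices\n", x$n_loc))
  }
  invisible(x)
}

#' Voxel-centre coordinates of a volumetric domain
#'
#' Centres are at `(i - 0.5) * spacing` for 1-based voxel index `i`, in the
#' domain's column-major location order.
#'
#' @param domain A volumetric [sample_domain()].
#' @return An `n_loc` x 3 matrix of coordinates in mm.
#' @export
voxel_centers <- function(domain) {
  stopifnot(inherits(domain, "sample_domain"))
  if (domain$type != "volume")
    stop("voxel_centers() is defined for volumetric domains only")
  g <- expand.grid(
    x = (seq_len(domain$dim[1]) - 0.5) * domain$spacing[1],
    y = (seq_len(domain$dim[2]) - 0.5) * domain$spacing[2],
    z = (seq_len(domain$dim[3]) - 0.5) * domain$spacing[3]
  )
  as.matrix(g)
}

#' Test whether two domains describe the same common space
#'
#' @param a,b [sample_domain()] objects.
#' @return `TRUE` when type, extent and spacing all agree.
#' @export
same_domain <- function(a, b) {
  inherits(a, "sample_domain") && inherits(b, "sample_domain") &&
    a$type == b$type && identical(a$dim, b$dim) &&
    isTRUE(all.equal(a$spacing, b$spacing)) && a$n_loc == b$n_loc
}

# per-location measure expanded to a full vector
.measure_vec <- function(domain) {
  rep_len(domain$measure, domain$n_loc)
}

.check_map_length <- function(values, domain, what = "map") {
  if (length(values) != domain$n_loc)
    stop(sprintf("%s has %d values but the domain has %d locations",
                 what, length(values), domain$n_loc))
  invisible(TRUE)
}

#' Wrap angles to [0, 2*pi)
#'
#' @param x Angles in radians.
#' @return Angles wrapped to the half-open interval `[0, 2*pi)`.
#' @export
wrap_to_2pi <- function(x) x %% (2 * pi)

#' Wrap angles to (-pi, pi]
#'
#' The convention used for phase differences: a difference that wraps through
#' zero (for example `0.1 - (2*pi - 0.1)`) maps to its small signed value.
#'
#' @param x Angles in radians.
#' @return Angles wrapped to the half-open interval `(-pi, pi]`.
#' @export
wrap_to_pi <- function(x) pi - ((pi - x) %% (2 * pi))
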