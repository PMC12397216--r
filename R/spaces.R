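#' Atlas coordinate spaces
#'
#' An `atlas_space` describes the geometry of one postnatal-age coordinate
#' space: the age in postnatal days, the voxel grid shape, the isotropic voxel
#' spacing in micrometres, and the voxel index of the anatomical reference
#' origin.
#'
#' Conventions used throughout the package:
#' * voxel coordinates are 0-based and continuous; voxel `(0,0,0)` is the
#'   first grid element,
#' * axis order is anterior-posterior, superior-inferior, left-right,
#' * displacement fields are stored in voxel units of the shared grid, so
#'   field composition is spacing-free as long as all spaces in a chain share
#'   shape and spacing (which the chain constructor enforces).
#'
#' @param age Postnatal day, an integer between 4 and 56 (the supported span
#'   of the developmental chain).
#' @param shape Integer vector of length 3: voxel counts along the AP, SI and
#'   LR axes.
#' @param spacing Isotropic voxel edge length in micrometres. Default 20.
#' @param origin Voxel index (0-based, length 3) of the anatomical reference
#'   origin. Purely metadata; defaults to `c(0, 0, 0)`.
#' @return An object of class `atlas_space`.
#' @examples
#' sp <- atlas_space(age = 14, shape = c(32, 24, 28))
#' sp
#' @export
atlas_space <- function(age, shape, spacing = 20, origin = c(0, 0, 0)) {
  if (length(age) != 1L || !is.finite(age)) {
    stop("`age` must be a single finite number", call. = FALSE)
  }
  if (age < 4 || age > 56) {
    stop("`age` must lie in the supported postnatal span P4-P56 (got ",
         age, ")", call. = FALSE)
  }
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L)) {
    stop("`shape` must be three positive integers", call. = FALSE)
  }
  if (length(spacing) != 1L || !is.finite(spacing) || spacing <= 0) {
    stop("`spacing` must be a single positive number (micrometres)",
         call. = FALSE)
  }
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be three finite voxel coordinates", call. = FALSE)
  }
  structure(
    list(age = as.numeric(age), shape = shape, spacing = as.numeric(spacing),
         origin = origin),
    class = "atlas_space"
  )
}

#' @export
print.atlas_space <- function(x, ...) {
  cat(sprintf("<atlas_space> P%g  %d x %d x %d voxels @ %g um  origin (%g, %g, %g)\n",
              x$age, x$shape[1], x$shape[2], x$shape[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' @export
format.atlas_space <- function(x, ...) {
  sprintf("P%g [%s] @ %g um", x$age, paste(x$shape, collapse = "x"),
          x$spacing)
}

#' @rdname atlas_space
#' @param x Object to test.
#' @export
is_atlas_space <- function(x) inherits(x, "atlas_space")

# Same grid geometry (shape + spacing); age and origin may differ.
same_grid <- function(a, b) {
  identical(a$shape, b$shape) && isTRUE(all.equal(a$spacing, b$spacing))
}

stopifnot_space <- function(x, arg = deparse(substitute(x))) {
  if (!is_atlas_space(x)) stop("`", arg, "` must be an atlas_space", call. = FALSE)
  invisible(x)
}

#' Convert voxel coordinates to physical micrometre coordinates
#'
#' Distances reported by the landmark-validation statistics are expressed in
#' micrometres; this is the conversion they use. Each voxel coordinate
#' component is multiplied by the space's isotropic spacing.
#'
#' @param p Numeric vector of length 3, or an n x 3 matrix of 0-based voxel
#'   coordinates.
#' @param space An [atlas_space()].
#' @return Coordinates in micrometres, same shape as `p`.
#' @examples
#' sp <- atlas_space(14, c(32, 32, 32), spacing = 20)
#' voxel_to_micron(c(1, 2, 3), sp)   # 20 40 60
#' @export
voxel_to_micron <- function(p, space) {
  stopifnot_space(space)
  p <- coerce_points(p)
  if (any(!is.finite(p))) {
    stop("voxel coordinates must be finite", call. = FALSE)
  }
  out <- p * space$spacing
  if (nrow(out) == 1L && is.null(dim(out))) out else out
}

#' @rdname voxel_to_micron
#' @export
micron_to_voxel <- function(p, space) {
  stopifnot_space(space)
  p <- coerce_points(p)
  if (any(!is.finite(p))) {
    stop("micrometre coordinates must be finite", call. = FALSE)
  }
  p / space$spacing
}

# Accept a length-3 vector or an n x 3 matrix; always return an n x 3 matrix.
coerce_points <- function(p) {
  if (is.null(dim(p))) {
    if (length(p) != 3L) stop("a point must have 3 coordinates", call. = FALSE)
    matrix(as.numeric(p), nrow = 1L)
  } else {
    p <- as.matrix(p)
    if (ncol(p) != 3L) stop("points must be an n x 3 matrix", call. = FALSE)
    storage.mode(p) <- "double"
    p
  }
}

#' Point sets in an atlas space
#'
#' A `point_set` bundles continuous 0-based voxel coordinates with the space
#' they live in. Points falling outside `[0, shape - 1]` are kept but carry an
#' out-of-domain flag, so that downstream statistics can exclude them
#' explicitly rather than silently dropping rows.
#'
#' @param points An n x 3 numeric matrix (or length-3 vector) of voxel
#'   coordinates.
#' @param space An [atlas_space()].
#' @return A `point_set`: list with elements `points` (n x 3 matrix),
#'   `space`, and `out_of_domain` (logical vector).
#' @export
point_set <- function(points, space) {
  stopifnot_space(space)
  points <- coerce_points(points)
  if (any(!is.finite(points))) {
    stop("point coordinates must be finite", call. = FALSE)
  }
  structure(
    list(points = points, space = space,
         out_of_domain = flag_out_of_domain(points, space)),
    class = "point_set"
  )
}

flag_out_of_domain <- function(points, space) {
  hi <- space$shape - 1
  apply(points, 1L, function(p) any(p < 0) || any(p > hi))
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("<point_set> %d points in %s (%d out of domain)\n",
              nrow(x$points), format(x$space), sum(x$out_of_domain)))
  invisible(x)
}

#' @rdname point_set
#' @param x Object to test.
#' @export
is_point_set <- function(x) inherits(x, "point_set")
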