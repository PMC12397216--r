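#' Intensity and label volumes
#'
#' The two volumetric containers of the package. An `intensity_volume` holds
#' a non-negative scalar grid (a template or an interpolated model); a
#' `label_volume` holds an integer segmentation grid plus a label table
#' describing the region ontology. Label id 0 is reserved for background.
#'
#' @param values 3D numeric array matching `space$shape`.
#' @param space An [atlas_space()].
#' @return An `intensity_volume` (list with `values`, `space`).
#' @export
intensity_volume <- function(values, space) {
  stopifnot_space(space)
  values <- check_grid(values, space)
  if (any(!is.finite(values))) {
    stop("intensity values must be finite", call. = FALSE)
  }
  structure(list(values = values, space = space), class = "intensity_volume")
}

#' @rdname intensity_volume
#' @param labels 3D integer array matching `space$shape`; 0 = background.
#' @param table A [label_table()] covering every nonzero label, or `NULL` to
#'   build a minimal one from the ids present.
#' @export
label_volume <- function(labels, space, table = NULL) {
  stopifnot_space(space)
  labels <- check_grid(labels, space)
  if (any(!is.finite(labels)) || any(labels != round(labels))) {
    stop("labels must be finite integers", call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  if (is.null(table)) {
    table <- label_table(ids = ids)
  } else {
    missing <- setdiff(ids, table$id)
    if (length(missing)) {
      stop("label ids absent from the label table: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(labels = labels, space = space, table = table),
            class = "label_volume")
}

check_grid <- function(values, space) {
  if (is.null(dim(values)) && length(values) == prod(space$shape)) {
    dim(values) <- space$shape
  }
  if (length(dim(values)) != 3L || !all(dim(values) == space$shape)) {
    stop("grid shape (", paste(dim(values), collapse = "x"),
         ") does not match space shape (",
         paste(space$shape, collapse = "x"), ")", call. = FALSE)
  }
  storage.mode(values) <- if (is.integer(values)) "integer" else "double"
  values
}

#' @export
print.intensity_volume <- function(x, ...) {
  cat(sprintf("<intensity_volume> %s  range [%g, %g]\n", format(x$space),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  ids <- setdiff(unique(as.vector(x$labels)), 0L)
  cat(sprintf("<label_volume> %s  %d regions\n", format(x$space), length(ids)))
  invisible(x)
}

#' @rdname intensity_volume
#' @param x Object to test.
#' @export
is_intensity_volume <- function(x) inherits(x, "intensity_volume")

#' @rdname intensity_volume
#' @export
is_label_volume <- function(x) inherits(x, "label_volume")

#' Region ontology metadata
#'
#' A minimal label table: one row per region id with a name, an acronym and
#' an RGB colour, in the style of viewer label-description files. Id 0
#' (background) is never listed.
#'
#' @param ids Integer region ids (unique, nonzero).
#' @param names Region names; defaults to `"region_<id>"`.
#' @param acronyms Region acronyms; defaults to `"R<id>"`.
#' @param colors A matrix of RGB triples (0-255), one row per id, or `NULL`
#'   for an automatic palette.
#' @return A tibble of class `label_table` with columns `id`, `name`,
#'   `acronym`, `red`, `green`, `blue`.
#' @export
label_table <- function(ids, names = NULL, acronyms = NULL, colors = NULL) {
  ids <- as.integer(ids)
  if (anyDuplicated(ids)) stop("label ids must be unique", call. = FALSE)
  if (any(ids == 0L)) stop("id 0 is reserved for background", call. = FALSE)
  n <- length(ids)
  if (is.null(names)) names <- paste0("region_", ids)
  if (is.null(acronyms)) acronyms <- paste0("R", ids)
  if (is.null(colors)) {
    # deterministic distinct-ish palette
    colors <- cbind((ids * 67L) %% 256L, (ids * 131L) %% 256L,
                    (ids * 199L) %% 256L)
  }
  colors <- matrix(as.integer(colors), ncol = 3L)
  out <- tibble::tibble(id = ids, name = as.character(names),
                        acronym = as.character(acronyms),
                        red = colors[, 1], green = colors[, 2],
                        blue = colors[, 3])
  class(out) <- c("label_table", class(out))
  out
}

#' Foreground centroid of a volume
#'
#' Intensity-weighted centroid in 0-based voxel coordinates, used by the
#' temporal-interpolation diagnostics (a translated phantom's centroid must
#' move linearly with age).
#'
#' @param vol An [intensity_volume()] or [label_volume()].
#' @return Length-3 numeric vector of voxel coordinates.
#' @export
volume_centroid <- function(vol) {
  arr <- if (is_label_volume(vol)) (vol$labels != 0L) * 1 else vol$values
  w <- sum(arr)
  if (w == 0) stop("cannot take the centroid of an empty volume", call. = FALSE)
  sh <- dim(arr)
  idx <- c(
    sum(arr * (slice.index(arr, 1L) - 1)),
    sum(arr * (slice.index(arr, 2L) - 1)),
    sum(arr * (slice.index(arr, 3L) - 1))
  )
  idx / w
}
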