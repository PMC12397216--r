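#' Sparse section stacks
#'
#' A `section_stack` is a list of registered 2D rasters with anchoring
#' metadata that maps each section pixel to a 3D voxel coordinate of an
#' [atlas_space()]. Two anchoring flavours are supported:
#'
#' * *plane*: an orthogonal section at integer `index` along `axis`
#'   (1 = anterior-posterior, 2 = superior-inferior, 3 = left-right); pixel
#'   `(i, j)` (0-based) fills the remaining two axes in order;
#' * *affine*: a general pixel-to-voxel map `v = A %*% c(i, j) + b` with `A`
#'   a 3 x 2 matrix and `b` a length-3 offset, rounded to the nearest voxel
#'   (ties toward the smaller index) — the form oblique registrations reduce
#'   to.
#'
#' @param sections List of sections, each a list with `values` (2D matrix)
#'   and `anchoring` (list with `type = "plane"`, `axis`, `index`, or
#'   `type = "affine"`, `A`, `b`).
#' @return A `section_stack`.
#' @export
section_stack <- function(sections) {
  if (!length(sections)) stop("at least one section required", call. = FALSE)
  for (s in sections) {
    if (!is.matrix(s$values)) {
      stop("each section needs a 2D `values` matrix", call. = FALSE)
    }
    a <- s$anchoring
    if (is.null(a$type) || !a$type %in% c("plane", "affine")) {
      stop("anchoring type must be \"plane\" or \"affine\"", call. = FALSE)
    }
    if (a$type == "plane" &&
        (!a$axis %in% 1:3 || is.null(a$index))) {
      stop("plane anchoring needs `axis` in 1:3 and an `index`",
           call. = FALSE)
    }
    if (a$type == "affine" &&
        (!all(dim(a$A) == c(3, 2)) || length(a$b) != 3L)) {
      stop("affine anchoring needs a 3x2 `A` and length-3 `b`", call. = FALSE)
    }
  }
  structure(list(sections = sections), class = "section_stack")
}

#' @export
print.section_stack <- function(x, ...) {
  cat(sprintf("<section_stack> %d sections\n", length(x$sections)))
  invisible(x)
}

# 0-based voxel coordinates (n x 3, integer) and values for one section.
section_voxels <- function(section, space) {
  v <- section$values
  nr <- nrow(v); nc <- ncol(v)
  i <- rep(seq_len(nr) - 1L, times = nc)
  j <- rep(seq_len(nc) - 1L, each = nr)
  a <- section$anchoring
  if (a$type == "plane") {
    ax <- a$axis
    others <- setdiff(1:3, ax)
    vox <- matrix(0L, nr * nc, 3L)
    vox[, ax] <- as.integer(round(a$index))
    vox[, others[1]] <- i
    vox[, others[2]] <- j
  } else {
    cont <- cbind(i, j) %*% t(a$A)
    cont <- sweep(cont, 2L, as.numeric(a$b), "+")
    vox <- matrix(as.integer(ceiling(cont - 0.5)), ncol = 3L)
  }
  list(vox = vox, values = as.vector(v))
}

#' Place registered sections into an empty volume
#'
#' Rasterizes every section into the target space: voxels hit by a section
#' pixel carry its value and are marked known; voxels hit more than once
#' (overlapping or coincident sections) average their contributions; all
#' other voxels stay unknown. Sections mapping entirely outside the grid are
#' an error.
#'
#' @param stack A [section_stack()].
#' @param space An [atlas_space()].
#' @return List with `volume` (an [intensity_volume()], unknown voxels 0)
#'   and `known` (logical array marking voxels covered by a section).
#' @export
place_sections <- function(stack, space) {
  stopifnot(inherits(stack, "section_stack"))
  stopifnot_space(space)
  sh <- space$shape
  acc <- array(0, sh)
  hits <- array(0L, sh)
  for (si in seq_along(stack$sections)) {
    sv <- section_voxels(stack$sections[[si]], space)
    inside <- sv$vox[, 1] >= 0 & sv$vox[, 1] < sh[1] &
      sv$vox[, 2] >= 0 & sv$vox[, 2] < sh[2] &
      sv$vox[, 3] >= 0 & sv$vox[, 3] < sh[3]
    if (!any(inside)) {
      stop("section ", si, " maps entirely outside the target grid",
           call. = FALSE)
    }
    idx <- sv$vox[inside, 1] + sh[1] * (sv$vox[inside, 2] +
             sh[2] * sv$vox[inside, 3]) + 1
    vals <- sv$values[inside]
    # accumulate sums and hit counts; collisions average
    add <- tapply(vals, idx, sum)
    cnt <- tapply(vals, idx, length)
    at <- as.integer(names(add))
    acc[at] <- acc[at] + as.numeric(add)
    hits[at] <- hits[at] + as.integer(cnt)
  }
  known <- hits > 0L
  acc[known] <- acc[known] / hits[known]
  list(volume = intensity_volume(acc, space), known = known)
}

#' Distance-weighted K-nearest-neighbour infill
#'
#' Fills the gaps between placed sections: each unknown voxel receives the
#' inverse-distance-weighted mean of its `k` nearest known voxels (3D
#' Euclidean distance in voxels, weights `1/d`). Known voxels are left
#' untouched, so the operation is idempotent and the output is bounded by
#' the known-value range. An unknown voxel coinciding exactly with a known
#' one (distance 0) takes that value directly.
#'
#' @param volume An [intensity_volume()] with known values placed.
#' @param known Logical array marking the known voxels.
#' @param k Number of neighbours, default 4.
#' @param chunk Internal: unknown voxels are processed in chunks of this
#'   many to bound the distance-matrix memory. Default 2048.
#' @return An [intensity_volume()] with every voxel filled.
#' @export
knn_fill <- function(volume, known, k = 4L, chunk = 2048L) {
  if (!is_intensity_volume(volume)) {
    stop("`volume` must be an intensity_volume", call. = FALSE)
  }
  k <- as.integer(k)
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  known <- as.logical(known)
  dim(known) <- volume$space$shape
  n_known <- sum(known)
  if (n_known < k) {
    stop("k = ", k, " exceeds the number of known voxels (", n_known, ")",
         call. = FALSE)
  }
  if (all(known)) return(volume)
  xg <- grid_coords(volume$space$shape)
  kn <- which(known)
  un <- which(!known)
  kp <- xg[kn, , drop = FALSE]
  kv <- as.vector(volume$values)[kn]
  out <- volume$values
  kp2 <- rowSums(kp^2)
  for (start in seq(1L, length(un), by = chunk)) {
    idx <- un[start:min(start + chunk - 1L, length(un))]
    up <- xg[idx, , drop = FALSE]
    # squared distances unknown x known via the expanded inner product
    d2 <- outer(rowSums(up^2), kp2, "+") - 2 * up %*% t(kp)
    d2[d2 < 0] <- 0
    filled <- vapply(seq_len(nrow(d2)), function(r) {
      nn <- order(d2[r, ])[seq_len(k)]
      d <- sqrt(d2[r, nn])
      if (any(d == 0)) return(mean(kv[nn[d == 0]]))
      w <- 1 / d
      sum(w * kv[nn]) / sum(w)
    }, numeric(1))
    out[idx] <- filled
  }
  intensity_volume(out, volume$space)
}

#' Region-wise feature load (area fraction)
#'
#' For each region of an atlas map, the fraction of its pixels/voxels that
#' are positive for a segmented feature — e.g. the load of a marker's
#' expression per major brain region, with white-matter tracts and
#' ventricles excluded via `exclude_ids`.
#'
#' @param labels A [label_volume()] or a plain integer array/matrix of
#'   region ids (0 = background).
#' @param positive_mask Logical (or 0/1) array of the same shape marking
#'   feature-positive elements.
#' @param exclude_ids Integer region ids to omit (e.g. fibre tracts,
#'   ventricular system). Default none.
#' @return A tibble of class `region_load_table` with columns `region_id`,
#'   `region_name`, `load`, `pixels_region`, `pixels_positive`. Regions with
#'   zero pixels are omitted; background (0) is never reported.
#' @export
region_load <- function(labels, positive_mask, exclude_ids = integer(0)) {
  tab <- NULL
  if (is_label_volume(labels)) {
    tab <- labels$table
    lab <- labels$labels
  } else {
    lab <- labels
  }
  same_shape <- length(lab) == length(positive_mask) &&
    (is.null(dim(lab)) || is.null(dim(positive_mask)) ||
       all(dim(lab) == dim(positive_mask)))
  if (!same_shape) {
    stop("label map and positive mask shapes differ", call. = FALSE)
  }
  pos <- as.logical(positive_mask)
  ids <- as.vector(lab)
  keep <- ids != 0L & !(ids %in% exclude_ids)
  ids_kept <- ids[keep]
  pos_kept <- pos[keep]
  region <- sort(unique(ids_kept))
  n_region <- vapply(region, function(id) sum(ids_kept == id), integer(1))
  n_pos <- vapply(region, function(id) sum(pos_kept[ids_kept == id]),
                  integer(1))
  name_of <- function(id) {
    if (!is.null(tab)) {
      nm <- tab$name[tab$id == id]
      if (length(nm)) return(nm)
    }
    paste0("region_", id)
  }
  out <- tibble::tibble(
    region_id = as.integer(region),
    region_name = vapply(region, name_of, character(1)),
    load = n_pos / n_region,
    pixels_region = n_region,
    pixels_positive = n_pos)
  class(out) <- c("region_load_table", class(out))
  out
}

#' Temporal interpolation of expression volumes
#'
#' Given reconstructed expression volumes at a sparse set of data ages,
#' synthesizes volumes for intermediate ages: the two bracketing data-age
#' volumes are translated into the requested age's space through the
#' template chain and averaged with the same linear temporal weights used
#' for templates. A requested age that *is* a data age returns its own
#' volume unchanged.
#'
#' @param volumes Named list of [intensity_volume()] objects, names the data
#'   ages.
#' @param chain A [template_chain()].
#' @param ages_out Ages to synthesize.
#' @return Named list of [intensity_volume()] objects, one per requested
#'   age.
#' @export
expression_timeseries <- function(volumes, chain, ages_out) {
  stopifnot(is_template_chain(chain))
  data_ages <- sort(as.numeric(names(volumes)))
  if (!length(data_ages)) stop("no data volumes supplied", call. = FALSE)
  out <- vector("list", length(ages_out))
  names(out) <- as.character(ages_out)
  for (i in seq_along(ages_out)) {
    a <- ages_out[i]
    if (a %in% data_ages) {
      out[[i]] <- volumes[[as.character(a)]]
      next
    }
    if (a < min(data_ages) || a > max(data_ages)) {
      stop(sprintf(
        "age P%g lies outside the data bracket span P%g-P%g", a,
        min(data_ages), max(data_ages)), call. = FALSE)
    }
    lo <- max(data_ages[data_ages < a])
    hi <- min(data_ages[data_ages > a])
    f <- (a - lo) / (hi - lo)
    v_lo <- translate_volume(volumes[[as.character(lo)]], lo, a, chain)
    v_hi <- translate_volume(volumes[[as.character(hi)]], hi, a, chain)
    out[[i]] <- intensity_volume((1 - f) * v_lo$values + f * v_hi$values,
                                 v_lo$space)
  }
  out
}
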