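#' Downsample a volume by an integer factor
#'
#' Reduces resolution by block pooling: intensities take the block mean,
#' labels the block mode (ties broken toward the smaller id). Axis extents
#' that are not multiples of `factor` drop their trailing remainder voxels.
#' The spacing is multiplied by the factor — downsampling the 10 micrometre
#' adult reference by 2 yields the standard 20 micrometre working grid.
#'
#' @param vol An [intensity_volume()] or [label_volume()].
#' @param factor Integer >= 2.
#' @return A volume of the same class on the coarser grid.
#' @export
downsample <- function(vol, factor) {
  factor <- as.integer(factor)
  if (length(factor) != 1L || is.na(factor) || factor < 2L) {
    stop("`factor` must be an integer >= 2", call. = FALSE)
  }
  is_lab <- is_label_volume(vol)
  arr <- if (is_lab) vol$labels else vol$values
  sh <- dim(arr)
  new_sh <- sh %/% factor
  if (any(new_sh < 1L)) {
    stop("volume too small to downsample by ", factor, call. = FALSE)
  }
  arr <- arr[seq_len(new_sh[1] * factor), seq_len(new_sh[2] * factor),
             seq_len(new_sh[3] * factor), drop = FALSE]
  # expose the block structure as a 6D array, then pool over block axes
  dim(arr) <- c(factor, new_sh[1], factor, new_sh[2], factor, new_sh[3])
  arr <- aperm(arr, c(1, 3, 5, 2, 4, 6))
  dim(arr) <- c(factor^3, prod(new_sh))
  sp <- vol$space
  new_space <- atlas_space(sp$age, new_sh, sp$spacing * factor,
                           sp$origin / factor)
  if (is_lab) {
    pooled <- apply(arr, 2L, block_mode)
    dim(pooled) <- new_sh
    label_volume(pooled, new_space, table = vol$table)
  } else {
    pooled <- colMeans(arr)
    dim(pooled) <- new_sh
    intensity_volume(pooled, new_space)
  }
}

# Mode of a block of labels; ties toward the smaller id. Relies on
# tabulate-style counting over the sorted unique values.
block_mode <- function(v) {
  u <- sort(unique(v))
  if (length(u) == 1L) return(u)
  counts <- tabulate(match(v, u))
  u[which.max(counts)]   # which.max takes the first (= smallest id) on ties
}

#' Pad the posterior end of a volume
#'
#' Appends `n_voxels` zero-valued voxels at the high-index (posterior) end of
#' the anterior-posterior axis. Matching the rostrocaudal extent of the adult
#' reference to the developmental templates uses 45 voxels at 20 micrometres.
#' The origin is unchanged (padding happens beyond it) and the total
#' intensity is conserved.
#'
#' @param vol An [intensity_volume()] or [label_volume()].
#' @param n_voxels Non-negative integer.
#' @return The padded volume.
#' @export
pad_posterior <- function(vol, n_voxels) {
  n <- as.integer(n_voxels)
  if (length(n) != 1L || is.na(n) || n < 0L) {
    stop("`n_voxels` must be a non-negative integer", call. = FALSE)
  }
  if (n == 0L) return(vol)
  is_lab <- is_label_volume(vol)
  arr <- if (is_lab) vol$labels else vol$values
  sh <- dim(arr)
  out <- array(if (is_lab) 0L else 0, c(sh[1] + n, sh[2], sh[3]))
  out[seq_len(sh[1]), , ] <- arr
  sp <- vol$space
  new_space <- atlas_space(sp$age, dim(out), sp$spacing, sp$origin)
  if (is_lab) label_volume(out, new_space, table = vol$table)
  else intensity_volume(out, new_space)
}

#' Resample an anisotropic volume to an isotropic grid
#'
#' Converts a volume with per-axis spacings (for instance the 20 x 20 x 50
#' micrometre serial two-photon stacks) to an isotropic output spacing (20
#' micrometres standard) by separable linear interpolation along each axis
#' whose spacing changes. The output extent per axis is
#' `round(extent_phys / out_spacing)`; samples are taken at voxel centres,
#' with linear extension from the two nearest input samples at the ends, so
#' linear-ramp signals are reproduced exactly.
#'
#' @param vol An [intensity_volume()].
#' @param in_spacing Length-3 vector of input spacings in micrometres.
#' @param out_spacing Single isotropic output spacing in micrometres.
#' @return An [intensity_volume()] with isotropic `out_spacing`.
#' @export
resample_to_isotropic <- function(vol, in_spacing, out_spacing) {
  if (!is_intensity_volume(vol)) {
    stop("`vol` must be an intensity_volume", call. = FALSE)
  }
  in_spacing <- as.numeric(in_spacing)
  if (length(in_spacing) == 1L) in_spacing <- rep(in_spacing, 3L)
  if (length(in_spacing) != 3L || any(!is.finite(in_spacing)) ||
      any(in_spacing <= 0)) {
    stop("`in_spacing` must be three positive spacings", call. = FALSE)
  }
  if (length(out_spacing) != 1L || !is.finite(out_spacing) ||
      out_spacing <= 0) {
    stop("`out_spacing` must be a single positive spacing", call. = FALSE)
  }
  arr <- vol$values
  for (ax in 1:3) {
    if (isTRUE(all.equal(in_spacing[ax], out_spacing))) next
    n_in <- dim(arr)[ax]
    n_out <- max(1L, as.integer(round(n_in * in_spacing[ax] / out_spacing)))
    # voxel-centre positions in physical units along this axis
    pos_in <- (seq_len(n_in) - 0.5) * in_spacing[ax]
    pos_out <- (seq_len(n_out) - 0.5) * out_spacing
    arr <- apply_along(arr, ax, function(v) {
      interp_linear_extend(pos_in, v, pos_out)
    }, n_out)
  }
  sp <- vol$space
  intensity_volume(arr, atlas_space(sp$age, dim(arr), out_spacing, sp$origin))
}

# 1D linear interpolation with linear extension beyond the sample range
# (exact on affine signals end to end).
interp_linear_extend <- function(x, y, xout) {
  n <- length(x)
  if (n == 1L) return(rep(y, length(xout)))
  i <- findInterval(xout, x, all.inside = TRUE)
  x0 <- x[i]; x1 <- x[i + 1L]
  w <- (xout - x0) / (x1 - x0)
  y[i] * (1 - w) + y[i + 1L] * w
}

# Apply a length-changing function along one axis of a 3D array.
apply_along <- function(arr, axis, fn, n_out) {
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- aperm(arr, perm)
  d <- dim(a)
  m <- matrix(a, nrow = d[1])
  out <- apply(m, 2L, fn)
  dim(out) <- c(n_out, d[2], d[3])
  aperm(out, order(perm))
}

#' Align a volume to a reference origin
#'
#' Integer-voxel translation with zero fill, shifting the content so that
#' `origin_voxel` lands on `target_origin_voxel` (the convention used to
#' align all templates on a common anatomical reference origin). Content is
#' conserved except for voxels shifted out of the grid; the origin metadata
#' is updated to the target.
#'
#' @param vol An [intensity_volume()] or [label_volume()].
#' @param origin_voxel Current 0-based voxel index (length 3) of the
#'   anatomical origin.
#' @param target_origin_voxel Desired 0-based voxel index after alignment.
#' @return The shifted volume.
#' @export
align_origin <- function(vol, origin_voxel, target_origin_voxel) {
  shift <- round(as.numeric(target_origin_voxel) - as.numeric(origin_voxel))
  if (length(shift) != 3L || any(!is.finite(shift))) {
    stop("origins must be two length-3 voxel coordinates", call. = FALSE)
  }
  is_lab <- is_label_volume(vol)
  arr <- if (is_lab) vol$labels else vol$values
  sh <- dim(arr)
  out <- array(if (is_lab) 0L else 0, sh)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    s <- shift[ax]
    # destination index range receiving content, and matching source range
    dst_rng <- seq(max(1L, 1L + s), min(sh[ax], sh[ax] + s))
    if (!length(dst_rng)) return(rebuild_shifted(vol, out, target_origin_voxel))
    src[[ax]] <- dst_rng - s
    dst[[ax]] <- dst_rng
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  rebuild_shifted(vol, out, target_origin_voxel)
}

rebuild_shifted <- function(vol, out, new_origin) {
  sp <- vol$space
  new_space <- atlas_space(sp$age, sp$shape, sp$spacing,
                           as.numeric(new_origin))
  if (is_label_volume(vol)) label_volume(out, new_space, table = vol$table)
  else intensity_volume(out, new_space)
}

#' 3D contrast-limited adaptive histogram equalization
#'
#' Local contrast enhancement applied to templates before registration. The
#' volume is divided into a grid of tiles; each tile's histogram is clipped
#' at `clip_limit` times the uniform bin height (the clipped excess is
#' redistributed uniformly) and turned into an equalization mapping; each
#' voxel's output blends the mappings of its 8 surrounding tile centres
#' trilinearly, which removes tile-boundary artefacts.
#'
#' @param vol An [intensity_volume()].
#' @param clip_limit Histogram clip limit as a multiple of the uniform bin
#'   height; larger means stronger equalization. Default 3.
#' @param tile_shape Integer length-3 tile grid (number of tiles per axis).
#'   Default `c(4, 4, 4)`. Tiles larger than the volume trigger a
#'   single-tile fallback with a warning.
#' @param n_bins Number of histogram bins. Default 256.
#' @return An [intensity_volume()] with values in the input range.
#' @export
clahe3d <- function(vol, clip_limit = 3, tile_shape = c(4L, 4L, 4L),
                    n_bins = 256L) {
  if (!is_intensity_volume(vol)) {
    stop("`vol` must be an intensity_volume", call. = FALSE)
  }
  if (clip_limit <= 0) stop("`clip_limit` must be positive", call. = FALSE)
  tile_shape <- as.integer(rep_len(tile_shape, 3L))
  if (any(tile_shape < 1L)) {
    stop("`tile_shape` must be positive tile counts", call. = FALSE)
  }
  arr <- vol$values
  sh <- dim(arr)
  if (any(tile_shape > sh)) {
    warning("tile grid exceeds the volume extent; falling back to a single tile",
            call. = FALSE)
    tile_shape <- c(1L, 1L, 1L)
  }
  rng <- range(arr)
  if (rng[1] == rng[2]) return(vol)   # degenerate histogram: constant volume
  # quantize to bins over the input range
  q <- pmin(as.integer(floor((arr - rng[1]) / (rng[2] - rng[1]) * n_bins)),
            n_bins - 1L)
  dim(q) <- sh
  # tile centres (0-based voxel coordinates) and per-tile bounds
  bounds <- lapply(1:3, function(ax) {
    cut_pts <- round(seq(0, sh[ax], length.out = tile_shape[ax] + 1L))
    cbind(lo = cut_pts[-length(cut_pts)] + 1L, hi = cut_pts[-1])
  })
  centres <- lapply(1:3, function(ax) {
    (bounds[[ax]][, "lo"] + bounds[[ax]][, "hi"]) / 2 - 1  # 0-based
  })
  # per-tile clipped-equalization lookup tables: map bin -> output value
  luts <- array(0, c(n_bins, tile_shape))
  for (i in seq_len(tile_shape[1])) for (j in seq_len(tile_shape[2]))
    for (k in seq_len(tile_shape[3])) {
      block <- q[bounds[[1]][i, 1]:bounds[[1]][i, 2],
                 bounds[[2]][j, 1]:bounds[[2]][j, 2],
                 bounds[[3]][k, 1]:bounds[[3]][k, 2]]
      luts[, i, j, k] <- clahe_lut(block, n_bins, clip_limit, rng)
    }
  # trilinear blending of tile mappings at each voxel
  xg <- grid_coords(sh)
  tix <- tile_frac(xg[, 1], centres[[1]])
  tjy <- tile_frac(xg[, 2], centres[[2]])
  tkz <- tile_frac(xg[, 3], centres[[3]])
  qv <- as.vector(q) + 1L
  nb <- n_bins
  t1 <- tile_shape[1]; t12 <- tile_shape[1] * tile_shape[2]
  val <- function(i, j, k) {
    luts[qv + nb * ((i - 1L) + t1 * (j - 1L) + t12 * (k - 1L))]
  }
  out <-
    ((val(tix$i0, tjy$i0, tkz$i0) * (1 - tix$f) +
      val(tix$i1, tjy$i0, tkz$i0) * tix$f) * (1 - tjy$f) +
     (val(tix$i0, tjy$i1, tkz$i0) * (1 - tix$f) +
      val(tix$i1, tjy$i1, tkz$i0) * tix$f) * tjy$f) * (1 - tkz$f) +
    ((val(tix$i0, tjy$i0, tkz$i1) * (1 - tix$f) +
      val(tix$i1, tjy$i0, tkz$i1) * tix$f) * (1 - tjy$f) +
     (val(tix$i0, tjy$i1, tkz$i1) * (1 - tix$f) +
      val(tix$i1, tjy$i1, tkz$i1) * tix$f) * tjy$f) * tkz$f
  dim(out) <- sh
  intensity_volume(out, vol$space)
}

# Clipped-histogram equalization LUT for one tile: bin index -> output value
# in the original intensity range.
clahe_lut <- function(block_bins, n_bins, clip_limit, rng) {
  h <- tabulate(as.vector(block_bins) + 1L, nbins = n_bins)
  n <- sum(h)
  clip <- clip_limit * n / n_bins
  excess <- sum(pmax(h - clip, 0))
  h <- pmin(h, clip) + excess / n_bins
  cdf <- cumsum(h) / n
  rng[1] + cdf * (rng[2] - rng[1])
}

# Fractional position of 0-based coordinates among tile centres: indices of
# the bracketing tiles (1-based) and the blend fraction, clamped at the ends.
tile_frac <- function(x, centres) {
  nt <- length(centres)
  if (nt == 1L) return(list(i0 = rep(1L, length(x)), i1 = rep(1L, length(x)),
                            f = rep(0, length(x))))
  i0 <- findInterval(x, centres, all.inside = TRUE)
  f <- (x - centres[i0]) / (centres[i0 + 1L] - centres[i0])
  f <- pmin(pmax(f, 0), 1)
  list(i0 = i0, i1 = i0 + 1L, f = f)
}

#' Match volumes to a common mean foreground intensity
#'
#' Rescales each volume multiplicatively so that its foreground mean (voxels
#' strictly greater than zero; the backgrounds are zero-padded) equals the
#' grand mean of all foreground means. Zeros stay zero.
#'
#' @param vols List of [intensity_volume()] objects.
#' @return List of rescaled volumes, with the grand mean as attribute
#'   `"target_mean"`.
#' @export
match_mean_intensity <- function(vols) {
  if (!length(vols)) stop("`vols` must be a non-empty list", call. = FALSE)
  means <- vapply(vols, function(v) {
    fg <- v$values[v$values > 0]
    if (!length(fg)) {
      stop("a volume has no positive foreground voxels", call. = FALSE)
    }
    mean(fg)
  }, numeric(1))
  grand <- mean(means)
  out <- mapply(function(v, m) {
    intensity_volume(v$values * (grand / m), v$space)
  }, vols, means, SIMPLIFY = FALSE)
  attr(out, "target_mean") <- grand
  out
}
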