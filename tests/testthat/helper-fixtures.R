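# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately naive (plain loops, no shared code with the package
# internals) so they can stand as independent references.

space_at <- function(age, shape = c(16, 16, 16), spacing = 20) {
  atlas_space(age, shape, spacing)
}

# A smooth separable test volume (band-limited-ish) on a given grid.
smooth_volume <- function(space, freq = 1.5) {
  sh <- space$shape
  x <- (seq_len(sh[1]) - 1) / (sh[1] - 1)
  y <- (seq_len(sh[2]) - 1) / (sh[2] - 1)
  z <- (seq_len(sh[3]) - 1) / (sh[3] - 1)
  arr <- outer(outer(sin(pi * freq * x), cos(pi * freq * y)),
               sin(pi * (freq / 2) * z) + 1.2)
  intensity_volume(arr - min(arr), space)
}

# Independent trilinear sampler: one point at a time, plain arithmetic,
# clamped to the grid; returns `fill` if the unclamped point is outside.
oracle_trilinear <- function(arr, p, fill = 0) {
  sh <- dim(arr)
  if (any(p < 0) || any(p > sh - 1)) return(fill)
  i0 <- pmin(floor(p), sh - 2); f <- p - i0
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[1] else 1 - f[1]) *
         (if (dy) f[2] else 1 - f[2]) *
         (if (dz) f[3] else 1 - f[3])
    acc <- acc + w * arr[i0[1] + dx + 1, i0[2] + dy + 1, i0[3] + dz + 1]
  }
  acc
}

# Interior sub-array of a 3D or 4D (field) array, trimming m voxels per face.
interior <- function(arr, m = 4L) {
  d <- dim(arr)
  ix <- (m + 1):(d[1] - m); iy <- (m + 1):(d[2] - m); iz <- (m + 1):(d[3] - m)
  if (length(d) == 3L) arr[ix, iy, iz] else arr[ix, iy, iz, , drop = FALSE]
}

# Zero-deformation chain over the full standard anchor set (cheap: all
# backward fields are identically zero).
zero_chain <- function(ages = c(4, 7, 14, 21, 28, 56), shape = c(12, 10, 10)) {
  make_synthetic_chain(ages = ages, shape = shape, kind = "translation",
                       velocity = c(0, 0, 0))
}
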