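#' Phantom specification
#'
#' Describes a deterministic ellipsoidal brain phantom: a smooth intensity
#' bump with nested ellipsoidal label shells, whose semi-axes grow as an
#' affine function of age (a stand-in for templates whose brains grow with
#' age — the growth law only needs to be monotone, no biological realism is
#' claimed).
#'
#' The outer semi-axis along each axis is
#' `(base_frac + growth_per_day * age) * shape / 2` voxels; the intensity is
#' the smooth bump `(1 - rho^2)^2` of the normalized ellipsoidal radius
#' `rho`, zero outside, so warped copies can be compared under interpolation.
#' Labels split `rho <= 1` into `n_shells` nested shells (1 = innermost).
#'
#' @param age Postnatal day (4-56).
#' @param shape Grid shape (length 3).
#' @param n_shells Number of nested label shells, >= 3 recommended.
#' @param base_frac,growth_per_day Affine growth-law parameters (fractions
#'   of the half-extent). Defaults 0.45 and 0.006 keep the P56 phantom
#'   inside the grid.
#' @param centre Phantom centre in 0-based voxel coordinates; default grid
#'   centre.
#' @param noise_sd Standard deviation of optional additive intensity noise
#'   (default 0: fully deterministic).
#' @param seed Seed for the noise. Identical specs give bit-identical
#'   phantoms.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(age, shape, n_shells = 3L, base_frac = 0.45,
                         growth_per_day = 0.006, centre = NULL,
                         noise_sd = 0, seed = 1L) {
  shape <- as.integer(shape)
  frac <- base_frac + growth_per_day * age
  if (frac >= 1) {
    stop("growth law pushes the outer shell outside the grid (fraction ",
         round(frac, 3), " of the half-extent)", call. = FALSE)
  }
  if (frac <= 0) stop("non-positive phantom extent", call. = FALSE)
  if (is.null(centre)) centre <- (shape - 1) / 2
  structure(list(age = age, shape = shape, n_shells = as.integer(n_shells),
                 base_frac = base_frac, growth_per_day = growth_per_day,
                 centre = as.numeric(centre), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a phantom template and segmentation
#'
#' @param spec A [phantom_spec()].
#' @param spacing Voxel spacing in micrometres. Default 20.
#' @return List with `intensity` (an [intensity_volume()]) and `labels`
#'   (a [label_volume()] of nested shells, 1 = innermost).
#' @export
make_phantom <- function(spec, spacing = 20) {
  stopifnot(inherits(spec, "phantom_spec"))
  sh <- spec$shape
  semi <- (spec$base_frac + spec$growth_per_day * spec$age) * sh / 2
  xg <- grid_coords(sh)
  rho2 <- ((xg[, 1] - spec$centre[1]) / semi[1])^2 +
    ((xg[, 2] - spec$centre[2]) / semi[2])^2 +
    ((xg[, 3] - spec$centre[3]) / semi[3])^2
  inside <- rho2 < 1
  intens <- numeric(nrow(xg))
  intens[inside] <- (1 - rho2[inside])^2
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    intens[inside] <- pmax(intens[inside] +
                             stats::rnorm(sum(inside), 0, spec$noise_sd), 0)
  }
  lab <- integer(nrow(xg))
  lab[inside] <- pmin(ceiling(sqrt(rho2[inside]) * spec$n_shells),
                      spec$n_shells)
  lab[inside & rho2 == 0] <- 1L
  dim(intens) <- sh
  dim(lab) <- sh
  space <- atlas_space(spec$age, sh, spacing)
  list(intensity = intensity_volume(intens, space),
       labels = label_volume(lab, space,
                             table = label_table(seq_len(spec$n_shells),
                                                 names = paste0("shell_",
                                                   seq_len(spec$n_shells)))))
}

#' Analytic warp fields with known inverses
#'
#' Closed-form displacement fields used as oracles for the field algebra:
#'
#' * `translation`: constant displacement `delta`; inverse is `-delta`.
#' * `centred_scaling`: `U(x) = (a - 1) * (x - centre)`; inverse has scale
#'   `1/a`.
#' * `sinusoidal`: `U_d(x) = amplitude * sin(2 * pi * x_d / period)` per
#'   axis; invertible when `amplitude * 2 * pi / period < 1` (the gradient
#'   bound), enforced with an error.
#'
#' For the closed-form kinds the exact inverse parameters are attached as
#' attribute `"inverse_params"`.
#'
#' @param kind `"translation"`, `"centred_scaling"` or `"sinusoidal"`.
#' @param params List: `delta` (translation); `a` and optional `centre`
#'   (scaling); `amplitude` and `period` (sinusoidal).
#' @param source,target [atlas_space()] objects sharing one grid.
#' @return A [displacement_field()].
#' @export
make_analytic_field <- function(kind = c("translation", "centred_scaling",
                                         "sinusoidal"),
                                params, source, target) {
  kind <- match.arg(kind)
  sh <- target$shape
  xg <- grid_coords(sh)
  disp <- switch(kind,
    translation = {
      d <- as.numeric(params$delta)
      cbind(rep(d[1], nrow(xg)), rep(d[2], nrow(xg)), rep(d[3], nrow(xg)))
    },
    centred_scaling = {
      a <- as.numeric(params$a)
      if (length(a) == 1L) a <- rep(a, 3L)
      ctr <- if (is.null(params$centre)) (sh - 1) / 2 else
        as.numeric(params$centre)
      cbind((a[1] - 1) * (xg[, 1] - ctr[1]),
            (a[2] - 1) * (xg[, 2] - ctr[2]),
            (a[3] - 1) * (xg[, 3] - ctr[3]))
    },
    sinusoidal = {
      A <- as.numeric(params$amplitude)
      per <- as.numeric(params$period)
      if (A * 2 * pi / per >= 1) {
        stop("sinusoidal field not invertible: amplitude * 2*pi/period = ",
             round(A * 2 * pi / per, 3), " >= 1", call. = FALSE)
      }
      cbind(A * sin(2 * pi * xg[, 1] / per),
            A * sin(2 * pi * xg[, 2] / per),
            A * sin(2 * pi * xg[, 3] / per))
    })
  dim(disp) <- c(sh, 3L)
  out <- displacement_field(disp, source, target)
  attr(out, "inverse_params") <- switch(kind,
    translation = list(kind = kind, delta = -as.numeric(params$delta)),
    centred_scaling = {
      a <- as.numeric(params$a)
      list(kind = kind, a = 1 / a,
           centre = if (is.null(params$centre)) (sh - 1) / 2 else
             params$centre)
    },
    NULL)
  out
}

#' Simulate rater annotations around ground-truth landmarks
#'
#' Each rater's coordinate is the true landmark plus isotropic Gaussian
#' noise — the simplest exchangeable model of independent expert
#' annotators. Optionally adds `"matrix"` rows (the transform under test)
#' with their own noise level, and replicates the table across ages.
#'
#' @param true_landmarks A [point_set()] or n x 3 matrix of true voxel
#'   coordinates.
#' @param n_raters Number of simulated raters. Default 4.
#' @param noise_sd Rater noise standard deviation in voxels.
#' @param seed Integer seed; identical seeds give identical tables.
#' @param ages Ages to replicate over. Default 14.
#' @param matrix_sd If non-`NULL`, also simulate `"matrix"` coordinates with
#'   this noise level.
#' @param spacing Spacing stored on the table (micrometres). Default 20.
#' @return A [landmark_table()].
#' @export
simulate_raters <- function(true_landmarks, n_raters = 4L, noise_sd = 1,
                            seed = 1L, ages = 14, matrix_sd = NULL,
                            spacing = 20) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  pts <- if (is_point_set(true_landmarks)) true_landmarks$points else
    coerce_points(true_landmarks)
  n <- nrow(pts)
  set.seed(seed)
  rows <- list()
  for (a in ages) {
    for (r in seq_len(n_raters)) {
      jit <- matrix(stats::rnorm(3L * n, 0, noise_sd), ncol = 3L)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        landmark_id = sprintf("lm_%03d", seq_len(n)),
        rater_id = paste0("rater_", r), age = a,
        x = pts[, 1] + jit[, 1], y = pts[, 2] + jit[, 2],
        z = pts[, 3] + jit[, 3])
    }
    if (!is.null(matrix_sd)) {
      jit <- matrix(stats::rnorm(3L * n, 0, matrix_sd), ncol = 3L)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        landmark_id = sprintf("lm_%03d", seq_len(n)),
        rater_id = "matrix", age = a,
        x = pts[, 1] + jit[, 1], y = pts[, 2] + jit[, 2],
        z = pts[, 3] + jit[, 3])
    }
  }
  landmark_table(dplyr::bind_rows(rows), spacing = spacing)
}

#' Extract every step-th slice as a registered section stack
#'
#' Emulates serial sectioning: orthogonal slices at indices
#' `0, step, 2*step, ...` along `axis`, each with exact plane anchoring, so
#' [place_sections()] followed by [knn_fill()] can be tested against the
#' original volume.
#'
#' @param volume An [intensity_volume()].
#' @param axis Sectioning axis (1 = AP, 2 = SI, 3 = LR).
#' @param step Slice period, >= 1.
#' @return A [section_stack()].
#' @export
make_sparse_sections <- function(volume, axis = 1L, step = 2L) {
  if (!axis %in% 1:3) stop("`axis` must be 1, 2 or 3", call. = FALSE)
  step <- as.integer(step)
  if (step < 1L) stop("`step` must be >= 1", call. = FALSE)
  sh <- volume$space$shape
  idx <- seq(0L, sh[axis] - 1L, by = step)
  sections <- lapply(idx, function(i) {
    sl <- switch(axis,
                 volume$values[i + 1L, , ],
                 volume$values[, i + 1L, ],
                 volume$values[, , i + 1L])
    list(values = as.matrix(sl),
         anchoring = list(type = "plane", axis = axis, index = i))
  })
  section_stack(sections)
}

#' Build a fully synthetic template chain
#'
#' Assembles a [template_chain()] of growing phantoms linked by analytic
#' backward fields, the end-to-end fixture for translation and interpolation
#' tests:
#'
#' * `kind = "translation"`: every template is the same phantom displaced by
#'   `velocity` voxels per day; backward fields are the exact constant
#'   displacements, so interpolated centroids must move linearly with age.
#' * `kind = "centred_scaling"`: phantoms grow by the affine law and each
#'   backward field is the centred scaling mapping the older onto the
#'   younger phantom exactly.
#'
#' @param ages Anchor ages, strictly increasing. Default `c(4, 7, 14)`.
#' @param shape Shared grid shape. Default `c(48, 40, 40)`.
#' @param kind Field family linking the anchors.
#' @param velocity Voxels of displacement per day of age (translation kind).
#' @param spacing Micrometres per voxel. Default 20.
#' @param ... Extra arguments passed to [phantom_spec()].
#' @return A [template_chain()] with attribute `"truth"` describing the
#'   generating parameters (for oracle checks).
#' @export
make_synthetic_chain <- function(ages = c(4, 7, 14), shape = c(48, 40, 40),
                                 kind = c("translation", "centred_scaling"),
                                 velocity = c(0.3, 0.15, 0), spacing = 20,
                                 ...) {
  kind <- match.arg(kind)
  shape <- as.integer(shape)
  centre0 <- (shape - 1) / 2
  templates <- list()
  truth <- list(kind = kind, ages = ages)
  if (kind == "translation") {
    velocity <- as.numeric(velocity)
    truth$velocity <- velocity
    truth$centres <- t(vapply(ages, function(a)
      centre0 + (a - ages[1]) * velocity, numeric(3)))
    for (i in seq_along(ages)) {
      spec <- phantom_spec(ages[i], shape,
                           centre = truth$centres[i, ],
                           growth_per_day = 0, ...)
      templates[[i]] <- make_phantom(spec, spacing = spacing)$intensity
    }
    fields <- list()
    for (i in seq_len(length(ages) - 1L)) {
      y <- ages[i]; o <- ages[i + 1L]
      # backward: indexed on the younger grid, reads the older template at
      # x + (o - y) * velocity (the structure sits that much further along)
      fields[[i]] <- make_analytic_field(
        "translation", list(delta = (o - y) * velocity),
        source = atlas_space(o, shape, spacing),
        target = atlas_space(y, shape, spacing))
    }
  } else {
    for (i in seq_along(ages)) {
      spec <- phantom_spec(ages[i], shape, ...)
      templates[[i]] <- make_phantom(spec, spacing = spacing)$intensity
    }
    base_frac <- list(...)$base_frac %||% 0.45
    growth <- list(...)$growth_per_day %||% 0.006
    truth$scale_per_pair <- vapply(seq_len(length(ages) - 1L), function(i) {
      (base_frac + growth * ages[i + 1L]) / (base_frac + growth * ages[i])
    }, numeric(1))
    fields <- list()
    for (i in seq_len(length(ages) - 1L)) {
      y <- ages[i]; o <- ages[i + 1L]
      # reading the older template at coordinates expanded by the size ratio
      # shrinks it onto the younger phantom
      fields[[i]] <- make_analytic_field(
        "centred_scaling", list(a = truth$scale_per_pair[i], centre = centre0),
        source = atlas_space(o, shape, spacing),
        target = atlas_space(y, shape, spacing))
    }
  }
  chain <- template_chain(templates, fields)
  attr(chain, "truth") <- truth
  chain
}

`%||%` <- function(a, b) if (is.null(a)) b else a
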