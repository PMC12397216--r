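src <- function(shape = c(16, 16, 16)) atlas_space(28, shape)
tgt <- function(shape = c(16, 16, 16)) atlas_space(14, shape)

test_that("warping with the zero field is the identity", {
  sp <- src(); vol <- smooth_volume(sp)
  out <- warp_volume(vol, zero_field(sp, tgt()))
  expect_identical(out$values, vol$values)
  expect_equal(out$space$age, 14)
})

test_that("a constant pull field shifts content the opposite way", {
  sp <- src(); arr <- array(0, sp$shape); arr[11, 6, 6] <- 1  # voxel (10,5,5)
  f <- make_analytic_field("translation", list(delta = c(2, 0, 0)), sp, tgt())
  out <- warp_volume(intensity_volume(arr, sp), f)
  expect_equal(out$values[9, 6, 6], 1)   # lands at voxel (8,5,5)
  expect_equal(sum(out$values), 1)
})

test_that("warping matches an independent brute-force trilinear evaluator", {
  sp <- src(); vol <- smooth_volume(sp)
  f <- make_analytic_field("sinusoidal",
                           list(amplitude = 0.8, period = 12), sp, tgt())
  out <- warp_volume(vol, f)
  sh <- sp$shape
  for (p in list(c(3, 4, 5), c(7, 7, 7), c(0, 0, 0), c(12, 9, 14))) {
    u <- 0.8 * sin(2 * pi * p / 12)
    expect_lt(abs(out$values[p[1] + 1, p[2] + 1, p[3] + 1] -
                    oracle_trilinear(vol$values, p + u)), 1e-6)
  }
})

test_that("point mapping follows the pull-field duality", {
  sp <- src(); ps <- point_set(rbind(c(3, 4, 5), c(8.5, 7.25, 2)), tgt())
  expect_equal(map_points(ps, zero_field(sp, tgt()))$points, ps$points)
  f <- make_analytic_field("translation", list(delta = c(1, -2, 0.5)),
                           sp, tgt())
  expect_equal(map_points(ps, f)$points,
               sweep(ps$points, 2, c(1, -2, 0.5), "+"))
  # linear scaling field: closed-form affine map
  fsc <- make_analytic_field("centred_scaling", list(a = 1.2), sp, tgt())
  ctr <- (sp$shape - 1) / 2
  got <- map_points(ps, fsc)$points
  want <- sweep(sweep(ps$points, 2, ctr, "-") * 1.2, 2, ctr, "+")
  expect_lt(max(abs(got - want)), 1e-6)
  expect_error(map_points(point_set(c(1, 1, 1), src()), f), "P28")
})

test_that("inversion recovers closed-form inverses", {
  sp <- src(); tg <- tgt()
  z <- invert_field(zero_field(sp, tg))
  expect_equal(max(abs(z$displacement)), 0)
  expect_equal(z$target$age, 28)
  f <- make_analytic_field("translation", list(delta = c(1.5, -0.5, 2)),
                           sp, tg)
  inv <- invert_field(f)
  expect_lt(max(abs(sweep(matrix(inv$displacement, ncol = 3), 2,
                          -c(1.5, -0.5, 2), "-"))), 1e-12)
  fs <- make_analytic_field("centred_scaling", list(a = 1.25), sp, tg)
  inv <- invert_field(fs, tol = 0.05)
  ip <- attr(fs, "inverse_params")
  truth <- make_analytic_field("centred_scaling",
                               list(a = ip$a, centre = ip$centre), tg, sp)
  expect_lt(max(abs(interior(inv$displacement) -
                      interior(truth$displacement))), 0.05)
  expect_lte(attr(inv, "residual"), 0.5)   # quality metric is attached
  expect_true(is.numeric(attr(inv, "iterations")))
})

test_that("composition has the expected algebra", {
  sp28 <- atlas_space(28, c(16, 16, 16))
  sp14 <- atlas_space(14, c(16, 16, 16))
  sp7 <- atlas_space(7, c(16, 16, 16))
  f <- make_analytic_field("sinusoidal", list(amplitude = 0.5, period = 10),
                           sp28, sp14)
  expect_equal(compose_fields(f, displacement_field(
    array(0, c(16, 16, 16, 3)), sp14, sp7))$displacement,
    f$displacement, tolerance = 1e-12)
  c1 <- make_analytic_field("translation", list(delta = c(1, 0, -1)),
                            sp28, sp14)
  c2 <- make_analytic_field("translation", list(delta = c(0.5, 2, 0)),
                            sp14, sp7)
  comp <- compose_fields(outer = c1, inner = c2)
  expect_equal(comp$source$age, 28); expect_equal(comp$target$age, 7)
  expect_equal(matrix(comp$displacement, ncol = 3)[1, ], c(1.5, 2, -1))
  # centred scalings compose to the product scaling
  s1 <- make_analytic_field("centred_scaling", list(a = 1.1), sp28, sp14)
  s2 <- make_analytic_field("centred_scaling", list(a = 1.15), sp14, sp7)
  comp <- compose_fields(s1, s2)
  want <- make_analytic_field("centred_scaling", list(a = 1.1 * 1.15),
                              sp28, sp7)
  expect_lt(max(abs(interior(comp$displacement) -
                      interior(want$displacement))), 1e-4)
  expect_error(compose_fields(s2, s1), "cannot chain")
})

test_that("temporal scaling is linear in the fraction", {
  sp <- src(); tg <- tgt()
  f <- make_analytic_field("translation", list(delta = c(2, -4, 6)), sp, tg)
  expect_equal(max(abs(scale_field(f, 0)$displacement)), 0)
  expect_identical(scale_field(f, 1)$displacement, f$displacement)
  expect_equal(matrix(scale_field(f, 0.5)$displacement, ncol = 3)[5, ],
               c(1, -2, 3))
  expect_error(scale_field(f, 1.5), "\\[0, 1\\]")
  expect_error(scale_field(f, -0.1), "\\[0, 1\\]")
})

test_that("warp-then-inverse recovers a smooth volume on the interior", {
  sp <- src(c(24, 24, 24)); tg <- tgt(c(24, 24, 24))
  vol <- smooth_volume(sp)
  f <- make_analytic_field("sinusoidal", list(amplitude = 0.6, period = 14),
                           sp, tg)
  back <- warp_volume(warp_volume(vol, f), invert_field(f))
  rng <- diff(range(vol$values))
  expect_lt(max(abs(interior(back$values) - interior(vol$values))) / rng,
            0.02)
})

test_that("point round trips and double inversion stay within tolerance", {
  sp <- src(c(20, 20, 20)); tg <- tgt(c(20, 20, 20))
  f <- make_analytic_field("sinusoidal", list(amplitude = 0.6, period = 12),
                           sp, tg)
  inv <- invert_field(f, tol = 0.05)
  set.seed(42)
  pts <- point_set(matrix(runif(90, 4, 15), ncol = 3), tg)
  there <- map_points(pts, f)          # P14 points -> P28
  back <- map_points(there, inv)       # and back
  expect_lt(max(abs(back$points - pts$points)), 2 * 0.05)
  twice <- invert_field(inv, tol = 0.05)
  expect_lt(max(abs(interior(twice$displacement) -
                      interior(f$displacement))), 2 * 0.05)
})

test_that("nearest-mode warping never invents label ids", {
  sp <- src(); tg <- tgt()
  set.seed(7)
  lab <- array(sample(c(0L, 3L, 5L, 9L), prod(sp$shape), replace = TRUE),
               sp$shape)
  lv <- label_volume(lab, sp)
  for (f in list(
    make_analytic_field("sinusoidal", list(amplitude = 0.9, period = 9),
                        sp, tg),
    make_analytic_field("centred_scaling", list(a = 1.3), sp, tg),
    make_analytic_field("translation", list(delta = c(3.7, -2.2, 0.5)),
                        sp, tg))) {
    out <- warp_volume(lv, f, mode = "nearest")
    expect_true(all(unique(as.vector(out$labels)) %in%
                      c(0L, unique(as.vector(lab)))))
  }
  expect_error(warp_volume(lv, zero_field(sp, tg), mode = "linear"),
               "nearest")
})

test_that("composition is associative on smooth fields", {
  mk <- function(a, s, t) make_analytic_field("centred_scaling",
                                              list(a = a), s, t)
  s56 <- atlas_space(56, c(16, 16, 16)); s28 <- atlas_space(28, c(16, 16, 16))
  s14 <- atlas_space(14, c(16, 16, 16)); s7 <- atlas_space(7, c(16, 16, 16))
  f1 <- mk(1.08, s56, s28); f2 <- mk(1.1, s28, s14); f3 <- mk(1.12, s14, s7)
  left <- compose_fields(compose_fields(f1, f2), f3)
  right <- compose_fields(f1, compose_fields(f2, f3))
  expect_lt(max(abs(interior(left$displacement) -
                      interior(right$displacement))), 1e-3)
})

test_that("mismatched spaces are rejected with ages named", {
  sp <- src(); tg <- tgt()
  vol <- smooth_volume(atlas_space(7, sp$shape))
  expect_error(warp_volume(vol, zero_field(sp, tg)), "P7")
})
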