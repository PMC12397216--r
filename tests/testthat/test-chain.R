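full_chain <- zero_chain()   # anchors 4,7,14,21,28,56; zero deformations

test_that("neighbors returns the tightest bracketing anchors", {
  expect_equal(neighbors(8, full_chain), c(7, 14))
  expect_equal(neighbors(14, full_chain), c(14, 14))
  expect_equal(neighbors(30, full_chain), c(28, 56))
  expect_error(neighbors(57, full_chain), "span")
})

test_that("interpolation weights are linear, monotone and sum to one", {
  p8 <- plan_interpolation(8, full_chain)
  expect_equal(p8$fraction, 1 / 7)
  expect_equal(p8$weight_young, 6 / 7)
  expect_equal(p8$weight_old, 1 / 7)
  p27 <- plan_interpolation(27, full_chain)       # mirror case
  expect_equal(p27$weight_young, 1 / 7)
  expect_equal(p27$weight_old, 6 / 7)
  mid <- plan_interpolation(10.5, full_chain)     # midpoint of (7, 14)
  expect_equal(mid$weight_young, 0.5)
  anchor <- plan_interpolation(21, full_chain)    # degenerate: weight 1
  expect_equal(anchor$weight_young, 1)
  expect_equal(anchor$weight_old, 0)
  ws <- vapply(seq(7.5, 13.5, by = 0.5), function(t)
    plan_interpolation(t, full_chain)$weight_young, numeric(1))
  expect_true(all(diff(ws) < 0))                  # monotone decreasing in t
  expect_true(all(abs(vapply(seq(5, 55), function(t) {
    p <- plan_interpolation(t, full_chain); p$weight_young + p$weight_old
  }, numeric(1)) - 1) < 1e-12))
})

test_that("anchor-age template requests are bit-identical", {
  got <- make_intermediate_template(14, full_chain)
  expect_identical(got, full_chain$templates[["14"]])
})

test_that("constant templates interpolate to a constant (convexity)", {
  sp <- function(a) atlas_space(a, c(8, 8, 8))
  ones <- function(a) intensity_volume(array(1, c(8, 8, 8)), sp(a))
  ch <- template_chain(list(ones(7), ones(14)),
                       list(zero_field(sp(14), sp(7))))
  m <- make_intermediate_template(9, ch)
  expect_true(all(abs(m$values - 1) < 1e-12))
})

test_that("interpolated centroids follow the known linear trajectory", {
  ch <- make_synthetic_chain(ages = c(4, 7, 14), shape = c(40, 36, 36),
                             velocity = c(0.3, 0.15, 0))
  truth <- attr(ch, "truth")
  c0 <- (c(40, 36, 36) - 1) / 2
  for (t in c(5, 6, 9, 12)) {
    m <- make_intermediate_template(t, ch)
    predicted <- c0 + (t - 4) * truth$velocity
    expect_lt(max(abs(volume_centroid(m) - predicted)), 0.25)
  }
})

test_that("routes decompose into the expected pairwise steps", {
  r <- build_route(56, 4, full_chain)
  expect_equal(vapply(r$steps, `[[`, numeric(1), "from"), c(56, 28, 21, 14, 7))
  expect_equal(vapply(r$steps, `[[`, numeric(1), "to"), c(28, 21, 14, 7, 4))
  expect_true(all(vapply(r$steps, `[[`, numeric(1), "fraction") == 1))
  expect_true(all(vapply(r$steps, `[[`, character(1), "direction") ==
                    "backward"))
  expect_length(build_route(14, 14, full_chain)$steps, 0)
  # a non-anchor endpoint contributes a single fractional terminal step
  r35 <- build_route(56, 35, full_chain)
  expect_length(r35$steps, 1L)
  expect_equal(r35$steps[[1]]$fraction, (56 - 35) / 28)
  expect_equal(r35$steps[[1]]$direction, "backward")
  expect_equal(r35$steps[[1]]$field$source$age, 56)
  expect_equal(r35$steps[[1]]$field$target$age, 35)
  # ascending mirror: forward steps via inversion
  r_up <- build_route(4, 56, full_chain)
  expect_true(all(vapply(r_up$steps, `[[`, character(1), "direction") ==
                    "forward"))
  expect_equal(vapply(r_up$steps, `[[`, numeric(1), "to"),
               c(7, 14, 21, 28, 56))
})

test_that("single-step volume translation reduces to a direct warp", {
  ch <- make_synthetic_chain(ages = c(21, 28), shape = c(20, 20, 20),
                             velocity = c(0.4, 0, -0.2))
  vol <- ch$templates[["28"]]
  via_route <- translate_volume(vol, 28, 21, ch)
  direct <- warp_volume(vol, ch$backward_fields[["28->21"]])
  expect_identical(via_route$values, direct$values)
  same <- translate_volume(vol, 28, 28, ch)
  expect_identical(same, vol)
})

test_that("volume round trips through intermediate ages stay accurate", {
  ch <- make_synthetic_chain(ages = c(4, 7, 14), shape = c(32, 28, 28),
                             velocity = c(0.25, 0.1, 0))
  ph <- make_phantom(phantom_spec(14, c(32, 28, 28)))$intensity
  there <- translate_volume(ph, 14, 5, ch)
  back <- translate_volume(there, 5, 14, ch)
  rng <- diff(range(ph$values))
  expect_lt(max(abs(interior(back$values, 5) -
                      interior(ph$values, 5))) / rng, 0.02)
})

test_that("segmentations only travel down from the adult space", {
  ch <- make_synthetic_chain(ages = c(21, 28), shape = c(24, 24, 24),
                             kind = "centred_scaling")
  ph <- make_phantom(phantom_spec(28, c(24, 24, 24)))
  lab28 <- label_volume(ph$labels$labels, atlas_space(28, c(24, 24, 24)),
                        table = ph$labels$table)
  expect_identical(transform_segmentation(lab28, 28, ch), lab28)
  down <- transform_segmentation(lab28, 21, ch)
  expect_true(all(unique(as.vector(down$labels)) %in%
                    c(0L, unique(as.vector(lab28$labels)))))
  # exact agreement with a brute-force nearest-neighbour resampling oracle
  a <- attr(ch, "truth")$scale_per_pair[1]
  ctr <- (c(24, 24, 24) - 1) / 2
  sh <- c(24L, 24L, 24L)
  oracle <- array(0L, sh)
  for (i in 0:(sh[1] - 1)) for (j in 0:(sh[2] - 1)) for (k in 0:(sh[3] - 1)) {
    p <- ctr + a * (c(i, j, k) - ctr)
    q <- pmin(pmax(ceiling(p - 0.5), 0), sh - 1)
    inside <- all(p >= 0) && all(p <= sh - 1)
    oracle[i + 1, j + 1, k + 1] <-
      if (inside) lab28$labels[q[1] + 1, q[2] + 1, q[3] + 1] else 0L
  }
  expect_identical(down$labels, oracle)
  for (id in sort(unique(as.vector(oracle)))) {
    expect_equal(sum(down$labels == id), sum(oracle == id))
  }
  expect_error(transform_segmentation(lab28, 56, ch), "down")
  lab21 <- transform_segmentation(lab28, 21, ch)
  expect_error(transform_segmentation(lab21, 14, ch), "adult")
})

test_that("zero-field chains leave segmentations unchanged at every age", {
  sh <- c(12, 10, 10)
  ph <- make_phantom(phantom_spec(56, sh))
  lab <- label_volume(ph$labels$labels, atlas_space(56, sh),
                      table = ph$labels$table)
  for (t in c(28, 14, 9, 4)) {
    out <- transform_segmentation(lab, t, full_chain)
    expect_equal(out$labels, ph$labels$labels, ignore_attr = TRUE)
  }
})

test_that("point translation round trips within 0.1 voxel", {
  ch <- make_synthetic_chain(ages = c(4, 7, 14), shape = c(32, 28, 28),
                             velocity = c(0.25, 0.1, 0))
  set.seed(11)
  pts <- point_set(cbind(runif(50, 6, 25), runif(50, 6, 21),
                         runif(50, 6, 21)), atlas_space(14, c(32, 28, 28)))
  same <- translate_points(pts, 14, 14, ch)
  expect_identical(same$points, pts$points)
  down <- translate_points(pts, 14, 4, ch)
  # pure translation chain: exact closed form
  expect_lt(max(abs(down$points -
                      sweep(pts$points, 2, 10 * c(0.25, 0.1, 0), "-"))),
            0.1)
  back <- translate_points(down, 4, 14, ch)
  expect_lt(max(abs(back$points - pts$points)), 0.1)
})

test_that("compile_4d accounts for every integer age and splits cleanly", {
  series <- compile_4d(full_chain, split = list(c(4, 20), c(21, 37),
                                                c(38, 56)))
  expect_equal(nrow(series$manifest), 53L)
  expect_equal(sum(series$manifest$kind == "interpolated"), 47L)
  expect_equal(sum(series$manifest$kind == "template"), 6L)
  expect_length(series$series, 3L)
  expect_equal(vapply(series$series, length, integer(1)),
               c("P4-P20" = 17L, "P21-P37" = 17L, "P38-P56" = 19L))
  # anchors verbatim
  expect_identical(series$volumes[["21"]], full_chain$templates[["21"]])
  anchors_only <- compile_4d(full_chain, ages = 4:7)
  expect_equal(sum(anchors_only$manifest$kind == "interpolated"), 2L)
  sub <- compile_4d(full_chain, ages = 14:21)
  expect_equal(sum(sub$manifest$kind == "template"), 2L)
  expect_error(compile_4d(full_chain, ages = c(4, 6, 8)), "contiguous")
})
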