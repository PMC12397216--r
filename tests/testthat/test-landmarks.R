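# Small deterministic four-rater table builder: truth plus fixed offsets.
toy_table <- function(truth, offsets, matrix_at = NULL, age = 14,
                      spacing = 20) {
  rows <- list()
  for (r in seq_along(offsets)) {
    rows[[r]] <- tibble::tibble(
      landmark_id = sprintf("lm_%02d", seq_len(nrow(truth))),
      rater_id = paste0("rater_", r), age = age,
      x = truth[, 1] + offsets[[r]][1], y = truth[, 2] + offsets[[r]][2],
      z = truth[, 3] + offsets[[r]][3])
  }
  if (!is.null(matrix_at)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      landmark_id = sprintf("lm_%02d", seq_len(nrow(truth))),
      rater_id = "matrix", age = age,
      x = matrix_at[, 1], y = matrix_at[, 2], z = matrix_at[, 3])
  }
  landmark_table(dplyr::bind_rows(rows), spacing = spacing)
}

test_that("the reference coordinate is the componentwise median", {
  pt <- c(4, 5, 6)
  expect_equal(median_of_others(rbind(pt, pt, pt)), pt,
               ignore_attr = TRUE)
  coords <- rbind(c(0, 1, 2), c(10, 1, 2), c(40, 1, 2))
  expect_equal(median_of_others(coords)[1], 10)
  # two remaining raters: componentwise midpoint
  expect_equal(median_of_others(rbind(c(0, 0, 0), c(4, 2, 6))), c(2, 1, 3),
               ignore_attr = TRUE)
  expect_error(median_of_others(rbind(pt, pt), exclude = 1), "2 remaining")
})

test_that("rater error is the mean micrometre distance to the others' median", {
  truth <- matrix(rep(c(10, 10, 10), 6), ncol = 3, byrow = TRUE)
  tab <- toy_table(truth, list(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0),
                               c(5, 0, 0)))
  # three raters agree; the fourth sits 5 voxels off -> 100 um at 20 um
  expect_equal(rater_error(tab, "rater_4", 14)$mean, 100)
  expect_equal(rater_error(tab, "rater_1", 14)$mean, 0)
  ident <- toy_table(truth, rep(list(c(0, 0, 0)), 4))
  for (r in paste0("rater_", 1:4)) {
    expect_equal(rater_error(ident, r, 14)$mean, 0)
  }
  expect_error(rater_error(tab, "rater_9", 14), "rater_9")
})

test_that("landmarks not identified by all raters are excluded", {
  truth <- matrix(runif(15, 5, 20), ncol = 3)
  tab <- toy_table(truth, rep(list(c(0, 0, 0)), 4))
  tab2 <- tab[!(tab$landmark_id == "lm_01" & tab$rater_id == "rater_2"), ]
  attr(tab2, "spacing") <- 20
  class(tab2) <- class(tab)
  re <- rater_error(tab2, "rater_1", 14)
  expect_false("lm_01" %in% names(re$per_landmark))
  expect_length(re$per_landmark, 4L)
})

test_that("matrix error equals exhaustive subset enumeration", {
  # all raters at the origin, matrix at a 3-4-5 offset: 100 um
  truth <- matrix(rep(0, 12), ncol = 3)
  tab <- toy_table(truth, rep(list(c(0, 0, 0)), 4),
                   matrix_at = matrix(rep(c(3, 4, 0), 4), ncol = 3,
                                      byrow = TRUE))
  expect_equal(matrix_error(tab, 14)$mean, 100)
  coincide <- toy_table(truth, rep(list(c(0, 0, 0)), 4),
                        matrix_at = truth)
  expect_equal(matrix_error(coincide, 14)$mean, 0)
  # random table against an independent enumeration oracle
  set.seed(21)
  truth <- matrix(runif(24, 5, 25), ncol = 3)
  offs <- lapply(1:4, function(i) rnorm(3))
  mx <- truth + matrix(rnorm(24, 0, 2), ncol = 3)
  tab <- toy_table(truth, offs, matrix_at = mx)
  got <- matrix_error(tab, 14)
  oracle <- vapply(seq_len(nrow(truth)), function(lm) {
    rater_pts <- t(vapply(1:4, function(r) truth[lm, ] + offs[[r]],
                          numeric(3)))
    subs <- utils::combn(4, 3)
    mean(apply(subs, 2, function(ss) {
      med <- apply(rater_pts[ss, ], 2, stats::median)
      sqrt(sum((mx[lm, ] - med)^2))
    })) * 20
  }, numeric(1))
  expect_equal(unname(got$per_landmark), oracle)
  expect_equal(got$mean, mean(oracle))
  expect_error(matrix_error(toy_table(truth, offs), 14), "matrix")
})

test_that("simulated rater error grows monotonically with noise", {
  set.seed(31)
  truth <- matrix(runif(60, 10, 40), ncol = 3)
  mean_err <- vapply(c(0.5, 1, 2, 4), function(sd) {
    reps <- vapply(1:50, function(i) {
      tab <- simulate_raters(truth, n_raters = 4, noise_sd = sd,
                             seed = 1000 * sd + i)
      rater_error(tab, "rater_1", 14)$mean
    }, numeric(1))
    mean(reps)
  }, numeric(1))
  expect_true(all(diff(mean_err) > 0))
})

test_that("error comparison reproduces the closed-form paired t test", {
  a <- c(120, 95, 140, 110, 133, 150)
  b <- c(100, 90, 150, 95, 120, 130)
  got <- compare_errors(a, b, paired = TRUE)
  d <- a - b
  t_cf <- mean(d) / (stats::sd(d) / sqrt(length(d)))
  p_cf <- 2 * stats::pt(-abs(t_cf), df = length(d) - 1)
  expect_equal(got$statistic, t_cf)
  expect_equal(got$p_value, p_cf)
  expect_equal(got$df, 5)
  expect_false(got$degenerate)
  ident <- compare_errors(a, a)
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
  expect_true(ident$degenerate)
  # mean difference zero but nonzero variance: t is 0, not degenerate
  sym <- compare_errors(c(1, 2, 1, 2), c(2, 1, 2, 1))
  expect_equal(sym$statistic, 0)
  welch <- compare_errors(a, b, paired = FALSE)
  expect_false(isTRUE(all.equal(welch$statistic, got$statistic)))
  expect_error(compare_errors(a, b[-1]), "equal length")
})

test_that("error statistics are invariant under a rigid translation", {
  set.seed(41)
  truth <- matrix(runif(30, 10, 30), ncol = 3)
  offs <- lapply(1:4, function(i) rnorm(3, 0, 0.5))
  mx <- truth + matrix(rnorm(30, 0, 1), ncol = 3)
  tab <- toy_table(truth, offs, matrix_at = mx)
  shift <- c(7, -3, 11)
  tab_shift <- tab
  tab_shift$x <- tab$x + shift[1]
  tab_shift$y <- tab$y + shift[2]
  tab_shift$z <- tab$z + shift[3]
  expect_equal(rater_error(tab_shift, "rater_2", 14)$mean,
               rater_error(tab, "rater_2", 14)$mean)
  expect_equal(matrix_error(tab_shift, 14)$mean, matrix_error(tab, 14)$mean)
})

test_that("the median reference is robust to a single wild outlier", {
  coords <- rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))
  med0 <- median_of_others(coords)
  wild <- coords; wild[3, ] <- c(1e6, 1e6, 1e6)
  med1 <- median_of_others(wild)
  expect_lt(max(abs(med1 - med0)), 2)  # bounded despite the unbounded move
})

test_that("error heatmaps assign every voxel its nearest landmark error", {
  sp <- atlas_space(14, c(16, 16, 16))
  one <- error_heatmap(matrix(c(3, 3, 3), ncol = 3), errors = 42, sp)
  expect_true(all(one$values == 42))
  # two landmarks on one axis: the equidistance plane splits the volume;
  # the plane itself (x = 8) ties toward the smaller landmark id
  two <- error_heatmap(rbind(c(4, 8, 8), c(12, 8, 8)), c(1, 2), sp)
  expect_true(all(two$values[1:9, , ] == 1))
  expect_true(all(two$values[10:16, , ] == 2))
  set.seed(51)
  sites <- matrix(runif(15, 0, 15), ncol = 3)
  errs <- runif(5, 10, 200)
  hm <- error_heatmap(sites, errs, sp)
  for (p in list(c(0, 0, 0), c(5, 9, 2), c(15, 15, 15), c(8, 3, 11))) {
    d <- colSums((t(sites) - p)^2)
    expect_equal(hm$values[p[1] + 1, p[2] + 1, p[3] + 1],
                 errs[which.min(d)])
  }
})

test_that("regional grouping follows the rounded-voxel label lookup", {
  sp <- atlas_space(14, c(8, 8, 8))
  lab <- array(1L, c(8, 8, 8)); lab[5:8, , ] <- 2L
  lv <- label_volume(lab, sp)
  coords <- rbind(c(1, 1, 1), c(2, 2, 2), c(6, 6, 6), c(3.5, 1, 1))
  # coordinate 3.5 ties at the boundary: rounds toward the smaller index (3)
  errs <- c(10, 20, 30, 40)
  got <- group_by_region(coords, errs, lv)
  expect_equal(got$mean_error[got$region_id == 1],
               mean(c(10, 20, 40)))
  expect_equal(got$mean_error[got$region_id == 2], 30)
  expect_warning(
    out <- group_by_region(rbind(c(1, 1, 1), c(50, 1, 1)), c(1, 2), lv),
    "excluded")
  expect_equal(sum(out$n_landmarks), 1L)
})

test_that("the concordance report assembles all subjects and tests", {
  set.seed(61)
  truth <- matrix(runif(36, 10, 40), ncol = 3)
  tab <- simulate_raters(truth, n_raters = 4, noise_sd = 1, seed = 7,
                         ages = c(7, 14), matrix_sd = 1)
  rep <- concordance_report(tab)
  expect_setequal(unique(rep$errors$subject),
                  c(paste0("rater_", 1:4), "average_rater", "matrix"))
  expect_equal(nrow(rep$tests), 2L)
  expect_true(all(rep$tests$p_value >= 0 & rep$tests$p_value <= 1))
  td <- tidy(rep)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 12L)
  gl <- glance(rep)
  expect_equal(gl$age, c(7, 14))
  expect_true(all(c("average_rater_um", "matrix_um", "p_value") %in%
                    names(gl)))
  # with equal noise, matrix and average-rater errors are comparable
  expect_lt(abs(gl$average_rater_um[1] - gl$matrix_um[1]) /
              gl$average_rater_um[1], 0.5)
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
})
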