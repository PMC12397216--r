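#' Landmark tables
#'
#' The substrate of the accuracy validation: one row per (landmark, subject,
#' age) with 0-based voxel coordinates. Subjects are the human raters plus,
#' optionally, the transform under test, recorded under the reserved
#' `rater_id` `"matrix"`. A landmark not identified by every rater at an age
#' is excluded from that age's statistics.
#'
#' @param df Data frame with columns `landmark_id`, `rater_id`, `age`, `x`,
#'   `y`, `z`.
#' @param spacing Voxel spacing in micrometres (isotropic), used to express
#'   distances in micrometres. Default 20.
#' @return A tibble of class `landmark_table` with a `spacing` attribute.
#' @export
landmark_table <- function(df, spacing = 20) {
  req <- c("landmark_id", "rater_id", "age", "x", "y", "z")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop("landmark table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (spacing <= 0) stop("`spacing` must be positive", call. = FALSE)
  out <- tibble::as_tibble(df[req])
  out$landmark_id <- as.character(out$landmark_id)
  out$rater_id <- as.character(out$rater_id)
  if (any(!is.finite(out$x) | !is.finite(out$y) | !is.finite(out$z))) {
    stop("landmark coordinates must be finite", call. = FALSE)
  }
  key <- paste(out$landmark_id, out$rater_id, out$age, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (landmark_id, rater_id, age) rows at row(s): ",
         paste(which(duplicated(key)), collapse = ", "), call. = FALSE)
  }
  attr(out, "spacing") <- spacing
  class(out) <- c("landmark_table", class(out))
  out
}

lm_spacing <- function(table) {
  sp <- attr(table, "spacing")
  if (is.null(sp)) 20 else sp
}

rater_ids <- function(table) {
  setdiff(unique(table$rater_id), "matrix")
}

# Landmarks identified by *all* human raters (and, if required, the matrix)
# at one age; others are excluded from that age's statistics.
complete_landmarks <- function(table, age, need_matrix = FALSE) {
  sub <- table[table$age == age, , drop = FALSE]
  raters <- rater_ids(sub)
  need <- if (need_matrix) c(raters, "matrix") else raters
  keep <- vapply(split(sub$rater_id, sub$landmark_id),
                 function(r) all(need %in% r), logical(1))
  sort(names(keep)[keep])
}

#' Componentwise median of the other raters' coordinates
#'
#' The reference coordinate each subject is scored against: the per-axis
#' median over the remaining raters. The median is used rather than the mean
#' because it is far less sensitive to a single outlying annotation. For an
#' even number of remaining raters the per-axis median is the midpoint of the
#' two central values.
#'
#' @param coords An r x 3 matrix of voxel coordinates, one row per rater.
#' @param exclude Row index (or logical vector) of the rater(s) to leave out.
#' @return Length-3 numeric coordinate.
#' @export
median_of_others <- function(coords, exclude = NULL) {
  coords <- coerce_points(coords)
  if (!is.null(exclude)) coords <- coords[-exclude, , drop = FALSE]
  if (nrow(coords) < 2L) {
    stop("need at least 2 remaining raters to form a median coordinate",
         call. = FALSE)
  }
  apply(coords, 2L, stats::median)
}

#' Per-rater landmark error
#'
#' For one rater at one age: the Euclidean distance (in micrometres) from
#' each of the rater's landmark coordinates to the componentwise median of
#' the *other* raters' coordinates for the same landmark, and the mean over
#' landmarks. Only landmarks identified by every rater at that age enter.
#'
#' @param table A [landmark_table()].
#' @param rater Rater id.
#' @param age Postnatal day.
#' @return List with `mean` (micrometres) and `per_landmark` (named vector).
#' @export
rater_error <- function(table, rater, age) {
  sub <- table[table$age == age, , drop = FALSE]
  if (!rater %in% sub$rater_id) {
    stop("rater ", rater, " has no landmarks at age P", age, call. = FALSE)
  }
  lms <- complete_landmarks(table, age)
  if (!length(lms)) {
    stop("no landmark was identified by all raters at age P", age,
         call. = FALSE)
  }
  others <- setdiff(rater_ids(sub), rater)
  d <- vapply(lms, function(lm) {
    rows <- sub[sub$landmark_id == lm, , drop = FALSE]
    own <- as.numeric(rows[rows$rater_id == rater, c("x", "y", "z")])
    oth <- as.matrix(rows[rows$rater_id %in% others, c("x", "y", "z")])
    med <- median_of_others(oth)
    sqrt(sum((own - med)^2)) * lm_spacing(table)
  }, numeric(1))
  list(mean = mean(d), per_landmark = d)
}

#' Transform ("matrix") landmark error by rater-subset enumeration
#'
#' The transform under test is scored against the same number of raters as
#' each human was: for every unique subset of `n_subset` raters (default one
#' fewer than the rater count), the distance from the transform's coordinate
#' to that subset's componentwise median is computed, and the distances are
#' averaged over subsets, then over landmarks.
#'
#' @param table A [landmark_table()] containing `"matrix"` rows.
#' @param age Postnatal day.
#' @param n_subset Raters per subset. Default `R - 1` for `R` raters.
#' @return List with `mean` (micrometres) and `per_landmark` (named vector,
#'   each already averaged over subsets).
#' @export
matrix_error <- function(table, age, n_subset = NULL) {
  sub <- table[table$age == age, , drop = FALSE]
  if (!"matrix" %in% sub$rater_id) {
    stop("no \"matrix\" rows at age P", age, call. = FALSE)
  }
  raters <- rater_ids(sub)
  if (is.null(n_subset)) n_subset <- length(raters) - 1L
  if (n_subset < 2L || n_subset > length(raters)) {
    stop("`n_subset` must lie in [2, number of raters]", call. = FALSE)
  }
  lms <- complete_landmarks(table, age, need_matrix = TRUE)
  if (!length(lms)) {
    stop("no landmark has matrix and all-rater coordinates at age P", age,
         call. = FALSE)
  }
  subsets <- utils::combn(raters, n_subset, simplify = FALSE)
  d <- vapply(lms, function(lm) {
    rows <- sub[sub$landmark_id == lm, , drop = FALSE]
    mx <- as.numeric(rows[rows$rater_id == "matrix", c("x", "y", "z")])
    per_subset <- vapply(subsets, function(ss) {
      pts <- as.matrix(rows[rows$rater_id %in% ss, c("x", "y", "z")])
      med <- median_of_others(pts)
      sqrt(sum((mx - med)^2))
    }, numeric(1))
    mean(per_subset) * lm_spacing(table)
  }, numeric(1))
  list(mean = mean(d), per_landmark = d)
}

#' Compare average-rater and transform errors
#'
#' Two-tailed t test on the per-landmark distances: the rater-averaged error
#' for each landmark against the transform's subset-averaged error for the
#' same landmark. Paired by default (both subjects are scored on the same
#' landmark set); an unpaired Welch variant is available via
#' `paired = FALSE`. Degenerate zero-variance differences report `t = 0`,
#' `p = 1` with a flag instead of failing.
#'
#' @param rater_avg,matrix_err Equal-length numeric vectors of per-landmark
#'   distances (micrometres).
#' @param paired Logical; paired test (default) or Welch two-sample.
#' @return List with `statistic`, `p_value`, `df`, `paired`, `degenerate`.
#' @export
compare_errors <- function(rater_avg, matrix_err, paired = TRUE) {
  if (length(rater_avg) != length(matrix_err)) {
    stop("per-landmark vectors must have equal length", call. = FALSE)
  }
  degenerate <- if (paired) {
    stats::sd(rater_avg - matrix_err) == 0
  } else {
    stats::sd(rater_avg) == 0 && stats::sd(matrix_err) == 0
  }
  if (isTRUE(degenerate) || is.na(degenerate)) {
    return(list(statistic = 0, p_value = 1,
                df = length(rater_avg) - 1L, paired = paired,
                degenerate = TRUE))
  }
  tt <- stats::t.test(rater_avg, matrix_err, paired = paired,
                      alternative = "two.sided")
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), paired = paired, degenerate = FALSE)
}

#' Full concordance report for a landmark table
#'
#' Computes, for each requested age, the mean error of every rater, the
#' average rater, and (when present) the transform under test, plus the
#' two-tailed t test comparing average-rater and transform per-landmark
#' errors.
#'
#' @param table A [landmark_table()].
#' @param ages Ages to evaluate; default all ages present.
#' @param paired Passed to [compare_errors()].
#' @return A `concordance_report`: list with `errors` (tibble: `age`,
#'   `subject`, `mean_um`, `n_landmarks`), `tests` (tibble: `age`,
#'   `statistic`, `p_value`, `df`, `degenerate`) and `per_landmark` (tibble).
#' @export
concordance_report <- function(table, ages = NULL, paired = TRUE) {
  if (is.null(ages)) ages <- sort(unique(table$age))
  err_rows <- list(); test_rows <- list(); lm_rows <- list()
  for (a in ages) {
    raters <- rater_ids(table[table$age == a, , drop = FALSE])
    per <- lapply(raters, function(r) rater_error(table, r, a))
    names(per) <- raters
    for (r in raters) {
      err_rows[[length(err_rows) + 1L]] <- tibble::tibble(
        age = a, subject = r, mean_um = per[[r]]$mean,
        n_landmarks = length(per[[r]]$per_landmark))
      lm_rows[[length(lm_rows) + 1L]] <- tibble::tibble(
        age = a, subject = r,
        landmark_id = names(per[[r]]$per_landmark),
        distance_um = unname(per[[r]]$per_landmark))
    }
    lm_ids <- names(per[[1]]$per_landmark)
    avg <- rowMeans(vapply(per, function(p) p$per_landmark[lm_ids],
                           numeric(length(lm_ids))))
    err_rows[[length(err_rows) + 1L]] <- tibble::tibble(
      age = a, subject = "average_rater", mean_um = mean(avg),
      n_landmarks = length(avg))
    has_matrix <- "matrix" %in% table$rater_id[table$age == a]
    if (has_matrix) {
      mx <- matrix_error(table, a)
      err_rows[[length(err_rows) + 1L]] <- tibble::tibble(
        age = a, subject = "matrix", mean_um = mx$mean,
        n_landmarks = length(mx$per_landmark))
      lm_rows[[length(lm_rows) + 1L]] <- tibble::tibble(
        age = a, subject = "matrix", landmark_id = names(mx$per_landmark),
        distance_um = unname(mx$per_landmark))
      common <- intersect(lm_ids, names(mx$per_landmark))
      ct <- compare_errors(avg[common], mx$per_landmark[common],
                           paired = paired)
      test_rows[[length(test_rows) + 1L]] <- tibble::tibble(
        age = a, statistic = ct$statistic, p_value = ct$p_value,
        df = ct$df, degenerate = ct$degenerate)
    }
  }
  structure(list(errors = dplyr::bind_rows(err_rows),
                 tests = dplyr::bind_rows(test_rows),
                 per_landmark = dplyr::bind_rows(lm_rows),
                 spacing = lm_spacing(table), paired = paired),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report>\n")
  print(x$errors, n = 20)
  if (nrow(x$tests)) {
    cat("average rater vs matrix (two-tailed",
        if (x$paired) "paired" else "Welch", "t test):\n")
    print(x$tests)
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a concordance report
#'
#' `tidy()` returns the per-subject mean errors, one row per (age, subject);
#' `glance()` returns one row per age with the average-rater and matrix means
#' and the comparison test.
#'
#' @param x A `concordance_report`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy concordance_report
#' @export
tidy.concordance_report <- function(x, ...) x$errors

#' @rdname tidy.concordance_report
#' @method glance concordance_report
#' @export
glance.concordance_report <- function(x, ...) {
  wide <- x$errors[x$errors$subject %in% c("average_rater", "matrix"), ]
  wide <- tidyr_pivot(wide)
  if (nrow(x$tests)) dplyr::left_join(wide, x$tests, by = "age") else wide
}

# minimal wide pivot (avoids a tidyr dependency for one call site)
tidyr_pivot <- function(df) {
  ages <- sort(unique(df$age))
  tibble::tibble(
    age = ages,
    average_rater_um = vapply(ages, function(a)
      df$mean_um[df$age == a & df$subject == "average_rater"][1], numeric(1)),
    matrix_um = vapply(ages, function(a) {
      v <- df$mean_um[df$age == a & df$subject == "matrix"]
      if (length(v)) v[1] else NA_real_
    }, numeric(1)))
}

#' Nearest-landmark error heatmap
#'
#' Expands per-landmark error values into a full volume for 3D inspection:
#' every voxel takes the error of its nearest assessed landmark (Euclidean
#' distance in voxels; ties go to the smaller landmark id). With a single
#' landmark the result is constant.
#'
#' @param coords An n x 3 matrix of landmark voxel coordinates.
#' @param errors Numeric vector of per-landmark errors (micrometres), same
#'   length and order; names, if present, define the tie-break order
#'   (otherwise row order is used).
#' @param space An [atlas_space()].
#' @return An [intensity_volume()] of nearest-landmark errors.
#' @export
error_heatmap <- function(coords, errors, space) {
  stopifnot_space(space)
  coords <- coerce_points(coords)
  if (nrow(coords) == 0L) {
    stop("at least one landmark is required", call. = FALSE)
  }
  if (length(errors) != nrow(coords)) {
    stop("`errors` must match the number of landmarks", call. = FALSE)
  }
  ord <- if (!is.null(names(errors))) order(names(errors)) else
    seq_along(errors)
  coords <- coords[ord, , drop = FALSE]
  errors <- errors[ord]
  xg <- grid_coords(space$shape)
  best_d <- rep(Inf, nrow(xg))
  best_i <- rep(1L, nrow(xg))
  for (i in seq_len(nrow(coords))) {
    d <- (xg[, 1] - coords[i, 1])^2 + (xg[, 2] - coords[i, 2])^2 +
      (xg[, 3] - coords[i, 3])^2
    better <- d < best_d   # strict: ties keep the earlier (smaller-id) site
    best_d[better] <- d[better]
    best_i[better] <- i
  }
  out <- errors[best_i]
  dim(out) <- space$shape
  intensity_volume(out, space)
}

#' Group landmark errors by brain region
#'
#' Looks up the segmentation label at each landmark's rounded voxel (ties at
#' .5 round toward the smaller index) and averages the errors per region.
#' Landmarks outside the grid are excluded with a warning.
#'
#' @param coords An n x 3 matrix of landmark voxel coordinates.
#' @param errors Numeric vector of per-landmark errors.
#' @param labels A [label_volume()] in the same space as the coordinates.
#' @return Tibble with `region_id`, `region_name`, `mean_error`,
#'   `n_landmarks`.
#' @export
group_by_region <- function(coords, errors, labels) {
  if (!is_label_volume(labels)) {
    stop("`labels` must be a label_volume", call. = FALSE)
  }
  coords <- coerce_points(coords)
  if (length(errors) != nrow(coords)) {
    stop("`errors` must match the number of landmarks", call. = FALSE)
  }
  sh <- labels$space$shape
  i <- ceiling(coords[, 1] - 0.5)
  j <- ceiling(coords[, 2] - 0.5)
  k <- ceiling(coords[, 3] - 0.5)
  inside <- i >= 0 & i <= sh[1] - 1 & j >= 0 & j <= sh[2] - 1 &
    k >= 0 & k <= sh[3] - 1
  if (any(!inside)) {
    warning(sum(!inside), " landmark(s) outside the grid were excluded",
            call. = FALSE)
  }
  ids <- labels$labels[cbind(i[inside] + 1L, j[inside] + 1L,
                             k[inside] + 1L)]
  err <- errors[inside]
  agg <- tapply(err, ids, mean)
  n <- tapply(err, ids, length)
  region_id <- as.integer(names(agg))
  name_of <- function(id) {
    if (id == 0L) return("background")
    nm <- labels$table$name[labels$table$id == id]
    if (length(nm)) nm else NA_character_
  }
  tibble::tibble(region_id = region_id,
                 region_name = vapply(region_id, name_of, character(1)),
                 mean_error = as.numeric(agg),
                 n_landmarks = as.integer(n))
}
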