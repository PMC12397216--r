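#' The developmental template chain
#'
#' A `template_chain` holds the ordered anchor ages (default postnatal days
#' 4, 7, 14, 21, 28 and 56), one anchor template per age, and one *backward*
#' displacement field per adjacent anchor pair. A backward field transforms
#' data down in age: its target is the younger anchor, its source the older.
#' Forward fields are obtained on demand by [invert_field()] and cached, as
#' are composed multi-step route fields.
#'
#' All spaces in a chain must share grid shape and spacing — the template
#' dimensions are standardized before registration, which is what makes
#' temporally scaled fields on the shared grid well-defined.
#'
#' @param templates Named list of [intensity_volume()] objects, names the
#'   anchor ages (e.g. `"4"`, `"7"`, ...).
#' @param backward_fields List of [displacement_field()] objects, one per
#'   adjacent anchor pair, each with `target` the younger and `source` the
#'   older age of its pair. Order is irrelevant; pairs are matched by age.
#' @param inversion_tol Tolerance (voxels) passed to [invert_field()] when
#'   forward fields are derived. Default 0.05.
#' @return A `template_chain`.
#' @export
template_chain <- function(templates, backward_fields, inversion_tol = 0.05) {
  if (!length(templates)) stop("at least one template required", call. = FALSE)
  ages <- sort(vapply(templates, function(t) t$space$age, numeric(1)))
  if (any(duplicated(ages))) {
    stop("duplicate template ages in chain", call. = FALSE)
  }
  names(templates) <- vapply(templates, function(t) as.character(t$space$age),
                             character(1))
  templates <- templates[as.character(ages)]
  ref <- templates[[1]]$space
  for (t in templates) {
    if (!same_grid(t$space, ref)) {
      stop("all chain templates must share grid shape and spacing",
           call. = FALSE)
    }
  }
  pairs <- if (length(ages) > 1) cbind(ages[-length(ages)], ages[-1]) else
    matrix(numeric(0), ncol = 2)
  fields <- list()
  for (f in backward_fields) {
    stopifnot(is_displacement_field(f))
    key <- pair_key(f$source$age, f$target$age)   # older -> younger
    fields[[key]] <- f
  }
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      key <- pair_key(pairs[r, 2], pairs[r, 1])
      f <- fields[[key]]
      if (is.null(f)) {
        stop("missing backward field for anchor pair P", pairs[r, 2],
             " -> P", pairs[r, 1], call. = FALSE)
      }
      if (f$source$age != pairs[r, 2] || f$target$age != pairs[r, 1]) {
        stop("backward field endpoints do not match anchor pair", call. = FALSE)
      }
      if (!same_grid(f$target, ref)) {
        stop("field grids must match the chain grid", call. = FALSE)
      }
    }
  }
  structure(
    list(anchor_ages = ages, templates = templates,
         backward_fields = fields, inversion_tol = inversion_tol,
         cache = new.env(parent = emptyenv())),
    class = "template_chain"
  )
}

pair_key <- function(older, younger) paste0(older, "->", younger)

#' @export
print.template_chain <- function(x, ...) {
  cat(sprintf("<template_chain> anchors P%s  grid %s @ %g um\n",
              paste(x$anchor_ages, collapse = ", P"),
              paste(x$templates[[1]]$space$shape, collapse = "x"),
              x$templates[[1]]$space$spacing))
  invisible(x)
}

#' @rdname template_chain
#' @param x Object to test.
#' @export
is_template_chain <- function(x) inherits(x, "template_chain")

chain_space <- function(chain, age) {
  ref <- chain$templates[[1]]$space
  atlas_space(age, ref$shape, ref$spacing, ref$origin)
}

backward_between <- function(chain, older, younger) {
  f <- chain$backward_fields[[pair_key(older, younger)]]
  if (is.null(f)) {
    stop("chain has no backward field P", older, " -> P", younger,
         call. = FALSE)
  }
  f
}

# Cached forward field (inverse of the stored backward) for a bracket.
forward_between <- function(chain, younger, older) {
  key <- sprintf("fwd_%g_%g_%g", younger, older, chain$inversion_tol)
  if (!is.null(chain$cache[[key]])) return(chain$cache[[key]])
  fwd <- invert_field(backward_between(chain, older, younger),
                      tol = chain$inversion_tol)
  chain$cache[[key]] <- fwd
  fwd
}

is_anchor <- function(age, chain) age %in% chain$anchor_ages

#' Bracketing anchors for an age
#'
#' Returns the tightest pair of anchor ages enclosing `age`. Anchor ages
#' bracket themselves: `neighbors(14, chain)` is `c(14, 14)`.
#'
#' @param age Postnatal day within the chain span.
#' @param chain A [template_chain()].
#' @return Numeric vector `c(younger, older)`.
#' @export
neighbors <- function(age, chain) {
  stopifnot(is_template_chain(chain))
  a <- chain$anchor_ages
  if (age < a[1] || age > a[length(a)]) {
    stop(sprintf("age P%g is outside the chain span P%g-P%g", age, a[1],
                 a[length(a)]), call. = FALSE)
  }
  if (is_anchor(age, chain)) return(c(age, age))
  c(max(a[a < age]), min(a[a > age]))
}

#' Temporal interpolation plan for an intermediate age
#'
#' For a target age `t` bracketed by anchors `y < t < o`, the interpolation
#' fraction is `f = (t - y) / (o - y)` and the averaging weights are
#' `w_y = 1 - f` (younger template) and `w_o = f` (older): the closer anchor
#' carries the larger weight, and the weights always sum to 1. An anchor age
#' yields a degenerate plan with a single weight of 1.
#'
#' @inheritParams neighbors
#' @return An `interpolation_plan`: list with `age`, `younger`, `older`,
#'   `fraction`, `weight_young`, `weight_old`.
#' @examples
#' \dontrun{
#' plan_interpolation(8, chain)  # f = 1/7: P7 weighted 6/7, P14 weighted 1/7
#' }
#' @export
plan_interpolation <- function(age, chain) {
  br <- neighbors(age, chain)
  if (br[1] == br[2]) {
    f <- 0
  } else {
    f <- (age - br[1]) / (br[2] - br[1])
  }
  structure(list(age = age, younger = br[1], older = br[2], fraction = f,
                 weight_young = 1 - f, weight_old = f),
            class = "interpolation_plan")
}

#' @export
print.interpolation_plan <- function(x, ...) {
  if (x$younger == x$older) {
    cat(sprintf("<interpolation_plan> P%g is an anchor (weight 1)\n", x$age))
  } else {
    cat(sprintf(
      "<interpolation_plan> P%g = %.3f * P%g + %.3f * P%g  (f = %.3f)\n",
      x$age, x$weight_young, x$younger, x$weight_old, x$older, x$fraction))
  }
  invisible(x)
}

#' Synthesize the template of an intermediate age
#'
#' Builds the model volume for an age between two anchors: the younger
#' anchor template is carried *forward* by the bracket's forward field scaled
#' to fraction `f`, the older anchor template is carried *backward* by the
#' stored backward field scaled to `1 - f`, both landing on the intermediate
#' grid, and the two warped volumes are averaged with the temporal weights
#' `1 - f` (younger) and `f` (older). Requests at an anchor age return the
#' stored template unchanged.
#'
#' @inheritParams neighbors
#' @return An [intensity_volume()] in the intermediate-age space.
#' @export
make_intermediate_template <- function(age, chain) {
  stopifnot(is_template_chain(chain))
  plan <- plan_interpolation(age, chain)
  if (plan$younger == plan$older) {
    return(chain$templates[[as.character(age)]])
  }
  t_y <- chain$templates[[as.character(plan$younger)]]
  t_o <- chain$templates[[as.character(plan$older)]]
  if (is.null(t_y) || is.null(t_o)) {
    stop("chain is missing a bracketing template for P", age, call. = FALSE)
  }
  inter <- chain_space(chain, age)
  bwd <- backward_between(chain, plan$older, plan$younger)
  fwd <- forward_between(chain, plan$younger, plan$older)
  f_y <- scale_field(fwd, plan$fraction, source = t_y$space, target = inter)
  f_o <- scale_field(bwd, 1 - plan$fraction, source = t_o$space,
                     target = inter)
  w_y <- warp_volume(t_y, f_y)
  w_o <- warp_volume(t_o, f_o)
  intensity_volume(plan$weight_young * w_y$values +
                     plan$weight_old * w_o$values, inter)
}

#' Plan a translation route between two ages
#'
#' Decomposes an age-to-age translation into pairwise steps through the
#' intervening anchors. Each step is a pull field: full backward (or forward)
#' fields between adjacent anchors, plus at most one temporally scaled
#' terminal step when an endpoint is not an anchor. A route between equal
#' ages is empty.
#'
#' @param source_age,target_age Postnatal days within the chain span.
#' @param chain A [template_chain()].
#' @return A `translation_route`: list with `source_age`, `target_age`,
#'   `steps` (each a list `field`, `fraction`, `direction`, `from`, `to`) and
#'   `description`.
#' @export
build_route <- function(source_age, target_age, chain) {
  stopifnot(is_template_chain(chain))
  span <- range(chain$anchor_ages)
  for (a in c(source_age, target_age)) {
    if (a < span[1] || a > span[2]) {
      stop(sprintf("age P%g is outside the chain span P%g-P%g", a, span[1],
                   span[2]), call. = FALSE)
    }
  }
  steps <- list()
  add <- function(field, fraction, direction, from, to) {
    steps[[length(steps) + 1L]] <<- list(field = field, fraction = fraction,
                                         direction = direction, from = from,
                                         to = to)
  }
  s <- source_age; t <- target_age
  if (s != t) {
    down <- s > t
    bs <- neighbors(s, chain); bt <- neighbors(t, chain)
    fs <- plan_interpolation(s, chain)$fraction
    ft <- plan_interpolation(t, chain)$fraction
    same_bracket <- !is_anchor(s, chain) && !is_anchor(t, chain) &&
      all(bs == bt)
    if (same_bracket) {
      if (down) {
        base <- backward_between(chain, bs[2], bs[1])
        add(scale_field(base, fs - ft, source = chain_space(chain, s),
                        target = chain_space(chain, t)),
            fs - ft, "backward", s, t)
      } else {
        base <- forward_between(chain, bs[1], bs[2])
        add(scale_field(base, ft - fs, source = chain_space(chain, s),
                        target = chain_space(chain, t)),
            ft - fs, "forward", s, t)
      }
    } else if (down) {
      # entry: descend from a fractional source onto its younger anchor
      a_from <- if (is_anchor(s, chain)) s else {
        base <- backward_between(chain, bs[2], bs[1])
        add(scale_field(base, fs, source = chain_space(chain, s),
                        target = chain_space(chain, bs[1])),
            fs, "backward", s, bs[1])
        bs[1]
      }
      a_to <- if (is_anchor(t, chain)) t else bt[2]
      anchors <- chain$anchor_ages
      path <- rev(anchors[anchors >= a_to & anchors <= a_from])
      if (length(path) > 1) {
        for (i in seq_len(length(path) - 1L)) {
          add(backward_between(chain, path[i], path[i + 1L]), 1,
              "backward", path[i], path[i + 1L])
        }
      }
      if (!is_anchor(t, chain)) {
        base <- backward_between(chain, bt[2], bt[1])
        add(scale_field(base, 1 - ft, source = chain_space(chain, bt[2]),
                        target = chain_space(chain, t)),
            1 - ft, "backward", bt[2], t)
      }
    } else {
      # ascending: forward fields (inverted backwards)
      a_from <- if (is_anchor(s, chain)) s else {
        base <- forward_between(chain, bs[1], bs[2])
        add(scale_field(base, 1 - fs, source = chain_space(chain, s),
                        target = chain_space(chain, bs[2])),
            1 - fs, "forward", s, bs[2])
        bs[2]
      }
      a_to <- if (is_anchor(t, chain)) t else bt[1]
      anchors <- chain$anchor_ages
      path <- anchors[anchors >= a_from & anchors <= a_to]
      if (length(path) > 1) {
        for (i in seq_len(length(path) - 1L)) {
          add(forward_between(chain, path[i], path[i + 1L]), 1,
              "forward", path[i], path[i + 1L])
        }
      }
      if (!is_anchor(t, chain)) {
        base <- forward_between(chain, bt[1], bt[2])
        add(scale_field(base, ft, source = chain_space(chain, bt[1]),
                        target = chain_space(chain, t)),
            ft, "forward", bt[1], t)
      }
    }
  }
  desc <- if (!length(steps)) {
    sprintf("P%g -> P%g: identity", s, t)
  } else {
    sprintf("P%g -> P%g: %s", s, t, paste(
      vapply(steps, function(st) {
        frac <- if (st$fraction < 1) sprintf(" (x%.3g)", st$fraction) else ""
        sprintf("P%g->P%g%s", st$from, st$to, frac)
      }, character(1)), collapse = ", "))
  }
  structure(list(source_age = s, target_age = t, steps = steps,
                 description = desc),
            class = "translation_route")
}

#' @export
print.translation_route <- function(x, ...) {
  cat("<translation_route> ", x$description, "\n", sep = "")
  invisible(x)
}

#' Compose a route into a single pull field
#'
#' Folds the steps of a [build_route()] result with [compose_fields()] into
#' one displacement field indexed on the target-age grid and sampling the
#' source-age space, caching the result in the chain. Empty routes return
#' `NULL` (the identity needs no field).
#'
#' @param route A `translation_route`.
#' @param chain The [template_chain()] the route was built from (for caching).
#' @return A [displacement_field()] or `NULL` for an identity route.
#' @export
route_field <- function(route, chain = NULL) {
  stopifnot(inherits(route, "translation_route"))
  if (!length(route$steps)) return(NULL)
  key <- sprintf("route_%g_%g", route$source_age, route$target_age)
  if (!is.null(chain) && !is.null(chain$cache[[key]])) {
    return(chain$cache[[key]])
  }
  acc <- route$steps[[1]]$field
  if (length(route$steps) > 1) {
    for (i in 2:length(route$steps)) {
      acc <- compose_fields(outer = acc, inner = route$steps[[i]]$field)
    }
  }
  if (!is.null(chain)) chain$cache[[key]] <- acc
  acc
}

#' Translate a volume between ages
#'
#' Carries an intensity or label volume from `source_age` space into
#' `target_age` space by warping through the composed route field.
#' Translation between equal ages returns the input unchanged.
#'
#' @param vol An [intensity_volume()] or [label_volume()] whose space age is
#'   `source_age`.
#' @param source_age,target_age Postnatal days within the chain span.
#' @param chain A [template_chain()].
#' @param mode Passed to [warp_volume()] (`NULL` picks linear for
#'   intensities, nearest for labels).
#' @return A volume in `target_age` space.
#' @export
translate_volume <- function(vol, source_age, target_age, chain,
                             mode = NULL) {
  if (vol$space$age != source_age) {
    stop(sprintf("volume is in P%g space, not the stated source age P%g",
                 vol$space$age, source_age), call. = FALSE)
  }
  if (source_age == target_age) return(vol)
  field <- route_field(build_route(source_age, target_age, chain), chain)
  warp_volume(vol, field, mode = mode)
}

#' Transform a segmentation down from the adult space
#'
#' Segmentation volumes are defined in the oldest (adult) anchor space and
#' are only ever transformed *down* in age, using the backward route with
#' nearest-neighbour sampling; the output label set is always a subset of the
#' input's. Requests to move a segmentation up in age are rejected.
#'
#' @param labels A [label_volume()] in the oldest anchor space.
#' @param target_age Postnatal day at or below the adult anchor.
#' @param chain A [template_chain()].
#' @return A [label_volume()] in `target_age` space.
#' @export
transform_segmentation <- function(labels, target_age, chain) {
  stopifnot(is_template_chain(chain))
  if (!is_label_volume(labels)) {
    stop("`labels` must be a label_volume", call. = FALSE)
  }
  adult <- max(chain$anchor_ages)
  if (labels$space$age != adult) {
    stop(sprintf("segmentations live in the adult anchor space (P%g); got P%g",
                 adult, labels$space$age), call. = FALSE)
  }
  if (target_age > adult) {
    stop("segmentations are only transformed down from the adult template ",
         "(backward transforms only); cannot move a segmentation up in age",
         call. = FALSE)
  }
  if (target_age == adult) return(labels)
  translate_volume(labels, adult, target_age, chain, mode = "nearest")
}

#' Translate point coordinates between ages
#'
#' Moves coordinates from `source_age` to `target_age` using the duality of
#' pull fields: a field that resamples volumes from an older age into a
#' younger space maps *points* from the younger to the older age directly;
#' the opposite direction uses the inverted field. Concretely, points are
#' pushed through the route built in the opposite direction of the volume
#' route and applied with [map_points()].
#'
#' @param points A [point_set()] whose space age is `source_age`.
#' @param source_age,target_age Postnatal days within the chain span.
#' @param chain A [template_chain()].
#' @return A [point_set()] in `target_age` space.
#' @export
translate_points <- function(points, source_age, target_age, chain) {
  stopifnot(is_point_set(points))
  if (points$space$age != source_age) {
    stop(sprintf("points are in P%g space, not the stated source age P%g",
                 points$space$age, source_age), call. = FALSE)
  }
  if (source_age == target_age) return(points)
  # the pull field indexed on source_age sampling target_age maps points
  # source -> target
  field <- route_field(build_route(target_age, source_age, chain), chain)
  map_points(points, field)
}

#' Compile the full 4D model series
#'
#' Generates one volume per integer age over `ages` (default: the whole
#' anchor span): anchor ages return their stored template verbatim, all other
#' ages an interpolated model via [make_intermediate_template()]. The
#' manifest records the provenance of every volume. An optional `split` into
#' contiguous age ranges (the standard split is P4-P20, P21-P37, P38-P56)
#' partitions the series into subset lists.
#'
#' @param chain A [template_chain()].
#' @param ages Integer ages to compile. Default `min:max` of the anchors.
#' @param split Optional list of length-2 age ranges, e.g.
#'   `list(c(4, 20), c(21, 37), c(38, 56))`.
#' @return A `compiled_series`: list with `volumes` (named list), `manifest`
#'   (tibble: `age`, `kind`, `younger`, `older`, `weight_young`,
#'   `weight_old`) and, when `split` is given, `series` (list of named
#'   volume lists).
#' @export
compile_4d <- function(chain, ages = NULL, split = NULL) {
  stopifnot(is_template_chain(chain))
  if (is.null(ages)) {
    ages <- seq(min(chain$anchor_ages), max(chain$anchor_ages))
  }
  ages <- as.numeric(ages)
  if (any(diff(ages) != 1)) {
    stop("`ages` must be contiguous integer ages", call. = FALSE)
  }
  vols <- vector("list", length(ages))
  names(vols) <- as.character(ages)
  rows <- vector("list", length(ages))
  for (i in seq_along(ages)) {
    a <- ages[i]
    plan <- plan_interpolation(a, chain)
    anchor <- plan$younger == plan$older
    vols[[i]] <- if (anchor) chain$templates[[as.character(a)]] else
      make_intermediate_template(a, chain)
    rows[[i]] <- tibble::tibble(
      age = a, kind = if (anchor) "template" else "interpolated",
      younger = plan$younger, older = plan$older,
      weight_young = if (anchor) 1 else plan$weight_young,
      weight_old = if (anchor) 0 else plan$weight_old)
  }
  out <- list(volumes = vols, manifest = dplyr::bind_rows(rows))
  if (!is.null(split)) {
    out$series <- lapply(split, function(rg) {
      keep <- ages >= rg[1] & ages <= rg[2]
      vols[keep]
    })
    names(out$series) <- vapply(split, function(rg)
      sprintf("P%g-P%g", rg[1], rg[2]), character(1))
  }
  structure(out, class = "compiled_series")
}

#' @export
print.compiled_series <- function(x, ...) {
  n <- nrow(x$manifest)
  ni <- sum(x$manifest$kind == "interpolated")
  cat(sprintf("<compiled_series> %d volumes (%d templates, %d interpolated)\n",
              n, n - ni, ni))
  if (!is.null(x$series)) {
    cat("  split:", paste(names(x$series), collapse = ", "), "\n")
  }
  invisible(x)
}
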