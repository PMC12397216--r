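#' Read and write volumes as NIfTI-1
#'
#' Volumes travel on disk as `.nii`/`.nii.gz` with spatial units in
#' millimetres (the NIfTI convention; 20 micrometres is written as pixdim
#' 0.02) and a JSON sidecar `<path>.json` carrying the atlas metadata the
#' NIfTI header cannot (age, origin voxel, volume kind). Label volumes are
#' written with an integer datatype; reading a float-typed file as labels is
#' an error.
#'
#' @param vol An [intensity_volume()] or [label_volume()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `write_volume()` returns `path` invisibly; `read_volume()`
#'   returns the volume.
#' @export
write_volume <- function(vol, path) {
  is_lab <- is_label_volume(vol)
  if (!is_lab && !is_intensity_volume(vol)) {
    stop("`vol` must be an intensity_volume or label_volume", call. = FALSE)
  }
  arr <- if (is_lab) vol$labels else vol$values
  img <- RNifti::asNifti(arr)
  mm <- vol$space$spacing / 1000
  RNifti::pixdim(img) <- rep(mm, 3L)
  RNifti::pixunits(img) <- c("mm", "s")
  RNifti::writeNifti(img, path,
                     datatype = if (is_lab) "int32" else "double")
  sidecar <- list(kind = if (is_lab) "labels" else "intensity",
                  age = vol$space$age, spacing_um = vol$space$spacing,
                  origin = vol$space$origin)
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  if (is_lab && nrow(vol$table)) {
    write_label_table(vol$table, label_table_path(path))
  }
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")
label_table_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".labels.txt")
}

#' @rdname write_volume
#' @param kind `"auto"` (use the sidecar, falling back to the datatype),
#'   `"intensity"` or `"labels"`.
#' @export
read_volume <- function(path, kind = c("auto", "intensity", "labels")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) {
                    stop("failed to parse NIfTI file ", path, ": ",
                         conditionMessage(e), call. = FALSE)
                  })
  arr <- strip_nifti_attrs(img)
  if (length(dim(arr)) != 3L) {
    stop("expected a 3D volume; got ", length(dim(arr)), " dimensions",
         call. = FALSE)
  }
  pd <- attr(img, "pixdim")
  spacing <- pd[1] * 1000   # mm on disk -> micrometres in memory
  meta <- read_sidecar(path)
  if (kind == "auto") {
    kind <- meta$kind %||%
      (if (grepl("^int|^uint", RNifti::niftiHeader(img)$datatype) ||
             all(arr == round(arr))) "labels_maybe" else "intensity")
    if (kind == "labels_maybe") kind <- "intensity"
  }
  if (!is.null(meta$spacing_um)) spacing <- meta$spacing_um
  space <- atlas_space(meta$age %||% 28, dim(arr), spacing,
                       meta$origin %||% c(0, 0, 0))
  if (kind == "labels") {
    if (any(arr != round(arr))) {
      stop("float-typed label file: ", path,
           " contains non-integer values", call. = FALSE)
    }
    tab_path <- label_table_path(path)
    tab <- if (file.exists(tab_path)) read_label_table(tab_path) else NULL
    label_volume(arr, space, table = tab)
  } else {
    intensity_volume(arr, space)
  }
}

# plain array with only a dim attribute (drop the niftiImage baggage)
strip_nifti_attrs <- function(img) {
  arr <- as.array(img)
  array(as.vector(arr), dim = dim(arr))
}

read_sidecar <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) return(list())
  jsonlite::read_json(sc, simplifyVector = TRUE)
}

#' Read and write displacement fields
#'
#' Fields are 4D NIfTI volumes with the component axis last (length 3) plus
#' a JSON sidecar naming source and target ages; without the sidecar the
#' field's temporal direction is unknowable, so reading fails with an
#' instruction to supply it.
#'
#' @param field A [displacement_field()].
#' @param path Output `.nii`/`.nii.gz` path.
#' @return `write_field()` returns `path` invisibly; `read_field()` the
#'   field.
#' @export
write_field <- function(field, path) {
  stopifnot(is_displacement_field(field))
  img <- RNifti::asNifti(field$displacement)
  mm <- field$target$spacing / 1000
  RNifti::pixdim(img) <- c(rep(mm, 3L), 1)
  RNifti::writeNifti(img, path, datatype = "double")
  sidecar <- list(kind = "displacement_field",
                  source_age = field$source$age,
                  target_age = field$target$age,
                  spacing_um = field$target$spacing,
                  source_origin = field$source$origin,
                  target_origin = field$target$origin)
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- strip_nifti_attrs(img)
  d <- dim(arr)
  if (length(d) != 4L || d[4] != 3L) {
    stop("a displacement field must be a 4D NIfTI with a trailing ",
         "component axis of length 3; got ", paste(d, collapse = "x"),
         call. = FALSE)
  }
  meta <- read_sidecar(path)
  if (is.null(meta$source_age) || is.null(meta$target_age)) {
    stop("missing sidecar ", sidecar_path(path),
         ": supply a JSON file with `source_age` and `target_age` ",
         "(and optionally `spacing_um`) next to the field", call. = FALSE)
  }
  spacing <- meta$spacing_um %||% (attr(img, "pixdim")[1] * 1000)
  displacement_field(
    arr,
    source = atlas_space(meta$source_age, d[1:3], spacing,
                         meta$source_origin %||% c(0, 0, 0)),
    target = atlas_space(meta$target_age, d[1:3], spacing,
                         meta$target_origin %||% c(0, 0, 0)))
}

#' Read and write landmark tables as CSV
#'
#' The native exchange format of the validation statistics: a header row
#' with columns `landmark_id`, `rater_id`, `age`, `x`, `y`, `z`.
#'
#' @param path CSV file path.
#' @param spacing Voxel spacing in micrometres. Default 20.
#' @return A [landmark_table()].
#' @export
read_landmarks <- function(path, spacing = 20) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("landmark_id", "rater_id", "age", "x", "y", "z")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop("landmark CSV ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  key <- paste(df$landmark_id, df$rater_id, df$age, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("duplicate (landmark_id, rater_id, age) at line(s) ",
         paste(dup + 1L, collapse = ", "), " of ", path, call. = FALSE)
  }
  landmark_table(df, spacing = spacing)
}

#' @rdname read_landmarks
#' @param table A [landmark_table()].
#' @export
write_landmarks <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Write a concordance report to CSV and JSON
#'
#' @param report A [concordance_report()].
#' @param path_prefix Output prefix; writes `<prefix>_errors.csv`,
#'   `<prefix>_tests.csv` and `<prefix>.json`.
#' @return The paths, invisibly.
#' @export
write_report <- function(report, path_prefix) {
  stopifnot(inherits(report, "concordance_report"))
  p1 <- paste0(path_prefix, "_errors.csv")
  p2 <- paste0(path_prefix, "_tests.csv")
  p3 <- paste0(path_prefix, ".json")
  utils::write.csv(as.data.frame(report$errors), p1, row.names = FALSE)
  utils::write.csv(as.data.frame(report$tests), p2, row.names = FALSE)
  jsonlite::write_json(
    list(errors = report$errors, tests = report$tests,
         spacing_um = report$spacing, paired = report$paired),
    p3, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(p1, p2, p3))
}

#' Read and write region label tables in label-description text format
#'
#' The viewer-compatible format: one line per region,
#' `id red green blue alpha visible mesh "name"`, `#` comments allowed.
#'
#' @param table A [label_table()].
#' @param path Output text file.
#' @return `write_label_table()` the path invisibly; `read_label_table()` a
#'   [label_table()].
#' @export
write_label_table <- function(table, path) {
  lines <- c("# id red green blue alpha visible mesh \"name\"",
             sprintf("%d %d %d %d 1 1 1 \"%s\"", table$id, table$red,
                     table$green, table$blue, table$name))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_label_table
#' @export
read_label_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) return(label_table(integer(0)))
  m <- regmatches(lines,
                  regexec("^\\s*(\\d+)\\s+(\\d+)\\s+(\\d+)\\s+(\\d+)\\s+\\S+\\s+\\S+\\s+\\S+\\s+\"(.*)\"",
                          lines))
  bad <- vapply(m, length, integer(1)) != 6L
  if (any(bad)) {
    stop("malformed label-description line(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  ids <- vapply(m, function(x) as.integer(x[2]), integer(1))
  cols <- t(vapply(m, function(x) as.integer(x[3:5]), integer(3)))
  nms <- vapply(m, function(x) x[6], character(1))
  label_table(ids, names = nms, colors = cols)
}

#' Write and read a template-chain manifest
#'
#' Serializes a whole chain to a directory: one NIfTI per anchor template,
#' one 4D NIfTI per backward field, and a `chain.json` manifest listing
#' anchor ages, grid geometry and relative paths. Loading validates that
#' every referenced file exists.
#'
#' @param chain A [template_chain()].
#' @param dir Output directory (created if needed).
#' @return `write_chain_manifest()` returns the manifest path invisibly;
#'   `read_chain_manifest()` a [template_chain()].
#' @export
write_chain_manifest <- function(chain, dir) {
  stopifnot(is_template_chain(chain))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tmpl <- list(); flds <- list()
  for (a in chain$anchor_ages) {
    rel <- sprintf("template_P%g.nii.gz", a)
    write_volume(chain$templates[[as.character(a)]], file.path(dir, rel))
    tmpl[[as.character(a)]] <- rel
  }
  for (key in names(chain$backward_fields)) {
    rel <- sprintf("backward_%s.nii.gz", gsub("->", "_to_", key))
    write_field(chain$backward_fields[[key]], file.path(dir, rel))
    flds[[key]] <- rel
  }
  ref <- chain$templates[[1]]$space
  manifest <- list(version = "1", anchor_ages = chain$anchor_ages,
                   shape = ref$shape, spacing_um = ref$spacing,
                   templates = tmpl, backward_fields = flds,
                   inversion_tol = chain$inversion_tol)
  path <- file.path(dir, "chain.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_chain_manifest
#' @param path Path to a `chain.json` manifest.
#' @export
read_chain_manifest <- function(path) {
  if (!file.exists(path)) stop("no such manifest: ", path, call. = FALSE)
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  dir <- dirname(path)
  ages <- sort(as.numeric(m$anchor_ages))
  if (is.unsorted(as.numeric(m$anchor_ages))) {
    stop("manifest anchor ages must be sorted", call. = FALSE)
  }
  all_paths <- file.path(dir, c(unlist(m$templates),
                                unlist(m$backward_fields)))
  gone <- all_paths[!file.exists(all_paths)]
  if (length(gone)) {
    stop("manifest references missing file(s): ",
         paste(basename(gone), collapse = ", "), call. = FALSE)
  }
  templates <- lapply(as.character(ages), function(a)
    read_volume(file.path(dir, m$templates[[a]]), kind = "intensity"))
  fields <- lapply(m$backward_fields, function(rel)
    read_field(file.path(dir, rel)))
  template_chain(templates, unname(fields),
                 inversion_tol = m$inversion_tol %||% 0.05)
}
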