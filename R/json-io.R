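RESULT_SCHEMA_VERSION <- "1.0"

.result_type <- function(x) {
  for (cl in c("precision_curve", "power_law_model", "budget_curve",
               "piecewise_fit", "psd_summary", "material_category"))
    if (inherits(x, cl)) return(cl)
  stop("no JSON serialization for class ", paste(class(x), collapse = "/"),
       call. = FALSE)
}

#' Write a result object to JSON
#'
#' Serializes any of the package's result objects (`precision_curve`,
#' `power_law_model`, `budget_curve`, `piecewise_fit`, `psd_summary`,
#' `material_category`) as JSON with a `schema_version` and `type` field.
#' Numeric values are written at full precision.
#'
#' @param x result object.
#' @param path output file path.
#' @param extra optional named list merged into the payload (e.g. input file
#'   digests, config echo).
#' @return Invisibly, `path`.
#' @export
write_result_json <- function(x, path, extra = NULL) {
  type <- .result_type(x)
  x <- unclass(x)
  if (!is.null(x$percentiles)) x$percentiles <- as.list(x$percentiles)
  payload <- c(list(schema_version = RESULT_SCHEMA_VERSION, type = type), x)
  if (!is.null(extra)) payload <- c(payload, extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a result object back from JSON
#'
#' Restores an object written by [write_result_json()], reattaching its
#' class from the `type` field.
#'
#' @param path JSON file path.
#' @return The result object.
#' @export
read_result_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  type <- obj$type
  if (is.null(type) || is.null(obj$schema_version))
    stop("not a psdcount result JSON (missing type/schema_version): ", path,
         call. = FALSE)
  obj$schema_version <- NULL
  obj$type <- NULL
  structure(obj, class = type)
}

#' Read or write a validation-design manifest
#'
#' The manifest is a small YAML file listing per-dataset CSV paths with day
#' and replicate indices, plus the design constants (certified value and its
#' uncertainty, relative calibration uncertainty, optionally a fixed relative
#' trueness uncertainty). Paths are resolved relative to the manifest file.
#'
#' @param path manifest path.
#' @param dialect table dialect passed to [read_particle_table()].
#' @return `read_design_manifest()` returns a list with `design` (a
#'   [validation_design()]) and `u_tr_rel` (or `NULL`).
#' @export
read_design_manifest <- function(path, dialect = "generic") {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  man <- yaml::read_yaml(path)
  if (is.null(man$datasets) || length(man$datasets) < 2L)
    stop("manifest must list at least 2 datasets", call. = FALSE)
  base <- dirname(normalizePath(path))
  paths <- vapply(man$datasets, `[[`, "", "path")
  abspaths <- ifelse(grepl("^(/|[A-Za-z]:)", paths), paths,
                     file.path(base, paths))
  datasets <- lapply(abspaths, read_particle_table, dialect = dialect)
  design <- validation_design(
    datasets,
    day = vapply(man$datasets, function(d) as.integer(d$day), 1L),
    replicate = vapply(man$datasets,
                       function(d) as.integer(d$replicate %||% 1L), 1L),
    certified_value = man$certified_value,
    u_certified = man$u_certified %||% 0,
    u_cal_rel = man$u_cal_rel %||% 0
  )
  list(design = design, u_tr_rel = man$u_tr_rel)
}

#' @rdname read_design_manifest
#' @param design a [validation_design()] whose datasets will be written as
#'   canonical CSVs next to the manifest.
#' @param dir output directory (created if needed).
#' @param name manifest file name.
#' @export
write_design_manifest <- function(design, dir, name = "design.yaml") {
  stopifnot(inherits(design, "validation_design"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- vector("list", length(design$datasets))
  for (j in seq_along(design$datasets)) {
    fn <- sprintf("day%d_rep%d.csv", design$day[j], design$replicate[j])
    write_particle_table(design$datasets[[j]], file.path(dir, fn))
    entries[[j]] <- list(path = fn, day = design$day[j],
                         replicate = design$replicate[j])
  }
  man <- list(schema_version = RESULT_SCHEMA_VERSION,
              u_cal_rel = design$u_cal_rel,
              datasets = entries)
  if (!is.null(design$certified_value)) {
    man$certified_value <- design$certified_value
    man$u_certified <- design$u_certified
  }
  path <- file.path(dir, name)
  yaml::write_yaml(man, path)
  invisible(path)
}
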