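#' Per-particle measurement datasets
#'
#' A `particle_dataset` holds one row per constituent particle with size
#' measurands in nanometres. Canonical columns are `fmin_nm` (minimum Feret
#' diameter), `fmax_nm` (maximum Feret diameter), `micd_nm` (maximum inscribed
#' circular diameter) and `ecd_nm` (area-equivalent circular diameter). Each
#' column is optional, but at least one size column must be present. The
#' aspect ratio AR = Fmax/Fmin is always derived, never stored.
#'
#' Validity requires all present size values to be finite and positive,
#' `fmax_nm >= fmin_nm` wherever both are present, and at least two particles.
#'
#' @param particles data frame with at least one canonical size column.
#' @param material_id character label for the material.
#' @return An object of class `particle_dataset`: a list with elements
#'   `material_id`, `particles` (data frame restricted to canonical columns)
#'   and `n_tot` (number of particle rows).
#' @examples
#' ds <- particle_dataset(data.frame(fmin_nm = c(10, 20, 30)))
#' ds$n_tot
#' @export
particle_dataset <- function(particles, material_id = "unknown") {
  if (!is.data.frame(particles))
    stop("`particles` must be a data frame", call. = FALSE)
  keep <- intersect(.size_columns, names(particles))
  if (length(keep) == 0L)
    stop("no recognizable size column among: ",
         paste(.size_columns, collapse = ", "), call. = FALSE)
  particles <- as.data.frame(particles)[keep]
  for (cl in keep) particles[[cl]] <- as.numeric(particles[[cl]])
  n <- nrow(particles)
  if (n < 2L)
    stop("a particle dataset needs at least 2 particles (got ", n, ")",
         call. = FALSE)
  for (cl in keep) {
    v <- particles[[cl]]
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad) > 0L)
      stop(sprintf("column %s has %d non-finite or non-positive value(s) (rows %s)",
                   cl, length(bad),
                   paste(utils::head(bad, 5L), collapse = ", ")),
           call. = FALSE)
  }
  if (all(c("fmin_nm", "fmax_nm") %in% keep)) {
    bad <- which(particles$fmax_nm < particles$fmin_nm)
    if (length(bad) > 0L)
      stop("fmax < fmin in row(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  structure(
    list(material_id = as.character(material_id)[1L],
         particles   = particles,
         n_tot       = n),
    class = "particle_dataset"
  )
}

.size_columns <- c("fmin_nm", "fmax_nm", "micd_nm", "ecd_nm")

#' @export
print.particle_dataset <- function(x, ...) {
  cat("Particle dataset:", x$material_id, "\n")
  cat("  particles:", x$n_tot, "\n")
  cat("  size columns:", paste(names(x$particles), collapse = ", "), "\n")
  invisible(x)
}

# Best-effort header map for the ImageJ/ParticleSizer results-table dialect.
# Headers are matched after make.names() normalization, case-insensitively.
.particlesizer_map <- c(
  "minferet"    = "fmin_nm",
  "min.feret"   = "fmin_nm",
  "feret"       = "fmax_nm",
  "maxferet"    = "fmax_nm",
  "ecd"         = "ecd_nm",
  "ced"         = "ecd_nm",
  "area.equivalent.diameter" = "ecd_nm",
  "micd"        = "micd_nm",
  "inscribed.circle.diameter" = "micd_nm",
  "max.inscribed.circle" = "micd_nm"
)

.detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  counts <- c("," = lengths(regmatches(header, gregexpr(",", header, fixed = TRUE))),
              "\t" = lengths(regmatches(header, gregexpr("\t", header, fixed = TRUE))),
              ";" = lengths(regmatches(header, gregexpr(";", header, fixed = TRUE))))
  if (all(counts == 0L)) return(",")
  names(counts)[which.max(counts)]
}

#' Read a per-particle measurement table
#'
#' Reads a delimited text table (comma, tab or semicolon; auto-detected) with
#' a header row into a [particle_dataset()]. The `particlesizer` dialect maps
#' common ImageJ/ParticleSizer result headers (`MinFeret`, `Feret`, ECD-type
#' columns) onto the canonical names; `column_map` supplies or overrides
#' mappings for any other dialect.
#'
#' Rows containing a non-finite or non-positive value in any recognized size
#' column are rejected with a warning stating how many were dropped. Rows with
#' `fmax < fmin` are an error (they indicate upstream segmentation faults and
#' must be surfaced, not repaired).
#'
#' @param path path to a delimited text file with a header row.
#' @param dialect `"generic"` (canonical headers) or `"particlesizer"`.
#' @param column_map optional named character vector `c(file_header = canonical)`
#'   mapping file headers to canonical names (`fmin_nm`, `fmax_nm`, `micd_nm`,
#'   `ecd_nm`).
#' @param material_id material label; defaults to the file name.
#' @return A [particle_dataset()].
#' @export
read_particle_table <- function(path,
                                dialect = c("generic", "particlesizer"),
                                column_map = NULL,
                                material_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  sep <- .detect_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = TRUE,
                           comment.char = "")
  nm <- names(raw)
  canon <- ifelse(tolower(nm) %in% tolower(.size_columns),
                  tolower(nm), NA_character_)
  if (dialect == "particlesizer") {
    hit <- .particlesizer_map[match(tolower(nm), names(.particlesizer_map))]
    canon <- ifelse(is.na(canon) & !is.na(hit), hit, canon)
  }
  if (!is.null(column_map)) {
    if (is.null(names(column_map)))
      stop("`column_map` must be a named character vector", call. = FALSE)
    hit <- column_map[match(tolower(nm), tolower(names(column_map)))]
    canon <- ifelse(!is.na(hit), unname(hit), canon)
  }
  keep <- which(!is.na(canon) & canon %in% .size_columns)
  if (length(keep) == 0L)
    stop("no recognizable size column in ", path,
         " (headers: ", paste(nm, collapse = ", "), ")", call. = FALSE)
  df <- raw[keep]
  names(df) <- canon[keep]
  df <- df[!duplicated(names(df))]
  for (cl in names(df)) df[[cl]] <- as.numeric(df[[cl]])
  ok <- Reduce(`&`, lapply(df, function(v) is.finite(v) & v > 0))
  if (any(!ok)) {
    warning(sprintf("rejected %d row(s) with non-finite or non-positive values",
                    sum(!ok)), call. = FALSE)
    df <- df[ok, , drop = FALSE]
  }
  if (all(c("fmin_nm", "fmax_nm") %in% names(df))) {
    bad <- which(df$fmax_nm < df$fmin_nm)
    if (length(bad) > 0L)
      stop("fmax < fmin in row(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  particle_dataset(df, material_id %||% basename(path))
}

#' Write a per-particle measurement table
#'
#' Writes the canonical CSV form of a dataset. Numeric values are written with
#' 17 significant digits so that reading the file back reproduces the original
#' doubles exactly.
#'
#' @param dataset a [particle_dataset()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_particle_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "particle_dataset"))
  df <- dataset$particles
  out <- as.data.frame(lapply(df, function(v) sprintf("%.17g", v)),
                       stringsAsFactors = FALSE)
  names(out) <- names(df)
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Measurands of a particle dataset
#'
#' The recognized measurands are the size measurands FMIN, FMAX, MICD, ECD
#' (stored columns, in nm) and the shape measurand AR (aspect ratio,
#' Fmax/Fmin, dimensionless, always derived).
#'
#' @return `measurands()` returns a data frame with columns `name` and `kind`.
#' @export
measurands <- function() {
  data.frame(name = c("fmin", "fmax", "micd", "ecd", "ar"),
             kind = c("size", "size", "size", "size", "shape"),
             stringsAsFactors = FALSE)
}

#' Extract one measurand as a numeric vector
#'
#' Returns one value per particle. Size measurands are returned as stored;
#' the aspect ratio is computed as `fmax/fmin` and requires both Feret
#' columns.
#'
#' @param dataset a [particle_dataset()].
#' @param measurand one of `"fmin"`, `"fmax"`, `"micd"`, `"ecd"`, `"ar"`
#'   (case-insensitive).
#' @return Numeric vector of length `dataset$n_tot`.
#' @examples
#' ds <- particle_dataset(data.frame(fmin_nm = c(10, 20), fmax_nm = c(30, 20)))
#' derive_measurand(ds, "ar")  # 3, 1
#' @export
derive_measurand <- function(dataset, measurand) {
  stopifnot(inherits(dataset, "particle_dataset"))
  m <- tolower(measurand)
  if (!m %in% measurands()$name)
    stop("unknown measurand: ", measurand, call. = FALSE)
  df <- dataset$particles
  if (m == "ar") {
    if (!all(c("fmin_nm", "fmax_nm") %in% names(df)))
      stop("aspect ratio requires both fmin and fmax columns", call. = FALSE)
    return(df$fmax_nm / df$fmin_nm)
  }
  col <- paste0(m, "_nm")
  if (!col %in% names(df))
    stop("measurand ", m, " not present in dataset (no column ", col, ")",
         call. = FALSE)
  df[[col]]
}

#' Days-by-replicates validation design
#'
#' Bundles repeated measurements of one material — several datasets acquired
#' on at least two different days, ideally with within-day replicates — with
#' the metrological constants needed for a total uncertainty budget: an
#' optional certified value with its standard uncertainty, and the relative
#' standard calibration uncertainty.
#'
#' @param datasets list of [particle_dataset()] objects.
#' @param day integer vector (>= 1) giving the measurement day of each dataset.
#' @param replicate integer vector (>= 1) giving the within-day replicate
#'   index; defaults to running indices within each day.
#' @param certified_value optional certified value of the measurand percentile
#'   under study, in nm.
#' @param u_certified standard uncertainty of the certified value, in nm.
#' @param u_cal_rel relative standard calibration uncertainty (dimensionless).
#' @return An object of class `validation_design`.
#' @export
validation_design <- function(datasets, day, replicate = NULL,
                              certified_value = NULL, u_certified = 0,
                              u_cal_rel = 0) {
  if (!is.list(datasets) || !all(vapply(datasets, inherits, TRUE, "particle_dataset")))
    stop("`datasets` must be a list of particle_dataset objects", call. = FALSE)
  day <- as.integer(day)
  if (length(day) != length(datasets) || any(day < 1L))
    stop("`day` must give one index >= 1 per dataset", call. = FALSE)
  if (length(datasets) < 2L || length(unique(day)) < 2L)
    stop("a validation design needs >= 2 datasets on >= 2 distinct days",
         call. = FALSE)
  if (is.null(replicate)) {
    replicate <- stats::ave(day, day, FUN = seq_along)
  }
  replicate <- as.integer(replicate)
  if (length(replicate) != length(datasets) || any(replicate < 1L))
    stop("`replicate` must give one index >= 1 per dataset", call. = FALSE)
  if (!is.null(certified_value)) {
    .assert_scalar_number(certified_value, "certified_value", positive = TRUE)
    .assert_scalar_number(u_certified, "u_certified")
    if (u_certified < 0) stop("`u_certified` must be >= 0", call. = FALSE)
  }
  .assert_scalar_number(u_cal_rel, "u_cal_rel")
  if (u_cal_rel < 0) stop("`u_cal_rel` must be >= 0", call. = FALSE)
  structure(
    list(datasets = datasets, day = day, replicate = replicate,
         certified_value = certified_value,
         u_certified = if (is.null(certified_value)) NULL else u_certified,
         u_cal_rel = u_cal_rel),
    class = "validation_design"
  )
}

#' @export
print.validation_design <- function(x, ...) {
  cat("Validation design:", length(x$datasets), "datasets over",
      length(unique(x$day)), "days\n")
  cat("  sizes:", paste(vapply(x$datasets, `[[`, 1L, "n_tot"), collapse = ", "), "\n")
  if (!is.null(x$certified_value))
    cat("  certified value:", x$certified_value, "nm (u =", x$u_certified, "nm)\n")
  cat("  u_cal (relative):", x$u_cal_rel, "\n")
  invisible(x)
}
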