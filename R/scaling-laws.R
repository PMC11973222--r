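#' Power-law fit of minimum count versus polydispersity
#'
#' Fits N_m = a * (IQR%)^b by least squares of `log(n_m)` on `log(iqr_pct)`,
#' mirroring the linear log-log presentation of the scaling (scale-free
#' residuals), rather than nonlinear least squares.
#'
#' @param iqr_pct numeric vector of normalized interquartile ranges (percent),
#'   all positive, at least 3 points with at least 2 distinct values.
#' @param n_m numeric vector of minimum particle counts, all positive.
#' @param u_target the target relative expanded uncertainty the `n_m` values
#'   refer to (recorded in the model, not used in the fit).
#' @return An object of class `power_law_model`: list with `coefficient_a`,
#'   `exponent_b`, `u_target`, `fit_r2` and `points` (data frame of the pairs
#'   used).
#' @examples
#' m <- fit_power_law(c(10, 20, 40), 0.5 * c(10, 20, 40)^2, u_target = 0.05)
#' c(m$coefficient_a, m$exponent_b)  # 0.5, 2
#' @export
fit_power_law <- function(iqr_pct, n_m, u_target = NA_real_) {
  if (length(iqr_pct) != length(n_m))
    stop("`iqr_pct` and `n_m` must have the same length", call. = FALSE)
  if (length(iqr_pct) < 3L)
    stop("need at least 3 points for a power-law fit", call. = FALSE)
  if (!all(is.finite(iqr_pct) & iqr_pct > 0) || !all(is.finite(n_m) & n_m > 0))
    stop("all `iqr_pct` and `n_m` values must be positive", call. = FALSE)
  if (length(unique(iqr_pct)) < 2L)
    stop("rank deficient: all `iqr_pct` values are identical", call. = FALSE)
  fit <- stats::lm(log(n_m) ~ log(iqr_pct))
  # exact log-linear input triggers a benign "perfect fit" note in summary()
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(
    list(coefficient_a = unname(exp(stats::coef(fit)[1L])),
         exponent_b = unname(stats::coef(fit)[2L]),
         u_target = u_target,
         fit_r2 = r2,
         points = data.frame(iqr_pct = iqr_pct, n_m = n_m)),
    class = "power_law_model"
  )
}

#' @export
print.power_law_model <- function(x, ...) {
  cat(sprintf("Power law: N_m = %.4g * (IQR%%)^%.3f  (R^2 = %.4f, %d points)\n",
              x$coefficient_a, x$exponent_b, x$fit_r2, nrow(x$points)))
  if (is.finite(x$u_target))
    cat(sprintf("  fitted for target U_N = %g%%\n", 100 * x$u_target))
  invisible(x)
}

# Category tables. Size categories partition (0, 80]; shape defines only
# I and II. Recommended counts are the published guidance values for the
# size categories at U_N = 10 % and 5 %; none are published for shape.
.size_categories <- data.frame(
  label = c("I", "II", "III"),
  lower = c(0, 30, 55),
  upper = c(30, 55, 80),
  n_at_10pct = c(35, 110, 260),
  n_at_5pct = c(150, 450, 1000),
  stringsAsFactors = FALSE
)
.shape_categories <- .size_categories[1:2, c("label", "lower", "upper")]

#' Polydispersity category of a material
#'
#' Assigns the material category from its IQR%: for size measurands,
#' (I) low (IQR% <= 30), (II) medium (30 < IQR% <= 55) and (III) large
#' (55 < IQR% <= 80) polydispersity, with the recommended minimum particle
#' counts 35/150 (I), 110/450 (II) and 260/1000 (III) for U_N = 10 %/5 %.
#' For the shape measurand (aspect ratio) only categories I and II are
#' defined, without published counts. Intervals are half-open with a closed
#' upper bound. Values beyond the categorized range (80 for size, 55 for
#' shape) yield an explicit out-of-range result, never a silent clamp: the
#' grouping is only anchored by the materials it was derived from.
#'
#' @param iqr_pct normalized interquartile range in percent (> 0).
#' @param mode `"size"` or `"shape"`.
#' @return An object of class `material_category`: list with `label` (`"I"`,
#'   `"II"`, `"III"`, or `NA` when out of range), `mode`, `in_range`,
#'   `iqr_range` (the category's interval) and `recommended_n` (named list
#'   with elements `"0.10"` and `"0.05"`, or `NULL`).
#' @examples
#' categorize(25, "size")$recommended_n
#' @export
categorize <- function(iqr_pct, mode = c("size", "shape")) {
  mode <- match.arg(mode)
  .assert_scalar_number(iqr_pct, "iqr_pct", positive = TRUE)
  tab <- if (mode == "size") .size_categories else .shape_categories
  hit <- which(iqr_pct > tab$lower & iqr_pct <= tab$upper)
  if (length(hit) == 0L) {
    return(structure(
      list(label = NA_character_, mode = mode, iqr_pct = iqr_pct,
           in_range = FALSE, iqr_range = NULL, recommended_n = NULL,
           message = sprintf("IQR%% = %g is out of the categorized range (0, %g] for %s",
                             iqr_pct, max(tab$upper), mode)),
      class = "material_category"))
  }
  row <- tab[hit, ]
  rec <- if (mode == "size")
    list("0.10" = as.integer(row$n_at_10pct), "0.05" = as.integer(row$n_at_5pct))
  else NULL
  structure(
    list(label = row$label, mode = mode, iqr_pct = iqr_pct, in_range = TRUE,
         iqr_range = c(lower = row$lower, upper = row$upper),
         recommended_n = rec),
    class = "material_category"
  )
}

#' @export
print.material_category <- function(x, ...) {
  if (!x$in_range) {
    cat(x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("Category %s (%s polydispersity, IQR%% in (%g, %g])\n",
              x$label, x$mode, x$iqr_range[["lower"]], x$iqr_range[["upper"]]))
  if (!is.null(x$recommended_n))
    cat(sprintf("  recommended counts: %d (U_N = 10%%), %d (U_N = 5%%)\n",
                x$recommended_n[["0.10"]], x$recommended_n[["0.05"]]))
  invisible(x)
}

#' Predict the minimum particle count from a fitted power law
#'
#' Evaluates `ceiling(a * iqr_pct^b)`. Predictions outside 0.5x--2x the fitted
#' IQR% range are allowed but flagged as extrapolation.
#'
#' @param model a [fit_power_law()] model.
#' @param iqr_pct normalized interquartile range in percent (> 0).
#' @return Integer predicted N_m with attribute `flags`.
#' @export
predict_nm <- function(model, iqr_pct) {
  stopifnot(inherits(model, "power_law_model"))
  .assert_scalar_number(iqr_pct, "iqr_pct", positive = TRUE)
  flags <- character(0)
  rng <- range(model$points$iqr_pct)
  if (iqr_pct < 0.5 * rng[1L] || iqr_pct > 2 * rng[2L])
    flags <- "extrapolated"
  pred <- model$coefficient_a * iqr_pct^model$exponent_b
  structure(as.integer(ceiling(pred - 1e-9)), flags = flags)
}
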