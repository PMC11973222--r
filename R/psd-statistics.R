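#' Percentile of a number-based distribution
#'
#' The fixed quantile convention used throughout the package (bootstrap
#' included): the order statistic with linear interpolation between closest
#' ranks at position `1 + (n - 1) * p` (R's type-7 quantile). Ties are handled
#' implicitly by sorting.
#'
#' @param values numeric vector, non-empty and finite.
#' @param p probability strictly between 0 and 1 (vectorized).
#' @return Numeric vector of percentile values, one per element of `p`.
#' @examples
#' psd_percentile(c(1, 2, 3, 4), 0.25)  # 1.75
#' @export
psd_percentile <- function(values, p) {
  if (length(values) == 0L)
    stop("`values` must be non-empty", call. = FALSE)
  if (!all(is.finite(values)))
    stop("`values` must be finite", call. = FALSE)
  if (!is.numeric(p) || length(p) == 0L || any(p <= 0 | p >= 1))
    stop("`p` must lie strictly between 0 and 1", call. = FALSE)
  stats::quantile(values, probs = p, type = 7, names = FALSE)
}

#' Percentile and width summary of a measurand distribution
#'
#' Computes D10, D25, D50, D75 and D90 of the number-based distribution,
#' the interquartile range IQR = D75 - D25, and the normalized interquartile
#' range IQR% = 100 * IQR / D50 used as the polydispersity measure. IQR% is
#' invariant under multiplicative rescaling of the data.
#'
#' @param values numeric vector of positive measurand values.
#' @return An object of class `psd_summary`: list with `percentiles` (named
#'   vector D10..D90), `iqr`, `iqr_pct` and `n`.
#' @examples
#' s <- psd_summary(stats::rlnorm(1000, log(20), 0.2))
#' s$iqr_pct
#' @export
psd_summary <- function(values) {
  if (length(values) == 0L)
    stop("`values` must be non-empty", call. = FALSE)
  if (!all(is.finite(values) & values > 0))
    stop("`values` must be finite and positive", call. = FALSE)
  q <- psd_percentile(values, .percentile_probs)
  names(q) <- .percentile_labels
  d50 <- q[["D50"]]
  if (d50 <= 0) stop("non-positive median", call. = FALSE)
  iqr <- q[["D75"]] - q[["D25"]]
  structure(
    list(percentiles = q,
         iqr = iqr,
         iqr_pct = 100 * iqr / d50,
         n = length(values)),
    class = "psd_summary"
  )
}

#' @export
print.psd_summary <- function(x, digits = 4, ...) {
  cat("PSD summary (n =", x$n, ")\n")
  print(signif(x$percentiles, digits))
  cat("IQR =", signif(x$iqr, digits),
      " IQR% =", signif(x$iqr_pct, digits), "\n")
  invisible(x)
}

#' Summaries for every available measurand of a dataset
#'
#' @param dataset a [particle_dataset()].
#' @return Named list of [psd_summary()] objects, one per measurand that can
#'   be derived from the dataset (AR included when both Feret columns exist).
#' @export
psd_summarize_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "particle_dataset"))
  avail <- sub("_nm$", "", names(dataset$particles))
  if (all(c("fmin", "fmax") %in% avail)) avail <- c(avail, "ar")
  out <- lapply(avail, function(m) psd_summary(derive_measurand(dataset, m)))
  names(out) <- avail
  out
}
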