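#' Default subsampling grid of particle counts
#'
#' Log-spaced integer grid from the floor (default 10) to `n_tot`, with
#' duplicates removed after rounding; `n_tot` is always included.
#'
#' @param n_tot largest available particle count.
#' @param points nominal number of grid points.
#' @param floor smallest subset size.
#' @return Strictly increasing integer vector.
#' @export
default_n_grid <- function(n_tot, points = 30, floor = 10) {
  n_tot <- as.integer(n_tot)
  if (n_tot <= floor) stop("`n_tot` must exceed the grid floor", call. = FALSE)
  g <- unique(as.integer(round(10^seq(log10(floor), log10(n_tot),
                                      length.out = points))))
  g[length(g)] <- n_tot
  sort(unique(g))
}

# Draw `reps` with-replacement subsets of size n from `values` and return the
# reps x 5 matrix of D10..D90 of each subset. One RNG substream per (seed, n).
.boot_matrix <- function(values, n, reps, seed) {
  old <- .Random.seed_safe_get()
  on.exit(.Random.seed_safe_set(old))
  set.seed(.derive_seed(seed, n))
  idx <- sample.int(length(values), n * reps, replace = TRUE)
  m <- matrix(values[idx], nrow = reps, ncol = n, byrow = TRUE)
  out <- t(apply(m, 1L, stats::quantile, probs = .percentile_probs,
                 type = 7, names = FALSE))
  colnames(out) <- .percentile_labels
  out
}

.Random.seed_safe_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_safe_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Bootstrap percentile draws at one subset size
#'
#' Draws `reps` random subsets of `n` particles with replacement from the full
#' dataset and computes D10, D25, D50, D75 and D90 of each subset. The result
#' is bit-identical for identical `(dataset, measurand, n, reps, seed)`.
#'
#' @param dataset a [particle_dataset()].
#' @param measurand measurand name, see [derive_measurand()].
#' @param n subset size, at least 10.
#' @param reps number of repeated draws, at least 2 (500 by default).
#' @param seed master seed; the per-`n` substream is derived from it, so a
#'   grid can be extended without reshuffling draws at other `n`.
#' @return `reps` x 5 numeric matrix with columns D10..D90.
#' @export
bootstrap_percentiles <- function(dataset, measurand, n, reps = 500, seed = 1) {
  stopifnot(inherits(dataset, "particle_dataset"))
  n <- as.integer(n); reps <- as.integer(reps)
  if (n < 10L) stop("`n` must be at least 10", call. = FALSE)
  if (reps < 2L) stop("`reps` must be at least 2", call. = FALSE)
  values <- derive_measurand(dataset, measurand)
  .boot_matrix(values, n, reps, seed)
}

#' Mean and standard deviation of percentile draws
#'
#' The spread of the repeated-subset percentile values: mean `dbar` and the
#' sample standard deviation `sigma` with divisor `reps - 1` (divisor 499 at
#' the default 500 repetitions).
#'
#' @param draws numeric vector of percentile values from repeated subsets.
#' @return Named numeric vector `c(dbar, sigma)`.
#' @examples
#' sigma_of_draws(c(1, 2, 3))  # dbar 2, sigma 1
#' @export
sigma_of_draws <- function(draws) {
  if (length(draws) < 2L) stop("need at least 2 draws", call. = FALSE)
  c(dbar = mean(draws), sigma = stats::sd(draws))
}

#' Count-limited relative expanded uncertainty
#'
#' U_N = 2 * sigma / dbar (coverage factor k = 2, ~95 % confidence),
#' dimensionless; multiply by 100 for percent.
#'
#' @param dbar mean percentile value over the repeated subsets (> 0).
#' @param sigma standard deviation of the percentile values (>= 0).
#' @return Relative expanded uncertainty (vectorized).
#' @examples
#' u_n(dbar = 20, sigma = 1)  # 0.10
#' @export
u_n <- function(dbar, sigma) {
  if (any(!is.finite(dbar)) || any(dbar <= 0))
    stop("`dbar` must be positive", call. = FALSE)
  if (any(sigma < 0)) stop("`sigma` must be >= 0", call. = FALSE)
  2 * sigma / dbar
}

# Shared engine: dbar and sigma matrices (grid x 5) for all five percentiles.
.boot_stats_grid <- function(values, n_grid, reps, seed) {
  k <- length(n_grid)
  dbar <- sigma <- matrix(NA_real_, k, 5L,
                          dimnames = list(NULL, .percentile_labels))
  for (i in seq_len(k)) {
    draws <- .boot_matrix(values, n_grid[i], reps, seed)
    dbar[i, ]  <- colMeans(draws)
    sigma[i, ] <- apply(draws, 2L, stats::sd)
  }
  list(dbar = dbar, sigma = sigma)
}

.fit_loglog <- function(n_grid, u) {
  pos <- u > 0
  if (sum(pos) < 3L)
    stop_numerical("too few positive U_N values for a log-log fit",
                   u_n = u, n_grid = n_grid)
  fit <- stats::lm(log10(u[pos]) ~ log10(n_grid[pos]))
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r2 = summary(fit)$r.squared)
}

.new_precision_curve <- function(measurand, label, n_grid, dbar, sigma,
                                 reps, seed, n_tot, material_id) {
  u <- u_n(dbar, sigma)
  if (all(u == 0))
    stop_numerical(
      "zero-dispersion data: U_N is zero at every N, no log-log fit possible",
      u_n = u, n_grid = n_grid)
  fit <- .fit_loglog(n_grid, u)
  structure(
    list(measurand = measurand, percentile_label = label,
         n_grid = n_grid, dbar = dbar, sigma = sigma, u_n = u,
         reps = reps, seed = seed, n_tot = n_tot, material_id = material_id,
         loglog_slope = fit$slope, loglog_intercept = fit$intercept,
         fit_r2 = fit$r2),
    class = "precision_curve"
  )
}

#' Precision curve: U_N as a function of particle count
#'
#' For each subset size N on the grid, draws `reps` with-replacement subsets,
#' computes the chosen percentile of each, and summarizes the draws into the
#' mean `dbar`, standard deviation `sigma` and relative expanded uncertainty
#' `u_n = 2*sigma/dbar` (k = 2). An ordinary least-squares fit of
#' `log10(u_n)` on `log10(N)` provides the slope, intercept and R^2 of the
#' (empirically linear) log-log precision law.
#'
#' @param dataset a [particle_dataset()].
#' @param measurand measurand name.
#' @param percentile one of `"D10"`, `"D25"`, `"D50"`, `"D75"`, `"D90"`.
#' @param n_grid strictly increasing integer vector within `[10, n_tot]`;
#'   defaults to [default_n_grid()] of the dataset.
#' @param reps repeated draws per grid point (500 by default).
#' @param seed master seed for the bootstrap substreams.
#' @return An object of class `precision_curve` with fields `n_grid`, `dbar`,
#'   `sigma`, `u_n`, `loglog_slope`, `loglog_intercept`, `fit_r2`, plus the
#'   provenance fields `measurand`, `percentile_label`, `reps`, `seed`,
#'   `n_tot`, `material_id`.
#' @seealso [minimum_count()], [fit_spline()], [percentile_profile()]
#' @export
precision_curve <- function(dataset, measurand, percentile = "D50",
                            n_grid = NULL, reps = 500, seed = 1) {
  stopifnot(inherits(dataset, "particle_dataset"))
  i <- .match_percentile(percentile)
  n_grid <- .check_grid(n_grid %||% default_n_grid(dataset$n_tot),
                        dataset$n_tot)
  values <- derive_measurand(dataset, measurand)
  bs <- .boot_stats_grid(values, n_grid, reps, seed)
  .new_precision_curve(tolower(measurand), .percentile_labels[i], n_grid,
                       bs$dbar[, i], bs$sigma[, i], as.integer(reps),
                       as.integer(seed), dataset$n_tot, dataset$material_id)
}

.check_grid <- function(n_grid, n_tot) {
  n_grid <- as.integer(n_grid)
  if (any(diff(n_grid) <= 0L)) stop("`n_grid` must be strictly increasing",
                                    call. = FALSE)
  if (n_grid[1L] < 10L) stop("`n_grid` values must be >= 10", call. = FALSE)
  if (n_grid[length(n_grid)] > n_tot)
    stop("`n_grid` exceeds the dataset size n_tot = ", n_tot, call. = FALSE)
  n_grid
}

#' @export
print.precision_curve <- function(x, ...) {
  cat(sprintf("Precision curve: %s %s of material '%s' (n_tot = %d)\n",
              x$percentile_label, toupper(x$measurand), x$material_id, x$n_tot))
  cat(sprintf("  grid: %d points in [%d, %d], reps = %d, seed = %d\n",
              length(x$n_grid), x$n_grid[1L], x$n_grid[length(x$n_grid)],
              x$reps, x$seed))
  cat(sprintf("  log-log fit: slope %.3f, intercept %.3f, R^2 %.4f\n",
              x$loglog_slope, x$loglog_intercept, x$fit_r2))
  invisible(x)
}

#' Monotone smooth-spline fit of a precision curve
#'
#' Fits a smoothing spline to `(log10 N, log10 U_N)` with the smoothing level
#' chosen by leave-one-out cross-validation, then post-corrects the fitted
#' values to be non-increasing (isotonic regression on the negated values).
#' Returns a function evaluable on `[min(n_grid), max(n_grid)]`.
#'
#' @param curve a [precision_curve()] with at least 5 grid points.
#' @param spar optional fixed smoothing parameter passed to
#'   [stats::smooth.spline()]; by default leave-one-out CV chooses it.
#' @return A function `f(n)` returning the fitted U_N, guaranteed
#'   non-increasing in `n`.
#' @export
fit_spline <- function(curve, spar = NULL) {
  stopifnot(inherits(curve, "precision_curve"))
  pos <- curve$u_n > 0
  if (sum(pos) < 5L) stop("need at least 5 grid points with positive U_N",
                          call. = FALSE)
  x <- log10(curve$n_grid[pos]); y <- log10(curve$u_n[pos])
  sp <- if (is.null(spar)) stats::smooth.spline(x, y, cv = TRUE)
        else stats::smooth.spline(x, y, spar = spar)
  xf <- seq(min(x), max(x), length.out = 400L)
  yf <- stats::predict(sp, xf)$y
  yf <- -stats::isoreg(xf, -yf)$yf  # enforce non-increasing
  lo <- min(curve$n_grid); hi <- max(curve$n_grid)
  structure(function(n) {
    if (any(n < lo | n > hi))
      stop(sprintf("spline is defined on [%d, %d]", lo, hi), call. = FALSE)
    10^stats::approx(xf, yf, xout = log10(n))$y
  }, range = c(lo, hi))
}

.nm_from_loglog <- function(slope, intercept, u_target) {
  if (slope >= 0)
    stop_numerical("non-negative log-log slope: cannot invert precision curve")
  10^((log10(u_target) - intercept) / slope)
}

#' Minimum particle count for a target precision
#'
#' Inverts the fitted precision curve at a target relative expanded
#' uncertainty: the smallest integer N with fitted U_N(N) <= `u_target`.
#' The default inversion uses the log-log line (robust to Monte-Carlo noise
#' at large N); `method = "spline"` inverts the monotone spline instead.
#' The result is clamped to the grid floor when the curve is already below
#' target there (flag `"at_grid_floor"`), and extrapolation beyond the
#' dataset size is permitted but flagged (`"extrapolated"`).
#'
#' @param curve a [precision_curve()].
#' @param u_target target relative expanded uncertainty in (0, 1), e.g. 0.10
#'   for 10 %.
#' @param method `"loglog"` (default) or `"spline"`.
#' @return Integer N_m with attribute `flags` (character vector, possibly
#'   empty).
#' @export
minimum_count <- function(curve, u_target, method = c("loglog", "spline")) {
  stopifnot(inherits(curve, "precision_curve"))
  method <- match.arg(method)
  .assert_scalar_number(u_target, "u_target", positive = TRUE)
  if (u_target >= 1) stop("`u_target` must be a fraction in (0, 1)",
                          call. = FALSE)
  flags <- character(0)
  floor_n <- curve$n_grid[1L]
  if (method == "loglog") {
    nm <- .nm_from_loglog(curve$loglog_slope, curve$loglog_intercept, u_target)
  } else {
    f <- fit_spline(curve)
    hi <- curve$n_grid[length(curve$n_grid)]
    if (f(floor_n) <= u_target) {
      nm <- floor_n
    } else if (f(hi) > u_target) {
      # spline never reaches target on the grid: extrapolate with the log-log line
      nm <- .nm_from_loglog(curve$loglog_slope, curve$loglog_intercept, u_target)
      flags <- c(flags, "extrapolated")
    } else {
      nm <- stats::uniroot(function(n) f(n) - u_target,
                           lower = floor_n, upper = hi)$root
    }
  }
  if (nm <= floor_n) {
    flags <- c(flags, "at_grid_floor")
    nm <- floor_n
  }
  nm <- as.integer(ceiling(nm - 1e-9))
  if (nm > curve$n_tot) flags <- unique(c(flags, "extrapolated"))
  structure(nm, flags = flags)
}

#' Minimum particle count per percentile (D10..D90)
#'
#' Runs the subsampling procedure once per grid point (all five percentiles
#' are extracted from the same draws) and inverts each percentile's fitted
#' precision curve at the target uncertainty, producing the per-percentile
#' minimum-count profile.
#'
#' @inheritParams precision_curve
#' @param u_target target relative expanded uncertainty in (0, 1).
#' @param method inversion method, see [minimum_count()].
#' @return Data frame with columns `percentile`, `n_m` and `flags`; the five
#'   underlying `precision_curve` objects are attached as attribute
#'   `curves`.
#' @export
percentile_profile <- function(dataset, measurand, u_target = 0.10,
                               n_grid = NULL, reps = 500, seed = 1,
                               method = "loglog") {
  stopifnot(inherits(dataset, "particle_dataset"))
  n_grid <- .check_grid(n_grid %||% default_n_grid(dataset$n_tot),
                        dataset$n_tot)
  values <- derive_measurand(dataset, measurand)
  bs <- .boot_stats_grid(values, n_grid, reps, seed)
  curves <- lapply(seq_along(.percentile_labels), function(i)
    .new_precision_curve(tolower(measurand), .percentile_labels[i], n_grid,
                         bs$dbar[, i], bs$sigma[, i], as.integer(reps),
                         as.integer(seed), dataset$n_tot, dataset$material_id))
  names(curves) <- .percentile_labels
  nm <- lapply(curves, minimum_count, u_target = u_target, method = method)
  out <- data.frame(
    percentile = .percentile_labels,
    n_m = vapply(nm, as.integer, 1L),
    flags = vapply(nm, function(z) paste(attr(z, "flags"), collapse = ";"), ""),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "curves") <- curves
  attr(out, "u_target") <- u_target
  out
}
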