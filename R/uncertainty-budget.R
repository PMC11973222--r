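#' Combine standard uncertainty components into an expanded uncertainty
#'
#' U = k * sqrt(u_ip^2 + u_tr^2 + u_cal^2), the root-sum-of-squares of the
#' relative standard uncertainties for intermediate precision, trueness and
#' calibration, expanded with coverage factor k (default 2, ~95 % confidence).
#'
#' @param u_ip,u_tr,u_cal relative standard uncertainties (>= 0; vectorized).
#' @param k coverage factor.
#' @return Relative expanded uncertainty.
#' @examples
#' combine_uncertainty(0.03, 0.04, 0)  # 0.10
#' @export
combine_uncertainty <- function(u_ip, u_tr, u_cal, k = 2) {
  if (any(c(u_ip, u_tr, u_cal) < 0))
    stop("uncertainty components must be >= 0", call. = FALSE)
  k * sqrt(u_ip^2 + u_tr^2 + u_cal^2)
}

# Core per-N engine shared by intermediate_precision() and budget_curve().
# For each of `reps` simulation draws: one with-replacement subset of size n
# per design dataset -> percentile per dataset -> one-way variance
# decomposition with day as grouping factor. All reps are handled in a single
# lm() fit with a matrix response (columns = reps).
.budget_at_n <- function(pvals, day, n, reps, seed, prob,
                         certified = NULL, u_certified = 0) {
  J <- length(pvals)
  Y <- matrix(NA_real_, J, reps)
  for (j in seq_len(J)) {
    old <- .Random.seed_safe_get()
    set.seed(.derive_seed(.derive_seed(seed, n), j))
    idx <- sample.int(length(pvals[[j]]), n * reps, replace = TRUE)
    m <- matrix(pvals[[j]][idx], nrow = reps, ncol = n, byrow = TRUE)
    Y[j, ] <- apply(m, 1L, stats::quantile, probs = prob, type = 7,
                    names = FALSE)
    .Random.seed_safe_set(old)
  }
  fday <- factor(day)
  k <- nlevels(fday)
  dbar_r <- colMeans(Y)
  if (J > k) {
    fit <- stats::lm.fit(stats::model.matrix(~fday), Y)
    rss <- colSums(as.matrix(fit$residuals)^2)
    ms_w <- rss / (J - k)
    tss <- colSums(sweep(Y, 2L, dbar_r)^2)
    ms_b <- (tss - rss) / (k - 1)
    r_bar <- k / sum(1 / table(fday))  # harmonic-mean replicates per day
    s_b2 <- pmax(0, (ms_b - ms_w) / r_bar)
    u_ip_r <- sqrt(s_b2 + ms_w) / dbar_r
  } else {
    # one replicate per day: no within-day df, fall back to total spread
    u_ip_r <- apply(Y, 2L, stats::sd) / dbar_r
  }
  out <- list(u_ip = mean(u_ip_r), dbar = mean(dbar_r))
  if (!is.null(certified)) {
    se_mean_r <- apply(Y, 2L, stats::sd) / sqrt(J)
    u_tr_r <- sqrt((dbar_r - certified)^2 + u_certified^2 + se_mean_r^2) /
      certified
    out$u_tr <- mean(u_tr_r)
  }
  out
}

#' Intermediate-precision uncertainty at one subset size
#'
#' Estimates the relative standard uncertainty u_IP, covering within-day and
#' between-day variation, at subset size `n`. Per simulation draw, one
#' with-replacement subset of size `n` is taken from each validation dataset
#' and its percentile computed; a one-way variance decomposition with day as
#' grouping factor gives the within-day mean square MS_w and between-day mean
#' square MS_b, combined as `sqrt(max(0, (MS_b - MS_w)/r) + MS_w)` with `r`
#' the harmonic-mean number of replicates per day, expressed relative to the
#' grand mean. The returned value is the average over `reps` simulation
#' draws. Negative between-day variance components are clipped to zero.
#'
#' @param design a [validation_design()].
#' @param measurand measurand name, see [derive_measurand()].
#' @param percentile percentile label, `"D50"` by default.
#' @param n subset size; must not exceed the smallest dataset.
#' @param reps simulation draws (500 by default).
#' @param seed master seed.
#' @return List with `u_ip` (relative standard uncertainty) and `dbar`
#'   (grand mean percentile, nm).
#' @export
intermediate_precision <- function(design, measurand, percentile = "D50",
                                   n, reps = 500, seed = 1) {
  stopifnot(inherits(design, "validation_design"))
  i <- .match_percentile(percentile)
  n <- as.integer(n)
  sizes <- vapply(design$datasets, `[[`, 1L, "n_tot")
  if (n < 10L) stop("`n` must be at least 10", call. = FALSE)
  if (n > min(sizes))
    stop("`n` exceeds the smallest validation dataset (", min(sizes), ")",
         call. = FALSE)
  pvals <- lapply(design$datasets, derive_measurand, measurand)
  res <- .budget_at_n(pvals, design$day, n, as.integer(reps), as.integer(seed),
                      .percentile_probs[i])
  res[c("u_ip", "dbar")]
}

#' Trueness uncertainty relative to a certified value
#'
#' Standard bias-assessment combination against a certified reference value:
#' `u_tr = sqrt(delta^2 + u_certified^2 + se_mean^2) / certified_value` with
#' `delta = dbar - certified_value`.
#'
#' @param dbar measured mean percentile value (nm).
#' @param certified_value certified value (nm, > 0).
#' @param u_certified standard uncertainty of the certified value (nm).
#' @param se_mean standard error of the measured mean (nm).
#' @return Relative standard trueness uncertainty.
#' @examples
#' trueness_uncertainty(20.4, 20, 0.3)  # 0.025
#' @export
trueness_uncertainty <- function(dbar, certified_value, u_certified = 0,
                                 se_mean = 0) {
  .assert_scalar_number(certified_value, "certified_value", positive = TRUE)
  if (u_certified < 0 || se_mean < 0)
    stop("`u_certified` and `se_mean` must be >= 0", call. = FALSE)
  sqrt((dbar - certified_value)^2 + u_certified^2 + se_mean^2) /
    certified_value
}

#' Total expanded uncertainty as a function of particle count
#'
#' For each subset size N on the grid, averages the intermediate-precision
#' and trueness components over repeated subsampling of the validation
#' datasets and combines them with the constant calibration component into
#' the total relative expanded uncertainty
#' `u_cx = 2 * sqrt(u_ip^2 + u_tr^2 + u_cal^2)`.
#'
#' The trueness component is computed against the design's certified value
#' when present; otherwise a fixed relative value must be supplied through
#' `u_tr_rel` (there is no silent default: when no reference value exists,
#' trueness cannot be assessed from the data alone). As a diagnostic, the
#' count-only uncertainty U_N of the pooled dataset is computed on the same
#' grid (`u_n_component`).
#'
#' @param design a [validation_design()].
#' @param measurand measurand name.
#' @param percentile percentile label.
#' @param n_grid increasing integer grid within the smallest dataset size;
#'   defaults to [default_n_grid()] of that size with 15 points.
#' @param reps simulation draws per grid point.
#' @param seed master seed.
#' @param u_tr_rel fixed relative standard trueness uncertainty, required
#'   when the design has no certified value.
#' @return An object of class `budget_curve`: list with `n_grid`, `u_ip`,
#'   `u_tr`, `u_cal` (scalar), `u_cx`, `u_n_component`, `dbar`, `reps`,
#'   `seed`, `measurand`, `percentile_label`.
#' @seealso [fit_piecewise()] for the breakpoint count N_opt.
#' @export
budget_curve <- function(design, measurand, percentile = "D50",
                         n_grid = NULL, reps = 500, seed = 1,
                         u_tr_rel = NULL) {
  stopifnot(inherits(design, "validation_design"))
  i <- .match_percentile(percentile)
  sizes <- vapply(design$datasets, `[[`, 1L, "n_tot")
  n_grid <- .check_grid(n_grid %||% default_n_grid(min(sizes), points = 15),
                        min(sizes))
  has_cert <- !is.null(design$certified_value)
  if (!has_cert && is.null(u_tr_rel))
    stop("design has no certified value: supply a fixed `u_tr_rel`",
         call. = FALSE)
  if (!is.null(u_tr_rel)) .assert_scalar_number(u_tr_rel, "u_tr_rel")
  pvals <- lapply(design$datasets, derive_measurand, measurand)
  k <- length(n_grid)
  u_ip <- u_tr <- dbar <- numeric(k)
  for (g in seq_len(k)) {
    res <- .budget_at_n(pvals, design$day, n_grid[g], as.integer(reps),
                        as.integer(seed), .percentile_probs[i],
                        certified = if (has_cert) design$certified_value,
                        u_certified = design$u_certified %||% 0)
    u_ip[g] <- res$u_ip
    dbar[g] <- res$dbar
    u_tr[g] <- if (has_cert) res$u_tr else u_tr_rel
  }
  common <- Reduce(intersect, lapply(design$datasets,
                                     function(z) names(z$particles)))
  pooled <- particle_dataset(
    do.call(rbind, lapply(design$datasets, function(d) d$particles[common])),
    material_id = paste0(design$datasets[[1L]]$material_id, "-pooled"))
  un_comp <- tryCatch({
    pc <- precision_curve(pooled, measurand, .percentile_labels[i],
                          n_grid = n_grid, reps = reps,
                          seed = .derive_seed(seed, 424243L))
    pc$u_n
  }, psdcount_numerical_error = function(e) rep(0, k))
  structure(
    list(n_grid = n_grid, u_ip = u_ip, u_tr = u_tr,
         u_cal = design$u_cal_rel,
         u_cx = combine_uncertainty(u_ip, u_tr, design$u_cal_rel),
         u_n_component = un_comp, dbar = dbar,
         reps = as.integer(reps), seed = as.integer(seed),
         measurand = tolower(measurand),
         percentile_label = .percentile_labels[i]),
    class = "budget_curve"
  )
}

#' @export
print.budget_curve <- function(x, ...) {
  cat(sprintf("Uncertainty budget curve: %s %s, %d grid points in [%d, %d]\n",
              x$percentile_label, toupper(x$measurand), length(x$n_grid),
              x$n_grid[1L], x$n_grid[length(x$n_grid)]))
  cat(sprintf("  u_cal = %.4g; U_cx from %.4g (N = %d) to %.4g (N = %d)\n",
              x$u_cal, x$u_cx[1L], x$n_grid[1L],
              x$u_cx[length(x$u_cx)], x$n_grid[length(x$n_grid)]))
  invisible(x)
}

#' Piecewise linear log-log fit and the breakpoint count N_opt
#'
#' Fits a continuous two-segment linear function to `(log10 N, log10 U_cx)`
#' by exhaustive search of the breakpoint over interior grid positions,
#' followed by a 10x sub-grid refinement around the best candidate, minimizing
#' the residual sum of squares. Ties break toward the smaller breakpoint
#' (conservative for measurement cost). When the two-segment fit improves the
#' single-line SSE by less than 5 %, the breakpoint is flagged
#' unidentifiable.
#'
#' @param n_grid increasing particle counts (>= 6 points spanning at least
#'   one decade).
#' @param u_cx positive total expanded uncertainties at those counts.
#' @return An object of class `piecewise_fit`: list with `breakpoint_log10n`,
#'   `slope_left`, `slope_right`, `intercept_left`, `n_opt`, `sse` and
#'   `identifiable`.
#' @export
fit_piecewise <- function(n_grid, u_cx) {
  if (inherits(n_grid, "budget_curve")) {
    u_cx <- n_grid$u_cx
    n_grid <- n_grid$n_grid
  }
  if (length(n_grid) != length(u_cx))
    stop("`n_grid` and `u_cx` must have the same length", call. = FALSE)
  if (length(n_grid) < 6L)
    stop("need at least 6 grid points", call. = FALSE)
  if (max(n_grid) / min(n_grid) < 10)
    stop("grid must span at least one decade", call. = FALSE)
  if (any(u_cx <= 0)) stop("`u_cx` must be positive", call. = FALSE)
  x <- log10(as.numeric(n_grid)); y <- log10(u_cx)
  m <- length(x)

  sse_line <- sum(stats::residuals(stats::lm(y ~ x))^2)
  hinge_fit <- function(cc) {
    h <- pmax(x - cc, 0)
    fit <- stats::lm(y ~ x + h)
    list(sse = sum(stats::residuals(fit)^2), coef = stats::coef(fit))
  }
  # candidates at interior data positions (>= 2 points on each side)
  cand <- x[3:(m - 2)]
  sses <- vapply(cand, function(cc) hinge_fit(cc)$sse, 0)
  best <- which(sses < min(sses) + 1e-15)[1L]
  lo <- if (best == 1L) x[2L] else cand[best - 1L]
  hi <- if (best == length(cand)) x[m - 1L] else cand[best + 1L]
  fine <- seq(lo, hi, length.out = 21L)
  fsses <- vapply(fine, function(cc) hinge_fit(cc)$sse, 0)
  fbest <- which(fsses < min(fsses) + 1e-15)[1L]  # ties -> smaller N_opt
  cc <- fine[fbest]
  ft <- hinge_fit(cc)
  b <- ft$coef
  # data already on a single line (SSE at numerical noise) is unidentifiable
  improvement <- if (sse_line > 1e-12) (sse_line - ft$sse) / sse_line else 0
  structure(
    list(breakpoint_log10n = cc,
         slope_left = unname(b[2L]),
         slope_right = unname(b[2L] + b[3L]),
         intercept_left = unname(b[1L]),
         n_opt = as.integer(round(10^cc)),
         sse = ft$sse,
         identifiable = improvement >= 0.05),
    class = "piecewise_fit"
  )
}

#' @export
print.piecewise_fit <- function(x, ...) {
  cat(sprintf("Piecewise log-log fit: N_opt = %d (breakpoint at log10 N = %.3f)\n",
              x$n_opt, x$breakpoint_log10n))
  cat(sprintf("  slopes: %.3f -> %.3f; SSE = %.4g; %s\n",
              x$slope_left, x$slope_right, x$sse,
              if (x$identifiable) "identifiable"
              else "breakpoint NOT identifiable (< 5% SSE improvement)"))
  invisible(x)
}
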