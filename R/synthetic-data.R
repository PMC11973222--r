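#' Lognormal shape parameter from a target IQR%
#'
#' Closed-form inversion used by the generators: for a lognormal with median
#' m and log-scale s, the quartiles are `m * exp(±z75 * s)` with
#' `z75 = qnorm(0.75) = 0.674490`, so `IQR% = 200 * sinh(z75 * s)` and hence
#' `s = asinh(IQR% / 200) / z75`.
#'
#' @param iqr_pct target normalized interquartile range in percent (> 0;
#'   vectorized).
#' @return Lognormal log-scale parameter s.
#' @examples
#' iqr_to_logsd(30)  # 0.22156...
#' @export
iqr_to_logsd <- function(iqr_pct) {
  if (any(!is.finite(iqr_pct) | iqr_pct <= 0))
    stop("`iqr_pct` must be positive", call. = FALSE)
  asinh(iqr_pct / 200) / stats::qnorm(0.75)
}

#' Specification of a synthetic particle population
#'
#' Describes a seeded population with prescribed median and polydispersity,
#' from one of five families emulating the spectrum of real nanomaterials:
#' `lognormal` (narrow colloids), `gamma` and `weibull` (skewed powders),
#' `bimodal_mixture` (multimodal powders) and `rod` (elongated particles,
#' filling width/length/MICD/ECD consistently). An optional `design`
#' component describes a days-by-replicates validation study with a
#' multiplicative between-day effect and a global multiplicative bias.
#'
#' For the unimodal size families the generated sample IQR% converges to the
#' target as n grows; the mixture is parameterized by component weight and
#' separation instead and matches the target only loosely. `iqr_pct = 0` is
#' accepted and yields a degenerate (constant-size) population, useful for
#' exercising zero-dispersion edge cases.
#'
#' @param family one of `"lognormal"`, `"gamma"`, `"weibull"`,
#'   `"bimodal_mixture"`, `"rod"`.
#' @param median target median in nm (> 0).
#' @param iqr_pct target IQR% (>= 0).
#' @param n number of particles (>= 2).
#' @param seed master seed.
#' @param family_params list of family-specific parameters:
#'   `ar_median`/`ar_iqr_pct` (lognormal/gamma/weibull: optional correlated
#'   Fmax; rod: length-to-width aspect ratio, defaults 3 and 20),
#'   `weight`/`separation`/`component_iqr_pct` (mixture: component weight,
#'   ratio of component medians > 0, per-component IQR%; defaults 0.5, 3, 20).
#' @param design optional list with `days`, `reps_per_day`,
#'   `between_day_cv` (relative, default 0), `bias_fraction` (default 0),
#'   `u_cal_rel` (default 0), `certified_value` (default the spec median) and
#'   `u_certified` (default 0).
#' @return An object of class `synthetic_spec`.
#' @seealso [generate_particles()], [analytic_un()]
#' @export
synthetic_spec <- function(family, median, iqr_pct, n, seed = 1,
                           family_params = list(), design = NULL) {
  family <- match.arg(family, c("lognormal", "gamma", "weibull",
                                "bimodal_mixture", "rod"))
  .assert_scalar_number(median, "median", positive = TRUE)
  .assert_scalar_number(iqr_pct, "iqr_pct")
  if (iqr_pct < 0) stop("`iqr_pct` must be >= 0", call. = FALSE)
  n <- as.integer(n)
  if (n < 2L) stop("`n` must be at least 2", call. = FALSE)
  if (family == "bimodal_mixture") {
    sep <- family_params$separation %||% 3
    if (!is.finite(sep) || sep <= 0)
      stop("mixture `separation` must be > 0", call. = FALSE)
  }
  if (!is.null(design)) {
    design$days <- as.integer(design$days)
    design$reps_per_day <- as.integer(design$reps_per_day %||% 1L)
    if (design$days < 2L)
      stop("a validation design needs at least 2 days", call. = FALSE)
    design$between_day_cv <- design$between_day_cv %||% 0
    design$bias_fraction <- design$bias_fraction %||% 0
    design$u_cal_rel <- design$u_cal_rel %||% 0
    design$certified_value <- design$certified_value %||% median
    design$u_certified <- design$u_certified %||% 0
  }
  structure(
    list(family = family, median = median, iqr_pct = iqr_pct, n = n,
         seed = as.integer(seed), family_params = family_params,
         design = design),
    class = "synthetic_spec"
  )
}

# Distribution functions (r, d, q) matching a spec's family/median/iqr_pct.
# Shape parameters for gamma and weibull are solved numerically so the
# population IQR% equals the target exactly (IQR% depends on shape only).
.dist_funs <- function(family, median, iqr_pct, fp = list()) {
  if (iqr_pct == 0) {
    return(list(r = function(n) rep(median, n),
                q = function(p) rep(median, length(p)),
                d = NULL, degenerate = TRUE))
  }
  switch(family,
    lognormal = {
      s <- iqr_to_logsd(iqr_pct); ml <- log(median)
      list(r = function(n) stats::rlnorm(n, ml, s),
           q = function(p) stats::qlnorm(p, ml, s),
           d = function(x) stats::dlnorm(x, ml, s),
           degenerate = FALSE)
    },
    gamma = {
      f <- function(lk) {
        k <- exp(lk)
        100 * (stats::qgamma(0.75, k) - stats::qgamma(0.25, k)) /
          stats::qgamma(0.5, k) - iqr_pct
      }
      k <- exp(stats::uniroot(f, c(-5, 18), tol = 1e-12)$root)
      th <- median / stats::qgamma(0.5, k)
      list(r = function(n) stats::rgamma(n, shape = k, scale = th),
           q = function(p) stats::qgamma(p, shape = k, scale = th),
           d = function(x) stats::dgamma(x, shape = k, scale = th),
           degenerate = FALSE)
    },
    weibull = {
      f <- function(lk) {
        k <- exp(lk)
        100 * (stats::qweibull(0.75, k) - stats::qweibull(0.25, k)) /
          stats::qweibull(0.5, k) - iqr_pct
      }
      k <- exp(stats::uniroot(f, c(-4, 12), tol = 1e-12)$root)
      lam <- median / stats::qweibull(0.5, k)
      list(r = function(n) stats::rweibull(n, shape = k, scale = lam),
           q = function(p) stats::qweibull(p, shape = k, scale = lam),
           d = function(x) stats::dweibull(x, shape = k, scale = lam),
           degenerate = FALSE)
    },
    bimodal_mixture = {
      w <- fp$weight %||% 0.5
      sep <- fp$separation %||% 3
      s <- iqr_to_logsd(fp$component_iqr_pct %||% 20)
      m1 <- log(median / sqrt(sep)); m2 <- log(median * sqrt(sep))
      pfun <- function(q) w * stats::plnorm(q, m1, s) +
        (1 - w) * stats::plnorm(q, m2, s)
      list(
        r = function(n) {
          z <- stats::runif(n) < w
          ifelse(z, stats::rlnorm(n, m1, s), stats::rlnorm(n, m2, s))
        },
        q = function(p) vapply(p, function(pp)
          stats::uniroot(function(q) pfun(q) - pp,
                         interval = c(exp(m1 - 10 * s), exp(m2 + 10 * s)),
                         tol = 1e-10)$root, 0),
        d = function(x) w * stats::dlnorm(x, m1, s) +
          (1 - w) * stats::dlnorm(x, m2, s),
        degenerate = FALSE)
    },
    stop("no closed-form distribution for family ", family, call. = FALSE)
  )
}

.generate_one <- function(spec, seed) {
  fp <- spec$family_params
  old <- .Random.seed_safe_get()
  on.exit(.Random.seed_safe_set(old))
  set.seed(seed)
  if (spec$family == "rod") {
    wdist <- .dist_funs("lognormal", spec$median, spec$iqr_pct)
    w <- wdist$r(spec$n)
    ar_med <- fp$ar_median %||% 3
    ar_iqr <- fp$ar_iqr_pct %||% 20
    ar <- if (ar_iqr == 0) rep(ar_med, spec$n)
          else pmax(stats::rlnorm(spec$n, log(ar_med), iqr_to_logsd(ar_iqr)), 1)
    len <- w * ar
    area <- w * (len - w) + pi * w^2 / 4  # spherocylinder projection
    df <- data.frame(fmin_nm = w, fmax_nm = len, micd_nm = w,
                     ecd_nm = sqrt(4 * area / pi))
  } else {
    dist <- .dist_funs(spec$family, spec$median, spec$iqr_pct, fp)
    x <- dist$r(spec$n)
    df <- data.frame(fmin_nm = x)
    if (!is.null(fp$ar_median)) {
      ar_iqr <- fp$ar_iqr_pct %||% 20
      ar <- if (ar_iqr == 0) rep(fp$ar_median, spec$n)
            else pmax(stats::rlnorm(spec$n, log(fp$ar_median),
                                    iqr_to_logsd(ar_iqr)), 1)
      df$fmax_nm <- x * ar
    }
  }
  df
}

#' Generate a synthetic particle dataset or validation design
#'
#' Draws the population described by a [synthetic_spec()], reproducibly for a
#' given seed. Unimodal size families fill `fmin_nm` (plus a correlated
#' `fmax_nm = fmin * AR` when aspect-ratio parameters are given); the rod
#' family fills width as `fmin_nm`/`micd_nm`, length as `fmax_nm`, and ECD
#' from the spherocylinder projected-area model
#' `A = W*(L - W) + pi*W^2/4`, `ECD = sqrt(4A/pi)`.
#'
#' When the spec carries a `design`, one independent dataset is generated per
#' (day, replicate); all sizes of a day are multiplied by a lognormal day
#' factor with the prescribed between-day CV (mean 1), and every value by the
#' global bias factor `1 + bias_fraction`. The realized day factors and bias
#' factor are attached as attributes `day_factors` and `bias_factor` — the
#' ground truth for variance-component recovery checks.
#'
#' @param spec a [synthetic_spec()].
#' @return A [particle_dataset()], or a [validation_design()] when the spec
#'   includes a design.
#' @export
generate_particles <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  material <- sprintf("synthetic-%s-m%g-iqr%g", spec$family, spec$median,
                      spec$iqr_pct)
  if (is.null(spec$design))
    return(particle_dataset(.generate_one(spec, .derive_seed(spec$seed, 1L)),
                            material_id = material))
  dg <- spec$design
  sdlog_day <- sqrt(log(1 + dg$between_day_cv^2))
  old <- .Random.seed_safe_get()
  set.seed(.derive_seed(spec$seed, 999983L))
  day_factors <- exp(stats::rnorm(dg$days, -sdlog_day^2 / 2, sdlog_day))
  .Random.seed_safe_set(old)
  bias_factor <- 1 + dg$bias_fraction
  datasets <- list(); day <- integer(0); repl <- integer(0)
  for (d in seq_len(dg$days)) {
    for (r in seq_len(dg$reps_per_day)) {
      df <- .generate_one(spec, .derive_seed(spec$seed, d * 1000L + r))
      df[] <- lapply(df, function(v) v * day_factors[d] * bias_factor)
      datasets <- c(datasets, list(particle_dataset(
        df, material_id = sprintf("%s-d%d-r%d", material, d, r))))
      day <- c(day, d); repl <- c(repl, r)
    }
  }
  vd <- validation_design(datasets, day, repl,
                          certified_value = dg$certified_value,
                          u_certified = dg$u_certified,
                          u_cal_rel = dg$u_cal_rel)
  attr(vd, "day_factors") <- day_factors
  attr(vd, "bias_factor") <- bias_factor
  vd
}

#' Asymptotic count-limited uncertainty of a sample percentile
#'
#' The large-sample sampling standard error of the p-th sample quantile of a
#' distribution with density f and quantile x_p is
#' `sqrt(p(1-p)/n) / f(x_p)`; expressed relative to x_p and expanded with
#' k = 2 this gives the analytic counterpart of the bootstrap U_N:
#' `U_N = 2 * sqrt(p(1-p)/n) / (f(x_p) * x_p)`. For the lognormal median it
#' reduces to `2 * s * sqrt(pi/2) / sqrt(n)`.
#'
#' @param family distribution family (`"lognormal"`, `"gamma"`, `"weibull"`
#'   or `"bimodal_mixture"`, whose density is evaluated numerically as the
#'   component mixture).
#' @param params list with `median`, `iqr_pct` and optional `family_params`.
#' @param p percentile fraction in (0, 1).
#' @param n particle count (>= 30 for the asymptotics to be meaningful).
#' @return Relative expanded uncertainty (dimensionless).
#' @examples
#' analytic_un("lognormal", list(median = 20, iqr_pct = 30), 0.5, 100)
#' @export
analytic_un <- function(family, params, p, n) {
  .assert_scalar_number(p, "p", positive = TRUE)
  if (p >= 1) stop("`p` must be in (0, 1)", call. = FALSE)
  if (any(n < 30)) stop("`n` must be >= 30", call. = FALSE)
  dist <- .dist_funs(family, params$median, params$iqr_pct,
                     params$family_params %||% list())
  if (isTRUE(dist$degenerate) || is.null(dist$d))
    stop("no density available for this family/parameters", call. = FALSE)
  xp <- dist$q(p)
  2 * sqrt(p * (1 - p) / n) / (dist$d(xp) * xp)
}
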