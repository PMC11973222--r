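# Shared fixture: a well-resolved precision curve on a lognormal surrogate
# (median 20 nm, IQR% 30). Reused by several blocks below.
ds30 <- make_lognormal(30, n = 20000, median = 20, seed = 11)
curve30 <- precision_curve(ds30, "fmin", "D50", reps = 500, seed = 42)

test_that("subsets of a constant population have zero percentile spread", {
  const <- particle_dataset(data.frame(fmin_nm = rep(20, 200)))
  draws <- bootstrap_percentiles(const, "fmin", n = 20, reps = 50, seed = 1)
  expect_true(all(draws == 20))
  expect_equal(unname(sigma_of_draws(draws[, "D50"])["sigma"]), 0)

  # the log-log fit cannot be formed; U_N diagnostics ride on the condition
  err <- tryCatch(
    precision_curve(const, "fmin", "D50", n_grid = c(10, 20, 50, 100),
                    reps = 50, seed = 1),
    psdcount_numerical_error = identity)
  expect_s3_class(err, "psdcount_numerical_error")
  expect_true(all(err$u_n == 0))
})

test_that("draws and curves are bit-reproducible under a fixed seed", {
  a <- bootstrap_percentiles(ds30, "fmin", n = 100, reps = 100, seed = 42)
  b <- bootstrap_percentiles(ds30, "fmin", n = 100, reps = 100, seed = 42)
  expect_identical(a, b)
  d <- bootstrap_percentiles(ds30, "fmin", n = 100, reps = 100, seed = 43)
  expect_false(identical(a, d))

  # extending the grid must not reshuffle draws at existing N
  c1 <- precision_curve(ds30, "fmin", "D50", n_grid = c(50, 100, 200),
                        reps = 100, seed = 7)
  c2 <- precision_curve(ds30, "fmin", "D50", n_grid = c(50, 100, 200, 400),
                        reps = 100, seed = 7)
  expect_identical(c1$u_n, c2$u_n[1:3])
})

test_that("draw summaries and U_N follow their definitions", {
  s <- sigma_of_draws(c(1, 2, 3))
  expect_equal(unname(s), c(2, 1))   # divisor reps - 1
  expect_error(sigma_of_draws(1), "at least 2")
  expect_equal(u_n(dbar = 20, sigma = 1), 0.10)
  expect_equal(u_n(dbar = 5, sigma = 0), 0)
  expect_error(u_n(dbar = 0, sigma = 1), "positive")
  expect_error(bootstrap_percentiles(ds30, "fmin", n = 5, reps = 10, seed = 1),
               "at least 10")
})

test_that("bootstrap spread matches the asymptotic quantile-SE oracle", {
  # analytic sd of the sample median at n = 100: s * median * sqrt(pi/2) / 10
  draws <- bootstrap_percentiles(ds30, "fmin", n = 100, reps = 500, seed = 3)
  sd_oracle <- iqr_to_logsd(30) * 20 * sqrt(pi / 2) / sqrt(100)
  expect_equal(sd(draws[, "D50"]), sd_oracle, tolerance = 0.15)

  # oracle closure across percentiles at a mid-grid N
  for (i in seq_along(c(0.10, 0.25, 0.50, 0.75, 0.90))) {
    p <- c(0.10, 0.25, 0.50, 0.75, 0.90)[i]
    st <- sigma_of_draws(draws[, i])
    expect_equal(u_n(st[["dbar"]], st[["sigma"]]),
                 analytic_un("lognormal", list(median = 20, iqr_pct = 30),
                             p, 100),
                 tolerance = 0.15)
  }
})

test_that("the precision curve follows the 1/sqrt(N) log-log law", {
  expect_equal(curve30$loglog_slope, -0.5, tolerance = 0.05 / 0.5)
  expect_gt(curve30$fit_r2, 0.99)
  # doubling N reduces fitted U_N by 1/sqrt(2)
  expect_equal(2^curve30$loglog_slope, 1 / sqrt(2), tolerance = 0.05)
  expect_true(all(curve30$sigma >= 0) && all(curve30$u_n >= 0))
  expect_equal(curve30$u_n, 2 * curve30$sigma / curve30$dbar)
})

test_that("U_N is invariant under rescaling of all particle sizes", {
  scaled <- particle_dataset(data.frame(fmin_nm = 3.7 * ds30$particles$fmin_nm))
  cs <- precision_curve(scaled, "fmin", "D50", n_grid = curve30$n_grid,
                        reps = 500, seed = 42)
  expect_equal(cs$u_n, curve30$u_n, tolerance = 1e-12)
})

test_that("minimum count inversion matches the analytic oracle", {
  nm10 <- minimum_count(curve30, 0.10)
  nm05 <- minimum_count(curve30, 0.05)
  expect_equal(as.integer(nm05), analytic_nm_median(30, 0.05),
               tolerance = 15 / 123)
  # slope -1/2 implies quadratic scaling of cost with precision
  expect_equal(as.integer(nm05) / as.integer(nm10), 4, tolerance = 0.5 / 4)

  # non-increasing in the target
  targets <- c(0.02, 0.05, 0.10, 0.20, 0.40)
  nms <- vapply(targets, function(u) as.integer(minimum_count(curve30, u)), 1L)
  expect_true(all(diff(nms) <= 0))

  # already below target at the grid floor
  nmf <- minimum_count(curve30, 0.60)
  expect_identical(as.integer(nmf), 10L)
  expect_true("at_grid_floor" %in% attr(nmf, "flags"))

  # a target below the reachable range extrapolates, flagged
  nmx <- minimum_count(curve30, 0.002)
  expect_true(as.integer(nmx) > curve30$n_tot)
  expect_true("extrapolated" %in% attr(nmx, "flags"))

  bad <- curve30; bad$loglog_slope <- 0.1
  expect_error(minimum_count(bad, 0.05), class = "psdcount_numerical_error")
  expect_error(minimum_count(curve30, 1.2), "fraction")
})

test_that("spline fit is accurate, monotone and agrees with the line", {
  # noiseless 1/sqrt(N) curve: fitted values within 1 % at the grid points
  g <- as.integer(round(10^seq(1, 4, length.out = 12)))
  exact <- structure(
    list(n_grid = g, u_n = 0.5 / sqrt(g), n_tot = max(g)),
    class = "precision_curve")
  f <- fit_spline(exact)
  expect_equal(f(g), 0.5 / sqrt(g), tolerance = 0.01)

  # monotone non-increasing everywhere on a real curve
  fs <- fit_spline(curve30)
  nn <- round(seq(min(curve30$n_grid), max(curve30$n_grid), length.out = 300))
  expect_true(all(diff(fs(nn)) <= 1e-12))
  expect_error(fs(5), "defined on")

  # spline and log-log line estimate the same curve at mid-grid
  mid <- 500
  line_val <- 10^(curve30$loglog_intercept +
                    curve30$loglog_slope * log10(mid))
  expect_equal(fs(mid), line_val, tolerance = 0.10)

  # spline-based inversion agrees with the log-log inversion
  nm_sp <- minimum_count(curve30, 0.05, method = "spline")
  expect_equal(as.integer(nm_sp), as.integer(minimum_count(curve30, 0.05)),
               tolerance = 0.15)

  few <- curve30; few$n_grid <- few$n_grid[1:4]; few$u_n <- few$u_n[1:4]
  expect_error(fit_spline(few), "at least 5")
})

test_that("percentile profile shows the asymmetric U-shape on lognormal data", {
  prof <- percentile_profile(ds30, "fmin", u_target = 0.10, reps = 300,
                             seed = 12)
  nm <- setNames(prof$n_m, prof$percentile)
  expect_true(nm[["D10"]] > nm[["D25"]])
  expect_true(nm[["D90"]] > nm[["D75"]])
  expect_true(nm[["D10"]] > nm[["D50"]] && nm[["D90"]] > nm[["D50"]])
  # outer-percentile penalty is bounded by the asymptotic normal-score
  # ratio (~1.86 for D10/D50); pre-asymptotic small-N grid points pull the
  # fitted ratio somewhat below it
  expect_gt(nm[["D10"]] / nm[["D50"]], 1.3)
  expect_lt(nm[["D10"]] / nm[["D50"]], 2.2)
})

test_that("profile asymmetry on skewed data follows the analytic oracle", {
  # right-skewed gamma: the oracle decides which tail percentile costs more
  dsg <- generate_particles(synthetic_spec("gamma", 20, 60, 10000, seed = 21))
  un90 <- analytic_un("gamma", list(median = 20, iqr_pct = 60), 0.9, 500)
  un10 <- analytic_un("gamma", list(median = 20, iqr_pct = 60), 0.1, 500)
  prof <- percentile_profile(dsg, "fmin", u_target = 0.10, reps = 200,
                             seed = 22)
  nm <- setNames(prof$n_m, prof$percentile)
  expect_identical(nm[["D90"]] > nm[["D10"]], un90 > un10)
})
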