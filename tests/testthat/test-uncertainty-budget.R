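# Shared fixture: synthetic 3-days x 2-replicates validation design with a
# 3 % multiplicative between-day effect and a +2 % global bias, certified
# value equal to the unbiased population median.
design_spec <- synthetic_spec(
  "lognormal", 20, 30, 20000, seed = 71,
  design = list(days = 3, reps_per_day = 2, between_day_cv = 0.03,
                bias_fraction = 0.02, u_cal_rel = 0.005,
                certified_value = 20, u_certified = 0))
vdesign <- generate_particles(design_spec)
day_factors <- attr(vdesign, "day_factors")
# realized ground truth: with 3 days the between-day spread actually present
# in the data is one 2-df draw, so recovery is checked against it
realized_cv <- sd(day_factors) / mean(day_factors)
realized_bias <- mean(day_factors) * attr(vdesign, "bias_factor") - 1

test_that("uncertainty combination follows the quadrature rule", {
  expect_equal(combine_uncertainty(0, 0, 0.01), 0.02)
  expect_equal(combine_uncertainty(0.03, 0.04, 0), 0.10)  # 3-4-5 triangle
  expect_error(combine_uncertainty(-0.01, 0, 0), ">= 0")
})

test_that("trueness uncertainty implements the CRM bias combination", {
  expect_equal(trueness_uncertainty(20, 20, 0, 0), 0)
  expect_equal(trueness_uncertainty(20.4, 20, 0.3, 0),
               sqrt(0.16 + 0.09) / 20)
  expect_equal(trueness_uncertainty(20.4, 20, 0.3, 0), 0.025)
  expect_error(trueness_uncertainty(20, -1), "> 0")
})

test_that("a design with no variation yields zero intermediate precision", {
  const <- particle_dataset(data.frame(fmin_nm = rep(20, 100)))
  vd <- validation_design(list(const, const, const, const),
                          day = c(1, 1, 2, 2))
  res <- intermediate_precision(vd, "fmin", "D50", n = 20, reps = 50,
                                seed = 1)
  expect_equal(res$u_ip, 0)
  expect_equal(res$dbar, 20)
  expect_error(intermediate_precision(vd, "fmin", "D50", n = 500),
               "exceeds the smallest")
})

test_that("u_IP recovers the generator's day effect at the large-n limit", {
  res <- intermediate_precision(vdesign, "fmin", "D50", n = 20000,
                                reps = 100, seed = 2)
  # at full n the count contribution is negligible; the estimator should
  # return the realized between-day spread
  expect_equal(res$u_ip, realized_cv, tolerance = 0.20)
  expect_equal(res$u_ip, 0.03, tolerance = 0.7)  # nominal CV, chi2-wide band

  # at small n the count contribution dominates and adds in quadrature:
  # sd of one dataset's D50 at n=20 is sigma_n; six datasets' spread combines
  # sigma_n with the day floor
  res20 <- intermediate_precision(vdesign, "fmin", "D50", n = 20,
                                  reps = 300, seed = 3)
  un20 <- 2 * iqr_to_logsd(30) * sqrt(pi / 2) / sqrt(20)
  expect_equal(res20$u_ip, sqrt((un20 / 2)^2 + realized_cv^2),
               tolerance = 0.25)
})

test_that("the budget curve recovers bias, floor and quadrature identity", {
  bc <- budget_curve(vdesign, "fmin", "D50",
                     n_grid = default_n_grid(20000, points = 12),
                     reps = 200, seed = 5)
  k <- length(bc$n_grid)

  # quadrature identity holds exactly on the stored components
  expect_equal(bc$u_cx,
               2 * sqrt(bc$u_ip^2 + bc$u_tr^2 + bc$u_cal^2),
               tolerance = 1e-12)
  expect_true(all(bc$u_cx >= 2 * bc$u_cal))

  # planted +2 % bias (through the realized mean day factor) is recovered
  delta_rel <- bc$dbar[k] / vdesign$certified_value - 1
  expect_equal(delta_rel, realized_bias, tolerance = 0.005 / realized_bias)

  # u_cx saturates at the floor set by the realized day effect, the bias
  # and the calibration component
  J <- length(vdesign$datasets)
  se_rel <- sd(rep(day_factors, each = 2) * attr(vdesign, "bias_factor")) /
    sqrt(J)
  u_tr_floor <- sqrt(realized_bias^2 + se_rel^2)
  floor <- combine_uncertainty(realized_cv, u_tr_floor, bc$u_cal)
  expect_equal(bc$u_cx[k], floor, tolerance = 0.10)

  # overall decreasing towards the floor, within Monte-Carlo wiggle
  expect_gt(bc$u_cx[1], bc$u_cx[k])
  expect_true(all(bc$u_cx >= floor * 0.9))

  # the count component is part of intermediate precision
  expect_true(all(bc$u_cx >= bc$u_n_component * 0.85))
})

test_that("a design without certified value requires an explicit u_tr", {
  vd2 <- validation_design(vdesign$datasets, vdesign$day, vdesign$replicate,
                           u_cal_rel = 0.005)
  expect_error(budget_curve(vd2, "fmin", "D50", reps = 20, seed = 1),
               "u_tr_rel")
  bc2 <- budget_curve(vd2, "fmin", "D50",
                      n_grid = c(10, 30, 100, 300, 1000, 3000, 10000),
                      reps = 50, seed = 1, u_tr_rel = 0.04)
  expect_true(all(bc2$u_tr == 0.04))
})

test_that("piecewise fit recovers exact and planted breakpoints", {
  # exact two-line data: breakpoint at log10 N = 2.3, slopes -0.5 / -0.05
  x <- seq(1, 4, by = 0.25)
  y <- ifelse(x <= 2.3, -0.5 * x, -0.5 * 2.3 - 0.05 * (x - 2.3))
  # rounding N to integer counts perturbs the log-abscissae, so recovery is
  # exact only up to the breakpoint-refinement spacing (~0.0125 decades)
  fit <- fit_piecewise(round(10^x), 10^y)
  expect_equal(fit$breakpoint_log10n, 2.3, tolerance = 0.03 / 2.3)
  expect_equal(fit$slope_left, -0.5, tolerance = 0.01)
  expect_equal(fit$slope_right, -0.05, tolerance = 0.01)
  expect_true(abs(fit$n_opt - 200L) <= 10)
  expect_true(fit$identifiable)
  expect_gt(fit$slope_right, fit$slope_left)

  # smooth crossing of a count-limited and a floor component at N = 200
  g <- as.integer(round(10^seq(1, 4, length.out = 15)))
  cc <- 0.03^2
  u <- 2 * sqrt(cc * 200 / g + cc)
  fit2 <- fit_piecewise(g, u)
  expect_gt(fit2$n_opt, 100)
  expect_lt(fit2$n_opt, 400)

  # monotone single-slope data: breakpoint not identifiable
  fit3 <- fit_piecewise(g, 10^(-0.5 * log10(g)))
  expect_false(fit3$identifiable)

  expect_error(fit_piecewise(c(10, 20, 40, 80, 100), rep(0.1, 5)),
               "at least 6")
  expect_error(fit_piecewise(c(10, 12, 14, 16, 18, 20), rep(0.1, 6)),
               "decade")
})

test_that("N_opt increases with polydispersity at a fixed day-effect floor", {
  # one shared seed so the three materials see the same realized day
  # factors: the property is about IQR% at a *fixed* day-effect floor
  nopts <- vapply(c(30, 45, 68), function(iq) {
    spec <- synthetic_spec(
      "lognormal", 20, iq, 5000, seed = 80,
      design = list(days = 3, reps_per_day = 2, between_day_cv = 0.03,
                    bias_fraction = 0, u_cal_rel = 0.005,
                    certified_value = 20))
    vd <- generate_particles(spec)
    bc <- budget_curve(vd, "fmin", "D50",
                       n_grid = default_n_grid(5000, points = 12),
                       reps = 150, seed = 9)
    fit_piecewise(bc)$n_opt
  }, 1L)
  expect_equal(cor(nopts, c(30, 45, 68), method = "spearman"), 1)
})
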