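# Shared fixtures: seeded synthetic populations used across test files.

make_lognormal <- function(iqr_pct, n = 20000, median = 20, seed = 1) {
  generate_particles(synthetic_spec("lognormal", median, iqr_pct, n,
                                    seed = seed))
}

write_tmp_csv <- function(lines) {
  p <- tempfile(fileext = ".csv")
  writeLines(lines, p)
  p
}

# Analytic minimum count for the median of a lognormal population:
# N_m = (2 * s * sqrt(pi/2) / u_target)^2 with s the log-scale parameter.
analytic_nm_median <- function(iqr_pct, u_target) {
  s <- iqr_to_logsd(iqr_pct)
  (2 * s * sqrt(pi / 2) / u_target)^2
}
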