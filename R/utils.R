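`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic substream seeds: one child stream per (master seed, integer key).
# Values stay strictly below 2^31 so they are valid R integer seeds.
.derive_seed <- function(seed, key) {
  s <- (as.double(seed) %% 2147483647) + 1
  k <- (as.double(key) %% 2147483647) + 1
  as.integer((s * 48271 + k * 69621) %% 2147483629)
}

# Numerical-failure condition (distinct from plain validation errors so the
# CLI can map it to its own exit code).
stop_numerical <- function(msg, ...) {
  stop(structure(
    list(message = msg, call = sys.call(-1), ...),
    class = c("psdcount_numerical_error", "error", "condition")
  ))
}

.assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  invisible(x)
}

.percentile_labels <- c("D10", "D25", "D50", "D75", "D90")
.percentile_probs  <- c(0.10, 0.25, 0.50, 0.75, 0.90)

.match_percentile <- function(label) {
  label <- toupper(label)
  i <- match(label, .percentile_labels)
  if (is.na(i))
    stop("`percentile` must be one of ", paste(.percentile_labels, collapse = ", "),
         call. = FALSE)
  i
}
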