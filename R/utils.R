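# Internal helpers shared across the package.

#' Signal a typed error
#'
#' All validation failures in the package raise conditions that inherit from
#' `incompatscan_error` plus a specific subclass, so callers and tests can
#' discriminate failure modes.
#'
#' @param msg message text.
#' @param class specific condition subclass, e.g. "isc_format_error".
#' @noRd
isc_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "incompatscan_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores .Random.seed so seeded operations do not perturb the
#' caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Canonical chromosome labels: seven placed chromosomes plus UNPLACED.
CHROMOSOME_LEVELS <- c("I", "II", "III", "IV", "V", "VI", "VII", "UNPLACED")

# Time points of the incompatibility time course, in hours after the
# temperature shift that triggers the reaction.
TIME_POINTS_H <- c(0, 0.5, 1, 2, 3, 4)

# Element-wise time label: "0", "0.5", "2" — never the common-width padding
# ("0.0") that vectorized format() would produce.
time_label <- function(t) {
  vapply(t, function(x) format(x, trim = TRUE, scientific = FALSE), character(1))
}

# Derive a stage-local seed from the master seed; keeps all derived seeds
# inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647L)
}
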