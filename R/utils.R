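# Internal helpers shared across modules.

# Canonical kinematic parameter names, in reporting order.
KIN_PARAMETERS <- c("TaskTime", "MovementTime", "PeakVel", "HPR",
                    "nPeak", "Score", "PercPeakVel")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_armkin <- function(fmt, ..., class = "armkin_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

# Validation errors are distinguished from parse/I/O errors so callers can
# react to malformed content vs. content that violates the domain grammar.
stop_validation <- function(fmt, ...) {
  stop_armkin(fmt, ..., class = c("armkin_validation_error", "armkin_error"))
}

stop_parse <- function(fmt, ...) {
  stop_armkin(fmt, ..., class = c("armkin_parse_error", "armkin_error"))
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_armkin("'%s' must be a single finite number", name)
  invisible(x)
}

# Deterministic child seed derived from a parent seed and an index,
# kept below 2^31 so it is always a valid R integer.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 16807) %% 2147483629) + 1L
}
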