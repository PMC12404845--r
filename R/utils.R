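#' @keywords internal
"_PACKAGE"

# Structured condition constructors. Every user-facing failure mode in the
# pipeline is a classed condition so callers (and the CLI exit-code mapping)
# can distinguish configuration problems from runtime problems.
ps_error <- function(class, message, ..., call. = FALSE) {
  cond <- structure(
    class = c(class, "picoscreen_error", "error", "condition"),
    list(message = message, call = NULL, ...)
  )
  stop(cond)
}

config_error <- function(message, ...) ps_error("config_error", message, ...)
parse_error <- function(message, ...) ps_error("parse_error", message, ...)
io_error <- function(message, ...) ps_error("io_error", message, ...)
accounting_error <- function(message, ...) ps_error("accounting_error", message, ...)
validation_error <- function(message, ...) ps_error("validation_error", message, ...)

# Raised by parse_model_json(); carries the raw backend text so the caller
# can retry with a repair reminder.
malformed_response_error <- function(message, raw) {
  ps_error("malformed_response", message, raw = raw)
}

transport_error <- function(message, ...) ps_error("transport_error", message, ...)
backend_unavailable_error <- function(message, ...) {
  ps_error("backend_unavailable", message, ...)
}

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; screening reports conventionally
#' round percentages half-up (99.375 prints as 99.38). A tiny epsilon guards
#' against binary representation artefacts such as `0.5 - 1e-16`.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up at `digits` decimals.
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# Format a fraction as a percentage string at 2 decimals, half-up.
format_percent <- function(x, digits = 2) {
  ifelse(is.na(x), "NA",
         paste0(formatC(round_half_up(100 * x, digits),
                        format = "f", digits = digits), "%"))
}

# Deterministic 31-bit string hash (polynomial rolling hash). Used to key
# the response cache and to drive the mock backend's reproducible noise:
# both must be stable across sessions, so R's RNG is not suitable.
string_hash <- function(text, seed = 0L) {
  codes <- utf8ToInt(enc2utf8(text))
  h <- (as.numeric(seed) * 2654435761) %% 2147483647
  for (c in codes) {
    h <- (h * 31 + c) %% 2147483647
  }
  h
}

# Uniform deviate in [0, 1) derived from a string + seed; one extra mixing
# round decorrelates it from the raw hash.
string_unif <- function(text, seed = 0L) {
  h <- string_hash(text, seed)
  h <- (h * 48271) %% 2147483647
  h / 2147483647
}

# Run an expression with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Scalar coalescing helpers for optional record fields: absent is NA, never "".
`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || (length(a) == 1 && is.na(a))) b else a

is_absent <- function(x) {
  is.null(x) || length(x) == 0 || (length(x) == 1 && (is.na(x) || identical(x, "")))
}
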