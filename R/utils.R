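# Internal condition helpers. Every user-facing failure is a classed
# condition so callers (and the command-line wrapper) can distinguish
# parse/data problems from argument misuse and computation failures.

abort_relexp <- function(msg, class) {
  stop(structure(
    class = c(class, "relexp_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

abort_parse <- function(msg) abort_relexp(msg, "relexp_parse_error")
abort_lookup <- function(msg) abort_relexp(msg, "relexp_lookup_error")
abort_argument <- function(msg) abort_relexp(msg, "relexp_argument_error")
abort_conflict <- function(msg) abort_relexp(msg, "relexp_conflict_error")
abort_merge <- function(msg) abort_relexp(msg, "relexp_merge_error")
abort_precondition <- function(msg) abort_relexp(msg, "relexp_precondition_error")

# Doubles are printed with 17 significant digits so that text round trips
# (write then read) reproduce the value bit-exactly.
format_value <- function(x) sprintf("%.17g", x)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
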