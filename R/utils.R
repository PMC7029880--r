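# Classed error helpers: every validation failure raises a typed condition so
# callers (and tests) can distinguish format, validation, lookup, computation
# and configuration errors.

tc_abort <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "tc_error"), call = call))
}

abort_format      <- function(msg) tc_abort(msg, "tc_format_error")
abort_validation  <- function(msg) tc_abort(msg, "tc_validation_error")
abort_lookup      <- function(msg) tc_abort(msg, "tc_lookup_error")
abort_computation <- function(msg) tc_abort(msg, "tc_computation_error")
abort_config      <- function(msg) tc_abort(msg, "tc_config_error")
abort_io          <- function(msg) tc_abort(msg, "tc_io_error")

#' @keywords internal
tc_verbose <- function() isTRUE(getOption("traitcooccur.verbose", FALSE))

# Structured progress log to stderr; silent unless
# options(traitcooccur.verbose = TRUE).
tc_log <- function(...) {
  if (tc_verbose()) message("[traitcooccur] ", ...)
}

# Canonical unordered pair key; species_a < species_b lexicographically.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\x1f")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
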