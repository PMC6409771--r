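# Classed conditions so callers can distinguish usage, parse, lookup and
# configuration failures without matching on message text.
xref_error <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "xref_error", "error")))
}

stop_parse <- function(msg, ...) xref_error("xref_parse_error", msg, ...)
stop_lookup <- function(msg, ...) xref_error("xref_lookup_error", msg, ...)
stop_config <- function(msg, ...) xref_error("xref_config_error", msg, ...)
stop_usage <- function(msg, ...) xref_error("xref_usage_error", msg, ...)
stop_empty <- function(msg, ...) xref_error("xref_empty_namespace_error", msg, ...)
stop_serialize <- function(msg, ...) xref_error("xref_serialize_error", msg, ...)

`%||%` <- function(x, y) if (is.null(x)) y else x

# Standard deviation with a choice of divisor. The population form (divisor
# N) is exact on tiny fixtures; the sample form matches stats::sd().
spread_sd <- function(x, type = c("population", "sample")) {
  type <- match.arg(type)
  n <- length(x)
  if (n == 0L) return(NA_real_)
  if (type == "sample") {
    if (n < 2L) return(0)
    return(stats::sd(x))
  }
  sqrt(sum((x - mean(x))^2) / n)
}

# Deterministic character sort, independent of the user's collation locale.
sort_c <- function(x) {
  if (length(x) == 0L) return(character(0))
  x[order(x, method = "radix")]
}

order_c <- function(...) order(..., method = "radix")
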