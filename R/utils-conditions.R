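# Structured error conditions. Every user-facing failure gets a condition
# class of the form "seqdbkit_<slug>" so callers (and the CLI layer) can
# dispatch on the kind of failure rather than matching message text.

sdk_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("seqdbkit_", class), "seqdbkit_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

sdk_warn <- function(class, msg) {
  warning(structure(
    class = c(paste0("seqdbkit_", class), "seqdbkit_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# ISO-8601 timestamp (UTC, second precision)
iso_now <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
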