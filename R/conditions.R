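# Classed error conditions shared across the package. Every user-facing
# failure mode has its own condition class so callers (and the CLI) can
# branch on the cause rather than on message text.

hh_error <- function(class, message, call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("hh_error_", class), "hh_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

# shorthands used throughout
err_empty_join        <- function(msg) hh_error("empty_join", msg)
err_degenerate_marker <- function(msg) hh_error("degenerate_marker", msg)
err_invalid_counts    <- function(msg) hh_error("invalid_counts", msg)
err_non_positive      <- function(msg) hh_error("non_positive_input", msg)
err_degenerate_spread <- function(msg) hh_error("degenerate_spread", msg)
err_format            <- function(msg) hh_error("format", msg)
err_duplicate_id      <- function(msg) hh_error("duplicate_id", msg)
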