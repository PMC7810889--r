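#' @keywords internal
"_PACKAGE"

# classed conditions so callers/tests can distinguish malformed files from
# contract violations
rd_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "residomics_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

format_error <- function(msg) rd_stop(msg, "residomics_format_error")
validation_error <- function(msg) rd_stop(msg, "residomics_validation_error")

rd_warn <- function(msg) warning(paste0("[residomics] ", msg), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}
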