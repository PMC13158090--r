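# Classed conditions so callers can distinguish failure modes with
# tryCatch(geometry_error = ...) rather than matching message strings.

sc_stop <- function(class, msg, ...) {
    stop(structure(
        class = c(class, "shellcontrast_error", "error", "condition"),
        list(message = msg, call = sys.call(-1), ...)
    ))
}

geometry_error       <- function(msg) sc_stop("geometry_error", msg)
mask_encoding_error  <- function(msg) sc_stop("mask_encoding_error", msg)
empty_region_error   <- function(msg) sc_stop("empty_region_error", msg)
no_boundary_error    <- function(msg) sc_stop("no_boundary_error", msg)
degenerate_histogram_error <- function(msg) sc_stop("degenerate_histogram_error", msg)
undefined_contrast_error   <- function(msg) sc_stop("undefined_contrast_error", msg)
undefined_correlation_error <- function(msg) sc_stop("undefined_correlation_error", msg)
config_error         <- function(msg) sc_stop("config_error", msg)
spec_error           <- function(msg) sc_stop("spec_error", msg)
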