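# Classed conditions so callers (and the CLI) can map failures to exit codes:
# usage errors, I/O / format errors, and archive corruption are distinct.

stop_refzip <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    list(message = message, call = call),
    class = c(class, "refzip_error", "error", "condition")
  ))
}

stop_usage <- function(message) stop_refzip(message, "refzip_usage_error")

stop_io <- function(message) stop_refzip(message, "refzip_io_error")

stop_format <- function(message) {
  stop_refzip(message, c("refzip_format_error", "refzip_io_error"))
}

stop_corrupt <- function(message, subclass = character()) {
  stop_refzip(message, c(subclass, "refzip_corruption"))
}
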