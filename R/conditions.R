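# Condition helpers: every user-facing failure is classed so callers (and the
# command-line wrapper) can distinguish validation problems from I/O problems.

apms_stop <- function(msg, class = "apms_validation_error", call. = FALSE) {
  cond <- structure(
    class = c(class, "apms_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  )
  stop(cond)
}

stop_validation <- function(...) apms_stop(paste0(...), "apms_validation_error")
stop_io <- function(...) apms_stop(paste0(...), "apms_io_error")

check_file_exists <- function(path) {
  if (!file.exists(path)) stop_io("file not found: ", path)
  invisible(path)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_validation(name, " must be TRUE or FALSE")
  }
  invisible(x)
}
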