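# Internal helpers shared across modules.

#' @keywords internal
stop_validation <- function(..., call. = FALSE) {
  msg <- paste0(...)
  cond <- structure(
    class = c("cellpatch_validation_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  )
  stop(cond)
}

#' @keywords internal
stop_io <- function(...) {
  msg <- paste0(...)
  cond <- structure(
    class = c("cellpatch_io_error", "error", "condition"),
    list(message = msg, call = NULL)
  )
  stop(cond)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Derive reproducible sub-seeds from one master seed without disturbing the
# caller's RNG stream more than once.
derive_seeds <- function(seed, n) {
  stopifnot(is_scalar_number(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
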