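#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a parent seed and a key
#'
#' Stable hash-based fan-out so that pipeline stages are independently
#' rerunnable from one global seed. The result is always a positive 32-bit
#' integer, suitable for [set.seed()].
#'
#' @param seed parent integer seed.
#' @param ... character or numeric key components naming the stage/frame.
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
fan_seed <- function(seed, ...) {
  key <- paste(c(as.character(seed), as.character(unlist(list(...)))),
               collapse = "/")
  h <- digest::digest2int(key)
  as.integer(as.double(h) %% 2147483646) + 1L
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

stop_with <- function(kind, fmt, ...) {
  stop(sprintf("[%s] %s", kind, sprintf(fmt, ...)), call. = FALSE)
}
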