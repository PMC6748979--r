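## Shared helpers: deterministic seed splitting, logging, small numerics.

#' Derive an independent child seed from a master seed
#'
#' All randomness in the package flows from one integer seed.  Sub-generators
#' (per sample, per bootstrap repeat, per phantom component) draw their own
#' seeds with a counter-based splitting scheme, so they are mutually
#' independent and insensitive to execution order.
#'
#' @param seed master integer seed.
#' @param ... one or more integer or character keys identifying the consumer
#'   (e.g. a stage name and a sample index).
#' @return a single integer in `[0, 2^31 - 1)`.
#' @export
split_seed <- function(seed, ...) {
  keys <- list(...)
  h <- as.double(seed %% 2147483647L)
  for (k in keys) {
    if (is.character(k)) k <- utf8ToInt(paste(k, collapse = "")) else k <- as.double(k)
    for (v in k) {
      # 32-bit style mixing kept in double precision (exact below 2^53)
      h <- (h * 69069 + as.double(v) + 1) %% 2147483647
      h <- (h * 1103515245 + 12345) %% 2147483647
    }
  }
  as.integer(h %% 2147483647)
}

vm_log <- function(..., verbose = getOption("vesselmink.verbose", FALSE)) {
  if (isTRUE(verbose)) {
    message(sprintf("[vesselmink %s] ", format(Sys.time(), "%H:%M:%S")),
            sprintf(...))
  }
  invisible(NULL)
}

# Timing wrapper used by the pipeline stages.
vm_stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- force(expr)
  vm_log("%s: %.2fs", name, proc.time()[["elapsed"]] - t0)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
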