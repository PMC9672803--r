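#' Derive a per-case random seed from a master seed
#'
#' Deterministic integer hash used everywhere a master seed has to fan out
#' into independent per-case or per-module streams. The map is
#' `(seed %% 10007) * 104729 + index * 7919 + salt`, reduced mod 2^31 - 1,
#' which keeps the result a valid 32-bit seed and makes distinct indices give
#' distinct streams.
#'
#' @param seed integer master seed.
#' @param index non-negative integer (e.g. case index).
#' @param salt optional extra integer to separate independent uses.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, index, salt = 0L) {
  s <- (as.double(seed %% 10007L) * 104729 +
        as.double(index) * 7919 + as.double(salt) * 52361) %% 2147483647
  as.integer(s)
}

msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(sprintf(...))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
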