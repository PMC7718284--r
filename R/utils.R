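# Internal validation helpers and deterministic seed fan-out.

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Derive a child RNG seed from a master seed
#'
#' Counter-based fan-out so that per-subject, per-stage seeds are stable:
#' adding subjects or stages never perturbs the streams already assigned.
#' The result always fits in a 32-bit signed integer.
#'
#' @param master integer master seed.
#' @param subject subject counter (1-based).
#' @param stage stage counter (1-based).
#' @return an integer seed.
#' @export
child_seed <- function(master, subject = 1L, stage = 1L) {
  stop_if_not(is_scalar_num(master), "`master` must be a single number")
  m <- as.double(master) %% 2097143          # prime < 2^21
  s <- (m * 1021 + as.double(subject) * 131 + as.double(stage)) %% 2147483629
  as.integer(s)
}
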