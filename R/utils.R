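# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Sets the RNG to `seed`, evaluates `code`, and restores the previous RNG
#' state afterwards, so seeded routines never disturb the caller's random
#' stream.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive `n` independent sub-seeds from one master seed.  All randomness in
# the package flows from a single user seed through this splitter, so the
# generator stream and the optimizer stream never collide.
split_seed <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_binary_matrix <- function(w) all(w == 0 | w == 1)

# fixed 6-decimal formatting used by every writer; NA prints as "NA"
fmt_real <- function(x) {
  out <- sprintf("%.6f", x)
  out[is.na(x)] <- "NA"
  out
}
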