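# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a master seed and integer context
#'
#' A single run seed fans out to per-stage and per-trial seeds through this
#' mixing function, so every stage is independently reproducible. The result
#' is always a positive integer below 2^31.
#'
#' @param seed master seed (integer).
#' @param ... integer context values (stage index, participant, trial, ...).
#' @return a positive integer seed.
#' @export
derive_seed <- function(seed, ...) {
  ctx <- c(as.numeric(seed), as.numeric(c(...)))
  m <- 2147483629 # prime below 2^31
  h <- 104729
  for (v in ctx) {
    h <- (h * 48271 + (v %% m) + 11) %% m
    h <- (h * 69621) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) &&
  x > 0 && x == round(x)
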