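#' Evaluate an expression under a local random seed
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so reproducible draws never disturb the session
#' stream. All stochastic operations in the package route through this.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Derive a stage-specific seed from a master seed
#'
#' Deterministic 31-bit hash of `(seed, label)` so each pipeline stage gets
#' its own reproducible random stream and adding a stage never shifts the
#' stream of another.
#'
#' @param seed master integer seed.
#' @param label stage name.
#' @return integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(paste0(label, ":", seed))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h + 1)
}
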