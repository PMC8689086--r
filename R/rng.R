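#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators do not disturb the global random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a master seed
#'
#' Deterministically maps a master seed and a stage name to a stage-specific
#' seed, so that pipeline stages can be re-run in isolation with the same
#' random stream they saw inside [run_experiment()]. The mapping hashes the
#' stage name (polynomial rolling hash) and mixes it with the master seed
#' modulo a prime below 2^31.
#'
#' @param master_seed integer master seed.
#' @param stage character stage name, e.g. `"geometry"`.
#' @return an integer seed in `[0, 2^31)`.
#' @examples
#' stage_seed(1, "geometry")
#' @export
stage_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.character(stage), length(stage) == 1L)
  m <- 2147480009  # prime < 2^31
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% m
  as.integer((h + (as.double(master_seed) %% m) * 7919) %% m)
}
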