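#' Run code under a temporary RNG seed
#'
#' Evaluates an expression with the global RNG seeded at `seed`, restoring the
#' caller's RNG state afterwards so package functions never clobber the
#' session stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream as-is.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a master seed
#'
#' Deterministic per-stage seeds keep every stochastic stage of a pipeline
#' reproducible from one master seed. Kept below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param stage character stage label.
#' @return integer seed.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(master) * 7919 + h) %% 2147483647L)
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a
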