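# Internal helpers: classed errors, seed management, small numerics.

af_stop <- function(type, msg, ...) {
  stop(structure(
    class = c(paste0("altifun_", type, "_error"), "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

af_warn <- function(msg, ...) {
  warning(sprintf(msg, ...), call. = FALSE)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the current RNG state, seeds it, evaluates `expr`, and restores the
#' previous state, so seeded operations never perturb the caller's stream.
#' With `seed = NULL` the expression runs on the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a deterministic per-operation seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its seed from the run seed
#' through this function, keyed by a stage tag, so full runs are
#' bit-reproducible while stages stay independent.
#'
#' @param seed Master integer seed.
#' @param tag Character tag naming the operation or stage.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
substream <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(tag))
  codes <- utf8ToInt(tag)
  h <- sum(codes * seq_along(codes)) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 48271 + h * 16807) %% 2147483647)
}

# Row-wise minima of a numeric matrix (C-level, no apply()).
row_mins <- function(m) {
  if (ncol(m) == 1L) return(as.vector(m))
  m[cbind(seq_len(nrow(m)), max.col(-m, ties.method = "first"))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
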