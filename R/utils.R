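#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed`, restoring the caller's RNG
#' state afterwards so library functions do not perturb user-level
#' reproducibility.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# derive a reproducible child seed from a parent seed and an index,
# staying inside the 32-bit integer range
child_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 1009) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(field, msg) {
  stop(sprintf("invalid parameter `%s`: %s", field, msg), call. = FALSE)
}

check_positive <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_param(field, "must be a single positive finite number")
  }
  invisible(x)
}

check_nonneg <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    stop_param(field, "must be a single non-negative finite number")
  }
  invisible(x)
}
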