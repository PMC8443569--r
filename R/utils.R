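#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed`, then restores the previous
#' RNG state so callers' random streams are unaffected.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
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
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic 31-bit polynomial hash of a string; combined with a user seed
# this keys the stub feature providers so features are a pure function of
# (sequence, seed).
string_hash <- function(s, seed = 0L) {
  h <- as.double(seed %% 2147483647)
  for (code in utf8ToInt(s)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

clip_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

# Map a function over all numeric leaves of a nested list, optionally zipping
# with a second tree of identical shape (used by the optimizer and gradient
# accumulation).
tree_map <- function(f, a, b = NULL) {
  if (is.list(a)) {
    out <- if (is.null(b)) lapply(a, function(x) tree_map(f, x))
           else Map(function(x, y) tree_map(f, x, y), a, b)
    attributes(out) <- attributes(a)
    out
  } else {
    if (is.null(b)) f(a) else f(a, b)
  }
}

tree_zeros_like <- function(a) tree_map(function(x) x * 0, a)

`%||%` <- function(a, b) if (is.null(a)) b else a
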