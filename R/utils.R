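## Internal numerical helpers shared across the package.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's random-number state, seeds the generator, evaluates
#' `expr`, and restores the previous state so that seeded package functions do
#' not disturb the session RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

## Numerically stable softplus; linear for large x, log1p(exp(x)) otherwise.
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

sigmoid <- function(x) 1 / (1 + exp(-x))

## Inverse of softplus, used to initialise pre-activation biases so the
## activated value starts at `y`.
softplus_inv <- function(y) ifelse(y > 30, y, log(expm1(y)))

leaky_relu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)

leaky_relu_grad <- function(x, slope = 0.2) ifelse(x > 0, 1, slope)

elu <- function(x) ifelse(x > 0, x, expm1(x))

elu_grad <- function(x) ifelse(x > 0, 1, exp(x))

## Row-wise softmax with max subtraction.
row_softmax <- function(m) {
  e <- exp(m - apply(m, 1L, max))
  e / rowSums(e)
}

## Add `values` (same ncol as `mat`) into rows of `mat` indexed by `idx`
## (duplicates accumulate). Returns the updated matrix.
index_add <- function(mat, idx, values) {
  rs <- rowsum(values, idx)
  rows <- as.integer(rownames(rs))
  mat[rows, ] <- mat[rows, , drop = FALSE] + rs
  mat
}

## Per-group maximum of `x` grouped by the integer vector `g` (levels 1..n);
## returns a vector aligned with `x`.
group_max_expand <- function(x, g, n) {
  mx <- rep(-Inf, n)
  o <- order(g, x)           # within each group the last element is the max
  gs <- g[o]
  keep <- c(gs[-1L] != gs[-length(gs)], TRUE)
  mx[gs[keep]] <- x[o][keep]
  mx[g]
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
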