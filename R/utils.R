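# Internal helpers shared across modules.

#' @importFrom stats rgamma rmultinom rnorm runif sd cor lm coef p.adjust
#'   residuals cor.test var quantile rbinom setNames reformulate as.formula
#'   complete.cases predict kmeans
#' @importFrom utils read.delim write.table head
NULL

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

# Deterministic 31-bit hash of a character vector; used to derive independent
# RNG streams (e.g. one per sample pair) from a single user seed.
hash31 <- function(x) {
  s <- paste(x, collapse = "\r")
  h <- 0
  for (v in utf8ToInt(s)) {
    h <- (h * 31 + v) %% 2147483647
  }
  as.integer(h)
}

# Seed for the null stream of an unordered id pair: symmetric in (a, b).
pair_seed <- function(seed, a, b) {
  ids <- sort(c(as.character(a), as.character(b)))
  as.integer((as.numeric(seed) %% 65536 * 32749 + hash31(ids)) %% 2147483647)
}

# One Dirichlet draw per row of `alpha` (n x k matrix, or vector for n = 1).
rdirichlet <- function(n, alpha) {
  if (is.vector(alpha)) alpha <- matrix(alpha, n, length(alpha), byrow = TRUE)
  x <- matrix(rgamma(length(alpha), shape = alpha), nrow(alpha), ncol(alpha))
  x / rowSums(x)
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) && all(is.finite(x)) && all(abs(x - round(x)) < tol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
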