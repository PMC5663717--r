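#' @include AllClasses.R
NULL

## internal argument checks -------------------------------------------------

.assertNumber <- function(x, name, lower = -Inf, upper = Inf,
                          strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  ok <- if (strict) (x > lower && x < upper) else (x >= lower && x <= upper)
  if (!ok)
    stop(sprintf("'%s' = %g is outside the allowed range (%g, %g)",
                 name, x, lower, upper), call. = FALSE)
  invisible(x)
}

.assertCount <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < min)
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

.assertSeed <- function(seed) {
  if (is.null(seed))
    stop("a 'seed' is required for every stochastic step", call. = FALSE)
  .assertCount(seed, "seed", min = 0L)
}

## rank transform with average ranks for ties, column-wise over a matrix
.rankColumns <- function(m) {
  apply(m, 2L, rank, ties.method = "average")
}

## residualize the columns of m on a fixed design (with intercept) via a
## prefactored QR; returns columns scaled to unit norm (zero-variance
## columns yield NaN and are the caller's problem to detect)
.residUnit <- function(m, qrX) {
  r <- qr.resid(qrX, m)
  if (is.null(dim(r))) r <- matrix(r, ncol = 1L)
  nrm <- sqrt(colSums(r^2))
  sweep(r, 2L, nrm, "/")
}

## covariate table -> numeric design matrix (no intercept column; factors
## and characters expanded to dummies)
.covarMatrix <- function(covars, n) {
  if (is.null(covars) || (is.data.frame(covars) && ncol(covars) == 0L))
    return(matrix(numeric(0), nrow = n, ncol = 0L))
  covars <- as.data.frame(covars)
  if (nrow(covars) != n)
    stop("covariate rows must match the number of subjects", call. = FALSE)
  if (any(!complete.cases(covars)))
    stop("covariates contain missing values", call. = FALSE)
  mm <- stats::model.matrix(~ ., data = covars)
  mm[, -1, drop = FALSE]
}

## deterministic child seeds below 2^31 for multi-stage simulations
.childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}

## union-find over n elements; returns root per element
.unionFind <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  if (length(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1L]); rb <- find(pairs[r, 2L])
      if (ra != rb) parent[rb] <- ra
    }
  }
  vapply(seq_len(n), find, integer(1))
}
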