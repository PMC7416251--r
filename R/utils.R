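# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All user-facing stochastic operations route through this so
# that `seed` arguments are self-contained.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        },
        add = TRUE
      )
    }
    set.seed(seed)
  }
  expr
}

as_feature_matrix <- function(X) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("feature matrix must be numeric")
  if (any(!is.finite(X))) stop("feature matrix contains non-finite values")
  storage.mode(X) <- "double"
  X
}

# Squared Euclidean distances between rows of X (n x d) and rows of C
# (k x d), returned as an n x k matrix. Single BLAS product; clamps tiny
# negative values from cancellation.
cross_dist2 <- function(X, C) {
  D2 <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * X %*% t(C)
  D2[D2 < 0] <- 0
  D2
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}
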