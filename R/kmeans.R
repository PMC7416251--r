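#' Within-cluster sum of squared errors
#'
#' The K-means objective: the sum over clusters of squared Euclidean
#' distances between each member point and the cluster centroid,
#' `SSE = sum_k sum_{i in c_k} ||x_i - mu_k||^2`.
#'
#' @param X numeric matrix, observations in rows.
#' @param labels integer assignment vector in `1..K`.
#' @param centroids `K x d` matrix of cluster centers.
#' @return a single non-negative number.
#' @export
sse_of <- function(X, labels, centroids) {
  X <- as_feature_matrix(X)
  centroids <- as_feature_matrix(centroids)
  labels <- as.integer(labels)
  if (length(labels) != nrow(X)) stop("labels length must equal nrow(X)")
  if (min(labels) < 1L || max(labels) > nrow(centroids)) {
    stop("label out of range 1..", nrow(centroids))
  }
  sum((X - centroids[labels, , drop = FALSE])^2)
}

#' Batch (Lloyd) K-means from given initial centroids
#'
#' Alternates nearest-centroid assignment and mean updates until the
#' assignment vector stops changing (the batch equivalent of "centroids
#' no longer move"), with a centroid-shift tolerance as a numerical
#' safeguard. Ties in assignment go to the lowest cluster index. A
#' cluster emptied during a sweep has its centroid reset to the point
#' farthest from it, so the number of clusters stays fixed at K.
#'
#' @param X numeric matrix, observations in rows.
#' @param init_centroids `K x d` matrix of pairwise-distinct starting
#'   centers (see [random_init()], [mst_init()], [ga_init()],
#'   [hier_init()]).
#' @param max_iter maximum number of assign-and-update sweeps.
#' @param tol stop when no centroid moves more than `tol` (Euclidean).
#' @return an object of class `km_partition`: `labels` (1-based),
#'   `centroids`, `K`, `sse`, `iterations` (completed sweeps; the final
#'   sweep that merely confirms stability is not counted), `converged`,
#'   and `sse_trace` (SSE after each sweep, non-increasing).
#' @export
run_kmeans <- function(X, init_centroids, max_iter = 300L, tol = 1e-9) {
  X <- as_feature_matrix(X)
  C <- as_feature_matrix(init_centroids)
  K <- nrow(C)
  n <- nrow(X)
  if (K > n) stop("K = ", K, " exceeds the number of observations ", n)
  if (ncol(C) != ncol(X)) stop("centroid dimension mismatch")
  if (anyDuplicated(C)) stop("initial centroids must be pairwise distinct")
  labels <- NULL
  iterations <- 0L
  converged <- FALSE
  sse_trace <- numeric(0)
  for (sweep in seq_len(max_iter)) {
    D2 <- cross_dist2(X, C)
    new_labels <- max.col(-D2, ties.method = "first")
    # empty-cluster repair: hand the emptied centroid the point farthest
    # from it (stolen points are excluded from later repairs in the sweep)
    empty <- setdiff(seq_len(K), unique(new_labels))
    taken <- integer(0)
    for (k in empty) {
      cand <- order(D2[, k], decreasing = TRUE)
      far <- cand[!(cand %in% taken)][1]
      new_labels[far] <- k
      taken <- c(taken, far)
    }
    if (!is.null(labels) && identical(new_labels, labels)) {
      converged <- TRUE
      break
    }
    labels <- new_labels
    C <- centroid_means(X, labels, K)
    iterations <- iterations + 1L
    sse_trace <- c(sse_trace, sse_of(X, labels, C))
    shift <- if (sweep == 1L) Inf else max(sqrt(rowSums((C - C_prev)^2)))
    C_prev <- C
    if (shift < tol) {
      converged <- TRUE
      break
    }
  }
  structure(
    list(labels = labels, centroids = C, K = K,
         sse = sse_of(X, labels, C),
         iterations = max(iterations, 1L),
         converged = converged, sse_trace = sse_trace),
    class = "km_partition"
  )
}

centroid_means <- function(X, labels, K) {
  M <- matrix(0, K, ncol(X))
  for (k in seq_len(K)) {
    M[k, ] <- colMeans(X[labels == k, , drop = FALSE])
  }
  M
}

#' @export
print.km_partition <- function(x, ...) {
  cat(sprintf(
    "<km_partition: K = %d, n = %d, SSE = %.4f, iterations = %d%s>\n",
    x$K, length(x$labels), x$sse, x$iterations,
    if (x$converged) "" else " (not converged)"
  ))
  invisible(x)
}

#' Random initial centroids
#'
#' Draws `K` distinct observation rows uniformly without replacement —
#' the classical random initialization the hybrid strategies compete
#' against.
#'
#' @param X numeric matrix, observations in rows.
#' @param K number of centroids.
#' @param seed integer seed.
#' @return a `K x d` matrix of starting centers.
#' @export
random_init <- function(X, K, seed = 1L) {
  X <- as_feature_matrix(X)
  K <- check_count(K, "K")
  distinct <- which(!duplicated(X))
  if (length(distinct) < K) {
    stop("fewer than K = ", K, " distinct rows available")
  }
  with_local_seed(seed, X[sample(distinct, K), , drop = FALSE])
}

#' K-means with random restarts
#'
#' Runs [run_kmeans()] from [random_init()] with seeds
#' `seed, seed + 1, ..., seed + restarts - 1` and keeps the lowest-SSE
#' solution; the reported iteration count is that of the winning run.
#'
#' @inheritParams random_init
#' @param restarts number of independent starts.
#' @param max_iter,tol passed to [run_kmeans()].
#' @return the best `km_partition` across restarts.
#' @export
best_of_restarts <- function(X, K, restarts = 25L, seed = 1L,
                             max_iter = 300L, tol = 1e-9) {
  restarts <- check_count(restarts, "restarts")
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- run_kmeans(X, random_init(X, K, seed = seed + r - 1L),
                      max_iter = max_iter, tol = tol)
    if (is.null(best) || fit$sse < best$sse) best <- fit
  }
  best
}
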