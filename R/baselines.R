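# Baseline clusterers the K-means variants are compared against in
# phase I: agglomerative hierarchical, DBSCAN, and an EM-fitted Gaussian
# mixture. DBSCAN and the mixture model are implemented here directly
# (textbook forms) since no suitable dependency is assumed.

baseline_result <- function(partition, method, params) {
  structure(list(partition = partition, method = method, params = params),
            class = "baseline_result")
}

#' @export
print.baseline_result <- function(x, ...) {
  cat(sprintf("<baseline_result '%s': K = %d, n = %d>\n",
              x$method, x$partition$K, length(x$partition$labels)))
  invisible(x)
}

partition_from_labels <- function(X, labels, iterations = 1L,
                                  converged = TRUE) {
  K <- max(labels)
  keep <- labels >= 1L
  C <- centroid_means(X[keep, , drop = FALSE], labels[keep], K)
  structure(
    list(labels = labels, centroids = C, K = K,
         sse = sse_of(X[keep, , drop = FALSE], labels[keep], C),
         iterations = iterations, converged = converged,
         sse_trace = numeric(0)),
    class = "km_partition"
  )
}

#' Agglomerative hierarchical clustering
#'
#' Hierarchical clustering on Euclidean distances cut into `K` groups —
#' the same tree [hier_init()] uses, but returning the cut itself rather
#' than feeding the group means to K-means.
#'
#' @inheritParams hier_init
#' @return a `baseline_result` whose partition holds the cut's labels
#'   and group means.
#' @export
agglomerative <- function(X, K, linkage = "ward") {
  X <- as_feature_matrix(X)
  K <- check_count(K, "K")
  groups <- stats::cutree(stats::hclust(stats::dist(X),
                                        method = linkage_method(linkage)), K)
  baseline_result(partition_from_labels(X, as.integer(groups)),
                  "hierarchical", list(K = K, linkage = linkage))
}

#' DBSCAN density-based clustering
#'
#' Classic DBSCAN: core points have at least `min_pts` points (counting
#' themselves) within radius `eps`; clusters grow from core points;
#' everything else is noise, labelled 0. With `eps = "auto"` the radius
#' is taken at the knee (maximum second difference) of the sorted
#' `min_pts`-nearest-neighbour distance curve.
#'
#' @param X numeric matrix, observations in rows.
#' @param eps neighbourhood radius, or `"auto"`.
#' @param min_pts minimum neighbourhood size for a core point (>= 2).
#' @return a `baseline_result`; noise points carry label 0, clusters are
#'   numbered 1..K in discovery order. The radius used is in `$params`.
#' @export
dbscan <- function(X, eps = "auto", min_pts = 4L) {
  X <- as_feature_matrix(X)
  min_pts <- check_count(min_pts, "min_pts", min = 2L)
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  if (identical(eps, "auto")) {
    knn <- apply(D, 1, function(r) sort(r)[min_pts])  # min_pts-NN incl. self
    curve <- sort(knn)
    eps <- if (n >= 3L) curve[which.max(diff(diff(curve))) + 1L]
           else max(curve)
  }
  labels <- rep(0L, n)
  visited <- rep(FALSE, n)
  neighbours <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(neighbours, length, integer(1)) >= min_pts
  k <- 0L
  for (i in seq_len(n)) {
    if (visited[i] || !core[i]) next
    k <- k + 1L
    queue <- i
    visited[i] <- TRUE
    labels[i] <- k
    while (length(queue) > 0L) {
      p <- queue[1L]
      queue <- queue[-1L]
      for (q in neighbours[[p]]) {
        if (labels[q] == 0L) labels[q] <- k      # border or newly reached
        if (!visited[q] && core[q]) {
          visited[q] <- TRUE
          queue <- c(queue, q)
        }
      }
    }
  }
  if (k == 0L) {
    warning("DBSCAN found no clusters: all points are noise")
    part <- structure(
      list(labels = labels, centroids = matrix(numeric(0), 0, ncol(X)),
           K = 0L, sse = NA_real_, iterations = 1L, converged = TRUE,
           sse_trace = numeric(0)),
      class = "km_partition"
    )
  } else {
    part <- partition_from_labels(X, labels)
  }
  baseline_result(part, "dbscan",
                  list(eps = eps, min_pts = min_pts,
                       n_noise = sum(labels == 0L)))
}

# Log-density of rows of X under N(mu, Sigma), via Cholesky.
mvn_logdens <- function(X, mu, sigma) {
  d <- ncol(X)
  ch <- chol(sigma)
  z <- forwardsolve(t(ch), t(X) - mu)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
}

#' Gaussian mixture clustering by expectation-maximization
#'
#' Fits a `K`-component full-covariance Gaussian mixture by EM (means
#' initialized from [random_init()], covariances from the pooled sample
#' covariance), keeps the best log-likelihood across restarts, and
#' labels each point by its maximum posterior responsibility.
#' Near-singular covariances are ridge-regularized by `1e-6` on the
#' diagonal (with a message).
#'
#' @param X numeric matrix, observations in rows.
#' @param K number of components.
#' @param restarts independent EM starts.
#' @param seed integer seed.
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood
#'   gain drops below `tol`.
#' @return a `baseline_result`; `$params$loglik` is the attained
#'   log-likelihood and `$params$loglik_trace` its (non-decreasing)
#'   within-run trace.
#' @export
em_gmm <- function(X, K, restarts = 5L, seed = 1L, max_iter = 200L,
                   tol = 1e-8) {
  X <- as_feature_matrix(X)
  K <- check_count(K, "K")
  restarts <- check_count(restarts, "restarts")
  n <- nrow(X)
  d <- ncol(X)
  if (K > n) stop("K exceeds the number of observations")
  pooled <- stats::cov(X) * (n - 1) / n + diag(1e-10, d)
  run_once <- function(s) {
    mu <- random_init(X, K, seed = s)
    sigma <- replicate(K, pooled, simplify = FALSE)
    w <- rep(1 / K, K)
    trace <- numeric(0)
    resp <- NULL
    for (it in seq_len(max_iter)) {
      logd <- vapply(seq_len(K), function(k) {
        log(w[k]) + mvn_logdens(X, mu[k, ], sigma[[k]])
      }, numeric(n))
      m <- apply(logd, 1, max)
      ll <- sum(m + log(rowSums(exp(logd - m))))
      resp <- exp(logd - m - log(rowSums(exp(logd - m))))
      trace <- c(trace, ll)
      if (it > 1L && ll - trace[it - 1L] < tol) break
      nk <- colSums(resp)
      w <- nk / n
      for (k in seq_len(K)) {
        mu[k, ] <- colSums(resp[, k] * X) / nk[k]
        Xc <- t(X) - mu[k, ]
        sk <- (Xc %*% (resp[, k] * t(Xc))) / nk[k]
        if (inherits(tryCatch(chol(sk), error = identity), "error")) {
          message("em_gmm: ridge-regularizing a singular covariance")
          sk <- sk + diag(1e-6, d)
        }
        sigma[[k]] <- sk
      }
    }
    list(mu = mu, sigma = sigma, w = w, resp = resp,
         loglik = trace[length(trace)], trace = trace, iterations = it)
  }
  fits <- lapply(seq_len(restarts) + seed - 1L, run_once)
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
  labels <- max.col(best$resp, ties.method = "first")
  # relabel to consecutive ids in case a component lost all points
  labels <- as.integer(factor(labels))
  part <- partition_from_labels(X, labels, iterations = best$iterations)
  baseline_result(part, "em",
                  list(K = K, restarts = restarts, loglik = best$loglik,
                       loglik_trace = best$trace, means = best$mu,
                       covariances = best$sigma, weights = best$w))
}
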