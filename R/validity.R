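#' Mean silhouette width
#'
#' Per-point silhouette `s_i = (b_i - a_i) / max(a_i, b_i)` where `a_i`
#' is the mean distance to the point's own cluster (excluding itself)
#' and `b_i` the smallest mean distance to any other cluster, averaged
#' over all points. Singletons get `s_i = 0`; coincident clusters
#' (`a_i = b_i = 0`) also contribute 0.
#'
#' @param X numeric matrix, observations in rows.
#' @param labels cluster assignment vector (>= 2 distinct clusters).
#' @return mean silhouette in `[-1, 1]`.
#' @export
silhouette_mean <- function(X, labels) {
  X <- as_feature_matrix(X)
  labels <- as.integer(factor(labels))
  ks <- sort(unique(labels))
  if (length(ks) < 2L) stop("silhouette undefined for a single cluster")
  D <- as.matrix(stats::dist(X))
  n <- nrow(X)
  sizes <- tabulate(labels)
  # column k of `sums`: total distance from each point to cluster k
  sums <- vapply(ks, function(k) {
    rowSums(D[, labels == k, drop = FALSE])
  }, numeric(n))
  s <- numeric(n)
  for (i in seq_len(n)) {
    k <- labels[i]
    if (sizes[k] == 1L) next                       # singleton convention
    a <- sums[i, k] / (sizes[k] - 1L)
    b <- min(sums[i, -k] / sizes[-k])
    m <- max(a, b)
    s[i] <- if (m > 0) (b - a) / m else 0
  }
  mean(s)
}

#' Dunn index
#'
#' Smallest between-cluster point distance divided by the largest
#' within-cluster diameter; higher is better. A zero maximum diameter
#' (all clusters collapsed) yields `Inf` with a warning.
#'
#' @inheritParams silhouette_mean
#' @return a non-negative number (possibly `Inf`).
#' @export
dunn_index <- function(X, labels) {
  X <- as_feature_matrix(X)
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2L) stop("Dunn index needs >= 2 clusters")
  D <- as.matrix(stats::dist(X))
  same <- outer(labels, labels, "==")
  diag(same) <- NA
  max_diam <- max(D[same & !is.na(same)])
  min_inter <- min(D[!same & !is.na(same)])
  if (max_diam == 0) {
    warning("all clusters have zero diameter; Dunn index is Inf")
    return(Inf)
  }
  min_inter / max_diam
}

#' Pair agreement counts between two partitions
#'
#' Counts, over all `n (n - 1) / 2` point pairs: `a` together in both
#' partitions, `b` together only in the first, `c` together only in the
#' second, `d` apart in both.
#'
#' @param u,v equal-length label vectors.
#' @return named numeric vector `c(a, b, c, d)`.
#' @export
pair_counts <- function(u, v) {
  if (length(u) != length(v)) stop("label vectors differ in length")
  n <- length(u)
  if (n < 2L) stop("need at least 2 observations")
  tab <- table(u, v)
  total <- choose(n, 2)
  a <- sum(choose(tab, 2))
  P <- sum(choose(rowSums(tab), 2))
  Q <- sum(choose(colSums(tab), 2))
  c(a = a, b = P - a, c = Q - a, d = total - P - Q + a)
}

#' Rand index and adjusted Rand index
#'
#' `RI = (a + d) / (a + b + c + d)` from [pair_counts()]; `ARI` is the
#' Hubert-Arabie chance-corrected form. When the chance correction is
#' degenerate (both partitions trivial) ARI is 1 for identical
#' partitions and 0 otherwise.
#'
#' @inheritParams pair_counts
#' @return named numeric vector `c(RI, ARI)`.
#' @export
rand_and_ari <- function(u, v) {
  pc <- pair_counts(u, v)
  total <- sum(pc)
  ri <- (pc["a"] + pc["d"]) / total
  P <- pc["a"] + pc["b"]
  Q <- pc["a"] + pc["c"]
  expected <- P * Q / total
  denom <- (P + Q) / 2 - expected
  ari <- if (denom == 0) {
    message("degenerate ARI denominator; using identity convention")
    if (pc["b"] == 0 && pc["c"] == 0) 1 else 0
  } else {
    (pc["a"] - expected) / denom
  }
  c(RI = unname(ri), ARI = unname(ari))
}

#' Clustering accuracy under optimal matching
#'
#' Fraction of points correctly labelled after matching clusters to
#' classes one-to-one so as to maximize agreement (Hungarian assignment
#' on the contingency table); unmatched clusters contribute nothing.
#'
#' @param u ground-truth class labels.
#' @param v cluster labels.
#' @return accuracy in `[0, 1]`.
#' @export
accuracy_matched <- function(u, v) {
  if (length(u) != length(v)) stop("label vectors differ in length")
  tab <- unclass(table(u, v))
  flip <- nrow(tab) > ncol(tab)
  if (flip) tab <- t(tab)
  match <- hungarian_min(max(tab) - tab)
  sum(tab[cbind(seq_len(nrow(tab)), match)]) / length(u)
}

#' Class-weighted F-measure
#'
#' For each true class, the best F1 score attained by any single
#' cluster (precision = class share of the cluster, recall = cluster
#' share of the class), weighted by class size.
#'
#' @inheritParams accuracy_matched
#' @return F-measure in `[0, 1]`.
#' @export
f_measure <- function(u, v) {
  if (length(u) != length(v)) stop("label vectors differ in length")
  tab <- unclass(table(u, v))
  n <- length(u)
  class_sizes <- rowSums(tab)
  cluster_sizes <- colSums(tab)
  total <- 0
  for (i in seq_len(nrow(tab))) {
    prec <- tab[i, ] / cluster_sizes
    rec <- tab[i, ] / class_sizes[i]
    f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
    total <- total + class_sizes[i] / n * max(f1)
  }
  unname(total)
}

#' Hubert's gamma between two partitions
#'
#' Pearson correlation, over all point pairs, between the binary
#' co-membership indicators of the two partitions.
#'
#' @inheritParams pair_counts
#' @return correlation in `[-1, 1]`.
#' @export
hubert_gamma <- function(u, v) {
  pc <- pair_counts(u, v)
  total <- sum(pc)
  P <- pc["a"] + pc["b"]
  Q <- pc["a"] + pc["c"]
  var2 <- P * (total - P) * Q * (total - Q)
  if (var2 == 0) {
    stop("Hubert's gamma undefined: a partition has constant co-membership")
  }
  unname((total * pc["a"] - P * Q) / sqrt(var2))
}

#' Mutual information and variation of information
#'
#' Entropies in nats from the joint contingency distribution:
#' `MI = H(U) + H(V) - H(U, V)` and the partition metric
#' `VI = H(U) + H(V) - 2 MI`.
#'
#' @inheritParams pair_counts
#' @return named numeric vector `c(MI, VI)`.
#' @export
mi_and_vi <- function(u, v) {
  if (length(u) != length(v)) stop("label vectors differ in length")
  n <- length(u)
  joint <- table(u, v) / n
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  hu <- ent(rowSums(joint))
  hv <- ent(colSums(joint))
  huv <- ent(as.vector(joint))
  mi <- hu + hv - huv
  c(MI = mi, VI = hu + hv - 2 * mi)
}

#' Robustness-performance trade-off (RPT)
#'
#' A stability-weighted silhouette: `RPT = Si * (1 + S)`, where `Si` is
#' the mean silhouette of the input clustering and `S` in `[0, 1]` is
#' the mean Rand index between the input labels and re-clusterings of
#' `B` bootstrap resamples (same method, same K), each comparison
#' restricted to the resampled points. Stable, well-separated
#' clusterings approach `2 * Si`; unstable ones stay near `Si`.
#'
#' @inheritParams silhouette_mean
#' @param B number of bootstrap resamples (at least 10).
#' @param seed integer seed.
#' @param recluster function `(X, K) -> label vector` used to re-cluster
#'   each resample; defaults to a single seeded random-start K-means.
#' @return the RPT value.
#' @export
rpt <- function(X, labels, B = 50L, seed = 1L, recluster = NULL) {
  X <- as_feature_matrix(X)
  labels <- as.integer(factor(labels))
  if (B < 10L) stop("B must be at least 10")
  K <- length(unique(labels))
  if (is.null(recluster)) {
    recluster <- function(Xb, K) {
      run_kmeans(Xb, random_init(Xb, K, seed = sample.int(2^31 - 1, 1)))$labels
    }
  }
  si <- silhouette_mean(X, labels)
  n <- nrow(X)
  agree <- with_local_seed(seed, vapply(seq_len(B), function(b) {
    idx <- sample(n, n, replace = TRUE)
    reb <- recluster(X[idx, , drop = FALSE], K)
    unname(rand_and_ari(labels[idx], reb)["RI"])
  }, numeric(1)))
  si * (1 + mean(agree))
}

#' Full validity report for one clustering
#'
#' Assembles the eleven-index report row: iteration count, SSE, the
#' three internal indices (silhouette, RPT, Dunn), and — when
#' ground-truth labels are supplied — the six external indices (RI, ARI,
#' AC, F, HI, VI).
#'
#' @param X numeric matrix, observations in rows.
#' @param part a `km_partition` (or list with `labels`, `centroids`,
#'   `sse`, `iterations`).
#' @param truth optional ground-truth labels.
#' @param rpt_B,seed,recluster passed to [rpt()].
#' @return one-row data frame with columns
#'   `I, SSE, Si, RPT, Dunn, RI, ARI, AC, F, HI, VI`.
#' @export
validity_report <- function(X, part, truth = NULL, rpt_B = 50L,
                            seed = 1L, recluster = NULL) {
  labels <- part$labels
  out <- data.frame(
    I = part$iterations,
    SSE = part$sse,
    Si = silhouette_mean(X, labels),
    RPT = rpt(X, labels, B = rpt_B, seed = seed, recluster = recluster),
    Dunn = dunn_index(X, labels),
    RI = NA_real_, ARI = NA_real_, AC = NA_real_,
    F = NA_real_, HI = NA_real_, VI = NA_real_
  )
  if (!is.null(truth)) {
    ra <- rand_and_ari(truth, labels)
    mv <- mi_and_vi(truth, labels)
    out$RI <- ra[["RI"]]
    out$ARI <- ra[["ARI"]]
    out$AC <- accuracy_matched(truth, labels)
    out$F <- f_measure(truth, labels)
    out$HI <- tryCatch(hubert_gamma(truth, labels),
                       error = function(e) NA_real_)
    out$VI <- mv[["VI"]]
  }
  out
}

#' Select the number of clusters by silhouette/gap/elbow majority
#'
#' Scans `k` over the search range, clustering with `method` at each
#' `k`, and proposes: the `k` maximizing mean silhouette; the smallest
#' `k` satisfying the gap-statistic one-standard-error rule (uniform
#' reference sets over the feature bounding box); and the `k` of
#' maximum curvature (largest second difference) of the SSE curve. The
#' final `k` is the majority vote, or the median of the three when all
#' disagree (flagged as a tie).
#'
#' @param X standardized numeric matrix.
#' @param method function `(X, K) -> list(labels, sse)`; defaults to
#'   [best_of_restarts()] with 10 restarts.
#' @param range integer vector `c(lo, hi)`, clipped to `[2, n - 1]`.
#' @param gap_B number of uniform reference datasets for the gap
#'   statistic.
#' @param seed integer seed.
#' @return an object of class `k_selection` with elements `k_elbow`,
#'   `k_gap`, `k_silhouette`, `k_final`, `tie`, `search_range`, and the
#'   per-k curves (`sse`, `silhouette`, `gap`, `gap_se`).
#' @export
select_k <- function(X, method = NULL, range = c(2L, 15L), gap_B = 50L,
                     seed = 1L) {
  X <- as_feature_matrix(X)
  n <- nrow(X)
  if (is.null(method)) {
    method <- function(Xk, K) {
      best_of_restarts(Xk, K, restarts = 10L,
                       seed = sample.int(2^31 - 1, 1))
    }
  }
  lo <- max(2L, range[1])
  hi <- min(n - 1L, range[2])
  if (lo != range[1] || hi != range[2]) {
    warning(sprintf("search range clipped to [%d, %d]", lo, hi))
  }
  ks <- lo:hi
  with_local_seed(seed, {
    fits <- lapply(ks, function(k) method(X, k))
    sse <- vapply(fits, function(f) f$sse, numeric(1))
    sil <- vapply(seq_along(ks), function(i) {
      silhouette_mean(X, fits[[i]]$labels)
    }, numeric(1))
    # gap statistic: uniform reference draws over the bounding box
    lob <- apply(X, 2, min)
    hib <- apply(X, 2, max)
    ref_logW <- matrix(0, gap_B, length(ks))
    for (b in seq_len(gap_B)) {
      Xr <- vapply(seq_len(ncol(X)), function(j) {
        stats::runif(n, lob[j], hib[j])
      }, numeric(n))
      ref_logW[b, ] <- vapply(ks, function(k) log(method(Xr, k)$sse),
                              numeric(1))
    }
    gap <- colMeans(ref_logW) - log(sse)
    gap_se <- apply(ref_logW, 2, stats::sd) * sqrt(1 + 1 / gap_B)
    k_gap <- ks[length(ks)]
    for (i in seq_len(length(ks) - 1L)) {
      if (gap[i] >= gap[i + 1L] - gap_se[i + 1L]) {
        k_gap <- ks[i]
        break
      }
    }
    k_sil <- ks[which.max(sil)]
    k_elbow <- if (length(ks) >= 3L) {
      ks[1L + which.max(diff(diff(sse)))]
    } else {
      ks[which.max(sil)]
    }
    votes <- c(k_elbow, k_gap, k_sil)
    tab <- sort(table(votes), decreasing = TRUE)
    tie <- length(tab) == 3L
    k_final <- if (tie) as.integer(round(stats::median(votes)))
               else as.integer(names(tab)[1L])
    structure(
      list(k_elbow = k_elbow, k_gap = k_gap, k_silhouette = k_sil,
           k_final = k_final, tie = tie, search_range = c(lo, hi),
           k = ks, sse = sse, silhouette = sil, gap = gap,
           gap_se = gap_se),
      class = "k_selection"
    )
  })
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf(
    "<k_selection: elbow %d, gap %d, silhouette %d -> k = %d%s>\n",
    x$k_elbow, x$k_gap, x$k_silhouette, x$k_final,
    if (x$tie) " (no majority; median)" else ""
  ))
  invisible(x)
}
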