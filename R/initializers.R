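#' Minimum spanning tree of the complete Euclidean graph
#'
#' Prim's algorithm on the complete graph whose vertices are the rows of
#' `X` and whose edge weights are Euclidean distances. Ties are broken
#' towards smaller vertex indices, so the tree is deterministic.
#' Duplicate rows are allowed (zero-weight edges).
#'
#' @param X numeric matrix, observations in rows (`n >= 2`).
#' @return an object of class `spanning_tree`: `edges` (data frame with
#'   columns `u`, `v`, `weight`, `u < v`), `degrees` (length-n vertex
#'   degrees), `total_weight`.
#' @export
prim_mst <- function(X) {
  X <- as_feature_matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 points")
  D <- as.matrix(stats::dist(X))
  in_tree <- rep(FALSE, n)
  best <- rep(Inf, n)       # cheapest connection of each vertex to the tree
  parent <- rep(NA_integer_, n)
  in_tree[1L] <- TRUE
  best_upd <- D[1L, ]
  improve <- best_upd < best
  best[improve] <- best_upd[improve]
  parent[improve] <- 1L
  edges <- matrix(0, n - 1L, 3L)
  for (e in seq_len(n - 1L)) {
    cand <- ifelse(in_tree, Inf, best)
    v <- which.min(cand)                 # first minimum = lowest index
    u <- parent[v]
    edges[e, ] <- c(min(u, v), max(u, v), D[u, v])
    in_tree[v] <- TRUE
    upd <- !in_tree & D[v, ] < best
    best[upd] <- D[v, upd]
    parent[upd] <- v
  }
  edges <- as.data.frame(edges)
  names(edges) <- c("u", "v", "weight")
  edges$u <- as.integer(edges$u)
  edges$v <- as.integer(edges$v)
  structure(
    list(edges = edges,
         degrees = tabulate(c(edges$u, edges$v), nbins = n),
         total_weight = sum(edges$weight)),
    class = "spanning_tree"
  )
}

#' @export
print.spanning_tree <- function(x, ...) {
  cat(sprintf("<spanning_tree: %d vertices, total weight %.4f>\n",
              length(x$degrees), x$total_weight))
  invisible(x)
}

#' Skeleton points of a spanning tree
#'
#' Skeleton points are the tree vertices through which the most edges
#' pass: all vertices of degree at least 2, ranked by degree
#' (descending), then by the sum of incident edge weights (ascending —
#' tighter hubs first), then by index. If fewer than `K` qualify, leaves
#' are appended under the same ranking so at least `K` candidates are
#' always available.
#'
#' @param tree a `spanning_tree`.
#' @param K number of centroids the skeleton must support.
#' @return integer vector of vertex indices, best candidate first.
#' @export
skeleton_points <- function(tree, K) {
  stopifnot(inherits(tree, "spanning_tree"))
  K <- check_count(K, "K")
  n <- length(tree$degrees)
  wsum <- rep(0, n)
  for (r in seq_len(nrow(tree$edges))) {
    e <- tree$edges[r, ]
    wsum[e$u] <- wsum[e$u] + e$weight
    wsum[e$v] <- wsum[e$v] + e$weight
  }
  rank_order <- order(-tree$degrees, wsum, seq_len(n))
  members <- rank_order[tree$degrees[rank_order] >= 2L]
  if (length(members) < K) {
    leaves <- rank_order[tree$degrees[rank_order] < 2L]
    members <- c(members, leaves[seq_len(min(K - length(members),
                                             length(leaves)))])
  }
  members
}

#' MST-based initial centroids
#'
#' Builds the minimum spanning tree, extracts its skeleton points, and
#' selects `K` of them: the top-ranked (highest-degree) skeleton point
#' first, then greedily the point whose smallest degree-weighted
#' distance `h(s_i, s_j) = (v_i + v_j) * d(s_i, s_j)` to the already
#' chosen centroids is largest (a maxi-min rule that pushes the starting
#' centers into distinct dense regions).
#'
#' @param X numeric matrix, observations in rows.
#' @param K number of centroids (`2 <= K <= n`).
#' @return a `K x d` matrix of starting centers (rows of `X`).
#' @export
mst_init <- function(X, K) {
  X <- as_feature_matrix(X)
  K <- check_count(K, "K", min = 2L)
  if (K > nrow(X)) stop("K exceeds the number of observations")
  tree <- prim_mst(X)
  skel <- skeleton_points(tree, K)
  deg <- tree$degrees
  chosen <- skel[1L]
  avail <- setdiff(skel, chosen)
  while (length(chosen) < K) {
    # r_i = max_s min_c h(s, c); ties towards the lower vertex index
    h_min <- vapply(avail, function(s) {
      min((deg[s] + deg[chosen]) *
            sqrt(colSums((t(X[chosen, , drop = FALSE]) - X[s, ])^2)))
    }, numeric(1))
    pick <- avail[order(-h_min, avail)][1L]
    chosen <- c(chosen, pick)
    avail <- setdiff(avail, pick)
  }
  X[chosen, , drop = FALSE]
}

#' Genetic-algorithm settings
#'
#' @param pop_size population size M.
#' @param generations number of generations T.
#' @param crossover_rate single-point crossover probability P_C.
#' @param mutation_rate per-chromosome mutation probability P_m.
#' @param elitism number of best chromosomes copied unchanged.
#' @param seed integer seed.
#' @return an object of class `ga_config`.
#' @export
ga_config <- function(pop_size = 50L, generations = 100L,
                      crossover_rate = 0.8, mutation_rate = 0.1,
                      elitism = 1L, seed = 1L) {
  pop_size <- check_count(pop_size, "pop_size", min = 2L)
  generations <- check_count(generations, "generations")
  elitism <- check_count(elitism, "elitism", min = 0L)
  if (crossover_rate < 0 || crossover_rate > 1) stop("crossover_rate in [0,1]")
  if (mutation_rate < 0 || mutation_rate > 1) stop("mutation_rate in [0,1]")
  if (elitism >= pop_size) stop("elitism must be < pop_size")
  structure(
    list(pop_size = pop_size, generations = generations,
         crossover_rate = crossover_rate, mutation_rate = mutation_rate,
         elitism = elitism, seed = as.integer(seed)),
    class = "ga_config"
  )
}

#' Genetic-algorithm initial centroids
#'
#' Each chromosome encodes `K` distinct observation rows as candidate
#' centroids; its fitness is `1 / (1 + SSE)` of a single
#' nearest-centroid assignment of the data to those rows, so fitter
#' chromosomes start K-means closer to a good optimum. Generations
#' evolve by roulette-wheel selection, single-point crossover at
#' centroid boundaries, and per-chromosome mutation that swaps one
#' centroid for a random data row; duplicated centroids inside an
#' offspring are resampled. The best chromosome ever seen is returned.
#'
#' @param X numeric matrix, observations in rows.
#' @param K number of centroids.
#' @param cfg a [ga_config()].
#' @return a `K x d` matrix of starting centers (rows of `X`), with the
#'   attained fitness in attribute `fitness`.
#' @export
ga_init <- function(X, K, cfg = ga_config()) {
  X <- as_feature_matrix(X)
  K <- check_count(K, "K", min = 2L)
  stopifnot(inherits(cfg, "ga_config"))
  distinct <- which(!duplicated(X))
  if (length(distinct) < K) stop("fewer than K distinct rows")
  fitness_of <- function(idx) {
    C <- X[idx, , drop = FALSE]
    1 / (1 + sum(do.call(pmin, as.data.frame(cross_dist2(X, C)))))
  }
  pick_one <- function(v) v[sample.int(length(v), 1L)]
  resample_repair <- function(idx) {
    while (anyDuplicated(idx)) {
      dup <- which(duplicated(idx))[1L]
      idx[dup] <- pick_one(setdiff(distinct, idx))
    }
    idx
  }
  with_local_seed(cfg$seed, {
    M <- cfg$pop_size
    pop <- replicate(M, sample(distinct, K), simplify = FALSE)
    fit <- vapply(pop, fitness_of, numeric(1))
    best_idx <- pop[[which.max(fit)]]
    best_fit <- max(fit)
    for (gen in seq_len(cfg$generations)) {
      ord <- order(fit, decreasing = TRUE)
      elite <- pop[ord[seq_len(cfg$elitism)]]
      parents <- pop[sample.int(M, M - cfg$elitism, replace = TRUE,
                                prob = fit / sum(fit))]
      offspring <- parents
      i <- 1L
      while (i + 1L <= length(offspring)) {
        if (stats::runif(1) < cfg$crossover_rate && K >= 2L) {
          cut <- sample.int(K - 1L, 1L)
          a <- offspring[[i]]
          b <- offspring[[i + 1L]]
          offspring[[i]] <- resample_repair(c(a[1:cut], b[(cut + 1L):K]))
          offspring[[i + 1L]] <- resample_repair(c(b[1:cut], a[(cut + 1L):K]))
        }
        i <- i + 2L
      }
      for (j in seq_along(offspring)) {
        if (stats::runif(1) < cfg$mutation_rate) {
          idx <- offspring[[j]]
          idx[sample.int(K, 1L)] <- pick_one(distinct)
          offspring[[j]] <- resample_repair(idx)
        }
      }
      pop <- c(elite, offspring)
      fit <- vapply(pop, fitness_of, numeric(1))
      if (max(fit) > best_fit) {
        best_fit <- max(fit)
        best_idx <- pop[[which.max(fit)]]
      }
    }
    structure(X[best_idx, , drop = FALSE], fitness = best_fit)
  })
}

linkage_method <- function(linkage) {
  map <- c(ward = "ward.D2", complete = "complete",
           average = "average", single = "single")
  if (!linkage %in% names(map)) {
    stop("linkage must be one of: ", paste(names(map), collapse = ", "))
  }
  map[[linkage]]
}

#' Hierarchical initial centroids
#'
#' Agglomerative clustering on Euclidean distances (Ward linkage by
#' default, which minimizes the same within-cluster variance objective
#' K-means does), the dendrogram cut into `K` groups, and the group
#' means returned as starting centers. Fully deterministic.
#'
#' @param X numeric matrix, observations in rows.
#' @param K number of centroids.
#' @param linkage one of `"ward"`, `"complete"`, `"average"`, `"single"`.
#' @return a `K x d` matrix of starting centers.
#' @export
hier_init <- function(X, K, linkage = "ward") {
  X <- as_feature_matrix(X)
  K <- check_count(K, "K")
  if (K > nrow(X)) stop("K exceeds the number of observations")
  groups <- stats::cutree(stats::hclust(stats::dist(X),
                                        method = linkage_method(linkage)), K)
  centroid_means(X, groups, K)
}
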