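# Independent brute-force oracles. These deliberately avoid the code
# paths they check: Kruskal instead of Prim, O(n^2) double loops instead
# of contingency-table algebra, exhaustive permutations instead of the
# assignment solver.

# Kruskal MST total weight with union-find.
kruskal_weight <- function(X) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  idx <- which(upper.tri(D), arr.ind = TRUE)
  ord <- order(D[upper.tri(D)])
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  total <- 0
  edges <- 0L
  for (e in ord) {
    u <- find(idx[e, 1])
    v <- find(idx[e, 2])
    if (u != v) {
      parent[u] <- v
      total <- total + D[idx[e, 1], idx[e, 2]]
      edges <- edges + 1L
      if (edges == n - 1L) break
    }
  }
  total
}

# Pair counts by explicit double loop.
naive_pair_counts <- function(u, v) {
  n <- length(u)
  a <- b <- cc <- d <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      su <- u[i] == u[j]
      sv <- v[i] == v[j]
      if (su && sv) a <- a + 1
      else if (su) b <- b + 1
      else if (sv) cc <- cc + 1
      else d <- d + 1
    }
  }
  c(a = a, b = b, c = cc, d = d)
}

# RI / ARI / Hubert's gamma straight from naive pair counts.
naive_external <- function(u, v) {
  pc <- naive_pair_counts(u, v)
  M <- sum(pc)
  P <- pc[["a"]] + pc[["b"]]
  Q <- pc[["a"]] + pc[["c"]]
  ri <- (pc[["a"]] + pc[["d"]]) / M
  exp_a <- P * Q / M
  ari <- (pc[["a"]] - exp_a) / ((P + Q) / 2 - exp_a)
  hi <- (M * pc[["a"]] - P * Q) / sqrt(P * (M - P) * Q * (M - Q))
  c(RI = ri, ARI = ari, HI = hi)
}

# Accuracy by exhaustive permutation of cluster ids (<= 6 clusters).
perm_accuracy <- function(u, v) {
  uu <- sort(unique(u))
  vv <- sort(unique(v))
  r <- length(uu)
  s <- length(vv)
  small <- min(r, s)
  big <- max(r, s)
  perms <- function(x) {
    if (length(x) <= 1) return(list(x))
    out <- list()
    for (i in seq_along(x)) {
      for (p in perms(x[-i])) out[[length(out) + 1]] <- c(x[i], p)
    }
    out
  }
  best <- 0
  for (p in perms(seq_len(big))) {
    sel <- p[seq_len(small)]
    correct <- if (r <= s) {
      sum(vapply(seq_len(r), function(i) {
        sum(u == uu[i] & v == vv[sel[i]])
      }, numeric(1)))
    } else {
      sum(vapply(seq_len(s), function(j) {
        sum(v == vv[j] & u == uu[sel[j]])
      }, numeric(1)))
    }
    best <- max(best, correct)
  }
  best / length(u)
}

# MI / VI by explicit sums over the joint table cells.
naive_mi_vi <- function(u, v) {
  n <- length(u)
  uu <- unique(u)
  vv <- unique(v)
  mi <- 0
  for (a in uu) {
    for (b in vv) {
      pab <- sum(u == a & v == b) / n
      if (pab > 0) {
        mi <- mi + pab * log(pab / (sum(u == a) / n * sum(v == b) / n))
      }
    }
  }
  h <- function(x) {
    p <- table(x) / length(x)
    -sum(p * log(p))
  }
  c(MI = mi, VI = h(u) + h(v) - 2 * mi)
}

# Class-weighted best-F1 by direct per-class/per-cluster loops.
naive_f_measure <- function(u, v) {
  n <- length(u)
  total <- 0
  for (a in unique(u)) {
    best <- 0
    for (b in unique(v)) {
      inter <- sum(u == a & v == b)
      if (inter > 0) {
        prec <- inter / sum(v == b)
        rec <- inter / sum(u == a)
        best <- max(best, 2 * prec * rec / (prec + rec))
      }
    }
    total <- total + sum(u == a) / n * best
  }
  total
}

# Mean silhouette by per-point double loops.
naive_silhouette <- function(X, labels) {
  n <- nrow(X)
  d2 <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  s <- numeric(n)
  for (i in 1:n) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0) {
      s[i] <- 0
      next
    }
    a <- mean(vapply(own, d2, numeric(1), i = i))
    b <- Inf
    for (k in setdiff(unique(labels), labels[i])) {
      others <- which(labels == k)
      b <- min(b, mean(vapply(others, d2, numeric(1), i = i)))
    }
    m <- max(a, b)
    s[i] <- if (m > 0) (b - a) / m else 0
  }
  mean(s)
}

# Dunn index by brute-force distance loops.
naive_dunn <- function(X, labels) {
  n <- nrow(X)
  min_inter <- Inf
  max_diam <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dd <- sqrt(sum((X[i, ] - X[j, ])^2))
      if (labels[i] == labels[j]) max_diam <- max(max_diam, dd)
      else min_inter <- min(min_inter, dd)
    }
  }
  min_inter / max_diam
}

# Global-optimum SSE of a 1-D 2-cluster problem by enumerating all
# bipartitions into two non-empty groups.
best_sse_2clusters_1d <- function(x) {
  n <- length(x)
  best <- Inf
  for (mask in 1:(2^n - 2)) {
    g <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    sse <- sum((x[g] - mean(x[g]))^2) + sum((x[!g] - mean(x[!g]))^2)
    best <- min(best, sse)
  }
  best
}

# Random label vector with every cluster represented at least once.
random_labels <- function(n, K) {
  repeat {
    l <- sample.int(K, n, replace = TRUE)
    if (length(unique(l)) == K) return(l)
  }
}

# Small standard fixtures.
two_pairs <- function() {
  matrix(c(0, 0, 0, 0.2, 10, 0, 10, 0.2), ncol = 2, byrow = TRUE)
}

triples_1d <- function() {
  matrix(c(0, 1, 2, 10, 11, 12, 20, 21, 22), ncol = 1)
}
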