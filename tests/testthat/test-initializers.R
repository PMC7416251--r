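test_that("prim_mst handles tiny and collinear configurations", {
  X2 <- matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)
  t2 <- prim_mst(X2)
  expect_equal(nrow(t2$edges), 1)
  expect_equal(t2$total_weight, 5)

  x <- matrix(c(0, 1, 3, 7, 20), ncol = 1)
  tp <- prim_mst(x[sample(5), , drop = FALSE])
  expect_equal(tp$total_weight, 20)        # path over the sorted chain
  expect_equal(sort(tp$degrees), c(1, 1, 2, 2, 2))
})

test_that("prim_mst equals a Kruskal oracle on random instances", {
  set.seed(2024)
  for (rep in 1:100) {
    n <- sample(5:25, 1)
    d <- sample(1:3, 1)
    X <- matrix(rnorm(n * d), n, d)
    tree <- prim_mst(X)
    expect_equal(nrow(tree$edges), n - 1)
    expect_equal(sum(tree$degrees), 2 * (n - 1))
    expect_equal(tree$total_weight, kruskal_weight(X), tolerance = 1e-9)
  }
})

test_that("skeleton_points ranks hubs first and falls back to leaves", {
  # star: hub at origin, 5 leaves evenly spread (chord > radius)
  ang <- 2 * pi * (0:4) / 5
  X <- rbind(c(0, 0), 3 * cbind(cos(ang), sin(ang)))
  tree <- prim_mst(X)
  expect_equal(tree$degrees[1], 5)
  expect_equal(skeleton_points(tree, 2)[1], 1L)

  # path on 9 vertices: internal 7 qualify, leaves excluded
  tp <- prim_mst(matrix(1:9, ncol = 1))
  skel <- skeleton_points(tp, 3)
  expect_setequal(skel, 2:8)

  # n = 2: both vertices are leaves, fallback must supply them
  t2 <- prim_mst(matrix(c(0, 1), ncol = 1))
  expect_setequal(skeleton_points(t2, 2), 1:2)
})

test_that("mst_init follows the degree-weighted maxi-min trace", {
  X9 <- triples_1d()
  C <- mst_init(X9, 3)
  # hand trace: first the tightest hub (value 1), then 21, then 11
  expect_equal(as.vector(C), c(1, 21, 11))
  fit <- run_kmeans(X9, C)
  expect_equal(fit$sse, 6.0)
  expect_equal(fit$iterations, 1L)

  # symmetric dumbbell: the two picks must straddle the lobes
  lobe <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(0.5, 0.5))
  dumbbell <- rbind(lobe, sweep(lobe, 2, c(20, 0), "+"))
  C2 <- mst_init(dumbbell, 2)
  expect_equal(sum(C2[, 1] > 10), 1)

  set.seed(5)
  X <- matrix(rnorm(40), 20, 2)
  C3 <- mst_init(X, 6)
  expect_equal(anyDuplicated(C3), 0)
})

test_that("ga_init solves enumerable instances and honours its contract", {
  # K = n distinct points: a zero-SSE chromosome exists and is optimal
  X <- matrix(c(0, 3, 10, 14), ncol = 1)
  C <- ga_init(X, 4, ga_config(pop_size = 10, generations = 5, seed = 1))
  expect_equal(attr(C, "fitness"), 1)
  expect_setequal(as.vector(C), as.vector(X))

  # two obvious quadruples: global optimum over all 28 centroid pairs
  x8 <- c(0, 1, 2, 3, 100, 101, 102, 103)
  X8 <- matrix(x8, ncol = 1)
  pair_sse <- function(i, j) {
    C <- X8[c(i, j), , drop = FALSE]
    sum(pmin((x8 - x8[i])^2, (x8 - x8[j])^2))
  }
  opt <- min(sapply(1:7, function(i) {
    sapply((i + 1):8, function(j) pair_sse(i, j))
  }) |> unlist())
  got <- ga_init(X8, 2, ga_config(pop_size = 20, generations = 30, seed = 3))
  got_sse <- sum(pmin((x8 - got[1, 1])^2, (x8 - got[2, 1])^2))
  expect_equal(got_sse, opt, tolerance = 1e-12)
  expect_equal(attr(got, "fitness"), 1 / (1 + opt), tolerance = 1e-12)

  expect_identical(
    as.vector(ga_init(X8, 2, ga_config(seed = 9))),
    as.vector(ga_init(X8, 2, ga_config(seed = 9)))
  )
})

test_that("ga_config validates operator rates", {
  expect_error(ga_config(pop_size = 1), "pop_size")
  expect_error(ga_config(crossover_rate = 1.5), "crossover_rate")
  expect_error(ga_config(elitism = 50, pop_size = 50), "elitism")
})

test_that("hier_init cuts the tree and averages groups", {
  X <- two_pairs()
  C <- hier_init(X, 2)
  expect_equal(C[order(C[, 1]), ], rbind(c(0, 0.1), c(10, 0.1)),
               ignore_attr = TRUE)
  # K = n: every point its own centroid
  Cn <- hier_init(X, 4)
  expect_equal(Cn[order(Cn[, 1], Cn[, 2]), ], X[order(X[, 1], X[, 2]), ],
               ignore_attr = TRUE)
  expect_error(hier_init(X, 2, linkage = "median"), "linkage")
})

test_that("all initializers feed run_kmeans K distinct centroids", {
  set.seed(31)
  for (rep in 1:5) {
    ds <- make_mixture(mixture_spec(60, 3, 3, separation = 2, seed = rep))
    X <- standardize(ds)$X
    for (init in list(mst_init(X, 3),
                      ga_init(X, 3, ga_config(20, 10, seed = rep)),
                      hier_init(X, 3))) {
      expect_equal(anyDuplicated(init), 0)
      fit <- run_kmeans(X, init)
      expect_setequal(unique(fit$labels), 1:3)
    }
  }
})

test_that("separated mixtures are perfectly recovered from every init", {
  for (s in 1:5) {
    ds <- make_mixture(mixture_spec(60, 2, 3, separation = 9, seed = s))
    X <- ds$X
    for (init in list(mst_init(X, 3),
                      ga_init(X, 3, ga_config(20, 20, seed = s)),
                      hier_init(X, 3))) {
      fit <- run_kmeans(X, init)
      expect_equal(rand_and_ari(ds$labels, fit$labels)[["ARI"]], 1)
    }
    # the ordinary route needs restarts: one random draw can straddle lobes
    fit <- best_of_restarts(X, 3, restarts = 10, seed = s)
    expect_equal(rand_and_ari(ds$labels, fit$labels)[["ARI"]], 1)
  }
})
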