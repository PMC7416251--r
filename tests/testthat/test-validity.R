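test_that("silhouette matches hand computation and conventions", {
  X <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  lab <- c(1, 1, 2, 2)
  # four-term hand computation: b1 = mean(10, 10.1), b2 = mean(9.9, 10)
  s1 <- (10.05 - 0.1) / 10.05
  s2 <- (9.95 - 0.1) / 9.95
  expect_equal(silhouette_mean(X, lab), mean(c(s1, s2, s2, s1)),
               tolerance = 1e-12)
  expect_equal(round(silhouette_mean(X, lab), 3), 0.990)

  # coincident pairs far apart: a_i = 0 convention gives 1
  Xc <- matrix(c(0, 0, 5, 5), ncol = 1)
  expect_equal(silhouette_mean(Xc, c(1, 1, 2, 2)), 1.0)

  expect_error(silhouette_mean(X, rep(1, 4)), "single cluster")
})

test_that("silhouette and Dunn agree with naive double-loop oracles", {
  set.seed(77)
  for (rep in 1:50) {
    n <- sample(8:25, 1)
    X <- matrix(rnorm(n * 2), n, 2)
    lab <- random_labels(n, sample(2:4, 1))
    expect_equal(silhouette_mean(X, lab), naive_silhouette(X, lab),
                 tolerance = 1e-12)
    expect_equal(dunn_index(X, lab), naive_dunn(X, lab), tolerance = 1e-12)
  }
})

test_that("Dunn index: hand value, translation scaling, Inf sentinel", {
  X <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  expect_equal(dunn_index(X, c(1, 1, 2, 2)), 99, tolerance = 1e-12)
  # translating duplicated shapes scales Dunn linearly for fixed diameters
  base <- c(0, 1)
  for (t in c(10, 20, 40)) {
    Xt <- matrix(c(base, base + t), ncol = 1)
    expect_equal(dunn_index(Xt, c(1, 1, 2, 2)), t - 1, tolerance = 1e-12)
  }
  Xz <- matrix(c(0, 0, 5, 5), ncol = 1)
  expect_warning(dz <- dunn_index(Xz, c(1, 1, 2, 2)), "Inf")
  expect_equal(dz, Inf)
})

test_that("pair_counts matches enumeration on the toy and degenerate cases", {
  u <- c(1, 1, 1, 2, 2, 2)
  v <- c(1, 1, 2, 2, 2, 2)
  expect_equal(pair_counts(u, v), c(a = 4, b = 2, c = 3, d = 6))
  expect_equal(pair_counts(u, u)[c("b", "c")], c(b = 0, c = 0))
  pc <- pair_counts(u, rep(1, 6))
  expect_equal(pc[["c"]], 9)     # all cross-class pairs joined in v
  expect_equal(pc[["d"]], 0)
  expect_error(pair_counts(u, v[-1]), "length")
})

test_that("RI/ARI match the hand-evaluated toy and chance correction", {
  u <- c(1, 1, 1, 2, 2, 2)
  v <- c(1, 1, 2, 2, 2, 2)
  ra <- rand_and_ari(u, v)
  expect_equal(ra[["RI"]], 10 / 15, tolerance = 1e-12)
  expect_equal(ra[["ARI"]], 1.2 / 3.7, tolerance = 1e-12)
  expect_equal(rand_and_ari(u, u), c(RI = 1, ARI = 1))
  # chance correction: independent labels average to ~0
  set.seed(10)
  aris <- replicate(100, {
    rand_and_ari(sample.int(4, 200, TRUE), sample.int(4, 200, TRUE))[["ARI"]]
  })
  expect_lt(abs(mean(aris)), 0.02)
  expect_message(
    d <- rand_and_ari(rep(1, 5), rep(1, 5))[["ARI"]], "degenerate")
  expect_equal(d, 1)
})

test_that("pair-counting indices equal naive oracles on random pairs", {
  set.seed(202)
  for (rep in 1:100) {
    n <- sample(10:60, 1)
    u <- random_labels(n, sample(2:5, 1))
    v <- random_labels(n, sample(2:5, 1))
    expect_equal(unname(pair_counts(u, v)), unname(naive_pair_counts(u, v)))
    o <- naive_external(u, v)
    ra <- rand_and_ari(u, v)
    expect_equal(ra[["RI"]], o[["RI"]], tolerance = 1e-12)
    expect_equal(ra[["ARI"]], o[["ARI"]], tolerance = 1e-12)
    expect_equal(hubert_gamma(u, v), o[["HI"]], tolerance = 1e-12)
    mv <- mi_and_vi(u, v)
    no <- naive_mi_vi(u, v)
    expect_equal(mv[["MI"]], no[["MI"]], tolerance = 1e-12)
    expect_equal(mv[["VI"]], no[["VI"]], tolerance = 1e-12)
    expect_equal(f_measure(u, v), naive_f_measure(u, v), tolerance = 1e-12)
  }
})

test_that("accuracy uses optimal matching, invariant to relabelling", {
  u <- c(1, 1, 1, 2, 2, 2)
  v <- c(1, 1, 2, 2, 2, 2)
  expect_equal(accuracy_matched(u, v), 5 / 6, tolerance = 1e-12)
  vperm <- c(2, 2, 1, 1, 1, 1)
  expect_equal(accuracy_matched(u, vperm), 5 / 6, tolerance = 1e-12)
  set.seed(303)
  for (rep in 1:100) {
    n <- sample(8:30, 1)
    u <- random_labels(n, sample(2:5, 1))
    v <- random_labels(n, sample(2:6, 1))
    expect_equal(accuracy_matched(u, v), perm_accuracy(u, v),
                 tolerance = 1e-12)
  }
})

test_that("F-measure matches the hand-worked toy", {
  u <- c(1, 1, 1, 2, 2, 2)
  v <- c(1, 1, 2, 2, 2, 2)
  expect_equal(f_measure(u, v), 0.5 * 0.8 + 0.5 * 6 / 7, tolerance = 1e-12)
  expect_equal(f_measure(u, u), 1)
})

test_that("Hubert's gamma: toy value, identity, degenerate error", {
  u <- c(1, 1, 1, 2, 2, 2)
  v <- c(1, 1, 2, 2, 2, 2)
  expect_equal(hubert_gamma(u, v), 18 / sqrt(54 * 56), tolerance = 1e-12)
  expect_equal(hubert_gamma(u, u), 1)
  expect_error(hubert_gamma(u, rep(1, 6)), "undefined")
})

test_that("VI is a metric: identity and triangle inequality", {
  u <- c(1, 1, 1, 2, 2, 2)
  v <- c(1, 1, 2, 2, 2, 2)
  mv <- mi_and_vi(u, v)
  expect_equal(mv[["MI"]], 0.3183, tolerance = 5e-4)  # printed precision
  expect_equal(mv[["VI"]], 0.6931, tolerance = 5e-4)
  expect_equal(mi_and_vi(u, u)[["VI"]], 0)
  set.seed(404)
  for (rep in 1:100) {
    n <- sample(10:40, 1)
    a <- random_labels(n, 3)
    b <- random_labels(n, 3)
    cc <- random_labels(n, 3)
    expect_lte(mi_and_vi(a, cc)[["VI"]],
               mi_and_vi(a, b)[["VI"]] + mi_and_vi(b, cc)[["VI"]] + 1e-12)
  }
})

test_that("RPT is a stability-weighted silhouette with bounded ratio", {
  ds <- make_mixture(mixture_spec(60, 2, 2, separation = 15, seed = 8))
  si <- silhouette_mean(ds$X, ds$labels)
  val <- rpt(ds$X, ds$labels, B = 20, seed = 1)
  expect_gt(val / si, 1.9)           # near-perfectly stable: RPT -> 2 Si
  expect_lte(val / si, 2)

  set.seed(5)
  Xn <- matrix(rnorm(80), 40, 2)
  ln <- random_labels(40, 2)
  sin_ <- silhouette_mean(Xn, ln)
  valn <- rpt(Xn, ln, B = 20, seed = 2)
  expect_gt(valn / sin_, 1)          # S in (0, 1] keeps the ratio in (1, 2]
  expect_lte(valn / sin_, 2)

  expect_error(rpt(ds$X, ds$labels, B = 5), "at least 10")
})

test_that("select_k votes correctly on unambiguous structure", {
  ds <- make_mixture(mixture_spec(90, 2, 3, separation = 8, seed = 6))
  X <- standardize(ds)$X
  sel <- select_k(X, range = c(2L, 6L), gap_B = 10, seed = 3)
  expect_equal(sel$k_silhouette, 3L)
  expect_equal(sel$k_gap, 3L)
  expect_equal(sel$k_elbow, 3L)
  expect_equal(sel$k_final, 3L)
  expect_false(sel$tie)
  expect_warning(select_k(X[1:8, ], range = c(2L, 15L), gap_B = 10),
                 "clipped")
})

test_that("validity_report respects ranges on random partitions", {
  set.seed(11)
  for (rep in 1:5) {
    ds <- make_mixture(mixture_spec(40, 2, 3, separation = 3, seed = rep))
    fit <- best_of_restarts(ds$X, 3, restarts = 5, seed = rep)
    repdf <- validity_report(ds$X, fit, truth = ds$labels, rpt_B = 10,
                             seed = rep)
    expect_true(repdf$Si >= -1 && repdf$Si <= 1)
    expect_true(repdf$RI >= 0 && repdf$RI <= 1)
    expect_true(repdf$ARI >= -1 && repdf$ARI <= 1)
    expect_true(repdf$AC >= 0 && repdf$AC <= 1)
    expect_true(repdf$F >= 0 && repdf$F <= 1)
    expect_true(is.na(repdf$HI) || (repdf$HI >= -1 && repdf$HI <= 1))
    expect_gte(repdf$VI, 0)
    expect_gte(repdf$Dunn, 0)
    expect_gte(repdf$I, 1)
    expect_equal(repdf$SSE, sse_of(ds$X, fit$labels, fit$centroids))
  }
})
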