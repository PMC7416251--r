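#' Specify a labelled Gaussian mixture
#'
#' Describes a synthetic dataset drawn from K isotropic unit-variance
#' Gaussian components whose means sit on an axis-aligned grid scaled so
#' that the distance between nearest component means equals `separation`
#' within-component standard deviations. `separation` therefore acts as
#' a direct overlap dial: values around 2-4 give visibly overlapping
#' classes, values of 8 or more give essentially disjoint ones.
#'
#' @param n total number of observations (`n >= 2 * K`).
#' @param d number of features.
#' @param K number of mixture components.
#' @param separation nearest-mean distance in units of within-component
#'   standard deviation; non-negative.
#' @param weights length-`K` vector of component probabilities summing
#'   to 1; defaults to equal weights.
#' @param outlier_frac fraction (in \[0, 0.2\]) of points replaced by
#'   uniform draws over a box 1.5 times the data bounding box; outliers
#'   are labelled by their nearest component mean so external indices
#'   remain well defined.
#' @param seed integer seed; the generated dataset is a pure function of
#'   the spec.
#' @return an object of class `mixture_spec`.
#' @export
mixture_spec <- function(n, d, K, separation = 3, weights = NULL,
                         outlier_frac = 0, seed = 1L) {
  n <- check_count(n, "n", min = 2L)
  d <- check_count(d, "d", min = 1L)
  K <- check_count(K, "K", min = 1L)
  if (n < 2L * K) stop("need n >= 2 * K")
  if (separation < 0) stop("separation must be >= 0")
  if (is.null(weights)) weights <- rep(1 / K, K)
  if (length(weights) != K) stop("weights length must equal K")
  if (abs(sum(weights) - 1) > 1e-12) stop("weights must sum to 1")
  if (any(weights <= 0)) stop("weights must be positive")
  if (outlier_frac < 0 || outlier_frac > 0.2) {
    stop("outlier_frac must lie in [0, 0.2]")
  }
  structure(
    list(n = n, d = d, K = K, separation = separation,
         weights = weights, outlier_frac = outlier_frac,
         seed = as.integer(seed)),
    class = "mixture_spec"
  )
}

# Component means on an axis-aligned unit grid scaled by `separation`:
# the first K points of the lexicographic m-ary grid in d dimensions,
# with m minimal such that m^d >= K. Nearest-mean distance equals
# `separation` exactly (adjacent grid codes differ in one coordinate).
mixture_means <- function(K, d, separation) {
  m <- max(2L, ceiling(K^(1 / d)))
  pts <- matrix(0, K, d)
  for (i in seq_len(K)) {
    code <- i - 1L
    for (j in seq_len(d)) {
      pts[i, d - j + 1L] <- code %% m
      code <- code %/% m
    }
  }
  pts * separation
}

#' Draw a synthetic dataset from a mixture specification
#'
#' @param spec a [mixture_spec()].
#' @return a labelled, unstandardized `km_dataset`; ground-truth labels
#'   are the generating components (1-based).
#' @export
make_mixture <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  with_local_seed(spec$seed, {
    mu <- mixture_means(spec$K, spec$d, spec$separation)
    # component sizes: multinomial, redrawn until every component has at
    # least 2 members so downstream K-cluster invariants hold
    repeat {
      sizes <- as.vector(stats::rmultinom(1, spec$n, spec$weights))
      if (all(sizes >= 2L)) break
    }
    labels <- rep(seq_len(spec$K), sizes)
    X <- mu[labels, , drop = FALSE] +
      matrix(stats::rnorm(spec$n * spec$d), spec$n, spec$d)
    n_out <- floor(spec$outlier_frac * spec$n)
    if (n_out > 0) {
      idx <- sample(spec$n, n_out)
      lo <- apply(X, 2, min)
      hi <- apply(X, 2, max)
      mid <- (lo + hi) / 2
      half <- pmax(hi - lo, 1) * 0.75      # 1.5x the bounding box
      for (j in seq_len(spec$d)) {
        X[idx, j] <- stats::runif(n_out, mid[j] - half[j], mid[j] + half[j])
      }
      labels[idx] <- max.col(-cross_dist2(X[idx, , drop = FALSE], mu),
                             ties.method = "first")
    }
    perm <- sample(spec$n)                 # shuffle away the sorted order
    dataset(X[perm, , drop = FALSE], labels = labels[perm],
            name = sprintf("mixture_n%d_d%d_K%d", spec$n, spec$d, spec$K))
  })
}

#' Synthesize a dataset matching a named benchmark profile
#'
#' Draws a Gaussian mixture whose sample size, dimensionality, and class
#' count equal the named row of [dataset_profiles()].
#'
#' @param name one of the seven profile names (see [dataset_profiles()]).
#' @param separation nearest-mean distance in within-SD units.
#' @param seed integer seed.
#' @param outlier_frac passed to [mixture_spec()].
#' @return a labelled `km_dataset` with the profile's `n`, `d`, and
#'   `n_classes`.
#' @export
emulate_profile <- function(name, separation = 3, seed = 1L,
                            outlier_frac = 0) {
  prof <- dataset_profiles()
  row <- prof[prof$name == name, ]
  if (nrow(row) != 1L) {
    stop("unknown profile '", name, "'; available: ",
         paste(prof$name, collapse = ", "))
  }
  ds <- make_mixture(mixture_spec(
    n = row$n, d = row$d, K = row$n_classes, separation = separation,
    outlier_frac = outlier_frac, seed = seed
  ))
  ds$name <- paste0(name, "_synthetic")
  ds
}
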