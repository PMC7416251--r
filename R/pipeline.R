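# Two-phase benchmarking pipeline: phase I compares four ordinary
# clusterers on internal indices; phase II compares ordinary K-means
# with the three hybrid initializations on all eleven indices plus the
# number of Lloyd sweeps needed to converge.

#' Phase I: compare the four ordinary clusterers
#'
#' Runs K-means (best of restarts), agglomerative hierarchical, DBSCAN
#' (auto parameters), and the EM Gaussian mixture at a common `k`, and
#' scores each by mean silhouette and RPT. For DBSCAN both indices are
#' computed on non-noise points only and its bootstrap re-clusterings
#' reuse the selected radius.
#'
#' @param ds a `km_dataset` (standardized recommended).
#' @param k number of clusters for K-means, hierarchical and EM.
#' @param restarts K-means and EM restarts.
#' @param rpt_B bootstrap resamples for RPT.
#' @param seed integer seed.
#' @return a data frame with one row per method and columns `method`,
#'   `silhouette`, `rpt`, `best_silhouette`, `best_rpt`; DBSCAN's chosen
#'   `eps`/`min_pts` and noise count are kept in
#'   `attr(, "provenance")`.
#' @export
run_phase1 <- function(ds, k, restarts = 25L, rpt_B = 50L, seed = 1L) {
  stopifnot(inherits(ds, "km_dataset"))
  X <- ds$X
  km <- best_of_restarts(X, k, restarts = restarts, seed = seed)
  hc <- agglomerative(X, k)
  db <- dbscan(X, eps = "auto", min_pts = 4L)
  em <- em_gmm(X, k, restarts = restarts, seed = seed)
  score <- function(Xs, labels, recluster) {
    c(silhouette = silhouette_mean(Xs, labels),
      rpt = rpt(Xs, labels, B = rpt_B, seed = seed, recluster = recluster))
  }
  rows <- list(
    kmeans = score(X, km$labels, function(Xb, K) {
      run_kmeans(Xb, random_init(Xb, K, seed = sample.int(2^31 - 1, 1)))$labels
    }),
    hierarchical = score(X, hc$partition$labels, function(Xb, K) {
      agglomerative(Xb, K)$partition$labels
    }),
    dbscan = local({
      keep <- db$partition$labels >= 1L
      if (db$partition$K < 2L || sum(keep) < 4L) {
        c(silhouette = NA_real_, rpt = NA_real_)
      } else {
        score(X[keep, , drop = FALSE], db$partition$labels[keep],
              function(Xb, K) {
                dbscan(Xb, eps = db$params$eps,
                       min_pts = db$params$min_pts)$partition$labels + 1L
              })
      }
    }),
    em = score(X, em$partition$labels, function(Xb, K) {
      em_gmm(Xb, K, restarts = 1L,
             seed = sample.int(2^31 - 1, 1))$partition$labels
    })
  )
  out <- data.frame(
    method = names(rows),
    silhouette = vapply(rows, `[[`, numeric(1), "silhouette"),
    rpt = vapply(rows, `[[`, numeric(1), "rpt"),
    row.names = NULL
  )
  out$best_silhouette <- !is.na(out$silhouette) &
    out$silhouette == max(out$silhouette, na.rm = TRUE)
  out$best_rpt <- !is.na(out$rpt) & out$rpt == max(out$rpt, na.rm = TRUE)
  attr(out, "provenance") <- list(
    k = k, restarts = restarts, rpt_B = rpt_B, seed = seed,
    dbscan = db$params
  )
  out
}

#' Phase II: ordinary versus hybrid K-means
#'
#' Runs four K-means variants at the same `k` — random restarts
#' (`K_Means`), hierarchical initialization (`K+H`), MST initialization
#' (`K+MST`), and GA initialization (`K+GA`) — and reports the full
#' eleven-index validity row for each, external indices only when the
#' dataset has ground-truth labels. Each variant's RPT bootstrap
#' re-clusters with its own initialization strategy.
#'
#' @param ds a `km_dataset`.
#' @param k number of clusters.
#' @param cfg [ga_config()] for the GA rows.
#' @param restarts restarts for the ordinary K-means row.
#' @param rpt_B bootstrap resamples for RPT.
#' @param seed integer seed.
#' @return a data frame with rows `K_Means`, `K+H`, `K+MST`, `K+GA` and
#'   the columns `I, SSE, Si, RPT, Dunn, RI, ARI, AC, F, HI, VI`; the
#'   fitted partitions are kept in `attr(, "partitions")`.
#' @export
run_phase2 <- function(ds, k, cfg = ga_config(), restarts = 25L,
                       rpt_B = 20L, seed = 1L) {
  stopifnot(inherits(ds, "km_dataset"))
  X <- ds$X
  ga_cfg <- function(s) {
    ga_config(pop_size = cfg$pop_size, generations = cfg$generations,
              crossover_rate = cfg$crossover_rate,
              mutation_rate = cfg$mutation_rate, elitism = cfg$elitism,
              seed = s)
  }
  fits <- list(
    "K_Means" = best_of_restarts(X, k, restarts = restarts, seed = seed),
    "K+H" = run_kmeans(X, hier_init(X, k)),
    "K+MST" = run_kmeans(X, mst_init(X, k)),
    "K+GA" = run_kmeans(X, ga_init(X, k, ga_cfg(cfg$seed)))
  )
  recluster <- list(
    "K_Means" = function(Xb, K) {
      run_kmeans(Xb, random_init(Xb, K, seed = sample.int(2^31 - 1, 1)))$labels
    },
    "K+H" = function(Xb, K) run_kmeans(Xb, hier_init(Xb, K))$labels,
    "K+MST" = function(Xb, K) run_kmeans(Xb, mst_init(Xb, K))$labels,
    "K+GA" = function(Xb, K) {
      run_kmeans(Xb, ga_init(Xb, K, ga_cfg(sample.int(2^31 - 1, 1))))$labels
    }
  )
  tab <- do.call(rbind, lapply(names(fits), function(m) {
    validity_report(X, fits[[m]], truth = ds$labels, rpt_B = rpt_B,
                    seed = seed, recluster = recluster[[m]])
  }))
  tab <- cbind(method = names(fits), tab)
  rownames(tab) <- NULL
  attr(tab, "partitions") <- fits
  attr(tab, "provenance") <- list(k = k, restarts = restarts,
                                  rpt_B = rpt_B, seed = seed,
                                  ga = unclass(cfg))
  tab
}

#' Run a full benchmarking study
#'
#' For each configured dataset: load or synthesize it, standardize,
#' select `k` by the silhouette/gap/elbow majority rule (unless
#' overridden), run both phases, and optionally write one JSON and one
#' TSV report per dataset. Fully reproducible from the configuration.
#'
#' @param config a list with element `datasets`, itself a list of
#'   entries; each entry has `source` (`"iris"`, `"wine"`, `"profile"`,
#'   or `"csv"`), and per source: `name` (profile name), `path` and
#'   `label_column` (csv), optional `k` override, optional `separation`
#'   and `seed` (profile). Optional top-level elements: `ga`
#'   ([ga_config()]), `restarts`, `rpt_B`, `gap_B`, `seed`, `out_dir`.
#' @return a named list of study reports, each with elements `dataset`,
#'   `k_used`, `k_selection`, `phase1`, `phase2`, `convergence`,
#'   `provenance`.
#' @export
run_study <- function(config) {
  stopifnot(is.list(config), is.list(config$datasets))
  seed <- config$seed %||% 1L
  restarts <- config$restarts %||% 25L
  rpt_B <- config$rpt_B %||% 20L
  gap_B <- config$gap_B %||% 20L
  cfg <- config$ga %||% ga_config(seed = seed)
  out_dir <- config$out_dir
  reports <- list()
  for (entry in config$datasets) {
    ds <- switch(entry$source %||% "profile",
      iris = bundled_iris(),
      wine = bundled_wine(),
      profile = emulate_profile(entry$name,
                                separation = entry$separation %||% 3,
                                seed = entry$seed %||% seed),
      csv = load_table(entry$path, label_column = entry$label_column),
      stop("unknown dataset source: ", entry$source)
    )
    ds <- standardize(ds)
    sel <- NULL
    k <- entry$k
    if (is.null(k)) {
      sel <- select_k(ds$X, gap_B = gap_B, seed = seed)
      k <- sel$k_final
    }
    p1 <- run_phase1(ds, k, restarts = restarts, rpt_B = max(rpt_B, 10L),
                     seed = seed)
    p2 <- run_phase2(ds, k, cfg = cfg, restarts = restarts,
                     rpt_B = max(rpt_B, 10L), seed = seed)
    rep <- list(
      dataset = ds$name,
      k_used = k,
      k_selection = if (is.null(sel)) NULL else
        sel[c("k_elbow", "k_gap", "k_silhouette", "k_final", "tie")],
      phase1 = p1,
      phase2 = p2,
      convergence = stats::setNames(p2$I, p2$method),
      provenance = list(seed = seed, restarts = restarts, rpt_B = rpt_B,
                        gap_B = gap_B, ga = unclass(cfg),
                        version = as.character(utils::packageVersion("kminit")))
    )
    reports[[ds$name]] <- rep
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_report_json(rep, file.path(out_dir, paste0(ds$name, ".json")))
      write_report_tsv(p2, file.path(out_dir, paste0(ds$name, ".tsv")))
    }
  }
  reports
}

#' Write a phase-II table as TSV
#'
#' Columns in the canonical report order:
#' `method, I, SSE, Si, RPT, Dunn, RI, ARI, AC, F, HI, VI`.
#'
#' @param tab a phase-II table from [run_phase2()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(tab, path) {
  cols <- c("method", "I", "SSE", "Si", "RPT", "Dunn",
            "RI", "ARI", "AC", "F", "HI", "VI")
  utils::write.table(tab[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a study report as JSON
#'
#' @param report one element of the [run_study()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  report$phase2 <- report$phase2          # drop heavy attributes
  attr(report$phase2, "partitions") <- NULL
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
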