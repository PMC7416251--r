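#' Construct a clustering dataset
#'
#' A `km_dataset` bundles a numeric feature matrix `X` (observations in
#' rows) with optional ground-truth class labels and a standardization
#' flag. Labels are only ever consumed by external validity indices,
#' never by the clustering algorithms themselves.
#'
#' @param X numeric matrix or data frame, one row per observation.
#' @param labels optional class label vector of length `nrow(X)`;
#'   recoded to consecutive integers starting at 1.
#' @param name dataset name used in reports.
#' @param standardized logical; `TRUE` if columns are already z-scored.
#' @param dropped number of rows removed during loading (missing data).
#' @return an object of class `km_dataset` with elements `name`, `X`,
#'   `labels`, `standardized`, `dropped`.
#' @export
dataset <- function(X, labels = NULL, name = "dataset",
                    standardized = FALSE, dropped = 0L) {
  X <- as_feature_matrix(X)
  if (nrow(X) < 2L) stop("dataset needs at least 2 complete rows")
  if (ncol(X) < 1L) stop("dataset needs at least 1 feature")
  if (!is.null(labels)) {
    if (length(labels) != nrow(X)) stop("labels length must equal nrow(X)")
    labels <- as.integer(factor(labels))
  }
  structure(
    list(name = as.character(name), X = X, labels = labels,
         standardized = isTRUE(standardized), dropped = as.integer(dropped)),
    class = "km_dataset"
  )
}

#' @export
print.km_dataset <- function(x, ...) {
  cat(sprintf(
    "<km_dataset '%s': n = %d, d = %d, %s, %s>\n",
    x$name, nrow(x$X), ncol(x$X),
    if (is.null(x$labels)) "unlabelled"
    else sprintf("%d classes", length(unique(x$labels))),
    if (x$standardized) "standardized" else "raw"
  ))
  invisible(x)
}

#' Load a delimited feature table
#'
#' Reads a CSV or TSV file (delimiter auto-detected from the header
#' line), optionally splits off a label column, drops rows with missing
#' values (counted in `$dropped`), and returns a raw (unstandardized)
#' [dataset()].
#'
#' @param path path to a delimited text file with a header row.
#' @param label_column optional name of the class-label column.
#' @param name dataset name; defaults to the file name without extension.
#' @return a `km_dataset`.
#' @export
load_table <- function(path, label_column = NULL, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(label_column)) {
    if (!label_column %in% names(df)) {
      stop("label column not found: ", label_column)
    }
    labels <- df[[label_column]]
    df <- df[setdiff(names(df), label_column)]
  } else {
    labels <- NULL
  }
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[j]]))) &
                     !is.na(df[[j]]))[1]
      if (!is.na(bad)) {
        stop(sprintf("non-numeric value in column '%s', row %d",
                     names(df)[j], bad))
      }
      df[[j]] <- as.numeric(df[[j]])
    }
  }
  keep <- stats::complete.cases(df)
  dropped <- sum(!keep)
  if (dropped > 0) {
    message(sprintf("load_table: dropped %d row(s) with missing values",
                    dropped))
    df <- df[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  if (nrow(df) < 2L) stop("fewer than 2 complete rows in ", path)
  dataset(as.matrix(df), labels = labels,
          name = name %||% sub("\\.[^.]*$", "", basename(path)),
          dropped = dropped)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a dataset back to CSV
#'
#' Inverse of [load_table()]: features plus a `class` column when labels
#' are present, in the dialect the loader reads back exactly.
#'
#' @param ds a `km_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "km_dataset"))
  df <- as.data.frame(ds$X)
  if (is.null(colnames(ds$X))) {
    names(df) <- paste0("V", seq_len(ncol(ds$X)))
  }
  if (!is.null(ds$labels)) df$class <- ds$labels
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Z-score the feature columns of a dataset
#'
#' Centers each column to mean zero and scales to unit sample standard
#' deviation (n - 1 denominator). Labels are untouched. Applying it to an
#' already standardized dataset is a no-op up to rounding.
#'
#' @param ds a `km_dataset`.
#' @return the standardized `km_dataset`.
#' @export
standardize <- function(ds) {
  stopifnot(inherits(ds, "km_dataset"))
  sds <- apply(ds$X, 2, stats::sd)
  if (any(sds == 0)) {
    nm <- colnames(ds$X) %||% paste0("V", seq_len(ncol(ds$X)))
    stop("zero-variance column(s): ", paste(nm[sds == 0], collapse = ", "))
  }
  X <- scale(ds$X)                       # scale() uses the n-1 denominator
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  out <- ds
  out$X <- X
  out$standardized <- TRUE
  out
}

#' Profiles of the seven benchmark datasets
#'
#' Shape descriptors (sample size, feature count, number of classes, and
#' the optimal cluster count found by the silhouette/gap/elbow majority
#' rule) for the seven benchmark datasets used throughout the package:
#' three reduced gene-expression sets (leukemia, prostate, colon) and
#' four UCI machine-learning sets (haberman, iris, wine, glass).
#'
#' @return a data frame with columns `name`, `n`, `d`, `n_classes`,
#'   `k_optimal`, one row per profile.
#' @export
dataset_profiles <- function() {
  data.frame(
    name = c("leukemia", "prostate", "colon", "haberman",
             "iris", "wine", "glass"),
    n = c(64L, 30L, 111L, 306L, 150L, 178L, 214L),
    d = c(4L, 3L, 4L, 3L, 4L, 13L, 10L),
    n_classes = c(2L, 2L, 2L, 2L, 3L, 3L, 7L),
    k_optimal = c(2L, 2L, 2L, 2L, 3L, 3L, 7L),
    stringsAsFactors = FALSE
  )
}

#' Bundled real datasets
#'
#' `bundled_iris()` wraps R's built-in iris measurements;
#' `bundled_wine()` reads the UCI wine recognition data shipped with the
#' package (178 wines, 13 chemical attributes, 3 cultivars).
#'
#' @return a raw (unstandardized) `km_dataset` with class labels.
#' @export
bundled_iris <- function() {
  dataset(as.matrix(datasets::iris[, 1:4]), labels = datasets::iris$Species,
          name = "iris")
}

#' @rdname bundled_iris
#' @export
bundled_wine <- function() {
  path <- system.file("extdata", "wine.csv", package = "kminit",
                      mustWork = TRUE)
  load_table(path, label_column = "class", name = "wine")
}
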