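#' Construct and validate a feature-selection dataset
#'
#' Bundles a numeric feature matrix (`L` samples by `D` features) with one
#' integer class label per sample. Labels are remapped internally to the
#' contiguous integers `0..C-1`; the original label values are retained in
#' `label_levels` for reporting. This canonical form is what stratified
#' folding and error counting operate on.
#'
#' @param features numeric matrix, samples in rows, features in columns.
#'   No missing values are allowed.
#' @param labels vector of class labels, one per row of `features`. Any
#'   atomic type; distinct values define the classes.
#' @param feature_names optional character vector of `D` feature identifiers;
#'   defaults to existing column names, else `f1..fD`.
#' @param name dataset identifier used in reporting.
#'
#' @return An object of class `fs_dataset`: a list with elements `features`
#'   (matrix with `feature_names` as column names), `labels` (integer vector
#'   in `0..C-1`), `label_levels` (original values, indexed by code + 1),
#'   `feature_names`, `name`, and the sizes `L`, `D`, `C`.
#'
#' @details Validation enforces: no missing/non-finite entries, at least 2
#'   samples, at least 1 feature, at least 2 classes, and at least 2 samples
#'   per class (required for stratified cross-validation folds).
#'
#' @examples
#' x <- matrix(rnorm(12), nrow = 4)
#' fs_dataset(x, c("a", "a", "b", "b"))
#' @export
fs_dataset <- function(features, labels, feature_names = NULL, name = "dataset") {
  if (!is.matrix(features)) features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (nrow(features) != length(labels)) {
    stop("shape mismatch: ", nrow(features), " rows in `features` but ",
         length(labels), " labels", call. = FALSE)
  }
  if (anyNA(features) || !all(is.finite(features))) {
    stop("missing values: `features` contains NA/NaN/Inf entries", call. = FALSE)
  }
  if (anyNA(labels)) stop("missing values in `labels`", call. = FALSE)

  if (is.null(feature_names)) feature_names <- colnames(features)
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(features)))
  if (length(feature_names) != ncol(features)) {
    stop("`feature_names` must have one entry per feature column", call. = FALSE)
  }
  colnames(features) <- feature_names

  levels <- sort(unique(labels))
  coded <- match(labels, levels) - 1L

  ds <- structure(
    list(
      features = features,
      labels = coded,
      label_levels = levels,
      feature_names = feature_names,
      name = name,
      L = nrow(features),
      D = ncol(features),
      C = length(levels)
    ),
    class = "fs_dataset"
  )
  validate_dataset(ds)
}

#' Validate an `fs_dataset`
#'
#' Checks the structural invariants of a dataset and returns it unchanged if
#' they all hold; otherwise signals an informative error. Called by
#' [fs_dataset()]; exported so externally assembled objects can be checked.
#'
#' @param dataset an `fs_dataset`.
#' @return `dataset`, invisibly unchanged, if valid.
#' @export
validate_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "fs_dataset"))
  f <- dataset$features
  y <- dataset$labels
  if (nrow(f) != length(y)) {
    stop("shape mismatch: ", nrow(f), " rows but ", length(y), " labels",
         call. = FALSE)
  }
  if (anyNA(f) || !all(is.finite(f))) {
    stop("missing values: `features` contains NA/NaN/Inf entries", call. = FALSE)
  }
  if (nrow(f) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (ncol(f) < 1L) stop("need at least 1 feature", call. = FALSE)
  counts <- table(y)
  if (length(counts) < 2L) stop("need at least 2 classes", call. = FALSE)
  small <- counts[counts < 2L]
  if (length(small) > 0L) {
    lev <- dataset$label_levels[as.integer(names(small)[1L]) + 1L]
    stop("class ", lev, " has fewer than 2 samples", call. = FALSE)
  }
  dataset
}

#' @export
print.fs_dataset <- function(x, ...) {
  cat(sprintf("<fs_dataset '%s'> %d samples x %d features, %d classes\n",
              x$name, x$L, x$D, x$C))
  cat("class sizes:",
      paste(sprintf("%s=%d", x$label_levels, tabulate(x$labels + 1L, x$C)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Construct a feature mask
#'
#' A binary selection vector over the `D` features: bit `j` is 1 when feature
#' `j` is part of the candidate subset.
#'
#' @param bits vector coercible to 0/1 integers.
#' @return Object of class `feature_mask`: integer 0/1 vector with attribute
#'   `size` (number of selected features).
#' @export
feature_mask <- function(bits) {
  bits <- as.integer(bits)
  if (anyNA(bits) || !all(bits %in% c(0L, 1L))) {
    stop("`bits` must be a 0/1 vector", call. = FALSE)
  }
  structure(bits, size = sum(bits), class = "feature_mask")
}

#' @export
print.feature_mask <- function(x, ...) {
  cat(sprintf("<feature_mask> %d of %d features selected\n",
              attr(x, "size"), length(x)))
  invisible(x)
}

#' Number of selected features in a mask
#' @param mask a `feature_mask` or plain 0/1 vector.
#' @return integer count of ones.
#' @export
mask_size <- function(mask) sum(as.integer(mask))

#' Optimizer configuration
#'
#' Collects every tunable of a GWO/AMGWO feature-selection run. Defaults
#' match the standard protocol: population 30, 100 iterations, KNN with
#' K = 5 scored by 10-fold stratified cross-validation.
#'
#' @param n population size (number of wolves), at least 4: three leaders
#'   plus at least one follower.
#' @param T maximum number of iterations (at least 1).
#' @param seed master RNG seed for the run; all randomness (initialization,
#'   coefficient draws, binarization, mutation, fold assignment) derives
#'   from it.
#' @param use_apc enable the nonlinear convergence-factor schedule.
#' @param use_afdb enable fitness-distance-balance reference selection.
#' @param use_adv enable adaptive neighborhood mutation of the guides.
#'   All three `TRUE` is AMGWO; all three `FALSE` is the baseline GWO.
#' @param knn_k number of nearest neighbours in the wrapper classifier.
#' @param folds number of stratified cross-validation folds (reduced to `L`
#'   when a dataset has fewer samples than folds).
#' @param scale_features z-score features inside each fold, with mean and SD
#'   fitted on the training folds only. Off by default: the benchmark
#'   datasets this protocol targets arrive pre-processed.
#' @param scalar_mutation_noise draw one standard-normal noise value per
#'   guide instead of one per dimension (sensitivity-check mode).
#' @return list of class `optimizer_config`.
#' @export
optimizer_config <- function(n = 30L, T = 100L, seed = 1L,
                             use_apc = TRUE, use_afdb = TRUE, use_adv = TRUE,
                             knn_k = 5L, folds = 10L,
                             scale_features = FALSE,
                             scalar_mutation_noise = FALSE) {
  n <- as.integer(n); T <- as.integer(T)
  knn_k <- as.integer(knn_k); folds <- as.integer(folds)
  if (n < 4L) stop("population size `n` must be at least 4", call. = FALSE)
  if (T < 1L) stop("`T` must be at least 1", call. = FALSE)
  if (folds < 2L) stop("`folds` must be at least 2", call. = FALSE)
  if (knn_k < 1L) stop("`knn_k` must be at least 1", call. = FALSE)
  structure(
    list(n = n, T = T, seed = as.integer(seed),
         use_apc = isTRUE(use_apc), use_afdb = isTRUE(use_afdb),
         use_adv = isTRUE(use_adv),
         knn_k = knn_k, folds = folds,
         scale_features = isTRUE(scale_features),
         scalar_mutation_noise = isTRUE(scalar_mutation_noise)),
    class = "optimizer_config"
  )
}

#' Write a dataset to CSV
#'
#' One row per sample: the feature columns (named by `feature_names`)
#' followed by a final `label` column carrying the original label values.
#'
#' @param dataset an `fs_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "fs_dataset"))
  df <- as.data.frame(dataset$features)
  names(df) <- dataset$feature_names
  df$label <- dataset$label_levels[dataset$labels + 1L]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a dataset from CSV
#'
#' Expects the layout written by [write_dataset_csv()]: a header row of
#' feature names, one row per sample, and a final `label` column.
#'
#' @param path CSV file path.
#' @param name dataset identifier; defaults to the file name without
#'   extension.
#' @return a validated `fs_dataset`.
#' @export
read_dataset_csv <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.csv(path, check.names = FALSE)
  if (!("label" %in% names(df))) {
    stop("CSV is missing the required `label` column: ", path, call. = FALSE)
  }
  labels <- df$label
  df$label <- NULL
  fs_dataset(as.matrix(df), labels, feature_names = names(df), name = name)
}

# Pure integer seed derivation (Lehmer-style hash mod 2^31 - 1). Keeps every
# derived seed strictly below 2^31 and makes per-run seeds a function of the
# run coordinates only, independent of global RNG state.
derive_seed <- function(master, ...) {
  parts <- c(as.double(master), vapply(list(...), as.double, numeric(1)))
  h <- 0
  m <- 2147483647
  for (v in parts) {
    h <- (h * 48271 + (abs(v) %% m) * 16807 + 12345) %% m
  }
  as.integer(h %% (m - 2)) + 1L
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library calls do not perturb user scripts.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
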