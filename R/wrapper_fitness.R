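#' Sigmoid transfer function
#'
#' Maps a continuous position coordinate to a feature-selection probability:
#' `sigma(a) = 1 / (1 + exp(-10 * (a - 0.5)))`. The steepness 10 and center
#' 0.5 are fixed by the protocol; the function is strictly increasing and
#' its output lies strictly in (0, 1) for finite input.
#'
#' @param alpha numeric vector of position coordinates (finite).
#' @return selection probabilities, same length as `alpha`.
#' @examples
#' sigmoid_transfer(0.5)  # 0.5
#' sigmoid_transfer(1.0)  # 1 / (1 + exp(-5))
#' @export
sigmoid_transfer <- function(alpha) {
  if (anyNA(alpha) || !all(is.finite(alpha))) {
    stop("`alpha` must be finite", call. = FALSE)
  }
  1 / (1 + exp(-10 * (alpha - 0.5)))
}

#' Binarize a continuous position into a feature mask
#'
#' Each bit is set to 1 when `sigmoid_transfer(position[j]) > r_j`, with
#' `r_j` drawn fresh from U(0, 1) per dimension — i.e. bit `j` is
#' Bernoulli with success probability `sigma(position[j])`. An all-zero
#' mask is repaired by setting one uniformly random bit to 1, since the
#' wrapper classifier needs at least one feature column.
#'
#' Consumes the current RNG stream; seed externally for reproducibility.
#'
#' @param position numeric vector in `[0, 1]^D` (any finite values accepted).
#' @param repair repair an empty mask to a random singleton (default TRUE).
#'   Set FALSE to observe the raw transfer output.
#' @return a [feature_mask].
#' @export
binarize <- function(position, repair = TRUE) {
  p <- sigmoid_transfer(position)
  bits <- as.integer(p > stats::runif(length(p)))
  if (repair && sum(bits) == 0L) {
    bits[sample.int(length(bits), 1L)] <- 1L
  }
  feature_mask(bits)
}

#' Stratified cross-validation fold assignment
#'
#' Partitions samples into `k` folds preserving class proportions: within
#' each class the samples are shuffled and dealt round-robin, with the
#' starting fold rotated across classes to balance fold sizes. If the
#' dataset has fewer samples than `k`, `k` is reduced to `L`
#' (leave-one-out).
#'
#' @param labels integer class codes (`0..C-1`).
#' @param k requested number of folds.
#' @param seed RNG seed for the shuffle; fixed per optimization run so all
#'   candidate masks within a run are scored on identical partitions.
#' @return integer vector of fold ids in `1..k`, one per sample.
#' @export
stratified_folds <- function(labels, k, seed) {
  L <- length(labels)
  k <- min(as.integer(k), L)
  if (k < 2L) stop("need at least 2 folds (and at least 2 samples)", call. = FALSE)
  with_seed(seed, {
    fold_id <- integer(L)
    offset <- 0L
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- if (length(idx) > 1L) sample(idx) else idx
      fold_id[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- offset + length(idx)
    }
    fold_id
  })
}

# Deterministic KNN cross-validation on a precomputed squared-distance
# matrix. Tie policy: neighbour-distance ties are broken by lowest class
# code then lowest sample index; vote ties by lowest class code.
# Returns the per-fold error rates.
knn_cv_from_sqdist <- function(sqd, labels, fold_id, k) {
  nfold <- max(fold_id)
  errs <- numeric(nfold)
  idx_all <- seq_along(labels)
  for (f in seq_len(nfold)) {
    te <- idx_all[fold_id == f]
    tr <- idx_all[fold_id != f]
    trl <- labels[tr]
    kk <- min(k, length(tr))
    sub <- sqd[te, tr, drop = FALSE]
    wrong <- 0L
    for (i in seq_along(te)) {
      o <- order(sub[i, ], trl, tr)[seq_len(kk)]
      votes <- tabulate(trl[o] + 1L)
      pred <- which.max(votes) - 1L
      if (pred != labels[te[i]]) wrong <- wrong + 1L
    }
    errs[f] <- wrong / length(te)
  }
  errs
}

# Pairwise squared Euclidean distances between rows of x.
row_sqdist <- function(x) {
  rn <- rowSums(x * x)
  d <- outer(rn, rn, "+") - 2 * tcrossprod(x)
  d[d < 0] <- 0  # clamp negative rounding residue
  diag(d) <- 0
  d
}

#' KNN cross-validated error of a feature mask
#'
#' The wrapper fitness: restricts the dataset to the selected feature
#' columns, builds stratified `folds`-fold partitions, and for each fold
#' classifies the held-out samples with a K-nearest-neighbour vote
#' (Euclidean distance) trained on the remaining folds. The fitness is the
#' mean of the per-fold error rates (misclassified / total in the fold),
#' so it always lies in `[0, 1]` and equals 0 exactly when every fold
#' classifies perfectly.
#'
#' Deterministic given (`dataset`, `mask`, `fold_seed`): ties in neighbour
#' distance or votes are broken toward the lowest class code.
#'
#' @param dataset an [fs_dataset].
#' @param mask a [feature_mask] or 0/1 vector of length `D` with at least
#'   one feature selected.
#' @param folds number of cross-validation folds (default 10; reduced to
#'   `L` when the dataset is smaller).
#' @param knn_k number of neighbours (default 5).
#' @param fold_seed seed for the fold shuffle.
#' @param scale_features z-score each selected column using mean/SD fitted
#'   on the training folds only.
#' @return list of class `fitness_result` with `fold_errors` (per-fold
#'   error rates) and `fitness` (their mean).
#' @examples
#' fx <- make_worked_fixture()
#' cv_error(fx$dataset, fx$ideal_mask)$fitness  # 0
#' @export
cv_error <- function(dataset, mask, folds = 10L, knn_k = 5L, fold_seed = 1L,
                     scale_features = FALSE) {
  stopifnot(inherits(dataset, "fs_dataset"))
  bits <- as.integer(mask)
  if (length(bits) != dataset$D) {
    stop("`mask` length must equal the number of features", call. = FALSE)
  }
  if (sum(bits) < 1L) stop("`mask` selects no features", call. = FALSE)
  fold_id <- stratified_folds(dataset$labels, folds, fold_seed)
  x <- dataset$features[, bits == 1L, drop = FALSE]
  if (scale_features) {
    errs <- knn_cv_scaled(x, dataset$labels, fold_id, knn_k)
  } else {
    errs <- knn_cv_from_sqdist(row_sqdist(x), dataset$labels, fold_id, knn_k)
  }
  structure(list(fold_errors = errs, fitness = mean(errs)),
            class = "fitness_result")
}

# Per-fold z-scored variant: scaling parameters are fitted on the training
# folds only, then applied to the held-out fold.
knn_cv_scaled <- function(x, labels, fold_id, k) {
  nfold <- max(fold_id)
  errs <- numeric(nfold)
  for (f in seq_len(nfold)) {
    tr <- fold_id != f
    mu <- colMeans(x[tr, , drop = FALSE])
    sdv <- apply(x[tr, , drop = FALSE], 2, stats::sd)
    sdv[sdv == 0 | !is.finite(sdv)] <- 1
    xs <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
    errs[f] <- knn_cv_from_sqdist(row_sqdist(xs), labels,
                                  ifelse(fold_id == f, 1L, 2L), k)[1L]
  }
  errs
}

# Fitness evaluator factory for the optimizer loop. Precomputes, when
# memory allows, the per-feature squared-difference matrix G (L*L rows by D
# columns) so that the masked squared-distance matrix for any mask is a
# single matrix-vector product G %*% bits; otherwise distances are computed
# per mask. Fold partitions are fixed once for the whole run.
make_evaluator <- function(dataset, fold_id, knn_k, scale_features = FALSE,
                           max_gram_bytes = 2.5e8) {
  x <- dataset$features
  labels <- dataset$labels
  L <- nrow(x)
  if (scale_features) {
    return(function(bits) {
      mean(knn_cv_scaled(x[, bits == 1L, drop = FALSE], labels, fold_id, knn_k))
    })
  }
  if (L * L * ncol(x) * 8 <= max_gram_bytes) {
    g <- matrix(0, L * L, ncol(x))
    for (j in seq_len(ncol(x))) {
      d <- outer(x[, j], x[, j], "-")
      g[, j] <- as.vector(d * d)
    }
    function(bits) {
      sqd <- matrix(g %*% bits, L, L)
      mean(knn_cv_from_sqdist(sqd, labels, fold_id, knn_k))
    }
  } else {
    function(bits) {
      sqd <- row_sqdist(x[, bits == 1L, drop = FALSE])
      mean(knn_cv_from_sqdist(sqd, labels, fold_id, knn_k))
    }
  }
}
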