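#' Generate a synthetic high-dimensional, small-sample dataset
#'
#' Emulates the regime of benchmark gene-expression matrices used in wrapper
#' feature-selection studies: many features (hundreds to thousands), few
#' samples (tens to low hundreds), and a small planted subset of
#' class-informative features among pure-noise features.
#'
#' The model is Gaussian class-conditional with equal spherical covariance:
#' every feature has noise standard deviation `noise_sd`; the `n_informative`
#' planted features additionally carry a class-dependent mean of
#' `class_sep * noise_sd * c` for class code `c` (adjacent classes are
#' separated by `class_sep` noise SDs). The remaining features are
#' label-independent noise. Class sizes are as equal as possible.
#'
#' @param n_samples number of samples `L` (each class must receive at
#'   least 2).
#' @param n_features number of features `D`.
#' @param n_informative number of planted class-informative features
#'   (at most `n_features`).
#' @param n_classes number of classes `C` (at least 2).
#' @param class_sep mean shift between adjacent classes on informative
#'   features, in units of `noise_sd`. Must be non-negative; `0` yields a
#'   dataset with no class signal at all (useful as a chance-level control).
#' @param noise_sd standard deviation of the feature noise.
#' @param seed RNG seed; identical seeds yield bit-identical datasets.
#'
#' @return list with elements `dataset` (an [fs_dataset]) and `informative`
#'   (integer indices of the planted features). The ground truth is returned
#'   alongside, not inside, the dataset, so selection algorithms cannot see
#'   it.
#'
#' @examples
#' sim <- make_microarray(n_samples = 60, n_features = 200,
#'                        n_informative = 10, class_sep = 3, seed = 1)
#' sim$dataset
#' sim$informative
#' @export
make_microarray <- function(n_samples = 60L, n_features = 200L,
                            n_informative = 10L, n_classes = 2L,
                            class_sep = 3, noise_sd = 1, seed = 1L) {
  n_samples <- as.integer(n_samples)
  n_features <- as.integer(n_features)
  n_informative <- as.integer(n_informative)
  n_classes <- as.integer(n_classes)
  if (n_informative > n_features) {
    stop("`n_informative` cannot exceed `n_features`", call. = FALSE)
  }
  if (n_informative < 0L) stop("`n_informative` must be non-negative", call. = FALSE)
  if (n_classes < 2L) stop("need at least 2 classes", call. = FALSE)
  if (class_sep < 0) stop("`class_sep` must be non-negative", call. = FALSE)
  if (noise_sd <= 0) stop("`noise_sd` must be positive", call. = FALSE)
  if (n_samples < 2L * n_classes) {
    stop("every class needs at least 2 samples: increase `n_samples`",
         call. = FALSE)
  }

  with_seed(seed, {
    # class sizes as equal as possible, remainder spread over the first classes
    base <- n_samples %/% n_classes
    sizes <- rep(base, n_classes) + c(rep(1L, n_samples %% n_classes),
                                      rep(0L, n_classes - n_samples %% n_classes))
    labels <- rep(seq_len(n_classes) - 1L, times = sizes)

    informative <- sort(sample.int(n_features, n_informative))
    x <- matrix(stats::rnorm(n_samples * n_features, sd = noise_sd),
                nrow = n_samples, ncol = n_features)
    if (n_informative > 0L) {
      shift <- class_sep * noise_sd * labels
      x[, informative] <- x[, informative] + shift
    }

    ds <- fs_dataset(x, labels,
                     name = sprintf("synthetic_L%d_D%d_sep%g_seed%d",
                                    n_samples, n_features, class_sep, seed))
    list(dataset = ds, informative = informative)
  })
}

#' Tiny deterministic worked fixture
#'
#' A fixed 20-sample by 6-feature, 2-class dataset in which feature 1 is a
#' perfect class separator (class means 0 and 1 with noise SD 0.05, so the
#' classes are separated by 20 SDs) and features 2-6 are pure standard-normal
#' noise. The ideal mask selects feature 1 only, and a KNN (K = 5) scored by
#' stratified 10-fold cross-validation classifies the fixture perfectly
#' under that mask.
#'
#' @return list with elements `dataset` (an [fs_dataset]) and `ideal_mask`
#'   (a [feature_mask], `c(1, 0, 0, 0, 0, 0)`).
#' @export
make_worked_fixture <- function() {
  with_seed(20240206L, {
    labels <- rep(c(0L, 1L), each = 10L)
    separator <- labels + stats::rnorm(20, sd = 0.05)
    noise <- matrix(stats::rnorm(20 * 5), nrow = 20, ncol = 5)
    x <- cbind(separator, noise)
    ds <- fs_dataset(x, labels,
                     feature_names = c("separator", paste0("noise", 1:5)),
                     name = "worked_fixture")
    list(dataset = ds, ideal_mask = feature_mask(c(1, 0, 0, 0, 0, 0)))
  })
}

#' Write a synthetic dataset with its ground-truth sidecar
#'
#' Writes the dataset as CSV (see [write_dataset_csv()]) plus a JSON sidecar
#' recording the planted informative feature indices and the generator
#' settings, for audit and blind-recovery experiments.
#'
#' @param sim result of [make_microarray()].
#' @param path CSV output path; the sidecar goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_synthetic_csv <- function(sim, path) {
  write_dataset_csv(sim$dataset, path)
  sidecar <- list(
    name = sim$dataset$name,
    informative = as.integer(sim$informative),
    L = sim$dataset$L, D = sim$dataset$D, C = sim$dataset$C
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
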