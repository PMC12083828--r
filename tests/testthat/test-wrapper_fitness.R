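test_that("sigmoid transfer matches its closed form and is symmetric", {
  expect_equal(sigmoid_transfer(0.5), 0.5)
  expect_equal(sigmoid_transfer(1.0), 1 / (1 + exp(-5)))
  expect_equal(sigmoid_transfer(1.0), 0.993307, tolerance = 1e-6)
  # logistic symmetry about the center
  x <- seq(-2, 2, by = 0.13)
  expect_equal(sigmoid_transfer(0.5 + x) + sigmoid_transfer(0.5 - x),
               rep(1, length(x)))
  # strictly increasing, output strictly inside (0, 1)
  # (range kept inside double-precision resolution of the logistic tails)
  v <- sigmoid_transfer(seq(-2, 3, by = 0.1))
  expect_true(all(diff(v) > 0))
  expect_true(all(v > 0 & v < 1))
  expect_error(sigmoid_transfer(NaN), "finite")
})

test_that("binarization is Bernoulli in the transfer probability", {
  set.seed(1)
  draws <- replicate(10000, as.integer(binarize(0.5, repair = FALSE)))
  expect_lt(abs(mean(draws) - 0.5), 0.02)
  # saturated coordinates are (almost) deterministic
  set.seed(2)
  hi <- replicate(200, as.integer(binarize(c(50, -50), repair = FALSE)))
  expect_true(all(hi[1, ] == 1L))
  expect_true(all(hi[2, ] == 0L))
})

test_that("an empty mask is repaired to exactly one random selected bit", {
  set.seed(3)
  reps <- replicate(200, as.integer(binarize(rep(-50, 5))))
  expect_true(all(colSums(reps) == 1L))
  # the repaired bit is uniform, not pinned to one position
  expect_true(all(rowSums(reps) > 0))
})

test_that("cv_error agrees exactly with the naive KNN oracle on random instances", {
  for (s in 1:50) {
    inst <- random_instance(s)
    set.seed(1000 + s)
    bits <- rbinom(inst$D, 1, 0.6)
    if (sum(bits) == 0) bits[1] <- 1L
    folds <- sample(2:5, 1)
    fold_id <- stratified_folds(inst$labels, folds, seed = s)
    res <- cv_error(fs_dataset(inst$x, inst$labels), bits,
                    folds = folds, knn_k = 5, fold_seed = s)
    orc <- oracle_knn_cv(inst$x[, bits == 1L, drop = FALSE], inst$labels,
                         fold_id, 5)
    expect_identical(res$fold_errors, orc$fold_errors)
  }
})

test_that("fitness is the mean fold error, bounded in [0, 1], and deterministic", {
  sim <- make_microarray(30, 40, 5, 2, class_sep = 1, seed = 5)
  m <- rep(1L, 40)
  r1 <- cv_error(sim$dataset, m, fold_seed = 11)
  r2 <- cv_error(sim$dataset, m, fold_seed = 11)
  expect_identical(r1, r2)
  expect_equal(r1$fitness, mean(r1$fold_errors))
  expect_true(all(r1$fold_errors >= 0 & r1$fold_errors <= 1))
  # different fold seed may differ, same contract
  r3 <- cv_error(sim$dataset, m, fold_seed = 12)
  expect_true(r3$fitness >= 0 && r3$fitness <= 1)
})

test_that("fitness is equivariant under a joint column/mask permutation", {
  sim <- make_microarray(24, 15, 3, 2, class_sep = 1.5, seed = 8)
  ds <- sim$dataset
  set.seed(9)
  bits <- rbinom(15, 1, 0.5); bits[1] <- 1L
  perm <- sample(15)
  ds_perm <- fs_dataset(ds$features[, perm], ds$label_levels[ds$labels + 1L])
  f1 <- cv_error(ds, bits, fold_seed = 2)$fitness
  f2 <- cv_error(ds_perm, bits[perm], fold_seed = 2)$fitness
  expect_identical(f1, f2)
})

test_that("constant features yield the tie-break prediction everywhere", {
  # all pairwise distances are 0, so every prediction is the vote of the
  # k nearest under the deterministic tie order: lowest class wins
  x <- matrix(1, nrow = 12, ncol = 3)
  ds <- fs_dataset(x + 0, rep(c(0, 1), each = 6))
  r <- cv_error(ds, c(1, 1, 1), folds = 4, knn_k = 5, fold_seed = 1)
  # predictions are always class 0 => class-0 samples right, class-1 wrong
  expect_equal(r$fitness, 0.5)
})

test_that("stratified folds preserve class proportions and handle tiny data", {
  labels <- rep(c(0L, 1L, 2L), times = c(12, 6, 6))
  fid <- stratified_folds(labels, 3, seed = 4)
  expect_equal(sort(unique(fid)), 1:3)
  for (f in 1:3) {
    expect_equal(as.vector(table(labels[fid == f])), c(4, 2, 2))
  }
  # fewer samples than folds degrades to leave-one-out
  fid2 <- stratified_folds(c(0L, 0L, 1L, 1L), 10, seed = 1)
  expect_equal(sort(fid2), 1:4)
})

test_that("the precomputed-distance evaluator matches cv_error", {
  sim <- make_microarray(25, 30, 4, 2, class_sep = 1, seed = 13)
  fold_id <- stratified_folds(sim$dataset$labels, 5, seed = 21)
  ev <- wolfselect:::make_evaluator(sim$dataset, fold_id, 5)
  set.seed(14)
  for (i in 1:10) {
    bits <- rbinom(30, 1, 0.5); bits[3] <- 1L
    direct <- cv_error(sim$dataset, bits, folds = 5, knn_k = 5, fold_seed = 21)
    expect_equal(ev(bits), direct$fitness, tolerance = 1e-12)
  }
})

test_that("fold-wise feature scaling fits on training folds only", {
  sim <- make_microarray(24, 10, 3, 2, class_sep = 2, seed = 17)
  r <- cv_error(sim$dataset, rep(1, 10), folds = 4, fold_seed = 3,
                scale_features = TRUE)
  expect_true(all(r$fold_errors >= 0 & r$fold_errors <= 1))
  # scaling a dataset with wildly different column scales recovers the
  # same geometry as the unscaled well-conditioned dataset
  ds <- sim$dataset
  ds_scaled_cols <- fs_dataset(sweep(ds$features, 2, c(1e4, rep(1, 9)), "*"),
                               ds$label_levels[ds$labels + 1L])
  bad <- cv_error(ds_scaled_cols, rep(1, 10), folds = 4, fold_seed = 3)
  fixed <- cv_error(ds_scaled_cols, rep(1, 10), folds = 4, fold_seed = 3,
                    scale_features = TRUE)
  expect_true(fixed$fitness <= bad$fitness + 0.25)
})

test_that("degenerate masks are rejected", {
  sim <- make_microarray(20, 8, 2, 2, seed = 1)
  expect_error(cv_error(sim$dataset, rep(0, 8)), "no features")
  expect_error(cv_error(sim$dataset, rep(1, 5)), "length")
})
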