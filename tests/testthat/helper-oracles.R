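# Independent brute-force oracles. These deliberately share no code with
# the package internals: naive loops, literal formula transcriptions.

# Naive O(L^2) KNN cross-validation: explicit loops over folds, test
# samples, and training samples, with the same tie policy as the package
# contract (neighbour-distance ties by lowest class then lowest index,
# vote ties by lowest class).
oracle_knn_cv <- function(x, labels, fold_id, k) {
  nfold <- max(fold_id)
  errs <- numeric(nfold)
  pred_all <- rep(NA_integer_, length(labels))
  for (f in seq_len(nfold)) {
    te <- which(fold_id == f)
    tr <- which(fold_id != f)
    wrong <- 0L
    for (i in te) {
      d <- numeric(length(tr))
      for (jj in seq_along(tr)) {
        diff <- x[i, ] - x[tr[jj], ]
        d[jj] <- sum(diff^2)
      }
      ord <- order(d, labels[tr], tr)
      kk <- min(k, length(tr))
      neigh <- labels[tr][ord[1:kk]]
      counts <- sapply(sort(unique(labels)), function(cl) sum(neigh == cl))
      pred <- sort(unique(labels))[which.max(counts)]
      pred_all[i] <- pred
      if (pred != labels[i]) wrong <- wrong + 1L
    }
    errs[f] <- wrong / length(te)
  }
  list(fold_errors = errs, fitness = mean(errs), predictions = pred_all)
}

# Literal re-implementation of the FDB scoring: per-candidate loops,
# explicit min-max normalization with best-error -> 1 orientation and the
# zero-range -> 0 rule.
oracle_fdb <- function(positions, fitness, best_position) {
  n <- nrow(positions)
  dp <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(ncol(positions))) s <- s + (positions[i, j] - best_position[j])^2
    dp[i] <- sqrt(s)
  }
  fmin <- min(fitness); fmax <- max(fitness)
  norm_f <- if (fmax > fmin) (fmax - fitness) / (fmax - fmin) else rep(0, n)
  dmin <- min(dp); dmax <- max(dp)
  norm_dp <- if (dmax > dmin) (dp - dmin) / (dmax - dmin) else rep(0, n)
  list(dp = dp, norm_f = norm_f, norm_dp = norm_dp, score = norm_f + norm_dp)
}

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# choose(n_a + n_b, n_a) assignments of ranks to sample A (no ties
# assumed): p = fraction of assignments whose rank-sum is at least as
# extreme as the observed one, on either tail.
oracle_wilcoxon_exact <- function(a, b) {
  n <- length(a) + length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_along(a)])
  combos <- utils::combn(n, length(a))
  w_all <- colSums(matrix(seq_len(n)[combos], nrow = length(a)))
  mu <- length(a) * (n + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Literal transcription of the encircling/hunting equations for one wolf,
# given pre-drawn coefficient vectors.
oracle_guides <- function(alpha, beta, delta, ref, ca, cb, cd) {
  d_a <- abs(ca$C * alpha - ref)
  d_b <- abs(cb$C * beta - ref)
  d_d <- abs(cd$C * delta - ref)
  list(d_alpha = d_a, d_beta = d_b, d_delta = d_d,
       x1 = alpha - ca$A * d_a,
       x2 = beta - cb$A * d_b,
       x3 = delta - cd$A * d_d)
}

# Small random classification instance for oracle comparisons.
random_instance <- function(seed, L_max = 30L, D_max = 10L) {
  set.seed(seed)
  L <- sample(10:L_max, 1)
  D <- sample(2:D_max, 1)
  C <- sample(2:3, 1)
  labels <- c(rep(0:(C - 1), each = 2),
              sample(0:(C - 1), L - 2 * C, replace = TRUE))
  x <- matrix(rnorm(L * D), L, D) + 0.8 * labels
  list(x = x, labels = labels, L = L, D = D, C = C)
}
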