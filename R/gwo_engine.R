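#' Linear convergence factor schedule
#'
#' The baseline GWO decays the convergence factor `a` linearly from 2 at
#' the first iteration to 0 at the last: `a = 2 * (1 - (t - 1) / (T - 1))`
#' for `T > 1`. The degenerate single-iteration run uses `a = 2`.
#'
#' @param t current iteration, 1-based, in `1..T`.
#' @param T maximum number of iterations.
#' @return the convergence factor, in `[0, 2]`.
#' @export
linear_a <- function(t, T) {
  if (any(t < 1L) || any(t > T)) stop("`t` must lie in 1..T", call. = FALSE)
  if (T == 1L) return(rep(2, length(t)))
  2 * (1 - (t - 1) / (T - 1))
}

#' Draw GWO step coefficients
#'
#' Per-dimension coefficient vectors for one leader: `A = 2 a r1 - a` and
#' `C = 2 r2` with `r1, r2 ~ U(0, 1)` drawn independently per dimension.
#' Every component of `A` lies in `[-a, a]` and of `C` in `[0, 2]`.
#' Consumes the current RNG stream.
#'
#' @param a convergence factor, in `[0, 2]`.
#' @param D problem dimension.
#' @return list with `A`, `C`, `r1`, `r2`, each length `D`.
#' @export
draw_coefficients <- function(a, D) {
  r1 <- stats::runif(D)
  r2 <- stats::runif(D)
  list(A = 2 * a * r1 - a, C = 2 * r2, r1 = r1, r2 = r2)
}

#' Compute the three leader-guided candidate positions
#'
#' The encircling/hunting step of GWO: for each leader (alpha, beta, delta)
#' a distance `D_l = |C_l * X_l - ref|` is computed componentwise with
#' independently drawn coefficients, and the guide position is
#' `X_l - A_l * D_l`. In the baseline algorithm `ref` is the moving wolf's
#' own position; the fitness-distance-balance mechanism substitutes the
#' highest-scoring candidate's position on odd iterations (see
#' [select_reference()]).
#'
#' Consumes the current RNG stream (six U(0,1) vectors of length `D`).
#'
#' @param alpha,beta,delta positions of the three best wolves (numeric
#'   vectors of length `D`).
#' @param reference reference position entering the distance terms.
#' @param a convergence factor for this iteration.
#' @return list of class `guide_set`: distance vectors `d_alpha`, `d_beta`,
#'   `d_delta` and guide positions `x1`, `x2`, `x3`.
#' @export
guide_positions <- function(alpha, beta, delta, reference, a) {
  if (is.null(alpha) || is.null(beta) || is.null(delta)) {
    stop("leaders are unset", call. = FALSE)
  }
  D <- length(reference)
  stopifnot(length(alpha) == D, length(beta) == D, length(delta) == D)
  ca <- draw_coefficients(a, D)
  cb <- draw_coefficients(a, D)
  cd <- draw_coefficients(a, D)
  d_alpha <- abs(ca$C * alpha - reference)
  d_beta  <- abs(cb$C * beta  - reference)
  d_delta <- abs(cd$C * delta - reference)
  structure(
    list(d_alpha = d_alpha, d_beta = d_beta, d_delta = d_delta,
         x1 = alpha - ca$A * d_alpha,
         x2 = beta  - cb$A * d_beta,
         x3 = delta - cd$A * d_delta),
    class = "guide_set"
  )
}

#' Combine guide positions into the new wolf position
#'
#' The hunting consensus: the new position is the arithmetic mean of the
#' three guides, `(X1 + X2 + X3) / 3`, then clipped to the unit hypercube
#' `[0, 1]^D` (the operating range of the sigmoid transfer). Clipping
#' happens only here — guides are never clipped individually.
#'
#' @param g a `guide_set` from [guide_positions()].
#' @return numeric vector in `[0, 1]^D`.
#' @export
combine_guides <- function(g) {
  pmin(pmax((g$x1 + g$x2 + g$x3) / 3, 0), 1)
}

# Shared search loop for GWO, AMGWO and the single-mechanism ablations.
# Structure (per iteration, after one evaluation of the initial population):
#   1. convergence factor from the linear or nonlinear schedule
#   2. reference position per wolf (own position, or FDB candidate on odd
#      iterations when the AFDB mechanism is on)
#   3. leader-guided candidate positions, optionally Gaussian-mutated
#      toward the best-so-far (ADV mechanism)
#   4. mean-combine, clip, binarize, evaluate; refresh leaders and
#      best-so-far
# Exactly n fitness evaluations per iteration regardless of toggles.
run_wolf_search <- function(dataset, config) {
  stopifnot(inherits(dataset, "fs_dataset"), inherits(config, "optimizer_config"))
  t_start <- proc.time()[["elapsed"]]
  n <- config$n; T <- config$T; D <- dataset$D

  fold_seed <- derive_seed(config$seed, 1L)
  search_seed <- derive_seed(config$seed, 2L)
  fold_id <- stratified_folds(dataset$labels, config$folds, fold_seed)
  evaluate <- make_evaluator(dataset, fold_id, config$knn_k,
                             config$scale_features)

  with_seed(search_seed, {
    positions <- matrix(stats::runif(n * D), nrow = n, ncol = D)
    masks <- matrix(0L, nrow = n, ncol = D)
    fitness <- numeric(n)
    for (i in seq_len(n)) {
      masks[i, ] <- as.integer(binarize(positions[i, ]))
      fitness[i] <- evaluate(masks[i, ])
    }
    n_evals <- n

    lead <- order(fitness)[1:3]
    best_fit <- fitness[lead[1L]]
    best_pos <- positions[lead[1L], ]
    best_mask <- masks[lead[1L], ]

    trace <- numeric(T)
    for (t in seq_len(T)) {
      a <- if (config$use_apc) nonlinear_a(t, T) else linear_a(t, T)

      x_fdb <- NULL
      if (config$use_afdb && t %% 2L == 1L) {
        sc <- fdb_scores(positions, fitness, best_pos)
        x_fdb <- positions[which.max(sc$score), ]
      }

      alpha <- positions[lead[1L], ]
      beta  <- positions[lead[2L], ]
      delta <- positions[lead[3L], ]

      new_positions <- positions
      for (i in seq_len(n)) {
        ref <- if (config$use_afdb) {
          select_reference(t, positions[i, ], x_fdb)
        } else {
          positions[i, ]
        }
        g <- guide_positions(alpha, beta, delta, ref, a)
        if (config$use_adv) {
          g <- adaptive_mutation(g, best_pos,
                                 scalar_noise = config$scalar_mutation_noise)
        }
        new_positions[i, ] <- combine_guides(g)
      }
      positions <- new_positions

      for (i in seq_len(n)) {
        masks[i, ] <- as.integer(binarize(positions[i, ]))
        fitness[i] <- evaluate(masks[i, ])
      }
      n_evals <- n_evals + n

      lead <- order(fitness)[1:3]
      if (fitness[lead[1L]] < best_fit) {
        best_fit <- fitness[lead[1L]]
        best_pos <- positions[lead[1L], ]
        best_mask <- masks[lead[1L], ]
      }
      trace[t] <- best_fit
    }

    structure(
      list(
        best_mask = feature_mask(best_mask),
        best_fitness = best_fit,
        best_position = best_pos,
        trace = trace,
        subset_size = sum(best_mask),
        n_evals = n_evals,
        fold_seed = fold_seed,
        runtime_s = proc.time()[["elapsed"]] - t_start,
        dataset_name = dataset$name,
        config = config
      ),
      class = "gwo_run"
    )
  })
}

#' Run the baseline grey wolf optimizer
#'
#' Wrapper feature selection with the original GWO dynamics: linear
#' convergence factor, own-position reference, no mutation. Equivalent to
#' [run_amgwo()] with all three mechanism toggles off (and bit-identical to
#' it under the same seed).
#'
#' @param dataset an [fs_dataset].
#' @param config an [optimizer_config]; its mechanism toggles are ignored
#'   (forced off).
#' @return object of class `gwo_run`: `best_mask`, `best_fitness`,
#'   `best_position`, the length-`T` nonincreasing best-so-far `trace`,
#'   `subset_size`, evaluation count `n_evals`, `fold_seed`, `runtime_s`,
#'   and the `config` used.
#' @examples
#' fx <- make_worked_fixture()
#' run_gwo(fx$dataset, optimizer_config(n = 8, T = 5, seed = 1))
#' @export
run_gwo <- function(dataset, config = optimizer_config()) {
  config$use_apc <- FALSE
  config$use_afdb <- FALSE
  config$use_adv <- FALSE
  run_wolf_search(dataset, config)
}

#' @export
print.gwo_run <- function(x, ...) {
  cat(sprintf("<gwo_run on '%s'> best fitness %.4f with %d/%d features (%d evals, %.1fs)\n",
              x$dataset_name, x$best_fitness, x$subset_size,
              length(x$best_mask), x$n_evals, x$runtime_s))
  invisible(x)
}
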