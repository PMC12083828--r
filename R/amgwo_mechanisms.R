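#' Nonlinear convergence factor schedule (adaptive parameter control)
#'
#' Replaces the linear decay of the convergence factor with
#' `a = 2 - 2 * sin((pi / 2) * (t / T)^3)`: near-flat early (sustained
#' exploration) and rapidly decaying late (fast exploitation). The value
#' decreases monotonically from 2 at ratio `t/T = 0` to 0 at `t/T = 1`.
#'
#' The loop uses the 1-based iteration counter directly, so the in-run
#' ratio lies in `(0, 1]`; `t = 0` is accepted as the analytic
#' start-of-search endpoint.
#'
#' @param t current iteration, in `0..T`.
#' @param T maximum number of iterations.
#' @return the convergence factor, in `[0, 2]`.
#' @export
nonlinear_a <- function(t, T) {
  if (any(t < 0L) || any(t > T)) stop("`t` must lie in 0..T", call. = FALSE)
  2 - 2 * sin((pi / 2) * (t / T)^3)
}

#' Fitness-distance-balance scores for a population
#'
#' Scores every candidate by the sum of its normalized solution quality and
#' its normalized Euclidean distance to the current best-so-far position:
#' `S = normF + normDP`. Both terms are min-max normalized over the
#' population; since the objective (cross-validation error) is minimized,
#' `normF` is oriented so the lowest error maps to 1. A zero range (all
#' fitnesses equal, or all distances equal) maps that term to 0 for every
#' candidate. High scores mark good-but-diverse candidates, counteracting
#' premature convergence.
#'
#' @param positions `n x D` matrix of wolf positions.
#' @param fitness numeric vector of `n` evaluated fitnesses (errors).
#' @param best_position position of the best-so-far solution (length `D`).
#' @return data frame with one row per candidate: `dp` (Euclidean distance
#'   to best), `norm_f`, `norm_dp`, and `score` in `[0, 2]`.
#' @export
fdb_scores <- function(positions, fitness, best_position) {
  if (!is.matrix(positions)) positions <- matrix(positions, nrow = length(fitness))
  n <- nrow(positions)
  if (n < 2L) stop("FDB scoring needs a population of at least 2", call. = FALSE)
  stopifnot(length(fitness) == n, ncol(positions) == length(best_position))

  diff <- sweep(positions, 2, best_position, "-")
  dp <- sqrt(rowSums(diff * diff))

  rf <- range(fitness)
  norm_f <- if (rf[2] > rf[1]) (rf[2] - fitness) / (rf[2] - rf[1]) else rep(0, n)
  rd <- range(dp)
  norm_dp <- if (rd[2] > rd[1]) (dp - rd[1]) / (rd[2] - rd[1]) else rep(0, n)

  data.frame(dp = dp, norm_f = norm_f, norm_dp = norm_dp,
             score = norm_f + norm_dp)
}

#' Select the reference position for the distance terms
#'
#' The adaptive part of the fitness-distance-balance mechanism alternates
#' the reference entering the encircling distances by iteration parity: on
#' even iterations each wolf references its own position (the original
#' update), on odd iterations all wolves reference the highest-scoring FDB
#' candidate. Iterations are 1-based, so the first iteration uses the FDB
#' candidate. Argmax ties in the FDB score are broken toward the lowest
#' agent index (done by the caller via `which.max`).
#'
#' @param t current iteration (1-based).
#' @param own the wolf's own position.
#' @param x_fdb position of the highest-scoring FDB candidate (required on
#'   odd iterations).
#' @return the reference position vector.
#' @export
select_reference <- function(t, own, x_fdb) {
  if (t %% 2L == 0L) return(own)
  if (is.null(x_fdb)) stop("`x_fdb` required on odd iterations", call. = FALSE)
  x_fdb
}

#' Adaptive neighborhood mutation of the guide positions
#'
#' Perturbs each guide toward (and beyond) the best-so-far solution with
#' intensity proportional to its offset from it: with `r_k = Xbest - Xk`,
#' the mutated guide is `Xk + r_k * randn` where `randn` are standard
#' normal draws (per dimension by default). A guide already at the best
#' position has zero offset and is left unchanged; the perturbation is
#' mean-zero, so guides are unbiased. Mutated guides are not re-clipped;
#' clipping happens once in [combine_guides()].
#'
#' Consumes the current RNG stream.
#'
#' @param g a `guide_set` from [guide_positions()].
#' @param best_position the best-so-far position (length `D`).
#' @param scalar_noise draw a single noise value per guide instead of one
#'   per dimension.
#' @return the mutated `guide_set`.
#' @export
adaptive_mutation <- function(g, best_position, scalar_noise = FALSE) {
  D <- length(g$x1)
  ndraw <- if (scalar_noise) function() stats::rnorm(1) else function() stats::rnorm(D)
  for (k in c("x1", "x2", "x3")) {
    off <- best_position - g[[k]]
    g[[k]] <- g[[k]] + off * ndraw()
  }
  g
}

#' Run the adaptive-mechanism grey wolf optimizer
#'
#' The full method: the GWO chassis plus, per the toggles in `config`, the
#' nonlinear convergence-factor schedule (`use_apc`), adaptive
#' fitness-distance-balance reference selection (`use_afdb`), and adaptive
#' neighborhood mutation (`use_adv`). All toggles on is AMGWO; exactly one
#' on gives the ablation variants (APCGWO, AFDBGWO, ADVGWO); all off
#' reproduces the baseline [run_gwo()] bit-for-bit under the same seed.
#' No mechanism adds a loop: every variant performs exactly `n` fitness
#' evaluations per iteration.
#'
#' @param dataset an [fs_dataset].
#' @param config an [optimizer_config].
#' @return object of class `gwo_run`; see [run_gwo()].
#' @examples
#' fx <- make_worked_fixture()
#' run_amgwo(fx$dataset, optimizer_config(n = 10, T = 20, seed = 1))
#' @export
run_amgwo <- function(dataset, config = optimizer_config()) {
  run_wolf_search(dataset, config)
}

#' Mechanism toggle presets for the named algorithm variants
#'
#' Maps an algorithm name to its mechanism toggles: `gwo` (none),
#' `apcgwo` (nonlinear schedule only), `afdbgwo` (FDB reference only),
#' `advgwo` (mutation only), `amgwo` (all three).
#'
#' @param algorithm one of `"gwo"`, `"apcgwo"`, `"afdbgwo"`, `"advgwo"`,
#'   `"amgwo"`.
#' @return named logical vector `use_apc`, `use_afdb`, `use_adv`.
#' @export
algorithm_toggles <- function(algorithm) {
  presets <- list(
    gwo     = c(use_apc = FALSE, use_afdb = FALSE, use_adv = FALSE),
    apcgwo  = c(use_apc = TRUE,  use_afdb = FALSE, use_adv = FALSE),
    afdbgwo = c(use_apc = FALSE, use_afdb = TRUE,  use_adv = FALSE),
    advgwo  = c(use_apc = FALSE, use_afdb = FALSE, use_adv = TRUE),
    amgwo   = c(use_apc = TRUE,  use_afdb = TRUE,  use_adv = TRUE)
  )
  if (!algorithm %in% names(presets)) {
    stop("unknown algorithm '", algorithm, "'; expected one of: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  presets[[algorithm]]
}
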