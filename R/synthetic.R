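#' Simulation configuration for synthetic food domains
#'
#' The generator emulates the study design the package models: food
#' positions drawn i.i.d. from a bivariate normal centred at the origin.
#' The default covariance `[[18, 5], [5, 9]]` matches the spread of the
#' bundled demonstration positions (coordinate variances near 17 and 9,
#' covariance near 6); it is fully configurable, as are the number of
#' foods, the candidate radial levels and the number of foraging steps.
#'
#' @param n_foods number of foods (default 20).
#' @param dims dimensionality (default 2; larger values model feature
#'   "intangible" locations).
#' @param mean numeric vector of length `dims`.
#' @param covariance symmetric positive-definite `dims x dims` matrix.
#' @param seed integer seed used by [sample_food_positions()].
#' @param levels candidate radial levels (default 2:5).
#' @param steps number of foraging steps N (default 14).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_foods = 20, dims = 2, mean = rep(0, dims),
                       covariance = NULL, seed = 1L,
                       levels = 2:5, steps = 14) {
  if (is.null(covariance)) {
    covariance <- if (dims == 2) matrix(c(18, 5, 5, 9), 2) else diag(dims)
  }
  covariance <- as.matrix(covariance)
  if (length(mean) != dims || !all(dim(covariance) == dims))
    stop("`mean` and `covariance` must match `dims`")
  if (any(abs(covariance - t(covariance)) > 1e-8) ||
      any(eigen(covariance, symmetric = TRUE,
                only.values = TRUE)$values <= 0))
    stop("`covariance` must be symmetric positive definite")
  if (n_foods < steps || steps < 1)
    stop("need `n_foods` >= `steps` >= 1")
  structure(list(n_foods = as.integer(n_foods), dims = as.integer(dims),
                 mean = as.numeric(mean), covariance = covariance,
                 seed = as.integer(seed), levels = as.integer(levels),
                 steps = as.integer(steps)),
            class = "sim_config")
}

#' Sample synthetic food positions
#'
#' Draws `config$n_foods` i.i.d. points from the configured multivariate
#' normal. The same seed always yields the same domain.
#'
#' @param config a [sim_config()].
#' @return A [food_domain()] with labels `1:n_foods`.
#' @export
sample_food_positions <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  xy <- local_seed(config$seed, MASS::mvrnorm(config$n_foods, config$mean,
                                              config$covariance))
  food_domain(matrix(xy, ncol = config$dims))
}

# evaluate `expr` under a temporary RNG state
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Synthesise an "observed" foraging path
#'
#' Stand-in for field data: starts from the modelled optimal path at
#' `(mode, level)` and optionally degrades it, emulating an agent that
#' follows the strategy imperfectly. Leg noise is multiplicative
#' log-normal (`legs * exp(rnorm(0, leg_noise_sd))`), applied to the legs
#' only - the label sequence keeps its geometry-independent legs the way
#' real observed paths carry measured distances. Adjacent label swaps
#' (each applied with probability `swap_rate`) reorder the visit sequence;
#' legs are recomputed from the geometry of the swapped sequence before
#' noise is applied.
#'
#' @param domain a [food_domain()].
#' @param mode `"lmrft"` or `"smrft"`.
#' @param level radial level of the generating strategy.
#' @param N number of steps.
#' @param leg_noise_sd standard deviation of the log-normal leg
#'   perturbation; 0 for none.
#' @param swap_rate per-adjacent-pair probability of swapping labels;
#'   0 for none.
#' @param seed integer seed.
#' @param start start label for SMRFT (default: the modelled default,
#'   i.e. the LMRFT-free choice must be supplied by the caller; for
#'   `"smrft"` this argument is required).
#' @return A [foraging_path()] with `mode = "observed"`; the generating
#'   mode and level are retained in the `generator` attribute.
#' @export
synth_observed_path <- function(domain, mode, level, N,
                                leg_noise_sd = 0, swap_rate = 0,
                                seed = 1L, start = NULL) {
  if (leg_noise_sd < 0) stop("`leg_noise_sd` must be >= 0")
  if (swap_rate < 0 || swap_rate > 1) stop("`swap_rate` must be in [0, 1]")
  base <- modelled_path(domain, mode, level, N, start = start)
  labels <- base$labels
  legs <- base$legs
  local_seed(seed, {
    if (swap_rate > 0 && length(labels) > 1) {
      for (i in seq_len(length(labels) - 1L)) {
        if (stats::runif(1) < swap_rate)
          labels[c(i, i + 1L)] <- labels[c(i + 1L, i)]
      }
      legs <- path_legs(domain, labels)
    }
    if (leg_noise_sd > 0 && length(legs) > 0)
      legs <- legs * exp(stats::rnorm(length(legs), 0, leg_noise_sd))
  })
  out <- foraging_path(labels, legs, "observed",
                       animal = base$animal, start = labels[1])
  attr(out, "generator") <- list(mode = mode, level = as.integer(level),
                                 leg_noise_sd = leg_noise_sd,
                                 swap_rate = swap_rate, seed = seed)
  out
}
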