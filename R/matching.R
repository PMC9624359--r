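#' Identify a foraging radial level by structural matching
#'
#' Embeds an observed path and a set of modelled optimal paths (one per
#' candidate radial level) as ascending vectors, computes the structural
#' distance at each level, and selects the level attaining the minimum.
#' Exact ties go to the lowest level.
#'
#' @param observed a [foraging_path()] (mode `"observed"`; its legs are
#'   data and used verbatim).
#' @param modelled named list of [foraging_path()]s, one per radial level;
#'   names are the levels (coercible to integer).
#' @param embedding,parse passed to [path_to_ascending()] and
#'   [structural_distance()].
#' @return An object of class `strategy_match`: list with `animal`,
#'   `mode`, `distances` (named numeric, one per level) and
#'   `selected_level`.
#' @export
match_strategy <- function(observed, modelled,
                           embedding = "cumulative", parse = "half_norm") {
  stopifnot(inherits(observed, "foraging_path"))
  if (!is.list(modelled) || length(modelled) == 0)
    stop("`modelled` must be a nonempty list of foraging paths")
  levels <- as.integer(names(modelled))
  if (anyNA(levels))
    stop("`modelled` must be named by radial level")
  ov <- path_to_ascending(observed, embedding)
  d <- vapply(modelled, function(p)
    structural_distance(ov, path_to_ascending(p, embedding), parse),
    numeric(1))
  names(d) <- levels
  o <- order(d, levels)  # ties -> lowest level
  structure(list(animal = observed$animal,
                 mode = modelled[[1]]$mode,
                 distances = d,
                 selected_level = levels[o[1]]),
            class = "strategy_match")
}

#' @export
print.strategy_match <- function(x, ...) {
  cat(sprintf("<strategy_match> animal %s, mode %s\n",
              x$animal, x$mode))
  for (k in names(x$distances))
    cat(sprintf("  level %s: %.4f%s\n", k, x$distances[[k]],
                if (as.integer(k) == x$selected_level) "  <- selected" else ""))
  invisible(x)
}

#' Batch strategy identification for several agents
#'
#' Builds the modelled optimal paths for every agent, mode and candidate
#' radial level, and matches each agent's observed path against them. The
#' SMRFT start is the first label of the agent's observed path.
#'
#' @param observed_paths named list of observed [foraging_path()]s, one
#'   per agent.
#' @param domains named list of [food_domain()]s, same names as
#'   `observed_paths`.
#' @param modes character subset of `c("lmrft", "smrft")`.
#' @param levels integer vector of candidate radial levels; nonempty.
#' @param N number of foraging steps for the modelled paths.
#' @inheritParams match_strategy
#' @return Nested named list: `result[[animal]][[mode]]` is a
#'   `strategy_match`.
#' @export
match_all <- function(observed_paths, domains, modes = c("lmrft", "smrft"),
                      levels = 2:5, N = 14,
                      embedding = "cumulative", parse = "half_norm") {
  modes <- match.arg(modes, c("lmrft", "smrft"), several.ok = TRUE)
  levels <- as.integer(levels)
  if (length(levels) == 0) stop("`levels` must be nonempty")
  if (!setequal(names(observed_paths), names(domains)))
    stop("`observed_paths` and `domains` must cover the same agents")
  out <- list()
  for (an in names(observed_paths)) {
    obs <- observed_paths[[an]]
    dom <- domains[[an]]
    out[[an]] <- list()
    for (mode in modes) {
      mp <- lapply(levels, function(k)
        modelled_path(dom, mode, k, N, start = obs$labels[1], animal = an))
      names(mp) <- levels
      out[[an]][[mode]] <- match_strategy(obs, mp, embedding, parse)
    }
  }
  out
}
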