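#' Foraging path record
#'
#' An ordered sequence of distinct food labels with one positive leg
#' distance per consecutive pair. Modelled paths (`mode = "lmrft"` or
#' `"smrft"`) carry legs equal to the Euclidean distances between the
#' visited foods and record the per-step objective value (the chosen k-th
#' relative minimum) in `scores`. Observed paths carry their legs verbatim
#' as data: an observed leg need not be consistent with any coordinate
#' geometry.
#'
#' @param labels integer vector of distinct food labels, length >= 1.
#' @param legs numeric vector of positive leg distances,
#'   `length(labels) - 1` entries.
#' @param mode one of `"lmrft"`, `"smrft"`, `"observed"`.
#' @param animal identifier of the agent (character), or `NA`.
#' @param level radial level used to build the path, or `NA` for observed
#'   paths.
#' @param start start label (SMRFT and observed), or `NA`.
#' @param scores optional numeric vector of per-step objective values
#'   (length `length(labels)` for modelled paths).
#' @return An object of class `foraging_path`.
#' @export
foraging_path <- function(labels, legs, mode,
                          animal = NA_character_, level = NA_integer_,
                          start = NA_integer_, scores = NULL) {
  labels <- as.integer(labels)
  legs <- as.numeric(legs)
  mode <- match.arg(mode, c("lmrft", "smrft", "observed"))
  if (length(labels) < 1 || anyDuplicated(labels))
    stop("`labels` must be a nonempty sequence of distinct food labels")
  if (length(legs) != length(labels) - 1L)
    stop("`legs` must have one entry per consecutive label pair")
  if (length(legs) && any(!is.finite(legs) | legs <= 0))
    stop("all legs must be positive and finite")
  structure(list(animal = animal, mode = mode,
                 level = if (is.na(level)) NA_integer_ else as.integer(level),
                 start = if (is.na(start)) NA_integer_ else as.integer(start),
                 labels = labels, legs = legs, scores = scores),
            class = "foraging_path")
}

#' @export
print.foraging_path <- function(x, ...) {
  cat(sprintf("<foraging_path> %s%s: %d foods, total distance %.4f\n",
              x$mode,
              if (!is.na(x$level)) paste0(" (level ", x$level, ")") else "",
              length(x$labels), sum(x$legs)))
  cat(" ", paste(x$labels, collapse = " -> "), "\n")
  invisible(x)
}

# Euclidean legs along a label sequence
path_legs <- function(domain, labels) {
  if (length(labels) < 2) return(numeric(0))
  xy <- domain$coords[match(as.integer(labels), domain$labels), ,
                      drop = FALSE]
  sqrt(rowSums((xy[-1, , drop = FALSE] -
                  xy[-nrow(xy), , drop = FALSE])^2))
}

#' One step of the LMRFT rule
#'
#' The long-term-memory forager surveys the whole remaining domain and
#' moves to the food whose k-th relative minimum within that domain is
#' smallest. Ties are broken by the smallest label.
#'
#' @param subset integer vector of remaining food labels.
#' @param k radial level.
#' @param D a `dist_matrix`.
#' @return List with `target` (chosen label) and `score` (its k-th
#'   relative minimum).
#' @export
lmrft_step <- function(subset, k, D) {
  subset <- sort(as.integer(subset))
  scores <- vapply(subset, function(e) relative_min(e, subset, k, D)$value,
                   numeric(1))
  i <- which.min(scores)  # first minimum = smallest label (subset sorted)
  list(target = subset[i], score = scores[i])
}

#' LMRFT optimal foraging path
#'
#' Iterates [lmrft_step()] for `N` steps, removing each eaten food from
#' the domain before the next step.
#'
#' @param domain a [food_domain()].
#' @param k radial level; must satisfy `k <= length(domain) - N + 1` so the
#'   level never exceeds the shrinking domain.
#' @param N number of foods to eat (path length).
#' @param animal optional agent identifier stored on the path.
#' @return A [foraging_path()] with `N` labels, `N - 1` Euclidean legs and
#'   `N` per-step scores.
#' @examples
#' dom <- food_domain(rbind(c(1, 2), c(-2, 4), c(0, 5), c(3, 1)))
#' lmrft_path(dom, k = 3, N = 2)$labels  # 1 then 3
#' @export
lmrft_path <- function(domain, k, N, animal = NA_character_) {
  stopifnot(inherits(domain, "food_domain"))
  n <- length(domain$labels)
  if (N < 1 || N > n) stop("`N` must be between 1 and the domain size")
  if (k < 1 || k > n - N + 1)
    stop("radial level k = ", k, " too large for N = ", N,
         " steps on ", n, " foods")
  D <- distance_matrix(domain)
  S <- domain$labels
  labels <- integer(0)
  scores <- numeric(0)
  for (i in seq_len(N)) {
    st <- lmrft_step(S, k, D)
    labels <- c(labels, st$target)
    scores <- c(scores, st$score)
    S <- setdiff(S, st$target)
  }
  foraging_path(labels, path_legs(domain, labels), "lmrft",
                animal = animal, level = k, start = labels[1],
                scores = scores)
}

#' One step of the SMRFT rule
#'
#' The short-term-memory forager only considers foods inside the radial
#' ball around its current position (radius: the k-th relative minimum
#' from there), and among those moves to the one whose own k-th relative
#' minimum within the remaining domain is smallest. Ties are broken by
#' proximity to the current position, then by ascending label.
#'
#' @param subset integer vector of remaining food labels (current food
#'   already removed).
#' @param current label of the current position; must not be in `subset`.
#' @param k radial level.
#' @param D a `dist_matrix`.
#' @return List with `target` and `score`.
#' @export
smrft_step <- function(subset, current, k, D) {
  subset <- as.integer(subset)
  if (as.integer(current) %in% subset)
    stop("`current` must already have been removed from `subset`")
  cand <- radial_ball(current, subset, k, D)
  scores <- vapply(cand, function(e) relative_min(e, subset, k, D)$value,
                   numeric(1))
  o <- order(scores, dm_row(D, current, cand), cand)
  list(target = cand[o[1]], score = scores[o[1]])
}

#' SMRFT optimal foraging path
#'
#' The first food is the empirical start (for matching against an observed
#' path, its first label). Each subsequent food follows [smrft_step()] on
#' the depleted domain.
#'
#' @inheritParams lmrft_path
#' @param start label of the empirical starting food.
#' @return A [foraging_path()] with `N` labels and `N - 1` Euclidean legs;
#'   `scores[1]` is `NA` (the start is not chosen by the objective).
#' @examples
#' dom <- food_domain(rbind(c(1, 2), c(-2, 4), c(0, 5), c(3, 1)))
#' smrft_path(dom, start = 4, k = 3, N = 2)$labels  # 4 then 3
#' @export
smrft_path <- function(domain, start, k, N, animal = NA_character_) {
  stopifnot(inherits(domain, "food_domain"))
  n <- length(domain$labels)
  start <- as.integer(start)
  if (!start %in% domain$labels) stop("`start` not in domain")
  if (N < 1 || N > n) stop("`N` must be between 1 and the domain size")
  if (k < 1 || (N > 1 && k > n - N + 1))
    stop("radial level k = ", k, " too large for N = ", N,
         " steps on ", n, " foods")
  D <- distance_matrix(domain)
  labels <- start
  scores <- NA_real_
  S <- setdiff(domain$labels, start)
  cur <- start
  for (i in seq_len(N - 1L)) {
    st <- smrft_step(S, cur, k, D)
    labels <- c(labels, st$target)
    scores <- c(scores, st$score)
    S <- setdiff(S, st$target)
    cur <- st$target
  }
  foraging_path(labels, path_legs(domain, labels), "smrft",
                animal = animal, level = k, start = start, scores = scores)
}

#' Build a modelled path in either mode
#'
#' Thin dispatcher used by the batch matcher and the command line.
#'
#' @inheritParams smrft_path
#' @param mode `"lmrft"` or `"smrft"`.
#' @param start required for `"smrft"`, ignored for `"lmrft"`.
#' @return A [foraging_path()].
#' @export
modelled_path <- function(domain, mode, k, N, start = NULL,
                          animal = NA_character_) {
  mode <- match.arg(mode, c("lmrft", "smrft"))
  if (mode == "lmrft") {
    lmrft_path(domain, k, N, animal = animal)
  } else {
    if (is.null(start)) stop("`start` is required for SMRFT paths")
    smrft_path(domain, start, k, N, animal = animal)
  }
}
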