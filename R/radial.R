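#' k-th relative minimum distance
#'
#' The radial primitive of the foraging models: the k-th least value of the
#' distance multiset from a centre food to the members of a subset of the
#' domain. When the centre itself belongs to the subset, its self-distance
#' 0 counts at rank 1. The radial level `k` parameterises an agent's
#' perceptive reach.
#'
#' @param center a food label (need not belong to `subset`).
#' @param subset integer vector of food labels; nonempty.
#' @param k radial level, `1 <= k <= length(subset)`.
#' @param D a `dist_matrix` from [distance_matrix()].
#' @return An object of class `radial_query`: list with `center`, `subset`,
#'   `k`, `value` (the k-th least distance) and `achiever` (the label
#'   attaining it; ties broken by ascending label).
#' @examples
#' dom <- food_domain(rbind(c(1, 2), c(-2, 4), c(0, 5), c(3, 1)))
#' D <- distance_matrix(dom)
#' relative_min(4, dom$labels, 3, D)$value  # exactly 5
#' @export
relative_min <- function(center, subset, k, D) {
  subset <- as.integer(subset)
  if (length(subset) == 0) stop("`subset` must be nonempty")
  k <- as.integer(k)
  if (k < 1) stop("radial level `k` must be >= 1")
  if (k > length(subset))
    stop("radial level k = ", k, " exceeds subset size ", length(subset))
  dv <- dm_row(D, center, subset)
  o <- order(dv, subset)
  structure(list(center = as.integer(center), subset = subset, k = k,
                 value = unname(dv[o[k]]), achiever = subset[o[k]]),
            class = "radial_query")
}

#' @export
print.radial_query <- function(x, ...) {
  cat(sprintf("<radial_query> center %d, k = %d: value %.6g (achiever %d)\n",
              x$center, x$k, x$value, x$achiever))
  invisible(x)
}

#' Radial ball around a food
#'
#' The closed ball around `center` whose radius is the k-th relative
#' minimum [relative_min()], intersected with `subset`. Borders are
#' included, so the ball holds at least `k` members.
#'
#' @inheritParams relative_min
#' @return Integer vector of labels in the ball, in ascending label order.
#' @examples
#' dom <- food_domain(rbind(c(1, 2), c(-2, 4), c(0, 5), c(3, 1)))
#' D <- distance_matrix(dom)
#' radial_ball(1, dom$labels, 2, D)  # the food itself and its neighbour
#' @export
radial_ball <- function(center, subset, k, D) {
  rm <- relative_min(center, subset, k, D)
  subset <- as.integer(subset)
  sort(subset[dm_row(D, center, subset) <= rm$value])
}
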