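#' Strictly ascending vector
#'
#' Domain of the structural metric: a real vector whose entries strictly
#' increase. Length-1 vectors are allowed; their difference vector is empty
#' and contributes norm 0.
#'
#' @param entries numeric vector, strictly increasing, length >= 1.
#' @return The validated numeric vector with class `ascending_vector`.
#' @export
ascending_vector <- function(entries) {
  entries <- as.numeric(entries)
  if (length(entries) < 1) stop("an ascending vector has length >= 1")
  if (!all(is.finite(entries))) stop("entries must be finite")
  if (length(entries) > 1 && any(diff(entries) <= 0))
    stop("entries must be strictly increasing")
  structure(entries, class = "ascending_vector")
}

as_ascending <- function(v) {
  if (inherits(v, "ascending_vector")) v else ascending_vector(v)
}

#' Common parts of two ascending vectors
#'
#' All entries of either vector that fall in the overlap window
#' `[max(v[1], w[1]), min(v[m], w[n])]`, deduplicated and sorted. The
#' result refines both vectors restricted to that window; it is empty when
#' the ranges are disjoint.
#'
#' @param v,w strictly ascending numeric vectors.
#' @return An `ascending_vector` (possibly of length 0, returned as a bare
#'   empty numeric vector).
#' @examples
#' common_parts(c(1, 4, 9, 10), c(2, 3, 7, 9, 12, 14, 17))
#' @export
common_parts <- function(v, w) {
  v <- as_ascending(v)
  w <- as_ascending(w)
  lo <- max(v[1], w[1])
  hi <- min(v[length(v)], w[length(w)])
  z <- sort(unique(c(unclass(v), unclass(w))))
  z <- z[z >= lo & z <= hi]
  if (length(z) == 0) return(numeric(0))
  ascending_vector(z)
}

# Euclidean norm of the consecutive-difference vector; 0 for length < 2
diff_norm <- function(u) if (length(u) < 2) 0 else sqrt(sum(diff(u)^2))

diff_sq <- function(u) if (length(u) < 2) 0 else sum(diff(u)^2)

#' Structural distance between strictly ascending vectors
#'
#' Compares the internal spacing structure of two ascending vectors of
#' possibly different lengths. With `z = common_parts(v, w)` and
#' `||.||` the Euclidean norm of the consecutive-difference vector, the
#' default form is
#' \deqn{d(v, w) = \tfrac12(\lVert\Delta v\rVert + \lVert\Delta w\rVert)
#'   - \lVert\Delta z\rVert.}
#' Because `z` refines both vectors inside their overlap window, the
#' subtracted term is at most `min(||dv||, ||dw||)` and the distance is
#' nonnegative; it is 0 iff `v == w`.
#'
#' Two alternative parses of the same ingredients are provided for
#' sensitivity analysis. `"squared"` skips all square roots,
#' \eqn{\tfrac12(\Sigma\Delta v^2 + \Sigma\Delta w^2) - \Sigma\Delta z^2};
#' it is not a metric (it fails homogeneity degree 1) but is the form some
#' legacy analyses used. `"rms"` is
#' \eqn{\sqrt{\tfrac12(\Sigma\Delta v^2 + \Sigma\Delta w^2)} -
#' \lVert\Delta z\rVert}.
#'
#' @param v,w strictly ascending numeric vectors.
#' @param parse one of `"half_norm"` (default), `"squared"`, `"rms"`.
#' @return A single number; nonnegative for `"half_norm"`.
#' @examples
#' structural_distance(c(1, 4, 9, 10), c(2, 3, 7, 9, 12, 14, 17))
#' # 2.236759
#' @export
structural_distance <- function(v, w, parse = c("half_norm", "squared", "rms")) {
  parse <- match.arg(parse)
  v <- as_ascending(v)
  w <- as_ascending(w)
  z <- common_parts(v, w)
  switch(parse,
    half_norm = 0.5 * (diff_norm(v) + diff_norm(w)) - diff_norm(z),
    squared   = 0.5 * (diff_sq(v) + diff_sq(w)) - diff_sq(z),
    rms       = sqrt(0.5 * (diff_sq(v) + diff_sq(w))) - diff_norm(z)
  )
}

#' Embed a foraging path as an ascending vector
#'
#' The structural metric needs strictly ascending vectors; a foraging path
#' is a label sequence with positive legs. Two embeddings are supported:
#'
#' * `"cumulative"` (default): cumulative leg sums with a leading 0, one
#'   entry per visited food; both compared paths then share their origin.
#' * `"cumulative_nozero"`: cumulative sums without the leading 0.
#' * `"sorted_legs"`: the legs themselves in ascending order, i.e. the
#'   path's distance profile irrespective of travel order. Duplicate leg
#'   values (which would break strict ascent) are deduplicated.
#'
#' @param path a [foraging_path()] with at least 2 foods, or a bare
#'   numeric vector of positive legs.
#' @param embedding one of `"cumulative"`, `"cumulative_nozero"`,
#'   `"sorted_legs"`.
#' @return An `ascending_vector`.
#' @export
path_to_ascending <- function(path,
                              embedding = c("cumulative",
                                            "cumulative_nozero",
                                            "sorted_legs")) {
  embedding <- match.arg(embedding)
  legs <- if (inherits(path, "foraging_path")) path$legs else as.numeric(path)
  if (length(legs) == 0 && embedding == "cumulative")
    return(ascending_vector(0))
  if (any(legs <= 0)) stop("all legs must be positive")
  ascending_vector(switch(embedding,
    cumulative        = cumsum(c(0, legs)),
    cumulative_nozero = cumsum(legs),
    sorted_legs       = sort(unique(legs))
  ))
}
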