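#' Euclidean distance matrix of a food domain
#'
#' @param domain a [food_domain()].
#' @return An object of class `dist_matrix`: a list with `labels` and
#'   `values`, a symmetric matrix of pairwise Euclidean distances with zero
#'   diagonal, rows/columns ordered and named as `domain$labels`.
#' @examples
#' dom <- food_domain(rbind(c(1, 2), c(-2, 4), c(0, 5), c(3, 1)))
#' D <- distance_matrix(dom)
#' D$values["1", "4"]  # sqrt(5)
#' @export
distance_matrix <- function(domain) {
  stopifnot(inherits(domain, "food_domain"))
  if (length(domain$labels) == 0) stop("domain is empty")
  v <- as.matrix(stats::dist(domain$coords))
  dimnames(v) <- list(domain$labels, domain$labels)
  structure(list(labels = domain$labels, values = v), class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix> %d x %d\n", length(x$labels), length(x$labels)))
  print(utils::head(x$values, 6))
  invisible(x)
}

dm_values <- function(D) {
  if (inherits(D, "dist_matrix")) D$values else as.matrix(D)
}

# distances from `center` to each label in `subset`, in subset order
dm_row <- function(D, center, subset) {
  v <- dm_values(D)
  ci <- match(as.character(center), rownames(v))
  si <- match(as.character(subset), colnames(v))
  if (is.na(ci)) stop("unknown label: ", center)
  if (anyNA(si)) stop("unknown label(s): ",
                      paste(subset[is.na(si)], collapse = ", "))
  v[ci, si]
}

#' Per-row rank matrix of a distance matrix
#'
#' Each row of the result ranks the distances from that food to every food
#' (itself included, so the diagonal is always rank 1). Ranks are ordinal;
#' ties are broken by ascending column label, the same tie rule the path
#' constructors use.
#'
#' @param D a `dist_matrix` from [distance_matrix()].
#' @return An object of class `rank_matrix`: list with `labels` and `ranks`,
#'   an integer matrix whose every row is a permutation of `1:n`.
#' @export
rank_matrix <- function(D) {
  v <- dm_values(D)
  labs <- if (inherits(D, "dist_matrix")) D$labels else seq_len(nrow(v))
  r <- t(apply(v, 1L, function(row) {
    out <- integer(length(row))
    out[order(row, labs)] <- seq_along(row)
    out
  }))
  dimnames(r) <- dimnames(v)
  structure(list(labels = labs, ranks = r), class = "rank_matrix")
}

#' @export
print.rank_matrix <- function(x, ...) {
  cat(sprintf("<rank_matrix> %d x %d\n", length(x$labels), length(x$labels)))
  print(utils::head(x$ranks, 6))
  invisible(x)
}

#' Relative order of two foods as seen from a third
#'
#' From a fixed vantage food `x`, any two foods `y` and `z` are comparable
#' by their distances to `x`; this relation is a total preorder on the
#' domain.
#'
#' @param x,y,z food labels present in `D`.
#' @param D a `dist_matrix`.
#' @return One of `"<"`, `"="`, `">"`: the order of `d(x, y)` versus
#'   `d(x, z)`.
#' @export
relative_order <- function(x, y, z, D) {
  dy <- dm_row(D, x, y)
  dz <- dm_row(D, x, z)
  if (dy < dz) "<" else if (dy > dz) ">" else "="
}

#' Write a distance or rank matrix as CSV
#'
#' Writes a square matrix with a `label` header column so the file
#' round-trips through [read_matrix_csv()].
#'
#' @param m a `dist_matrix` or `rank_matrix`.
#' @param path file path.
#' @export
write_matrix_csv <- function(m, path) {
  v <- if (inherits(m, "rank_matrix")) m$ranks else dm_values(m)
  tab <- data.frame(label = rownames(v), v, check.names = FALSE)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  v <- as.matrix(tab[, -1, drop = FALSE])
  rownames(v) <- tab[[1]]
  v
}
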