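#' Labelled food domain
#'
#' A food domain is a finite set of labelled food items, each located by a
#' real coordinate vector of common dimension `d >= 2`. Coordinates may be
#' physical positions (the usual 2-D case) or feature vectors describing
#' "intangible" locations such as nutrition scores; the downstream machinery
#' only ever sees Euclidean distances, so both are handled identically.
#' The domain is the set that depletes as a forager eats: removing a label
#' yields a valid smaller domain.
#'
#' @param coords numeric matrix, one row per food, `d >= 2` columns; all
#'   entries must be finite.
#' @param labels integer vector of unique positive labels, one per row of
#'   `coords`. Defaults to `1:nrow(coords)`, matching the usual numbering
#'   of placed foods.
#' @return An object of class `food_domain`: a list with elements `labels`
#'   (integer), `coords` (matrix with labels as rownames) and `d`.
#' @examples
#' dom <- food_domain(rbind(c(1, 2), c(-2, 4), c(0, 5), c(3, 1)))
#' dom
#' remove_food(dom, 2)
#' @export
food_domain <- function(coords, labels = NULL) {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) < 2)
    stop("`coords` must be a numeric matrix with at least 2 columns")
  if (!all(is.finite(coords)))
    stop("all coordinates must be finite")
  if (is.null(labels)) labels <- seq_len(nrow(coords))
  labels <- as.integer(labels)
  if (length(labels) != nrow(coords))
    stop("`labels` must have one entry per row of `coords`")
  if (anyDuplicated(labels) || any(labels < 1L) || anyNA(labels))
    stop("`labels` must be unique positive integers")
  rownames(coords) <- labels
  structure(list(labels = labels, coords = coords, d = ncol(coords)),
            class = "food_domain")
}

#' @export
print.food_domain <- function(x, ...) {
  cat(sprintf("<food_domain> %d foods in %d dimensions\n",
              length(x$labels), x$d))
  print(utils::head(x$coords, 6))
  if (length(x$labels) > 6) cat("...\n")
  invisible(x)
}

#' @export
length.food_domain <- function(x) length(x$labels)

#' Remove a food from a domain
#'
#' @param domain a [food_domain()].
#' @param label label of the food to remove; must be present.
#' @return A `food_domain` with one fewer food.
#' @export
remove_food <- function(domain, label) {
  stopifnot(inherits(domain, "food_domain"))
  i <- match(as.integer(label), domain$labels)
  if (is.na(i)) stop("label ", label, " not in domain")
  food_domain(domain$coords[-i, , drop = FALSE], domain$labels[-i])
}

#' Coordinates of one food
#'
#' @inheritParams remove_food
#' @return Numeric vector of length `domain$d`.
#' @export
food_coords <- function(domain, label) {
  stopifnot(inherits(domain, "food_domain"))
  i <- match(as.integer(label), domain$labels)
  if (is.na(i)) stop("label ", label, " not in domain")
  domain$coords[i, ]
}

#' Read / write food domains as CSV
#'
#' The on-disk format has a header `label,x1,...,xd` and one row per food
#' (UTF-8, comma separated, `.` decimal point).
#'
#' @param path file path.
#' @return `read_foods_csv()` returns a [food_domain()];
#'   `write_foods_csv()` returns `path` invisibly.
#' @export
read_foods_csv <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  if (!"label" %in% names(tab) || ncol(tab) < 3)
    stop("foods CSV must have columns label,x1,...,xd: ", path)
  food_domain(as.matrix(tab[, setdiff(names(tab), "label"), drop = FALSE]),
              tab$label)
}

#' @rdname read_foods_csv
#' @param domain a [food_domain()].
#' @export
write_foods_csv <- function(domain, path) {
  stopifnot(inherits(domain, "food_domain"))
  tab <- data.frame(label = domain$labels, domain$coords,
                    check.names = FALSE)
  names(tab) <- c("label", paste0("x", seq_len(domain$d)))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
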