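#' Read / write foraging paths as JSON
#'
#' Format: an object with fields `animal`, `mode`, `level`, `start`,
#' `labels`, `legs` and optionally `scores`; `level`, `start` and `scores`
#' may be `null`.
#'
#' @param path file path.
#' @return `read_path_json()` returns a [foraging_path()].
#' @export
read_path_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  foraging_path(x$labels, x$legs, x$mode,
                animal = x$animal %||% NA_character_,
                level = x$level %||% NA_integer_,
                start = x$start %||% NA_integer_,
                scores = x$scores)
}

#' @rdname read_path_json
#' @param p a [foraging_path()].
#' @export
write_path_json <- function(p, path) {
  stopifnot(inherits(p, "foraging_path"))
  x <- list(animal = p$animal, mode = p$mode,
            level = if (is.na(p$level)) NULL else p$level,
            start = if (is.na(p$start)) NULL else p$start,
            labels = p$labels, legs = p$legs, scores = p$scores)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read / write foraging paths as CSV
#'
#' Columns `step,label,leg`; the first row's `leg` is empty (no leg leads
#' into the first food). Mode and provenance are not stored in the CSV
#' variant; supply them on read.
#'
#' @param path file path.
#' @param mode,animal,level,start provenance for the path being read.
#' @return `read_path_csv()` returns a [foraging_path()].
#' @export
read_path_csv <- function(path, mode = "observed", animal = NA_character_,
                          level = NA_integer_, start = NA_integer_) {
  tab <- utils::read.csv(path)
  foraging_path(tab$label, tab$leg[-1], mode, animal = animal,
                level = level, start = start)
}

#' @rdname read_path_csv
#' @param p a [foraging_path()].
#' @export
write_path_csv <- function(p, path) {
  stopifnot(inherits(p, "foraging_path"))
  tab <- data.frame(step = seq_along(p$labels), label = p$labels,
                    leg = c(NA, p$legs))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a strategy match report as JSON
#'
#' @param m a `strategy_match` from [match_strategy()].
#' @param path file path.
#' @export
write_match_json <- function(m, path) {
  stopifnot(inherits(m, "strategy_match"))
  jsonlite::write_json(
    list(animal = m$animal, mode = m$mode,
         distances = as.list(m$distances),
         selected_level = m$selected_level),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
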