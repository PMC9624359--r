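#' Load a bundled demonstration fixture
#'
#' The package ships the small datasets of its three-agent demonstration
#' study: three 20-food position sets (`table1_animal1` .. `table1_animal3`),
#' the three observed ("hypothetically real") foraging paths
#' (`table4_observed1` .. `table4_observed3`, whose legs are data, not
#' geometry), the four-point toy domain (`example1_toy`) and the worked
#' metric example pair (`example4_vectors`).
#'
#' @param name fixture name; one of `table1_animal1`, `table1_animal2`,
#'   `table1_animal3`, `table4_observed1`, `table4_observed2`,
#'   `table4_observed3`, `example1_toy`, `example4_vectors`.
#' @return A [food_domain()], a [foraging_path()], or (for
#'   `example4_vectors`) a list with ascending vectors `v`, `w` and the
#'   reference `distance`.
#' @examples
#' load_fixture("example1_toy")
#' @export
load_fixture <- function(name) {
  known <- c(paste0("table1_animal", 1:3), paste0("table4_observed", 1:3),
             "example1_toy", "example4_vectors")
  if (!name %in% known)
    stop("unknown fixture: ", name, "; available: ",
         paste(known, collapse = ", "))
  if (grepl("^table1|^example1", name)) {
    read_foods_csv(fixture_file(paste0(name, ".csv")))
  } else if (grepl("^table4", name)) {
    read_path_json(fixture_file(paste0(name, ".json")))
  } else {
    x <- jsonlite::read_json(fixture_file("example4_vectors.json"),
                             simplifyVector = TRUE)
    list(v = ascending_vector(x$v), w = ascending_vector(x$w),
         distance = x$distance)
  }
}

fixture_file <- function(file) {
  p <- system.file("extdata", file, package = "radforage")
  if (p == "") stop("fixture file not found: ", file)
  p
}

# reference values the reproduction driver compares against
load_reference_results <- function() {
  jsonlite::read_json(fixture_file("reference_results.json"),
                      simplifyVector = TRUE)
}
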