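#' Load the packaged peptide design table
#'
#' Reads the packaged TSV of the design family: the parent fragment
#' (residues 25-37 of parathyroid hormone) and the twelve photoswitch
#' variants P1-P12 with their sequences, modification type (\code{"i"}
#' insertion / \code{"e"} exchange), modification description and the
#' measured thermal cis half-life in hours where one was determined (seven
#' peptides: P1, P2, P4, P7, P8, P9, P12; \code{NA} elsewhere). The fixture
#' is validated structurally (row count, required columns, half-life
#' presence pattern and sum) and loading fails with a checksum error if it
#' has been corrupted.
#'
#' @param path Fixture path; defaults to the packaged file.
#' @return A tibble with columns \code{peptide}, \code{sequence},
#'   \code{modification_type}, \code{modification}, \code{t_half_hours}.
#' @export
load_table1 <- function(path = system.file("extdata", "table1.tsv",
                                           package = "photofibril")) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           peptide = readr::col_character(),
                           sequence = readr::col_character(),
                           modification_type = readr::col_character(),
                           modification = readr::col_character(),
                           t_half_hours = readr::col_double()))
  with_thalf <- tab$peptide[!is.na(tab$t_half_hours)]
  ok <- nrow(tab) == 13 &&
    identical(tab$peptide, c("PTH25-37", paste0("P", 1:12))) &&
    setequal(with_thalf, c("P1", "P2", "P4", "P7", "P8", "P9", "P12")) &&
    isTRUE(all.equal(sum(tab$t_half_hours, na.rm = TRUE), 587))
  if (!ok) {
    rlang::abort("design-table fixture is corrupted (checksum mismatch)",
                 class = "photofibril_fixture_error")
  }
  tab
}

#' Packaged in-study constraint sets
#'
#' Load the two constraint sets used to infer the fibril architectures: the
#' parent fragment's (reflections at 4.7 and 10.3 A, no reflection at 9.4 A,
#' no L28-F34 cross-peak hence a > 6 A bound) and the trans photoswitch
#' variant P4's (reflections at 4.6 and 9.2 A, an L28-F34 cross-peak hence a
#' < 6 A bound). The P4 file also records the sample's interstrand spacing
#' (4.6 A), returned as the \code{"d_strand"} attribute for building the
#' matching lattice.
#'
#' @return An [observable_set()]; for \code{p4_constraints()} with a
#'   \code{"d_strand"} attribute.
#' @export
pth_constraints <- function() {
  read_constraints(system.file("extdata", "pth_constraints.json",
                               package = "photofibril"))
}

#' @rdname pth_constraints
#' @export
p4_constraints <- function() {
  path <- system.file("extdata", "p4_constraints.json",
                      package = "photofibril")
  obs <- read_constraints(path)
  attr(obs, "d_strand") <- jsonlite::fromJSON(path)$d_strand
  obs
}

#' Read and write ThT traces as CSV
#'
#' The on-disk dialect has columns \code{time_h}, \code{fluorescence_au},
#' \code{replicate}.
#' @param path CSV file path.
#' @param trace A trace tibble (e.g. from [gen_tht_trace()]).
#' @return \code{read_tht_csv}: a tibble; \code{write_tht_csv}: \code{path},
#'   invisibly.
#' @export
read_tht_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    time_h = readr::col_double(),
                    fluorescence_au = readr::col_double(),
                    replicate = readr::col_integer()))
}

#' @rdname read_tht_csv
#' @export
write_tht_csv <- function(trace, path) {
  stopifnot(all(c("time_h", "fluorescence_au", "replicate") %in% names(trace)))
  readr::write_csv(trace, path, progress = FALSE)
  invisible(path)
}
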