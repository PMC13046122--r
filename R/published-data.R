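#' Published index ranks of the top drought-screen accessions
#'
#' The printed genotype-by-index rank matrix for the accessions selected at
#' 20% intensity in the published 150-accession soybean screen that also
#' provides the calibration targets in [soy_trait_targets()]: one rank per
#' genotype for each of `Ys`, `Yp` and the eight drought-tolerance indices
#' (1 = most tolerant), together with the published rank mean, rank SD and
#' rank sum (`ref_R`, `ref_SDR`, `ref_RS`). Feeding the rank columns to
#' [rank_sum()] reproduces the published aggregation exactly.
#'
#' @return A tibble with one row per accession.
#' @export
#' @examples
#' rk <- soy_rank_matrix()
#' rank_sum(dplyr::select(rk, -dplyr::starts_with("ref_")))
soy_rank_matrix <- function() {
  path <- system.file("extdata", "soy_rank_matrix.csv", package = "ideoselect",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}
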