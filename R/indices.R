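#' Drought-tolerance indices from stress and non-stress yield means
#'
#' Computes the eight classical indices from per-genotype mean yield under
#' water stress (`Ys`) and under irrigation (`Yp`):
#' \describe{
#'   \item{STI}{stress tolerance index, `Ys*Yp / ybar_p^2`}
#'   \item{GMP}{geometric mean productivity, `sqrt(Ys*Yp)`}
#'   \item{MP}{mean productivity, `(Ys+Yp)/2`}
#'   \item{HM}{harmonic mean, `2*Ys*Yp/(Ys+Yp)`}
#'   \item{TOL}{tolerance, `Yp - Ys`}
#'   \item{SSI}{stress susceptibility index, `(1 - Ys/Yp) / SI`}
#'   \item{YSI}{yield stability index, `Ys/Yp`}
#'   \item{YI}{yield index, `Ys/ybar_s`}
#' }
#' where `ybar_s` and `ybar_p` are the trial means over all genotypes in each
#' regime and `SI = 1 - ybar_s/ybar_p` is the stress intensity.
#'
#' @param yields Data frame with columns `genotype`, `Ys`, `Yp` (yields in
#'   the same units, typically kg/ha). Genotypes with non-positive yield in
#'   either regime are excluded with a warning.
#' @return A tibble with `genotype`, `Ys`, `Yp` and the eight index columns.
#'   The trial-level context is attached as attribute `"stress"` (a list
#'   with `ybar_s`, `ybar_p`, `SI`) and is also available via
#'   [stress_context()].
#' @export
#' @examples
#' yl <- tibble::tibble(genotype = c("A", "B"),
#'                      Ys = c(500, 1500), Yp = c(2000, 2000))
#' compute_indices(yl)
compute_indices <- function(yields) {
  needed <- c("genotype", "Ys", "Yp")
  missing_cols <- setdiff(needed, names(yields))
  if (length(missing_cols)) {
    abort(paste0("`yields` is missing columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "ideo_schema_error")
  }
  bad <- !is.finite(yields$Ys) | !is.finite(yields$Yp) |
    yields$Ys <= 0 | yields$Yp <= 0
  if (any(bad)) {
    warn(sprintf("%d genotype(s) with non-positive or missing yield excluded: %s",
                 sum(bad), paste(yields$genotype[bad], collapse = ", ")))
    yields <- yields[!bad, , drop = FALSE]
  }
  if (nrow(yields) == 0) {
    abort("No genotypes with positive yields in both regimes.",
          class = "ideo_data_error")
  }
  ybar_s <- mean(yields$Ys)
  ybar_p <- mean(yields$Yp)
  si <- 1 - ybar_s / ybar_p
  if (si == 0) {
    abort("Stress intensity is zero (regime means equal); SSI is undefined.",
          class = "ideo_data_error")
  }
  out <- yields %>%
    mutate(
      STI = .data$Ys * .data$Yp / ybar_p^2,
      GMP = sqrt(.data$Ys * .data$Yp),
      MP = (.data$Ys + .data$Yp) / 2,
      HM = 2 * .data$Ys * .data$Yp / (.data$Ys + .data$Yp),
      TOL = .data$Yp - .data$Ys,
      SSI = (1 - .data$Ys / .data$Yp) / si,
      YSI = .data$Ys / .data$Yp,
      YI = .data$Ys / ybar_s
    ) %>%
    as_tibble()
  attr(out, "stress") <- list(ybar_s = ybar_s, ybar_p = ybar_p, SI = si)
  out
}

#' Trial-level stress context of an index table
#'
#' @param dti A table produced by [compute_indices()].
#' @return A list with `ybar_s`, `ybar_p` and the stress intensity `SI`.
#' @export
stress_context <- function(dti) {
  ctx <- attr(dti, "stress")
  if (is.null(ctx)) {
    abort("No stress context found; was this table made by compute_indices()?",
          class = "ideo_data_error")
  }
  ctx
}

# columns ranked "largest is best"; TOL and SSI are susceptibility measures
# and rank ascending (smallest is best).
descending_indices <- c("Ys", "Yp", "STI", "GMP", "MP", "HM", "YSI", "YI")
ascending_indices <- c("TOL", "SSI")

#' Rank genotypes on every drought-tolerance index
#'
#' Assigns rank 1 to the best-performing genotype per index: the largest
#' value for `Ys`, `Yp`, `STI`, `GMP`, `MP`, `HM`, `YSI` and `YI`, and the
#' smallest for the susceptibility measures `TOL` and `SSI`. Ties receive
#' the average rank.
#'
#' @param dti A table from [compute_indices()] (any subset of its index
#'   columns is ranked; other columns are ignored).
#' @return A tibble with `genotype` and one rank column per index present.
#' @export
rank_indices <- function(dti) {
  if (nrow(dti) < 2) {
    abort("At least two genotypes are required for ranking.",
          class = "ideo_data_error")
  }
  cols <- intersect(c(descending_indices, ascending_indices), names(dti))
  if (!length(cols)) {
    abort("No index columns found to rank.", class = "ideo_schema_error")
  }
  ranks <- map(cols, function(cl) {
    x <- dti[[cl]]
    if (length(unique(x)) == 1) {
      warn(sprintf("Index '%s' is constant; all ranks set to (g+1)/2.", cl))
    }
    if (cl %in% ascending_indices) rank(x, ties.method = "average")
    else rank(-x, ties.method = "average")
  })
  names(ranks) <- cols
  bind_cols(tibble(genotype = dti$genotype), as_tibble(ranks))
}

#' Rank mean, rank standard deviation and rank sum per genotype
#'
#' Aggregates a genotype-by-index rank matrix into the screening statistic
#' `RS = R + SDR`, where `R` is the mean of the genotype's ranks over the
#' indices and `SDR` is their sample standard deviation (n-1 denominator).
#' Low `RS` identifies genotypes that rank consistently well across indices.
#'
#' @param ranks A tibble with a `genotype` column and one numeric rank column
#'   per index (at least two indices).
#' @return A tibble with `genotype`, `R`, `SDR`, `RS`.
#' @export
#' @examples
#' rk <- tibble::tibble(genotype = "SY010",
#'                      Ys = 1, Yp = 44, STI = 2, GMP = 2, MP = 7,
#'                      TOL = 22, HM = 2, YSI = 8, YI = 1, SSI = 9)
#' rank_sum(rk)  # R = 9.8, SDR = 13.61209, RS = 23.41209
rank_sum <- function(ranks) {
  idx_cols <- setdiff(names(ranks), "genotype")
  idx_cols <- idx_cols[vapply(ranks[idx_cols], is.numeric, logical(1))]
  if (length(idx_cols) < 2) {
    abort("At least two index rank columns are required to compute SDR.",
          class = "ideo_data_error")
  }
  m <- as.matrix(ranks[idx_cols])
  tibble(
    genotype = ranks$genotype,
    R = rowMeans(m),
    SDR = apply(m, 1, stats::sd),
  ) %>%
    mutate(RS = .data$R + .data$SDR)
}

#' Select genotypes with the smallest rank sum
#'
#' Keeps the `round(g * intensity)` genotypes (half-up rounding) with the
#' lowest `RS`; ties are broken by smaller rank mean `R`, then by genotype
#' label.
#'
#' @param summary A tibble from [rank_sum()].
#' @param intensity Selection intensity in `(0, 1]` (default 0.20).
#' @return The selected rows, ordered by `RS`.
#' @export
select_by_rank_sum <- function(summary, intensity = 0.20) {
  n_sel <- selection_size(nrow(summary), intensity)
  summary %>%
    arrange(.data$RS, .data$R, .data$genotype) %>%
    slice(seq_len(n_sel))
}

# shared by the rank-sum and MGIDI selections
selection_size <- function(g, intensity) {
  if (!is.numeric(intensity) || intensity <= 0 || intensity > 1) {
    abort("`intensity` must lie in (0, 1].", class = "ideo_config_error")
  }
  n_sel <- round_half_up(g * intensity)
  if (n_sel < 1) {
    abort("Selection intensity yields zero selected genotypes.",
          class = "ideo_config_error")
  }
  as.integer(n_sel)
}
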