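#' Pearson correlations with t-based p-values
#'
#' Pairwise Pearson correlations between the numeric columns of a
#' genotype-by-variable table, with two-sided p-values from the t reference
#' distribution on `g - 2` degrees of freedom and conventional significance
#' codes. Constant columns are flagged and their pairs masked as `NA`.
#'
#' @param table Data frame with an optional `genotype` column and at least
#'   two numeric variable columns; at least three rows.
#' @return A tibble in long form: `var1`, `var2`, `r`, `p_value`, `signif`,
#'   one row per unordered pair plus the unit diagonal. The correlation
#'   matrix itself is attached as attribute `"r_matrix"`.
#' @export
#' @examples
#' d <- tibble::tibble(x = 1:10, y = (1:10) + rnorm(10), z = -(1:10))
#' correlate(d)
correlate <- function(table) {
  num <- table[vapply(table, is.numeric, logical(1))]
  if (ncol(num) < 2) {
    abort("At least two numeric columns are required.", class = "ideo_data_error")
  }
  g <- nrow(num)
  if (g < 3) {
    abort("At least three rows are required.", class = "ideo_data_error")
  }
  const <- vapply(num, function(x) stats::sd(x) == 0, logical(1))
  if (any(const)) {
    warn(paste0("Constant column(s) masked: ",
                paste(names(num)[const], collapse = ", ")))
  }
  R <- suppressWarnings(stats::cor(as.matrix(num)))
  R[const, ] <- NA; R[, const] <- NA; diag(R) <- ifelse(const, NA, 1)
  vars <- names(num)
  pairs <- expand.grid(i = seq_along(vars), j = seq_along(vars))
  pairs <- pairs[pairs$i <= pairs$j, ]
  out <- map_dfr(seq_len(nrow(pairs)), function(k) {
    i <- pairs$i[k]; j <- pairs$j[k]
    r <- R[i, j]
    if (is.na(r)) {
      p <- NA_real_
    } else if (i == j) {
      p <- 0
    } else {
      tstat <- r * sqrt((g - 2) / max(1 - r^2, .Machine$double.eps))
      p <- 2 * stats::pt(abs(tstat), df = g - 2, lower.tail = FALSE)
    }
    tibble(var1 = vars[i], var2 = vars[j], r = r, p_value = p)
  })
  out$signif <- star_code(out$p_value)
  attr(out, "r_matrix") <- R
  out
}

#' Genotype-by-index biplot decomposition
#'
#' Column-standardizes the genotype-by-index matrix (mean 0, SD 1 per
#' index), takes its singular value decomposition, and returns the variance
#' share of each axis together with symmetric-scaling coordinates
#' (`U sqrt(d)` for genotypes, `V sqrt(d)` for indices) on the first two
#' axes. On standardized data the cosine of the angle between two index
#' vectors approximates their correlation.
#'
#' @param dti A table from [compute_indices()], or any data frame with a
#'   `genotype` column and at least three numeric index columns over at
#'   least three genotypes.
#' @return A list of class `"index_biplot"`: `axis_variance` (tibble with
#'   percentage per axis), `genotype_coords`, `index_coords`, and the
#'   singular values.
#' @export
index_biplot <- function(dti) {
  num <- dti[setdiff(names(dti), c("genotype", "regime"))]
  num <- num[vapply(num, is.numeric, logical(1))]
  if (nrow(num) < 3 || ncol(num) < 3) {
    abort("At least three genotypes and three index columns are required.",
          class = "ideo_data_error")
  }
  X <- scale(as.matrix(num))
  # a constant column standardizes to NaN; drop it rather than fail
  keep <- apply(is.finite(X), 2, all)
  if (!all(keep)) {
    warn(paste0("Constant column(s) dropped: ",
                paste(colnames(X)[!keep], collapse = ", ")))
    X <- X[, keep, drop = FALSE]
  }
  sv <- svd(X)
  var_pct <- 100 * sv$d^2 / sum(sv$d^2)
  k <- min(2, length(sv$d))
  gcoord <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sqrt(sv$d[seq_len(k)]), k)
  icoord <- sv$v[, seq_len(k), drop = FALSE] %*% diag(sqrt(sv$d[seq_len(k)]), k)
  colnames(gcoord) <- colnames(icoord) <- paste0("axis", seq_len(k))
  structure(
    list(
      axis_variance = tibble(axis = seq_along(var_pct), variance_pct = var_pct),
      genotype_coords = bind_cols(
        tibble(genotype = dti$genotype %||% paste0("g", seq_len(nrow(X)))),
        as_tibble(gcoord)),
      index_coords = bind_cols(tibble(index = colnames(X)), as_tibble(icoord)),
      singular_values = sv$d
    ),
    class = "index_biplot"
  )
}

#' @export
print.index_biplot <- function(x, ...) {
  v <- x$axis_variance$variance_pct
  cat("Genotype-by-index biplot decomposition\n")
  cat(sprintf("  axis I %.2f%%, axis II %.2f%% (first two: %.1f%%)\n",
              v[1], ifelse(length(v) > 1, v[2], 0),
              sum(v[seq_len(min(2, length(v)))])))
  invisible(x)
}

#' Compare named genotype selection sets
#'
#' Enumerates every exclusive intersection region of `k` named sets (the
#' `2^k - 1` cells of a Venn diagram), reports the membership of each, the
#' pairwise overlap counts, and the consensus genotypes picked by all
#' methods.
#'
#' @param sets Named list of character vectors of genotype labels (at least
#'   two sets); tibbles with a `genotype` column are accepted.
#' @return A list of class `"selection_comparison"`: `regions` (tibble with
#'   the membership pattern, count and genotypes of every exclusive region),
#'   `pairwise` (overlap counts per set pair), `consensus` (character
#'   vector), `sets`.
#' @export
#' @examples
#' compare_selections(list(A = c("g1", "g2", "g3"),
#'                         B = c("g2", "g3", "g4"), C = c("g3", "g5")))
compare_selections <- function(sets) {
  sets <- map(sets, function(s) if (is.data.frame(s)) s$genotype else s)
  if (length(sets) < 2) {
    abort("At least two selection sets are required.", class = "ideo_data_error")
  }
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  k <- length(sets)
  universe <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, names(sets)))
  patterns <- expand.grid(rep(list(c(TRUE, FALSE)), k))
  names(patterns) <- names(sets)
  patterns <- patterns[rowSums(patterns) > 0, , drop = FALSE]
  regions <- map_dfr(seq_len(nrow(patterns)), function(i) {
    pat <- unlist(patterns[i, ])
    inside <- if (length(universe)) {
      apply(member, 1, function(m) all(m == pat))
    } else logical(0)
    tibble(
      region = paste(names(sets)[pat], collapse = "&"),
      n_sets = sum(pat),
      count = sum(inside),
      genotypes = list(universe[inside])
    )
  })
  pairs <- utils::combn(names(sets), 2)
  pairwise <- map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    tibble(set1 = a, set2 = b,
           overlap = length(intersect(sets[[a]], sets[[b]])))
  })
  consensus <- Reduce(intersect, sets)
  structure(
    list(regions = regions, pairwise = pairwise,
         consensus = sort(consensus), sets = sets),
    class = "selection_comparison"
  )
}

#' @export
print.selection_comparison <- function(x, ...) {
  cat("Selection-set comparison of", length(x$sets), "methods\n")
  cat("  sizes:", paste(sprintf("%s=%d", names(x$sets),
                                vapply(x$sets, length, integer(1))),
                        collapse = ", "), "\n")
  cat("  consensus (", length(x$consensus), "): ",
      paste(x$consensus, collapse = ", "), "\n", sep = "")
  invisible(x)
}
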