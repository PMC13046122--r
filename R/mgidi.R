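#' Rescale genotype means to the 0-100 ideotype scale
#'
#' Linearly maps each trait column so that the most desirable observed value
#' scores 100 and the least desirable scores 0: traits bred upward map their
#' maximum to 100, traits bred downward (e.g. days to flowering, lodging)
#' map their minimum to 100. The hypothetical ideotype therefore scores 100
#' on every trait. The map is invariant to positive affine transforms of the
#' input column.
#'
#' @param blues Genotype-by-trait table of adjusted means: a data frame with
#'   a `genotype` column and one numeric column per trait (as from
#'   [blues()]).
#' @param senses Direction of selection per trait: a named character vector
#'   (`"increase"` or `"decrease"`), a two-column data frame
#'   (`trait`, `sense`), or `NULL` to treat every trait as `"increase"`.
#'   Traits not named default to `"increase"`.
#' @return A tibble of the same shape with every trait column in `[0, 100]`.
#' @export
#' @examples
#' b <- tibble::tibble(genotype = c("A", "B", "C"),
#'                     GY = c(40, 60, 50), D50F = c(42, 45, 48))
#' rescale_traits(b, c(D50F = "decrease"))
rescale_traits <- function(blues, senses = NULL) {
  traits <- setdiff(names(blues), "genotype")
  senses <- normalize_senses(senses, traits)
  out <- blues
  for (tr in traits) {
    x <- blues[[tr]]
    rng <- range(x)
    if (rng[1] == rng[2]) {
      abort(sprintf("Trait '%s' is constant; its 0-100 rescale is undefined.", tr),
            class = "ideo_data_error")
    }
    out[[tr]] <- if (senses[[tr]] == "increase") {
      100 * (x - rng[1]) / (rng[2] - rng[1])
    } else {
      100 * (rng[2] - x) / (rng[2] - rng[1])
    }
  }
  as_tibble(out)
}

normalize_senses <- function(senses, traits) {
  if (is.null(senses)) {
    return(stats::setNames(rep("increase", length(traits)), traits))
  }
  if (is.data.frame(senses)) {
    senses <- stats::setNames(senses$sense, senses$trait)
  }
  bad <- setdiff(unique(senses), c("increase", "decrease"))
  if (length(bad)) {
    abort(paste0("Unknown sense value(s): ", paste(bad, collapse = ", ")),
          class = "ideo_config_error")
  }
  full <- stats::setNames(rep("increase", length(traits)), traits)
  known <- intersect(names(senses), traits)
  full[known] <- senses[known]
  full
}

#' Exploratory factor analysis of the rescaled trait matrix
#'
#' Eigen-decomposes the trait correlation matrix of the rescaled genotype
#' means, retains the factors with eigenvalue strictly greater than 1
#' (at least one is always kept), applies varimax rotation to the initial
#' loadings (eigenvectors scaled by the square-root eigenvalues), and
#' computes regression factor scores `F = Z R^-1 A` for the genotypes and
#' for the ideotype row (all traits at 100, standardized with the genotype
#' column means and SDs). A 1e-8 ridge is added to near-singular correlation
#' matrices before inversion.
#'
#' @param rescaled Output of [rescale_traits()].
#' @return An object of class `"factor_model"`: a list with `eigenvalues`,
#'   `n_factors`, `loadings` (traits x factors, varimax-rotated),
#'   `communality`, `uniqueness`, `scores` (genotypes x factors),
#'   `ideotype_scores`, `correlation`, and the standardization parameters.
#' @export
factor_analysis <- function(rescaled) {
  traits <- setdiff(names(rescaled), "genotype")
  if (length(traits) < 2) {
    abort("At least two traits are required for factor analysis.",
          class = "ideo_data_error")
  }
  X <- as.matrix(rescaled[traits])
  rownames(X) <- rescaled$genotype
  R <- stats::cor(X)
  ev <- eigen(R, symmetric = TRUE)
  eigenvalues <- ev$values
  f <- sum(eigenvalues > 1)
  if (f == 0) {
    warn("No eigenvalue exceeds 1; retaining a single factor.")
    f <- 1L
  }
  A <- ev$vectors[, seq_len(f), drop = FALSE] %*%
    diag(sqrt(eigenvalues[seq_len(f)]), f)
  if (f > 1) {
    rot <- stats::varimax(A)
    A <- A %*% rot$rotmat
  }
  # orient each factor so its dominant loading is positive (sign is arbitrary)
  signs <- apply(A, 2, function(cl) sign(cl[which.max(abs(cl))]))
  signs[signs == 0] <- 1
  A <- sweep(A, 2, signs, `*`)
  dimnames(A) <- list(traits, paste0("FA", seq_len(f)))
  communality <- rowSums(A^2)

  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  Z <- scale(X, center = ctr, scale = scl)
  z_ideo <- (rep(100, length(traits)) - ctr) / scl
  Rinv <- solve_ridged(R)
  B <- Rinv %*% A                       # p x f score coefficients
  scores <- Z %*% B
  ideotype_scores <- drop(z_ideo %*% B)
  structure(
    list(
      correlation = R, eigenvalues = eigenvalues, n_factors = f,
      loadings = A, communality = communality,
      uniqueness = 1 - communality,
      scores = scores, ideotype_scores = ideotype_scores,
      center = ctr, scale = scl, genotypes = rescaled$genotype
    ),
    class = "factor_model"
  )
}

solve_ridged <- function(R, ridge = 1e-8) {
  out <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(out) || !all(is.finite(out)) || kappa(R) > 1e12) {
    out <- solve(R + diag(ridge, nrow(R)))
  }
  out
}

#' @export
print.factor_model <- function(x, ...) {
  cat("Factor model:", x$n_factors, "factor(s) retained (eigenvalue > 1)\n")
  cat("Eigenvalues:", paste(round(x$eigenvalues, 3), collapse = ", "), "\n")
  cat("Average communality:", round(mean(x$communality), 3), "\n")
  invisible(x)
}

#' Genotype-ideotype distances in factor-score space
#'
#' For each genotype, the per-factor squared distance to the ideotype score
#' and the Euclidean distance `MGIDI = sqrt(sum_j (F_ij - F_ideotype_j)^2)`.
#' The genotype closest to the ideotype is the most desirable over all
#' traits jointly.
#'
#' @param model A `"factor_model"` from [factor_analysis()].
#' @return A tibble `genotype`, `MGIDI`, ordered as the input genotypes,
#'   with the genotypes-by-factors squared-distance matrix attached as
#'   attribute `"d2"`.
#' @export
mgidi_distance <- function(model) {
  dev <- sweep(model$scores, 2, model$ideotype_scores)
  d2 <- dev^2
  out <- tibble(genotype = model$genotypes, MGIDI = unname(sqrt(rowSums(d2))))
  attr(out, "d2") <- d2
  out
}

#' Select genotypes closest to the ideotype
#'
#' Keeps the `round(g * intensity)` genotypes (half-up rounding) with the
#' smallest MGIDI; ties are broken by genotype label.
#'
#' @param distances A tibble from [mgidi_distance()] (columns `genotype`,
#'   `MGIDI`).
#' @param intensity Selection intensity in `(0, 1]` (default 0.20).
#' @return The selected rows, ordered by distance.
#' @export
select_by_mgidi <- function(distances, intensity = 0.20) {
  n_sel <- selection_size(nrow(distances), intensity)
  distances %>%
    arrange(.data$MGIDI, .data$genotype) %>%
    slice(seq_len(n_sel))
}

#' Per-trait selection differentials of a selected set
#'
#' `SD% = 100 * (mean(selected) - mean(all)) / mean(all)` on the original
#' trait scale, flagged as desirable when its sign matches the trait's
#' breeding sense. When per-trait heritabilities are supplied the
#' heritability-weighted gain `SD% * H2` is reported alongside (the expected
#' genetic, rather than phenotypic, response).
#'
#' @param blues Genotype-by-trait table of adjusted means.
#' @param selected Character vector of selected genotype labels (or a tibble
#'   with a `genotype` column).
#' @param senses Trait senses as in [rescale_traits()].
#' @param h2 Optional named vector of broad-sense heritabilities
#'   (proportions) per trait.
#' @return A tibble per trait: `trait`, `sense`, `mean_all`,
#'   `mean_selected`, `sd_pct`, `desirable` (and `gain_pct` if `h2` given).
#' @export
selection_gains <- function(blues, selected, senses = NULL, h2 = NULL) {
  if (is.data.frame(selected)) selected <- selected$genotype
  if (!length(selected)) {
    abort("`selected` is empty.", class = "ideo_data_error")
  }
  traits <- setdiff(names(blues), "genotype")
  senses <- normalize_senses(senses, traits)
  sel <- blues[blues$genotype %in% selected, , drop = FALSE]
  out <- map_dfr(traits, function(tr) {
    m_all <- mean(blues[[tr]])
    if (m_all == 0) {
      abort(sprintf("Overall mean of trait '%s' is zero; SD%% undefined.", tr),
            class = "ideo_data_error")
    }
    m_sel <- mean(sel[[tr]])
    sd_pct <- 100 * (m_sel - m_all) / m_all
    tibble(trait = tr, sense = senses[[tr]], mean_all = m_all,
           mean_selected = m_sel, sd_pct = sd_pct,
           desirable = (sd_pct >= 0) == (senses[[tr]] == "increase"))
  })
  if (!is.null(h2)) {
    out$h2 <- unname(h2[out$trait])
    out$gain_pct <- out$sd_pct * out$h2
  }
  out
}

#' Per-factor contributions to each genotype's MGIDI
#'
#' `omega_ij = D2_ij / sum_j D2_ij`, the share of a genotype's squared
#' distance to the ideotype carried by factor j. Small values mark the
#' genotype's strengths (factors on which it already sits near the
#' ideotype); within each genotype factors are ranked by ascending omega.
#' A genotype at distance exactly 0 has undefined shares and is reported as
#' uniform with `undefined = TRUE`.
#'
#' @param distances Output of [mgidi_distance()] (carries the per-factor
#'   squared distances).
#' @return A long tibble: `genotype`, `factor`, `omega`,
#'   `strength_rank` (1 = strongest factor), `undefined`.
#' @export
contributions <- function(distances) {
  d2 <- attr(distances, "d2")
  if (is.null(d2)) {
    abort("No per-factor distances found; use the output of mgidi_distance().",
          class = "ideo_data_error")
  }
  tot <- rowSums(d2)
  undef <- tot == 0
  omega <- d2 / ifelse(tot == 0, 1, tot)
  omega[undef, ] <- 1 / ncol(d2)
  imap_dfr(seq_len(nrow(d2)), function(i, ...) {
    om <- omega[i, ]
    tibble(genotype = distances$genotype[i], factor = colnames(d2),
           omega = unname(om),
           strength_rank = unname(rank(om, ties.method = "first")),
           undefined = undef[i])
  })
}

#' Multi-trait genotype-ideotype distance index (MGIDI)
#'
#' End-to-end ideotype selection from a genotype-by-trait table of adjusted
#' means: 0-100 rescaling toward the desired direction per trait
#' ([rescale_traits()]), exploratory factor analysis with eigenvalue-above-1
#' retention and varimax rotation ([factor_analysis()]), Euclidean
#' genotype-ideotype distance in factor-score space ([mgidi_distance()]),
#' selection of the closest fraction ([select_by_mgidi()]), per-trait
#' selection differentials ([selection_gains()]) and per-factor
#' strength/weakness shares ([contributions()]).
#'
#' @inheritParams rescale_traits
#' @param intensity Selection intensity in `(0, 1]` (default 0.20).
#' @param h2 Optional named vector of per-trait heritabilities forwarded to
#'   [selection_gains()].
#' @return An object of class `"mgidi_result"`: a list with `distances`,
#'   `selected`, `model`, `rescaled`, `gains`, `contributions`, `intensity`.
#'   Use [tidy()] for the per-genotype table and [glance()] for the one-row
#'   fit summary.
#' @export
#' @examples
#' cfg <- soy_trial_config(seed = 11)
#' sim <- simulate_trials(cfg)
#' b <- blues(sim$trials, regime = "WS")
#' fit <- mgidi(b, senses = trait_senses(cfg))
#' glance(fit)
mgidi <- function(blues, senses = NULL, intensity = 0.20, h2 = NULL) {
  rescaled <- rescale_traits(blues, senses)
  model <- factor_analysis(rescaled)
  distances <- mgidi_distance(model)
  selected <- select_by_mgidi(distances, intensity)
  gains <- selection_gains(blues, selected$genotype, senses, h2 = h2)
  omega <- contributions(distances)
  structure(
    list(distances = distances, selected = selected, model = model,
         rescaled = rescaled, gains = gains, contributions = omega,
         intensity = intensity),
    class = "mgidi_result"
  )
}

#' Trait senses stored in a trial configuration
#'
#' @param config A `"trial_config"`.
#' @return Named character vector mapping trait to `"increase"`/`"decrease"`.
#' @export
trait_senses <- function(config) {
  tr <- distinct(config$traits, .data$trait, .data$sense)
  stats::setNames(tr$sense, tr$trait)
}

#' @export
print.mgidi_result <- function(x, ...) {
  cat("MGIDI selection\n")
  cat("  genotypes:", nrow(x$distances),
      " factors retained:", x$model$n_factors, "\n")
  cat("  selected:", nrow(x$selected),
      sprintf("(intensity %.0f%%)\n", 100 * x$intensity))
  cat("  best:", paste(utils::head(x$selected$genotype, 5), collapse = ", "),
      if (nrow(x$selected) > 5) "..." else "", "\n")
  invisible(x)
}

#' @describeIn mgidi Per-genotype tibble: distance, selection flag and rank.
#' @param x An `"mgidi_result"`.
#' @param ... Unused.
#' @method tidy mgidi_result
#' @export
tidy.mgidi_result <- function(x, ...) {
  x$distances %>%
    mutate(rank = rank(.data$MGIDI, ties.method = "first"),
           selected = .data$genotype %in% x$selected$genotype) %>%
    arrange(.data$rank)
}

#' @describeIn mgidi One-row summary: factor count, average communality,
#'   selection size and cumulative gains by sense.
#' @method glance mgidi_result
#' @export
glance.mgidi_result <- function(x, ...) {
  inc <- x$gains$sd_pct[x$gains$sense == "increase"]
  dec <- x$gains$sd_pct[x$gains$sense == "decrease"]
  tibble(
    n_genotypes = nrow(x$distances),
    n_traits = length(x$model$communality),
    n_factors = x$model$n_factors,
    avg_communality = mean(x$model$communality),
    n_selected = nrow(x$selected),
    intensity = x$intensity,
    total_gain_increase = sum(inc),
    total_gain_decrease = sum(dec)
  )
}
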