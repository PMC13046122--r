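#' Specify a simulated trait
#'
#' Builds the per-regime rows describing one trait for the trial simulator:
#' its regime means, the variance components of the generating linear model
#' (genotype, genotype-by-environment, environment, replicate,
#' block-within-replicate and residual), an optional multiplicative mean
#' reduction under water stress, optional truncation bounds, and the
#' direction of selection used downstream by the ideotype methods.
#'
#' @param name Trait identifier (e.g. `"GY"`).
#' @param mean Grand mean under the well-watered (non-stress) regime, in
#'   trait units.
#' @param sigma2_g,sigma2_ge,sigma2_env,sigma2_rep,sigma2_block,sigma2_e
#'   Variance components in squared trait units; all must be `>= 0`.
#' @param stress_reduction Multiplicative factor in `(0, 1]` applied to the
#'   mean under the water-stressed regime (`1` = no mean shift).
#' @param lower,upper Optional truncation bounds applied to simulated values
#'   (e.g. a 1-5 lodging score).
#' @param sense Direction in which larger values are desirable: `"increase"`
#'   or `"decrease"`.
#' @return A tibble with one row per regime (`WS`, `WW`) holding the
#'   generating parameters for this trait.
#' @export
#' @examples
#' trait_spec("GY", mean = 2300, sigma2_g = 4e4, sigma2_ge = 1e4,
#'            sigma2_e = 9e4, stress_reduction = 0.4)
trait_spec <- function(name, mean, sigma2_g = 0, sigma2_ge = 0, sigma2_env = 0,
                       sigma2_rep = 0, sigma2_block = 0, sigma2_e = 0,
                       stress_reduction = 1, lower = -Inf, upper = Inf,
                       sense = c("increase", "decrease")) {
  sense <- match.arg(sense)
  vars <- c(sigma2_g, sigma2_ge, sigma2_env, sigma2_rep, sigma2_block, sigma2_e)
  if (any(vars < 0)) {
    abort("All variance components must be non-negative.", class = "ideo_config_error")
  }
  if (stress_reduction <= 0 || stress_reduction > 1) {
    abort("`stress_reduction` must lie in (0, 1].", class = "ideo_config_error")
  }
  tibble(
    trait = name,
    regime = c("WS", "WW"),
    mean = c(mean * stress_reduction, mean),
    sigma2_g = sigma2_g, sigma2_ge = sigma2_ge, sigma2_env = sigma2_env,
    sigma2_rep = sigma2_rep, sigma2_block = sigma2_block, sigma2_e = sigma2_e,
    lower = lower, upper = upper, sense = sense
  )
}

#' Configure a multi-environment trial simulation
#'
#' Assembles the design (genotypes, regimes crossed with years, replicates,
#' incomplete blocks) and the trait generating parameters into a single
#' configuration object consumed by [simulate_trials()]. Each water regime
#' crossed with each year defines one environment (e.g. `WS_23`), matching
#' the combined-analysis convention for staged drought trials.
#'
#' @param traits A tibble of per-trait, per-regime parameters as produced by
#'   [trait_spec()] (rows from several calls may be bound together), or a
#'   tibble in the same shape with regime-specific variance components.
#' @param n_genotypes Number of genotypes (accessions).
#' @param years Character vector of year labels; each regime is run in every
#'   year, so `length(years)` is the number of environments per regime.
#' @param regimes Water regimes to simulate (default both `WS` and `WW`).
#' @param n_reps Replicates per environment.
#' @param n_blocks Incomplete blocks per replicate; genotypes are laid out in
#'   blocks of `ceiling(n_genotypes / n_blocks)` with a cyclic shift between
#'   replicates, emulating an alpha-lattice arrangement.
#' @param genetic_cor Correlation of a genotype's genetic effect between the
#'   two water regimes, in `[-1, 1]`. Controls how strongly performance under
#'   stress tracks performance under irrigation.
#' @param seed Integer seed; fixing it makes [simulate_trials()] fully
#'   deterministic.
#' @return A list of class `"trial_config"`.
#' @export
trial_config <- function(traits, n_genotypes = 150, years = c("23", "24"),
                         regimes = c("WS", "WW"), n_reps = 3, n_blocks = 10,
                         genetic_cor = 0.5, seed = 1L) {
  if (!is.data.frame(traits) || nrow(traits) == 0) {
    abort("`traits` must be a non-empty data frame of trait specifications.",
          class = "ideo_config_error")
  }
  needed <- c("trait", "regime", "mean", "sigma2_g", "sigma2_ge", "sigma2_env",
              "sigma2_rep", "sigma2_block", "sigma2_e", "lower", "upper", "sense")
  missing_cols <- setdiff(needed, names(traits))
  if (length(missing_cols)) {
    abort(paste0("`traits` is missing columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "ideo_config_error")
  }
  var_cols <- c("sigma2_g", "sigma2_ge", "sigma2_env", "sigma2_rep",
                "sigma2_block", "sigma2_e")
  if (any(as.matrix(traits[var_cols]) < 0)) {
    abort("All variance components must be non-negative.", class = "ideo_config_error")
  }
  if (n_genotypes < 1 || n_reps < 1 || n_blocks < 1 || length(years) < 1) {
    abort("All design counts must be >= 1.", class = "ideo_config_error")
  }
  if (abs(genetic_cor) > 1) {
    abort("`genetic_cor` must lie in [-1, 1].", class = "ideo_config_error")
  }
  structure(
    list(
      traits = as_tibble(traits), n_genotypes = as.integer(n_genotypes),
      years = as.character(years), regimes = regimes,
      n_reps = as.integer(n_reps), n_blocks = as.integer(n_blocks),
      genetic_cor = genetic_cor, seed = as.integer(seed)
    ),
    class = "trial_config"
  )
}

#' Printed trial-level summaries used to parameterize the default simulation
#'
#' Per-trait regime means, residual coefficients of variation and broad-sense
#' heritabilities summarizing a published 150-accession soybean drought
#' screen (two water regimes by two years, three replicates, alpha-lattice
#' with ten blocks). These summary statistics are the calibration targets for
#' [soy_trial_config()]; the underlying plot data are not public.
#'
#' @return A tibble with columns `trait`, `regime`, `mean`, `cv_pct`,
#'   `h2_pct`, `lower`, `upper`, `sense`.
#' @export
soy_trait_targets <- function() {
  ws <- tibble(
    trait = c("D50F", "D95M", "FB", "PH", "NPP", "NSPP", "LS", "HSW", "GY"),
    regime = "WS",
    mean  = c(44, 109, 34.38, 62.11, 114.7, 2.31, 2.2, 12.12, 859.49),
    cv_pct = c(3.74, 2.58, 36.24, 12.98, 29.46, 7.78, 36.53, 5.01, 21.52),
    h2_pct = c(77.45, 38.45, 74.20, 71.99, 57.54, 30.24, 86.56, 28.56, 42.97)
  )
  ww <- tibble(
    trait = ws$trait,
    regime = "WW",
    mean  = c(43, 105, 121.52, 71.04, 129, 2.59, 2.33, 14.07, 2324.26),
    cv_pct = c(6.92, 3.12, 33.37, 17.75, 30.24, 9.76, 44.89, 9.82, 30.67),
    h2_pct = c(81.67, 72.51, 77.71, 66.46, 54.70, 67.98, 78.93, 76.30, 21.56)
  )
  out <- bind_rows(ws, ww)
  out$lower <- ifelse(out$trait == "LS", 1, -Inf)
  out$upper <- ifelse(out$trait == "LS", 5, Inf)
  # earliness and lodging are bred downward; everything else upward
  out$sense <- ifelse(out$trait %in% c("D50F", "D95M", "LS"), "decrease", "increase")
  out
}

#' Default configuration emulating a 150-accession soybean drought screen
#'
#' Builds a [trial_config()] whose generating parameters reproduce, in
#' expectation, the trial-level summaries in [soy_trait_targets()]: the
#' regime means are used directly; the residual variance is backed out of the
#' printed CV (`sigma2_e = (cv/100 * mean)^2`); and the genotypic variance is
#' solved in closed form from the target broad-sense heritability
#' `H2 = sigma2_g / (sigma2_g + sigma2_ge/nEnv + sigma2_e/(nEnv*nRep))`
#' with the genotype-by-environment component fixed at
#' `ge_ratio * sigma2_g`. Environment, replicate and block variances are set
#' to small fractions of the residual variance (nuisance structure only).
#'
#' @param seed Integer seed passed through to the configuration.
#' @param ge_ratio Ratio `sigma2_ge / sigma2_g` (default 0.25: interaction
#'   present but smaller than the genotypic signal).
#' @param genetic_cor Cross-regime genetic correlation (default 0.5).
#' @return A `"trial_config"` with 150 genotypes, regimes WS and WW each run
#'   in years 23 and 24, 3 replicates and 10 incomplete blocks.
#' @export
#' @examples
#' cfg <- soy_trial_config(seed = 42)
#' cfg$n_genotypes
soy_trial_config <- function(seed = 1L, ge_ratio = 0.25, genetic_cor = 0.5) {
  tg <- soy_trait_targets()
  n_env <- 2; n_rep <- 3
  h2 <- tg$h2_pct / 100
  sigma2_e <- (tg$cv_pct / 100 * tg$mean)^2
  denom <- 1 - h2 * (1 + ge_ratio / n_env)
  stopifnot(all(denom > 0))
  sigma2_g <- h2 * sigma2_e / (n_env * n_rep) / denom
  traits <- tibble(
    trait = tg$trait, regime = tg$regime, mean = tg$mean,
    sigma2_g = sigma2_g, sigma2_ge = ge_ratio * sigma2_g,
    sigma2_env = 0.05 * sigma2_e, sigma2_rep = 0.05 * sigma2_e,
    sigma2_block = 0.05 * sigma2_e, sigma2_e = sigma2_e,
    lower = tg$lower, upper = tg$upper, sense = tg$sense
  )
  trial_config(traits, n_genotypes = 150, years = c("23", "24"),
               regimes = c("WS", "WW"), n_reps = 3, n_blocks = 10,
               genetic_cor = genetic_cor, seed = seed)
}

#' Simulate a multi-environment trial with known ground truth
#'
#' Draws one realization of the additive plot-level model
#' `value = mean(regime) + g + e + ge + rep + block + residual`
#' for every trait in the configuration. Genotype and genotype-by-environment
#' effects are drawn once per genotype (by environment) and reused across
#' replicates; a genotype's genetic effects in the two regimes share a latent
#' component with correlation `genetic_cor`. All effects are Gaussian;
#' bounded traits are truncated to their bounds after assembly.
#'
#' @param config A `"trial_config"` object.
#' @return A list of class `"trial_sim"` with elements:
#'   \describe{
#'     \item{trials}{tibble of plot records: `genotype`, `environment`,
#'       `regime`, `rep`, `block`, `trait`, `value`.}
#'     \item{genotype_effects}{tibble of true genetic effects per genotype,
#'       trait and regime (for parameter-recovery checks).}
#'     \item{ge_effects}{tibble of true genotype-by-environment effects.}
#'     \item{config}{the input configuration.}
#'   }
#' @export
#' @examples
#' cfg <- trial_config(trait_spec("GY", 100, sigma2_g = 4, sigma2_e = 6),
#'                     n_genotypes = 20, n_reps = 2, n_blocks = 2)
#' sim <- simulate_trials(cfg)
#' head(sim$trials)
simulate_trials <- function(config) {
  if (!inherits(config, "trial_config")) {
    abort("`config` must be created with trial_config().", class = "ideo_config_error")
  }
  set.seed(config$seed)
  g <- config$n_genotypes
  genos <- sprintf("SY%03d", seq_len(g))
  traits <- config$traits[config$traits$regime %in% config$regimes, , drop = FALSE]
  if (nrow(traits) == 0) {
    abort("No trait rows match the requested regimes.", class = "ideo_config_error")
  }
  trait_names <- unique(traits$trait)

  block_size <- ceiling(g / config$n_blocks)
  # cyclic alpha-lattice-like layout: shift genotype order by one block per rep
  block_of <- function(rep_idx) {
    pos <- ((seq_len(g) - 1 + (rep_idx - 1) * block_size) %% g)
    pos %/% block_size + 1L
  }

  # latent genetic draws shared across regimes so WS and WW performance correlate
  rho <- config$genetic_cor
  u_shared <- matrix(rnorm(g * length(trait_names)), g,
                     dimnames = list(genos, trait_names))

  geno_truth <- list(); ge_truth <- list(); recs <- list()
  for (tr in trait_names) {
    for (rg in intersect(config$regimes, unique(traits$regime[traits$trait == tr]))) {
      p <- traits[traits$trait == tr & traits$regime == rg, ]
      envs <- paste(rg, config$years, sep = "_")
      ne <- length(envs)
      u_own <- rnorm(g)
      g_eff <- sqrt(p$sigma2_g) * (rho * u_shared[, tr] + sqrt(1 - rho^2) * u_own)
      e_eff <- rnorm(ne, 0, sqrt(p$sigma2_env))
      ge_eff <- matrix(rnorm(g * ne, 0, sqrt(p$sigma2_ge)), g, ne,
                       dimnames = list(genos, envs))
      geno_truth[[length(geno_truth) + 1L]] <-
        tibble(trait = tr, regime = rg, genotype = genos, effect = unname(g_eff))
      ge_truth[[length(ge_truth) + 1L]] <-
        tibble(trait = tr, regime = rg,
               genotype = rep(genos, ne), environment = rep(envs, each = g),
               effect = as.vector(ge_eff))
      for (j in seq_len(ne)) {
        for (k in seq_len(config$n_reps)) {
          rep_eff <- rnorm(1, 0, sqrt(p$sigma2_rep))
          blocks <- block_of(k)
          blk_eff <- rnorm(max(blocks), 0, sqrt(p$sigma2_block))
          eps <- rnorm(g, 0, sqrt(p$sigma2_e))
          val <- p$mean + g_eff + e_eff[j] + ge_eff[, j] + rep_eff +
            blk_eff[blocks] + eps
          val <- pmin(pmax(val, p$lower), p$upper)
          recs[[length(recs) + 1L]] <- tibble(
            genotype = genos, environment = envs[j], regime = rg,
            rep = k, block = blocks, trait = tr, value = unname(val)
          )
        }
      }
    }
  }
  structure(
    list(
      trials = bind_rows(recs),
      genotype_effects = bind_rows(geno_truth),
      ge_effects = bind_rows(ge_truth),
      config = config
    ),
    class = "trial_sim"
  )
}

#' @export
print.trial_sim <- function(x, ...) {
  cat("Simulated multi-environment trial\n")
  cat("  genotypes:", x$config$n_genotypes,
      " environments:", length(unique(x$trials$environment)),
      " reps:", x$config$n_reps, "\n")
  cat("  traits:", paste(unique(x$trials$trait), collapse = ", "), "\n")
  cat("  plot records:", nrow(x$trials), "\n")
  invisible(x)
}
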