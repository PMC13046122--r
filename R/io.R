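#' Read a plot-level trial table from CSV
#'
#' Expects the long format written by [write_trials()]: columns `genotype`,
#' `environment`, `regime`, `rep`, `block`, `trait`, `value` (UTF-8, header
#' row, `.` decimal). Unknown extra columns are preserved. A missing
#' required column raises a schema error naming it; non-numeric values raise
#' a row-level error with the offending line numbers.
#'
#' @param path Path to a CSV file.
#' @return A tibble of plot records.
#' @export
read_trials <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_guess()))
  needed <- c("genotype", "environment", "regime", "rep", "block", "trait", "value")
  missing_cols <- setdiff(needed, names(d))
  if (length(missing_cols)) {
    abort(paste0("Trial file is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "ideo_schema_error")
  }
  if (!is.numeric(d$value)) {
    suppressWarnings(num <- as.numeric(d$value))
    bad <- which(is.na(num) & !is.na(d$value))
    abort(paste0("Non-numeric `value` at data row(s): ",
                 paste(utils::head(bad, 10), collapse = ", ")),
          class = "ideo_schema_error")
  }
  d$genotype <- as.character(d$genotype)
  d
}

#' Write a plot-level trial table to CSV
#'
#' @param trials Tibble of plot records (or a `"trial_sim"`, whose `$trials`
#'   element is written).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  if (inherits(trials, "trial_sim")) trials <- trials$trials
  readr::write_csv(trials, path)
  invisible(path)
}

#' Configure the end-to-end selection pipeline
#'
#' @param trials A plot-level trial table (tibble or CSV path), or `NULL` to
#'   simulate from `sim_config`.
#' @param sim_config A `"trial_config"` used when `trials` is `NULL`
#'   (default [soy_trial_config()]).
#' @param regimes The two water regimes to analyse, stress first.
#' @param yield_trait Trait used for the drought-tolerance indices.
#' @param intensity Selection intensity for both methods (default 0.20).
#' @param senses Trait sense map as in [rescale_traits()]; default taken
#'   from `sim_config` when simulating, else all `"increase"`.
#' @param seed Integer seed controlling simulation.
#' @param out_dir Output directory for the result CSVs; `NULL` to skip
#'   writing.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(trials = NULL, sim_config = NULL,
                            regimes = c("WS", "WW"), yield_trait = "GY",
                            intensity = 0.20, senses = NULL, seed = 1L,
                            out_dir = NULL) {
  if (intensity <= 0 || intensity > 1) {
    abort("`intensity` must lie in (0, 1].", class = "ideo_config_error")
  }
  if (length(regimes) != 2) {
    abort("Exactly two regimes (stress, non-stress) are required.",
          class = "ideo_config_error")
  }
  if (is.null(trials) && is.null(sim_config)) {
    sim_config <- soy_trial_config(seed = seed)
  }
  structure(
    list(trials = trials, sim_config = sim_config, regimes = regimes,
         yield_trait = yield_trait, intensity = intensity, senses = senses,
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("Pipeline stage '", name, "' failed: ", conditionMessage(e)),
          class = "ideo_pipeline_error", parent = e)
  })
}

#' Run the full multi-trait drought-selection pipeline
#'
#' Executes, in order: (optional) trial simulation; per-regime REML variance
#' components, heritability, combined ANOVA and genotype BLUEs for every
#' trait; drought-tolerance indices on the yield BLUEs of the two regimes
#' with rank-sum screening; MGIDI selection within each regime; correlation
#' and biplot analyses of the index table; and the comparison of the three
#' selection sets. Deterministic given the configuration and seed. When
#' `out_dir` is set, every table is written as CSV together with a run log
#' of package version and parameters.
#'
#' @param config A `"pipeline_config"`.
#' @return A list of class `"pipeline_result"` with elements `trials`,
#'   `heritability`, `anova`, `blues` (per regime), `dti`, `ranks`,
#'   `rank_summary`, `selected_rs`, `mgidi` (per regime), `comparison`,
#'   `correlations`, `biplot`, `config`.
#' @export
#' @examples
#' \donttest{
#' cfg <- pipeline_config(sim_config = soy_trial_config(seed = 7), seed = 7)
#' res <- run_pipeline(cfg)
#' res$comparison
#' }
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be created with pipeline_config().",
          class = "ideo_config_error")
  }
  regimes <- config$regimes
  senses <- config$senses

  trials <- stage("simulate", {
    if (is.null(config$trials)) {
      sc <- config$sim_config
      sc$seed <- config$seed
      sim <- simulate_trials(sc)
      if (is.null(senses)) senses <- trait_senses(sc)
      sim$trials
    } else if (is.character(config$trials)) {
      read_trials(config$trials)
    } else {
      as_tibble(config$trials)
    }
  })

  fit <- stage("fit", {
    needed <- c("genotype", "environment", "rep", "trait", "value")
    missing_cols <- setdiff(needed, names(trials))
    if (length(missing_cols)) {
      abort(paste0("Trial table is missing columns: ",
                   paste(missing_cols, collapse = ", ")),
            class = "ideo_schema_error")
    }
    traits <- unique(trials$trait)
    per_regime <- map(regimes, function(rg) {
      vc <- map_dfr(traits, fit_variance_components, trials = trials, regime = rg)
      list(
        heritability = heritability(vc),
        anova = map_dfr(traits, function(tr) {
          mutate(trial_anova(trials, tr, rg), trait = tr, regime = rg,
                 .before = 1)
        }),
        blues = blues(trials, regime = rg)
      )
    })
    names(per_regime) <- regimes
    per_regime
  })

  dti_res <- stage("dti", {
    ys <- fit[[regimes[1]]]$blues
    yp <- fit[[regimes[2]]]$blues
    yl <- tibble(genotype = ys$genotype,
                 Ys = ys[[config$yield_trait]],
                 Yp = yp[[config$yield_trait]][match(ys$genotype, yp$genotype)])
    dti <- compute_indices(yl)
    ranks <- rank_indices(dti)
    rs <- rank_sum(ranks)
    list(dti = dti, ranks = ranks, rank_summary = rs,
         selected = select_by_rank_sum(rs, config$intensity))
  })

  mgidi_res <- stage("mgidi", {
    out <- map(regimes, function(rg) {
      h <- fit[[rg]]$heritability
      mgidi(fit[[rg]]$blues, senses = senses, intensity = config$intensity,
            h2 = stats::setNames(h$H2, h$trait))
    })
    names(out) <- regimes
    out
  })

  assoc <- stage("compare", {
    sets <- c(list(RS = dti_res$selected$genotype),
              stats::setNames(
                map(regimes, function(rg) mgidi_res[[rg]]$selected$genotype),
                paste0("MGIDI_", regimes)))
    list(comparison = compare_selections(sets),
         correlations = correlate(select(dti_res$dti, -"genotype")),
         biplot = index_biplot(dti_res$dti))
  })

  res <- structure(
    list(trials = trials, heritability = map(fit, "heritability"),
         anova = map(fit, "anova"), blues = map(fit, "blues"),
         dti = dti_res$dti, ranks = dti_res$ranks,
         rank_summary = dti_res$rank_summary, selected_rs = dti_res$selected,
         mgidi = mgidi_res, comparison = assoc$comparison,
         correlations = assoc$correlations, biplot = assoc$biplot,
         config = config),
    class = "pipeline_result"
  )
  if (!is.null(config$out_dir)) {
    stage("write", write_pipeline(res, config$out_dir))
  }
  res
}

#' Write every pipeline table to a directory of CSV files
#'
#' @param res A `"pipeline_result"`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(res, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(x, name) readr::write_csv(x, file.path(dir, name))
  write_trials(res$trials, file.path(dir, "trials.csv"))
  for (rg in names(res$heritability)) {
    w(res$heritability[[rg]], paste0("heritability_", rg, ".csv"))
    w(res$anova[[rg]], paste0("anova_", rg, ".csv"))
    w(res$blues[[rg]], paste0("blues_", rg, ".csv"))
    m <- res$mgidi[[rg]]
    w(tidy(m), paste0("mgidi_", rg, ".csv"))
    w(as_tibble(m$model$loadings) %>%
        mutate(trait = rownames(m$model$loadings),
               communality = m$model$communality,
               uniqueness = m$model$uniqueness, .before = 1),
      paste0("loadings_", rg, ".csv"))
    w(m$gains, paste0("gains_", rg, ".csv"))
    w(m$contributions, paste0("contributions_", rg, ".csv"))
  }
  w(res$dti, "dti.csv")
  w(res$ranks, "ranks.csv")
  w(res$rank_summary, "rank_sum.csv")
  w(res$selected_rs, "selected_rs.csv")
  w(res$correlations %>% select(-dplyr::any_of("r_matrix")),
    "correlations_indices.csv")
  w(res$biplot$axis_variance, "biplot_axes.csv")
  w(bind_rows(
    mutate(res$biplot$genotype_coords, item = "genotype",
           label = .data$genotype) %>% select(-"genotype"),
    mutate(res$biplot$index_coords, item = "index", label = .data$index) %>%
      select(-"index")), "biplot_coords.csv")
  w(res$comparison$regions %>%
      mutate(genotypes = vapply(.data$genotypes, paste, "", collapse = ";")),
    "venn_regions.csv")
  # run log: versions and parameters only, so repeated runs are byte-identical
  cfg <- res$config
  log_lines <- c(
    paste0("ideoselect version: ",
           as.character(utils::packageVersion("ideoselect"))),
    paste0("seed: ", cfg$seed),
    paste0("intensity: ", cfg$intensity),
    paste0("regimes: ", paste(cfg$regimes, collapse = ",")),
    paste0("yield_trait: ", cfg$yield_trait),
    paste0("n_genotypes: ", length(unique(res$trials$genotype))),
    paste0("traits: ", paste(sort(unique(res$trials$trait)), collapse = ","))
  )
  writeLines(log_lines, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Drought-selection pipeline result\n")
  cat("  genotypes:", length(unique(x$trials$genotype)),
      " traits:", length(unique(x$trials$trait)), "\n")
  cat("  rank-sum selection:", nrow(x$selected_rs), "genotypes\n")
  for (rg in names(x$mgidi)) {
    cat("  MGIDI", rg, "selection:", nrow(x$mgidi[[rg]]$selected),
        "genotypes,", x$mgidi[[rg]]$model$n_factors, "factors\n")
  }
  cat("  consensus:", paste(x$comparison$consensus, collapse = ", "), "\n")
  invisible(x)
}
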