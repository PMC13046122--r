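#' @title Mixed-model analysis of multi-environment trials
#' @description Per-trait, per-regime REML variance components, broad-sense
#'   heritability, combined ANOVA and genotype BLUEs for plot-level trial
#'   tables in the long format produced by [simulate_trials()] or
#'   [read_trials()].
#' @name met_model
NULL

# Subset one trait/regime and build the design factors used by all fits.
prepare_trial_frame <- function(trials, trait, regime) {
  needed <- c("genotype", "environment", "rep", "trait", "value")
  missing_cols <- setdiff(needed, names(trials))
  if (length(missing_cols)) {
    abort(paste0("Trial table is missing columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "ideo_schema_error")
  }
  d <- trials[trials$trait == trait, , drop = FALSE]
  if ("regime" %in% names(trials) && !is.null(regime)) {
    d <- d[d$regime == regime, , drop = FALSE]
  }
  if (nrow(d) == 0) {
    abort(sprintf("No records for trait '%s' in regime '%s'.", trait,
                  regime %||% "<any>"), class = "ideo_data_error")
  }
  d$genotype <- factor(d$genotype)
  d$environment <- factor(d$environment)
  d$rep_f <- interaction(d$environment, d$rep, drop = TRUE)
  if ("block" %in% names(d)) {
    d$block_f <- interaction(d$environment, d$rep, d$block, drop = TRUE)
  } else {
    d$block_f <- d$rep_f
  }
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two damped Newton steps on lme4's profiled REML deviance, to sharpen the
# optimizer solution to ~1e-8 relative on the variance scale.
polish_theta <- function(dfun, th, steps = 2L, h = 1e-4) {
  k <- length(th)
  for (s in seq_len(steps)) {
    f0 <- dfun(th)
    gr <- numeric(k); H <- matrix(0, k, k)
    for (i in seq_len(k)) {
      ei <- replace(numeric(k), i, h)
      fp <- dfun(th + ei); fm <- dfun(th - ei)
      gr[i] <- (fp - fm) / (2 * h)
      H[i, i] <- (fp - 2 * f0 + fm) / h^2
    }
    if (k > 1) {
      for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
        ei <- replace(numeric(k), i, h); ej <- replace(numeric(k), j, h)
        H[i, j] <- H[j, i] <-
          (dfun(th + ei + ej) - dfun(th + ei - ej) -
             dfun(th - ei + ej) + dfun(th - ei - ej)) / (4 * h^2)
      }
    }
    step <- tryCatch(solve(H, gr), error = function(e) NULL)
    if (is.null(step)) break
    cand <- pmax(th - step, 0)
    if (dfun(cand) <= f0 + 1e-10) th <- cand else break
  }
  th
}

#' REML variance components for one trait under one water regime
#'
#' Fits the all-random plot-level model
#' `value ~ (1|genotype) + (1|environment) + (1|genotype:environment) +
#' (1|rep-in-environment) + (1|block-in-rep)` by REML (lme4, with a Newton
#' refinement of the profiled deviance) and returns the variance components.
#' Negative solutions are constrained to zero. On fully balanced complete
#' block data the estimates coincide with the expected-mean-squares
#' (Henderson III) method-of-moments solution whenever that solution is
#' non-negative; [ems_variance_components()] provides that route
#' independently.
#'
#' @param trials Long plot-level table with columns `genotype`,
#'   `environment`, `rep`, (`block`,) (`regime`,) `trait`, `value`.
#' @param trait Trait name to analyse.
#' @param regime Water regime to subset on (`NULL` to use all rows).
#' @param polish Refine the optimizer solution with Newton steps (default
#'   `TRUE`).
#' @return A one-row tibble: `trait`, `regime`, `sigma2_g`, `sigma2_ge`,
#'   `sigma2_env`, `sigma2_rep`, `sigma2_block`, `sigma2_e`, `n_env`,
#'   `n_rep`, `grand_mean`.
#' @export
#' @examples
#' cfg <- trial_config(trait_spec("GY", 100, sigma2_g = 4, sigma2_ge = 2,
#'                                sigma2_e = 6), n_genotypes = 30,
#'                     n_reps = 2, n_blocks = 2, seed = 7)
#' sim <- simulate_trials(cfg)
#' fit_variance_components(sim$trials, "GY", "WS")
fit_variance_components <- function(trials, trait, regime = NULL, polish = TRUE) {
  d <- prepare_trial_frame(trials, trait, regime)
  n_env <- nlevels(d$environment)
  n_rep <- length(unique(d$rep))
  grand_mean <- mean(d$value)
  zero_row <- function(...) {
    vals <- list(...)
    tibble(trait = trait, regime = regime %||% NA_character_,
           sigma2_g = vals$g %||% 0, sigma2_ge = vals$ge %||% 0,
           sigma2_env = vals$env %||% 0, sigma2_rep = vals$rep %||% 0,
           sigma2_block = vals$block %||% 0, sigma2_e = vals$e %||% 0,
           n_env = n_env, n_rep = n_rep, grand_mean = grand_mean)
  }
  if (stats::var(d$value) < .Machine$double.eps * max(1, grand_mean^2)) {
    return(zero_row())
  }
  if (nlevels(d$genotype) < 2) {
    abort("At least two genotypes are required.", class = "ideo_data_error")
  }

  terms <- c("(1 | genotype)")
  if (n_env > 1) {
    terms <- c(terms, "(1 | environment)", "(1 | genotype:environment)")
  } else {
    warn("Single environment: genotype-by-environment variance is not estimable and is reported as 0.")
  }
  if (nlevels(d$rep_f) > n_env) terms <- c(terms, "(1 | rep_f)")
  if (nlevels(d$block_f) > nlevels(d$rep_f)) terms <- c(terms, "(1 | block_f)")
  form <- stats::as.formula(paste("value ~", paste(terms, collapse = " + ")))

  # the optimizer's gradient check is moot here: the Newton polish below
  # refines the solution past the check's tolerance
  ctrl <- lme4::lmerControl(
    check.nobs.vs.nlev = "ignore", check.nobs.vs.nRE = "ignore",
    check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4),
    check.conv.grad = lme4::.makeCC(action = "ignore", tol = 2e-3)
  )
  m <- suppressMessages(lme4::lmer(form, data = d, REML = TRUE, control = ctrl))
  if (polish) {
    dfun <- stats::update(m, devFunOnly = TRUE)
    th <- polish_theta(dfun, lme4::getME(m, "theta"))
    m <- stats::update(m, start = th,
                       control = lme4::lmerControl(
                         optimizer = NULL,
                         check.nobs.vs.nlev = "ignore", check.nobs.vs.nRE = "ignore",
                         check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4)))
  }
  vc <- as.data.frame(lme4::VarCorr(m))
  v <- stats::setNames(vc$vcov, vc$grp)
  pick <- function(nm) if (nm %in% names(v)) unname(v[[nm]]) else 0
  zero_row(g = pick("genotype"), ge = pick("genotype:environment"),
           env = pick("environment"), rep = pick("rep_f"),
           block = pick("block_f"), e = pick("Residual"))
}

#' Expected-mean-squares (Henderson III) variance components
#'
#' Method-of-moments estimates from the sequential ANOVA of the balanced
#' layout `environment + rep-in-environment + genotype +
#' genotype:environment`: `sigma2_e = MS_res`,
#' `sigma2_ge = (MS_GxE - MS_res)/nRep`,
#' `sigma2_g = (MS_G - MS_GxE)/(nRep*nEnv)`, and so on. Intended for
#' complete-block (or block-free) balanced data, where it coincides with the
#' REML solution when all estimates are positive; incomplete-block structure
#' is ignored. Negative solutions are truncated to zero.
#'
#' @inheritParams fit_variance_components
#' @param truncate Truncate negative solutions at zero (default `TRUE`; the
#'   untruncated values are what REML-equivalence checks need).
#' @return Same shape as [fit_variance_components()].
#' @export
ems_variance_components <- function(trials, trait, regime = NULL, truncate = TRUE) {
  d <- prepare_trial_frame(trials, trait, regime)
  n_env <- nlevels(d$environment)
  n_rep <- length(unique(d$rep))
  g <- nlevels(d$genotype)
  grand_mean <- mean(d$value)
  if (stats::var(d$value) < .Machine$double.eps * max(1, grand_mean^2)) {
    return(tibble(trait = trait, regime = regime %||% NA_character_,
                  sigma2_g = 0, sigma2_ge = 0, sigma2_env = 0, sigma2_rep = 0,
                  sigma2_block = 0, sigma2_e = 0,
                  n_env = n_env, n_rep = n_rep, grand_mean = grand_mean))
  }
  if (n_env > 1) {
    a <- anova(lm(value ~ environment + rep_f + genotype + genotype:environment,
                  data = d))
    ms <- stats::setNames(a$`Mean Sq`, rownames(a))
    s2e <- ms[["Residuals"]]
    s2ge <- (ms[["environment:genotype"]] - s2e) / n_rep
    s2g <- (ms[["genotype"]] - ms[["environment:genotype"]]) / (n_rep * n_env)
    s2rep <- (ms[["rep_f"]] - s2e) / g
    s2env <- (ms[["environment"]] - ms[["rep_f"]] -
                ms[["environment:genotype"]] + s2e) / (g * n_rep)
  } else {
    a <- anova(lm(value ~ rep_f + genotype, data = d))
    ms <- stats::setNames(a$`Mean Sq`, rownames(a))
    s2e <- ms[["Residuals"]]
    s2g <- (ms[["genotype"]] - s2e) / n_rep
    s2rep <- (ms[["rep_f"]] - s2e) / g
    s2ge <- 0; s2env <- 0
  }
  out <- c(g = s2g, ge = s2ge, env = s2env, rep = s2rep, e = s2e)
  if (truncate) out <- pmax(out, 0)
  tibble(trait = trait, regime = regime %||% NA_character_,
         sigma2_g = out[["g"]], sigma2_ge = out[["ge"]],
         sigma2_env = out[["env"]], sigma2_rep = out[["rep"]],
         sigma2_block = 0, sigma2_e = out[["e"]],
         n_env = n_env, n_rep = n_rep, grand_mean = grand_mean)
}

#' Broad-sense heritability on an entry-mean basis
#'
#' Computes `H2 = sigma2_g / (sigma2_g + sigma2_ge/nEnv +
#' sigma2_e/(nEnv*nRep))`, the residual coefficient of variation
#' `CV% = 100*sqrt(sigma2_e)/grand_mean`, and the conventional
#' classification: low below 30%, moderate between 30% and 60%, high above
#' 60%.
#'
#' @param vc Tibble of variance components as returned by
#'   [fit_variance_components()] (any number of rows).
#' @return The input rows with `H2` (proportion), `h2_pct`, `cv_pct` and
#'   `category` appended.
#' @export
#' @examples
#' vc <- tibble::tibble(trait = "GY", regime = "WS", sigma2_g = 4,
#'                      sigma2_ge = 2, sigma2_env = 0, sigma2_rep = 0,
#'                      sigma2_block = 0, sigma2_e = 6, n_env = 2, n_rep = 3,
#'                      grand_mean = 100)
#' heritability(vc)$H2  # 4 / (4 + 1 + 1)
heritability <- function(vc) {
  denom <- vc$sigma2_g + vc$sigma2_ge / vc$n_env +
    vc$sigma2_e / (vc$n_env * vc$n_rep)
  H2 <- ifelse(denom > 0, vc$sigma2_g / denom, 0)
  if (any(denom <= 0)) {
    warn("All variance components are zero for some rows; H2 reported as 0.")
  }
  h2_pct <- 100 * H2
  vc$H2 <- H2
  vc$h2_pct <- h2_pct
  vc$cv_pct <- ifelse(vc$grand_mean != 0,
                      100 * sqrt(vc$sigma2_e) / abs(vc$grand_mean), NA_real_)
  vc$category <- dplyr::case_when(
    h2_pct < 30 ~ "low",
    h2_pct > 60 ~ "high",
    TRUE ~ "moderate"
  )
  vc
}

star_code <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "", p < 0.001 ~ "***", p < 0.01 ~ "**",
    p < 0.05 ~ "*", TRUE ~ "ns"
  )
}

#' Combined analysis of variance for one trait under one regime
#'
#' Sequential (type I) ANOVA of
#' `environment + rep-in-environment + block-in-rep + genotype +
#' genotype:environment`, with F denominators chosen by
#' expected-mean-squares logic for the random-effects layout: genotype is
#' tested against the genotype-by-environment mean square, environment
#' against the replicate-within-environment mean square, and all remaining
#' terms against the residual. With incomplete blocks fitted before
#' genotype, the genotype line is block-adjusted. Unbalanced data trigger a
#' warning (the sequential decomposition is then order-dependent).
#'
#' @inheritParams fit_variance_components
#' @return A tibble with one row per source: `source`, `df`, `sum_sq`,
#'   `mean_sq`, `f_value`, `p_value`, `signif`.
#' @export
trial_anova <- function(trials, trait, regime = NULL) {
  d <- prepare_trial_frame(trials, trait, regime)
  n_env <- nlevels(d$environment)
  counts <- table(d$genotype, d$environment)
  if (length(unique(as.vector(counts))) > 1) {
    warn("Design is unbalanced; sequential sums of squares are order-dependent.")
  }
  rhs <- c("environment"[n_env > 1],
           if (nlevels(d$rep_f) > n_env) "rep_f",
           if (nlevels(d$block_f) > nlevels(d$rep_f)) "block_f",
           "genotype",
           if (n_env > 1) "genotype:environment")
  a <- anova(lm(stats::reformulate(rhs, "value"), data = d))
  lab <- c(environment = "Env", rep_f = "Rep(Env)", block_f = "Block(Rep)",
           genotype = "Gen", `genotype:environment` = "Env x Gen",
           `environment:genotype` = "Env x Gen", Residuals = "Residual")
  tab <- tibble(
    source = unname(lab[rownames(a)]),
    df = a$Df, sum_sq = a$`Sum Sq`, mean_sq = a$`Mean Sq`
  )
  ms <- stats::setNames(tab$mean_sq, tab$source)
  dfs <- stats::setNames(tab$df, tab$source)
  denom_of <- function(src) {
    if (src == "Gen" && "Env x Gen" %in% tab$source) "Env x Gen"
    else if (src == "Env" && "Rep(Env)" %in% tab$source) "Rep(Env)"
    else "Residual"
  }
  tab$f_value <- NA_real_; tab$p_value <- NA_real_
  for (i in seq_len(nrow(tab))) {
    src <- tab$source[i]
    if (src == "Residual") next
    dn <- denom_of(src)
    if (ms[[dn]] > 0) {
      tab$f_value[i] <- ms[[src]] / ms[[dn]]
      tab$p_value[i] <- stats::pf(tab$f_value[i], dfs[[src]], dfs[[dn]],
                                  lower.tail = FALSE)
    } else if (ms[[src]] > 0) {
      tab$f_value[i] <- Inf; tab$p_value[i] <- 0
    }
  }
  tab$signif <- star_code(tab$p_value)
  tab
}

#' Genotype BLUEs (adjusted means)
#'
#' Best linear unbiased estimates of genotype means with genotype fixed and
#' environment, genotype-by-environment, replicate and block random —
#' generalized least squares given the REML nuisance components. On balanced
#' noise-free data the BLUE equals the raw genotype mean. Degenerate inputs
#' (no residual variance, or no estimable random structure) fall back to
#' ordinary least squares, which gives the same answer there.
#'
#' @inheritParams fit_variance_components
#' @param traits Traits to compute BLUEs for; default all traits present.
#' @param wide Return a genotype-by-trait wide table (default) or a long
#'   tibble `genotype, trait, blue`.
#' @return A tibble; wide format has one row per genotype, one column per
#'   trait.
#' @export
#' @examples
#' cfg <- trial_config(trait_spec("GY", 100, sigma2_g = 4, sigma2_e = 6),
#'                     n_genotypes = 15, n_reps = 2, n_blocks = 3, seed = 3)
#' sim <- simulate_trials(cfg)
#' blues(sim$trials, regime = "WS")
blues <- function(trials, regime = NULL, traits = NULL, wide = TRUE) {
  traits <- traits %||% unique(trials$trait)
  long <- map_dfr(traits, function(tr) {
    d <- prepare_trial_frame(trials, tr, regime)
    n_env <- nlevels(d$environment)
    rterms <- c(if (n_env > 1) c("(1 | environment)", "(1 | genotype:environment)"),
                if (nlevels(d$rep_f) > n_env) "(1 | rep_f)",
                if (nlevels(d$block_f) > nlevels(d$rep_f)) "(1 | block_f)")
    est <- NULL
    if (length(rterms) && stats::var(d$value) > 1e-12 * max(1, mean(d$value)^2)) {
      form <- stats::as.formula(
        paste("value ~ 0 + genotype +", paste(rterms, collapse = " + ")))
      est <- tryCatch({
        # small gradient warnings on balanced designs are benign for fixed
        # effects; the BLUEs are insensitive to the nuisance-variance tail
        ctrl <- lme4::lmerControl(
          check.nobs.vs.nlev = "ignore", check.nobs.vs.nRE = "ignore",
          check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4),
          check.conv.grad = lme4::.makeCC(action = "ignore", tol = 2e-3))
        m <- suppressMessages(lme4::lmer(form, data = d, REML = TRUE,
                                         control = ctrl))
        b <- lme4::fixef(m)
        stats::setNames(unname(b), sub("^genotype", "", names(b)))
      }, error = function(e) NULL)
    }
    if (is.null(est)) {
      b <- coef(lm(value ~ 0 + genotype, data = d))
      est <- stats::setNames(unname(b), sub("^genotype", "", names(b)))
    }
    tibble(genotype = names(est), trait = tr, blue = unname(est))
  })
  if (wide) {
    pivot_wider(long, names_from = "trait", values_from = "blue") %>%
      arrange(.data$genotype)
  } else {
    arrange(long, .data$trait, .data$genotype)
  }
}
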