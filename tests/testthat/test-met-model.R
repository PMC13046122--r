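test_that("constant response gives all-zero variance components", {
  cfg <- trial_config(trait_spec("GY", 100), n_genotypes = 10, n_reps = 2,
                      n_blocks = 2, seed = 1)
  sim <- simulate_trials(cfg)
  vc <- fit_variance_components(sim$trials, "GY", "WS")
  expect_equal(vc$sigma2_g, 0)
  expect_equal(vc$sigma2_ge, 0)
  expect_equal(vc$sigma2_e, 0)
})

test_that("genotype-only signal decomposes exactly", {
  # genotype effects, no other variation: all variance is genotypic
  cfg <- trial_config(trait_spec("GY", 100, sigma2_g = 4),
                      n_genotypes = 15, n_reps = 2, n_blocks = 1, seed = 2)
  sim <- simulate_trials(cfg)
  vc <- fit_variance_components(sim$trials, "GY", "WS")
  expect_equal(vc$sigma2_e, 0, tolerance = 1e-6)
  expect_equal(vc$sigma2_ge, 0, tolerance = 1e-6)
  expect_gt(vc$sigma2_g, 0)
})

test_that("REML equals the Henderson III EMS oracle on balanced designs", {
  # random small balanced complete-block designs; equivalence holds whenever
  # the unconstrained moment solution is interior
  checked <- 0
  for (seed in 1:6) {
    cfg <- rcbd_config(n_genotypes = 12 + (seed %% 3) * 4,
                       n_env_years = 2 + seed %% 2, n_reps = 2 + seed %% 2,
                       sigma2_g = 5, sigma2_ge = 3, sigma2_e = 4,
                       sigma2_env = 25, sigma2_rep = 2, seed = 100 + seed)
    sim <- simulate_trials(cfg)
    ems_raw <- ems_variance_components(sim$trials, "GY", "WS", truncate = FALSE)
    comps <- c("sigma2_g", "sigma2_ge", "sigma2_e", "sigma2_rep", "sigma2_env")
    if (any(unlist(ems_raw[comps]) < 0)) next
    reml <- fit_variance_components(sim$trials, "GY", "WS")
    for (cm in comps) {
      expect_equal(reml[[cm]], ems_raw[[cm]], tolerance = 1e-6,
                   label = paste("REML", cm, "seed", seed))
    }
    checked <- checked + 1
  }
  expect_gte(checked, 3)
})

test_that("variance components are recovered on a 300-genotype trial", {
  cfg <- rcbd_config(n_genotypes = 300, n_env_years = 2, n_reps = 3,
                     sigma2_g = 4, sigma2_ge = 2, sigma2_e = 6,
                     sigma2_env = 9, sigma2_rep = 1, seed = 1)
  sim <- simulate_trials(cfg)
  vc <- fit_variance_components(sim$trials, "GY", "WS")
  # compare against the realized variance of the drawn effects (the draw
  # noise of the effects themselves is not estimation error)
  true_g <- var(sim$genotype_effects$effect)
  true_ge <- var(sim$ge_effects$effect)
  expect_lt(abs(vc$sigma2_g - true_g) / true_g, 0.15)
  expect_lt(abs(vc$sigma2_ge - true_ge) / true_ge, 0.15)
  expect_lt(abs(vc$sigma2_e - 6) / 6, 0.15)
  # entry-mean heritability lands near its closed-form target 2/3
  h <- heritability(vc)
  expect_lt(abs(h$H2 - 2 / 3), 0.1)
})

test_that("heritability follows its closed form and classification rule", {
  vc_row <- function(g, ge, e, n_env = 2, n_rep = 3) {
    tibble::tibble(trait = "t", regime = "WS", sigma2_g = g, sigma2_ge = ge,
                   sigma2_env = 0, sigma2_rep = 0, sigma2_block = 0,
                   sigma2_e = e, n_env = n_env, n_rep = n_rep,
                   grand_mean = 100)
  }
  expect_equal(heritability(vc_row(4, 2, 6))$H2, 4 / 6, tolerance = 1e-12)
  expect_equal(heritability(vc_row(3, 0, 0))$H2, 1)
  expect_warning(h0 <- heritability(vc_row(0, 0, 0)), "zero")
  expect_equal(h0$H2, 0)
  # 30/60 thresholds on the percent scale; a trait at 28.56% is "low"
  g_for <- function(h2) h2 / (1 - h2)  # with ge = 0, e = 6, nEnv*nRep = 6
  h <- heritability(dplyr::bind_rows(
    vc_row(g_for(0.2856), 0, 6), vc_row(g_for(0.45), 0, 6),
    vc_row(g_for(0.80), 0, 6)))
  expect_equal(h$h2_pct, c(28.56, 45, 80), tolerance = 1e-10)
  expect_equal(h$category, c("low", "moderate", "high"))
  # CV is the residual SD relative to the grand mean
  expect_equal(heritability(vc_row(4, 2, 25))$cv_pct, 5)
})

test_that("heritability is monotone in its components", {
  base <- function(g, e, n_rep) {
    heritability(tibble::tibble(
      trait = "t", regime = "WS", sigma2_g = g, sigma2_ge = 2, sigma2_env = 0,
      sigma2_rep = 0, sigma2_block = 0, sigma2_e = e, n_env = 2,
      n_rep = n_rep, grand_mean = 100))$H2
  }
  h_g <- sapply(seq(0.5, 10, length.out = 12), base, e = 6, n_rep = 3)
  expect_true(all(diff(h_g) > 0))
  h_e <- sapply(seq(0.5, 20, length.out = 12), function(e) base(4, e, 3))
  expect_true(all(diff(h_e) < 0))
  h_r <- sapply(1:8, function(r) base(4, 6, r))
  expect_true(all(diff(h_r) > 0))
  expect_true(all(h_g >= 0 & h_g <= 1))
})

test_that("the combined ANOVA has the design degrees of freedom and EMS F-tests", {
  cfg <- rcbd_config(n_genotypes = 150, n_env_years = 2, n_reps = 3, seed = 7)
  sim <- simulate_trials(cfg)
  a <- trial_anova(sim$trials, "GY", "WS")
  expect_equal(a$df[a$source == "Gen"], 149)
  expect_equal(a$df[a$source == "Env"], 1)
  expect_equal(a$df[a$source == "Env x Gen"], 149)
  expect_equal(sum(a$df), nrow(sim$trials) - 1)
  expect_true(all(a$mean_sq >= 0))
  # genotype F uses the interaction mean square as denominator
  ms <- setNames(a$mean_sq, a$source)
  expect_equal(a$f_value[a$source == "Gen"], ms[["Gen"]] / ms[["Env x Gen"]])
})

test_that("genotype-only signal yields zero interaction mean square", {
  cfg <- trial_config(trait_spec("GY", 100, sigma2_g = 4),
                      n_genotypes = 12, n_reps = 2, n_blocks = 1, seed = 8)
  sim <- simulate_trials(cfg)
  # base anova warns on an essentially perfect fit; the decomposition stands
  a <- suppressWarnings(trial_anova(sim$trials, "GY", "WS"))
  expect_equal(a$mean_sq[a$source == "Env x Gen"], 0, tolerance = 1e-20)
})

test_that("the genotype F-test holds its nominal size under pure noise", {
  # all effect variances zero: rejections at alpha = 0.05 should be rare
  n_sig <- 0; n_trials <- 200
  for (i in seq_len(n_trials)) {
    cfg <- trial_config(trait_spec("GY", 100, sigma2_e = 1),
                        n_genotypes = 12, years = "1", n_reps = 3,
                        n_blocks = 1, seed = 1000 + i)
    sim <- simulate_trials(cfg)
    a <- trial_anova(sim$trials, "GY", "WS")
    p <- a$p_value[a$source == "Gen"]
    if (p < 0.05) n_sig <- n_sig + 1
  }
  expect_lte(n_sig / n_trials, 0.10)
})

test_that("BLUEs reduce to genotype means and are translation-equivariant", {
  cfg <- trial_config(trait_spec("GY", 100, sigma2_g = 4, sigma2_e = 0),
                      n_genotypes = 10, n_reps = 2, n_blocks = 1, seed = 9)
  sim <- simulate_trials(cfg)
  # lme4's scaling advice on the noise-free fixture is expected and harmless
  b <- suppressWarnings(blues(sim$trials, "WS"))
  raw <- tapply(sim$trials$value[sim$trials$regime == "WS"],
                sim$trials$genotype[sim$trials$regime == "WS"], mean)
  expect_equal(b$GY, as.numeric(raw[b$genotype]), tolerance = 1e-8)

  cfg2 <- rcbd_config(n_genotypes = 15, seed = 10)
  sim2 <- simulate_trials(cfg2)
  b1 <- suppressWarnings(blues(sim2$trials, "WS"))
  shifted <- dplyr::mutate(sim2$trials, value = value + 37)
  b2 <- suppressWarnings(blues(shifted, "WS"))
  expect_equal(b2$GY, b1$GY + 37, tolerance = 1e-6)
})

test_that("BLUEs rank genotypes by true mean performance at moderate heritability", {
  cfg <- rcbd_config(n_genotypes = 300, sigma2_g = 4, sigma2_ge = 2,
                     sigma2_e = 6, seed = 11)
  sim <- simulate_trials(cfg)
  b <- blues(sim$trials, "WS")
  # target: the genotype's true expected performance over the sampled
  # environments (genetic effect plus its mean interaction effect)
  ge_mean <- tapply(sim$ge_effects$effect, sim$ge_effects$genotype, mean)
  truth <- setNames(sim$genotype_effects$effect,
                    sim$genotype_effects$genotype)
  truth <- truth + ge_mean[names(truth)]
  expect_gt(cor(b$GY, truth[b$genotype], method = "spearman"), 0.9)
})

test_that("single-environment data warn and report no interaction variance", {
  cfg <- trial_config(trait_spec("GY", 100, sigma2_g = 4, sigma2_e = 2),
                      n_genotypes = 12, years = "1", n_reps = 3,
                      n_blocks = 1, seed = 12)
  sim <- simulate_trials(cfg)
  expect_warning(vc <- fit_variance_components(sim$trials, "GY", "WS"),
                 "Single environment")
  expect_equal(vc$sigma2_ge, 0)
  expect_gt(vc$sigma2_g, 0)
})
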