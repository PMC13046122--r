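# shared fixtures built in code

# one-trait RCBD-style config (complete blocks): the layout where the
# balanced-data EMS estimator is exact
rcbd_config <- function(n_genotypes = 20, n_env_years = 2, n_reps = 3,
                        sigma2_g = 4, sigma2_ge = 2, sigma2_e = 6,
                        sigma2_env = 9, sigma2_rep = 1, mean = 100,
                        seed = 1) {
  trial_config(
    trait_spec("GY", mean, sigma2_g = sigma2_g, sigma2_ge = sigma2_ge,
               sigma2_env = sigma2_env, sigma2_rep = sigma2_rep,
               sigma2_e = sigma2_e),
    n_genotypes = n_genotypes, years = as.character(seq_len(n_env_years)),
    regimes = "WS", n_reps = n_reps, n_blocks = 1, seed = seed
  )
}

# tiny genotype-by-trait mean table with a known best genotype
toy_blues <- function() {
  tibble::tibble(
    genotype = c("g1", "g2", "g3", "g4", "g5"),
    yield = c(50, 80, 65, 90, 70),
    height = c(110, 95, 120, 130, 100),
    flowering = c(48, 45, 52, 44, 50)
  )
}

# literal transcription of the ideotype-distance recipe, kept independent of
# the package implementation: rescale, correlation eigendecomposition with
# eigenvalue>1 retention, unrotated loadings, regression scores, Euclidean
# distance. Distances are invariant to the varimax rotation the package
# applies, so agreement is exact.
brute_force_mgidi <- function(blues, senses) {
  traits <- setdiff(names(blues), "genotype")
  X <- sapply(traits, function(tr) {
    x <- blues[[tr]]
    if (senses[[tr]] == "increase") {
      (100 - 0) / (max(x) - min(x)) * (x - max(x)) + 100
    } else {
      (0 - 100) / (max(x) - min(x)) * (x - max(x)) + 0
    }
  })
  R <- cor(X)
  ev <- eigen(R, symmetric = TRUE)
  f <- max(1, sum(ev$values > 1))
  A <- ev$vectors[, seq_len(f), drop = FALSE] %*%
    diag(sqrt(ev$values[seq_len(f)]), f)
  ctr <- colMeans(X); scl <- apply(X, 2, sd)
  Z <- scale(X, ctr, scl)
  zi <- (100 - ctr) / scl
  B <- solve(R) %*% A
  Fsc <- Z %*% B
  Fi <- drop(zi %*% B)
  sqrt(rowSums(sweep(Fsc, 2, Fi)^2))
}
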