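test_that("rescaling maps endpoints and midpoints as promised", {
  b <- tibble::tibble(genotype = c("a", "b", "c"),
                      up = c(40, 60, 50), down = c(40, 60, 50))
  r <- rescale_traits(b, c(up = "increase", down = "decrease"))
  expect_equal(r$up, c(0, 100, 50))
  expect_equal(r$down, c(100, 0, 50))
  expect_error(rescale_traits(tibble::tibble(genotype = c("a", "b"),
                                             t = c(1, 1))),
               class = "ideo_data_error")
})

test_that("rescaling is invariant to positive affine transforms", {
  set.seed(1)
  b <- tibble::tibble(genotype = paste0("g", 1:8), t = rnorm(8, 50, 10))
  r1 <- rescale_traits(b, c(t = "decrease"))
  r2 <- rescale_traits(dplyr::mutate(b, t = 3.7 * t + 12),
                       c(t = "decrease"))
  expect_equal(r1$t, r2$t, tolerance = 1e-12)
})

test_that("two perfectly correlated traits collapse to one factor", {
  b <- tibble::tibble(genotype = paste0("g", 1:6),
                      t1 = c(1, 3, 2, 5, 4, 6))
  b$t2 <- 2 * b$t1 + 1
  fm <- factor_analysis(rescale_traits(b))
  expect_equal(fm$eigenvalues, c(2, 0), tolerance = 1e-12)
  expect_equal(fm$n_factors, 1)
})

test_that("independent traits put all eigenvalues near one", {
  set.seed(2)
  g <- 2000
  b <- tibble::tibble(genotype = paste0("g", seq_len(g)),
                      a = rnorm(g), b = rnorm(g), c = rnorm(g), d = rnorm(g))
  fm <- factor_analysis(rescale_traits(b))
  expect_true(all(abs(fm$eigenvalues - 1) < 0.15))
})

test_that("communality and uniqueness partition each trait's variance", {
  cfg <- soy_trial_config(seed = 5)
  sim <- simulate_trials(cfg)
  b <- blues(sim$trials, regime = "WS")
  fm <- factor_analysis(rescale_traits(b, trait_senses(cfg)))
  expect_true(all(fm$communality >= 0 & fm$communality <= 1 + 1e-12))
  expect_equal(unname(fm$communality + fm$uniqueness), rep(1, 9))
  expect_gte(fm$n_factors, 1)
})

test_that("a genotype matching the ideotype has distance zero", {
  b <- toy_blues()
  # make g4 the best on every trait (it already is for yield/height; lowest
  # flowering too)
  senses <- c(yield = "increase", height = "increase", flowering = "decrease")
  fit <- mgidi(b, senses, intensity = 0.2)
  expect_equal(fit$distances$MGIDI[fit$distances$genotype == "g4"], 0,
               tolerance = 1e-10)
  expect_equal(fit$selected$genotype, "g4")
})

test_that("distances match the literal brute-force recipe on small toys", {
  set.seed(3)
  for (rep in 1:6) {
    g <- sample(4:6, 1); p <- sample(2:3, 1)
    b <- tibble::tibble(genotype = paste0("g", seq_len(g)))
    for (j in seq_len(p)) b[[paste0("t", j)]] <- runif(g, 10, 100)
    senses <- setNames(sample(c("increase", "decrease"), p, replace = TRUE),
                       paste0("t", seq_len(p)))
    fit <- mgidi(b, senses, intensity = 1)
    expect_equal(fit$distances$MGIDI, unname(brute_force_mgidi(b, senses)),
                 tolerance = 1e-10)
  }
})

test_that("distances are invariant to orthogonal rotation of the scores", {
  cfg <- soy_trial_config(seed = 6)
  sim <- simulate_trials(cfg)
  b <- blues(sim$trials, regime = "WW")
  fm <- factor_analysis(rescale_traits(b, trait_senses(cfg)))
  d0 <- mgidi_distance(fm)
  f <- fm$n_factors
  set.seed(7)
  Q <- qr.Q(qr(matrix(rnorm(f * f), f)))
  fm_rot <- fm
  fm_rot$scores <- fm$scores %*% Q
  fm_rot$ideotype_scores <- drop(fm$ideotype_scores %*% Q)
  d1 <- mgidi_distance(fm_rot)
  expect_equal(d1$MGIDI, d0$MGIDI, tolerance = 1e-10)
})

test_that("ranking is invariant to trait order and genotype relabelling", {
  set.seed(8)
  b <- tibble::tibble(genotype = paste0("g", 1:20),
                      t1 = runif(20), t2 = runif(20), t3 = runif(20),
                      t4 = runif(20))
  fit1 <- mgidi(b, intensity = 0.2)
  b2 <- b[, c("genotype", "t3", "t1", "t4", "t2")]
  fit2 <- mgidi(b2, intensity = 0.2)
  expect_equal(fit2$distances$MGIDI, fit1$distances$MGIDI, tolerance = 1e-8)
  perm <- sample(20)
  fit3 <- mgidi(b[perm, ], intensity = 0.2)
  expect_equal(fit3$distances$MGIDI[match(b$genotype, fit3$distances$genotype)],
               fit1$distances$MGIDI, tolerance = 1e-8)
  expect_setequal(fit3$selected$genotype, fit1$selected$genotype)
})

test_that("duplicating a trait column keeps the all-best genotype at zero", {
  b <- toy_blues()
  senses <- c(yield = "increase", height = "increase", flowering = "decrease",
              yield2 = "increase")
  b$yield2 <- b$yield
  fit <- mgidi(b, senses, intensity = 0.2)
  expect_equal(fit$distances$MGIDI[fit$distances$genotype == "g4"], 0,
               tolerance = 1e-8)
})

test_that("MGIDI selection sizes follow the half-up rounding rule", {
  set.seed(9)
  make_d <- function(g) tibble::tibble(genotype = sprintf("g%03d", 1:g),
                                       MGIDI = runif(g))
  expect_equal(nrow(select_by_mgidi(make_d(150), 0.20)), 30)
  expect_equal(nrow(select_by_mgidi(make_d(25), 0.20)), 5)
  expect_equal(nrow(select_by_mgidi(make_d(10), 1.0)), 10)
  expect_error(select_by_mgidi(make_d(10), 0), class = "ideo_config_error")
})

test_that("selection differentials behave at the boundaries", {
  b <- toy_blues()
  # selecting everyone: zero differential for every trait
  g0 <- selection_gains(b, b$genotype)
  expect_true(all(g0$sd_pct == 0))
  # selected mean 1.1x the overall mean: SD% = 10
  b2 <- tibble::tibble(genotype = c("a", "b"), t = c(110, 90))
  g1 <- selection_gains(b2, "a")
  expect_equal(g1$sd_pct, 10)
  expect_true(g1$desirable)
  # a decrease-sense trait counts a negative differential as desirable
  g2 <- selection_gains(b2, "b", senses = c(t = "decrease"))
  expect_equal(g2$sd_pct, -10)
  expect_true(g2$desirable)
  # heritability weighting scales the reported gain
  g3 <- selection_gains(b2, "a", h2 = c(t = 0.5))
  expect_equal(g3$gain_pct, 5)
})

test_that("factor contributions are normalized shares of squared distance", {
  cfg <- soy_trial_config(seed = 10)
  sim <- simulate_trials(cfg)
  b <- blues(sim$trials, regime = "WS")
  fit <- mgidi(b, trait_senses(cfg))
  sums <- tapply(fit$contributions$omega, fit$contributions$genotype, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # toy arithmetic: squared distances (1, 3) give shares (0.25, 0.75)
  d <- tibble::tibble(genotype = "g", MGIDI = 2)
  attr(d, "d2") <- matrix(c(1, 3), 1, dimnames = list(NULL, c("FA1", "FA2")))
  ct <- contributions(d)
  expect_equal(ct$omega, c(0.25, 0.75))
  expect_equal(ct$strength_rank, c(1, 2))
  # a zero-distance genotype gets uniform flagged shares
  d0 <- tibble::tibble(genotype = "z", MGIDI = 0)
  attr(d0, "d2") <- matrix(c(0, 0), 1, dimnames = list(NULL, c("FA1", "FA2")))
  c0 <- contributions(d0)
  expect_true(all(c0$undefined))
  expect_equal(c0$omega, c(0.5, 0.5))
})

test_that("tidy and glance summarize the fit", {
  cfg <- soy_trial_config(seed = 11)
  sim <- simulate_trials(cfg)
  fit <- mgidi(blues(sim$trials, regime = "WS"), trait_senses(cfg))
  td <- tidy(fit)
  expect_equal(nrow(td), 150)
  expect_equal(sum(td$selected), 30)
  expect_equal(td$rank, seq_len(150))
  gl <- glance(fit)
  expect_equal(gl$n_selected, 30)
  expect_true(gl$n_factors >= 1 && gl$n_factors <= 9)
  expect_true(is.finite(gl$total_gain_increase))
})
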