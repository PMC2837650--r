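test_that("identical control values give zero effects", {
  obs <- make_trial(year_effects = c(Y1 = 0, Y2 = 0),
                    subblock_effects = c(s1 = 0, s2 = 0), noise_sd = 0)
  obs$value[obs$is_control] <- 20
  fx <- estimate_control_effects(obs)
  expect_equal(fx$mu_control, 20)
  expect_equal(fx$year_effects$effect, c(0, 0))
  expect_equal(fx$subblock_effects$effect, rep(0, 4))
})

test_that("an injected year offset is recovered exactly on noiseless data", {
  obs <- make_trial(year_effects = c(Y1 = 2, Y2 = 0),
                    subblock_effects = c(s1 = 0.7, s2 = -0.7), noise_sd = 0)
  fx <- estimate_control_effects(obs)
  yfx <- fx$year_effects
  # sum-to-zero parameterisation: +2 in Y1 appears as +1 / -1
  expect_equal(yfx$effect[yfx$year == "Y1"], 1, tolerance = 1e-9)
  expect_equal(yfx$effect[yfx$year == "Y2"], -1, tolerance = 1e-9)
  expect_equal(sum(fx$subblock_effects$effect), 0, tolerance = 1e-9)
  sfx <- fx$subblock_effects
  expect_equal(sfx$effect[sfx$sub_block == "s1"], c(0.7, 0.7),
               tolerance = 1e-9)
})

test_that("sub-blocks without controls are rejected by name", {
  obs <- make_trial()
  obs <- obs[!(obs$is_control & obs$sub_block == "s2"), ]
  expect_error(estimate_control_effects(obs), "s2")
})

test_that("correction is an identity under zero effects and absorbs shifts", {
  obs <- make_trial(year_effects = c(Y1 = 0, Y2 = 0),
                    subblock_effects = c(s1 = 0, s2 = 0), noise_sd = 0)
  fx <- estimate_control_effects(obs)
  z <- correct_phenotypes(obs, fx)
  expect_equal(z$Z, z$value)
  # a constant added to every plot of one sub-block is absorbed by the
  # refitted effects: all corrected values move only by the common
  # recentring of the control mean, none differentially
  obs2 <- obs
  shift <- obs2$sub_block == "s1"
  obs2$value[shift] <- obs2$value[shift] + 3
  z2 <- correct_phenotypes(obs2, estimate_control_effects(obs2))
  delta <- z2$Z - z$Z
  expect_equal(max(delta) - min(delta), 0, tolerance = 1e-9)
  expect_lt(max(abs(delta)), 3)
  # unseen sub-block errors
  obs3 <- dplyr::mutate(obs, sub_block = ifelse(!is_control &
                                                  sub_block == "s1",
                                                "s9", sub_block))
  expect_error(correct_phenotypes(obs3, fx), "s9")
})

test_that("correction shrinks between-sub-block variance on layered data", {
  obs <- make_trial(year_effects = c(Y1 = 1.5, Y2 = -1.5),
                    subblock_effects = c(s1 = 1, s2 = -1), noise_sd = 0.2,
                    n_genotypes = 12, seed = 3)
  z <- correct_phenotypes(obs, estimate_control_effects(obs))
  raw_spread <- var(tapply(z$value, paste(z$year, z$sub_block), mean))
  cor_spread <- var(tapply(z$Z, paste(z$year, z$sub_block), mean))
  expect_lt(cor_spread, raw_spread / 4)
})

test_that("genotypic values reduce to plot means and recover simulated truth", {
  one <- tibble::tibble(
    genotype_id = "g1", year = "Y1", block = "B1",
    population = "Late", generation = 1L, Z = c(10, 12)
  )
  fit1 <- fit_genotypic_values(one)
  expect_equal(fit1$values$value, 11)

  set.seed(42)
  truth <- rnorm(80, 0, 2)
  z <- tidyr::expand_grid(g = seq_len(80), year = c("Y1", "Y2"),
                          block = c("B1", "B2"))
  z <- dplyr::mutate(z,
    genotype_id = sprintf("g%02d", g),
    population = "Late", generation = ((g - 1) %% 4) + 1L,
    Z = truth[g] + (year == "Y1") * 1.2 + (block == "B1") * (-0.4) +
      rnorm(dplyr::n(), 0, 1))
  fit <- fit_genotypic_values(z)
  est <- fit$values$value[order(fit$values$genotype_id)]
  expect_gt(cor(est, truth), 0.9)
})

test_that("a trial-shaped table (2 years x 2 blocks, 114 genotypes) fits", {
  set.seed(9)
  z <- tidyr::expand_grid(g = seq_len(114), year = c("2004", "2005"),
                          block = c("B1", "B2"))
  z <- dplyr::mutate(z,
    genotype_id = sprintf("g%03d", g), population = "Late",
    generation = ((g - 1) %% 7) + 1L,
    Z = rnorm(dplyr::n(), 25, 1))
  fit <- fit_genotypic_values(z)
  expect_equal(nrow(fit$values), 114)
  expect_true(all(glance(fit)$h2 >= 0 & glance(fit)$h2 <= 1))
})

test_that("heritability is the clamped variance ratio, monotone in s2G", {
  expect_equal(population_heritability(0, 1), 0)
  expect_equal(population_heritability(2, 2), 0.5)
  expect_equal(population_heritability(-0.5, 1), 0)
  expect_equal(population_heritability(-0.5, 1, clamp = FALSE), -1)
  expect_error(population_heritability(1, 0), "s2e")
  h <- population_heritability(seq(0, 5, 0.5), 2)
  expect_true(all(diff(h) > 0))
  expect_true(all(h >= 0 & h <= 1))
})

test_that("response slopes match closed forms and recover simulated slopes", {
  flat <- tibble::tibble(population = "Late", generation = rep(1:7, each = 3),
                         value = 5)
  rs <- response_slope(flat)
  expect_equal(rs$slope, 0)
  lin <- tibble::tibble(population = "Late", generation = rep(1:7, each = 3),
                        value = 0.5 * rep(1:7, each = 3))
  rl <- response_slope(lin)
  expect_equal(rl$slope, 0.5)
  expect_equal(rl$se, 0)
  expect_error(response_slope(dplyr::filter(lin, generation == 1)),
               "2 distinct generations")

  # recovery: slope beta within 3 standard errors in nearly all replicates
  set.seed(11)
  hits <- replicate(300, {
    d <- tibble::tibble(population = "p", generation = rep(1:7, each = 10),
                        value = 0.4 * rep(1:7, each = 10) + rnorm(70, 0, 1))
    r <- response_slope(d)
    abs(r$slope - 0.4) < 3 * r$se
  })
  expect_gte(mean(hits), 0.98)
})

test_that("synthetic controls calibrate to the configured line means and sds", {
  exp1 <- gen_experiment(fixture_spec(), seed = 21)
  for (ln in c("F252", "MBS")) {
    d <- dplyr::filter(exp1$phenotypes, line == ln)
    fx <- estimate_control_effects(d)
    want <- dplyr::filter(fixture_spec()$lines, line == ln)
    expect_equal(fx$mu_control, want$control_mean, tolerance = 0.05)
    expect_equal(sqrt(fx$sigma2), want$sd_e, tolerance = 0.1)
  }
})
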