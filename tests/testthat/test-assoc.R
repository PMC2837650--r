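test_that("Mendelian selfing weights chain through generations", {
  expect_equal(unname(mendelian_weights("het")), c(0.25, 0.5, 0.25))
  expect_equal(unname(mendelian_weights("hom_alt")), c(0, 0, 1))
  expect_equal(unname(mendelian_weights("hom_ref")), c(1, 0, 0))
  expect_equal(unname(mendelian_weights("het", steps = 2)),
               c(0.375, 0.25, 0.375))
  expect_equal(unname(mendelian_weights(1, steps = 3)),
               c(0.4375, 0.125, 0.4375))
  expect_equal(sum(mendelian_weights("het", 5)), 1)
})

test_that("selfing decay utilities give the textbook values", {
  expect_equal(selfing_heterozygosity(12), 2^-12)
  expect_equal(selfing_heterozygosity(0), 1)
  expect_equal(selfing_heterozygosity(2, h0 = 0.5), 0.125)
  expect_equal(prob_offspring_all_hom(4), 0.25^4)
  expect_equal(prob_offspring_all_hom(4, allele = "either"), 2 * 0.25^4)
  expect_equal(residual_het_frequency(1, 31), 1 / 31)
  expect_error(residual_het_frequency(3, 2), "n_het")
})

test_that("constructed genotype effects are recovered exactly", {
  d <- tibble::tibble(
    id = sprintf("i%02d", 1:15),
    generation = rep(0:4, each = 3),
    genotype = rep(c(0, 1, 2), 5),
    value = 10 + rep(0:4, each = 3) + 2 * (rep(c(0, 1, 2), 5) - 1) -
      0.5 * (rep(c(0, 1, 2), 5) == 1)
  )
  fit <- estimate_additive_dominance(d)
  expect_equal(fit$a, 2, tolerance = 1e-9)
  expect_equal(fit$d, -0.5, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_identical(tidy(fit)$estimate, c(fit$a, fit$d))
})

test_that("the estimator equals an unweighted regression oracle on complete data", {
  set.seed(31)
  g <- sample(0:2, 40, replace = TRUE)
  d <- tibble::tibble(id = sprintf("i%02d", 1:40),
                      generation = rep(1:4, each = 10),
                      genotype = g, value = rnorm(40, 25, 1.5))
  fit <- estimate_additive_dominance(d)
  mu <- ave(d$value, d$generation)
  oracle <- lm(I(value - mu) ~ I(genotype - 1) + I(genotype == 1), data = d)
  expect_equal(fit$a, unname(coef(oracle)[2]), tolerance = 1e-10)
  expect_equal(fit$d, unname(coef(oracle)[3]), tolerance = 1e-10)
})

test_that("pure-noise phenotypes show no significant genotype effect", {
  set.seed(32)
  reps <- replicate(40, {
    g <- sample(0:2, 30, replace = TRUE, prob = c(0.4, 0.2, 0.4))
    d <- tibble::tibble(id = sprintf("i%02d", 1:30),
                        generation = rep(1:3, each = 10),
                        genotype = g, value = rnorm(30, 25, 1))
    estimate_additive_dominance(d)$a
  })
  expect_lt(abs(mean(reps)), 3 * sd(reps) / sqrt(length(reps)))
})

test_that("missing genotypes are triplicated with Mendelian weights", {
  ped <- chain_pedigree(3)
  d <- tibble::tibble(
    id = c("f", "a1", "a2", "a3"),
    generation = 0:3,
    genotype = c(1, NA, NA, 0),
    value = c(25, 26, 24, 25)
  )
  fit <- estimate_additive_dominance(d, ped)
  r1 <- dplyr::filter(fit$rows, id == "a1")
  expect_equal(r1$w[order(r1$geno)], c(0.25, 0.5, 0.25))
  # a2 marginalises two selfing steps from its het grandparent
  r2 <- dplyr::filter(fit$rows, id == "a2")
  expect_equal(r2$w[order(r2$geno)], c(0.375, 0.25, 0.375))
  # no genotyped ancestor -> error
  d_bad <- dplyr::mutate(d, genotype = c(NA, NA, 1, 0))
  expect_error(estimate_additive_dominance(d_bad, ped), "ancestor")
  # identical genotypes are singular
  d_same <- dplyr::mutate(d, genotype = 2)
  expect_error(estimate_additive_dominance(d_same), "identical")
})

test_that("missing trait values are imputed from subfamily means", {
  d <- tibble::tibble(
    id = c("i1", "i2", "i3", "i4", "i5", "i6"),
    generation = rep(1:2, each = 3),
    subfamily = rep(c("A", "B", "A"), 2),
    genotype = c(0, 1, 2, 0, 1, 2),
    value = c(24, 25, 26, NA, 25, 27)
  )
  fit <- estimate_additive_dominance(d)
  imputed <- dplyr::filter(fit$rows, id == "i4")
  # subfamily A mean at generation 2 is 27; mu_2 = mean(27, 25, 27)
  expect_equal(unique(imputed$r), 27 - mean(c(27, 25, 27)), tolerance = 1e-9)
})

test_that("gene dropping reproduces the selfing-chain marginals", {
  ped <- chain_pedigree(3)
  g <- gene_drop_genotypes(ped, "f", n_sims = 10000, seed = 33)
  for (gen in 1:3) {
    freq <- as.numeric(table(factor(g[paste0("a", gen), ], levels = 0:2)))
    want <- unname(mendelian_weights("het", gen)) * 10000
    se <- sqrt(want * (1 - want / 10000))
    expect_true(all(abs(freq - want) < 3 * pmax(se, 1)))
  }
})

test_that("the gene-dropping null is centred and flags true effects", {
  ped <- make_genealogy(n_founders = 2, G = 7, seed = 4)
  geno <- gene_drop_genotypes(ped, c("f1", "f2"), 1, seed = 8)[, 1]
  set.seed(5)
  d <- tibble::tibble(
    id = ped$id, generation = ped$generation, genotype = geno,
    value = 25 + 2 * (geno - 1) + rnorm(nrow(ped), 0, 1)
  )
  gd <- gene_drop_null(d, ped, c("f1", "f2"), n_sims = 20000, seed = 9)
  # label symmetry: null additive effects are centred on zero
  expect_lt(abs(mean(gd$null$a, na.rm = TRUE)),
            3 * sd(gd$null$a, na.rm = TRUE) / sqrt(sum(!is.na(gd$null$a))))
  # an embedded effect of ~2 residual sd is essentially never exceeded
  expect_lt(gd$p_a, 1e-3)
  expect_s3_class(autoplot(gd), "ggplot")
  expect_error(gene_drop_null(d, ped, character(0)), "founder")
})

test_that("one-tailed gene-dropping P values are calibrated under the null", {
  ped <- make_genealogy(n_founders = 2, G = 5, n_selected = 6, seed = 6)
  set.seed(35)
  p_vals <- replicate(100, {
    # redraw the observed genotypes if the drop happens to be monomorphic
    repeat {
      g_obs <- gene_drop_genotypes(ped, c("f1", "f2"), 1)[, 1]
      if (length(unique(g_obs)) > 1) break
    }
    d <- tibble::tibble(id = ped$id, generation = ped$generation,
                        genotype = g_obs, value = rnorm(nrow(ped), 25, 1))
    gene_drop_null(d, ped, c("f1", "f2"), n_sims = 1000)$p_a
  })
  # the one-tailed value in the direction of the observed effect is the
  # half-tail: doubling maps it back to Uniform(0, 1)
  expect_gt(stats::ks.test(pmin(2 * p_vals, 1), "punif")$p.value, 0.01)
})

test_that("drift exceedance respects absorbing states and neutrality", {
  expect_equal(drift_exceedance(0, rep(10, 5), 0.5, n_sims = 500,
                                seed = 1)$prob, 0)
  expect_equal(drift_exceedance(1, rep(10, 5), 0.5, n_sims = 500,
                                seed = 2)$prob, 1)
  # fixation probability of a neutral allele equals its initial frequency
  d <- drift_exceedance(0.3, rep(5, 60), threshold = 0.999,
                        n_sims = 10000, seed = 3)
  se <- sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(d$prob - 0.3), 3 * se)
  # haploid switch uses half the gene copies
  dh <- drift_exceedance(0.5, c(10, 10), 0.5, n_sims = 100, seed = 4,
                         ploidy = "haploid")
  expect_equal(dh$copies, c(10, 10))
  expect_error(drift_exceedance(1.5, rep(10, 3), 0.5), "f0")
})
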