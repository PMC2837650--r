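test_that("founder scaling hits the target variance by construction", {
  for (seed in 1:4) {
    f <- build_founders(n_P = 50, n_H = 30, h20 = 0.28, s2e = 5, seed = seed)
    h <- f$haplotypes
    p <- (colSums(h$A) + colSums(h$B)) / 4
    realized <- sum(2 * p * (1 - p) * (2 * f$loci$effect * f$lambda)^2)
    expect_equal(realized, 0.28 * 5, tolerance = 1e-9)
  }
  # one-locus closed form: lambda = sqrt(target / (2 a^2)); a = 1, target = 2
  # gives lambda = 1
  f1 <- build_founders(n_P = 1, n_H = 1, h20 = 2, s2e = 1, seed = 1)
  expect_equal(f1$lambda, sqrt(2 / (2 * f1$loci$effect^2)), tolerance = 1e-12)
  expect_error(build_founders(10, 5, h20 = 0, s2e = 1), "must be > 0")
  expect_error(build_founders(0, 0, h20 = 0.1, s2e = 1), "n_P")
})

test_that("gametes of a homozygous genome copy the parent", {
  f <- build_founders(n_P = 30, n_H = 0, h20 = 0.1, s2e = 1, seed = 2)
  h1 <- f$haplotypes$A[1, ]
  g <- gamete(h1, h1, f$loci)
  expect_identical(as.integer(g), as.integer(h1))
})

test_that("crossover counts match the Poisson mean of the map length", {
  f <- build_founders(n_P = 20, n_H = 20, h20 = 0.1, s2e = 1,
                      map = genetic_map(1, 150), seed = 3)
  # force the whole 150 cM to matter by pinning loci at the ends
  f$loci$pos_cM[1] <- 0
  f$loci$pos_cM[nrow(f$loci)] <- 150
  f$loci <- f$loci[order(f$loci$pos_cM), ]
  set.seed(4)
  n_co <- replicate(3000, attr(gamete(f$haplotypes$A[1, ],
                                      f$haplotypes$A[2, ], f$loci),
                               "n_crossovers"))
  se <- sqrt(1.5 / 3000)
  expect_lt(abs(mean(n_co) - 1.5), 3 * se)
})

test_that("two-point recombination follows the Haldane map function", {
  loci <- tibble::tibble(locus = 1:2, chromosome = 1, pos_cM = c(20, 30),
                         effect = c(1, 1))
  h1 <- c(1L, 1L); h2 <- c(0L, 0L)
  r_expect <- (1 - exp(-2 * 0.1)) / 2
  # single-gamete path (sequential exponential inter-arrivals)
  set.seed(5)
  rec1 <- mean(replicate(4000, {
    g <- gamete(h1, h2, loci)
    g[1] != g[2]
  }))
  expect_lt(abs(rec1 - r_expect), 3 * sqrt(r_expect * (1 - r_expect) / 4000))
  # batch path (inter-locus Markov switches) agrees in law
  iv <- divselect:::chromosome_intervals(loci)
  set.seed(6)
  gm <- divselect:::recombine_batch(matrix(h1, 1, 2), matrix(h2, 1, 2),
                                    rep(1L, 40000), iv$chrom_split,
                                    iv$switch_prob)
  rec2 <- mean(gm[, 1] != gm[, 2])
  expect_lt(abs(rec2 - r_expect), 3 * sqrt(r_expect * (1 - r_expect) / 40000))
})

test_that("phenotypes are the scaled allelic sums plus residual noise", {
  f <- build_founders(n_P = 12, n_H = 0, h20 = 0.2, s2e = 1, seed = 7)
  L <- nrow(f$loci)
  all_plus <- matrix(1L, 1, L)
  v <- divselect:::genetic_values(all_plus, all_plus,
                                  2 * f$lambda * f$loci$effect)
  expect_equal(v, 2 * f$lambda * sum(f$loci$effect), tolerance = 1e-12)
  # heterozygote contributes zero under additivity
  het1 <- matrix(1L, 1, L); het0 <- matrix(0L, 1, L)
  expect_equal(divselect:::genetic_values(het1, het0,
                                          2 * f$lambda * f$loci$effect), 0)
  # complete dominance expresses the "+" homozygote value
  expect_equal(divselect:::genetic_values(het1, het0,
                                          2 * f$lambda * f$loci$effect,
                                          gene_action = "dominant"), v)
  # residual-only variance across clonal copies
  set.seed(8)
  phen <- v + rnorm(5000, 0, sqrt(2))
  expect_lt(abs(var(phen) - 2), 3 * 2 * sqrt(2 / 5000) * 2)
})

test_that("selfing without selection halves heterozygosity per generation", {
  ratios <- sapply(1:150, function(s) {
    f <- build_founders(40, 40, h20 = 0.3, s2e = 1, seed = 1000 + s)
    sim <- run_selection_sim(f, s2e = 1, n_offspring = 20, n_selected = 5,
                             G = 5, selection = "random", seed = 2000 + s)
    h <- sim$summary$heterozygosity
    h[-1] / h[-length(h)]
  })
  m <- rowMeans(ratios)
  se <- apply(ratios, 1, sd) / sqrt(ncol(ratios))
  expect_true(all(abs(m - 0.5) < 3 * se))
})

test_that("selfing conserves alleles and depletes variance under selection", {
  f <- build_founders(30, 30, h20 = 0.4, s2e = 1, seed = 9)
  sim <- run_selection_sim(f, s2e = 1, n_offspring = 30, n_selected = 5,
                           G = 6, seed = 10)
  # variance under the no-mutation null trends down, never re-inflates
  v <- sim$summary$var_genetic
  expect_lt(v[length(v)], v[1])
  # a locus fixed in the founders stays fixed: rerun with no heterozygous loci
  ffix <- build_founders(10, 0, h20 = 0.2, s2e = 1, seed = 11)
  simfix <- run_selection_sim(ffix, s2e = 1, n_offspring = 20,
                              n_selected = 4, G = 4, seed = 12)
  expect_true(all(simfix$summary$heterozygosity <= 1))
})

test_that("the first selection step obeys the breeder's equation", {
  res <- t(sapply(1:120, function(s) {
    f <- build_founders(60, 60, h20 = 0.5, s2e = 1, seed = 3000 + s)
    sim <- run_selection_sim(f, s2e = 1, n_offspring = 100, n_selected = 10,
                             G = 2, seed = 4000 + s)
    c(s2A = sim$summary$var_genetic[1],
      resp = mean(sim$Z$Z[sim$Z$generation == 2]))
  }))
  # finite-sample intensity oracle: mean of the top 10 of 200 normals
  set.seed(99)
  io <- mean(replicate(2000, mean(sort(rnorm(200), decreasing = TRUE)[1:10])))
  pred <- io * mean(res[, "s2A"]) / sqrt(mean(res[, "s2A"]) + 1)
  se <- sd(res[, "resp"]) / sqrt(nrow(res))
  expect_lt(abs(mean(res[, "resp"]) - pred), 4 * se)
})

test_that("identical seeds give bit-identical simulation results", {
  f <- build_founders(25, 15, h20 = 0.3, s2e = 2, seed = 13)
  s1 <- run_selection_sim(f, s2e = 2, n_offspring = 25, n_selected = 5,
                          G = 4, seed = 14)
  s2 <- run_selection_sim(f, s2e = 2, n_offspring = 25, n_selected = 5,
                          G = 4, seed = 14)
  expect_identical(s1$Z, s2$Z)
  expect_identical(s1$summary, s2$summary)
})

test_that("stored Z matrices reproduce the external response regression", {
  f <- build_founders(30, 20, h20 = 0.3, s2e = 1, seed = 15)
  sim <- run_selection_sim(f, s2e = 1, n_offspring = 30, n_selected = 5,
                           G = 6, seed = 16)
  ext <- response_slope(dplyr::transmute(sim$Z, population = "sim",
                                         generation, value = Z))
  expect_equal(sim_response_slope(sim), ext$slope, tolerance = 1e-12)
})

test_that("response distributions resample draws and tidy cleanly", {
  draws <- tibble::tibble(h20 = c(0.2, 0.3), s2e = c(2, 4))
  rd <- response_distribution(draws, n_sims = 6, n_P = 20, n_H = 12,
                              n_offspring = 20, n_selected = 4, G = 4,
                              keep_Z = TRUE, seed = 17)
  expect_equal(nrow(rd$results), 6)
  expect_true(all(rd$results$h20 %in% draws$h20))
  expect_s3_class(tidy(rd), "tbl_df")
  expect_false("Z" %in% names(tidy(rd)))
  expect_equal(glance(rd)$mean_slope, mean(rd$results$slope))
  expect_s3_class(autoplot(rd, observed = 0.4), "ggplot")
})

test_that("empirical P values count the nearer tail", {
  slopes <- seq(-1, 1, length.out = 201)
  expect_equal(empirical_pvalue(slopes, 0)$p_value, 101 / 201)
  beyond <- empirical_pvalue(slopes, 2)
  expect_equal(beyond$p_value, 0)
  expect_match(beyond$label, "^< ")
  expect_error(empirical_pvalue(slopes[1:50], 0), "100")
})
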