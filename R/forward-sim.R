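#' Genetic map for the forward simulator
#'
#' @param n_chromosomes Number of chromosomes.
#' @param length_cM Chromosome length in centimorgans (recycled).
#' @return A tibble of class `genetic_map` with `chromosome` and `length_cM`.
#' @export
genetic_map <- function(n_chromosomes = 10, length_cM = 150) {
  if (any(length_cM <= 0)) abort("chromosome lengths must be > 0")
  out <- tibble(chromosome = seq_len(n_chromosomes),
                length_cM = rep_len(length_cM, n_chromosomes))
  class(out) <- c("genetic_map", class(out))
  out
}

#' Build the two founder genomes of a simulated selection experiment
#'
#' Places `n_P` diallelic loci uniformly on the map; `n_H` of them are
#' heterozygous in both founders and the remaining `n_P - n_H` are fixed
#' differences between them. Allelic effects are drawn from an Exponential(1)
#' distribution with random sign, and rescaled by a coefficient `lambda` so
#' that the standing additive variance `sum_l 2 p_l (1 - p_l) (2 a_l
#' lambda)^2` (with `p_l` the frequency of the "+" allele over the four
#' founder haplotypes) equals the target `h20 * s2e`.
#'
#' @param n_P Number of polymorphic loci.
#' @param n_H Number of loci heterozygous in both founders (`<= n_P`).
#' @param h20 Target initial heritability (fraction of `s2e`).
#' @param s2e Residual variance.
#' @param map A [genetic_map()].
#' @param seed Optional seed.
#' @return A list of class `founder_set`: `loci` (tibble with `locus`,
#'   `chromosome`, `pos_cM`, `effect`), `lambda`, and `haplotypes`, a list of
#'   two 2-row 0/1 matrices (rows = haplotypes, columns = loci; 1 codes the
#'   "+" allele).
#' @export
build_founders <- function(n_P = 100, n_H = 60, h20, s2e,
                           map = genetic_map(), seed = NULL) {
  if (n_P < 1) abort("n_P must be >= 1")
  if (n_H < 0 || n_H > n_P) abort("n_H must be in [0, n_P]")
  target <- h20 * s2e
  if (target <= 0) abort("target initial variance h20 * s2e must be > 0")
  with_seed_if(seed, {
    chrom <- sample(map$chromosome, n_P, replace = TRUE)
    pos <- runif(n_P, 0, map$length_cM[match(chrom, map$chromosome)])
    a <- rexp(n_P) * sample(c(-1, 1), n_P, replace = TRUE)
    is_het <- sample(c(rep(TRUE, n_H), rep(FALSE, n_P - n_H)))
    zA <- rbinom(n_P, 1, 0.5) # fixed-difference allele carried by founder A
    h <- list(
      A = rbind(ifelse(is_het, 1L, zA), ifelse(is_het, 0L, zA)),
      B = rbind(ifelse(is_het, 1L, 1L - zA), ifelse(is_het, 0L, 1L - zA))
    )
  })
  ord <- order(chrom, pos)
  loci <- tibble(locus = seq_len(n_P), chromosome = chrom[ord],
                 pos_cM = pos[ord], effect = a[ord], het_in_founders = is_het[ord])
  h$A <- h$A[, ord, drop = FALSE]
  h$B <- h$B[, ord, drop = FALSE]
  p <- (colSums(h$A) + colSums(h$B)) / 4
  denom <- sum(2 * p * (1 - p) * (2 * loci$effect)^2)
  lambda <- sqrt(target / denom)
  structure(list(loci = loci, lambda = lambda, haplotypes = h,
                 n_P = n_P, n_H = n_H, map = map, target_s2A = target),
            class = "founder_set")
}

#' @export
print.founder_set <- function(x, ...) {
  cat("Founder set:", x$n_P, "loci (", x$n_H, "het in both founders ),",
      "lambda =", format(x$lambda, digits = 4), "\n")
  invisible(x)
}

#' Draw one gamete from a diploid genome
#'
#' Crossover positions on each chromosome follow a Poisson process of rate 1
#' per Morgan (sequential Exponential inter-arrival draws), with no
#' interference and an independent random starting haplotype per chromosome.
#'
#' @param h1,h2 Integer 0/1 haplotype vectors over the loci.
#' @param loci Locus table (from a [build_founders()] `founder_set`).
#' @return A 0/1 vector; attribute `n_crossovers` carries the total crossover
#'   count.
#' @export
gamete <- function(h1, h2, loci) {
  out <- integer(length(h1))
  n_co <- 0L
  for (ch in unique(loci$chromosome)) {
    idx <- which(loci$chromosome == ch)
    len <- max(loci$pos_cM[idx]) # positions beyond the last locus are inert
    xo <- numeric(0)
    pos <- 100 * rexp(1)
    while (pos <= len) {
      xo <- c(xo, pos)
      pos <- pos + 100 * rexp(1)
    }
    n_co <- n_co + length(xo)
    start <- sample(0:1, 1)
    phase <- (start + findInterval(loci$pos_cM[idx], xo)) %% 2
    out[idx] <- ifelse(phase == 0, h1[idx], h2[idx])
  }
  attr(out, "n_crossovers") <- n_co
  out
}

# Batch recombination for all gametes of a generation. Exploits the Markov
# property of the no-interference crossover process: the parental phase
# switches between adjacent loci at distance d Morgans with Haldane
# probability (1 - exp(-2d))/2, independently across intervals. Identical in
# law (at the loci) to drawing Poisson crossover positions.
recombine_batch <- function(H1, H2, parent_idx, chrom_split, switch_prob) {
  n_g <- length(parent_idx)
  out <- matrix(0L, n_g, ncol(H1))
  for (ci in seq_along(chrom_split)) {
    idx <- chrom_split[[ci]]
    Lc <- length(idx)
    start <- (runif(n_g) < 0.5) + 0
    if (Lc > 1) {
      r <- switch_prob[[ci]]
      sw <- (matrix(runif(n_g * (Lc - 1)), n_g) <
               matrix(r, n_g, Lc - 1, byrow = TRUE)) + 0
      U <- upper.tri(diag(Lc - 1), diag = TRUE) + 0
      phase <- (start + cbind(0, sw %*% U)) %% 2
    } else {
      phase <- matrix(start, n_g, 1)
    }
    out[, idx] <- H1[parent_idx, idx, drop = FALSE] * (1 - phase) +
      H2[parent_idx, idx, drop = FALSE] * phase
  }
  out
}

chromosome_intervals <- function(loci) {
  split_idx <- split(seq_len(nrow(loci)), loci$chromosome)
  switch_prob <- lapply(split_idx, function(idx) {
    d <- diff(loci$pos_cM[idx]) / 100
    (1 - exp(-2 * d)) / 2
  })
  list(chrom_split = split_idx, switch_prob = switch_prob)
}

genetic_values <- function(H1, H2, eff2, gene_action = "additive") {
  if (gene_action == "additive") {
    drop((H1 + H2 - 1) %*% eff2)
  } else {
    # complete dominance of the "+"-labelled allele
    drop((2 * pmin(H1 + H2, 1) - 1) %*% eff2)
  }
}

#' Forward simulation of divergent selection on standing variation
#'
#' Simulates the selection experiment under the no-mutation null: starting
#' from the two founders at generation 1, every selected individual is selfed
#' to produce `n_offspring` progeny (two gametes drawn per seed with
#' Poisson-process recombination), offspring are phenotyped as the sum of
#' their scaled allelic effects plus Gaussian noise, and the `n_selected`
#' most extreme phenotypes found the next generation. The mean offspring
#' phenotype `Z` of each selected individual (its progeny-test value, as in
#' the field trial) is recorded for generations `2..G`.
#'
#' @param founders A `founder_set` from [build_founders()].
#' @param s2e Residual variance used for phenotyping.
#' @param n_offspring Selfed offspring per selected individual.
#' @param n_selected Individuals selected per generation.
#' @param G Number of generations.
#' @param direction `"high"` selects the latest (largest) phenotypes,
#'   `"low"` the smallest.
#' @param gene_action `"additive"` or `"dominant"`.
#' @param selection `"truncation"` (default) or `"random"` (no selection;
#'   useful for neutral checks).
#' @param seed Optional seed.
#' @return A list of class `selection_sim`: `Z` (tibble `generation`, `k`,
#'   `Z`), `summary` (per-generation polymorphism and variance summaries),
#'   `lambda`, and the call settings.
#' @export
run_selection_sim <- function(founders, s2e, n_offspring = 100,
                              n_selected = 10, G = 7,
                              direction = c("high", "low"),
                              gene_action = c("additive", "dominant"),
                              selection = c("truncation", "random"),
                              seed = NULL) {
  direction <- match.arg(direction)
  gene_action <- match.arg(gene_action)
  selection <- match.arg(selection)
  stopifnot(inherits(founders, "founder_set"))
  loci <- founders$loci
  eff2 <- 2 * founders$lambda * loci$effect
  iv <- chromosome_intervals(loci)
  with_seed_if(seed, {
    H1 <- rbind(founders$haplotypes$A[1, ], founders$haplotypes$B[1, ])
    H2 <- rbind(founders$haplotypes$A[2, ], founders$haplotypes$B[2, ])
    z_rows <- list()
    sum_rows <- list()
    for (j in 2:(G + 1)) {
      n_par <- nrow(H1)
      parent_idx <- rep(seq_len(n_par), each = n_offspring)
      O1 <- recombine_batch(H1, H2, parent_idx, iv$chrom_split, iv$switch_prob)
      O2 <- recombine_batch(H1, H2, parent_idx, iv$chrom_split, iv$switch_prob)
      if (nrow(O1) == 0) abort("population went extinct")
      g_val <- genetic_values(O1, O2, eff2, gene_action)
      phen <- g_val + rnorm(length(g_val), 0, sqrt(s2e))
      if (j >= 3) {
        # progeny-test value of each individual selected at generation j - 1
        z_rows[[length(z_rows) + 1]] <- tibble(
          generation = j - 1L, k = seq_len(n_par),
          Z = as.numeric(tapply(phen, parent_idx, mean))
        )
      }
      if (j > G) break
      keep <- if (selection == "random") {
        sample(length(phen), n_selected)
      } else {
        ord <- order(phen, runif(length(phen)),
                     decreasing = (direction == "high"))
        ord[seq_len(n_selected)]
      }
      H1 <- O1[keep, , drop = FALSE]
      H2 <- O2[keep, , drop = FALSE]
      het <- mean(H1 != H2)
      seg <- mean(colSums(rbind(H1, H2)) %% (2 * n_selected) != 0)
      sum_rows[[length(sum_rows) + 1]] <- tibble(
        generation = j, n_candidates = length(phen),
        mean_genetic = mean(g_val), var_genetic = stats::var(g_val),
        heterozygosity = het, prop_segregating = seg
      )
    }
  })
  structure(
    list(Z = bind_rows(z_rows), summary = bind_rows(sum_rows),
         lambda = founders$lambda,
         settings = list(s2e = s2e, n_offspring = n_offspring,
                         n_selected = n_selected, G = G,
                         direction = direction, gene_action = gene_action,
                         selection = selection, seed = seed,
                         n_P = founders$n_P, n_H = founders$n_H)),
    class = "selection_sim")
}

#' @export
print.selection_sim <- function(x, ...) {
  cat("Forward selection simulation:", x$settings$G, "generations,",
      x$settings$n_P, "loci; response slope",
      format(sim_response_slope(x), digits = 3), "\n")
  invisible(x)
}

#' Response slope of a simulated experiment
#'
#' OLS slope of the per-individual progeny means `Z` on the generation
#' number, the simulated analogue of the field response regression.
#'
#' @param sim A `selection_sim`.
#' @return Slope (trait units per generation).
#' @export
sim_response_slope <- function(sim) {
  unname(coef(lm(Z ~ generation, data = sim$Z))["generation"])
}

#' Null distribution of response slopes under standing variation only
#'
#' Repeats [run_selection_sim()] with `(h20, s2e)` pairs drawn from an
#' empirical distribution (typically the converged draws of a model-2
#' [fit_heritability()]), and collects the response slope of each run.
#'
#' @param draws A data frame with columns `h20` and `s2e`; one row is
#'   resampled per simulation.
#' @param n_sims Number of simulations.
#' @param n_P,n_H,map Founder configuration, see [build_founders()].
#' @param n_offspring,n_selected,G,direction,gene_action Passed to
#'   [run_selection_sim()].
#' @param keep_Z Keep each run's `Z` table (needed for
#'   [breakpoint_histogram()])?
#' @param seed Optional seed.
#' @return A list of class `sim_response_dist`: `results` (tibble with one
#'   row per simulation: `sim`, `h20`, `s2e`, `slope`, and optionally a `Z`
#'   list-column), `mean_slope` and the 2.5/97.5 percentile interval.
#' @export
response_distribution <- function(draws, n_sims = 500, n_P = 100, n_H = 60,
                                  map = genetic_map(), n_offspring = 100,
                                  n_selected = 10, G = 7,
                                  direction = "high",
                                  gene_action = "additive",
                                  keep_Z = TRUE, seed = NULL) {
  if (n_sims < 2) abort("n_sims must be >= 2")
  stopifnot(all(c("h20", "s2e") %in% names(draws)))
  draws <- as_tibble(draws) %>% filter(.data$h20 > 0, .data$s2e > 0)
  with_seed_if(seed, {
    picks <- draws[sample(nrow(draws), n_sims, replace = TRUE), ]
    res <- purrr::map_dfr(seq_len(n_sims), function(s) {
      f <- build_founders(n_P, n_H, h20 = picks$h20[s], s2e = picks$s2e[s],
                          map = map)
      run <- run_selection_sim(f, s2e = picks$s2e[s],
                               n_offspring = n_offspring,
                               n_selected = n_selected, G = G,
                               direction = direction,
                               gene_action = gene_action)
      slope_s <- sim_response_slope(run)
      z_s <- if (keep_Z) list(run$Z) else list(NULL)
      tibble(sim = s, h20 = picks$h20[s], s2e = picks$s2e[s],
             slope = slope_s, Z = z_s)
    })
  })
  structure(
    list(results = res, mean_slope = mean(res$slope),
         interval = unname(quantile(res$slope, c(0.025, 0.975))),
         settings = list(n_sims = n_sims, n_P = n_P, n_H = n_H,
                         direction = direction, gene_action = gene_action,
                         seed = seed)),
    class = "sim_response_dist")
}

#' @export
print.sim_response_dist <- function(x, ...) {
  cat(sprintf(
    "Simulated response distribution (%d runs): mean %.3f (%.3f-%.3f)\n",
    nrow(x$results), x$mean_slope, x$interval[1], x$interval[2]))
  invisible(x)
}

#' @export
tidy.sim_response_dist <- function(x, ...) x$results %>% select(-dplyr::any_of("Z"))

#' @export
glance.sim_response_dist <- function(x, ...) {
  tibble(n_sims = nrow(x$results), mean_slope = x$mean_slope,
         conf.low = x$interval[1], conf.high = x$interval[2])
}

#' @export
autoplot.sim_response_dist <- function(object, observed = NULL, ...) {
  p <- ggplot2::ggplot(object$results, ggplot2::aes(x = .data$slope)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey35") +
    ggplot2::labs(x = "response slope (days / generation)", y = "simulations") +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_vline(xintercept = observed, colour = "red")
  }
  p
}

#' Empirical P value of an observed response against simulated slopes
#'
#' One-sided tail fraction on the side where the observed response falls:
#' `P = min(#slopes <= R_obs, #slopes >= R_obs) / n`.
#'
#' @param slopes Numeric vector of simulated slopes (>= 100), or a
#'   `sim_response_dist`.
#' @param R_obs Observed response slope.
#' @return A one-row tibble with `p_value`, `n_sims`, and a printable
#'   `label` (`"< 1/n"` when the observation is beyond every slope).
#' @export
empirical_pvalue <- function(slopes, R_obs) {
  if (inherits(slopes, "sim_response_dist")) slopes <- slopes$results$slope
  n <- length(slopes)
  if (n < 100) abort("need at least 100 simulated slopes")
  p <- min(sum(slopes <= R_obs), sum(slopes >= R_obs)) / n
  tibble(p_value = p, n_sims = n,
         label = if (p == 0) paste0("< ", format(1 / n, digits = 2))
                 else format(p, digits = 3))
}
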