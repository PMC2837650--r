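#' Mendelian selfing transition weights
#'
#' Genotype distribution of a selfed offspring (or a descendant `steps`
#' generations down a selfing chain) given the parent's genotype at a
#' diallelic locus. Reversion (mutation) is neglected, so homozygotes breed
#' true and a heterozygote segregates 1/4 : 1/2 : 1/4.
#'
#' @param parent `"hom_ref"`, `"het"` or `"hom_alt"` (equivalently 0, 1, 2
#'   alt-allele copies).
#' @param steps Number of selfing generations (>= 1).
#' @return A named numeric vector of probabilities over
#'   `c(hom_ref, het, hom_alt)`.
#' @examples
#' mendelian_weights("het")            # 0.25 0.50 0.25
#' mendelian_weights("het", steps = 2) # 0.375 0.25 0.375
#' @export
mendelian_weights <- function(parent, steps = 1) {
  Tm <- selfing_transition()
  code <- genotype_code(parent)
  v <- c(0, 0, 0); v[code + 1] <- 1
  for (s in seq_len(steps)) v <- drop(v %*% Tm)
  setNames(v, c("hom_ref", "het", "hom_alt"))
}

selfing_transition <- function() {
  matrix(c(1, 0, 0,
           0.25, 0.5, 0.25,
           0, 0, 1), 3, 3, byrow = TRUE,
         dimnames = list(c("hom_ref", "het", "hom_alt"),
                         c("hom_ref", "het", "hom_alt")))
}

genotype_code <- function(g) {
  if (is.character(g) || is.factor(g)) {
    m <- c(hom_ref = 0L, het = 1L, hom_alt = 2L)
    out <- m[as.character(g)]
    if (anyNA(out) && !all(is.na(g))) abort("unknown genotype label")
    unname(out)
  } else {
    as.integer(g)
  }
}

#' Additive and dominance effects of a candidate locus along a genealogy
#'
#' Regresses generation-centred genotypic values on the genotype indicator
#' pair `(x, y)` with `x = -1/0/+1` for hom-ref/het/hom-alt and `y = 1` for
#' heterozygotes: `G_jk - mu_j = a x_k + d y_k + e_k`, where `mu_j` is the
#' mean trait value over all individuals of generation `j`. Missing
#' genotypes are handled by triplicating the individual over the three
#' genotype classes, weighted by the Mendelian transition probabilities from
#' its nearest genotyped ancestor; missing trait values are imputed by the
#' same-subfamily, same-generation mean when a `subfamily` column is present
#' (same-generation mean otherwise).
#'
#' @param data A tibble with columns `id`, `generation`, `genotype` (0/1/2
#'   counts of the alternative allele, or labels, `NA` allowed), `value`
#'   (genotypic value, `NA` allowed), and optionally `subfamily`.
#' @param pedigree A pedigree (needed only when genotypes are missing).
#' @return An object of class `assoc_fit` with elements `a`, `d`,
#'   `r_squared`, `n`, and the expanded regression rows in `$rows`.
#' @export
estimate_additive_dominance <- function(data, pedigree = NULL) {
  data <- as_tibble(data)
  stopifnot(all(c("id", "generation", "genotype", "value") %in% names(data)))
  data$genotype <- genotype_code(data$genotype)
  # impute missing trait values from subfamily (or generation) means
  grp <- if ("subfamily" %in% names(data)) {
    c("generation", "subfamily")
  } else {
    "generation"
  }
  data <- data %>%
    group_by(across(dplyr::all_of(grp))) %>%
    mutate(value = dplyr::coalesce(.data$value,
                                   mean(.data$value, na.rm = TRUE))) %>%
    ungroup()
  if (anyNA(data$value)) abort("trait values missing for a whole subfamily")
  mu <- data %>%
    group_by(.data$generation) %>%
    summarise(mu_j = mean(.data$value), .groups = "drop")
  data <- data %>% left_join(mu, by = "generation") %>%
    mutate(r = .data$value - .data$mu_j)

  known <- data %>% filter(!is.na(.data$genotype)) %>%
    mutate(w = 1, geno = .data$genotype)
  miss <- data %>% filter(is.na(.data$genotype))
  miss_rows <- NULL
  if (nrow(miss) > 0) {
    if (is.null(pedigree)) {
      abort("missing genotypes require a pedigree to derive Mendelian weights")
    }
    parent_of <- setNames(pedigree$parent_id, pedigree$id)
    geno_of <- setNames(data$genotype, data$id)
    miss_rows <- purrr::map_dfr(seq_len(nrow(miss)), function(r) {
      ind <- miss$id[r]
      anc <- parent_of[[ind]]
      steps <- 1L
      while (!is.na(anc) && (!anc %in% names(geno_of) ||
                             is.na(geno_of[[anc]]))) {
        anc <- parent_of[[anc]]
        steps <- steps + 1L
      }
      if (is.na(anc)) {
        abort(paste0("no genotyped ancestor for individual ", ind))
      }
      w <- mendelian_weights(geno_of[[anc]], steps)
      miss[r, ] %>%
        select(-"genotype") %>%
        tidyr::expand_grid(geno = 0:2) %>%
        mutate(w = as.numeric(w))
    })
  }
  rows <- bind_rows(known %>% select(-"genotype"), miss_rows) %>%
    filter(.data$w > 0) %>%
    mutate(x = .data$geno - 1, y = as.numeric(.data$geno == 1))
  if (dplyr::n_distinct(rows$x) < 2) {
    abort("all genotypes identical: additive effect not estimable")
  }
  # the intercept absorbs the part of the genotype effects already carried by
  # the generation means, so constructed effects are recovered exactly
  fit <- lm(r ~ x + y, data = rows, weights = rows$w)
  a <- unname(coef(fit)["x"]); d <- unname(coef(fit)["y"])
  rbar <- stats::weighted.mean(rows$r, rows$w)
  r2 <- 1 - sum(rows$w * resid(fit)^2) / sum(rows$w * (rows$r - rbar)^2)
  structure(list(a = a, d = d, r_squared = r2,
                 n = dplyr::n_distinct(data$id), rows = rows),
            class = "assoc_fit")
}

#' @export
print.assoc_fit <- function(x, ...) {
  cat(sprintf("Candidate-locus association: a = %.3f, d = %.3f, R2 = %.2f (n = %d)\n",
              x$a, x$d, x$r_squared, x$n))
  invisible(x)
}

#' @export
tidy.assoc_fit <- function(x, ...) {
  tibble(term = c("additive", "dominance"), estimate = c(x$a, x$d))
}

#' @export
glance.assoc_fit <- function(x, ...) {
  tibble(a = x$a, d = x$d, r_squared = x$r_squared, n = x$n)
}

#' Simulate Mendelian gene dropping through a selfing pedigree
#'
#' Drops the two alleles of the designated heterozygous founders through the
#' genealogy: every other founder is homozygous reference, homozygotes breed
#' true, and each offspring of a heterozygote draws its genotype from the
#' 1/4 : 1/2 : 1/4 selfing segregation.
#'
#' @param pedigree A pedigree.
#' @param founders Ids of the heterozygous founders.
#' @param n_sims Number of independent drops.
#' @param seed Optional seed.
#' @return An integer matrix (individuals x simulations; rownames are ids)
#'   of 0/1/2 alt-allele counts.
#' @export
gene_drop_genotypes <- function(pedigree, founders, n_sims, seed = NULL) {
  stopifnot(inherits(pedigree, "pedigree"))
  unknown <- setdiff(founders, pedigree$id)
  if (length(unknown) > 0) {
    abort(paste0("unknown founder id(s): ", paste(unknown, collapse = ", ")))
  }
  ord <- pedigree %>% arrange(.data$generation)
  id_pos <- setNames(seq_len(nrow(ord)), ord$id)
  with_seed_if(seed, {
    g <- matrix(0L, nrow(ord), n_sims,
                dimnames = list(ord$id, NULL))
    for (i in seq_len(nrow(ord))) {
      if (ord$id[i] %in% founders) {
        g[i, ] <- 1L
        next
      }
      p <- ord$parent_id[i]
      if (!is.na(p)) {
        pg <- g[id_pos[[p]], ]
        het <- pg == 1L
        g[i, ] <- pg
        if (any(het)) {
          g[i, het] <- sample(0:2, sum(het), replace = TRUE,
                              prob = c(0.25, 0.5, 0.25))
        }
      }
    }
    g
  })
}

#' Gene-dropping null distribution for a candidate-locus association
#'
#' Tests whether an observed additive (and dominance) effect could arise
#' from random Mendelian segregation along the fixed genealogy. Each
#' simulation drops the two alleles of the designated heterozygous founders
#' through the pedigree by selfing transitions (all other founders are
#' homozygous reference), re-estimates `(a, d)` against the fixed observed
#' trait values, and the one-tailed empirical P value counts simulations at
#' least as extreme as the observation in its direction.
#'
#' @param data Observed association table as in
#'   [estimate_additive_dominance()].
#' @param pedigree A pedigree covering all individuals in `data`.
#' @param founders Ids of the founders assumed heterozygous.
#' @param n_sims Number of gene-dropping simulations (>= 1000).
#' @param seed Optional seed.
#' @return An object of class `gene_drop_test`: observed `a_obs`, `d_obs`,
#'   the null draws in `$null` (tibble `sim`, `a`, `d`), and `p_a`, `p_d`.
#' @export
gene_drop_null <- function(data, pedigree, founders, n_sims = 20000,
                           seed = NULL) {
  if (length(founders) < 1) abort("specify at least one heterozygous founder")
  if (n_sims < 1000) abort("n_sims must be >= 1000")
  stopifnot(inherits(pedigree, "pedigree"))
  data <- as_tibble(data)
  obs <- estimate_additive_dominance(data, pedigree)

  if (!all(data$id %in% pedigree$id)) {
    abort("data contains ids not in the pedigree")
  }
  geno <- gene_drop_genotypes(pedigree, founders, n_sims, seed)
  id_pos <- setNames(seq_len(nrow(geno)), rownames(geno))

  # fixed phenotypic side: the generation-centred (and, where needed,
  # imputed) values used by the observed fit
  vals <- obs$rows %>% distinct(.data$id, .data$r)
  keep <- id_pos[vals$id]
  gm <- geno[keep, , drop = FALSE]
  n_ind <- nrow(gm)
  # centred closed form, equivalent to the with-intercept regression of the
  # observed fit
  x <- gm - 1
  y <- (gm == 1L) + 0
  x <- sweep(x, 2, colMeans(x))
  y <- sweep(y, 2, colMeans(y))
  r <- vals$r - mean(vals$r)
  sxx <- colSums(x * x); syy <- colSums(y * y); sxy <- colSums(x * y)
  sxr <- colSums(x * r); syr <- colSums(y * r)
  det <- sxx * syy - sxy^2
  eps <- 1e-10
  full <- det > eps
  a <- rep(NA_real_, n_sims); d <- rep(NA_real_, n_sims)
  a[full] <- (syy[full] * sxr[full] - sxy[full] * syr[full]) / det[full]
  d[full] <- (sxx[full] * syr[full] - sxy[full] * sxr[full]) / det[full]
  # when an effect's regressor is constant (e.g. no heterozygote left) the
  # other effect is still defined by simple regression
  ax_only <- !full & sxx > eps
  a[ax_only] <- sxr[ax_only] / sxx[ax_only]
  dy_only <- !full & syy > eps & sxx <= eps
  d[dy_only] <- syr[dy_only] / syy[dy_only]
  null <- tibble(sim = seq_len(n_sims), a = a, d = d)
  tail_p <- function(obs_val, null_val) {
    # the dominance effect is inestimable when no heterozygote was observed
    if (is.na(obs_val)) return(NA_real_)
    null_val <- null_val[!is.na(null_val)]
    if (obs_val >= 0) mean(null_val >= obs_val) else mean(null_val <= obs_val)
  }
  structure(
    list(a_obs = obs$a, d_obs = obs$d, r_squared_obs = obs$r_squared,
         null = null, p_a = tail_p(obs$a, null$a),
         p_d = tail_p(obs$d, null$d),
         n_sims = n_sims, n_degenerate_a = sum(is.na(a)),
         n_degenerate_d = sum(is.na(d)), seed = seed),
    class = "gene_drop_test")
}

#' @export
print.gene_drop_test <- function(x, ...) {
  cat(sprintf(
    "Gene-dropping test (%d sims): a_obs = %.3f (one-tailed p = %.2g), d_obs = %.3f (p = %.2g)\n",
    x$n_sims, x$a_obs, x$p_a, x$d_obs, x$p_d))
  invisible(x)
}

#' @export
tidy.gene_drop_test <- function(x, ...) {
  tibble(term = c("additive", "dominance"),
         estimate = c(x$a_obs, x$d_obs),
         p.value = c(x$p_a, x$p_d))
}

#' @export
autoplot.gene_drop_test <- function(object, ...) {
  ggplot2::ggplot(object$null, ggplot2::aes(x = .data$a)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey35") +
    ggplot2::geom_vline(xintercept = object$a_obs, colour = "red") +
    ggplot2::labs(x = "additive effect under gene dropping",
                  y = "simulations") +
    ggplot2::theme_minimal()
}

#' Neutral drift exceedance probability for an allele frequency
#'
#' Simulates pure-drift allele-frequency trajectories by per-generation
#' binomial resampling of gene copies (twice the rounded effective size per
#' generation under the default diploid interpretation) and reports the
#' probability that the final frequency reaches a threshold.
#'
#' @param f0 Initial allele frequency.
#' @param Ne Per-generation effective sizes (length = number of
#'   generations).
#' @param threshold Frequency threshold for the exceedance probability.
#' @param n_sims Number of trajectories.
#' @param ploidy `"diploid"` resamples `2 * round(Ne)` gene copies,
#'   `"haploid"` uses `round(Ne)`.
#' @param seed Optional seed.
#' @return An object of class `drift_sim`: `prob` = P(f_G >= threshold),
#'   the vector of final frequencies in `$f_final`, and the settings.
#' @export
drift_exceedance <- function(f0, Ne, threshold, n_sims = 10000,
                             ploidy = c("diploid", "haploid"), seed = NULL) {
  ploidy <- match.arg(ploidy)
  if (f0 < 0 || f0 > 1) abort("f0 must be in [0, 1]")
  copies <- round(Ne) * if (ploidy == "diploid") 2 else 1
  if (any(copies < 1)) abort("effective sizes too small after rounding")
  f <- with_seed_if(seed, {
    fr <- rep(f0, n_sims)
    for (m in copies) fr <- rbinom(n_sims, m, fr) / m
    fr
  })
  structure(list(prob = mean(f >= threshold), f_final = f, f0 = f0,
                 Ne = Ne, copies = copies, threshold = threshold,
                 n_sims = n_sims, ploidy = ploidy, seed = seed),
            class = "drift_sim")
}

#' @export
print.drift_sim <- function(x, ...) {
  cat(sprintf(
    "Drift exceedance: P(f_%d >= %.3g | f_0 = %.3g) = %.4g (%d trajectories)\n",
    length(x$Ne), x$threshold, x$f0, x$prob, x$n_sims))
  invisible(x)
}

#' @export
glance.drift_sim <- function(x, ...) {
  tibble(prob = x$prob, f0 = x$f0, threshold = x$threshold,
         generations = length(x$Ne), n_sims = x$n_sims, ploidy = x$ploidy)
}
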