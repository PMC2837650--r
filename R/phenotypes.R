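#' Estimate environmental effects from control plots
#'
#' Field-trial phenotypes are corrected with repeated control plots (the
#' initial inbred line sown throughout the design). Control values are
#' decomposed by least squares into a grand mean, year effects, sub-block
#' within year effects and seed-lot effects, all under sum-to-zero
#' parameterisation (sub-block effects sum to zero within each year).
#'
#' @param obs A tibble of plot observations with columns `genotype_id`,
#'   `year`, `block`, `sub_block`, `value`, `is_control`, `seed_lot`.
#' @return An object of class `control_effects`: a list with `mu_control`,
#'   `year_effects`, `subblock_effects`, `seedlot_effects` (tibbles) and the
#'   residual variance `sigma2`.
#' @export
estimate_control_effects <- function(obs) {
  needed <- c("year", "sub_block", "value", "is_control", "seed_lot")
  missing_cols <- setdiff(needed, names(obs))
  if (length(missing_cols) > 0) {
    abort(paste0("observations are missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  obs <- as_tibble(obs)
  ctl <- obs %>% filter(.data$is_control)
  cover <- obs %>%
    distinct(.data$year, .data$sub_block) %>%
    left_join(ctl %>% count(.data$year, .data$sub_block),
              by = c("year", "sub_block")) %>%
    mutate(n = dplyr::coalesce(.data$n, 0L))
  if (any(cover$n == 0)) {
    bad <- cover %>% filter(.data$n == 0)
    abort(paste0("sub-block(s) without control plots: ",
                 paste(paste(bad$year, bad$sub_block, sep = "/"),
                       collapse = ", ")))
  }
  if (any(cover$n == 1)) {
    warn("some sub-blocks have a single control plot; effects will be noisy")
  }
  ctl <- ctl %>%
    mutate(.ysb = interaction(.data$year, .data$sub_block, drop = TRUE),
           .lot = factor(.data$seed_lot))
  fit <- if (nlevels(ctl$.lot) > 1) {
    lm(value ~ .ysb + .lot, data = ctl)
  } else {
    lm(value ~ .ysb, data = ctl)
  }
  # read effects off cell predictions so the decomposition is contrast-free
  grid <- tidyr::expand_grid(
    .ysb = factor(levels(ctl$.ysb), levels = levels(ctl$.ysb)),
    .lot = factor(levels(ctl$.lot), levels = levels(ctl$.lot))
  )
  grid$pred <- predict(fit, newdata = grid)
  key <- ctl %>% distinct(.data$.ysb, .data$year, .data$sub_block)
  grid <- grid %>% left_join(key, by = ".ysb")
  cell <- grid %>%
    group_by(.data$year, .data$sub_block) %>%
    summarise(pred = mean(.data$pred), .groups = "drop")
  year_means <- cell %>%
    group_by(.data$year) %>%
    summarise(m = mean(.data$pred), .groups = "drop")
  mu <- mean(year_means$m)
  year_effects <- year_means %>%
    mutate(effect = .data$m - mu) %>% select("year", "effect")
  subblock_effects <- cell %>%
    left_join(year_means, by = "year") %>%
    mutate(effect = .data$pred - .data$m) %>%
    select("year", "sub_block", "effect")
  lot_means <- grid %>%
    group_by(seed_lot = as.character(.data$.lot)) %>%
    summarise(m = mean(.data$pred), .groups = "drop")
  seedlot_effects <- lot_means %>%
    mutate(effect = .data$m - mean(.data$m)) %>% select("seed_lot", "effect")
  structure(
    list(mu_control = mu, year_effects = year_effects,
         subblock_effects = subblock_effects,
         seedlot_effects = seedlot_effects,
         sigma2 = summary(fit)$sigma^2, n_controls = nrow(ctl)),
    class = "control_effects"
  )
}

#' @export
print.control_effects <- function(x, ...) {
  cat("Control-plot effects: mean", format(x$mu_control, digits = 4),
      "| residual sd", format(sqrt(x$sigma2), digits = 3),
      "|", nrow(x$subblock_effects), "sub-blocks\n")
  invisible(x)
}

#' @export
tidy.control_effects <- function(x, ...) {
  bind_rows(
    tibble(term = "mu_control", year = NA_character_, sub_block = NA_character_,
           estimate = x$mu_control),
    x$year_effects %>%
      mutate(term = "year", year = as.character(.data$year),
             sub_block = NA_character_, estimate = .data$effect) %>%
      select("term", "year", "sub_block", "estimate"),
    x$subblock_effects %>%
      mutate(term = "sub_block", year = as.character(.data$year),
             sub_block = as.character(.data$sub_block),
             estimate = .data$effect) %>%
      select("term", "year", "sub_block", "estimate")
  )
}

#' Correct plot phenotypes with control-plot effects
#'
#' Subtracts the fitted year and sub-block effects from every non-control
#' plot: `Z = value - year_effect - subblock_effect`. Control rows are
#' dropped from the output.
#'
#' @param obs Plot observations (see [estimate_control_effects()]).
#' @param fx A `control_effects` object fitted on the same design.
#' @return The non-control rows of `obs` with an added column `Z`.
#' @export
correct_phenotypes <- function(obs, fx) {
  stopifnot(inherits(fx, "control_effects"))
  dat <- as_tibble(obs) %>% filter(!.data$is_control)
  eff <- fx$subblock_effects %>%
    left_join(fx$year_effects %>% rename(year_effect = "effect"),
              by = "year") %>%
    rename(subblock_effect = "effect")
  out <- dat %>% left_join(eff, by = c("year", "sub_block"))
  if (any(is.na(out$subblock_effect))) {
    bad <- out %>% filter(is.na(.data$subblock_effect)) %>%
      distinct(.data$year, .data$sub_block)
    abort(paste0("no fitted effects for sub-block(s): ",
                 paste(paste(bad$year, bad$sub_block, sep = "/"),
                       collapse = ", ")))
  }
  out %>%
    mutate(Z = .data$value - .data$year_effect - .data$subblock_effect) %>%
    select(-"year_effect", -"subblock_effect")
}

#' Genotypic values, variance components and heritabilities
#'
#' Fits corrected phenotypes by fixed-effect least squares with year and
#' block-within-year effects plus a genotype term, and reads genotypic values
#' off as least-squares means. Within each (population, generation) cell the
#' genetic variance is estimated by method of moments as the variance of the
#' genotypic values minus their estimation noise, and the broad-sense
#' heritability is `h2 = s2G / (s2G + s2e)`.
#'
#' @param z Corrected observations: columns `genotype_id`, `year`, `block`,
#'   `population`, `generation`, `Z`.
#' @param clamp If `TRUE` (default), negative genetic-variance estimates are
#'   clamped to zero before the heritability ratio.
#' @param correct_noise If `TRUE` (default), subtract the sampling variance of
#'   the genotypic-value estimates (`s2e` / plots per genotype) from the
#'   between-genotype variance; this is what allows negative estimates.
#' @return An object of class `genvalue_fit`: list with `values` (one row per
#'   genotype) and `cells` (one row per population x generation with `mean`,
#'   `s2G`, `s2e`, `h2`).
#' @export
fit_genotypic_values <- function(z, clamp = TRUE, correct_noise = TRUE) {
  needed <- c("genotype_id", "year", "block", "population", "generation", "Z")
  missing_cols <- setdiff(needed, names(z))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  z <- as_tibble(z) %>%
    mutate(.g = factor(.data$genotype_id),
           .yb = interaction(.data$year, .data$block, drop = TRUE))
  cells_by_geno <- z %>% distinct(.data$genotype_id, .data$population,
                                  .data$generation)
  if (any(duplicated(cells_by_geno$genotype_id))) {
    abort("a genotype_id maps to more than one (population, generation)")
  }
  fit <- if (nlevels(z$.yb) > 1 && nlevels(z$.g) > 1) {
    lm(Z ~ 0 + .g + .yb, data = z)
  } else if (nlevels(z$.g) > 1) {
    lm(Z ~ 0 + .g, data = z)
  } else if (nlevels(z$.yb) > 1) {
    lm(Z ~ .yb, data = z)
  } else {
    lm(Z ~ 1, data = z)
  }
  if (anyNA(coef(fit)[grep("^\\.g", names(coef(fit)))])) {
    abort("singular design: some genotypes are not estimable")
  }
  grid <- tidyr::expand_grid(
    .g = factor(levels(z$.g), levels = levels(z$.g)),
    .yb = factor(levels(z$.yb), levels = levels(z$.yb))
  )
  grid$pred <- predict(fit, newdata = grid)
  gvals <- grid %>%
    group_by(genotype_id = as.character(.data$.g)) %>%
    summarise(value = mean(.data$pred), .groups = "drop") %>%
    left_join(cells_by_geno, by = "genotype_id") %>%
    left_join(z %>% count(genotype_id = as.character(.data$.g)), by = "genotype_id")
  s2e <- summary(fit)$sigma^2
  cells <- gvals %>%
    group_by(.data$population, .data$generation) %>%
    summarise(
      mean = mean(.data$value),
      s2G_raw = if (n() > 1) {
        stats::var(.data$value) -
          (if (correct_noise) s2e * mean(1 / .data$n) else 0)
      } else NA_real_,
      n_genotypes = n(), .groups = "drop"
    ) %>%
    mutate(s2e = s2e,
           s2G = if (clamp) pmax(.data$s2G_raw, 0) else .data$s2G_raw,
           h2 = population_heritability(.data$s2G, .data$s2e, clamp = clamp))
  structure(list(values = gvals %>% select(-"n"), cells = cells, s2e = s2e),
            class = "genvalue_fit")
}

#' @export
print.genvalue_fit <- function(x, ...) {
  cat("Genotypic-value fit:", nrow(x$values), "genotypes,",
      nrow(x$cells), "population x generation cells, residual sd",
      format(sqrt(x$s2e), digits = 3), "\n")
  invisible(x)
}

#' @export
tidy.genvalue_fit <- function(x, ...) x$values

#' @export
glance.genvalue_fit <- function(x, ...) x$cells

#' Within-population broad-sense heritability
#'
#' `h2 = s2G / (s2G + s2e)`. With `clamp = TRUE` negative genetic-variance
#' estimates are truncated at zero first, bounding the result in \[0, 1\].
#'
#' @param s2G Genetic variance (may be negative when `clamp = FALSE`).
#' @param s2e Residual variance (> 0).
#' @param clamp Truncate negative `s2G` at zero?
#' @return Heritability (vectorised).
#' @export
population_heritability <- function(s2G, s2e, clamp = TRUE) {
  if (any(s2e <= 0, na.rm = TRUE)) abort("s2e must be > 0")
  if (clamp) s2G <- pmax(s2G, 0)
  s2G / (s2G + s2e)
}

#' Response to selection as a regression slope
#'
#' Ordinary least-squares regression of genotypic values on the generation of
#' selection, fitted separately within each population.
#'
#' @param values A tibble with columns `population`, `generation` and `value`
#'   (genotypic values on the corrected scale).
#' @return A tibble of class `response_estimate` with one row per population:
#'   `slope` (days per generation), `se`, `intercept`, `n`.
#' @export
response_slope <- function(values) {
  stopifnot(all(c("population", "generation", "value") %in% names(values)))
  out <- as_tibble(values) %>%
    group_by(.data$population) %>%
    group_modify(function(d, key) {
      if (dplyr::n_distinct(d$generation) < 2) {
        abort("need at least 2 distinct generations to estimate a response")
      }
      f <- lm(value ~ generation, data = d)
      s <- summary(f)$coefficients
      tibble(slope = s["generation", "Estimate"],
             se = s["generation", "Std. Error"],
             intercept = s["(Intercept)", "Estimate"],
             n = nrow(d))
    }) %>%
    ungroup()
  class(out) <- c("response_estimate", class(out))
  out
}
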