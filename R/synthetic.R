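#' Specification of a synthetic divergent-selection experiment
#'
#' Collects every parameter of the synthetic-data generator with defaults
#' that emulate the real experimental design: two inbred seed lots (an
#' F252-like line with control mean 22 days and residual sd 0.90, an
#' MBS-like line with mean 35 and sd 0.56), divergent Early/Late truncation
#' selection over 7 generations with 10 selected individuals each evaluated
#' through 100 selfed offspring, a 2-year x 2-block evaluation trial with
#' sub-blocks and duplicated control plots, residual heterozygote frequency
#' 0.032 at a candidate locus, and optional per-generation mutational input.
#'
#' @param lines A tibble with columns `line`, `control_mean`, `sd_e`.
#' @param G Generations of selection.
#' @param n_founders Seed-lot individuals sown at generation 0.
#' @param n_founder_selected Founders selected into each population.
#' @param n_selected Individuals selected per population per generation.
#' @param n_offspring Selfed offspring evaluated per selected individual.
#' @param h20 True initial heritability (standing variance / `s2e`).
#' @param h2m True mutational heritability (per-generation input / `s2e`).
#' @param het_freq Residual heterozygote frequency at the candidate locus.
#' @param major_locus `NULL`, or `list(a = , d = )`: additive/dominance
#'   effect (days) of a candidate locus segregating from a heterozygous
#'   Late founder.
#' @param years,blocks Labels of the evaluation-trial years and blocks.
#' @param subblock_size Genotype plots per sub-block.
#' @param year_sd,subblock_sd Standard deviations of the simulated
#'   year and sub-block environmental effects (days).
#' @param seedlot_offset Offset of the commercial versus initial control
#'   seed lot (days).
#' @param family_cap Maximum selected per family (`Inf` to disable, the
#'   default; the real scheme used 3).
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(lines = tibble(line = c("F252", "MBS"),
                                        control_mean = c(22, 35),
                                        sd_e = c(0.90, 0.56)),
                         G = 7, n_founders = 60, n_founder_selected = 3,
                         n_selected = 10, n_offspring = 100,
                         h20 = 0.05, h2m = 0.02, het_freq = 0.032,
                         major_locus = NULL,
                         years = c("2004", "2005"), blocks = c("B1", "B2"),
                         subblock_size = 6, year_sd = 1, subblock_sd = 0.4,
                         seedlot_offset = 0.2, family_cap = Inf) {
  stopifnot(h20 >= 0, h2m >= 0, het_freq >= 0, het_freq <= 1,
            n_selected >= 1, n_offspring >= 1, G >= 1)
  structure(as.list(environment()), class = "fixture_spec")
}

#' Generate a complete synthetic selection experiment
#'
#' Simulates the whole experiment with known truth: breeding values follow
#' an infinitesimal model in which each offspring inherits its parent's
#' value plus a mutational increment `N(0, h2m * s2e)` and a segregation
#' increment from residual heterozygosity whose variance starts at
#' `h20 * s2e` and halves each selfing generation; drift acts through the
#' realised pedigree of selected individuals. Early populations select the
#' lowest, Late the highest phenotypes. The evaluation trial lays the
#' selected genotypes out in years, blocks and sub-blocks with additive
#' environmental effects and duplicated control plots, and a candidate
#' locus (heterozygous in a configurable fraction of the seed lot, plus the
#' optional major-effect copy in one Late founder) is gene-dropped through
#' the pedigree.
#'
#' @param spec A [fixture_spec()].
#' @param seed Integer seed; identical seeds give identical experiments.
#' @return A list of class `synthetic_experiment` with elements `pedigree`
#'   (validated pedigree tibble), `phenotypes` (plot observations),
#'   `genotypes` (`individual_id`, `locus`, `genotype`), and `truth` (all
#'   generator parameters plus the seed).
#' @export
gen_experiment <- function(spec = fixture_spec(), seed = 1) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed_if(seed, {
    out <- purrr::map(seq_len(nrow(spec$lines)), function(li) {
      gen_line(spec, spec$lines$line[li], spec$lines$control_mean[li],
               spec$lines$sd_e[li]^2)
    })
    ped <- bind_rows(purrr::map(out, "pedigree"))
    bv <- bind_rows(purrr::map(out, "bv"))
    geno <- bind_rows(purrr::map(out, "genotypes"))
    phen <- bind_rows(purrr::map(seq_len(nrow(spec$lines)), function(li) {
      gen_trial(spec, spec$lines$line[li], spec$lines$control_mean[li],
                spec$lines$sd_e[li], bv)
    }))
  })
  structure(
    list(pedigree = as_pedigree(ped), phenotypes = phen, genotypes = geno,
         breeding_values = bv,
         truth = list(h20 = spec$h20, h2m = spec$h2m,
                      het_freq = spec$het_freq,
                      major_locus = spec$major_locus,
                      lines = spec$lines, G = spec$G,
                      n_selected = spec$n_selected,
                      n_offspring = spec$n_offspring,
                      year_sd = spec$year_sd, subblock_sd = spec$subblock_sd,
                      family_cap = spec$family_cap, seed = seed)),
    class = "synthetic_experiment")
}

# Breeding scheme of one line: seed lot at generation 0, divergent selection
# over G generations, candidate-locus gene dropping.
gen_line <- function(spec, line, control_mean, s2e) {
  n0 <- spec$n_founders
  founder_id <- sprintf("%s_G0_%02d", line, seq_len(n0))
  founder_bv <- rnorm(n0, 0, sqrt(spec$h20 * s2e))
  # candidate locus: residual heterozygosity in the seed lot
  founder_geno <- rbinom(n0, 1, spec$het_freq)
  phen0 <- founder_bv + rnorm(n0, 0, sqrt(s2e))
  early_f <- order(phen0)[seq_len(spec$n_founder_selected)]
  late_f <- order(-phen0)[seq_len(spec$n_founder_selected)]
  if (!is.null(spec$major_locus)) {
    founder_geno[late_f[1]] <- 1L # seed the major allele in one Late lineage
  }
  ped <- tibble(id = founder_id, parent_id = NA_character_,
                generation = 0L, population = "SeedLot", line = line,
                selected = seq_len(n0) %in% c(early_f, late_f))
  bv_rows <- list()
  geno_rows <- list(tibble(id = founder_id, genotype = founder_geno))
  ped_rows <- list(ped)

  for (pop in c("Early", "Late")) {
    sel_ids <- founder_id[if (pop == "Early") early_f else late_f]
    sel_bv <- founder_bv[if (pop == "Early") early_f else late_f]
    sel_geno <- founder_geno[if (pop == "Early") early_f else late_f]
    for (g in seq_len(spec$G)) {
      n_par <- length(sel_ids)
      par_idx <- rep(seq_len(n_par), each = spec$n_offspring)
      n_off <- length(par_idx)
      seg_sd <- sqrt(spec$h20 * s2e * 0.5^g)
      off_bv <- sel_bv[par_idx] + rnorm(n_off, 0, sqrt(spec$h2m * s2e)) +
        rnorm(n_off, 0, seg_sd)
      off_geno <- drop_genotype(sel_geno[par_idx])
      major <- if (is.null(spec$major_locus)) rep(0, n_off) else
        spec$major_locus$a * (off_geno - 1) +
        spec$major_locus$d * (off_geno == 1)
      off_phen <- off_bv + major + rnorm(n_off, 0, sqrt(s2e))
      keep <- select_with_cap(off_phen, par_idx,
                              decreasing = (pop == "Late"),
                              n = spec$n_selected, cap = spec$family_cap)
      new_ids <- sprintf("%s_%s_G%d_%02d", line, pop, g,
                         seq_along(keep))
      ped_rows[[length(ped_rows) + 1]] <- tibble(
        id = new_ids, parent_id = sel_ids[par_idx[keep]],
        generation = g, population = pop, line = line, selected = TRUE)
      bv_rows[[length(bv_rows) + 1]] <- tibble(
        id = new_ids, line = line, population = pop, generation = g,
        bv = off_bv[keep] + major[keep], genotypic_mean = control_mean)
      geno_rows[[length(geno_rows) + 1]] <- tibble(
        id = new_ids, genotype = off_geno[keep])
      sel_ids <- new_ids
      sel_bv <- off_bv[keep]
      sel_geno <- off_geno[keep]
    }
  }
  list(pedigree = bind_rows(ped_rows),
       bv = bind_rows(bv_rows),
       genotypes = bind_rows(geno_rows) %>%
         mutate(locus = "candidate") %>%
         select(individual_id = "id", "locus", "genotype"))
}

# Mendelian selfing transmission of a 0/1/2 genotype vector.
drop_genotype <- function(parent_geno) {
  out <- parent_geno
  het <- which(parent_geno == 1L)
  if (length(het) > 0) {
    out[het] <- sample(0:2, length(het), replace = TRUE,
                       prob = c(0.25, 0.5, 0.25))
  }
  out
}

# Truncation selection of n indices by phenotype, optionally capping the
# number selected per family (the real scheme allowed at most 3). When too
# few families exist for the cap (as at the first generation, bred from only
# three founders) the cap is relaxed to the smallest feasible value.
select_with_cap <- function(phen, family, decreasing, n, cap) {
  ord <- order(phen, runif(length(phen)), decreasing = decreasing)
  if (!is.finite(cap)) return(ord[seq_len(n)])
  cap <- max(cap, ceiling(n / length(unique(family))))
  keep <- integer(0)
  counts <- setNames(rep(0L, length(unique(family))),
                     as.character(unique(family)))
  for (i in ord) {
    fam <- as.character(family[i])
    if (counts[[fam]] < cap) {
      keep <- c(keep, i)
      counts[[fam]] <- counts[[fam]] + 1L
      if (length(keep) == n) break
    }
  }
  if (length(keep) < n) abort("family cap too strict to select n individuals")
  keep
}

# Evaluation trial of one line: selected genotypes + control plots laid out
# in years, blocks and sub-blocks.
gen_trial <- function(spec, line, control_mean, sd_e, bv) {
  genos <- bv %>% filter(.data$line == !!line)
  year_eff <- setNames(rnorm(length(spec$years), 0, spec$year_sd),
                       spec$years)
  year_eff <- year_eff - mean(year_eff)
  rows <- purrr::map_dfr(spec$years, function(yr) {
    purrr::map_dfr(paste(line, spec$blocks, sep = "_"), function(bl) {
      g <- genos[sample(nrow(genos)), ]
      n_sb <- ceiling(nrow(g) / spec$subblock_size)
      sb_of <- rep(seq_len(n_sb), each = spec$subblock_size)[seq_len(nrow(g))]
      sb_eff <- rnorm(n_sb, 0, spec$subblock_sd)
      sb_eff <- sb_eff - mean(sb_eff)
      sb_lab <- sprintf("%s_%s_sb%02d", yr, bl, seq_len(n_sb))
      plots <- tibble(
        genotype_id = g$id, year = yr, block = bl,
        sub_block = sb_lab[sb_of],
        value = control_mean + g$bv + year_eff[[yr]] + sb_eff[sb_of] +
          rnorm(nrow(g), 0, sd_e),
        is_control = FALSE, seed_lot = NA_character_,
        population = g$population, generation = g$generation, line = line)
      controls <- purrr::map_dfr(seq_len(n_sb), function(p) {
        lot <- c("Initial", "Commercial")
        tibble(genotype_id = paste0(line, "_control"), year = yr, block = bl,
               sub_block = sb_lab[p],
               value = control_mean + year_eff[[yr]] + sb_eff[p] +
                 c(0, spec$seedlot_offset) - spec$seedlot_offset / 2 +
                 rnorm(2, 0, sd_e),
               is_control = TRUE, seed_lot = lot,
               population = NA_character_, generation = NA_integer_,
               line = line)
      })
      bind_rows(plots, controls)
    })
  })
  rows
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat("Synthetic selection experiment:", nrow(x$pedigree), "pedigree records,",
      nrow(x$phenotypes), "plots,", nrow(x$genotypes), "genotype calls\n")
  invisible(x)
}

#' Write a synthetic experiment to disk
#'
#' Emits `pedigree.tsv`, `phenotypes.tsv`, `genotypes.tsv` and `truth.json`
#' in the dialects read by [read_pedigree()] and the analysis functions.
#'
#' @param x A `synthetic_experiment`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(x, dir) {
  stopifnot(inherits(x, "synthetic_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_pedigree(x$pedigree, file.path(dir, "pedigree.tsv"))
  readr::write_tsv(x$phenotypes, file.path(dir, "phenotypes.tsv"))
  readr::write_tsv(x$genotypes, file.path(dir, "genotypes.tsv"))
  jsonlite::write_json(x$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Generate a synthetic response trajectory
#'
#' Ten progeny-mean values per generation 2..7 (by default) with a chosen
#' mean structure, for exercising the segmented-regression machinery:
#' `"linear"` (constant slope), `"kink"` (slope changes by `slope_change`
#' after generation `b`), or `"plateau"` (slope drops to zero after `b`).
#'
#' @param shape `"linear"`, `"kink"` or `"plateau"`.
#' @param b Breakpoint generation for the non-linear shapes.
#' @param slope Initial slope (days per generation).
#' @param slope_change Added slope after the breakpoint (`"kink"` only).
#' @param level_change Added level shift after the breakpoint (`"kink"`
#'   only). A purely continuous kink is ambiguous for independent-segment
#'   fitting (the second line extends exactly through the kink point), so a
#'   non-zero shift makes the breakpoint uniquely identifiable.
#' @param noise_sd Residual standard deviation of each point.
#' @param n_per_gen Points per generation.
#' @param generations Generations covered.
#' @param seed Optional seed.
#' @return A tibble with `generation`, `k`, `Z`.
#' @export
gen_trajectory <- function(shape = c("linear", "kink", "plateau"), b = 4,
                           slope = 0.4, slope_change = 0.5,
                           level_change = 0.3, noise_sd = 0.05,
                           n_per_gen = 10, generations = 2:7, seed = NULL) {
  shape <- match.arg(shape)
  g <- rep(generations, each = n_per_gen)
  mu <- switch(shape,
    linear = slope * g,
    kink = slope * g + slope_change * pmax(g - b, 0) +
      level_change * (g > b),
    plateau = slope * pmin(g, b)
  )
  with_seed_if(seed, tibble(
    generation = g, k = rep(seq_len(n_per_gen), length(generations)),
    Z = mu + rnorm(length(g), 0, noise_sd)
  ))
}
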