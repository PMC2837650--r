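# Small pedigree and trajectory fixtures built in code.

# straight selfing chain f -> a1 -> a2 -> ... within one population
chain_pedigree <- function(n_gen = 6, population = "Late", line = "F252") {
  ids <- c("f", paste0("a", seq_len(n_gen)))
  as_pedigree(tibble::tibble(
    id = ids,
    parent_id = c(NA, ids[-length(ids)]),
    generation = 0:n_gen,
    population = population, line = line, selected = TRUE
  ))
}

# genealogy shaped like the field experiment: founders at generation 1,
# 10 selected individuals per generation thereafter
make_genealogy <- function(n_founders = 2, G = 7, n_selected = 10, seed = 1) {
  set.seed(seed)
  founder_ids <- paste0("f", seq_len(n_founders))
  rows <- tibble::tibble(
    id = founder_ids, parent_id = NA_character_, generation = 1L,
    population = "Late", line = "F252", selected = TRUE
  )
  prev <- founder_ids
  for (g in 2:G) {
    par <- sort(sample(prev, n_selected, replace = TRUE))
    ids <- sprintf("g%d_%02d", g, seq_len(n_selected))
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      id = ids, parent_id = par, generation = g,
      population = "Late", line = "F252", selected = TRUE
    ))
    prev <- ids
  }
  as_pedigree(rows)
}

# random single-parent forest for oracle comparisons (<= 50 nodes)
random_pedigree <- function(n = 40, seed = 1) {
  set.seed(seed)
  gens <- sort(sample(0:4, n, replace = TRUE))
  gens[1] <- 0L
  ids <- sprintf("n%02d", seq_len(n))
  parent <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (gens[i] > 0) {
      cand <- ids[gens == gens[i] - 1 & seq_len(n) < i]
      if (length(cand) == 0) {
        gens[i] <- 0L
      } else {
        parent[i] <- sample(cand, 1)
      }
    }
  }
  as_pedigree(tibble::tibble(
    id = ids, parent_id = parent, generation = gens,
    population = "Late", line = "F252", selected = TRUE
  ))
}

# brute-force descendant oracle: repeated scans of the parent map
descendants_oracle <- function(ped, id) {
  out <- character(0)
  repeat {
    nxt <- ped$id[!is.na(ped$parent_id) &
                    (ped$parent_id %in% c(id, out)) & !(ped$id %in% out)]
    if (length(nxt) == 0) break
    out <- c(out, nxt)
  }
  sort(out)
}

# plot observations with known environmental layers
make_trial <- function(year_effects = c(Y1 = 1, Y2 = -1),
                       subblock_effects = c(s1 = 0.5, s2 = -0.5),
                       noise_sd = 0, n_genotypes = 6, genotype_values = NULL,
                       seed = 1) {
  set.seed(seed)
  if (is.null(genotype_values)) genotype_values <- rnorm(n_genotypes)
  grid <- tidyr::expand_grid(
    genotype_id = sprintf("g%02d", seq_len(n_genotypes)),
    year = names(year_effects), sub_block = names(subblock_effects)
  )
  grid$block <- "B1"
  gv <- stats::setNames(genotype_values, sprintf("g%02d", seq_len(n_genotypes)))
  plots <- dplyr::mutate(grid,
    value = 20 + gv[genotype_id] + year_effects[year] +
      subblock_effects[sub_block] + stats::rnorm(dplyr::n(), 0, noise_sd),
    is_control = FALSE, seed_lot = NA_character_
  )
  controls <- tidyr::expand_grid(
    year = names(year_effects), sub_block = names(subblock_effects), rep = 1:2
  )
  controls <- dplyr::mutate(controls,
    genotype_id = "ctl", block = "B1",
    value = 20 + year_effects[year] + subblock_effects[sub_block] +
      stats::rnorm(dplyr::n(), 0, noise_sd),
    is_control = TRUE, seed_lot = "Initial"
  )
  dplyr::bind_rows(plots, dplyr::select(controls, -"rep"))
}
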