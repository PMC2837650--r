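#' Selfing pedigrees
#'
#' A pedigree is a tibble with one row per individual and columns `id`,
#' `parent_id` (`NA` for founders), `generation` (0 = initial seed lot),
#' `population`, `line` and `selected`. Individuals reproduce by selfing, so
#' each has a single parent and the genealogy is a forest rooted at the
#' founders. `as_pedigree()` validates a data frame and stamps the class;
#' `read_pedigree()`/`write_pedigree()` use a tab-separated dialect in which a
#' missing parent is encoded as `"."`.
#'
#' @param x A data frame with the columns listed above.
#' @return A tibble of class `pedigree`.
#' @examples
#' ped <- as_pedigree(tibble::tibble(
#'   id = c("f", "a", "b"), parent_id = c(NA, "f", "a"),
#'   generation = 0:2, population = "Late", line = "F252", selected = TRUE
#' ))
#' descendants(ped, "f")
#' @export
as_pedigree <- function(x) {
  needed <- c("id", "parent_id", "generation", "population", "line", "selected")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("pedigree is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  ped <- as_tibble(x) %>%
    mutate(
      id = as.character(.data$id),
      parent_id = dplyr::if_else(.data$parent_id %in% c(".", ""), NA_character_,
                                 as.character(.data$parent_id)),
      generation = as.integer(.data$generation),
      population = as.character(.data$population),
      line = as.character(.data$line),
      selected = as.logical(.data$selected)
    )
  dup <- ped$id[duplicated(ped$id)]
  if (length(dup) > 0) {
    abort(paste0("duplicated individual id(s): ",
                 paste(unique(dup), collapse = ", ")))
  }
  nonfounder <- ped[!is.na(ped$parent_id), ]
  unknown <- setdiff(nonfounder$parent_id, ped$id)
  if (length(unknown) > 0) {
    bad <- nonfounder$id[nonfounder$parent_id %in% unknown]
    abort(paste0("parent not found for individual(s): ",
                 paste(bad, collapse = ", ")))
  }
  gen_of <- setNames(ped$generation, ped$id)
  bad_gen <- nonfounder$id[gen_of[nonfounder$parent_id] !=
                             nonfounder$generation - 1L]
  if (length(bad_gen) > 0) {
    abort(paste0("parent generation must be offspring generation - 1 for: ",
                 paste(bad_gen, collapse = ", ")))
  }
  for (pop in unique(ped$population)) {
    gens <- sort(unique(ped$generation[ped$population == pop]))
    top <- max(gens)
    if (top > 0) {
      gap <- setdiff(seq_len(top), gens)
      if (length(gap) > 0) {
        abort(paste0("population ", pop, " has empty generation(s): ",
                     paste(gap, collapse = ", ")))
      }
    }
  }
  class(ped) <- c("pedigree", class(ped))
  ped
}

#' @rdname as_pedigree
#' @param file Path to a tab-separated pedigree file.
#' @export
read_pedigree <- function(file) {
  raw <- readr::read_tsv(file, col_types = readr::cols(
    id = readr::col_character(), parent_id = readr::col_character(),
    generation = readr::col_integer(), population = readr::col_character(),
    line = readr::col_character(), selected = readr::col_logical()
  ), na = character())
  as_pedigree(raw)
}

#' @rdname as_pedigree
#' @param ped A validated pedigree.
#' @export
write_pedigree <- function(ped, file) {
  out <- as_tibble(ped) %>%
    mutate(parent_id = dplyr::if_else(is.na(.data$parent_id), ".",
                                      .data$parent_id))
  readr::write_tsv(out, file)
  invisible(file)
}

#' Offspring-number summary for one generation of a pedigree
#'
#' For the selected parents of generation `generation - 1`, counts how many
#' selected offspring each contributed to `generation` (zeros included). These
#' counts drive the variance effective size of the breeding scheme.
#'
#' @param ped A pedigree.
#' @param population Population label to summarise.
#' @param generation Offspring generation (>= 1).
#' @return A one-row tibble with `population`, `generation`, `N` (number of
#'   parents), `mean_k`, `V_o` and a `counts` list-column of per-parent
#'   offspring numbers.
#' @export
offspring_count_summary <- function(ped, population, generation) {
  stopifnot(inherits(ped, "pedigree"))
  generation <- as.integer(generation)
  if (generation < 1) abort("generation must be >= 1")
  kids <- ped %>%
    filter(.data$population == !!population,
           .data$generation == !!generation, .data$selected)
  # parents: selected individuals of the population at generation - 1; at the
  # first generation the parents live in the seed lot, so any parent-of-record
  # of the offspring is included too
  parents_pop <- ped %>%
    filter(.data$population == !!population,
           .data$generation == !!generation - 1L, .data$selected)
  parent_ids <- union(parents_pop$id, unique(kids$parent_id))
  if (length(parent_ids) == 0 || nrow(kids) == 0) {
    abort(paste0("no selected individuals at generations ", generation - 1L,
                 "/", generation, " for population ", population))
  }
  counts <- as.integer(table(factor(kids$parent_id, levels = parent_ids)))
  tibble(
    population = population, generation = generation,
    N = length(parent_ids), mean_k = sum(counts) / length(parent_ids),
    V_o = stats::var(counts), counts = list(counts)
  )
}

#' Variance effective population size
#'
#' Converts the offspring-number distribution of a monoecious selfing
#' population into an effective size. The default estimator is the diploid
#' variance effective size `(4N - 2) / (V_o + 2)`; `variant = "crow_kimura"`
#' uses the haploid form `(N * mean_k - 1) / (mean_k - 1 + V_o / mean_k)`.
#' A zero denominator yields `Inf` (no drift).
#'
#' @param N Number of parents (>= 2).
#' @param V_o Variance of offspring number (>= 0).
#' @param mean_k Mean offspring number (needed for `"crow_kimura"`).
#' @param variant `"diploid"` (default) or `"crow_kimura"`.
#' @return Effective size (positive real, possibly `Inf`).
#' @examples
#' effective_size(10, 0) # 19
#' effective_size(10, 2) # 9.5
#' @export
effective_size <- function(N, V_o, mean_k = NULL,
                           variant = c("diploid", "crow_kimura")) {
  variant <- match.arg(variant)
  if (any(N < 2)) abort("N must be >= 2")
  if (any(V_o < 0)) abort("V_o must be >= 0")
  if (variant == "diploid") {
    (4 * N - 2) / (V_o + 2)
  } else {
    if (is.null(mean_k)) abort("mean_k is required for the crow_kimura variant")
    den <- mean_k - 1 + V_o / mean_k
    ifelse(den <= 0, Inf, (N * mean_k - 1) / den)
  }
}

#' Per-generation effective sizes from a pedigree
#'
#' @param ped A pedigree.
#' @param variant Passed to [effective_size()].
#' @return A tibble with one row per (population, generation >= 1):
#'   `N`, `mean_k`, `V_o`, `Ne`.
#' @export
ne_table <- function(ped, variant = c("diploid", "crow_kimura")) {
  variant <- match.arg(variant)
  cells <- ped %>%
    filter(.data$generation >= 1, .data$selected) %>%
    distinct(.data$line, .data$population, .data$generation)
  purrr::pmap_dfr(cells, function(line, population, generation) {
    sub <- as_pedigree(ped[ped$line == line, ])
    s <- offspring_count_summary(sub, population, generation)
    s %>%
      mutate(line = line, .before = 1) %>%
      mutate(Ne = effective_size(.data$N, .data$V_o, .data$mean_k, variant)) %>%
      select(-"counts")
  }) %>%
    arrange(.data$line, .data$population, .data$generation)
}

#' Descendants and founders in a selfing genealogy
#'
#' `descendants()` returns all individuals reachable from `id` through
#' offspring links (excluding `id` itself). `founder_count()` counts the
#' distinct generation-0 ancestors of a population's final generation.
#'
#' @param ped A pedigree.
#' @param id Individual identifier.
#' @return `descendants()`: a character vector of ids; `founder_count()`: an
#'   integer.
#' @export
descendants <- function(ped, id) {
  stopifnot(inherits(ped, "pedigree"))
  if (!id %in% ped$id) abort(paste0("unknown individual id: ", id))
  kids_of <- split(ped$id, factor(ped$parent_id, levels = ped$id))
  out <- character(0)
  frontier <- id
  while (length(frontier) > 0) {
    nxt <- unlist(kids_of[frontier], use.names = FALSE)
    out <- c(out, nxt)
    frontier <- nxt
  }
  sort(unique(out))
}

#' @rdname descendants
#' @param population Population label.
#' @export
founder_count <- function(ped, population) {
  stopifnot(inherits(ped, "pedigree"))
  sub <- ped %>% filter(.data$population == !!population)
  if (nrow(sub) == 0) abort(paste0("unknown population: ", population))
  last <- sub %>% filter(.data$generation == max(.data$generation))
  parent_of <- setNames(ped$parent_id, ped$id)
  gen_of <- setNames(ped$generation, ped$id)
  roots <- vapply(last$id, function(i) {
    while (gen_of[[i]] > 0) i <- parent_of[[i]]
    i
  }, character(1))
  length(unique(roots))
}
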