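#' Segmented regression of a response trajectory with one breakpoint
#'
#' Fits the trajectory in two independent pieces: generations `gmin..b` and
#' `b+1..gmax`. A piece spanning several generations is fit by a least-squares
#' line; a piece reduced to a single generation is fit by its mean. When
#' `b = gmax` there is a single line over the whole range. Model size `k`
#' counts all location parameters plus one residual variance (3 for the
#' single line, 4 when one piece is a point, 5 for two lines), and models are
#' scored by the small-sample corrected Akaike criterion
#' `AICc = n log(RSS/n) + 2k + 2k(k+1)/(n-k-1)`.
#'
#' @param data A tibble with columns `generation` and `Z` (multiple points
#'   per generation allowed).
#' @param b Breakpoint generation: the last generation of the first piece.
#' @param rss_floor Lower bound applied to RSS before the log, so exact fits
#'   stay finite.
#' @return A one-row tibble: `b`, `k`, `rss`, `aicc`, plus the per-piece
#'   parameters in list-columns `fit1`, `fit2`.
#' @export
fit_with_breakpoint <- function(data, b, rss_floor = 1e-12) {
  data <- normalise_trajectory(data)
  gens <- sort(unique(data$generation))
  gmin <- min(gens); gmax <- max(gens)
  if (b < gmin || b > gmax) abort("breakpoint outside the generation range")
  seg1 <- data %>% filter(.data$generation <= b)
  seg2 <- data %>% filter(.data$generation > b)
  fit_piece <- function(d) {
    if (nrow(d) == 0) return(list(par = NULL, rss = 0, k = 0))
    if (dplyr::n_distinct(d$generation) == 1) {
      m <- mean(d$Z)
      list(par = c(mean = m), rss = sum((d$Z - m)^2), k = 1)
    } else {
      f <- lm(Z ~ generation, data = d)
      list(par = c(intercept = unname(coef(f)[1]),
                   slope = unname(coef(f)[2])),
           rss = sum(resid(f)^2), k = 2)
    }
  }
  f1 <- fit_piece(seg1); f2 <- fit_piece(seg2)
  n <- nrow(data)
  k <- f1$k + f2$k + 1 # + residual variance
  if (n <= k + 1) abort("too few points for AICc (n <= k + 1)")
  rss <- max(f1$rss + f2$rss, rss_floor * n)
  aicc <- n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  tibble(b = b, k = k, rss = rss, aicc = aicc,
         fit1 = list(f1$par), fit2 = list(f2$par))
}

normalise_trajectory <- function(data) {
  data <- as_tibble(data)
  if (!"Z" %in% names(data) && "value" %in% names(data)) {
    data <- data %>% rename(Z = "value")
  }
  stopifnot(all(c("generation", "Z") %in% names(data)))
  if (dplyr::n_distinct(data$generation) < 2) {
    abort("need at least 2 distinct generations")
  }
  data
}

#' Breakpoint profile: AICc and Akaike weights over candidate breakpoints
#'
#' Fits [fit_with_breakpoint()] at every candidate generation and converts
#' the AICc values into Akaike weights
#' `w_b = exp(-(AICc_b - min AICc)/2) / sum(...)`, interpretable as the
#' probability that the change in the rate of response occurred at each
#' generation (a best breakpoint at the last generation means the response
#' is a single line, i.e. linear).
#'
#' @inheritParams fit_with_breakpoint
#' @return A tibble of class `breakpoint_profile` with columns `b`, `k`,
#'   `rss`, `aicc`, `weight`; the best breakpoint is in
#'   `attr(, "best_b")`.
#' @export
breakpoint_profile <- function(data, rss_floor = 1e-12) {
  data <- normalise_trajectory(data)
  gens <- sort(unique(data$generation))
  prof <- purrr::map_dfr(gens, function(b) {
    fit_with_breakpoint(data, b, rss_floor) %>% select(-"fit1", -"fit2")
  })
  d <- prof$aicc - min(prof$aicc)
  prof$weight <- exp(-d / 2) / sum(exp(-d / 2))
  attr(prof, "best_b") <- prof$b[which.min(prof$aicc)]
  class(prof) <- c("breakpoint_profile", class(prof))
  prof
}

#' @export
autoplot.breakpoint_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$b), y = .data$weight)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "breakpoint generation", y = "AICc weight") +
    ggplot2::theme_minimal()
}

#' Distribution of best breakpoints over simulated trajectories
#'
#' Applies [breakpoint_profile()] to each simulated `Z` table and tallies
#' the best breakpoint generation. The fraction of simulations whose best
#' model is the single line (breakpoint at the last generation) measures how
#' often a linear response arises under the simulated model.
#'
#' @param sims A `sim_response_dist` (run with `keep_Z = TRUE`) or a list of
#'   trajectory tables.
#' @inheritParams fit_with_breakpoint
#' @return A tibble with one row per candidate breakpoint: `b`, `n`,
#'   `fraction`; `attr(, "linear_fraction")` is the fraction at the last
#'   generation.
#' @export
breakpoint_histogram <- function(sims, rss_floor = 1e-12) {
  z_list <- if (inherits(sims, "sim_response_dist")) {
    if (!"Z" %in% names(sims$results) ||
        is.null(sims$results$Z[[1]])) {
      abort("run response_distribution() with keep_Z = TRUE")
    }
    sims$results$Z
  } else {
    sims
  }
  if (length(z_list) < 1) abort("need at least one simulation")
  best <- purrr::map_int(z_list, function(z) {
    as.integer(attr(breakpoint_profile(z, rss_floor), "best_b"))
  })
  gens <- sort(unique(normalise_trajectory(z_list[[1]])$generation))
  out <- tibble(b = gens,
                n = as.integer(table(factor(best, levels = gens)))) %>%
    mutate(fraction = .data$n / length(best))
  attr(out, "linear_fraction") <- out$fraction[out$b == max(gens)]
  out
}
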