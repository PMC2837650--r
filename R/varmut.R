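#' Selection intensity of truncation selection
#'
#' Mean phenotypic deviation, in residual standard deviations, of the
#' selected fraction `p` under truncation selection on a Gaussian trait:
#' the mean of the upper `p` tail of a standard normal,
#' `i = phi(Phi^-1(1 - p)) / p`.
#'
#' @param p Selected fraction, in (0, 1].
#' @return Selection intensity (vectorised over `p`).
#' @examples
#' selection_intensity(0.01) # ~2.67: 10 selected out of 1000
#' @export
selection_intensity <- function(p) {
  if (any(p <= 0 | p > 1)) abort("p must be in (0, 1]")
  ifelse(p == 1, 0, dnorm(qnorm(1 - p)) / p)
}

#' Drift coefficients of a schedule of effective sizes
#'
#' For per-generation effective sizes `Ne_g` the per-generation retention of
#' genetic variance is `c_g = 1 - 1/Ne_g` (haploid line model; a diploid
#' `1 - 1/(2 Ne_g)` switch is provided). The cumulative coefficients are
#' `k_g = prod_{j<=g} c_j` (fate of the initial variance, `k_0 = 1`) and
#' `Pi_g = sum_{l=1..g} prod_{j=l+1..g} c_j` (accumulation of a constant
#' per-generation variance input).
#'
#' @param Ne Vector of effective sizes for generations `1..G` (> 1 or `Inf`).
#' @param drift_divisor `"haploid"` uses `1/Ne`, `"diploid"` uses `1/(2 Ne)`.
#' @return A tibble with columns `generation`, `Ne`, `c`, `k`, `Pi`.
#' @examples
#' drift_coefficients(c(10, 10)) # k = (0.9, 0.81), Pi = (1, 1.9)
#' @export
drift_coefficients <- function(Ne, drift_divisor = c("haploid", "diploid")) {
  drift_divisor <- match.arg(drift_divisor)
  if (any(Ne <= 1)) abort("all Ne must be > 1 (or Inf)")
  cc <- 1 - 1 / (Ne * if (drift_divisor == "diploid") 2 else 1)
  G <- length(Ne)
  k <- cumprod(cc)
  Pi <- numeric(G)
  Pi[1] <- 1
  if (G > 1) for (g in 2:G) Pi[g] <- Pi[g - 1] * cc[g] + 1
  tibble(generation = seq_len(G), Ne = Ne, c = cc, k = k, Pi = Pi)
}

#' Genetic and phenotypic variance trajectory under drift and mutation
#'
#' Iterates `s2A(g) = c_g * s2A(g-1) + s2m` from `s2A(0) = s2A0`, with
#' `c_g = 1 - 1/Ne_g`: drift removes a fraction `1/Ne` of the genetic
#' variance each generation while mutation adds a constant `s2m`. The
#' phenotypic variance is `s2P(g) = s2A(g) + s2e`.
#'
#' @param s2A0 Initial additive genetic variance.
#' @param s2m Per-generation mutational variance input.
#' @param s2e Residual (environmental) variance.
#' @param Ne Effective sizes for the `G` drift steps.
#' @inheritParams drift_coefficients
#' @return A tibble with `generation` (0..G), `s2A`, `s2P`.
#' @export
variance_trajectory <- function(s2A0, s2m, s2e, Ne,
                                drift_divisor = c("haploid", "diploid")) {
  dc <- drift_coefficients(Ne, drift_divisor)
  s2A <- numeric(length(Ne) + 1)
  s2A[1] <- s2A0
  for (g in seq_along(Ne)) s2A[g + 1] <- dc$c[g] * s2A[g] + s2m
  tibble(generation = 0:length(Ne), s2A = s2A, s2P = s2A + s2e)
}

# Variance weights at each response increment.
#
# The response slope over G observed generations spans the increments between
# consecutive generations; at each increment the breeder's equation applies to
# the genetic variance then present. The genetic variance decomposes as
# s2A(j) = w0_j * s2A0 + wm_j * s2m, and this helper returns the two weight
# vectors. Conventions:
#  * increments = "span" (default, G - 1 increments j = 1..G-1): standing
#    variance starts undepleted (w0_1 = 1) and decays by drift AND, when
#    selfing_decay is on, Mendelian halving of residual heterozygosity
#    (factor c_j/2 per generation); mutational variance first appears at the
#    second increment (M_1 = 0, M_j = c_j * M_{j-1} + s2m) and is depleted by
#    drift only.
#  * increments = "per_generation" (G increments g = 1..G): the plain
#    k/Pi closed form with s2A at g - 1, no selfing decay distinction.
response_weights <- function(G, Ne, drift_divisor = "haploid",
                             selfing_decay = TRUE,
                             increments = c("span", "per_generation")) {
  increments <- match.arg(increments)
  stopifnot(length(Ne) == G)
  if (increments == "span" && G < 2) {
    abort("span increments need G >= 2; use increments = \"per_generation\"")
  }
  half <- if (selfing_decay) 0.5 else 1
  cc <- 1 - 1 / (Ne * if (drift_divisor == "diploid") 2 else 1)
  if (increments == "span") {
    n <- G - 1
    w0 <- wm <- numeric(n)
    w0[1] <- 1; wm[1] <- 0
    if (n > 1) {
      for (j in 2:n) {
        w0[j] <- w0[j - 1] * cc[j] * half
        wm[j] <- wm[j - 1] * cc[j] + 1
      }
    }
  } else {
    n <- G
    dc <- drift_coefficients(Ne, drift_divisor)
    w0 <- c(1, dc$k[seq_len(G - 1)])
    wm <- c(0, dc$Pi[seq_len(G - 1)])
    if (selfing_decay) {
      w0 <- c(1, cumprod(dc$c[seq_len(G - 1)] * half))
    }
  }
  list(w0 = w0, wm = wm, n = n)
}

#' Expected mean response to selection under the drift + mutation model
#'
#' Averages the breeder's equation `i * s2A / sP` over the response
#' increments of the experiment, with the genetic variance fed by standing
#' variation (`h20 * s2e`, depleted by drift and by selfing) and by new
#' mutations (`h2m * s2e` per generation, depleted by drift). This is the
#' forward model inverted by [fit_heritability()].
#'
#' @param h2m Mutational heritability (per-generation mutational variance as a
#'   fraction of `s2e`).
#' @param h20 Initial heritability (standing genetic variance as a fraction of
#'   `s2e`).
#' @param s2e Residual variance (days^2).
#' @param Ne Effective sizes: either length `G` (generations 1..G) or length
#'   `G - 1` (generations 2..G, as usually tabulated; the generation-1 value
#'   is set to the first element).
#' @param i Selection intensity.
#' @param G Number of generations of selection.
#' @param drift_divisor,selfing_decay,increments Model switches; see
#'   [fit_heritability()] for their meaning and defaults.
#' @return Expected mean response, in trait units per generation.
#' @export
expected_mean_response <- function(h2m, h20, s2e, Ne, i, G = 7,
                                   drift_divisor = "haploid",
                                   selfing_decay = TRUE,
                                   increments = "span") {
  Ne <- expand_ne(Ne, G)
  w <- response_weights(G, Ne, drift_divisor, selfing_decay, increments)
  s2A <- w$w0 * h20 * s2e + w$wm * h2m * s2e
  (i / w$n) * sum(s2A / sqrt(s2A + s2e))
}

expand_ne <- function(Ne, G) {
  if (length(Ne) == G) return(Ne)
  if (length(Ne) == G - 1) return(c(Ne[1], Ne))
  if (length(Ne) == 1) return(rep(Ne, G))
  abort(paste0("Ne must have length G, G - 1 or 1 (got ", length(Ne), ")"))
}

#' Estimate mutational and initial heritability from an observed response
#'
#' Monte-Carlo EM inversion of [expected_mean_response()]. Each draw samples
#' the observed response `R ~ Normal(R_obs, se_R)` and the residual variance
#' `s2e ~ Uniform(s2e_range)`, then solves the expected-response equation for
#' the free heritability by a fixed-point iteration that equates the
#' phenotypic standard deviations to their previous iterate (starting from
#' zero). Negative solutions are truncated at zero. The point estimate is the
#' mean over draws and the confidence interval the 2.5/97.5 percentiles.
#'
#' Three models are supported:
#' * `"model1"`: no standing variation (`h20 = 0`); all response is mutational.
#'   Solves for `h2m` (its upper bound).
#' * `"model2"`: no mutation (`h2m = 0`); all response is standing variation.
#'   Solves for `h20`.
#' * `"model3"`: both sources; scans a grid of `h20` values (step `grid_step`)
#'   and keeps the largest `h20` whose `h2m` confidence interval still has a
#'   positive lower bound, reporting `h2m` at that `h20`.
#'
#' @param model `"model1"`, `"model2"` or `"model3"`.
#' @param R_obs Observed response slope (days per generation). Responses to
#'   downward selection should be passed as magnitudes.
#' @param se_R Standard error of `R_obs`.
#' @param Ne Effective sizes (see [expected_mean_response()]).
#' @param i Selection intensity; defaults to truncation selection of 10 in
#'   1000.
#' @param G Number of generations of selection.
#' @param s2e_range Sampling interval for the residual variance (days^2).
#' @param n_draws Monte-Carlo draws (>= 100).
#' @param seed Optional integer seed.
#' @param drift_divisor `"haploid"` (`c = 1 - 1/Ne`, default: selfed lines act
#'   as haploid lineages) or `"diploid"` (`1 - 1/(2Ne)`).
#' @param selfing_decay Should standing variance additionally halve each
#'   generation (Mendelian decay of residual heterozygosity under selfing)?
#'   Default `TRUE`.
#' @param increments `"span"` (default): the slope over `G` observed
#'   generations averages `G - 1` between-generation gains, with mutational
#'   variance first expressed at the second gain. `"per_generation"`: `G`
#'   gains using the variance at `g - 1`.
#' @param tol,max_iter Fixed-point convergence control.
#' @param grid_step Grid resolution on `h20` for `"model3"`.
#' @return An object of class `varmut_fit`; see [tidy.varmut_fit()]. The
#'   per-draw results are in `$draws` (columns `R`, `s2e`, `h2m`, `h20`,
#'   `converged`).
#' @examples
#' fit <- fit_heritability("model1", R_obs = 0.40, se_R = 0.039,
#'                         Ne = c(13.5, 13.5, 13.5, 12.5, 10.1, 8.1),
#'                         i = 2.67, n_draws = 500, seed = 1)
#' tidy(fit)
#' @export
fit_heritability <- function(model = c("model1", "model2", "model3"),
                             R_obs, se_R, Ne,
                             i = selection_intensity(0.01), G = 7,
                             s2e_range = c(0.6, 12),
                             n_draws = 10000, seed = NULL,
                             drift_divisor = "haploid",
                             selfing_decay = TRUE, increments = "span",
                             tol = 1e-8, max_iter = 1000, grid_step = 1e-3) {
  model <- match.arg(model)
  if (n_draws < 100) abort("n_draws must be >= 100")
  Ne <- expand_ne(Ne, G)
  w <- response_weights(G, Ne, drift_divisor, selfing_decay, increments)
  draws <- with_seed_if(seed, tibble(
    R = rnorm(n_draws, R_obs, se_R),
    s2e = runif(n_draws, s2e_range[1], s2e_range[2])
  ))

  solve_free <- function(w_free, w_fixed, theta_fixed) {
    # R = (i/n) sum_j (theta w_free_j + theta_fixed w_fixed_j) s2e / sP_j
    theta <- rep(0, n_draws)
    converged <- rep(FALSE, n_draws)
    fixed_part <- outer(draws$s2e * theta_fixed, w_fixed)
    free_scale <- outer(draws$s2e, w_free)
    for (it in seq_len(max_iter)) {
      s2A <- pmax(free_scale * theta, 0) + fixed_part
      sP <- sqrt(s2A + draws$s2e)
      A <- (i / w$n) * rowSums(free_scale / sP)
      B <- (i / w$n) * rowSums(fixed_part / sP)
      theta_new <- (draws$R - B) / A
      converged <- abs(theta_new - theta) <= tol * pmax(abs(theta_new), 1e-12)
      theta <- theta_new
      if (all(converged)) break
    }
    list(theta = pmax(theta, 0), converged = converged)
  }

  summarise_draws <- function(theta, converged) {
    ok <- theta[converged]
    list(estimate = mean(ok),
         ci = unname(quantile(ok, c(0.025, 0.975))))
  }

  check_convergence <- function(converged) {
    bad <- sum(!converged)
    if (bad > 0.1 * n_draws) {
      abort(paste0(bad, " of ", n_draws,
                   " draws failed to converge (> 10%)"))
    }
    if (bad > 0) {
      warn(paste0(bad, " non-convergent draw(s) excluded"))
    }
    bad
  }

  if (model == "model1") {
    sol <- solve_free(w$wm, w$w0, 0)
    n_bad <- check_convergence(sol$converged)
    s <- summarise_draws(sol$theta, sol$converged)
    h2m <- s$estimate; ci_h2m <- s$ci; h20 <- 0; ci_h20 <- c(0, 0)
    draws <- draws %>% mutate(h2m = sol$theta, h20 = 0,
                              converged = sol$converged)
  } else if (model == "model2") {
    sol <- solve_free(w$w0, w$wm, 0)
    n_bad <- check_convergence(sol$converged)
    s <- summarise_draws(sol$theta, sol$converged)
    h20 <- s$estimate; ci_h20 <- s$ci; h2m <- 0; ci_h2m <- c(0, 0)
    draws <- draws %>% mutate(h2m = 0, h20 = sol$theta,
                              converged = sol$converged)
  } else {
    h20_grid <- 0
    best <- NULL
    repeat {
      sol <- solve_free(w$wm, w$w0, h20_grid)
      lower <- quantile(sol$theta[sol$converged], 0.025)
      if (is.na(lower) || lower <= 0) break
      best <- list(h20 = h20_grid, sol = sol)
      h20_grid <- h20_grid + grid_step
      if (h20_grid > 1) {
        warn("model3 grid capped at h20 = 1")
        break
      }
    }
    if (is.null(best)) {
      # not significant: even with no standing variation the mutational CI
      # touches zero
      draws <- draws %>% mutate(h2m = NA_real_, h20 = NA_real_,
                                converged = TRUE)
      out <- structure(
        list(model = model, h2m = NA_real_, h20 = NA_real_,
             ci_h2m = c(NA_real_, NA_real_), ci_h20 = c(NA_real_, NA_real_),
             significant = FALSE, draws = draws, n_draws = n_draws,
             n_nonconverged = 0L, seed = seed,
             settings = list(R_obs = R_obs, se_R = se_R, Ne = Ne, i = i,
                             G = G, s2e_range = s2e_range,
                             drift_divisor = drift_divisor,
                             selfing_decay = selfing_decay,
                             increments = increments)),
        class = "varmut_fit")
      return(out)
    }
    n_bad <- check_convergence(best$sol$converged)
    s <- summarise_draws(best$sol$theta, best$sol$converged)
    h2m <- s$estimate; ci_h2m <- s$ci
    h20 <- best$h20; ci_h20 <- c(best$h20, best$h20)
    draws <- draws %>% mutate(h2m = best$sol$theta, h20 = best$h20,
                              converged = best$sol$converged)
  }

  structure(
    list(model = model, h2m = h2m, h20 = h20, ci_h2m = ci_h2m,
         ci_h20 = ci_h20, significant = TRUE, draws = draws,
         n_draws = n_draws, n_nonconverged = n_bad, seed = seed,
         settings = list(R_obs = R_obs, se_R = se_R, Ne = Ne, i = i, G = G,
                         s2e_range = s2e_range, drift_divisor = drift_divisor,
                         selfing_decay = selfing_decay,
                         increments = increments)),
    class = "varmut_fit")
}

#' @export
print.varmut_fit <- function(x, ...) {
  cat("Heritability fit (", x$model, ", ", x$n_draws, " draws)\n", sep = "")
  if (!x$significant) {
    cat("  not significant: mutational CI includes 0 at h20 = 0\n")
    return(invisible(x))
  }
  cat(sprintf("  h2m = %.4f (%.4f-%.4f)\n", x$h2m, x$ci_h2m[1], x$ci_h2m[2]))
  cat(sprintf("  h20 = %.4f (%.4f-%.4f)\n", x$h20, x$ci_h20[1], x$ci_h20[2]))
  invisible(x)
}

#' Tidiers for heritability fits
#'
#' @param x A `varmut_fit` from [fit_heritability()].
#' @param ... Unused.
#' @return `tidy()`: one row per heritability (`h2m`, `h20`) with `estimate`,
#'   `conf.low`, `conf.high`; `glance()`: a one-row model summary.
#' @export
tidy.varmut_fit <- function(x, ...) {
  tibble(term = c("h2m", "h20"),
         estimate = c(x$h2m, x$h20),
         conf.low = c(x$ci_h2m[1], x$ci_h20[1]),
         conf.high = c(x$ci_h2m[2], x$ci_h20[2]))
}

#' @rdname tidy.varmut_fit
#' @export
glance.varmut_fit <- function(x, ...) {
  tibble(model = x$model, h2m = x$h2m, h20 = x$h20,
         significant = x$significant, n_draws = x$n_draws,
         n_nonconverged = x$n_nonconverged,
         R_obs = x$settings$R_obs, G = x$settings$G, i = x$settings$i)
}

#' @rdname tidy.varmut_fit
#' @param object A `varmut_fit`.
#' @export
autoplot.varmut_fit <- function(object, ...) {
  free <- if (object$model == "model2") "h20" else "h2m"
  d <- object$draws %>% filter(.data$converged)
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[free]])) +
    ggplot2::geom_histogram(bins = 60, fill = "grey35") +
    ggplot2::geom_vline(xintercept = if (free == "h2m") object$h2m else
      object$h20, colour = "red") +
    ggplot2::labs(x = free, y = "draws",
                  title = paste0("Monte-Carlo draws (", object$model, ")")) +
    ggplot2::theme_minimal()
}
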