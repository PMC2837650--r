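#' Expected residual heterozygosity after selfing
#'
#' Without mutation, heterozygosity halves every selfing generation:
#' `H_g = H_0 / 2^g`. An inbred line derived through `g` generations of
#' single-seed descent therefore retains `0.5^g` of its initial
#' heterozygosity.
#'
#' @param generations Number of selfing generations.
#' @param h0 Initial heterozygosity (default 1, i.e. return the retained
#'   fraction).
#' @return Expected heterozygosity (vectorised).
#' @examples
#' selfing_heterozygosity(12) # ~0.00024
#' @export
selfing_heterozygosity <- function(generations, h0 = 1) {
  if (any(generations < 0)) abort("generations must be >= 0")
  h0 * 0.5^generations
}

#' Probability that selfed offspring hide a heterozygous parent
#'
#' A heterozygous parent produces homozygotes of a given class with
#' probability 1/4 under selfing, so the probability that `n` selfed
#' offspring are all homozygous for that one allele is `0.25^n` (the
#' probability of misclassifying the parent as homozygous when genotyping
#' its progeny). With `allele = "either"` both homozygous classes count.
#'
#' @param n Number of selfed offspring genotyped.
#' @param allele `"one"` (default): all offspring homozygous for one given
#'   allele; `"either"`: all homozygous for the same, unspecified allele.
#' @return Probability.
#' @examples
#' prob_offspring_all_hom(4) # 0.0039
#' @export
prob_offspring_all_hom <- function(n, allele = c("one", "either")) {
  allele <- match.arg(allele)
  if (any(n < 1)) abort("n must be >= 1")
  0.25^n * if (allele == "either") 2 else 1
}

#' Residual heterozygote frequency in a genotyped sample
#'
#' @param n_het Number of heterozygotes observed.
#' @param n_total Number of individuals genotyped.
#' @return Point estimate `n_het / n_total`.
#' @examples
#' residual_het_frequency(1, 31) # ~0.032
#' @export
residual_het_frequency <- function(n_het, n_total) {
  if (any(n_total < 1) || any(n_het < 0) || any(n_het > n_total)) {
    abort("need 0 <= n_het <= n_total and n_total >= 1")
  }
  n_het / n_total
}
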