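---
title: "Models and methods in divselect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in divselect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divselect)
library(dplyr)
```

`divselect` analyses divergent truncation-selection experiments begun from
inbred seed lots propagated by selfing. This vignette explains the models
behind each component, the parameters that matter, the numerical choices,
and what the synthetic-data tests do and do not establish.

## The experimental design being modelled

Two commercial inbred seed lots (an early line with control mean about 22
days after July 1st and residual sd 0.90, a late line with mean 35 and sd
0.56) are each split into an Early and a Late population. Every generation,
each selected individual is selfed; about 100 of its offspring are
evaluated and the 10 most extreme individuals are selected. After seven
generations all selected genotypes are evaluated together in a two-year,
two-block trial with sub-blocks, each sub-block carrying at least two
control plots of the initial inbred. Generation 0 is the seed lot itself.

## Pedigrees and effective sizes

Selfing makes the genealogy a single-parent forest. The strength of drift
in the breeding scheme is summarised by the variance effective size
computed per generation from the number of parents `N` and the variance
`V_o` of their (selected-)offspring numbers. The default estimator is the
diploid monoecious form

\[ N_e = \frac{4N - 2}{V_o + 2}, \]

with the haploid Crow–Kimura form
\((N\bar k - 1)/(\bar k - 1 + V_o/\bar k)\) behind a flag. The exact
correction used to produce historically published values of this quantity
is not always recoverable; downstream estimation therefore accepts any
externally supplied `Ne` schedule as data, and `ne_table()` is used when
the pedigree itself is the source.

## Control correction and genotypic values

Control plots estimate the environmental field structure. Their values are
decomposed by least squares into a grand mean, year effects, sub-block
within year effects and seed-lot effects, all read off cell predictions so
the decomposition is contrast-free and sums to zero (sub-blocks within
year). Non-control plots are corrected as
\(Z = \text{value} - \hat y_l - \hat c_{lp}\); the seed-lot effect is a
property of the controls only and is not subtracted from experimental
plots. Note one consequence of sum-to-zero effects: a constant added to a
single sub-block is absorbed into the effect estimates up to a common
recentring of the control mean, so corrected *contrasts* are invariant but
absolute values shift by a shared constant (this is tested as such).

Genotypic values are least-squares means of a fixed-effect model with
year, block-within-year and genotype terms — point estimates equivalent to
the random-genotype formulation under balanced data; no shrinkage is
applied. Within each population × generation cell the genetic variance is
estimated by method of moments as the variance of the genotypic values
minus their average sampling variance (`s2e`/plots per genotype); this can
be negative, and is clamped to zero by default (configurable) before the
broad-sense heritability \(h^2 = \sigma^2_G/(\sigma^2_G + \sigma^2_e)\).
The response to selection `R` is the OLS slope of genotypic values on the
generation of selection.

## The drift + mutation response model

The core model links the observed response slope to two heritabilities:
the **mutational heritability** \(h^2_m = \sigma^2_m/\sigma^2_e\) (variance
input per generation by new mutations, as a fraction of the residual
variance) and the **initial heritability**
\(h^2_0 = \sigma^2_A(0)/\sigma^2_e\) (standing variance in the seed lot).

Because the populations are selfed lines, drift is modelled on haploid
lineages: each generation a fraction \(1/N_{e,g}\) of the between-line
genetic variance is lost, i.e. multiplied by \(c_g = 1 - 1/N_{e,g}\)
(a \(1/(2N_e)\) switch exists). Standing variance resides largely in
residual heterozygosity, which Mendelian segregation halves every selfing
generation *in addition to* drift; mutational variance is counted as the
realised net per-generation increment and is depleted by drift only.
A regression slope over \(G\) observed generations spans \(G - 1\)
between-generation gains; the gain into generation \(j + 1\) applies the
breeder's equation to the variance among generation-\(j\) candidates, with
mutational variance first expressed at the second gain (the first
experimental meioses). Concretely, for increments \(j = 1..G-1\):

\[ S_1 = h^2_0\sigma^2_e,\quad S_j = \tfrac{c_j}{2} S_{j-1};\qquad
   M_1 = 0,\quad M_j = c_j M_{j-1} + h^2_m \sigma^2_e, \]

\[ \bar R = \frac{i}{G-1} \sum_{j=1}^{G-1}
   \frac{S_j + M_j}{\sqrt{S_j + M_j + \sigma^2_e}}, \]

where \(i\) is the truncation-selection intensity
(\(i = \varphi(\Phi^{-1}(1-p))/p\); selecting 10 of 1000 gives
\(i = 2.67\)). These index conventions were fixed by requiring the model
to reproduce the full set of published reference estimates for all four
populations of the motivating experiment under both the mutation-only and
the standing-variation-only model — the alternative conventions (G
increments of the plain \(k/\Pi\) closed form, no selfing decay) are
retained as the switches `increments = "per_generation"` and
`selfing_decay = FALSE`.

**Estimation.** `fit_heritability()` repeats, for `n_draws` (default
10,000) Monte-Carlo draws of \(R \sim N(R_{obs}, se_R)\) and
\(\sigma^2_e \sim U(0.6, 12)\) days² (the interval observed across the
selection seasons), a fixed-point solve of the equation above for the free
heritability: the phenotypic standard deviations are frozen at their
previous iterate, making the equation linear in the free parameter, and
iterated from 0 until the relative change is below `1e-8` (max 1000
iterations; non-convergent draws are excluded, more than 10% is an error).
Negative solutions are truncated at zero. The point estimate is the mean
of the draws and the confidence interval their 2.5/97.5 percentiles.

* **Model 1** (`h20 = 0`): all response mutational; an upper bound on
  \(h^2_m\).
* **Model 2** (`h2m = 0`): all response from standing variation; solves for
  \(h^2_0\), and its per-draw \((h^2_0, \sigma^2_e)\) pairs are the input
  distribution of the forward simulator.
* **Model 3**: scans \(h^2_0\) upward in steps of `1e-3` and keeps the
  largest value whose \(h^2_m\) interval still excludes zero — the most
  standing variation the data tolerate while mutation remains demonstrably
  necessary. If even \(h^2_0 = 0\) leaves the interval touching zero the
  model is reported as not significant.

\(h^2_0\) and \(h^2_m\) are expressed as fractions of \(\sigma^2_e\)
throughout.

## The forward simulator

The simulator instantiates the standing-variation-only null as an explicit
genetic model. Two founders carry `n_P` diallelic loci placed uniformly on
ten 150 cM chromosomes; `n_H` loci are heterozygous in both founders and
the rest are fixed differences between them. Allelic effects are drawn
from Exponential(1) with random sign and rescaled by \(\lambda\) so that

\[ \sum_l 2 p_l (1 - p_l) (2 a_l \lambda)^2 = h^2_0 \sigma^2_e, \]

with \(p_l\) the "+"-allele frequency over the four founder haplotypes.
Because the founders are not in Hardy–Weinberg proportions, the realised
candidate variance in the first generations somewhat exceeds this formula
value when `n_P > n_H`; the formula is used as specified and the
discrepancy is part of the simulated null.

Selfing draws two gametes per seed. Crossovers follow a Poisson process of
rate 1 per Morgan with no interference: the single-gamete path
(`gamete()`) draws sequential exponential inter-arrivals, while the
batched generation loop uses the exactly equivalent inter-locus Markov
switches with Haldane probabilities \((1 - e^{-2d})/2\) — the two are
tested against each other. Phenotypes add \(N(0, \sigma^2_e)\) noise, with
\(\sigma^2_e\) drawn once per simulation. Each generation the 10 most
extreme phenotypes (ties broken at random) are selected out of the 1000
candidates (200 in the first selfed generation); selection constraints of
the real field scheme (row/family caps, lineage maintenance) are *not*
applied, matching the simulated design. The recorded outcome \(Z_{jk}\) is
the mean phenotype of the 100 offspring of selected individual \(k\) of
generation \(j\) — its progeny-test value, the simulated analogue of the
trial's genotypic values — for generations 2..7, and the response slope is
the OLS regression of \(Z\) on \(j\). An optional complete-dominance mode
expresses the "+"-homozygote value in heterozygotes.

`response_distribution()` repeats this over pairs \((h^2_0, \sigma^2_e)\)
resampled from a model-2 fit, and `empirical_pvalue()` reports the
one-sided tail fraction of the simulated slopes on the side where the
observed response falls.

## Segmented regression

To ask whether a response trajectory is linear or bends as variation is
exhausted, each candidate breakpoint \(b\) splits generations 2..7 into
2..\(b\) and \(b{+}1\)..7; multi-generation pieces are fit by independent
least-squares lines (no continuity constraint), single-generation pieces
by their mean. The parameter count `k` includes one shared residual
variance: 3 for the single line (\(b = 7\)), 4 when one piece is a point,
5 for two lines. Models are compared by
\(\mathrm{AICc} = n\ln(RSS/n) + 2k + 2k(k+1)/(n-k-1)\) and Akaike weights
\(w_b \propto e^{-\Delta_b/2}\).

Numerical choices: the RSS is floored at \(10^{-12} n\) so exact fits stay
finite (parsimony then decides, and an exactly linear trajectory selects
\(b = 7\)); a *continuous* noiseless kink at \(b\) is inherently ambiguous
because the second line extends exactly through the kink point, so the
synthetic kink generator adds a level shift (`level_change`, default 0.3
days) that makes the breakpoint identifiable. With 60 points and residual
noise, spurious breakpoints win AICc a substantial fraction of the time
even for truly linear data — which is why observed-versus-simulated
comparisons use the full weight distribution, not just the argmin.

## Genealogy association and gene dropping

The additive and dominance effects of a candidate locus are estimated by
weighted regression of generation-centred genotypic values on the
indicator pair \(x \in \{-1, 0, 1\}\), \(y = 1\) for heterozygotes:
\(G_{jk} - \mu_j = a x_k + d y_k + \epsilon_k\), with \(\mu_j\) the mean
over *all* individuals of generation \(j\). An intercept is included: the
generation means do not annihilate a constant offset of the genotype-class
effects, and without the intercept constructed effects are not recovered
exactly. Missing genotypes are triplicated over the three classes with
Mendelian weights propagated from the nearest genotyped ancestor
(selfing transition 1/4 : 1/2 : 1/4 for heterozygotes, homozygotes breed
true, reversion neglected); missing trait values are imputed by the
same-subfamily same-generation mean.

`gene_drop_null()` drops the two alleles of designated heterozygous
founders through the fixed genealogy (20,000 simulations by default),
re-estimates \((a, d)\) against the *observed* phenotypes each time, and
reports one-tailed empirical P values in the direction of the observed
effect. Under the null this directed one-tailed value is the half-tail —
uniform on (0, ½) — so its doubled value is the two-sided equivalent; the
calibration test checks \(2 p_a \sim U(0,1)\). Simulations in which a
regressor is constant (e.g. the allele was lost) retain whichever effect
remains estimable.

`drift_exceedance()` asks whether an observed allele-frequency rise could
be drift alone: binomial resampling of \(2\,\mathrm{round}(N_{e,g})\) gene
copies per generation (haploid switch available; the rounding is forced by
non-integer effective sizes) and the fraction of trajectories reaching the
threshold.

## The synthetic-data generator

`gen_experiment()` emulates the full design with known truth: founder
breeding values \(N(0, h^2_0\sigma^2_e)\); offspring values equal to the
parent's plus a mutational increment \(N(0, h^2_m\sigma^2_e)\) and a
residual-heterozygosity segregation increment whose variance halves each
generation — the infinitesimal counterpart of the estimation model, chosen
deliberately so that the estimator is tested against its own assumptions,
while the locus-based forward simulator provides the misspecified
counterpart. Divergent truncation selection (Early lowest, Late highest)
acts on phenotypes with the line's residual sd; the optional per-family
cap of the real scheme is off by default and relaxes automatically when
fewer families exist than the cap requires. The evaluation trial lays each
genotype out once per year × block, in sub-blocks of 6 with two control
plots each (seed-lot effect ±0.1 days), year effects of sd 1 day and
sub-block effects of sd 0.4 days. A candidate locus is heterozygous in
each founder with probability 0.032 and gene-dropped through the
pedigree; an optional major locus with chosen \((a, d)\) is seeded in one
Late founder.

What the generator does **not** emulate: spatial field trends beyond
sub-block effects, genotype × year interaction, selection on the
kernel-weight tie-breaker, seed-storage effects, and linkage (breeding
values are transmitted infinitesimally). Passing end-to-end tests
therefore demonstrate internal consistency of the estimators under their
own assumptions — not robustness to these real-data features.

## Problem sizes, seeds and tolerances

All randomness flows through explicit `seed` arguments (`withr::with_seed`,
so the caller's RNG state is untouched). The test suite uses reduced but
non-trivial sizes chosen to keep Monte-Carlo standard errors well inside
the asserted bounds: 10,000 EM draws for reference-value checks, 150
forward simulations for the simulated-response check (the analysis script
runs 500, the size used throughout for response distributions), 20,000
gene-dropping simulations, 100,000 drift trajectories in the analysis
script. Fixed-point tolerance is `1e-8` relative; closed-form versus
recursive variance trajectories agree to `1e-12`; the model-3 grid step is
`1e-3`.

## Known limitations

* The drift recursion neglects the depletion of variance by selection
  itself, so mutational heritabilities are upper bounds in strongly
  selected, small populations.
* Model 2's initial-heritability scale depends on the selfing-decay
  convention; the package's default reproduces the published reference
  values, but the alternative conventions remain switches rather than
  settled facts.
* The association model is single-locus with additive/dominance coding;
  no kinship correction beyond the gene-dropping null, no haplotypes.
* Effective sizes below ~1.5 (possible in tiny realised pedigrees) are
  outside the drift model's domain (`c_g \le 0`) and must be truncated by
  the caller.
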