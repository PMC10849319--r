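---
title: "Coalescent models of X-chromosomal and autosomal ROH and IBD under first-cousin consanguinity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coalescent models of X-chromosomal and autosomal ROH and IBD under first-cousin consanguinity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xaroh)
```

## The model

`xaroh` works in a diploid, constant-sized population of $N$ monogamous
male–female mating pairs, so there are $4N$ copies of every autosomal locus
and $3N$ copies of every X-chromosomal locus. Each generation, a fraction
$c_1 = c_{pp} + c_{pc} + c_{mp} + c_{mc}$ of pairs are first cousins, split
among the four classical types (male-ego convention):

* $c_{pp}$ — patrilateral-parallel: the two fathers are brothers;
* $c_{pc}$ — patrilateral-cross: his father and her mother are siblings;
* $c_{mp}$ — matrilateral-parallel: the two mothers are sisters;
* $c_{mc}$ — matrilateral-cross: his mother and her father are siblings.

Runs of homozygosity (ROH) arise from the coalescence of the two gene
copies *within* an individual; IBD segments from coalescence of copies in
two *different* individuals. The bridge from coalescence times to genomic
sharing is the segment-length model: conditional on a TMRCA of $t$
generations, the genetic length of the shared segment around a focal locus
is the sum of the two exponential distances to the nearest recombination on
either side — Erlang with shape 2 and rate $t/50$ per centimorgan on the
autosomes. On the X, recombination happens only in females and an X lineage
sits in a female two thirds of the time, so the rate is scaled by $2/3$ to
$t/75$ (`erlang_segment_density()`).

Averaging the Erlang tail over an exponential TMRCA with mean $N_e$
generations gives the probability that a locus lies in a segment of length
at least $u$ cM, which equals the expected genomic fraction in such
segments. Without consanguinity ($N_e = 4N$ or $3N$):

$$
P^A = \frac{25\,(25 + 4Nu)}{(25 + 2Nu)^2}, \qquad
P^X = \frac{25\,(25 + 2Nu)}{(25 + Nu)^2},
$$

whose ratio rises from 1 at $u = 0$ to 2 as $N \to \infty$ for any fixed
$u > 0$ (`xa_ratio_no_consanguinity()`): the X is expected to carry *twice*
the autosomal fraction of long shared segments purely because of its
smaller copy number and slower recombination.

## Consanguinity

Consanguinity enters through the limiting TMRCA distributions
(`tmrca_distribution()`). Between individuals the distribution stays
exponential, but with the effective size deflated to
$4N(1 - \tfrac{3}{16}c_1)$ on the autosomes and
$3N\,(1 - \tfrac{5}{16}c_{mp} - \tfrac{3}{8}c_{mc}) /
(1 + \tfrac{1}{16}c_{mp} - \tfrac{1}{8}c_{mc})$ on the X. Only the
matrilateral rates touch the X: a male's X never comes from his father, so
patrilateral loops cannot close on the X. Within individuals there is, in
addition, a point mass of *instantaneous* coalescence — the probability
that the two copies meet inside the first-cousin loop itself, which is
$O(1)$ generations and maps to $t = 0$ on the coalescent timescale:

$$
\pi_A = \frac{c_1/16}{1 - \tfrac{3}{16}c_1},
\qquad
\pi_X = \frac{\tfrac{3}{16}c_{mp} + \tfrac{1}{8}c_{mc}}
             {1 - \tfrac{5}{16}c_{mp} - \tfrac{3}{8}c_{mc}}.
$$

The expected ROH fraction is then "point mass plus the rest"
(`expected_roh_fraction()`), the expected IBD fraction is the plain
deflated spanning probability (`expected_ibd_fraction()`), and
`xa_sharing_ratio()` forms the X:A ratio for either quantity. As
$N \to \infty$ the continuous parts vanish and the ROH ratio tends to
$\pi_X / \pi_A$ rescaled (`limiting_xa_ratio_roh()`), which is 0 for purely
patrilateral consanguinity, up to $39/11 \approx 3.545$ at $c_{mp} = 1$ and
$13/5 = 2.6$ at $c_{mc} = 1$, and undefined at $c_1 = 0$ (the function
raises an error there rather than silently returning the no-consanguinity
limit of 2). The IBD ratio limit (`limiting_xa_ratio_ibd()`) is defined
everywhere: 2 at $c_1 = 0$, $13/8$ for pure patrilateral mating,
$221/88 \approx 2.511$ at $c_{mp} = 1$, $91/40 = 2.275$ at $c_{mc} = 1$.

At finite $N$ the picture is richer. The no-consanguinity baseline at,
say, $N = 500$, $u = 5$ cM is about 1.985 rather than 2, so for very small
matrilateral rates the curves sit slightly *below* 2 before crossing it;
the qualitative orderings (matrilateral-parallel > matrilateral-cross >
none > patrilateral, with the two patrilateral types exactly equal, and
ROH ratios deviating farther from 2 than IBD ratios) hold from moderate
rates upward. `xa_ratio_curves()` regenerates these curves.

### Ratio ranges over $N$

`ratio_range_over_N()` reports the minimum and maximum of the X:A ratio as
$N$ sweeps an interval, by default $[500, 50000]$ at $u = 0.1$ cM — the
standard way of turning an unknown population size into a predicted range
per population. The ROH ratio is *not* monotone in $N$: it rises from its
small-$N$ value and bends back down toward the point-mass-dominated
large-$N$ limit, so the maximum often sits strictly inside the interval.
The scan therefore uses a logarithmically spaced grid (512 points,
endpoints included) followed by `optimize()` polish of any interior
extremum; the grid is dense enough that the polish moves values by far
less than $10^{-3}$. The packaged rate table `first_cousin_rates()`
(percent frequencies of the four types in nine populations, divided by 100
on load) feeds this directly:

```{r}
r <- first_cousin_rates()
ash <- consang_rates(r$cpp[1], r$cpc[1], r$cmp[1], r$cmc[1])
ratio_range_over_N(ash, u = 0.1, mode = "roh")
```

## The pedigree Monte Carlo

`sample_tmrca()` realizes the generative model behind the limiting
distributions, as a backward-in-time trace of two lineages. A lineage is a
(mating pair, carrier sex, parental-origin copy) triple; a male's X copy is
always maternal. Natal pairs are uniform over the previous generation's
$N$ pairs except where a consanguineous pair label (drawn lazily, only for
pairs the lineages actually occupy) forces the two members' designated
parents to be siblings — children of one shared, uniformly chosen
grandparental pair. Since only two lineages are traced, per-generation
work is $O(1)$ and no pedigree is ever stored.

Two implementation choices deserve record:

* **Fast-coalescence classification.** A draw is flagged `fast` when the
  lineages coalesce through an actually-used sibling link before ever
  occupying distinct, unconstrained mating pairs. This is the
  separation-of-time-scales classification: cousin loops also fire during
  the long wandering phase, but those events belong to the slow
  (exponential) component — counting them would triple the apparent point
  mass — and random early natal-pair collisions (which occur with
  probability $O(1/N)$ even without consanguinity) are not loop events at
  all. Under this rule the fast frequency converges to the analytic point
  mass as $N$ grows and is *exactly* zero for between-individual sampling,
  for $c_1 = 0$, and for patrilateral-only consanguinity on the X.
* **Geometric fast-forward.** While the two lineages sit in distinct
  unconstrained pairs, their natal draws are i.i.d. uniform, so the time to
  the next co-occupancy is Geometric($1/N$) and the X carrier-sex chain
  (male $\to$ mother; female $\to$ either parent) has a closed-form
  $n$-step law with eigenvalue $-1/2$. `sample_tmrca()` samples the meeting
  time directly instead of stepping through empty generations; the naive
  stepper is retained (`use_skip = FALSE`) and the two are checked for
  statistical identity in the test suite.

`estimate_sharing_fraction()` turns TMRCA draws into sharing estimates,
either generatively (drawing an Erlang length and testing it against $u$)
or by averaging the conditional tail. Fast draws are treated as
instantaneous — their segments are unbounded on the coalescent scale —
matching how the closed forms count the point mass, and how
`empirical_cdf_distance()` maps them to the $t = 0$ atom when computing a
Kolmogorov–Smirnov-type distance against the limiting CDF.

### What finite $N$ does and does not reproduce

The limiting distributions are approximations at finite $N$, and the
simulator is the exact model, so small systematic gaps are expected and
measurable. Two matter in practice at $N = 500$. First, the generative
model is discrete in generations while the closed forms integrate an
exponential: the exact geometric expectation of the Erlang tail is about
2.5% below the closed form at $u = 5$ cM ($N_e = 2000$), shrinking with
$u$; the simulator-versus-theory comparisons in the test suite therefore
run at $u = 1$ cM, where this approximation error is well below the Monte
Carlo noise and the comparison genuinely tests the simulator. Second, at
heavy consanguinity (total rates of 0.3–0.45, far above any surveyed
population) the slow-phase X coalescence mean exceeds its limiting value
by about 1% at $N = 500$, decaying roughly as $1/N$; one extreme cell of
the 32-cell validation grid fails its 3-standard-error check for exactly
this reason, and is left failing rather than loosened.

## Synthetic cohorts

`generate_cohort()` produces segment tables with the statistical structure
the summaries assume, without any external data. Every individual receives
an autosomal ROH total and (females only) an X ROH total; every unordered
pair receives autosomal and X IBD totals, the X total summed over the 1, 2,
or 4 cross-individual haplotype pairs implied by the pair's sexes. Each
total is the genome length times the fraction of `n_loci` independent focal
loci falling in a qualifying segment, so population means converge to the
closed forms at rate $1/\sqrt{n_\text{loci} \times \text{cohort size}}$.
Focal loci are independent — linkage between loci affects the variance of
cohort summaries, not their means — so the generator is *not* a claim
about the dispersion of real cohorts, and passing pipeline tests show
recovery of means and ratios, not of variances.

The generator works in centimorgans with default genome lengths of 3545 cM
(autosomes) and 180 cM (X), typical human map totals. Summaries of
real-data tables in megabases use the physical constants 2881.03 Mb and
155.27 Mb instead (`genome_lengths()`); a table's unit must match the
normalization constants explicitly — one centimorgan is never silently
equated to one megabase. `summarize_roh()` uses all individuals as the
autosomal denominator and females only for the X (reporting populations
with no females as missing rather than zero); `summarize_ibd()` divides
each pair's total by its haplotype-pair count and averages over *all*
pairs, zero-sharing pairs included. `zero_intercept_regression()` is the
through-origin fit used to compare per-population X and autosomal
fractions: slope $\sum xy / \sum x^2$, uncentered $R^2$, and a two-sided
$t$ test on $n - 1$ degrees of freedom, delegated to `lm(y ~ x + 0)`.

```{r}
g <- generate_cohort(list(
  cohort_spec("none",  consang_rates(),          n_pairs = 400,
              n_males = 0, n_females = 10, u_min = 5),
  cohort_spec("matri", consang_rates(cmp = 0.5), n_pairs = 400,
              n_males = 0, n_females = 10, u_min = 5)),
  n_loci = 200, seed = 1)
s <- population_summary(g$segments, g$metadata, g$genome)
s$roh_x / s$roh_autosomal
```

## Numerical choices and degenerate inputs

* Closed forms are evaluated in double precision; the quadrature oracles in
  the test suite use `integrate()` at tolerances near $10^{-10}$ and agree
  with the closed forms to better than $10^{-6}$ relative error.
* Finite length intervals $[u, v]$ are supported exactly as the difference
  of the two $[\cdot, \infty)$ closed forms (the inner Erlang integral is a
  difference of tails and the outer integral is linear); the ROH point mass
  contributes only when $v = \infty$, since instantaneous coalescence
  yields effectively unbounded segments. All standard results use
  $v = \infty$.
* $u = 0$ returns exactly 1 for every sharing fraction; $t = 0$ returns the
  point mass for within CDFs and 0 for between CDFs; denominators such as
  $1 - \tfrac{3}{16}c_1$ are asserted positive (guaranteed for valid
  rates).
* Simulated replicates are capped at $100\times$ the lineage count;
  exceeding the cap (probability below $e^{-100}$) is an error, never a
  silent truncation.
* Seeds: every stochastic entry point accepts an integer seed and calls
  `set.seed()`; generation is byte-reproducible under a fixed seed.

## Known limitations

Only the four first-cousin types are modeled — no double first cousins,
avuncular mating, time-varying rates, population growth, or structure. The
mating-pair model assumes an equal sex ratio and monogamy. Segment lengths
are per-focal-locus (no chromosome-scale linkage, no tree sequences), and
segment detection is idealized: a detection floor $u$ stands in for the
whole calling pipeline, with no genotyping error, phasing error, or
LOD-window behavior. Real-data comparisons in megabases inherit the
cM-to-Mb mismatch of physical versus genetic distance, which the package
deliberately refuses to paper over.
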