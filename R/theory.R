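# Closed-form coalescent theory of ROH/IBD sharing on autosomes and X.
#
# Model: a constant-sized diploid population of N monogamous male-female
# mating pairs, hence 4N autosomal lineages and 3N X-chromosomal lineages.
# Recombination is parameterized so that, conditional on a coalescence time
# of t generations, the genetic length of the shared segment around a focal
# locus is Erlang(2, t/50) in centimorgans on the autosomes and
# Erlang(2, t/75) on the X (recombination happens in females only, and an X
# spends two thirds of its time in females). Consanguinity enters through
# the limiting coalescence-time distributions: an exponential "slow" part
# whose rate is inflated by the consanguinity rates, plus (within
# individuals) a point mass of instantaneous coalescence at t = 0.

recomb_scale <- function(chrom = c("autosomal", "x")) {
  chrom <- match.arg(chrom)
  if (chrom == "autosomal") 50 else 75
}

check_u <- function(u) {
  if (!is.numeric(u) || length(u) != 1L || is.na(u) || u < 0) {
    stop("`u` must be a single nonnegative length in centimorgans",
         call. = FALSE)
  }
  u
}

check_n_pairs <- function(n_pairs) {
  if (!is.numeric(n_pairs) || anyNA(n_pairs) || any(n_pairs < 1)) {
    stop("`n_pairs` must be a positive number of mating pairs", call. = FALSE)
  }
  n_pairs
}

# X-chromosome slow-process slow-down factor; the X between-individual
# coalescence rate is (1/(3N)) / x_slowdown(rates). Depends only on the
# matrilateral rates: patrilateral first-cousin mating leaves X-chromosomal
# coalescence untouched.
x_slowdown <- function(rates) {
  den <- 1 - 5 * rates$cmp / 16 - 3 * rates$cmc / 8
  num <- 1 + rates$cmp / 16 - rates$cmc / 8
  stopifnot(den > 0, num > 0)
  den / num
}

a_slowdown <- function(rates) {
  den <- 1 - 3 * rates$c1 / 16
  stopifnot(den > 0)
  den
}

# Effective number of lineages for the slow (exponential) process: the
# between-individual TMRCA is Exp(1 / ne_eff).
ne_eff <- function(n_pairs, rates, chrom) {
  if (chrom == "autosomal") 4 * n_pairs * a_slowdown(rates)
  else 3 * n_pairs * x_slowdown(rates)
}

#' Erlang density of the shared-segment length at a focal locus
#'
#' Conditional on two lineages coalescing `tmrca` generations ago, the
#' genetic length of the segment they share around a focal locus is the sum
#' of two independent exponential distances (to the nearest recombination on
#' either side), i.e. Erlang with shape 2 and rate `tmrca / 50` per
#' centimorgan on the autosomes, `tmrca / 75` on the X.
#'
#' @param length_cM Segment length(s) in centimorgans, > 0.
#' @param tmrca Coalescence time in generations, > 0.
#' @param chrom `"autosomal"` or `"x"`.
#' @return Density value(s); the density integrates to 1 over (0, Inf) and
#'   has its mode at `recomb_scale / tmrca`.
#' @export
erlang_segment_density <- function(length_cM, tmrca,
                                   chrom = c("autosomal", "x")) {
  chrom <- match.arg(chrom)
  if (any(length_cM <= 0)) stop("`length_cM` must be positive", call. = FALSE)
  if (any(tmrca <= 0)) stop("`tmrca` must be positive", call. = FALSE)
  r <- tmrca / recomb_scale(chrom)
  r^2 * length_cM * exp(-r * length_cM)
}

# Spanning probability for an exponential TMRCA with mean ne: the chance a
# focal locus sits in a segment of length >= u. Closed form
# (1 + 2m) / (1 + m)^2 with m = ne * u / scale.
spanning_closed <- function(ne, u, scale) {
  m <- ne * u / scale
  (1 + 2 * m) / (1 + m)^2
}

# Tail over a finite interval [u, v]: exact difference of the two [*, Inf)
# forms (the inner Erlang integral is a difference of tails and the outer
# exponential integral is linear).
spanning_interval <- function(ne, u, v, scale) {
  if (v < u) stop("`v` must be at least `u`", call. = FALSE)
  if (is.infinite(v)) return(spanning_closed(ne, u, scale))
  spanning_closed(ne, u, scale) - spanning_closed(ne, v, scale)
}

#' Probability that a locus lies in a long shared segment, no consanguinity
#'
#' The probability that a focal locus is spanned by an IBD segment of
#' genetic length in `[u, v]` between two lineages drawn from a population
#' of `n_pairs` mating pairs without consanguinity. Equals the expected
#' fraction of the genome lying in such segments.
#'
#' @param n_pairs Number of mating pairs N.
#' @param u Lower segment-length bound in centimorgans.
#' @param chrom `"autosomal"` (4N lineages, scale 50) or `"x"` (3N lineages,
#'   scale 75).
#' @param v Upper bound in centimorgans; default `Inf`, the interval used by
#'   all the standard closed forms.
#' @return A probability in \[0, 1\]; `1` at `u = 0`, decreasing in both `N`
#'   and `u`.
#' @export
spanning_prob_no_consanguinity <- function(n_pairs, u,
                                           chrom = c("autosomal", "x"),
                                           v = Inf) {
  chrom <- match.arg(chrom)
  check_n_pairs(n_pairs); check_u(u)
  ne <- if (chrom == "autosomal") 4 * n_pairs else 3 * n_pairs
  spanning_interval(ne, u, v, recomb_scale(chrom))
}

#' X:autosome ratio of expected sharing without consanguinity
#'
#' Ratio of the X-chromosomal to the autosomal expected genomic fraction in
#' segments of length at least `u`:
#' `(25 + 2Nu)^3 / ((25 + Nu)^2 (25 + 4Nu))`. Equals 1 at `u = 0` and tends
#' to 2 as `N` grows for any fixed `u > 0`: the X has 3N copies against 4N
#' autosomal copies and a 2/3 recombination rate, so long segments are twice
#' as likely to cover a locus.
#'
#' @inheritParams spanning_prob_no_consanguinity
#' @return The ratio, a positive number.
#' @export
xa_ratio_no_consanguinity <- function(n_pairs, u) {
  check_n_pairs(n_pairs); check_u(u)
  (25 + 2 * n_pairs * u)^3 /
    ((25 + n_pairs * u)^2 * (25 + 4 * n_pairs * u))
}

#' Limiting TMRCA distribution under first-cousin consanguinity
#'
#' The large-N coalescence-time distribution for two lineages sampled within
#' one individual (`mode = "within"`, the ROH case) or in two individuals
#' from different mating pairs (`mode = "between"`, the IBD case). The
#' distribution is a mixture of a point mass at t = 0 (instantaneous
#' coalescence through a first-cousin loop; zero for between-individual
#' sampling) and an exponential "slow" component.
#'
#' @inheritParams spanning_prob_no_consanguinity
#' @param rates A [consang_rates()] object (or coercible list). For the X
#'   chromosome only the matrilateral rates `cmp`, `cmc` have any effect.
#' @param mode `"within"` (ROH) or `"between"` (IBD).
#' @return An object of class `tmrca_distribution`: a list with
#'   `point_mass` (probability of instantaneous coalescence),
#'   `rate` (of the exponential part, per generation), and the inputs.
#' @export
tmrca_distribution <- function(n_pairs, rates = consang_rates(),
                               chrom = c("autosomal", "x"),
                               mode = c("within", "between")) {
  chrom <- match.arg(chrom); mode <- match.arg(mode)
  check_n_pairs(n_pairs)
  rates <- as_consang_rates(rates)
  pm <- if (mode == "between") 0 else instantaneous_coalescence_prob(rates, chrom)
  structure(list(point_mass = pm,
                 rate = 1 / ne_eff(n_pairs, rates, chrom),
                 n_pairs = n_pairs, rates = rates,
                 chrom = chrom, mode = mode),
            class = "tmrca_distribution")
}

#' @export
print.tmrca_distribution <- function(x, ...) {
  cat(sprintf("Limiting TMRCA distribution (%s, %s-individuals):\n",
              x$chrom, x$mode))
  cat(sprintf("  point mass at t = 0 : %.6g\n", x$point_mass))
  cat(sprintf("  exponential rate    : %.6g per generation (mean %.6g)\n",
              x$rate, 1 / x$rate))
  invisible(x)
}

#' Cumulative distribution of the limiting TMRCA
#'
#' @param t Time(s) in generations, >= 0.
#' @inheritParams tmrca_distribution
#' @return CDF value(s): `point_mass + (1 - point_mass) * (1 - exp(-rate t))`.
#'   Nondecreasing in `t`; 0 at `t = 0` for between-individual sampling.
#' @export
tmrca_cdf <- function(t, n_pairs, rates = consang_rates(),
                      chrom = c("autosomal", "x"),
                      mode = c("within", "between")) {
  if (any(t < 0)) stop("`t` must be nonnegative", call. = FALSE)
  d <- tmrca_distribution(n_pairs, rates, chrom, mode)
  d$point_mass + (1 - d$point_mass) * (1 - exp(-d$rate * t))
}

#' Density of the between-individual TMRCA
#'
#' Exponential density of the coalescence time for two lineages in two
#' distinct mating pairs; its mean is `4N (1 - 3 c1 / 16)` on the autosomes
#' and `3N (1 - 5 cmp/16 - 3 cmc/8) / (1 + cmp/16 - cmc/8)` on the X.
#'
#' @param t Time(s) in generations, > 0.
#' @inheritParams tmrca_distribution
#' @export
tmrca_pdf_between <- function(t, n_pairs, rates = consang_rates(),
                              chrom = c("autosomal", "x")) {
  if (any(t <= 0)) stop("`t` must be positive", call. = FALSE)
  d <- tmrca_distribution(n_pairs, rates, chrom, "between")
  d$rate * exp(-d$rate * t)
}

#' Probability of instantaneous coalescence within an individual
#'
#' The point mass at t = 0 in the limiting within-individual TMRCA
#' distribution: `(c1/16) / (1 - 3 c1/16)` on the autosomes and
#' `(3 cmp/16 + cmc/8) / (1 - 5 cmp/16 - 3 cmc/8)` on the X. Purely
#' patrilateral consanguinity gives a zero X point mass: a male's X never
#' traces through his father, so patrilateral loops cannot close on the X.
#'
#' @inheritParams tmrca_distribution
#' @export
instantaneous_coalescence_prob <- function(rates, chrom = c("autosomal", "x")) {
  chrom <- match.arg(chrom)
  rates <- as_consang_rates(rates)
  if (chrom == "autosomal") {
    (rates$c1 / 16) / a_slowdown(rates)
  } else {
    den <- 1 - 5 * rates$cmp / 16 - 3 * rates$cmc / 8
    stopifnot(den > 0)
    (3 * rates$cmp / 16 + rates$cmc / 8) / den
  }
}

#' Expected genomic fraction in IBD segments of length at least u
#'
#' Expected fraction of the genome shared identically by descent, in
#' segments with genetic length in `[u, v]`, between two individuals in
#' different mating pairs, under first-cousin consanguinity. Obtained by
#' integrating the Erlang segment-length tail against the between-individual
#' TMRCA density; with `v = Inf` this has the closed form
#' `25 (25 + 4N a u) / (25 + 2N a u)^2` with `a = 1 - 3 c1/16` on the
#' autosomes, and `25 (25 + 2N d u) / (25 + N d u)^2` with
#' `d = (1 - 5 cmp/16 - 3 cmc/8) / (1 + cmp/16 - cmc/8)` on the X.
#'
#' @inheritParams tmrca_distribution
#' @inheritParams spanning_prob_no_consanguinity
#' @return Expected fraction in \[0, 1\]; reduces to
#'   [spanning_prob_no_consanguinity()] when all rates are zero.
#' @export
expected_ibd_fraction <- function(n_pairs, rates = consang_rates(), u,
                                  chrom = c("autosomal", "x"), v = Inf) {
  chrom <- match.arg(chrom)
  check_n_pairs(n_pairs); check_u(u)
  rates <- as_consang_rates(rates)
  spanning_interval(ne_eff(n_pairs, rates, chrom), u, v, recomb_scale(chrom))
}

#' Expected genomic fraction in runs of homozygosity of length at least u
#'
#' Expected fraction of the genome an individual carries in ROH with genetic
#' length in `[u, v]`. A fraction equal to the instantaneous-coalescence
#' point mass is homozygous by descent through a first-cousin loop and
#' counts fully (the associated segments are long on the coalescent
#' timescale); the remainder follows the between-individual sharing
#' fraction with the consanguinity-inflated coalescence rate.
#'
#' @inheritParams expected_ibd_fraction
#' @return Expected fraction in \[0, 1\]; equals 1 at `u = 0`, tends to the
#'   point mass as `u` grows, and equals [expected_ibd_fraction()] when all
#'   rates are zero.
#' @export
expected_roh_fraction <- function(n_pairs, rates = consang_rates(), u,
                                  chrom = c("autosomal", "x"), v = Inf) {
  chrom <- match.arg(chrom)
  check_n_pairs(n_pairs); check_u(u)
  rates <- as_consang_rates(rates)
  pm <- instantaneous_coalescence_prob(rates, chrom)
  cont <- spanning_interval(ne_eff(n_pairs, rates, chrom), u, v,
                            recomb_scale(chrom))
  # segments from instantaneous coalescence are effectively unbounded in
  # length, so the point mass contributes only when v = Inf
  if (is.infinite(v)) pm + (1 - pm) * cont else (1 - pm) * cont
}

#' X:autosome ratio of expected ROH or IBD sharing
#'
#' The per-population ratio of the expected X-chromosomal sharing fraction
#' to the autosomal one, for segments of length at least `u`.
#'
#' @inheritParams expected_ibd_fraction
#' @param mode `"roh"` (within-individual) or `"ibd"` (between-individual).
#' @return The ratio; with all rates zero it equals
#'   [xa_ratio_no_consanguinity()]. Matrilateral consanguinity pushes it
#'   above that baseline, patrilateral below.
#' @export
xa_sharing_ratio <- function(n_pairs, rates = consang_rates(), u,
                             mode = c("roh", "ibd")) {
  mode <- match.arg(mode)
  rates <- as_consang_rates(rates)
  if (mode == "ibd") {
    num <- expected_ibd_fraction(n_pairs, rates, u, "x")
    den <- expected_ibd_fraction(n_pairs, rates, u, "autosomal")
  } else {
    num <- expected_roh_fraction(n_pairs, rates, u, "x")
    den <- expected_roh_fraction(n_pairs, rates, u, "autosomal")
  }
  stopifnot(all(den > 0))
  num / den
}

#' Large-N limit of the X:autosome ROH ratio
#'
#' As N grows with `u` fixed, the continuous sharing components vanish and
#' the ROH ratio tends to the ratio of the two instantaneous-coalescence
#' point masses:
#' `(1 - 3 c1/16)(3 cmp/16 + cmc/8) / ((c1/16)(1 - 5 cmp/16 - 3 cmc/8))`.
#' The limit is undefined at `c1 = 0` (both point masses vanish); purely
#' patrilateral consanguinity gives 0.
#'
#' @inheritParams tmrca_distribution
#' @export
limiting_xa_ratio_roh <- function(rates) {
  rates <- as_consang_rates(rates)
  if (rates$c1 == 0) {
    stop("the limiting ROH ratio is undefined at c1 = 0; ",
         "use xa_ratio_no_consanguinity() (limit 2) instead", call. = FALSE)
  }
  den_x <- 1 - 5 * rates$cmp / 16 - 3 * rates$cmc / 8
  a_slowdown(rates) * (3 * rates$cmp / 16 + rates$cmc / 8) /
    ((rates$c1 / 16) * den_x)
}

#' Large-N limit of the X:autosome IBD ratio
#'
#' `2 (1 - 3 c1/16)(1 + cmp/16 - cmc/8) / (1 - 5 cmp/16 - 3 cmc/8)`;
#' equals 2 with no consanguinity.
#'
#' @inheritParams tmrca_distribution
#' @export
limiting_xa_ratio_ibd <- function(rates) {
  rates <- as_consang_rates(rates)
  2 * a_slowdown(rates) / x_slowdown(rates)
}

#' Range of the X:autosome sharing ratio over a population-size interval
#'
#' Scans [xa_sharing_ratio()] over `N` in `[n_min, n_max]` and returns the
#' minimum and maximum. The scan uses a logarithmically spaced grid and then
#' polishes any interior extremum with [stats::optimize()]; the ROH ratio is
#' typically unimodal in N (rising from its small-N value and bending down
#' toward the point-mass-dominated large-N limit), so interior maxima are
#' real and expected.
#'
#' @inheritParams xa_sharing_ratio
#' @param n_min,n_max Bounds of the scanned range of mating-pair counts.
#' @param n_grid Number of grid points (default 512).
#' @return Named vector `c(min = , max = )`, with attributes `argmin` and
#'   `argmax` giving the N at which each extremum is attained.
#' @export
ratio_range_over_N <- function(rates, u, n_min = 500, n_max = 50000,
                               mode = c("roh", "ibd"), n_grid = 512) {
  mode <- match.arg(mode)
  if (!(n_min < n_max)) stop("`n_min` must be below `n_max`", call. = FALSE)
  if (check_u(u) <= 0) stop("`u` must be positive for a meaningful range",
                            call. = FALSE)
  rates <- as_consang_rates(rates)
  grid <- exp(seq(log(n_min), log(n_max), length.out = n_grid))
  f <- function(n) xa_sharing_ratio(n, rates, u, mode)
  vals <- vapply(grid, f, numeric(1))
  polish <- function(idx, maximum) {
    lo <- grid[max(idx - 1L, 1L)]; hi <- grid[min(idx + 1L, n_grid)]
    if (idx == 1L || idx == n_grid) {
      list(value = vals[idx], arg = grid[idx])
    } else {
      o <- optimize(f, c(lo, hi), maximum = maximum, tol = 1e-9)
      if (maximum) list(value = o$objective, arg = o$maximum)
      else list(value = o$objective, arg = o$minimum)
    }
  }
  mn <- polish(which.min(vals), maximum = FALSE)
  mx <- polish(which.max(vals), maximum = TRUE)
  structure(c(min = mn$value, max = mx$value),
            argmin = mn$arg, argmax = mx$arg)
}

#' X:autosome ratio curves for one consanguinity type at a time
#'
#' Convenience sweep used for illustrating how each first-cousin mating type
#' moves the X:A sharing ratio away from its no-consanguinity baseline:
#' one rate is varied while the other three are held at zero.
#'
#' @param n_pairs Number of mating pairs (default 500).
#' @param u Minimum segment length in centimorgans (default 5).
#' @param rate_grid Values of the varied rate.
#' @return A tibble with columns `type`, `rate`, `mode`, `ratio`.
#' @export
xa_ratio_curves <- function(n_pairs = 500, u = 5,
                            rate_grid = seq(0, 1, by = 0.05)) {
  types <- c("cpp", "cpc", "cmp", "cmc")
  out <- expand.grid(type = types, rate = rate_grid, mode = c("roh", "ibd"),
                     stringsAsFactors = FALSE)
  out$ratio <- mapply(function(ty, r, md) {
    args <- setNames(list(r), ty)
    xa_sharing_ratio(n_pairs, do.call(consang_rates, args), u, md)
  }, out$type, out$rate, out$mode)
  tibble::as_tibble(out)
}
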