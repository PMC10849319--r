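#' Simulate coalescence times in the diploid mating-pair model
#'
#' Backward-in-time Monte Carlo for the time to the most recent common
#' ancestor (TMRCA) of two lineages, either within one individual (the ROH
#' case) or in two individuals from distinct mating pairs (the IBD case),
#' in a population of `n_pairs` monogamous male-female pairs with
#' first-cousin consanguinity. This is the brute-force generative model
#' behind the limiting analytic distributions of [tmrca_distribution()]:
#' consanguineous pairs draw their two members' designated parents as
#' siblings of one shared grandparental pair, which lets lineage pairs
#' coalesce in O(1) generations ("fast" coalescence, the finite-N analogue
#' of the point mass at t = 0).
#'
#' @inheritParams tmrca_distribution
#' @param n_replicates Number of independent TMRCA draws.
#' @param seed Optional integer; when supplied, [set.seed()] is called so
#'   the result is reproducible.
#' @param carrier_sex For `mode = "within"`: the sex of the sampled
#'   individual, `"female"`, `"male"`, or `NULL` (random for autosomes,
#'   female for the X). Two X lineages within one individual require a
#'   female carrier; requesting a male is an error.
#' @param use_skip Internal switch: fast-forward geometrically over
#'   generations in which the two lineages occupy distinct unconstrained
#'   pairs (default `TRUE`; statistically identical to naive stepping).
#' @return An object of class `tmrca_sim`: list with `tmrca` (integer
#'   generations, each >= 1) and `fast`: `TRUE` when the pair coalesced
#'   during its initial consanguineous-loop episode, before the two
#'   lineages ever dispersed into distinct unrelated mating pairs. Fast
#'   coalescence takes O(1) generations and is the finite-N realization of
#'   the limiting distribution's point mass at t = 0; its frequency
#'   converges to [instantaneous_coalescence_prob()] as N grows, and is
#'   identically `FALSE` for between-individual sampling and for the X
#'   under purely patrilateral consanguinity.
#' @examples
#' sim <- sample_tmrca(100, consang_rates(cmp = 0.3), "x", "within",
#'                     n_replicates = 500, seed = 1)
#' mean(sim$fast) # finite-N analogue of the X point mass
#' @export
sample_tmrca <- function(n_pairs, rates = consang_rates(),
                         chrom = c("autosomal", "x"),
                         mode = c("within", "between"),
                         n_replicates = 10000, seed = NULL,
                         carrier_sex = NULL, use_skip = TRUE) {
  chrom <- match.arg(chrom); mode <- match.arg(mode)
  rates <- as_consang_rates(rates)
  if (n_pairs < 10) stop("`n_pairs` must be at least 10", call. = FALSE)
  if (n_replicates < 1) stop("`n_replicates` must be positive", call. = FALSE)
  cs <- -1L
  if (!is.null(carrier_sex)) {
    carrier_sex <- match.arg(carrier_sex, c("female", "male"))
    if (chrom == "x" && mode == "within" && carrier_sex == "male") {
      stop("two X lineages within one individual require a female carrier",
           call. = FALSE)
    }
    cs <- if (carrier_sex == "male") 0L else 1L
  }
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_sample_tmrca(as.integer(n_pairs),
                          c(rates$cpp, rates$cpc, rates$cmp, rates$cmc),
                          chrom == "x", mode == "within",
                          as.integer(n_replicates), use_skip, cs)
  structure(list(tmrca = res$tmrca, fast = res$fast,
                 n_pairs = n_pairs, rates = rates, chrom = chrom,
                 mode = mode, n_replicates = n_replicates, seed = seed),
            class = "tmrca_sim")
}

#' @export
print.tmrca_sim <- function(x, ...) {
  cat(sprintf("TMRCA simulation: %d replicates, N = %d pairs, %s, %s\n",
              x$n_replicates, x$n_pairs, x$chrom, x$mode))
  cat(sprintf("  mean TMRCA: %.1f generations; fast-coalescence freq: %.4g\n",
              mean(x$tmrca), mean(x$fast)))
  invisible(x)
}

#' Monte Carlo estimate of the expected sharing fraction
#'
#' Estimates the expected genomic fraction in ROH (`mode = "within"`) or IBD
#' (`mode = "between"`) segments of length at least `u` centimorgans by
#' simulating TMRCA draws and, for each draw `t`, either sampling the
#' segment length as the sum of two independent exponentials with rate
#' `t / recomb_scale` per centimorgan (`method = "indicator"`) or
#' evaluating the conditional Erlang tail `(1 + u t / s) exp(-u t / s)`
#' directly (`method = "tail"`, lower variance).
#'
#' @inheritParams sample_tmrca
#' @param u Minimum segment length in centimorgans, > 0 (or 0, giving 1).
#' @param method `"indicator"` (generative) or `"tail"` (Rao-Blackwellized).
#' @return List with `estimate`, `se` (Monte Carlo standard error),
#'   `n_replicates`, and the underlying `sim`.
#' @export
estimate_sharing_fraction <- function(n_pairs, rates = consang_rates(),
                                      chrom = c("autosomal", "x"),
                                      mode = c("within", "between"),
                                      u, n_replicates = 10000, seed = NULL,
                                      method = c("indicator", "tail"),
                                      use_skip = TRUE) {
  chrom <- match.arg(chrom); mode <- match.arg(mode)
  method <- match.arg(method)
  check_u(u)
  if (u == 0) {
    return(list(estimate = 1, se = 0, n_replicates = n_replicates,
                sim = NULL))
  }
  sim <- sample_tmrca(n_pairs, rates, chrom, mode, n_replicates, seed,
                      use_skip = use_skip)
  s <- recomb_scale(chrom)
  # fast coalescences are instantaneous on the coalescent timescale: their
  # segments are effectively unbounded and span any cutoff u
  vals <- if (method == "indicator") {
    len <- stats::rgamma(length(sim$tmrca), shape = 2, rate = sim$tmrca / s)
    as.numeric(len >= u | sim$fast)
  } else {
    ifelse(sim$fast, 1,
           (1 + u * sim$tmrca / s) * exp(-u * sim$tmrca / s))
  }
  list(estimate = mean(vals),
       se = stats::sd(vals) / sqrt(length(vals)),
       n_replicates = n_replicates, sim = sim)
}

#' Supremum distance between simulated and limiting TMRCA distributions
#'
#' Kolmogorov-Smirnov-type statistic comparing the empirical distribution
#' of simulated TMRCA draws with the limiting analytic CDF for the same
#' parameters. Fast-coalescence draws are mapped to the point mass at
#' t = 0; the distance is computed on the mixed (atom + exponential)
#' distribution.
#'
#' @param sim A `tmrca_sim` object from [sample_tmrca()].
#' @return The supremum distance, a number in \[0, 1\].
#' @export
empirical_cdf_distance <- function(sim) {
  stopifnot(inherits(sim, "tmrca_sim"))
  x <- ifelse(sim$fast, 0, sim$tmrca)
  n <- length(x)
  if (n == 0) stop("empty simulation", call. = FALSE)
  d <- tmrca_distribution(sim$n_pairs, sim$rates, sim$chrom, sim$mode)
  theo <- function(t) d$point_mass + (1 - d$point_mass) * (1 - exp(-d$rate * t))
  xs <- sort(unique(x))
  Fn <- ecdf(x)
  Ft <- theo(xs)
  # left limits: subtract the atom at 0, and use the empirical value just
  # below each support point
  Ft_left <- ifelse(xs == 0, 0, theo(xs))
  Fn_left <- c(0, Fn(xs)[-length(xs)])
  max(abs(Fn(xs) - Ft), abs(Fn_left - Ft_left))
}
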