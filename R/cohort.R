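# Synthetic cohort generation. Per-individual ROH totals and per-pair IBD
# totals are built from independent focal-locus draws of the pedigree Monte
# Carlo, so the expectation of every emitted population mean is the
# corresponding analytic sharing fraction; variance comes solely from locus
# sampling (no linkage between focal loci is modeled).

#' Specification of one synthetic population cohort
#'
#' @param population Population label (unique across a cohort set).
#' @param rates A [consang_rates()] object.
#' @param n_pairs Mating-pair count N of the underlying model.
#' @param n_males,n_females Cohort composition (at least 2 individuals
#'   total).
#' @param u_min Detection floor: minimum segment length emitted, in
#'   centimorgans (> 0).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(population, rates = consang_rates(), n_pairs = 500,
                        n_males = 5, n_females = 5, u_min = 0.1) {
  rates <- as_consang_rates(rates)
  stopifnot(n_males >= 0, n_females >= 0, n_males + n_females >= 2,
            u_min > 0, n_pairs >= 10)
  structure(list(population = population, rates = rates, n_pairs = n_pairs,
                 n_males = n_males, n_females = n_females, u_min = u_min),
            class = "cohort_spec")
}

# Bernoulli focal-locus indicators: does a segment of length >= u span the
# locus? One draw per (replicate) = per (entity, locus).
sim_share_indicators <- function(n_pairs, rates, chrom, mode, u, n) {
  sim <- sample_tmrca(n_pairs, rates, chrom, mode, n_replicates = n)
  len <- stats::rgamma(n, shape = 2, rate = sim$tmrca / recomb_scale(chrom))
  len >= u
}

#' Generate synthetic segment tables for a set of population cohorts
#'
#' For each cohort: every individual receives an autosomal ROH total and
#' (females only) an X ROH total; every unordered pair of individuals
#' receives autosomal and X IBD totals, with the X total summed over the
#' 1, 2, or 4 cross-individual haplotype pairs implied by the pair's sexes.
#' Each total is `genome length x (share of n_loci independent focal loci
#' that fall in a qualifying segment)`, so population means converge to the
#' analytic expected fractions at rate `1/sqrt(n_loci x cohort size)`.
#' Cohorts whose specification contains no females produce no X ROH
#' records (reported with a message), mirroring real female-poor samples.
#'
#' @param specs A `cohort_spec` or list of them (distinct population
#'   labels).
#' @param n_loci Number of independent focal loci per entity (default 100).
#' @param genome A [genome_lengths()] object in centimorgans; the default
#'   uses a 3545 cM autosomal map and a 180 cM X map.
#' @param seed Optional integer seed for full reproducibility.
#' @return List with `segments` (a [segment_table()], unit cM), `metadata`
#'   (tibble: `id`, `population`, `sex`), and the generation parameters.
#' @export
generate_cohort <- function(specs, n_loci = 100,
                            genome = genome_lengths(3545, 180, unit = "cM"),
                            seed = NULL) {
  if (inherits(specs, "cohort_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1,
            all(vapply(specs, inherits, TRUE, "cohort_spec")))
  pops <- vapply(specs, `[[`, "", "population")
  if (anyDuplicated(pops)) stop("population labels must be distinct",
                                call. = FALSE)
  if (genome$unit != "cM") stop("the generator works in centimorgans",
                                call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  seg_rows <- list()
  meta_rows <- list()
  add_seg <- function(pop, kind, chrom, id1, id2, len) {
    keep <- len > 0
    if (!any(keep)) return()
    seg_rows[[length(seg_rows) + 1]] <<- tibble::tibble(
      population = pop, kind = kind, chrom = chrom,
      id1 = id1[keep], id2 = id2[keep], length = len[keep])
  }

  for (sp in specs) {
    ids_m <- if (sp$n_males > 0) sprintf("%s_M%02d", sp$population,
                                         seq_len(sp$n_males)) else character()
    ids_f <- if (sp$n_females > 0) sprintf("%s_F%02d", sp$population,
                                           seq_len(sp$n_females)) else character()
    ids <- c(ids_m, ids_f)
    sexes <- c(rep("male", sp$n_males), rep("female", sp$n_females))
    meta_rows[[length(meta_rows) + 1]] <-
      tibble::tibble(id = ids, population = sp$population, sex = sexes)

    # ROH: autosomal for everyone, X for females
    frac <- function(ind) colMeans(matrix(ind, nrow = n_loci))
    n_ind <- length(ids)
    f_a <- frac(sim_share_indicators(sp$n_pairs, sp$rates, "autosomal",
                                     "within", sp$u_min, n_loci * n_ind))
    add_seg(sp$population, "roh", "autosomal", ids, NA_character_,
            f_a * genome$autosomal)
    if (sp$n_females > 0) {
      f_x <- frac(sim_share_indicators(sp$n_pairs, sp$rates, "x", "within",
                                       sp$u_min, n_loci * sp$n_females))
      add_seg(sp$population, "roh", "x", ids_f, NA_character_,
              f_x * genome$x)
    } else {
      message("cohort ", sp$population, " has no females; no X ROH emitted")
    }

    # IBD: every unordered pair, haplotype-pair count set by the sexes
    if (n_ind >= 2) {
      pr <- utils::combn(n_ind, 2)
      np <- ncol(pr)
      f_pa <- frac(sim_share_indicators(sp$n_pairs, sp$rates, "autosomal",
                                        "between", sp$u_min, n_loci * np))
      add_seg(sp$population, "ibd", "autosomal",
              ids[pr[1, ]], ids[pr[2, ]], 4 * f_pa * genome$autosomal)
      # X: draw each haplotype-pair's indicator set; total scales with the
      # number of haplotype pairs so the weighted summary recovers the mean
      w <- (1 + (sexes[pr[1, ]] == "female")) *
           (1 + (sexes[pr[2, ]] == "female"))
      f_px <- vapply(seq_len(np), function(j) {
        mean(sim_share_indicators(sp$n_pairs, sp$rates, "x", "between",
                                  sp$u_min, n_loci * w[j]))
      }, numeric(1))
      add_seg(sp$population, "ibd", "x",
              ids[pr[1, ]], ids[pr[2, ]], w * f_px * genome$x)
    }
  }

  seg <- dplyr::bind_rows(seg_rows)
  if (nrow(seg) == 0) {
    seg <- tibble::tibble(population = character(), kind = character(),
                          chrom = character(), id1 = character(),
                          id2 = character(), length = numeric())
  }
  segments <- segment_table(seg$population, seg$kind, seg$chrom, seg$id1,
                            seg$id2, seg$length, unit = "cM")
  list(segments = segments,
       metadata = dplyr::bind_rows(meta_rows),
       genome = genome, n_loci = n_loci, specs = specs, seed = seed)
}

#' Synthetic population-level fraction pairs for regression tests
#'
#' Emits per-population (autosomal, X) mean-sharing fraction pairs with
#' `x_chrom = ratio * autosomal + noise`, the autosomal values log-spaced
#' over a range mimicking the spread of mean ROH proportions across real
#' populations (roughly half a percent to several percent of the genome).
#'
#' @param n_pops Number of populations (>= 3).
#' @param ratio Generating X:A slope.
#' @param noise_sd Standard deviation of the additive noise on the X
#'   fractions.
#' @param seed Optional integer seed.
#' @param x_range Range of autosomal fractions (default 0.005 to 0.08).
#' @return Tibble with columns `population`, `autosomal`, `x_chrom`.
#' @export
generate_regression_panel <- function(n_pops = 13, ratio = 2,
                                      noise_sd = 0, seed = NULL,
                                      x_range = c(0.005, 0.08)) {
  stopifnot(n_pops >= 3, ratio > 0, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  a <- exp(seq(log(x_range[1]), log(x_range[2]), length.out = n_pops))
  tibble::tibble(population = sprintf("pop%02d", seq_len(n_pops)),
                 autosomal = a,
                 x_chrom = ratio * a + stats::rnorm(n_pops, 0, noise_sd))
}
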