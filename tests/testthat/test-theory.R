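test_that("the segment-length density is a proper Erlang with mode scale/t", {
  # vanishes at the origin and integrates to one
  expect_equal(erlang_segment_density(1e-12, 100, "autosomal"), 0,
               tolerance = 1e-9)
  total <- integrate(function(l) erlang_segment_density(l, 100, "autosomal"),
                     0, Inf, rel.tol = 1e-10)$value
  expect_equal(total, 1, tolerance = 1e-8)
  # at t = 50 on the autosomes the rate is 1 per cM, so the mode is 1 cM
  grid <- seq(0.01, 6, by = 0.001)
  dens <- erlang_segment_density(grid, 50, "autosomal")
  expect_equal(grid[which.max(dens)], 1, tolerance = 2e-3)
  # the X rate is t/75: same density at 1.5x the time
  expect_equal(erlang_segment_density(2, 75, "x"),
               erlang_segment_density(2, 50, "autosomal"))
  expect_error(erlang_segment_density(-1, 10), "positive")
  expect_error(erlang_segment_density(1, 0), "positive")
})

test_that("spanning probabilities match the numeric double integral", {
  for (chrom in c("autosomal", "x")) {
    for (cfg in list(c(500, 5), c(200, 1), c(2000, 0.5))) {
      closed <- spanning_prob_no_consanguinity(cfg[1], cfg[2], chrom)
      numeric <- oracle_spanning_double(cfg[1], cfg[2], chrom)
      expect_equal(closed, numeric, tolerance = 1e-6)
    }
  }
})

test_that("spanning probability limits behave", {
  expect_equal(spanning_prob_no_consanguinity(500, 0, "autosomal"), 1)
  expect_equal(spanning_prob_no_consanguinity(500, 0, "x"), 1)
  expect_lt(spanning_prob_no_consanguinity(1e12, 5, "autosomal"), 1e-9)
  # finite upper bounds: [u, v] = [u, Inf) - [v, Inf), and [0, Inf) = 1
  p_uv <- spanning_prob_no_consanguinity(500, 2, "autosomal", v = 8)
  expect_equal(p_uv,
               spanning_prob_no_consanguinity(500, 2, "autosomal") -
                 spanning_prob_no_consanguinity(500, 8, "autosomal"))
  expect_gt(p_uv, 0)
})

test_that("the no-consanguinity X:A ratio runs from 1 to 2", {
  expect_equal(xa_ratio_no_consanguinity(500, 0), 1)
  expect_equal(xa_ratio_no_consanguinity(1e8, 5), 2, tolerance = 1e-4)
  # consistency with the two spanning probabilities
  expect_equal(xa_ratio_no_consanguinity(500, 5),
               spanning_prob_no_consanguinity(500, 5, "x") /
                 spanning_prob_no_consanguinity(500, 5, "autosomal"))
  # monotone increasing in N for u > 0
  ns <- c(100, 1000, 10000, 1e6)
  vals <- vapply(ns, xa_ratio_no_consanguinity, numeric(1), u = 5)
  expect_true(all(diff(vals) > 0))
})

test_that("TMRCA cumulative distributions have the right shape", {
  r <- consang_rates(cpp = 0.2, cpc = 0.1, cmp = 0.3, cmc = 0.1)
  for (chrom in c("autosomal", "x")) {
    # between-individuals: no atom at zero
    expect_equal(tmrca_cdf(0, 500, r, chrom, "between"), 0)
    ts <- seq(0, 2e4, length.out = 200)
    cdf_w <- tmrca_cdf(ts, 500, r, chrom, "within")
    expect_true(all(diff(cdf_w) > 0))
    expect_equal(tmrca_cdf(1e9, 500, r, chrom, "within"), 1, tolerance = 1e-12)
    # the within atom equals the instantaneous-coalescence probability
    expect_equal(tmrca_cdf(0, 500, r, chrom, "within"),
                 instantaneous_coalescence_prob(r, chrom))
  }
  # all-first-cousin autosomal atom: (1/16) / (13/16) = 1/13
  expect_equal(tmrca_cdf(0, 500, consang_rates(cpp = 1), "autosomal",
                         "within"), 1 / 13)
  # no consanguinity reduces to the standard coalescent
  for (t in c(100, 1000, 5000)) {
    expect_equal(tmrca_cdf(t, 500, consang_rates(), "autosomal", "between"),
                 1 - exp(-t / 2000))
    expect_equal(tmrca_cdf(t, 500, consang_rates(), "x", "between"),
                 1 - exp(-t / 1500))
  }
  # the X distribution ignores patrilateral rates entirely
  expect_equal(tmrca_cdf(700, 500, consang_rates(cpp = 0.5, cpc = 0.3,
                                                 cmp = 0.1), "x", "within"),
               tmrca_cdf(700, 500, consang_rates(cmp = 0.1), "x", "within"))
})

test_that("the between-individual density integrates to 1 with mean ne_eff", {
  for (cfg in list(list(r = consang_rates(), m = 4 * 500),
                   list(r = consang_rates(cpp = 0.2, cmc = 0.2),
                        m = 4 * 500 * (1 - 3 * 0.4 / 16)))) {
    total <- integrate(function(t) tmrca_pdf_between(t, 500, cfg$r,
                                                     "autosomal"),
                       0, Inf, rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-8)
    mean_t <- integrate(function(t) t * tmrca_pdf_between(t, 500, cfg$r,
                                                          "autosomal"),
                        0, Inf, rel.tol = 1e-10)$value
    expect_equal(mean_t, cfg$m, tolerance = 1e-6)
  }
})

test_that("instantaneous coalescence probabilities hit the pure-type values", {
  expect_equal(instantaneous_coalescence_prob(consang_rates(), "autosomal"), 0)
  expect_equal(instantaneous_coalescence_prob(consang_rates(), "x"), 0)
  expect_equal(instantaneous_coalescence_prob(consang_rates(cpp = 1),
                                              "autosomal"), 1 / 13)
  expect_equal(instantaneous_coalescence_prob(consang_rates(cmp = 1), "x"),
               3 / 11)
  # patrilateral mating closes no loops on the X
  expect_equal(instantaneous_coalescence_prob(consang_rates(cpp = 0.7,
                                                            cpc = 0.3), "x"),
               0)
  # strictly increasing in each relevant rate
  pm <- function(...) instantaneous_coalescence_prob(consang_rates(...),
                                                     "autosomal")
  expect_true(all(diff(vapply(seq(0, 1, 0.1), function(v) pm(cpc = v),
                              numeric(1))) > 0))
})

test_that("expected sharing fractions agree with quadrature and reduce", {
  for (r in rate_grid()) {
    for (chrom in c("autosomal", "x")) {
      for (cfg in list(c(500, 5), c(1000, 0.1), c(5000, 1))) {
        ibd <- expected_ibd_fraction(cfg[1], r, cfg[2], chrom)
        roh <- expected_roh_fraction(cfg[1], r, cfg[2], chrom)
        expect_equal(ibd, oracle_ibd_fraction(cfg[1], r, cfg[2], chrom),
                     tolerance = 1e-7)
        expect_equal(roh, oracle_roh_fraction(cfg[1], r, cfg[2], chrom),
                     tolerance = 1e-7)
        expect_gte(ibd, 0); expect_lte(ibd, 1)
        expect_gte(roh, ibd - 1e-15)  # the ROH atom only adds sharing
      }
      # u = 0 saturates; huge u leaves only the atom
      expect_equal(expected_roh_fraction(500, r, 0, chrom), 1)
      expect_equal(expected_ibd_fraction(500, r, 0, chrom), 1)
      expect_equal(expected_roh_fraction(500, r, 1e12, chrom),
                   instantaneous_coalescence_prob(r, chrom),
                   tolerance = 1e-10)
    }
  }
  # zero consanguinity collapses to the plain spanning probabilities
  r0 <- consang_rates()
  for (chrom in c("autosomal", "x")) {
    expect_identical(expected_ibd_fraction(500, r0, 5, chrom),
                     spanning_prob_no_consanguinity(500, 5, chrom))
    expect_identical(expected_roh_fraction(500, r0, 5, chrom),
                     expected_ibd_fraction(500, r0, 5, chrom))
  }
  # IBD sharing increases with the rates that matter for each chromosome
  base <- expected_ibd_fraction(500, consang_rates(), 5, "autosomal")
  expect_gt(expected_ibd_fraction(500, consang_rates(cpc = 0.3), 5,
                                  "autosomal"), base)
  base_x <- expected_ibd_fraction(500, consang_rates(), 5, "x")
  expect_gt(expected_ibd_fraction(500, consang_rates(cmp = 0.3), 5, "x"),
            base_x)
})

test_that("limiting X:A ratios hit their closed-form landmarks", {
  expect_error(limiting_xa_ratio_roh(consang_rates()), "undefined")
  expect_equal(limiting_xa_ratio_roh(consang_rates(cpp = 0.5)), 0)
  expect_equal(limiting_xa_ratio_roh(consang_rates(cmp = 1)), 39 / 11)
  expect_equal(limiting_xa_ratio_roh(consang_rates(cmc = 1)), 13 / 5)

  expect_equal(limiting_xa_ratio_ibd(consang_rates()), 2)
  expect_equal(limiting_xa_ratio_ibd(consang_rates(cpp = 0.6, cpc = 0.4)),
               13 / 8)
  expect_equal(limiting_xa_ratio_ibd(consang_rates(cmp = 1)), 221 / 88)
  expect_equal(limiting_xa_ratio_ibd(consang_rates(cmc = 1)), 91 / 40)
})

test_that("finite-N sharing ratios converge to their large-N limits", {
  for (r in rate_grid()) {
    if (r$c1 == 0) next
    expect_equal(xa_sharing_ratio(1e8, r, 5, "roh"),
                 limiting_xa_ratio_roh(r), tolerance = 1e-3)
    expect_equal(xa_sharing_ratio(1e8, r, 5, "ibd"),
                 limiting_xa_ratio_ibd(r), tolerance = 1e-3)
  }
  expect_equal(xa_sharing_ratio(500, consang_rates(), 5, "roh"),
               xa_ratio_no_consanguinity(500, 5))
  expect_equal(xa_sharing_ratio(500, consang_rates(), 5, "ibd"),
               xa_ratio_no_consanguinity(500, 5))
})

test_that("single mating types order the ratio as matrilateral > none > patrilateral", {
  base_roh <- xa_sharing_ratio(500, consang_rates(), 5, "roh")
  base_ibd <- xa_sharing_ratio(500, consang_rates(), 5, "ibd")
  for (v in c(0.05, 0.2, 0.5, 0.8)) {
    roh <- vapply(c("cpp", "cpc", "cmp", "cmc"), function(ty) {
      xa_sharing_ratio(500, do.call(consang_rates, setNames(list(v), ty)),
                       5, "roh")
    }, numeric(1))
    ibd <- vapply(c("cpp", "cpc", "cmp", "cmc"), function(ty) {
      xa_sharing_ratio(500, do.call(consang_rates, setNames(list(v), ty)),
                       5, "ibd")
    }, numeric(1))
    # patrilateral-parallel and -cross act identically
    expect_equal(roh[["cpp"]], roh[["cpc"]], tolerance = 1e-12)
    expect_equal(ibd[["cpp"]], ibd[["cpc"]], tolerance = 1e-12)
    # matrilateral-parallel > matrilateral-cross > baseline > patrilateral
    expect_gt(roh[["cmp"]], roh[["cmc"]])
    expect_gt(roh[["cmc"]], base_roh)
    expect_lt(roh[["cpp"]], base_roh)
    expect_gt(ibd[["cmp"]], ibd[["cmc"]])
    expect_gt(ibd[["cmc"]], base_ibd)
    expect_lt(ibd[["cpp"]], base_ibd)
    # away from the smallest rates (where the finite-N baseline of 1.985
    # still dominates), consanguinity distorts ROH ratios at least as much
    # as IBD ratios
    if (v >= 0.2) {
      expect_gte(abs(roh[["cmp"]] - 2), abs(ibd[["cmp"]] - 2))
      expect_gte(abs(roh[["cmc"]] - 2), abs(ibd[["cmc"]] - 2))
      expect_gte(abs(roh[["cpp"]] - 2), abs(ibd[["cpp"]] - 2))
    }
  }
})

test_that("ratio ranges over N find interior maxima and degenerate limits", {
  r <- consang_rates(cpp = 0.02685, cpc = 0.01342, cmp = 0.04027,
                     cmc = 0.02685)
  rng <- ratio_range_over_N(r, 0.1, 500, 50000, "roh")
  expect_lt(rng[["min"]], rng[["max"]])
  # this population's ROH maximum sits strictly inside the N range
  expect_gt(attr(rng, "argmax"), 1000)
  expect_lt(attr(rng, "argmax"), 49000)
  # grid extrema are genuine: the polished value beats every grid value
  grid_vals <- vapply(exp(seq(log(500), log(50000), length.out = 200)),
                      function(n) xa_sharing_ratio(n, r, 0.1, "roh"),
                      numeric(1))
  expect_gte(rng[["max"]], max(grid_vals) - 1e-9)
  expect_lte(rng[["min"]], min(grid_vals) + 1e-9)
  # as u -> 0 the ratio flattens to 1
  tiny <- ratio_range_over_N(consang_rates(), 1e-9, 500, 50000, "roh")
  expect_equal(as.vector(tiny), c(1, 1), tolerance = 1e-4)
  expect_error(ratio_range_over_N(r, 0.1, 5000, 500), "below")
})
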