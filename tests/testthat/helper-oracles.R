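# Independent numerical oracles: expected sharing fractions recomputed by
# adaptive quadrature from the coalescence-time density and the Erlang
# segment-length model, without using the closed forms under test.

oracle_scale <- function(chrom) if (chrom == "autosomal") 50 else 75

# exponential rate of the between-individual TMRCA, from first principles
oracle_rate <- function(n_pairs, rates, chrom) {
  if (chrom == "autosomal") {
    1 / (4 * n_pairs * (1 - 3 * rates$c1 / 16))
  } else {
    (1 + rates$cmp / 16 - rates$cmc / 8) /
      (3 * n_pairs * (1 - 5 * rates$cmp / 16 - 3 * rates$cmc / 8))
  }
}

oracle_point_mass <- function(rates, chrom) {
  if (chrom == "autosomal") {
    (rates$c1 / 16) / (1 - 3 * rates$c1 / 16)
  } else {
    (3 * rates$cmp / 16 + rates$cmc / 8) /
      (1 - 5 * rates$cmp / 16 - 3 * rates$cmc / 8)
  }
}

# E[f] between individuals: integral of the TMRCA density against the
# analytic Erlang tail (1 + u t / s) exp(-u t / s)
oracle_ibd_fraction <- function(n_pairs, rates, u, chrom) {
  lam <- oracle_rate(n_pairs, rates, chrom)
  s <- oracle_scale(chrom)
  integrate(function(t) {
    lam * exp(-lam * t) * (1 + u * t / s) * exp(-u * t / s)
  }, 0, Inf, rel.tol = 1e-12, abs.tol = 1e-13)$value
}

oracle_roh_fraction <- function(n_pairs, rates, u, chrom) {
  pm <- oracle_point_mass(rates, chrom)
  pm + (1 - pm) * oracle_ibd_fraction(n_pairs, rates, u, chrom)
}

# fully numeric double integral: outer over TMRCA, inner over the Erlang
# segment-length density itself (no analytic tail); slow, used sparingly
oracle_spanning_double <- function(n_pairs, u, chrom) {
  ne <- if (chrom == "autosomal") 4 * n_pairs else 3 * n_pairs
  s <- oracle_scale(chrom)
  outer_f <- function(t) {
    vapply(t, function(ti) {
      r <- ti / s
      # truncate the inner integral where the Erlang tail is negligible
      inner <- if (r * u > 500) 0 else {
        integrate(function(l) r^2 * l * exp(-r * l), u, u + 500 / r,
                  rel.tol = 1e-10)$value
      }
      exp(-ti / ne) / ne * inner
    }, numeric(1))
  }
  # the integrand decays at rate 1/ne + u/s; keep the range tight so the
  # adaptive rule resolves the near-origin mass
  integrate(outer_f, 0, 60 / (1 / ne + u / s), rel.tol = 1e-9)$value
}

# deterministic grid of rate vectors spanning the four mating types
rate_grid <- function() {
  list(
    consang_rates(),
    consang_rates(cpp = 0.4),
    consang_rates(cpc = 0.3),
    consang_rates(cmp = 0.4),
    consang_rates(cmc = 0.4),
    consang_rates(cpp = 0.1, cpc = 0.1, cmp = 0.1, cmc = 0.1),
    consang_rates(cpp = 0.05, cmp = 0.3),
    consang_rates(cpc = 0.2, cmc = 0.25)
  )
}
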