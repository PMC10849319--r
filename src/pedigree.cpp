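// Backward-in-time Monte Carlo on the diploid mating-pair model with
// first-cousin consanguinity.
//
// Two gene lineages are traced generation by generation. A lineage is
// identified by (mating pair, carrier sex, copy), where copy records which
// parent the carried gene copy came from (0 = paternal, 1 = maternal); a
// male's X copy is always maternal. Each generation, the natal (parental)
// mating pair of a carrier is uniform over the N pairs of the previous
// generation, except where consanguinity constrains it: a mating pair is,
// independently each generation, consanguineous of type pp/pc/mp/mc with
// probabilities (cpp, cpc, cmp, cmc), in which case the two members'
// designated parents are siblings, i.e. children of one shared
// (uniformly chosen) grandparental pair. Only the pairs currently occupied
// by the traced lineages ever need their labels resolved, so the pedigree
// is never built explicitly and per-generation work is O(1).
//
// When the two lineages sit in distinct pairs with no pending sibling
// constraint, their natal draws are i.i.d. uniform, so the number of
// generations until they next occupy one pair is Geometric(1/N) and the
// X carrier-sex chain (male -> mother; female -> either parent) has a
// closed-form n-step law. That meeting time is sampled directly instead of
// stepping through the empty generations; the two code paths are
// statistically identical and the naive path is kept for verification.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Lin {
  int pair;
  int sex;   // 0 = male, 1 = female
  int copy;  // 0 = paternal, 1 = maternal
};

struct Link {
  bool active;
  int pair_a, sex_a, pair_b, sex_b;
};

inline int rand_pair(int n) {
  int k = static_cast<int>(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

inline int rand_pair_excl(int n, int excl) {
  int k = static_cast<int>(unif_rand() * (n - 1));
  if (k >= n - 1) k = n - 2;
  return k >= excl ? k + 1 : k;
}

inline int rand_bit() { return unif_rand() < 0.5 ? 0 : 1; }

// P(carrier is male after g more generations | current sex), X chromosome.
// Two-state chain: male -> female w.p. 1; female -> male w.p. 1/2.
inline double x_male_prob(int sex, double g) {
  double mag = std::pow(0.5, g);
  double sgn = (static_cast<long long>(g) % 2 == 0) ? 1.0 : -1.0;  // (-1/2)^g
  double eig = sgn * mag;
  return (sex == 0) ? (1.0 / 3.0 + 2.0 / 3.0 * eig)
                    : (1.0 / 3.0 - 1.0 / 3.0 * eig);
}

// Move one lineage into its parent: the natal pair q was already resolved.
inline void descend(Lin &l, int q, bool is_x) {
  int parent_sex = (l.copy == 0) ? 0 : 1;
  l.pair = q;
  l.sex = parent_sex;
  if (is_x) {
    l.copy = (parent_sex == 0) ? 1 : rand_bit();  // male X is maternal
  } else {
    l.copy = rand_bit();
  }
}

// One backward generation for both lineages. Resolves natal pairs (honoring
// a pending sibling link and creating a new one when a co-occupied pair is
// consanguineous), moves both lineages, and reports coalescence.
inline bool step_generation(Lin &a, Lin &b, int n, bool is_x,
                            const double *cr, Link &link, bool &escaped,
                            bool &link_used) {
  int qa, qb;
  Link newlink = {false, 0, 0, 0, 0};

  if (a.pair == b.pair) {
    if (a.sex == b.sex) {
      // same individual: one natal pair for both lineages
      qa = qb = rand_pair(n);
    } else {
      // spouses of one mating pair: the pair's consanguinity label matters
      double u = unif_rand();
      int type = 0;  // 0 none, 1 pp, 2 pc, 3 mp, 4 mc
      double acc = 0.0;
      for (int k = 0; k < 4; ++k) {
        acc += cr[k];
        if (u < acc) { type = k + 1; break; }
      }
      if (type == 0) {
        qa = rand_pair(n);
        qb = rand_pair(n);
      } else {
        int qm = rand_pair(n);             // natal pair of the male member
        int qf = rand_pair_excl(n, qm);    // natal pair of the female member
        qa = (a.sex == 0) ? qm : qf;
        qb = (b.sex == 0) ? qm : qf;
        // which parent of each member is one of the two siblings
        int sm = (type <= 2) ? 0 : 1;               // in qm: pp,pc father; mp,mc mother
        int sf = (type == 1 || type == 4) ? 0 : 1;  // in qf: pp,mc father; pc,mp mother
        newlink = {true, qm, sm, qf, sf};
      }
    }
  } else {
    bool use_link = false;
    if (link.active) {
      bool direct = (a.pair == link.pair_a && a.sex == link.sex_a &&
                     b.pair == link.pair_b && b.sex == link.sex_b);
      bool swapped = (b.pair == link.pair_a && b.sex == link.sex_a &&
                      a.pair == link.pair_b && a.sex == link.sex_b);
      use_link = direct || swapped;
    }
    if (use_link) {
      link_used = true;
      qa = qb = rand_pair(n);  // the two siblings share one natal pair
    } else {
      // unconstrained independent draws: the consanguineous-loop episode
      // (if any) is over and the slow phase has begun
      escaped = true;
      qa = rand_pair(n);
      qb = rand_pair(n);
    }
  }

  link = newlink;
  descend(a, qa, is_x);
  descend(b, qb, is_x);
  return a.pair == b.pair && a.sex == b.sex && a.copy == b.copy;
}

}  // namespace

// [[Rcpp::export]]
List cpp_sample_tmrca(int n_pairs, NumericVector rates, bool is_x,
                      bool within, int n_reps, bool use_skip,
                      int carrier_sex) {
  if (n_pairs < 2) stop("n_pairs must be at least 2");
  if (rates.size() != 4) stop("rates must be length 4 (cpp, cpc, cmp, cmc)");
  const double *cr = REAL(rates);

  std::vector<double> tmrca(n_reps);
  LogicalVector fast(n_reps);
  const long long cap =
      100LL * static_cast<long long>(n_pairs) * (is_x ? 3LL : 4LL);

  for (int rep = 0; rep < n_reps; ++rep) {
    Lin a, b;
    if (within) {
      int p = rand_pair(n_pairs);
      int s = is_x ? 1 : (carrier_sex >= 0 ? carrier_sex : rand_bit());
      a = {p, s, 0};
      b = {p, s, 1};
    } else {
      int p1 = rand_pair(n_pairs);
      int p2 = rand_pair_excl(n_pairs, p1);
      for (int i = 0; i < 2; ++i) {
        Lin &l = (i == 0) ? a : b;
        int p = (i == 0) ? p1 : p2;
        if (is_x) {
          int s = (unif_rand() < 1.0 / 3.0) ? 0 : 1;  // uniform over 3N copies
          l = {p, s, (s == 0) ? 1 : rand_bit()};
        } else {
          l = {p, rand_bit(), rand_bit()};
        }
      }
    }

    long long t = 0;
    Link link = {false, 0, 0, 0, 0};
    bool coalesced = false;
    // "fast" (point-mass analogue) = coalescence through a closed
    // consanguineous loop during the initial episode, before the two
    // lineages ever occupy distinct mating pairs with no pending sibling
    // constraint; once they disperse, the slow (exponential) phase has
    // begun. Requiring an actually-used sibling link excludes the O(1/N)
    // random early collisions that exist even without consanguinity.
    bool escaped = (a.pair != b.pair);
    bool link_used = false;

    while (!coalesced) {
      if (use_skip && a.pair != b.pair && !link.active) {
        escaped = true;
        // fast-forward over the generations in which the two lineages
        // wander in distinct, unconstrained pairs
        double g = R::rgeom(1.0 / n_pairs) + 1.0;
        t += static_cast<long long>(g);
        if (t > cap) stop("lineages failed to coalesce within 100x the lineage count");
        int q = rand_pair(n_pairs);
        for (int i = 0; i < 2; ++i) {
          Lin &l = (i == 0) ? a : b;
          if (is_x) {
            int s = (unif_rand() < x_male_prob(l.sex, g)) ? 0 : 1;
            l = {q, s, (s == 0) ? 1 : rand_bit()};
          } else {
            l = {q, rand_bit(), rand_bit()};
          }
        }
        coalesced = (a.sex == b.sex && a.copy == b.copy);
      } else {
        ++t;
        if (t > cap) stop("lineages failed to coalesce within 100x the lineage count");
        coalesced = step_generation(a, b, n_pairs, is_x, cr, link, escaped,
                                    link_used);
      }
    }
    tmrca[rep] = static_cast<double>(t);
    fast[rep] = !escaped && link_used;
  }

  return List::create(_["tmrca"] = NumericVector(tmrca.begin(), tmrca.end()),
                      _["fast"] = fast);
}
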