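// Fast theta-seeded coalescent replicates with infinite-sites mutation.
// Time is in coalescent units (2 * base_Ne generations); population sizes
// are relative to base_Ne, so the pairwise coalescence rate in a deme of
// relative size f is 1 / f, and mutations arrive at rate theta / 2 per
// lineage per unit time. Clades are stored as 64-bit masks, so n <= 64.
// Uses R's RNG so results honour set.seed() on the calling side.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

struct Lineage {
  uint64_t mask;
  double birth;
  int deme;
};

// coalesce within a single pool (deme id `deme`) until t_max or one
// lineage left; piecewise-constant relative sizes
static void coalesce_pool(std::vector<Lineage>& act, double& t, double t_max,
                          const std::vector<double>& breaks,
                          const std::vector<double>& sizes,
                          std::vector<uint64_t>& emask,
                          std::vector<double>& elen) {
  size_t e = 0;
  while (e + 1 < breaks.size() && breaks[e + 1] <= t) ++e;
  for (;;) {
    int k = (int)act.size();
    if (k <= 1 || t >= t_max) return;
    double rate = k * (k - 1) / 2.0 / sizes[e];
    double w = exp_rand() / rate;
    double epoch_end = (e + 1 < breaks.size()) ? breaks[e + 1] : R_PosInf;
    double bound = epoch_end < t_max ? epoch_end : t_max;
    if (t + w >= bound) {
      t = bound;
      if (bound == epoch_end && epoch_end < t_max) ++e;
      continue;
    }
    t += w;
    int i = (int)(unif_rand() * k); if (i >= k) i = k - 1;
    int j = (int)(unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
    if (j >= i) ++j;
    emask.push_back(act[i].mask); elen.push_back(t - act[i].birth);
    emask.push_back(act[j].mask); elen.push_back(t - act[j].birth);
    act[i].mask |= act[j].mask;
    act[i].birth = t;
    act.erase(act.begin() + j);
  }
}

// structured phase: two isolated demes of relative size 1 between t and
// t_max; lineage deme labels already assigned
static void coalesce_two_demes(std::vector<Lineage>& act, double& t,
                               double t_max,
                               std::vector<uint64_t>& emask,
                               std::vector<double>& elen) {
  for (;;) {
    int kA = 0;
    for (auto& l : act) if (l.deme == 0) ++kA;
    int kB = (int)act.size() - kA;
    double rA = kA * (kA - 1) / 2.0, rB = kB * (kB - 1) / 2.0;
    if (rA + rB <= 0 || t >= t_max) return;
    double w = exp_rand() / (rA + rB);
    if (t + w >= t_max) { t = t_max; return; }
    t += w;
    int deme = (unif_rand() * (rA + rB) < rA) ? 0 : 1;
    std::vector<int> pool;
    for (int i = 0; i < (int)act.size(); ++i)
      if (act[i].deme == deme) pool.push_back(i);
    int k = (int)pool.size();
    int a = (int)(unif_rand() * k); if (a >= k) a = k - 1;
    int b = (int)(unif_rand() * (k - 1)); if (b >= k - 1) b = k - 2;
    if (b >= a) ++b;
    int i = pool[a], j = pool[b];
    emask.push_back(act[i].mask); elen.push_back(t - act[i].birth);
    emask.push_back(act[j].mask); elen.push_back(t - act[j].birth);
    act[i].mask |= act[j].mask;
    act[i].birth = t;
    act.erase(act.begin() + j);
  }
}

static inline int popcount64(uint64_t x) {
#ifdef __GNUC__
  return __builtin_popcountll(x);
#else
  int c = 0; while (x) { x &= x - 1; ++c; } return c;
#endif
}

// [[Rcpp::export]]
NumericMatrix cpp_null_summaries(int n, NumericVector theta, int n_reps,
                                 int model_type, NumericVector breaks,
                                 NumericVector sizes, double t_fuse,
                                 double t_div, double mix) {
  if (n < 2 || n > 64) stop("compiled path requires 2 <= n <= 64");
  int n_loci = theta.size();
  NumericMatrix out(n_reps * n_loci, 7);
  colnames(out) = CharacterVector::create("S", "K", "etaS", "Knos", "Hn",
                                          "R2", "ZnS");
  std::vector<double> brk(breaks.begin(), breaks.end());
  std::vector<double> sz(sizes.begin(), sizes.end());
  std::vector<double> one_brk(1, 0.0), one_sz(1, 1.0);
  double npairs = n * (n - 1) / 2.0;
  uint64_t full = (n == 64) ? ~0ULL : ((1ULL << n) - 1);

  std::vector<uint64_t> emask;
  std::vector<double> elen;
  std::vector<uint64_t> sites;
  std::vector<uint64_t> groups, next_groups;
  std::vector<int> U(n);

  for (int rep = 0; rep < n_reps; ++rep) {
    for (int loc = 0; loc < n_loci; ++loc) {
      emask.clear(); elen.clear();
      // --- genealogy ---
      std::vector<Lineage> act(n);
      for (int i = 0; i < n; ++i) act[i] = { 1ULL << i, 0.0, 0 };
      double t = 0.0;
      if (model_type == 1) {
        coalesce_pool(act, t, t_fuse, one_brk, one_sz, emask, elen);
        if (act.size() > 1) {
          for (auto& l : act) l.deme = (unif_rand() < mix) ? 0 : 1;
          t = t_fuse;
          coalesce_two_demes(act, t, t_div, emask, elen);
          if (act.size() > 1) {
            t = t_div;
            coalesce_pool(act, t, R_PosInf, one_brk, one_sz, emask, elen);
          }
        }
      } else {
        coalesce_pool(act, t, R_PosInf, brk, sz, emask, elen);
      }
      // --- infinite-sites mutations ---
      double tot = 0.0;
      for (double l : elen) tot += l;
      int nmut = (int)R::rpois(theta[loc] / 2.0 * tot);
      sites.clear();
      for (int m = 0; m < nmut; ++m) {
        double u = unif_rand() * tot, cum = 0.0;
        size_t e = 0;
        for (; e < elen.size(); ++e) { cum += elen[e]; if (u <= cum) break; }
        if (e >= elen.size()) e = elen.size() - 1;
        sites.push_back(emask[e]);
      }
      // --- per-locus summaries ---
      int S = (int)sites.size();
      double K = 0.0, Knos = 0.0;
      int etaS = 0;
      std::fill(U.begin(), U.end(), 0);
      for (int s = 0; s < S; ++s) {
        int c = popcount64(sites[s]);
        double contrib = (double)c * (n - c) / npairs;
        K += contrib;
        bool sing = (c == 1 || c == n - 1) && n > 2;
        if (sing) {
          ++etaS;
          uint64_t carrier = (c == 1) ? sites[s] : (~sites[s] & full);
#ifdef __GNUC__
          U[__builtin_ctzll(carrier)]++;
#else
          for (int i = 0; i < n; ++i) if (carrier >> i & 1) { U[i]++; break; }
#endif
        } else {
          Knos += contrib;
        }
      }
      // haplotype count by partition refinement
      groups.clear(); groups.push_back(full);
      for (int s = 0; s < S; ++s) {
        next_groups.clear();
        for (uint64_t g : groups) {
          uint64_t in = g & sites[s], outm = g & ~sites[s];
          if (in) next_groups.push_back(in);
          if (outm) next_groups.push_back(outm);
        }
        groups.swap(next_groups);
      }
      int Hn = (int)groups.size();
      // R2
      double R2 = NA_REAL;
      if (S > 0) {
        double ss = 0.0;
        for (int i = 0; i < n; ++i) {
          double d = U[i] - K / 2.0;
          ss += d * d;
        }
        R2 = std::sqrt(ss / n) / S;
      }
      // ZnS over pairs of (biallelic) sites
      double ZnS = NA_REAL;
      if (S >= 2) {
        double sum = 0.0; long cnt = 0;
        for (int s1 = 0; s1 < S; ++s1) {
          double c1 = popcount64(sites[s1]);
          double p1 = c1 / n;
          for (int s2 = s1 + 1; s2 < S; ++s2) {
            double c2 = popcount64(sites[s2]);
            double p2 = c2 / n;
            double p11 = popcount64(sites[s1] & sites[s2]) / (double)n;
            double dd = p11 - p1 * p2;
            sum += dd * dd / (p1 * (1 - p1) * p2 * (1 - p2));
            ++cnt;
          }
        }
        ZnS = sum / cnt;
      }
      int row = rep * n_loci + loc;
      out(row, 0) = S; out(row, 1) = K; out(row, 2) = etaS;
      out(row, 3) = Knos; out(row, 4) = Hn;
      out(row, 5) = R2; out(row, 6) = ZnS;
    }
  }
  return out;
}
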