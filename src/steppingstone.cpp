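// Individual-based diploid stepping-stone simulator of polygenic divergence
// with gene flow.  Genotypes are stored as two haplotype arrays (0/1 = lake/
// stream allele) so that both free recombination (unlinked loci) and a
// single-chromosome crossover variant are available.  All randomness comes
// from R's RNG (GetRNGstate/PutRNGstate via Rcpp), so set.seed() on the R
// side makes runs reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

// cache of random bits carved out of single unif_rand() draws
struct BitStream {
  uint32_t bits = 0;
  int n = 0;
  inline int next() {
    if (n == 0) {
      bits = (uint32_t)(unif_rand() * 4294967296.0);
      n = 32;
    }
    int b = bits & 1u;
    bits >>= 1;
    --n;
    return b;
  }
};

typedef std::vector<signed char> HapVec;

inline int rand_below(int n) {
  int r = (int)(unif_rand() * n);
  return r >= n ? n - 1 : r;
}

void gather_members(const std::vector<int>& deme, int D,
                    std::vector<std::vector<int> >& members) {
  members.assign(D, std::vector<int>());
  for (size_t i = 0; i < deme.size(); ++i) members[deme[i]].push_back((int)i);
}

// migration: round(m*N) individuals per deme per adjacent neighbour, chosen
// without replacement (the two migrant sets of an interior deme are
// disjoint); all moves are based on the pre-migration state
void migrate_phase(std::vector<int>& deme, int D, double m) {
  if (m < 0 || 2 * m > 1) stop("migration rate must satisfy 0 <= 2m <= 1");
  if (m == 0 || D < 2) return;
  std::vector<std::vector<int> > members;
  gather_members(deme, D, members);
  std::vector<int> newdeme = deme;
  for (int d = 0; d < D; ++d) {
    int N = (int)members[d].size();
    if (N == 0) continue;
    int k = (int)std::lround(m * N);
    bool left = d > 0, right = d + 1 < D;
    int need = k * ((int)left + (int)right);
    if (k == 0 || need == 0) continue;
    if (need > N) need = N;
    std::vector<int>& v = members[d];
    for (int j = 0; j < need; ++j) {           // partial Fisher-Yates
      int r = j + rand_below(N - j);
      std::swap(v[j], v[r]);
    }
    int idx = 0;
    if (left)
      for (int j = 0; j < k && idx < need; ++j) newdeme[v[idx++]] = d - 1;
    if (right)
      for (int j = 0; j < k && idx < need; ++j) newdeme[v[idx++]] = d + 1;
  }
  deme.swap(newdeme);
}

inline int pick_parent(const std::vector<double>& cum) {
  double u = unif_rand() * cum.back();
  return (int)(std::upper_bound(cum.begin(), cum.end(), u) - cum.begin());
}

void make_gamete(const HapVec& h1, const HapVec& h2, int parent, int L,
                 signed char* out, int linkage, int crossover_mode,
                 BitStream& bs, std::vector<int>& cuts_buf) {
  const signed char* a = &h1[(size_t)parent * L];
  const signed char* b = &h2[(size_t)parent * L];
  if (linkage == 0) {                          // unlinked: free recombination
    for (int l = 0; l < L; ++l)
      out[l] = (a[l] == b[l]) ? a[l] : (bs.next() ? a[l] : b[l]);
  } else {                                     // one chromosome
    int nx = (crossover_mode == 0) ? 1 : (int)R::rpois(1.0);
    cuts_buf.clear();
    for (int j = 0; j < nx; ++j) cuts_buf.push_back(1 + rand_below(L - 1));
    std::sort(cuts_buf.begin(), cuts_buf.end());
    int cur = bs.next();                       // starting haplotype
    size_t ci = 0;
    for (int l = 0; l < L; ++l) {
      while (ci < cuts_buf.size() && cuts_buf[ci] == l) { cur ^= 1; ++ci; }
      out[l] = cur ? a[l] : b[l];
    }
  }
}

// fitness-weighted reproduction restoring target deme sizes exactly
void reproduce_phase(HapVec& h1, HapVec& h2, std::vector<int>& deme,
                     const std::vector<int>& target, int L,
                     const std::vector<double>& s, int fitness_mode,
                     int linkage, int crossover_mode, bool forbid_selfing) {
  int D = (int)target.size();
  std::vector<std::vector<int> > members;
  gather_members(deme, D, members);
  int Ntot_new = 0;
  for (int d = 0; d < D; ++d) Ntot_new += target[d];
  HapVec nh1((size_t)Ntot_new * L), nh2((size_t)Ntot_new * L);
  std::vector<int> ndeme(Ntot_new);
  std::vector<double> log1ms(L);
  if (fitness_mode == 1)
    for (int l = 0; l < L; ++l) log1ms[l] = std::log1p(-s[l]);

  BitStream bs;
  std::vector<int> cuts_buf;
  int row = 0;
  for (int d = 0; d < D; ++d) {
    const std::vector<int>& mem = members[d];
    int N = (int)mem.size();
    if (N == 0) stop("deme %d is empty after migration", d + 1);
    std::vector<double> cum(N);
    double tot = 0;
    for (int i = 0; i < N; ++i) {
      const signed char* a = &h1[(size_t)mem[i] * L];
      const signed char* b = &h2[(size_t)mem[i] * L];
      double w;
      if (fitness_mode == 0) {                 // additive, floored at 0
        double load = 0;
        if (d == 0)                            // lake: stream allele maladaptive
          for (int l = 0; l < L; ++l) load += s[l] * (a[l] + b[l]);
        else
          for (int l = 0; l < L; ++l) load += s[l] * (2 - a[l] - b[l]);
        w = load >= 1 ? 0.0 : 1.0 - load;
      } else {                                 // multiplicative
        double lw = 0;
        if (d == 0)
          for (int l = 0; l < L; ++l) lw += log1ms[l] * (a[l] + b[l]);
        else
          for (int l = 0; l < L; ++l) lw += log1ms[l] * (2 - a[l] - b[l]);
        w = std::exp(lw);
      }
      tot += w;
      cum[i] = tot;
    }
    if (!(tot > 0)) stop("extinction: all fitness zero in deme %d", d + 1);
    for (int o = 0; o < target[d]; ++o, ++row) {
      int p1 = pick_parent(cum);
      int p2 = pick_parent(cum);
      if (forbid_selfing && N > 1)
        while (p2 == p1) p2 = pick_parent(cum);
      make_gamete(h1, h2, mem[p1], L, &nh1[(size_t)row * L], linkage,
                  crossover_mode, bs, cuts_buf);
      make_gamete(h1, h2, mem[p2], L, &nh2[(size_t)row * L], linkage,
                  crossover_mode, bs, cuts_buf);
      ndeme[row] = d;
    }
  }
  h1.swap(nh1);
  h2.swap(nh2);
  deme.swap(ndeme);
}

NumericMatrix deme_freqs(const HapVec& h1, const HapVec& h2,
                         const std::vector<int>& deme, int D, int L) {
  NumericMatrix freq(D, L);
  std::vector<int> n(D, 0);
  for (size_t i = 0; i < deme.size(); ++i) {
    int d = deme[i];
    ++n[d];
    const signed char* a = &h1[i * L];
    const signed char* b = &h2[i * L];
    for (int l = 0; l < L; ++l) freq(d, l) += a[l] + b[l];
  }
  for (int d = 0; d < D; ++d)
    for (int l = 0; l < L; ++l) freq(d, l) /= (2.0 * n[d]);
  return freq;
}

NumericVector deme_medians(const NumericMatrix& freq) {
  int D = freq.nrow(), L = freq.ncol();
  NumericVector med(D);
  std::vector<double> buf(L);
  for (int d = 0; d < D; ++d) {
    for (int l = 0; l < L; ++l) buf[l] = freq(d, l);
    std::sort(buf.begin(), buf.end());
    med[d] = (L % 2) ? buf[L / 2] : 0.5 * (buf[L / 2 - 1] + buf[L / 2]);
  }
  return med;
}

void init_state(HapVec& h1, HapVec& h2, std::vector<int>& deme,
                const std::vector<int>& sizes, int L, double p0) {
  int Ntot = 0;
  for (size_t d = 0; d < sizes.size(); ++d) Ntot += sizes[d];
  h1.assign((size_t)Ntot * L, 0);
  h2.assign((size_t)Ntot * L, 0);
  deme.assign(Ntot, 0);
  int i = 0;
  for (size_t d = 0; d < sizes.size(); ++d)
    for (int j = 0; j < sizes[d]; ++j) deme[i++] = (int)d;
  for (size_t t = 0; t < h1.size(); ++t) {
    h1[t] = unif_rand() < p0 ? 1 : 0;
    h2[t] = unif_rand() < p0 ? 1 : 0;
  }
}

}  // namespace

// [[Rcpp::export]]
List ss_run_cpp(IntegerVector deme_sizes, int L, NumericVector s, double m,
                int generations, int fitness_mode, int linkage,
                int crossover_mode, double p0, bool forbid_selfing,
                int record_every) {
  if (L < 1) stop("L must be >= 1");
  if ((int)s.size() != L) stop("s must have one entry per locus");
  for (int l = 0; l < L; ++l)
    if (s[l] < 0 || s[l] >= 1) stop("selection coefficients must lie in [0, 1)");
  int D = deme_sizes.size();
  std::vector<int> sizes(deme_sizes.begin(), deme_sizes.end());
  std::vector<double> sv(s.begin(), s.end());

  HapVec h1, h2;
  std::vector<int> deme;
  init_state(h1, h2, deme, sizes, L, p0);

  std::vector<NumericVector> traj;
  std::vector<int> traj_gen;
  for (int gen = 1; gen <= generations; ++gen) {
    migrate_phase(deme, D, m);
    reproduce_phase(h1, h2, deme, sizes, L, sv, fitness_mode, linkage,
                    crossover_mode, forbid_selfing);
    if (record_every > 0 && (gen % record_every == 0 || gen == generations)) {
      traj.push_back(deme_medians(deme_freqs(h1, h2, deme, D, L)));
      traj_gen.push_back(gen);
    }
    if (gen % 200 == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix freq = deme_freqs(h1, h2, deme, D, L);
  NumericVector med = deme_medians(freq);
  NumericMatrix tr(traj.size(), D);
  for (size_t r = 0; r < traj.size(); ++r)
    for (int d = 0; d < D; ++d) tr(r, d) = traj[r][d];
  return List::create(_["freq"] = freq, _["median_freq"] = med,
                      _["traj"] = tr,
                      _["traj_generation"] = IntegerVector(traj_gen.begin(),
                                                           traj_gen.end()));
}

// [[Rcpp::export]]
IntegerVector ss_migrate_cpp(IntegerVector deme0, int D, double m) {
  std::vector<int> deme(deme0.begin(), deme0.end());
  migrate_phase(deme, D, m);
  return IntegerVector(deme.begin(), deme.end());
}

// [[Rcpp::export]]
List ss_reproduce_cpp(IntegerMatrix h1m, IntegerMatrix h2m,
                      IntegerVector deme0, IntegerVector target_sizes,
                      NumericVector s, int fitness_mode, int linkage,
                      int crossover_mode, bool forbid_selfing) {
  int N = h1m.nrow(), L = h1m.ncol();
  if (h2m.nrow() != N || h2m.ncol() != L || deme0.size() != N)
    stop("haplotype/deme dimensions disagree");
  if ((int)s.size() != L) stop("s must have one entry per locus");
  HapVec h1((size_t)N * L), h2((size_t)N * L);
  for (int i = 0; i < N; ++i)
    for (int l = 0; l < L; ++l) {
      h1[(size_t)i * L + l] = (signed char)h1m(i, l);
      h2[(size_t)i * L + l] = (signed char)h2m(i, l);
    }
  std::vector<int> deme(deme0.begin(), deme0.end());
  std::vector<int> target(target_sizes.begin(), target_sizes.end());
  std::vector<double> sv(s.begin(), s.end());
  reproduce_phase(h1, h2, deme, target, L, sv, fitness_mode, linkage,
                  crossover_mode, forbid_selfing);
  int N2 = (int)deme.size();
  IntegerMatrix o1(N2, L), o2(N2, L);
  for (int i = 0; i < N2; ++i)
    for (int l = 0; l < L; ++l) {
      o1(i, l) = h1[(size_t)i * L + l];
      o2(i, l) = h2[(size_t)i * L + l];
    }
  return List::create(_["h1"] = o1, _["h2"] = o2,
                      _["deme"] = IntegerVector(deme.begin(), deme.end()));
}
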