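#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// Counter-based substreams: a row index plus the user seed initialise a
// local xoshiro256++ generator, so panels are reproducible independently of
// R's RNG state and of how many rows were simulated before them.
namespace {

struct Xoshiro {
  uint64_t s[4];

  static uint64_t splitmix(uint64_t& x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  Xoshiro(uint64_t seed, uint64_t stream) {
    uint64_t x = seed ^ (stream * 0xD1B54A32D192ED03ULL + 0x8BB84B93962EACC9ULL);
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
    // avoid the all-zero state
    if (!(s[0] | s[1] | s[2] | s[3])) s[0] = 1;
  }

  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  inline double unif() {  // [0, 1)
    return (next() >> 11) * 0x1.0p-53;
  }

  inline double expo(double rate) {
    double u = unif();
    return -std::log1p(-u) / rate;
  }

  inline int below(int n) {  // uniform on {0, ..., n-1} (Lemire)
    return (int)(((next() >> 32) * (uint64_t)n) >> 32);
  }
};

// event codes (kept in sync with the R-side encoder in scenario.R)
const int EV_MERGE = 0;   // all lineages of pop a move to pop b; a retired
const int EV_ADMIX = 1;   // pop a founded by admixture: each lineage -> b w.p. rate, else c
const int EV_PULSE = 2;   // each lineage of pop a -> pop b w.p. rate; a stays alive
const int EV_SIZE  = 3;   // diploid size of pop a set to `rate`

}  // namespace

// Simulate a panel of unlinked biallelic SNPs under an event-list demography.
// One coalescent genealogy per locus; exactly one mutation placed on the
// genealogy with probability proportional to branch length (fixed-S scheme).
// Loci whose pooled minor allele frequency falls below maf_min are redrawn.
//
// ev_*: events sorted by time (ties applied in the given order).
// pop_sizes: diploid size per population at time 0.
// samp: diploid sample counts per population.
// Returns list(dosage = n_ind x n_loci integer matrix, heights = TMRCA per locus).
// [[Rcpp::export]]
List sim_panel_cpp(NumericVector ev_time, IntegerVector ev_type,
                   IntegerVector ev_a, IntegerVector ev_b, IntegerVector ev_c,
                   NumericVector ev_rate, NumericVector pop_sizes,
                   IntegerVector samp, int n_loci, double maf_min,
                   double seed, double stream, int max_tries = 10000) {
  const int npop = pop_sizes.size();
  const int nev = ev_time.size();
  int n_ind = 0;
  for (int p = 0; p < npop; ++p) n_ind += samp[p];
  const int L = 2 * n_ind;  // haploid tips
  if (L < 2) stop("need at least one diploid sample in total");
  const int max_nodes = 2 * L - 1;

  Xoshiro rng((uint64_t)seed, (uint64_t)stream);

  IntegerMatrix dosage(n_ind, n_loci);
  NumericVector heights(n_loci);

  // per-population lineage lists in one contiguous buffer
  std::vector<int> membuf(npop * L);
  std::vector<int> mcount(npop);
  std::vector<double> birth(max_nodes), blen(max_nodes);
  std::vector<int> ch1(max_nodes), ch2(max_nodes);
  std::vector<int> stack_(max_nodes);
  std::vector<char> derived(L);
  std::vector<double> inv4N(npop);

  for (int loc = 0; loc < n_loci; ++loc) {
    bool accepted = false;
    for (int attempt = 0; attempt < max_tries && !accepted; ++attempt) {
      // initialise tips
      int id = 0;
      for (int p = 0; p < npop; ++p) {
        int* m = &membuf[p * L];
        mcount[p] = 2 * samp[p];
        for (int k = 0; k < 2 * samp[p]; ++k) m[k] = id++;
        inv4N[p] = pop_sizes[p] > 0 ? 1.0 / (4.0 * pop_sizes[p]) : 0.0;
      }
      for (int v = 0; v < L; ++v) birth[v] = 0.0;
      int nn = L, nlin = L, ei = 0;
      double t = 0.0;

      // populations are independent between demographic events, so each one
      // runs its own coalescent within the current epoch
      while (nlin > 1) {
        const double t_next = (ei < nev) ? ev_time[ei] : R_PosInf;
        for (int p = 0; p < npop && nlin > 1; ++p) {
          int k = mcount[p];
          if (k < 2 || inv4N[p] <= 0) continue;
          int* m = &membuf[p * L];
          double tp = t;
          while (k > 1) {
            const double dt = rng.expo(k * (k - 1) * inv4N[p]);
            if (tp + dt > t_next) break;
            tp += dt;
            int i = rng.below(k);
            int j = rng.below(k - 1);
            if (j >= i) ++j;
            const int a = m[i], b = m[j];
            const int v = nn++;
            birth[v] = tp;
            ch1[v] = a;
            ch2[v] = b;
            blen[a] = tp - birth[a];
            blen[b] = tp - birth[b];
            m[i] = v;
            m[j] = m[--k];
            --nlin;
          }
          mcount[p] = k;
        }
        if (nlin <= 1) break;
        // past the last event every population has fully coalesced internally
        if (!R_FINITE(t_next))
          stop("lineages cannot coalesce: no further events and no coalescence rate");
        t = t_next;
        const int type = ev_type[ei], a = ev_a[ei], b = ev_b[ei], c = ev_c[ei];
        const double r = ev_rate[ei];
        int* ma = &membuf[a * L];
        if (type == EV_MERGE) {
          int* mb = &membuf[b * L];
          for (int k = 0; k < mcount[a]; ++k) mb[mcount[b]++] = ma[k];
          mcount[a] = 0;
        } else if (type == EV_ADMIX) {
          int* mb = &membuf[b * L];
          int* mc = &membuf[c * L];
          for (int k = 0; k < mcount[a]; ++k) {
            if (rng.unif() < r) mb[mcount[b]++] = ma[k];
            else mc[mcount[c]++] = ma[k];
          }
          mcount[a] = 0;
        } else if (type == EV_PULSE) {
          int* mb = &membuf[b * L];
          int keep = 0;
          for (int k = 0; k < mcount[a]; ++k) {
            if (rng.unif() < r) mb[mcount[b]++] = ma[k];
            else ma[keep++] = ma[k];
          }
          mcount[a] = keep;
        } else if (type == EV_SIZE) {
          inv4N[a] = r > 0 ? 1.0 / (4.0 * r) : 0.0;
        }
        ++ei;
      }

      const int root = nn - 1;
      heights[loc] = birth[root];

      // place one mutation proportional to branch length
      double total_len = 0.0;
      for (int v = 0; v < root; ++v) total_len += blen[v];
      double target = rng.unif() * total_len;
      int mut = root - 1;
      for (int v = 0; v < root; ++v) {
        target -= blen[v];
        if (target < 0) { mut = v; break; }
      }
      // derived allele = tips below the mutated branch
      for (int v = 0; v < L; ++v) derived[v] = 0;
      int top = 0, nderived = 0;
      stack_[top++] = mut;
      while (top > 0) {
        const int v = stack_[--top];
        if (v < L) {
          derived[v] = 1;
          ++nderived;
        } else {
          stack_[top++] = ch1[v];
          stack_[top++] = ch2[v];
        }
      }
      const int minor = nderived <= L - nderived ? nderived : L - nderived;
      if (maf_min > 0 && (double)minor < maf_min * L) continue;  // redraw locus
      // diploid dosages: tips 2i, 2i+1 belong to individual i
      for (int ind = 0; ind < n_ind; ++ind)
        dosage(ind, loc) = derived[2 * ind] + derived[2 * ind + 1];
      accepted = true;
    }
    if (!accepted) stop("SNP ascertainment failed: minor-allele criterion never met");
  }

  return List::create(_["dosage"] = dosage, _["heights"] = heights);
}
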