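#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <random>
using namespace Rcpp;

// Incremental state for the summed contingency-table likelihood ratio.
// Counts are kept per locus as K x n tables plus row totals; column totals
// and grand totals never change under single-individual moves, so their
// contribution is folded into a per-dataset constant. All x*log(x) values
// are served from a lookup table indexed by integer count, and each
// individual's non-missing calls are pre-compressed into contiguous
// (locus, allele, multiplicity) lists so a move evaluation streams memory.
struct LRState {
  int N, S, ploidy, K;
  std::vector<int> nall;       // alleles per locus
  std::vector<long> off;       // offset of locus s in O
  std::vector<int> O;          // per-locus K x n counts, group-major
  std::vector<int> R;          // per-locus row totals, S*K
  std::vector<double> f;       // f[x] = x*log(x), f[0] = 0
  double const_term;           // sum_s ( f(G_s) - sum_i f(C_si) )
  std::vector<int> z;          // 0-based group labels
  double lr;

  // per-individual compressed calls: for individual i, loci entries
  // ind_start[i]..ind_start[i+1]-1 in (e_s, e_m, e_pair_start); allele
  // multiplicities in (pa, pc) at e_pair_start[t]..e_pair_start[t+1]-1
  std::vector<long> ind_start, e_pair_start;
  std::vector<int> e_s, e_m, pa, pc;

  LRState(const IntegerMatrix& calls, const IntegerVector& nall_, int K_,
          const IntegerVector& z1based)
      : N(calls.nrow()), S(nall_.size()), K(K_) {
    ploidy = calls.ncol() / S;
    nall.assign(nall_.begin(), nall_.end());
    off.resize(S + 1);
    off[0] = 0;
    for (int s = 0; s < S; ++s) off[s + 1] = off[s] + (long)K * nall[s];
    f.resize((long)N * ploidy + 1);
    f[0] = 0.0;
    for (long x = 1; x < (long)f.size(); ++x) f[x] = (double)x * std::log((double)x);
    z.resize(N);
    for (int i = 0; i < N; ++i) z[i] = z1based[i] - 1;

    ind_start.resize(N + 1);
    e_pair_start.push_back(0);
    std::vector<int> aa(ploidy), ca(ploidy);
    for (int i = 0; i < N; ++i) {
      ind_start[i] = (long)e_s.size();
      for (int s = 0; s < S; ++s) {
        int m = 0, nu = 0;
        for (int j = 0; j < ploidy; ++j) {
          int a = calls(i, s * ploidy + j);
          if (a == NA_INTEGER) continue;
          ++m;
          bool seen = false;
          for (int q = 0; q < nu; ++q)
            if (aa[q] == a) { ca[q] += 1; seen = true; break; }
          if (!seen) { aa[nu] = a; ca[nu] = 1; ++nu; }
        }
        if (m == 0) continue;
        e_s.push_back(s);
        e_m.push_back(m);
        for (int q = 0; q < nu; ++q) { pa.push_back(aa[q]); pc.push_back(ca[q]); }
        e_pair_start.push_back((long)pa.size());
      }
    }
    ind_start[N] = (long)e_s.size();
    rebuild();
  }

  void rebuild() {
    O.assign(off[S], 0);
    R.assign((size_t)S * K, 0);
    std::vector<int> colcnt(off[S] ? *std::max_element(nall.begin(), nall.end()) : 1, 0);
    std::vector<int> grand(S, 0);
    std::vector<std::vector<int>> cols(S);
    for (int s = 0; s < S; ++s) cols[s].assign(nall[s], 0);
    for (int i = 0; i < N; ++i) {
      for (long t = ind_start[i]; t < ind_start[i + 1]; ++t) {
        int s = e_s[t];
        R[(size_t)s * K + z[i]] += e_m[t];
        grand[s] += e_m[t];
        for (long q = e_pair_start[t]; q < e_pair_start[t + 1]; ++q) {
          O[off[s] + (long)z[i] * nall[s] + pa[q]] += pc[q];
          cols[s][pa[q]] += pc[q];
        }
      }
    }
    const_term = 0.0;
    for (int s = 0; s < S; ++s) {
      double c = f[grand[s]];
      for (int a = 0; a < nall[s]; ++a) c -= f[cols[s][a]];
      const_term += c;
    }
    lr = full_lr();
  }

  double full_lr() const {
    double v = const_term;
    for (long t = 0; t < off[S]; ++t) v += f[O[t]];
    for (size_t t = 0; t < R.size(); ++t) v -= f[R[t]];
    return v;
  }

  // objective change of moving individual i to each group; delta[z[i]] = 0
  void deltas_for(int i, std::vector<double>& delta) const {
    int g = z[i];
    std::fill(delta.begin(), delta.end(), 0.0);
    for (long t = ind_start[i]; t < ind_start[i + 1]; ++t) {
      int s = e_s[t], m = e_m[t], n_s = nall[s];
      const int* Os = &O[off[s]];
      const int* Rs = &R[(size_t)s * K];
      double d_g = f[Rs[g] - m] - f[Rs[g]];   // row-total change, outgoing
      double c_g = 0.0;                       // cell change, outgoing
      for (long q = e_pair_start[t]; q < e_pair_start[t + 1]; ++q) {
        int og = Os[(long)g * n_s + pa[q]];
        c_g += f[og - pc[q]] - f[og];
      }
      for (int k = 0; k < K; ++k) {
        if (k == g) continue;
        double dc = c_g;
        for (long q = e_pair_start[t]; q < e_pair_start[t + 1]; ++q) {
          int ok = Os[(long)k * n_s + pa[q]];
          dc += f[ok + pc[q]] - f[ok];
        }
        double dr = d_g + f[Rs[k] + m] - f[Rs[k]];
        delta[k] += dc - dr;
      }
    }
  }

  void apply(int i, int to) {
    int g = z[i];
    if (to == g) return;
    for (long t = ind_start[i]; t < ind_start[i + 1]; ++t) {
      int s = e_s[t], n_s = nall[s];
      for (long q = e_pair_start[t]; q < e_pair_start[t + 1]; ++q) {
        O[off[s] + (long)g * n_s + pa[q]] -= pc[q];
        O[off[s] + (long)to * n_s + pa[q]] += pc[q];
      }
      R[(size_t)s * K + g] -= e_m[t];
      R[(size_t)s * K + to] += e_m[t];
    }
    z[i] = to;
  }
};

// deterministic uniform(0,1) stream independent of R's RNG state
struct Rng {
  std::mt19937_64 eng;
  explicit Rng(uint64_t seed) : eng(seed) {}
  double unif() { return (eng() >> 11) * (1.0 / 9007199254740992.0); }
  int unif_int(int n) {
    int v = (int)(unif() * n);
    return v >= n ? n - 1 : v;
  }
};

// [[Rcpp::export]]
double total_lr_core(IntegerMatrix calls, IntegerVector n_alleles,
                     IntegerVector z, int K) {
  LRState st(calls, n_alleles, K, z);
  return st.lr;
}

// [[Rcpp::export]]
List anneal_core(IntegerMatrix calls, IntegerVector n_alleles, int K,
                 IntegerVector z0, double t0, double alpha, int n_epochs,
                 int greedy_epochs, int steps_per_epoch, double seed) {
  LRState st(calls, n_alleles, K, z0);
  Rng rng((uint64_t)seed);
  int N = st.N;
  std::vector<double> delta(K), w(K);
  std::vector<int> best_z = st.z;
  double best_lr = st.lr;
  std::vector<double> trace;
  trace.reserve(n_epochs + greedy_epochs);

  double T = t0;
  for (int ep = 0; ep < n_epochs; ++ep) {
    for (int step = 0; step < steps_per_epoch; ++step) {
      int r = rng.unif_int(N);
      st.deltas_for(r, delta);
      double maxd = 0.0;
      for (int k = 0; k < K; ++k) if (delta[k] > maxd) maxd = delta[k];
      double tot = 0.0;
      for (int k = 0; k < K; ++k) { w[k] = std::exp((delta[k] - maxd) / T); tot += w[k]; }
      double u = rng.unif() * tot, cum = 0.0;
      int pick = K - 1;
      for (int k = 0; k < K; ++k) { cum += w[k]; if (u <= cum) { pick = k; break; } }
      if (pick != st.z[r]) {
        st.apply(r, pick);
        st.lr += delta[pick];
        if (st.lr > best_lr + 1e-12) { best_lr = st.lr; best_z = st.z; }
      }
    }
    trace.push_back(best_lr);
    T *= alpha;
  }

  for (int pass = 0; pass < greedy_epochs; ++pass) {
    bool moved = false;
    for (int i = 0; i < N; ++i) {
      st.deltas_for(i, delta);
      int best_k = st.z[i];
      double bestd = 0.0;
      // strictly improving moves only; first (smallest) label wins near-ties
      for (int k = 0; k < K; ++k)
        if (delta[k] > bestd + 1e-10) { bestd = delta[k]; best_k = k; }
      if (best_k != st.z[i]) {
        st.apply(i, best_k);
        st.lr += bestd;
        moved = true;
        if (st.lr > best_lr + 1e-12) { best_lr = st.lr; best_z = st.z; }
      }
    }
    trace.push_back(best_lr);
    if (!moved) break;
  }

  // return the exactly recomputed LR of the best state (no incremental drift)
  st.z = best_z;
  st.rebuild();
  IntegerVector zout(N);
  for (int i = 0; i < N; ++i) zout[i] = best_z[i] + 1;
  return List::create(_["z"] = zout, _["best_lr"] = st.lr,
                      _["trace"] = NumericVector(trace.begin(), trace.end()));
}
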