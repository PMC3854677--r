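// Metropolis sampler over drug partitions for typed-network block models.
//
// State space: assignments of N drugs to N potential group labels (so every
// set partition is reachable and the single-drug-move proposal is symmetric
// on assignments).  Target density on assignments is exp(-H(P)) / (N)_b,
// where b is the number of occupied groups and (N)_b the falling factorial,
// so that the marginal over set partitions is exp(-H(P)) / Z -- the weight
// the Bayesian model average assigns to each partition, with each partition
// counted once.
//
// H(P) = sum over group pairs (a <= b) of
//        lgamma(n_ab + K) - sum_k lgamma(n^k_ab + 1) - lgamma(K)
// i.e. minus the log Dirichlet marginal likelihood of the pair's type
// counts under a uniform prior on the K-simplex.  Empty cells contribute 0.
// Incremental updates use the one-observation identities
//   add type k:    dH = log(n + K) - log(n_k + 1)
//   remove type k: dH = log(n_k)   - log(n + K - 1).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <random>

using namespace Rcpp;

namespace {

inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

struct SBMState {
  int N, K;
  bool prior_const;                       // include -lgamma(K) per cell
  std::vector<std::vector<std::pair<int, int> > > adj;  // drug -> (nbr, type)
  std::vector<int> g;                      // group of each drug
  std::vector<int> gsize;                  // occupancy of each label
  int nblocks;                             // occupied labels
  std::vector<int> cnt;                    // cell(a,b)*K + k type counts
  std::vector<int> ntot;                   // cell(a,b) totals
  std::vector<double> logtab;              // log(i) for the small integers
  double H;                                // all count updates need

  inline int cell(int a, int b) const {
    return (a <= b) ? a * N + b : b * N + a;
  }

  void init(int N_, int K_, const IntegerMatrix& edges, bool prior_const_) {
    N = N_; K = K_; prior_const = prior_const_;
    adj.assign(N, std::vector<std::pair<int, int> >());
    for (int e = 0; e < edges.nrow(); ++e) {
      int i = edges(e, 0), j = edges(e, 1), k = edges(e, 2);
      adj[i].push_back(std::make_pair(j, k));
      adj[j].push_back(std::make_pair(i, k));
    }
    cnt.assign((size_t)N * N * K, 0);
    ntot.assign((size_t)N * N, 0);
    gsize.assign(N, 0);
    g.assign(N, 0);
    int tabmax = edges.nrow() + K + 2;
    if (tabmax < N + 2) tabmax = N + 2;
    logtab.resize(tabmax);
    logtab[0] = 0.0;  // never consulted
    for (int i = 1; i < tabmax; ++i) logtab[i] = std::log((double)i);
  }

  // set assignment and rebuild counts + H from scratch
  void set_assignment(const std::vector<int>& assign,
                      const IntegerMatrix& edges) {
    g = assign;
    std::fill(cnt.begin(), cnt.end(), 0);
    std::fill(ntot.begin(), ntot.end(), 0);
    std::fill(gsize.begin(), gsize.end(), 0);
    nblocks = 0;
    for (int i = 0; i < N; ++i) {
      if (gsize[g[i]] == 0) ++nblocks;
      ++gsize[g[i]];
    }
    for (int e = 0; e < edges.nrow(); ++e) {
      int c = cell(g[edges(e, 0)], g[edges(e, 1)]);
      ++cnt[(size_t)c * K + edges(e, 2)];
      ++ntot[c];
    }
    H = scratch_H();
  }

  double scratch_H() const {
    double h = 0.0;
    const double lgK = std::lgamma((double)K);
    for (size_t c = 0; c < ntot.size(); ++c) {
      if (ntot[c] == 0) continue;
      double t = std::lgamma((double)ntot[c] + K) - lgK;
      for (int k = 0; k < K; ++k)
        t -= std::lgamma((double)cnt[c * K + k] + 1.0);
      h += t;
    }
    if (!prior_const) {
      // without the per-cell prior constant, every cell of the b(b+1)/2
      // occupied-group pairs contributes +lgamma(K), empties included
      h += lgK * 0.5 * (double)nblocks * (nblocks + 1);
    }
    return h;
  }

  inline double remove_obs(int c, int k) {
    double d = logtab[cnt[(size_t)c * K + k]] - logtab[ntot[c] + K - 1];
    --cnt[(size_t)c * K + k];
    --ntot[c];
    return d;
  }

  inline double add_obs(int c, int k) {
    double d = logtab[ntot[c] + K] - logtab[cnt[(size_t)c * K + k] + 1];
    ++cnt[(size_t)c * K + k];
    ++ntot[c];
    return d;
  }

  // move drug i from its group to label b; returns dH (H already updated)
  double apply_move(int i, int b) {
    int a = g[i];
    double dH = 0.0;
    for (size_t t = 0; t < adj[i].size(); ++t)
      dH += remove_obs(cell(a, g[adj[i][t].first]), adj[i][t].second);
    g[i] = b;
    for (size_t t = 0; t < adj[i].size(); ++t)
      dH += add_obs(cell(b, g[adj[i][t].first]), adj[i][t].second);
    int nb_old = nblocks;
    --gsize[a];
    if (gsize[a] == 0) --nblocks;
    if (gsize[b] == 0) ++nblocks;
    ++gsize[b];
    if (!prior_const)
      dH += std::lgamma((double)K) * 0.5 *
            ((double)nblocks * (nblocks + 1) - (double)nb_old * (nb_old + 1));
    H += dH;
    return dH;
  }
};

class Chain {
 public:
  SBMState st;
  std::mt19937_64 rng;
  std::uniform_real_distribution<double> unif;

  Chain() : unif(0.0, 1.0) {}

  void random_init(const IntegerMatrix& edges) {
    std::vector<int> a(st.N);
    for (int i = 0; i < st.N; ++i)
      a[i] = (int)(rng() % (uint64_t)st.N);
    st.set_assignment(a, edges);
  }

  long sweeps_done = 0;

  // one elementary move attempt
  void step() {
    int N = st.N;
    if (N < 2) return;
    int i = (int)(rng() % (uint64_t)N);
    int a = st.g[i];
    int b = (int)(rng() % (uint64_t)(N - 1));
    if (b >= a) ++b;
    int nb_old = st.nblocks;
    double dH = st.apply_move(i, b);
    int nb_new = st.nblocks;
    // log of (N)_{b_old} / (N)_{b_new}: corrects label multiplicity so the
    // set-partition marginal is exp(-H)/Z
    double lmult = 0.0;
    if (nb_new == nb_old + 1) lmult = -st.logtab[N - nb_old];
    else if (nb_new == nb_old - 1) lmult = st.logtab[N - nb_old + 1];
    double logacc = -dH + lmult;
    if (logacc < 0.0 && std::log(unif(rng)) >= logacc) {
      st.apply_move(i, a);  // reject: revert
    }
  }

  void sweep() {
    for (int m = 0; m < st.N; ++m) step();
    // guard against float drift in the incremental H
    if (++sweeps_done % 4096 == 0) st.H = st.scratch_H();
  }
};

// first lag at which autocorrelation of x drops below 1/e (capped)
int decorrelation_time(const std::vector<double>& x, int cap) {
  int n = (int)x.size();
  double mean = 0.0;
  for (int i = 0; i < n; ++i) mean += x[i];
  mean /= n;
  double var = 0.0;
  for (int i = 0; i < n; ++i) var += (x[i] - mean) * (x[i] - mean);
  if (var <= 1e-12) return 1;
  const double thresh = std::exp(-1.0);
  int maxlag = std::min(cap, n / 4);
  for (int lag = 1; lag <= maxlag; ++lag) {
    double acf = 0.0;
    for (int i = 0; i + lag < n; ++i)
      acf += (x[i] - mean) * (x[i + lag] - mean);
    acf /= var;
    if (acf <= thresh) return lag;
  }
  return maxlag < 1 ? 1 : maxlag;
}

// run sweeps until two consecutive windows of `window` sweeps have H means
// within one pooled standard error; returns sweeps used, thermalized flag
bool thermalize(Chain& ch, int window, int cap, int* sweeps_used) {
  std::vector<double> hist;
  hist.reserve(2 * window);
  int sweeps = 0;
  bool ok = false;
  while (sweeps < cap) {
    ch.sweep();
    ++sweeps;
    hist.push_back(ch.st.H);
    if ((int)hist.size() == 2 * window) {
      double m1 = 0, m2 = 0, v1 = 0, v2 = 0;
      for (int i = 0; i < window; ++i) m1 += hist[i];
      for (int i = window; i < 2 * window; ++i) m2 += hist[i];
      m1 /= window; m2 /= window;
      for (int i = 0; i < window; ++i) v1 += (hist[i] - m1) * (hist[i] - m1);
      for (int i = window; i < 2 * window; ++i)
        v2 += (hist[i] - m2) * (hist[i] - m2);
      v1 /= (window - 1); v2 /= (window - 1);
      double se = std::sqrt((v1 + v2) / window);
      double diff = std::fabs(m1 - m2);
      if (diff <= se || (se == 0.0 && diff == 0.0)) { ok = true; break; }
      hist.erase(hist.begin(), hist.begin() + window);  // slide one window
    }
  }
  *sweeps_used = sweeps;
  return ok;
}

}  // namespace

// [[Rcpp::export]]
List sbm_sampler_cpp(int n_drugs, IntegerMatrix edges, int K,
                     int n_chains, int samples_per_chain, double seed,
                     int thinning, int therm_window, int therm_cap,
                     int probe_sweeps, int thin_cap, bool prior_const) {
  int total = n_chains * samples_per_chain;
  IntegerMatrix assign(total, n_drugs);
  NumericVector Hout(total);
  IntegerVector chain_id(total);
  IntegerVector burnin(n_chains), thin_used(n_chains);
  LogicalVector thermalized(n_chains);

  int row = 0;
  for (int c = 0; c < n_chains; ++c) {
    Chain ch;
    ch.st.init(n_drugs, K, edges, prior_const);
    ch.rng.seed(splitmix64(splitmix64((uint64_t)(int64_t)seed) +
                           (uint64_t)c));
    ch.random_init(edges);

    int used = 0;
    thermalized[c] = thermalize(ch, therm_window, therm_cap, &used);
    burnin[c] = used;

    int thin = thinning;
    if (thin <= 0) {  // auto: decorrelation time of per-sweep H
      std::vector<double> probe(probe_sweeps);
      for (int s = 0; s < probe_sweeps; ++s) {
        ch.sweep();
        probe[s] = ch.st.H;
      }
      thin = decorrelation_time(probe, thin_cap);
    }
    if (thin < 1) thin = 1;
    thin_used[c] = thin;

    for (int s = 0; s < samples_per_chain; ++s) {
      for (int t = 0; t < thin; ++t) ch.sweep();
      for (int i = 0; i < n_drugs; ++i) assign(row, i) = ch.st.g[i];
      Hout[row] = ch.st.H;
      chain_id[row] = c + 1;
      ++row;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["assign"] = assign, _["H"] = Hout,
                      _["chain"] = chain_id, _["burnin"] = burnin,
                      _["thinning"] = thin_used,
                      _["thermalized"] = thermalized);
}

// Raw diagnostic chain: records the assignment at the end of every sweep,
// no thermalization test, no thinning.
// [[Rcpp::export]]
List sbm_raw_chain_cpp(int n_drugs, IntegerMatrix edges, int K,
                       int n_sweeps, int burnin_sweeps, double seed,
                       bool prior_const) {
  Chain ch;
  ch.st.init(n_drugs, K, edges, prior_const);
  ch.rng.seed(splitmix64((uint64_t)(int64_t)seed));
  ch.random_init(edges);
  for (int s = 0; s < burnin_sweeps; ++s) ch.sweep();
  IntegerMatrix assign(n_sweeps, n_drugs);
  NumericVector Hout(n_sweeps);
  for (int s = 0; s < n_sweeps; ++s) {
    ch.sweep();
    for (int i = 0; i < n_drugs; ++i) assign(s, i) = ch.st.g[i];
    Hout[s] = ch.st.H;
    if (s % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["assign"] = assign, _["H"] = Hout);
}

// Posterior type probabilities for query pairs, averaged over sampled
// partitions.  qtype[q] >= 0 marks the pair's own observed type, whose
// single count is excluded before evaluating the estimator (fully-observed
// mode); qtype[q] = -1 applies no correction.
// [[Rcpp::export]]
NumericMatrix sbm_posterior_cpp(IntegerMatrix assign, IntegerMatrix edges,
                                int n_drugs, int K,
                                IntegerVector qi, IntegerVector qj,
                                IntegerVector qtype) {
  int S = assign.nrow(), Q = qi.size(), M = edges.nrow();
  int N = n_drugs;
  std::vector<int> cnt((size_t)N * N * K, 0);
  std::vector<int> ntot((size_t)N * N, 0);
  NumericMatrix out(Q, K);

  for (int s = 0; s < S; ++s) {
    for (int e = 0; e < M; ++e) {
      int a = assign(s, edges(e, 0)), b = assign(s, edges(e, 1));
      int c = (a <= b ? a * N + b : b * N + a);
      ++cnt[(size_t)c * K + edges(e, 2)];
      ++ntot[c];
    }
    for (int q = 0; q < Q; ++q) {
      int a = assign(s, qi[q]), b = assign(s, qj[q]);
      int c = (a <= b ? a * N + b : b * N + a);
      int n = ntot[c];
      for (int k = 0; k < K; ++k) {
        int nk = cnt[(size_t)c * K + k];
        int n_adj = n, nk_adj = nk;
        if (qtype[q] >= 0) {
          --n_adj;
          if (k == qtype[q]) --nk_adj;
        }
        out(q, k) += (nk_adj + 1.0) / (n_adj + (double)K);
      }
    }
    for (int e = 0; e < M; ++e) {  // reset touched cells
      int a = assign(s, edges(e, 0)), b = assign(s, edges(e, 1));
      int c = (a <= b ? a * N + b : b * N + a);
      --cnt[(size_t)c * K + edges(e, 2)];
      --ntot[c];
    }
    if (s % 256 == 0) Rcpp::checkUserInterrupt();
  }
  for (int q = 0; q < Q; ++q) {
    double tot = 0.0;
    for (int k = 0; k < K; ++k) tot += out(q, k);
    for (int k = 0; k < K; ++k) out(q, k) /= tot;
  }
  return out;
}

// Fraction of samples in which each drug pair shares a group.
// [[Rcpp::export]]
NumericMatrix sbm_coclass_cpp(IntegerMatrix assign) {
  int S = assign.nrow(), N = assign.ncol();
  NumericMatrix out(N, N);
  for (int s = 0; s < S; ++s)
    for (int i = 0; i < N; ++i)
      for (int j = i; j < N; ++j)
        if (assign(s, i) == assign(s, j)) out(i, j) += 1.0;
  for (int i = 0; i < N; ++i)
    for (int j = i; j < N; ++j) {
      out(i, j) /= S;
      out(j, i) = out(i, j);
    }
  return out;
}

// From-scratch H for a single assignment (bookkeeping cross-check).
// [[Rcpp::export]]
double sbm_H_cpp(IntegerVector assignment, IntegerMatrix edges, int K,
                 bool prior_const) {
  int N = assignment.size();
  SBMState st;
  st.init(N, K, edges, prior_const);
  std::vector<int> a(N);
  for (int i = 0; i < N; ++i) a[i] = assignment[i];
  st.set_assignment(a, edges);
  return st.H;
}
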