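// Compiled core of the biallelic coalescent likelihood.
//
// Partial-likelihood tables live on states (k, r): k ancestral lineages of
// which r carry the red allele, k = 0..K. Tables are matrices with one
// column per site pattern, so one branch pull-back serves every pattern.
// Pulled and combined tables are cached by content hashes of the subtree
// (structure, branch durations, population size), which makes repeated
// evaluations during MCMC cheap when only part of the tree changes.

#include <RcppArmadillo.h>
#include <unordered_map>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int ptdim(int K) { return (K + 1) * (K + 2) / 2; }
static inline int ptidx(int k, int r) { return k * (k + 1) / 2 + r; }

// splitmix64 mixing for content hashes
static inline uint64_t mix64(uint64_t h, uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL + h;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}
static inline uint64_t dbits(double d) {
  uint64_t u;
  std::memcpy(&u, &d, sizeof(u));
  return u;
}

static arma::mat lineage_gen(int K, double neu, double u, double v,
                             double mu) {
  int d = ptdim(K);
  arma::mat A(d, d, arma::fill::zeros);
  double lam = 1.0 / (2.0 * neu);
  for (int k = 0; k <= K; ++k) {
    for (int r = 0; r <= k; ++r) {
      int i = ptidx(k, r);
      A(i, i) = -(k * (k - 1) / 2.0 * lam + r * u * mu + (k - r) * v * mu);
      if (r > 0) A(i, ptidx(k, r - 1)) = r * u * mu;
      if (r < k) A(i, ptidx(k, r + 1)) = (k - r) * v * mu;
      if (k < K) {
        A(i, ptidx(k + 1, r + 1)) = lam * (k + 1) * r / 2.0;
        A(i, ptidx(k + 1, r)) = lam * (k + 1) * (k - r) / 2.0;
      }
    }
  }
  return A;
}

// conserved left functional of the generator: phi' F is invariant, with
// phi(1, .) equal to the stationary color law; terminates the recursion at
// the root without truncating the infinite root branch.
static arma::vec root_phi(int K, double neu, double u, double v, double mu,
                          double pi) {
  arma::vec phi(ptdim(K), arma::fill::zeros);
  phi(ptidx(0, 0)) = 1.0;
  if (K >= 1) {
    phi(ptidx(1, 0)) = pi;
    phi(ptidx(1, 1)) = 1.0 - pi;
  }
  double lam = 1.0 / (2.0 * neu);
  for (int k = 2; k <= K; ++k) {
    int d = k + 1;
    arma::mat D(d, d, arma::fill::zeros);
    for (int r = 0; r <= k; ++r) {
      D(r, r) = -(k * (k - 1) / 2.0 * lam + r * u * mu + (k - r) * v * mu);
      if (r > 0) D(r, r - 1) = r * u * mu;
      if (r < k) D(r, r + 1) = (k - r) * v * mu;
    }
    arma::vec b(d, arma::fill::zeros);
    for (int rp = 0; rp <= k - 1; ++rp) {
      double f = phi(ptidx(k - 1, rp));
      b(rp + 1) += f * lam * k * rp / 2.0;
      b(rp) += f * lam * k * (k - 1 - rp) / 2.0;
    }
    arma::vec x = arma::solve(D.t(), -b);
    for (int r = 0; r <= k; ++r) phi(ptidx(k, r)) = x(r);
  }
  return phi;
}

// binomial coefficients (exact in double well beyond the sizes used here)
static const std::vector<std::vector<double>>& pascal(int n) {
  static std::vector<std::vector<double>> C;
  if ((int)C.size() < n + 1) {
    int old = C.size();
    C.resize(n + 1);
    for (int i = old; i <= n; ++i) {
      C[i].resize(i + 1);
      C[i][0] = C[i][i] = 1.0;
      for (int j = 1; j < i; ++j) C[i][j] = C[i - 1][j - 1] + C[i - 1][j];
    }
  }
  return C;
}

// hypergeometric-weighted merge of two sibling tables
static arma::mat combine_pair(const arma::mat& Fx, int K1, const arma::mat& Fy,
                              int K2) {
  int K = K1 + K2;
  const auto& C = pascal(K);
  int P = Fx.n_cols;
  int Dz = ptdim(K), Dx = ptdim(K1), Dy = ptdim(K2);
  arma::mat Fz(Dz, P, arma::fill::zeros);
  const double* fx = Fx.memptr();
  const double* fy = Fy.memptr();
  double* fz = Fz.memptr();
  for (int k = 0; k <= K; ++k) {
    int k1lo = std::max(0, k - K2), k1hi = std::min(k, K1);
    for (int k1 = k1lo; k1 <= k1hi; ++k1) {
      int k2 = k - k1;
      for (int r = 0; r <= k; ++r) {
        int r1lo = std::max(0, r - k2), r1hi = std::min(r, k1);
        int iz = ptidx(k, r);
        for (int r1 = r1lo; r1 <= r1hi; ++r1) {
          int r2 = r - r1;
          double w = C[r][r1] * C[k - r][k1 - r1] / C[k][k1];
          int ix = ptidx(k1, r1), iy = ptidx(k2, r2);
          for (int c = 0; c < P; ++c)
            fz[iz + c * Dz] += w * fx[ix + c * Dx] * fy[iy + c * Dy];
        }
      }
    }
  }
  return Fz;
}

struct CacheEntry {
  uint64_t last;
  int K;
  arma::mat F;
};

// eigendecomposition of the generator, cached per (K, neu): the mutation
// blocks are reversible birth-death chains and the coalescent coupling is
// block-triangular, so the spectrum is real; a reconstruction check guards
// against ill-conditioned eigenvector bases (fallback: expmat).
struct EigEntry {
  uint64_t last;
  bool ok;
  arma::mat V, Vinv;
  arma::vec d;
};

struct Engine {
  int N;                       // tips
  double u, v, mu, pi;
  std::vector<arma::mat> leafF;  // per tip: table over patterns
  std::vector<int> leafK;
  uint64_t gen = 0;
  std::unordered_map<uint64_t, CacheEntry> tabcache;  // pulled/combined
  std::unordered_map<uint64_t, CacheEntry> expcache;  // branch exponentials
  std::unordered_map<uint64_t, CacheEntry> phicache;  // root functionals
  std::unordered_map<uint64_t, EigEntry> eigcache;    // generator eigen
};

static void build_leaves(Engine& e, const IntegerMatrix& n,
                         const IntegerMatrix& r) {
  int P = n.ncol();
  e.leafF.resize(e.N);
  e.leafK.resize(e.N);
  for (int s = 0; s < e.N; ++s) {
    int K = 0;
    for (int p = 0; p < P; ++p) K = std::max(K, n(s, p));
    e.leafK[s] = K;
    arma::mat F(ptdim(K), P, arma::fill::zeros);
    for (int p = 0; p < P; ++p) F(ptidx(n(s, p), r(s, p)), p) = 1.0;
    e.leafF[s] = std::move(F);
  }
}

// [[Rcpp::export]]
SEXP engine_create(int n_tips, IntegerMatrix n, IntegerMatrix r, double u,
                   double v, double mu, double pi) {
  Engine* e = new Engine();
  e->N = n_tips;
  e->u = u;
  e->v = v;
  e->mu = mu;
  e->pi = pi;
  build_leaves(*e, n, r);
  XPtr<Engine> p(e, true);
  return p;
}

static const EigEntry& gen_eigen(Engine& e, int K, double neu) {
  uint64_t key = mix64(mix64(3ULL, K), dbits(neu));
  auto it = e.eigcache.find(key);
  if (it != e.eigcache.end()) {
    it->second.last = e.gen;
    return it->second;
  }
  arma::mat A = lineage_gen(K, neu, e.u, e.v, e.mu);
  EigEntry ee;
  ee.last = e.gen;
  ee.ok = false;
  arma::cx_vec dc;
  arma::cx_mat Vc;
  if (arma::eig_gen(dc, Vc, A) &&
      arma::norm(arma::imag(dc), "inf") < 1e-8) {
    arma::mat V = arma::real(Vc);
    arma::vec d = arma::real(dc);
    arma::mat Vinv;
    if (arma::inv(Vinv, V)) {
      // reconstruction check against ill-conditioned bases
      double err = arma::norm(V * arma::diagmat(d) * Vinv - A, "inf");
      double scale = std::max(1.0, arma::norm(A, "inf"));
      if (err / scale < 1e-10) {
        ee.ok = true;
        ee.V = std::move(V);
        ee.Vinv = std::move(Vinv);
        ee.d = std::move(d);
      }
    }
  }
  auto res = e.eigcache.emplace(key, std::move(ee));
  return res.first->second;
}

// pull a table down a branch: eigen path when well-conditioned, otherwise
// a cached dense exponential
static arma::mat pull_table(Engine& e, int K, double dur, double neu,
                            const arma::mat& F);

static const arma::mat& branch_exp(Engine& e, int K, double dur, double neu) {
  uint64_t key = mix64(mix64(mix64(1ULL, K), dbits(dur)), dbits(neu));
  auto it = e.expcache.find(key);
  if (it != e.expcache.end()) {
    it->second.last = e.gen;
    return it->second.F;
  }
  arma::mat E = arma::expmat(lineage_gen(K, neu, e.u, e.v, e.mu) * dur);
  CacheEntry ce{e.gen, K, std::move(E)};
  auto res = e.expcache.emplace(key, std::move(ce));
  return res.first->second.F;
}

static arma::mat pull_table(Engine& e, int K, double dur, double neu,
                            const arma::mat& F) {
  const EigEntry& ee = gen_eigen(e, K, neu);
  if (ee.ok) {
    arma::mat W = ee.Vinv * F;
    arma::vec s = arma::exp(ee.d * dur);
    W.each_col() %= s;
    return ee.V * W;
  }
  return branch_exp(e, K, dur, neu) * F;
}

static const arma::vec root_vec(Engine& e, int K, double neu) {
  uint64_t key = mix64(mix64(2ULL, K), dbits(neu));
  auto it = e.phicache.find(key);
  if (it != e.phicache.end()) {
    it->second.last = e.gen;
    return it->second.F.col(0);
  }
  arma::vec phi = root_phi(K, neu, e.u, e.v, e.mu, e.pi);
  CacheEntry ce{e.gen, K, arma::mat(phi)};
  e.phicache.emplace(key, std::move(ce));
  return phi;
}

static void prune(std::unordered_map<uint64_t, CacheEntry>& m, uint64_t gen,
                  uint64_t keep) {
  if (m.size() < 512) return;
  for (auto it = m.begin(); it != m.end();) {
    if (it->second.last + keep < gen)
      it = m.erase(it);
    else
      ++it;
  }
}

// Evaluate per-pattern probabilities for one tree.
// order: internal node ids (1-based, > n_tips) in post-order, root last;
// children / durations: per ordered node, child ids and branch lengths.
// [[Rcpp::export]]
NumericVector engine_eval(SEXP ptr, IntegerVector order, List children,
                          List durations, double neu) {
  XPtr<Engine> ep(ptr);
  Engine& e = *ep;
  ++e.gen;
  int M = order.size();
  int maxid = e.N + M;
  std::vector<uint64_t> key(maxid + 1, 0);
  std::vector<const arma::mat*> tab(maxid + 1, nullptr);
  std::vector<int> Kof(maxid + 1, 0);
  for (int s = 0; s < e.N; ++s) {
    key[s + 1] = mix64(0xabcdULL, s + 1);
    tab[s + 1] = &e.leafF[s];
    Kof[s + 1] = e.leafK[s];
  }
  const arma::mat* rootF = nullptr;
  int rootK = 0;
  for (int i = 0; i < M; ++i) {
    int id = order[i];
    IntegerVector kids = children[i];
    NumericVector durs = durations[i];
    uint64_t nk = 0x5eedULL;
    std::vector<uint64_t> pkeys(kids.size());
    for (int c = 0; c < kids.size(); ++c) {
      uint64_t pk = mix64(mix64(key[kids[c]], dbits(durs[c])), dbits(neu));
      pkeys[c] = pk;
      nk = mix64(nk, pk);
    }
    auto hit = e.tabcache.find(nk);
    if (hit != e.tabcache.end()) {
      hit->second.last = e.gen;
      tab[id] = &hit->second.F;
      Kof[id] = hit->second.K;
      key[id] = nk;
    } else {
      // pull each child, using cached pulled tables where possible
      arma::mat acc;
      int Kacc = 0;
      for (int c = 0; c < kids.size(); ++c) {
        int ch = kids[c];
        const arma::mat* pulled;
        int Kc = Kof[ch];
        auto ph = e.tabcache.find(pkeys[c]);
        if (ph != e.tabcache.end()) {
          ph->second.last = e.gen;
          pulled = &ph->second.F;
        } else {
          arma::mat P = pull_table(e, Kc, durs[c], neu, *tab[ch]);
          CacheEntry ce{e.gen, Kc, std::move(P)};
          auto res = e.tabcache.emplace(pkeys[c], std::move(ce));
          pulled = &res.first->second.F;
        }
        if (c == 0) {
          acc = *pulled;
          Kacc = Kc;
        } else {
          acc = combine_pair(acc, Kacc, *pulled, Kc);
          Kacc += Kc;
        }
      }
      CacheEntry ce{e.gen, Kacc, std::move(acc)};
      auto res = e.tabcache.emplace(nk, std::move(ce));
      tab[id] = &res.first->second.F;
      Kof[id] = Kacc;
      key[id] = nk;
    }
    if (i == M - 1) {
      rootF = tab[id];
      rootK = Kof[id];
    }
  }
  arma::vec phi = root_vec(e, rootK, neu);
  arma::rowvec p = phi.t() * (*rootF);
  prune(e.tabcache, e.gen, 4);
  prune(e.expcache, e.gen, 64);
  prune(e.phicache, e.gen, 64);
  if (e.eigcache.size() > 256) e.eigcache.clear();
  return NumericVector(p.begin(), p.end());
}

// Stateless convenience path used by pattern_probabilities()
// [[Rcpp::export]]
NumericVector lik_patterns_cpp(int n_tips, IntegerVector order, List children,
                               List durations, IntegerMatrix n,
                               IntegerMatrix r, double neu, double u, double v,
                               double mu, double pi) {
  Engine e;
  e.N = n_tips;
  e.u = u;
  e.v = v;
  e.mu = mu;
  e.pi = pi;
  build_leaves(e, n, r);
  // direct evaluation without persistent caching
  int M = order.size();
  int maxid = n_tips + M;
  std::vector<arma::mat> tab(maxid + 1);
  std::vector<int> Kof(maxid + 1, 0);
  for (int s = 0; s < n_tips; ++s) {
    tab[s + 1] = e.leafF[s];
    Kof[s + 1] = e.leafK[s];
  }
  arma::rowvec out;
  for (int i = 0; i < M; ++i) {
    int id = order[i];
    IntegerVector kids = children[i];
    NumericVector durs = durations[i];
    arma::mat acc;
    int Kacc = 0;
    for (int c = 0; c < kids.size(); ++c) {
      int ch = kids[c];
      int Kc = Kof[ch];
      arma::mat P =
          arma::expmat(lineage_gen(Kc, neu, u, v, mu) * durs[c]) * tab[ch];
      if (c == 0) {
        acc = std::move(P);
        Kacc = Kc;
      } else {
        acc = combine_pair(acc, Kacc, P, Kc);
        Kacc += Kc;
      }
    }
    tab[id] = std::move(acc);
    Kof[id] = Kacc;
    if (i == M - 1) {
      arma::vec phi = root_phi(Kacc, neu, u, v, mu, pi);
      out = phi.t() * tab[id];
    }
  }
  return NumericVector(out.begin(), out.end());
}
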