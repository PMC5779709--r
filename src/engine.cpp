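// Compiled network-likelihood engine: the same labeled-partial-likelihood
// traversal as the R reference implementation, shared across all site
// patterns of a data set (per-branch matrix exponentials are computed once
// per call).  Kept in lock-step with the R path by an equivalence test.

#include <RcppArmadillo.h>
#include <map>
using namespace Rcpp;

static inline int sidx(int n, int r) { return n * (n + 1) / 2 + r; }

struct LPL {
  arma::vec F;
  std::vector<int> s;
};

struct LPLSet {
  std::vector<LPL> v;
  double logscale = 0.0;
};

static arma::mat build_Q(double theta, double u, double v, int M) {
  const int l = (M + 1) * (M + 2) / 2;
  arma::mat Q(l, l, arma::fill::zeros);
  for (int n = 1; n <= M; ++n) for (int r = 0; r <= n; ++r) {
    const int i = sidx(n, r);
    if (r - 1 >= 0) Q(i, sidx(n, r - 1)) = (double)(n - r + 1) * v;
    if (r + 1 <= n) Q(i, sidx(n, r + 1)) = (double)(r + 1) * u;
    if (n - 1 >= r && n - 1 - r > 0) Q(i, sidx(n - 1, r)) = (double)(n - 1 - r) * n / theta;
    if (r - 1 > 0) Q(i, sidx(n - 1, r - 1)) = (double)(r - 1) * n / theta;
    Q(i, i) = -(double)n * (n - 1) / theta - (double)(n - r) * v - (double)r * u;
  }
  return Q;
}

static arma::vec stationary_x(double theta, double u, double v, int M) {
  const int l = (M + 1) * (M + 2) / 2;
  arma::mat Q = build_Q(theta, u, v, M);
  arma::mat sub = Q.submat(1, 1, l - 1, l - 1);
  arma::mat U, V; arma::vec sv;
  arma::svd(U, sv, V, sub);
  arma::vec x0 = V.col(V.n_cols - 1);
  double norm = x0(sidx(1, 0) - 1) + x0(sidx(1, 1) - 1);
  x0 /= norm;
  arma::vec x(l, arma::fill::zeros);
  for (int i = 1; i < l; ++i) x(i) = std::max(x0(i - 1), 0.0);
  return x;
}

static void rescale(LPLSet &S) {
  double mx = 0.0;
  for (const auto &p : S.v) {
    double m = arma::abs(p.F).max();
    if (m > mx) mx = m;
  }
  if (mx > 0.0 && mx < 1e-100) {
    for (auto &p : S.v) p.F /= mx;
    S.logscale += std::log(mx);
  }
}

static bool compatible(const std::vector<int> &a, const std::vector<int> &b) {
  for (size_t i = 0; i < a.size(); ++i)
    if (a[i] != b[i] && a[i] != 0 && b[i] != 0) return false;
  return true;
}

static double nCk(const arma::mat &C, int n, int k) { return C(n, k); }

// Sum LPLs sharing an identical label vector: every downstream operation
// (propagation, merge convolution, splitting, articulation summation) is
// linear in F for a fixed label, so this collapse is exact and keeps the
// set size bounded by the number of live label combinations.
static void dedup_labels(LPLSet &S) {
  if (S.v.size() < 2) return;
  std::map<std::vector<int>, size_t> seen;
  std::vector<LPL> out;
  out.reserve(S.v.size());
  for (auto &p : S.v) {
    auto it = seen.find(p.s);
    if (it == seen.end()) {
      seen.emplace(p.s, out.size());
      out.push_back(std::move(p));
    } else {
      out[it->second].F += p.F;
    }
  }
  S.v = std::move(out);
}

// [[Rcpp::export]]
NumericVector cpp_site_logliks(IntegerVector kind,
                               IntegerVector eparent, IntegerVector echild,
                               NumericVector elen, NumericVector etheta,
                               NumericVector egamma,
                               int root, double root_theta,
                               IntegerVector ret_coord,
                               IntegerVector order_children_first,
                               IntegerVector lowest_artic,
                               IntegerVector leaf_slot,
                               arma::cube leafF,
                               double u, double v, int M,
                               List kill_coords) {
  const int nN = kind.size();
  const int nE = eparent.size();
  const int l = (M + 1) * (M + 2) / 2;
  const int npat = leafF.n_slices;
  int k = 0;
  for (int i = 0; i < nN; ++i) if (ret_coord[i] >= 0) ++k;

  // per-node edge lists (1-based node ids in the inputs)
  std::vector<std::vector<int>> out_e(nN), in_e(nN);
  for (int e = 0; e < nE; ++e) {
    out_e[eparent[e] - 1].push_back(e);
    in_e[echild[e] - 1].push_back(e);
  }

  // binomial table up to M
  arma::mat C(M + 1, M + 1, arma::fill::zeros);
  for (int n = 0; n <= M; ++n) {
    C(n, 0) = 1.0;
    for (int j = 1; j <= n; ++j)
      C(n, j) = C(n - 1, j - 1) + (j <= n - 1 ? C(n - 1, j) : 0.0);
  }

  // coordinates fully resolved at each edge (labels zeroed there)
  std::vector<std::vector<int>> kill(nE);
  for (int e = 0; e < nE; ++e) {
    IntegerVector kc = kill_coords[e];
    kill[e].assign(kc.begin(), kc.end());
  }

  // per-edge transition matrices, shared across patterns and memoized
  // across calls: MCMC moves change only one or two branches per
  // iteration, so most exponentials repeat exactly (the cache returns the
  // identical bitwise result a fresh computation would).
  static std::map<std::tuple<double, double, double, double, int>, arma::mat> Tcache;
  if (Tcache.size() > 20000) Tcache.clear();
  std::vector<const arma::mat *> T(nE);
  for (int e = 0; e < nE; ++e) {
    auto key = std::make_tuple(etheta[e], elen[e], u, v, M);
    auto it = Tcache.find(key);
    if (it == Tcache.end())
      it = Tcache.emplace(key, arma::expmat(build_Q(etheta[e], u, v, M) * elen[e])).first;
    T[e] = &it->second;
  }

  static std::map<std::tuple<double, double, double, int>, arma::vec> Xcache;
  if (Xcache.size() > 4096) Xcache.clear();
  arma::vec x;
  {
    auto key = std::make_tuple(root_theta, u, v, M);
    auto it = Xcache.find(key);
    if (it == Xcache.end())
      it = Xcache.emplace(key, stationary_x(root_theta, u, v, M)).first;
    x = it->second;
  }

  // state-index -> (n, r)
  std::vector<int> st_n(l), st_r(l);
  for (int n = 0; n <= M; ++n) for (int r = 0; r <= n; ++r) {
    st_n[sidx(n, r)] = n; st_r[sidx(n, r)] = r;
  }

  NumericVector out(npat);
  for (int pi = 0; pi < npat; ++pi) {
    std::vector<LPLSet> top(nE);
    std::vector<int> counters(std::max(k, 1), 0);
    LPLSet root_set;

    auto finish_edge = [&](int e, LPLSet S) {
      for (int c : kill[e])
        for (auto &p : S.v) p.s[c] = 0;
      dedup_labels(S);
      for (auto &p : S.v) p.F = T[e]->t() * p.F;  // F exp(Qt)
      rescale(S);
      top[e] = std::move(S);
    };

    for (int oi = 0; oi < nN; ++oi) {
      const int vtx = order_children_first[oi] - 1;
      const int kd = kind[vtx];
      if (kd == 0) {                                     // leaf
        LPLSet B;
        LPL p; p.F = leafF.slice(pi).col(leaf_slot[vtx]);
        p.s.assign(k, 0);
        B.v.push_back(std::move(p));
        finish_edge(in_e[vtx][0], std::move(B));
      } else if (kd == 2) {                              // reticulation
        const int xe = out_e[vtx][0];
        LPLSet S = std::move(top[xe]);
        if (lowest_artic[vtx]) {                         // collapse labels
          LPL m; m.F = arma::vec(l, arma::fill::zeros); m.s.assign(k, 0);
          for (const auto &p : S.v) m.F += p.F;
          S.v.clear(); S.v.push_back(std::move(m));
        }
        const int e1 = in_e[vtx][0], e2 = in_e[vtx][1];
        const double g = egamma[e1];
        const int coord = ret_coord[vtx];
        LPLSet Py, Pz;
        Py.logscale = S.logscale;                        // scale carried once
        Pz.logscale = 0.0;
        int &o = counters[coord];
        for (const auto &p : S.v) {
          arma::uvec nz = arma::find(p.F != 0.0);
          if (nz.n_elem == 0) { Py.v.push_back(p); Pz.v.push_back(p); continue; }
          for (arma::uword a = 0; a < nz.n_elem; ++a) {
            const int i = nz(a);
            const int ni = st_n[i], ri = st_r[i];
            const double val = p.F(i);
            for (int ny = 0; ny <= ni; ++ny) {
              const int lo = std::max(0, ri - (ni - ny));
              const int hi = std::min(ri, ny);
              for (int ry = lo; ry <= hi; ++ry) {
                ++o;
                LPL py, pz;
                py.s = p.s; py.s[coord] = o;
                pz.s = py.s;
                py.F = arma::vec(l, arma::fill::zeros);
                py.F(sidx(ny, ry)) = val * nCk(C, ni, ny) *
                  std::pow(g, ny) * std::pow(1.0 - g, ni - ny);
                pz.F = arma::vec(l, arma::fill::zeros);
                pz.F(sidx(ni - ny, ri - ry)) = 1.0;
                Py.v.push_back(std::move(py));
                Pz.v.push_back(std::move(pz));
              }
            }
          }
        }
        finish_edge(e1, std::move(Py));
        finish_edge(e2, std::move(Pz));
      } else {                                           // tree node / root
        LPLSet B;
        if (out_e[vtx].size() == 1) {
          B = std::move(top[out_e[vtx][0]]);
        } else {
          LPLSet &A = top[out_e[vtx][0]];
          LPLSet &Z = top[out_e[vtx][1]];
          B.logscale = A.logscale + Z.logscale;
          for (const auto &pa : A.v) {
            arma::uvec nza = arma::find(pa.F != 0.0);
            for (const auto &pz : Z.v) {
              if (!compatible(pa.s, pz.s)) continue;
              arma::uvec nzz = arma::find(pz.F != 0.0);
              LPL m;
              m.s.resize(k);
              for (int c = 0; c < k; ++c)
                m.s[c] = pa.s[c] != 0 ? pa.s[c] : pz.s[c];
              m.F = arma::vec(l, arma::fill::zeros);
              for (arma::uword a = 0; a < nza.n_elem; ++a) {
                const int ia = nza(a);
                const int ny = st_n[ia], ry = st_r[ia];
                for (arma::uword b = 0; b < nzz.n_elem; ++b) {
                  const int ib = nzz(b);
                  const int nz2 = st_n[ib], rz2 = st_r[ib];
                  const int n = ny + nz2;
                  if (n > M) continue;
                  const int r = ry + rz2;
                  const double w = nCk(C, r, ry) * nCk(C, n - r, ny - ry) /
                                   nCk(C, n, ny);
                  m.F(sidx(n, r)) += pa.F(ia) * pz.F(ib) * w;
                }
              }
              B.v.push_back(std::move(m));
            }
          }
        }
        if (lowest_artic[vtx] && (vtx + 1) != root) {
          LPL m; m.F = arma::vec(l, arma::fill::zeros); m.s.assign(k, 0);
          for (const auto &p : B.v) m.F += p.F;
          double ls = B.logscale;
          B.v.clear(); B.v.push_back(std::move(m)); B.logscale = ls;
        }
        if ((vtx + 1) == root) { root_set = std::move(B); break; }
        finish_edge(in_e[vtx][0], std::move(B));
      }
    }

    arma::vec Frho(l, arma::fill::zeros);
    for (const auto &p : root_set.v) Frho += p.F;
    const double lik = arma::dot(Frho, x);
    out[pi] = (lik > 0.0 ? std::log(lik) : R_NegInf) + root_set.logscale;
  }
  return out;
}
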