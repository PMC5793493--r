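// Core BHV tree-space geometry: geodesic supports via the GTP scheme
// (successive refinement of the cone path through min-weight vertex covers,
// solved by max-flow), geodesic lengths and points, and the iterative
// Frechet-mean / projection loops that dominate runtime.
//
// Trees cross the R boundary as (integer bitmask, double length) pairs:
// bit i-1 of a mask marks leaf i (leaves 1..N; the root leaf 0 is never
// stored, since splits are kept canonically as the side away from the root).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

typedef unsigned int mask_t;

static inline bool compat(mask_t a, mask_t b) {
  mask_t i = a & b;
  return i == 0u || i == a || i == b;
}

// ---------------------------------------------------------------------------
// Geodesic support
// ---------------------------------------------------------------------------

struct Geo {
  // splits of x and y that are incompatible with the other tree
  std::vector<mask_t> am, bm;
  std::vector<double> al, bl;
  // ordered blocks (indices into am / bm) and their norms
  std::vector< std::vector<int> > A, B;
  std::vector<double> nA, nB;
  // common part C(x,y): splits compatible with everything in both trees
  std::vector<mask_t> cm;
  std::vector<double> cx, cy;
  double len2;
};

// Min-weight vertex cover on the bipartite incompatibility graph of one
// block, via Edmonds-Karp max-flow on source -> A -> B -> sink.
// Returns the cover weight; marks cover membership in inC / inD.
static double min_cover(const std::vector<int>& ai, const std::vector<int>& bi,
                        const std::vector<mask_t>& am, const std::vector<mask_t>& bm,
                        const std::vector<double>& u, const std::vector<double>& v,
                        std::vector<char>& inC, std::vector<char>& inD) {
  const int na = (int)ai.size(), nb = (int)bi.size();
  const int n = na + nb + 2, S = 0, T = n - 1;
  const double INF = 1e30;
  static thread_local std::vector<double> cap;
  cap.assign((size_t)n * n, 0.0);
  for (int i = 0; i < na; ++i) cap[(size_t)S * n + (1 + i)] = u[i];
  for (int j = 0; j < nb; ++j) cap[(size_t)(1 + na + j) * n + T] = v[j];
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < nb; ++j)
      if (!compat(am[ai[i]], bm[bi[j]]))
        cap[(size_t)(1 + i) * n + (1 + na + j)] = INF;

  static thread_local std::vector<int> prev;
  prev.resize(n);
  double flow = 0.0;
  static thread_local std::vector<int> q;
  for (;;) {
    // BFS for an augmenting path in the residual graph
    std::fill(prev.begin(), prev.end(), -1);
    prev[S] = S;
    q.clear(); q.push_back(S);
    for (size_t h = 0; h < q.size() && prev[T] < 0; ++h) {
      int c = q[h];
      for (int w = 0; w < n; ++w)
        if (prev[w] < 0 && cap[(size_t)c * n + w] > 1e-14) { prev[w] = c; q.push_back(w); }
    }
    if (prev[T] < 0) break;
    double bott = INF;
    for (int w = T; w != S; w = prev[w])
      bott = std::min(bott, cap[(size_t)prev[w] * n + w]);
    for (int w = T; w != S; w = prev[w]) {
      cap[(size_t)prev[w] * n + w] -= bott;
      cap[(size_t)w * n + prev[w]] += bott;
    }
    flow += bott;
  }
  // residual reachability from the source -> min cut -> min cover
  static thread_local std::vector<char> reach;
  reach.assign(n, 0); reach[S] = 1;
  q.clear(); q.push_back(S);
  for (size_t h = 0; h < q.size(); ++h) {
    int c = q[h];
    for (int w = 0; w < n; ++w)
      if (!reach[w] && cap[(size_t)c * n + w] > 1e-14) { reach[w] = 1; q.push_back(w); }
  }
  inC.assign(na, 0); inD.assign(nb, 0);
  for (int i = 0; i < na; ++i) if (!reach[1 + i]) inC[i] = 1;
  for (int j = 0; j < nb; ++j) if (reach[1 + na + j]) inD[j] = 1;
  return flow;
}

// Recursively refine one block; append final blocks in path order.
static void refine_block(std::vector<int> ai, std::vector<int> bi,
                         const Geo& g, double tol,
                         std::vector< std::vector<int> >& outA,
                         std::vector< std::vector<int> >& outB) {
  if (ai.size() > 1 || bi.size() > 1) {
    double a2 = 0.0, b2 = 0.0;
    for (size_t i = 0; i < ai.size(); ++i) a2 += g.al[ai[i]] * g.al[ai[i]];
    for (size_t j = 0; j < bi.size(); ++j) b2 += g.bl[bi[j]] * g.bl[bi[j]];
    std::vector<double> u(ai.size()), v(bi.size());
    for (size_t i = 0; i < ai.size(); ++i) u[i] = g.al[ai[i]] * g.al[ai[i]] / a2;
    for (size_t j = 0; j < bi.size(); ++j) v[j] = g.bl[bi[j]] * g.bl[bi[j]] / b2;
    std::vector<char> inC, inD;
    double w = min_cover(ai, bi, g.am, g.bm, u, v, inC, inD);
    if (w < 1.0 - tol) {
      // split (A,B) -> (C, B\D), (A\C, D); no edges run between A\C and B\D
      std::vector<int> a1, a2i, b1, b2i;
      for (size_t i = 0; i < ai.size(); ++i) (inC[i] ? a1 : a2i).push_back(ai[i]);
      for (size_t j = 0; j < bi.size(); ++j) (inD[j] ? b2i : b1).push_back(bi[j]);
      // a minimal cover of weight < 1 always yields two proper sub-blocks;
      // if floating-point degeneracy (near-zero edge weights) produces an
      // empty side, keep the block whole rather than recurse forever
      if (!a1.empty() && !b1.empty() && !a2i.empty() && !b2i.empty()) {
        refine_block(a1, b1, g, tol, outA, outB);
        refine_block(a2i, b2i, g, tol, outA, outB);
        return;
      }
    }
  }
  outA.push_back(ai);
  outB.push_back(bi);
}

static void build_geo(const std::vector<mask_t>& xm, const std::vector<double>& xl,
                      const std::vector<mask_t>& ym, const std::vector<double>& yl,
                      double tol, Geo& g) {
  g.am.clear(); g.bm.clear(); g.al.clear(); g.bl.clear();
  g.A.clear(); g.B.clear(); g.nA.clear(); g.nB.clear();
  g.cm.clear(); g.cx.clear(); g.cy.clear();

  const size_t nx = xm.size(), ny = ym.size();
  std::vector<char> ydone(ny, 0);
  for (size_t i = 0; i < nx; ++i) {
    bool ok = true;
    for (size_t j = 0; j < ny; ++j)
      if (!compat(xm[i], ym[j])) { ok = false; break; }
    if (ok) {
      double ly = 0.0;
      for (size_t j = 0; j < ny; ++j)
        if (ym[j] == xm[i]) { ly = yl[j]; ydone[j] = 1; break; }
      g.cm.push_back(xm[i]); g.cx.push_back(xl[i]); g.cy.push_back(ly);
    } else {
      g.am.push_back(xm[i]); g.al.push_back(xl[i]);
    }
  }
  for (size_t j = 0; j < ny; ++j) {
    if (ydone[j]) continue;
    bool ok = true;
    for (size_t i = 0; i < nx; ++i)
      if (!compat(ym[j], xm[i])) { ok = false; break; }
    if (ok) { g.cm.push_back(ym[j]); g.cx.push_back(0.0); g.cy.push_back(yl[j]); }
    else    { g.bm.push_back(ym[j]); g.bl.push_back(yl[j]); }
  }

  if (!g.am.empty()) {
    std::vector<int> ai(g.am.size()), bi(g.bm.size());
    for (size_t i = 0; i < ai.size(); ++i) ai[i] = (int)i;
    for (size_t j = 0; j < bi.size(); ++j) bi[j] = (int)j;
    refine_block(ai, bi, g, tol, g.A, g.B);
  }

  g.len2 = 0.0;
  g.nA.resize(g.A.size()); g.nB.resize(g.B.size());
  for (size_t l = 0; l < g.A.size(); ++l) {
    double a2 = 0.0, b2 = 0.0;
    for (size_t i = 0; i < g.A[l].size(); ++i) a2 += g.al[g.A[l][i]] * g.al[g.A[l][i]];
    for (size_t j = 0; j < g.B[l].size(); ++j) b2 += g.bl[g.B[l][j]] * g.bl[g.B[l][j]];
    g.nA[l] = std::sqrt(a2); g.nB[l] = std::sqrt(b2);
    double s = g.nA[l] + g.nB[l];
    g.len2 += s * s;
  }
  for (size_t c = 0; c < g.cm.size(); ++c) {
    double d = g.cx[c] - g.cy[c];
    g.len2 += d * d;
  }
}

static void geo_point(const Geo& g, double lambda,
                      std::vector<mask_t>& om, std::vector<double>& ol) {
  om.clear(); ol.clear();
  for (size_t l = 0; l < g.A.size(); ++l) {
    double denom = g.nA[l] + g.nB[l];
    double bp = denom > 0 ? g.nA[l] / denom : 0.0;
    if (lambda < bp) {
      double f = ((1.0 - lambda) * g.nA[l] - lambda * g.nB[l]) / g.nA[l];
      for (size_t i = 0; i < g.A[l].size(); ++i) {
        double w = g.al[g.A[l][i]] * f;
        if (w > 0) { om.push_back(g.am[g.A[l][i]]); ol.push_back(w); }
      }
    } else if (lambda > bp) {
      double f = (lambda * g.nB[l] - (1.0 - lambda) * g.nA[l]) / g.nB[l];
      for (size_t j = 0; j < g.B[l].size(); ++j) {
        double w = g.bl[g.B[l][j]] * f;
        if (w > 0) { om.push_back(g.bm[g.B[l][j]]); ol.push_back(w); }
      }
    }
  }
  for (size_t c = 0; c < g.cm.size(); ++c) {
    double w = (1.0 - lambda) * g.cx[c] + lambda * g.cy[c];
    if (w > 0) { om.push_back(g.cm[c]); ol.push_back(w); }
  }
}

// ---------------------------------------------------------------------------
// R interface helpers
// ---------------------------------------------------------------------------

static void unpack(SEXP masks, SEXP lens, std::vector<mask_t>& m, std::vector<double>& l) {
  IntegerVector mi(masks);
  NumericVector li(lens);
  m.resize(mi.size()); l.resize(li.size());
  for (int i = 0; i < mi.size(); ++i) m[i] = (mask_t)mi[i];
  for (int i = 0; i < li.size(); ++i) l[i] = li[i];
}

static List pack_tree(const std::vector<mask_t>& m, const std::vector<double>& l) {
  IntegerVector mi(m.size());
  NumericVector li(l.size());
  for (size_t i = 0; i < m.size(); ++i) mi[i] = (int)m[i];
  for (size_t i = 0; i < l.size(); ++i) li[i] = l[i];
  return List::create(Named("mask") = mi, Named("len") = li);
}

// [[Rcpp::export]]
bool cpp_compat(int a, int b) { return compat((mask_t)a, (mask_t)b); }

// [[Rcpp::export]]
List cpp_support(IntegerVector xm, NumericVector xl,
                 IntegerVector ym, NumericVector yl, double tol) {
  std::vector<mask_t> x, y; std::vector<double> lx, ly;
  unpack(xm, xl, x, lx); unpack(ym, yl, y, ly);
  Geo g; build_geo(x, lx, y, ly, tol, g);
  List A(g.A.size()), B(g.B.size());
  for (size_t l = 0; l < g.A.size(); ++l) {
    IntegerVector av(g.A[l].size()); NumericVector aw(g.A[l].size());
    for (size_t i = 0; i < g.A[l].size(); ++i) { av[i] = (int)g.am[g.A[l][i]]; aw[i] = g.al[g.A[l][i]]; }
    A[l] = List::create(Named("mask") = av, Named("len") = aw);
    IntegerVector bv(g.B[l].size()); NumericVector bw(g.B[l].size());
    for (size_t j = 0; j < g.B[l].size(); ++j) { bv[j] = (int)g.bm[g.B[l][j]]; bw[j] = g.bl[g.B[l][j]]; }
    B[l] = List::create(Named("mask") = bv, Named("len") = bw);
  }
  IntegerVector cm(g.cm.size()); NumericVector cx(g.cm.size()), cy(g.cm.size());
  for (size_t c = 0; c < g.cm.size(); ++c) { cm[c] = (int)g.cm[c]; cx[c] = g.cx[c]; cy[c] = g.cy[c]; }
  NumericVector nA(g.nA.begin(), g.nA.end()), nB(g.nB.begin(), g.nB.end());
  return List::create(Named("A") = A, Named("B") = B,
                      Named("C_mask") = cm, Named("C_xlen") = cx, Named("C_ylen") = cy,
                      Named("normA") = nA, Named("normB") = nB,
                      Named("length") = std::sqrt(g.len2));
}

// [[Rcpp::export]]
double cpp_distance(IntegerVector xm, NumericVector xl,
                    IntegerVector ym, NumericVector yl, double tol) {
  std::vector<mask_t> x, y; std::vector<double> lx, ly;
  unpack(xm, xl, x, lx); unpack(ym, yl, y, ly);
  Geo g; build_geo(x, lx, y, ly, tol, g);
  return std::sqrt(g.len2);
}

// [[Rcpp::export]]
List cpp_geodesic_point(IntegerVector xm, NumericVector xl,
                        IntegerVector ym, NumericVector yl,
                        double lambda, double tol) {
  std::vector<mask_t> x, y, om; std::vector<double> lx, ly, ol;
  unpack(xm, xl, x, lx); unpack(ym, yl, y, ly);
  Geo g; build_geo(x, lx, y, ly, tol, g);
  geo_point(g, lambda, om, ol);
  return pack_tree(om, ol);
}

// [[Rcpp::export]]
NumericVector cpp_dist_to_many(IntegerVector zm, NumericVector zl,
                               List masks, List lens, double tol) {
  std::vector<mask_t> z; std::vector<double> lz;
  unpack(zm, zl, z, lz);
  int n = masks.size();
  NumericVector out(n);
  Geo g;
  for (int i = 0; i < n; ++i) {
    std::vector<mask_t> t; std::vector<double> lt;
    unpack(masks[i], lens[i], t, lt);
    build_geo(z, lz, t, lt, tol, g);
    out[i] = std::sqrt(g.len2);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Iterative Frechet means and projection
// ---------------------------------------------------------------------------

struct Conv {
  // stopping rule: sum of the last (m-1) step lengths < eps, which bounds the
  // diameter of the last m iterates (the pairwise-within-eps test)
  std::vector<double> buf;
  int m1, pos, nfill;
  double sum;
  Conv(int m) : buf(std::max(m - 1, 1), 0.0), m1(std::max(m - 1, 1)),
                pos(0), nfill(0), sum(0.0) {}
  bool push(double step) {
    sum -= buf[pos];
    buf[pos] = step;
    sum += step;
    pos = (pos + 1) % m1;
    if (nfill < m1) ++nfill;
    return nfill == m1;
  }
};

static void copy_tree(const std::vector<mask_t>& m, const std::vector<double>& l,
                      std::vector<mask_t>& om, std::vector<double>& ol) {
  om = m; ol = l;
}

// Cyclic (Bacak-style) weighted Frechet mean: vertex j = i mod (k+1) at
// overall iteration i, step s_i = p_j (k+1) / (i+2) clipped to [0,1].
// Reduces to the Sturm step 1/(i+2) for uniform weights.
// [[Rcpp::export]]
List cpp_mean_bacak(List masks, List lens, NumericVector p,
                    double eps, int m, int maxit, double tol) {
  const int k1 = masks.size();
  std::vector< std::vector<mask_t> > vm(k1);
  std::vector< std::vector<double> > vl(k1);
  for (int j = 0; j < k1; ++j) unpack(masks[j], lens[j], vm[j], vl[j]);

  std::vector<mask_t> mu, nm; std::vector<double> ml, nl;
  copy_tree(vm[0], vl[0], mu, ml);
  Conv cv(m);
  Geo g;
  bool converged = false;
  double last_step = 0.0;
  int it = 0;
  for (; it < maxit; ++it) {
    int j = it % k1;
    double s = p[j] * k1 / (it + 2.0);
    if (s > 1.0) s = 1.0;
    build_geo(mu, ml, vm[j], vl[j], tol, g);
    double d = std::sqrt(g.len2);
    geo_point(g, s, nm, nl);
    mu.swap(nm); ml.swap(nl);
    last_step = s * d;
    if (cv.push(last_step) && cv.sum < eps) { converged = true; ++it; break; }
  }
  List out = pack_tree(mu, ml);
  out["iterations"] = it;
  out["converged"] = converged;
  out["final_step"] = last_step;
  return out;
}

// Sturm's stochastic scheme: vertex sampled with probability p_j, step
// 1/(i+2).  Uses R's RNG so set.seed() on the R side fixes the stream.
// [[Rcpp::export]]
List cpp_mean_sturm(List masks, List lens, NumericVector p,
                    double eps, int m, int maxit, double tol) {
  const int k1 = masks.size();
  std::vector< std::vector<mask_t> > vm(k1);
  std::vector< std::vector<double> > vl(k1);
  for (int j = 0; j < k1; ++j) unpack(masks[j], lens[j], vm[j], vl[j]);
  std::vector<double> cum(k1);
  double acc = 0.0;
  for (int j = 0; j < k1; ++j) { acc += p[j]; cum[j] = acc; }

  RNGScope scope;
  std::vector<mask_t> mu, nm; std::vector<double> ml, nl;
  copy_tree(vm[0], vl[0], mu, ml);
  Conv cv(m);
  Geo g;
  bool converged = false;
  double last_step = 0.0;
  int it = 0;
  for (; it < maxit; ++it) {
    double u = unif_rand() * acc;
    int j = 0;
    while (j < k1 - 1 && u > cum[j]) ++j;
    double s = 1.0 / (it + 2.0);
    build_geo(mu, ml, vm[j], vl[j], tol, g);
    double d = std::sqrt(g.len2);
    geo_point(g, s, nm, nl);
    mu.swap(nm); ml.swap(nl);
    last_step = s * d;
    if (cv.push(last_step) && cv.sum < eps) { converged = true; ++it; break; }
  }
  List out = pack_tree(mu, ml);
  out["iterations"] = it;
  out["converged"] = converged;
  out["final_step"] = last_step;
  return out;
}

// Geometric projection of z onto Pi(V): greedy Sturm-type iteration.
// Candidates y_{i,j} sit a proportion 1/(i+2) along Gamma(mu_i, v_j); the
// one nearest z is kept and the weight estimate counts the moves.
// [[Rcpp::export]]
List cpp_project(IntegerVector zm, NumericVector zl,
                 List masks, List lens,
                 IntegerVector sm, NumericVector sl,
                 double eps, int m, int maxit, double tol) {
  const int k1 = masks.size();
  std::vector< std::vector<mask_t> > vm(k1);
  std::vector< std::vector<double> > vl(k1);
  for (int j = 0; j < k1; ++j) unpack(masks[j], lens[j], vm[j], vl[j]);
  std::vector<mask_t> z; std::vector<double> lz;
  unpack(zm, zl, z, lz);

  std::vector<mask_t> mu; std::vector<double> ml;
  unpack(sm, sl, mu, ml);

  std::vector<double> counts(k1, 0.0);
  std::vector<mask_t> best_m, cand_m; std::vector<double> best_l, cand_l;
  Conv cv(m);
  Geo g;
  bool converged = false;
  int it = 0;
  for (; it < maxit; ++it) {
    double s = 1.0 / (it + 2.0);
    int r = -1;
    double bestd = 0.0, beststep = 0.0;
    for (int j = 0; j < k1; ++j) {
      build_geo(mu, ml, vm[j], vl[j], tol, g);
      double dj = std::sqrt(g.len2);
      geo_point(g, s, cand_m, cand_l);
      build_geo(z, lz, cand_m, cand_l, tol, g);
      double dz = std::sqrt(g.len2);
      if (r < 0 || dz < bestd) {
        r = j; bestd = dz; beststep = s * dj;
        best_m.swap(cand_m); best_l.swap(cand_l);
      }
    }
    mu.swap(best_m); ml.swap(best_l);
    counts[r] += 1.0;
    if (cv.push(beststep) && cv.sum < eps) { converged = true; ++it; break; }
  }
  build_geo(z, lz, mu, ml, tol, g);
  NumericVector w(k1);
  for (int j = 0; j < k1; ++j) w[j] = it > 0 ? counts[j] / it : 1.0 / k1;
  List out = pack_tree(mu, ml);
  out["weights"] = w;
  out["distance"] = std::sqrt(g.len2);
  out["iterations"] = it;
  out["converged"] = converged;
  return out;
}
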