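// Felsenstein pruning kernel for amino-acid likelihoods.
//
// Trees arrive as ape-style edge matrices in postorder; tips are coded as
// integer states 1..nstates with 0 meaning fully ambiguous (gap/X).  The
// rate matrix is supplied pre-eigendecomposed (Q = V diag(lam) Vinv), so
// P(t) = V diag(exp(lam t)) Vinv.  Per-pattern scaling keeps partials in
// range; log scalers are tracked per node and rate category.
//
// Branch-length optimisation is coordinate ascent: per sweep, one down
// pass and one up pass build the partials, then each edge is optimised by
// golden section on its conditional likelihood; after an accepted move the
// down partials on the path to the root are refolded so later edges see
// fresh subtree partials (up partials refresh once per sweep).  A sweep
// that fails to improve the full log-likelihood is rejected, so the
// per-sweep trace is non-decreasing.

#include <RcppArmadillo.h>
#include <functional>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat pmat(const mat& V, const mat& Vinv, const vec& lam, double t) {
  mat P = V * diagmat(exp(lam * t)) * Vinv;
  // numerical contract: clamp reconstructed probabilities into [0,1]
  P.clamp(0.0, 1.0);
  return P;
}

struct TreeLik {
  imat edge;             // nedge x 2, postorder, 1-based node ids
  vec el;                // edge lengths
  int ntip, nnode, ns, npat, ncat, nedge;
  imat tipstate;         // ntip x npat, 0 = ambiguous
  vec w;                 // pattern weights
  mat V, Vinv;
  vec lam, pi, rates, rw;

  std::vector<std::vector<int>> child_edges;  // per node, edge indices
  std::vector<int> parent_edge;               // per node, -1 at root
  std::vector<int> node_post;                 // internal nodes, postorder
  int root;

  // per category containers
  std::vector<cube> L;   // L[c]: ns x npat x nnode (scaled down partials)
  std::vector<mat> sc;   // sc[c]: npat x nnode (log scalers, tips zero)
  std::vector<cube> E;   // E[c]: ns x npat x nedge (P_e * partial[child])
  std::vector<cube> H;   // H[c]: ns x npat x nnode (edge context of the
                         //   edge above each node, own transition excluded)
  std::vector<mat> hs;   // hs[c]: npat x nnode (log scalers for H)
  std::vector<cube> A;   // A[c]: node context including the transition
                         //   across the edge above the node; A[root] = pi
  std::vector<mat> as_;  // as_[c]: npat x nnode (log scalers for A)

  TreeLik(const imat& edge_, const vec& el_, int ntip_, const imat& tip_,
          const vec& w_, const mat& V_, const mat& Vinv_, const vec& lam_,
          const vec& pi_, const vec& rates_, const vec& rw_)
    : edge(edge_), el(el_), ntip(ntip_), tipstate(tip_), w(w_),
      V(V_), Vinv(Vinv_), lam(lam_), pi(pi_), rates(rates_), rw(rw_) {
    ns = pi.n_elem;
    npat = tipstate.n_cols;
    ncat = rates.n_elem;
    nedge = edge.n_rows;
    nnode = edge.max();
    child_edges.assign(nnode, {});
    parent_edge.assign(nnode, -1);
    for (int e = 0; e < nedge; ++e) {
      child_edges[edge(e, 0) - 1].push_back(e);
      parent_edge[edge(e, 1) - 1] = e;
    }
    root = edge(nedge - 1, 0);
    // postorder over internal nodes: parents of postorder edges, deduped
    std::vector<char> seen(nnode, 0);
    for (int e = 0; e < nedge; ++e) {
      int u = edge(e, 0);
      if (!seen[u - 1]) { seen[u - 1] = 1; node_post.push_back(u); }
    }
    L.assign(ncat, cube(ns, npat, nnode));
    sc.assign(ncat, mat(npat, nnode, fill::zeros));
    E.assign(ncat, cube(ns, npat, nedge));
    H.assign(ncat, cube(ns, npat, nnode));
    hs.assign(ncat, mat(npat, nnode, fill::zeros));
    A.assign(ncat, cube(ns, npat, nnode));
    as_.assign(ncat, mat(npat, nnode, fill::zeros));
  }

  mat tip_partial(int tip) const {
    mat M(ns, npat);
    for (int p = 0; p < npat; ++p) {
      int s = tipstate(tip - 1, p);
      if (s == 0) M.col(p).ones();
      else { M.col(p).zeros(); M(s - 1, p) = 1.0; }
    }
    return M;
  }

  void edge_E(int e, int c) {
    int v = edge(e, 1);
    mat P = pmat(V, Vinv, lam, el(e) * rates(c));
    E[c].slice(e) = (v <= ntip) ? mat(P * tip_partial(v))
                                : mat(P * L[c].slice(v - 1));
  }

  // refold L[u], sc[u] from the E slices of its child edges
  void fold(int u) {
    for (int c = 0; c < ncat; ++c) {
      mat acc(ns, npat, fill::ones);
      rowvec s(npat, fill::zeros);
      for (int e : child_edges[u - 1]) {
        acc %= E[c].slice(e);
        int v = edge(e, 1);
        if (v > ntip) s += sc[c].col(v - 1).t();
      }
      rowvec mx = max(acc, 0);
      mx.transform([](double x) { return x > 1e-290 ? x : 1e-290; });
      acc.each_row() /= mx;
      L[c].slice(u - 1) = acc;
      sc[c].col(u - 1) = (s + log(mx)).t();
    }
  }

  void down() {
    for (int u : node_post) {
      for (int e : child_edges[u - 1])
        for (int c = 0; c < ncat; ++c) edge_E(e, c);
      fold(u);
    }
  }

  // after el(e) changed: refresh E[e] and refold the chain up to the root
  void refresh_edge(int e) {
    for (int c = 0; c < ncat; ++c) edge_E(e, c);
    int u = edge(e, 0);
    while (true) {
      fold(u);
      int pe = parent_edge[u - 1];
      if (pe < 0) break;
      for (int c = 0; c < ncat; ++c) edge_E(pe, c);
      u = edge(pe, 0);
    }
  }

  double lnl_from_down() const {
    mat lp(npat, ncat);
    for (int c = 0; c < ncat; ++c) {
      rowvec site = pi.t() * L[c].slice(root - 1);
      site.transform([](double x) { return x > 0 ? x : 1e-300; });
      lp.col(c) = (log(site).t() + sc[c].col(root - 1)) + std::log(rw(c));
    }
    vec m = max(lp, 1);
    vec ll = m + log(sum(exp(lp.each_col() - m), 1));
    return dot(w, ll);
  }

  void up() {
    init_A_root();
    for (int e = nedge - 1; e >= 0; --e) {  // parents before children
      set_H(e);
      set_A(e);
    }
  }

  void init_A_root() {
    for (int c = 0; c < ncat; ++c) {
      A[c].slice(root - 1).each_col() = pi;
      as_[c].col(root - 1).zeros();
    }
  }

  // A[v] = P(el(e))^T H[v] for edge e = (u, v); call after H[v] is set
  void set_A(int e) {
    int v = edge(e, 1);
    if (v <= ntip) return;
    for (int c = 0; c < ncat; ++c) {
      mat P = pmat(V, Vinv, lam, el(e) * rates(c));
      mat Av = P.t() * H[c].slice(v - 1);
      rowvec mx = max(Av, 0);
      mx.transform([](double x) { return x > 1e-290 ? x : 1e-290; });
      Av.each_row() /= mx;
      A[c].slice(v - 1) = Av;
      as_[c].col(v - 1) = (hs[c].col(v - 1).t() + log(mx)).t();
    }
  }

  // compute H[v], hs[v] for edge e = (u, v) from A[u] and sibling E slices
  void set_H(int e) {
    int u = edge(e, 0), v = edge(e, 1);
    for (int c = 0; c < ncat; ++c) {
      mat Hv = A[c].slice(u - 1);
      rowvec hsv = as_[c].col(u - 1).t();
      for (int e2 : child_edges[u - 1]) {
        if (e2 == e) continue;
        Hv %= E[c].slice(e2);
        int v2 = edge(e2, 1);
        if (v2 > ntip) hsv += sc[c].col(v2 - 1).t();
      }
      rowvec mx = max(Hv, 0);
      mx.transform([](double x) { return x > 1e-290 ? x : 1e-290; });
      Hv.each_row() /= mx;
      H[c].slice(v - 1) = Hv;
      hs[c].col(v - 1) = (hsv + log(mx)).t();
    }
  }

  // preorder sweep: every edge is optimised against fresh partials
  void sweep(double llo, double lhi, int iter);

  // lnL as a function of one edge length, using cached H and L
  double edge_lnl(int e, double t) const {
    int v = edge(e, 1);
    mat lp(npat, ncat);
    for (int c = 0; c < ncat; ++c) {
      mat P = pmat(V, Vinv, lam, t * rates(c));
      mat PL = (v <= ntip) ? mat(P * tip_partial(v))
                           : mat(P * L[c].slice(v - 1));
      rowvec site = sum(H[c].slice(v - 1) % PL, 0);
      site.transform([](double x) { return x > 0 ? x : 1e-300; });
      rowvec lsc = hs[c].col(v - 1).t();
      if (v > ntip) lsc += sc[c].col(v - 1).t();
      lp.col(c) = (log(site) + lsc).t() + std::log(rw(c));
    }
    vec m = max(lp, 1);
    vec ll = m + log(sum(exp(lp.each_col() - m), 1));
    return dot(w, ll);
  }
};

// [[Rcpp::export(name = ".pruning_lnl")]]
double pruning_lnl(const arma::imat& edge, const arma::vec& el, int ntip,
                   const arma::imat& tipstate, const arma::vec& w,
                   const arma::mat& V, const arma::mat& Vinv,
                   const arma::vec& lam, const arma::vec& pi,
                   const arma::vec& rates, const arma::vec& rw) {
  TreeLik T(edge, el, ntip, tipstate, w, V, Vinv, lam, pi, rates, rw);
  T.down();
  return T.lnl_from_down();
}

// golden-section maximisation of f on [lo, hi]
template <typename F>
static double golden(F f, double lo, double hi, int iter) {
  const double g = 0.6180339887498949;
  double a = lo, b = hi;
  double x1 = b - g * (b - a), x2 = a + g * (b - a);
  double f1 = f(x1), f2 = f(x2);
  for (int i = 0; i < iter; ++i) {
    if (f1 < f2) {
      a = x1; x1 = x2; f1 = f2;
      x2 = a + g * (b - a); f2 = f(x2);
    } else {
      b = x2; x2 = x1; f2 = f1;
      x1 = b - g * (b - a); f1 = f(x1);
    }
  }
  return f1 > f2 ? x1 : x2;
}

void TreeLik::sweep(double llo, double lhi, int iter) {
  init_A_root();
  std::function<void(int)> visit = [&](int u) {
    for (int e : child_edges[u - 1]) {
      int v = edge(e, 1);
      set_H(e);                        // fresh: nothing below v touched yet
      double f_cur = edge_lnl(e, el(e));
      double lt = golden([&](double x) { return edge_lnl(e, std::exp(x)); },
                         llo, lhi, iter);
      double t = std::exp(lt);
      if (edge_lnl(e, t) > f_cur) {
        el(e) = t;
        for (int c = 0; c < ncat; ++c) edge_E(e, c);
      }
      if (v > ntip) {
        set_A(e);
        visit(v);
        fold(v);                       // subtree changed below v
        for (int c = 0; c < ncat; ++c) edge_E(e, c);
      }
    }
  };
  visit(root);
}

// [[Rcpp::export(name = ".optim_edges")]]
Rcpp::List optim_edges(const arma::imat& edge, const arma::vec& el0, int ntip,
                       const arma::imat& tipstate, const arma::vec& w,
                       const arma::mat& V, const arma::mat& Vinv,
                       const arma::vec& lam, const arma::vec& pi,
                       const arma::vec& rates, const arma::vec& rw,
                       int max_sweeps, double tol, double min_t,
                       double max_t, int iter) {
  TreeLik T(edge, el0, ntip, tipstate, w, V, Vinv, lam, pi, rates, rw);
  T.el.clamp(min_t, max_t);
  T.down();
  double lnl = T.lnl_from_down();
  std::vector<double> trace;
  trace.push_back(lnl);
  bool converged = false;
  // optimise edges in log branch length: lengths span orders of magnitude
  double llo = std::log(min_t), lhi = std::log(max_t);
  for (int s = 0; s < max_sweeps; ++s) {
    vec el_prev = T.el;
    T.sweep(llo, lhi, iter);
    T.fold(T.root);
    double lnl_new = T.lnl_from_down();
    if (lnl_new < lnl) {        // numerical guard: reject the sweep
      T.el = el_prev;
      T.down();
      converged = true;
      break;
    }
    bool done = (lnl_new - lnl) < tol;
    lnl = lnl_new;
    trace.push_back(lnl);
    if (done) { converged = true; break; }
  }
  return Rcpp::List::create(Rcpp::Named("el") = T.el,
                            Rcpp::Named("loglik") = lnl,
                            Rcpp::Named("trace") = trace,
                            Rcpp::Named("converged") = converged);
}

// consistency probe: conditional edge likelihood must equal the full lnL
// [[Rcpp::export(name = ".edge_lnl_check")]]
double edge_lnl_check(const arma::imat& edge, const arma::vec& el, int ntip,
                      const arma::imat& tipstate, const arma::vec& w,
                      const arma::mat& V, const arma::mat& Vinv,
                      const arma::vec& lam, const arma::vec& pi,
                      const arma::vec& rates, const arma::vec& rw,
                      int e1based) {
  TreeLik T(edge, el, ntip, tipstate, w, V, Vinv, lam, pi, rates, rw);
  T.down();
  T.up();
  return T.edge_lnl(e1based - 1, el(e1based - 1));
}
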