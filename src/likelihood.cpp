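#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Shared layouts (all 0-based):
//   edges: IntegerMatrix nedge x 2, columns (parent, child), in postorder.
//          Node ids follow the ape convention shifted to 0-base:
//          tips 0..ntip-1, root = ntip, internals ntip..nnode-1.
//   P:     flat transition-probability stack; entry for edge e, rate
//          category c, parent state s, child state b sits at
//          P[((e*ncat + c)*4 + s)*4 + b].
//   tipcode: IntegerMatrix npat x ntip; IUPAC bitmask A=1, C=2, G=4, T=8
//          (missing/'?'/'-'/'N' = 15).
//   partials (down/up): node n, pattern p, category c, state s at
//          X[((n*npat + p)*ncat + c)*4 + s].

static inline void tip_partial(int code, double* out) {
  out[0] = (code & 1) ? 1.0 : 0.0;
  out[1] = (code & 2) ? 1.0 : 0.0;
  out[2] = (code & 4) ? 1.0 : 0.0;
  out[3] = (code & 8) ? 1.0 : 0.0;
}

// Per-pattern log-likelihood of a fixed tree by Felsenstein pruning,
// averaging over equal-weight rate categories.
// [[Rcpp::export]]
NumericVector cpp_site_loglik(IntegerMatrix edges, int nnode,
                              IntegerMatrix tipcode, NumericVector P,
                              NumericVector pi, int ncat) {
  const int nedge = edges.nrow();
  const int npat = tipcode.nrow();
  const int ntip = tipcode.ncol();
  const int root = ntip;
  NumericVector out(npat);
  std::vector<double> part(static_cast<size_t>(nnode) * ncat * 4);
  std::vector<double> msg(4);

  for (int p = 0; p < npat; ++p) {
    double logscale = 0.0;
    // init partials
    for (int n = 0; n < nnode; ++n) {
      double* pp = &part[(static_cast<size_t>(n) * ncat) * 4];
      if (n < ntip) {
        double tp[4];
        tip_partial(tipcode(p, n), tp);
        for (int c = 0; c < ncat; ++c)
          for (int s = 0; s < 4; ++s) pp[c * 4 + s] = tp[s];
      } else {
        for (int i = 0; i < ncat * 4; ++i) pp[i] = 1.0;
      }
    }
    for (int e = 0; e < nedge; ++e) {
      const int par = edges(e, 0), ch = edges(e, 1);
      double* pc = &part[(static_cast<size_t>(ch) * ncat) * 4];
      double* pa = &part[(static_cast<size_t>(par) * ncat) * 4];
      // rescale child if tiny (complete by postorder)
      double mx = 0.0;
      for (int i = 0; i < ncat * 4; ++i) mx = std::max(mx, pc[i]);
      if (mx > 0.0 && mx < 1e-240) {
        for (int i = 0; i < ncat * 4; ++i) pc[i] /= mx;
        logscale += std::log(mx);
      }
      const double* Pe = &P[static_cast<size_t>(e) * ncat * 16];
      for (int c = 0; c < ncat; ++c) {
        const double* Pc = Pe + c * 16;
        for (int s = 0; s < 4; ++s) {
          double acc = 0.0;
          for (int b = 0; b < 4; ++b) acc += Pc[s * 4 + b] * pc[c * 4 + b];
          msg[s] = acc;
        }
        for (int s = 0; s < 4; ++s) pa[c * 4 + s] *= msg[s];
      }
    }
    const double* pr = &part[(static_cast<size_t>(root) * ncat) * 4];
    double L = 0.0;
    for (int c = 0; c < ncat; ++c)
      for (int s = 0; s < 4; ++s) L += pi[s] * pr[c * 4 + s];
    L /= ncat;
    out[p] = std::log(L) + logscale;
  }
  return out;
}

// Down (subtree) and up (rest-of-tree, conditioned on the state at the
// child's parent) conditional likelihoods for every node, plus per-edge
// messages. No rescaling: intended for trees up to ~150 tips.
// [[Rcpp::export]]
List cpp_tree_partials(IntegerMatrix edges, int nnode, IntegerMatrix tipcode,
                       NumericVector P, int ncat) {
  const int nedge = edges.nrow();
  const int npat = tipcode.nrow();
  const int ntip = tipcode.ncol();
  const int root = ntip;
  const size_t blk = static_cast<size_t>(ncat) * 4;
  NumericVector down(static_cast<size_t>(nnode) * npat * blk);
  NumericVector up(static_cast<size_t>(nnode) * npat * blk);
  std::vector<double> msg(static_cast<size_t>(nnode) * npat * blk);
  std::vector<double> mup(static_cast<size_t>(nnode) * npat * blk);
  std::vector<std::vector<int> > kids(nnode);
  std::vector<int> paredge(nnode, -1);
  for (int e = 0; e < nedge; ++e) {
    kids[edges(e, 0)].push_back(edges(e, 1));
    paredge[edges(e, 1)] = e;
  }

  // postorder: down + msg
  for (int n = 0; n < nnode; ++n) {
    for (int p = 0; p < npat; ++p) {
      double* d = &down[(static_cast<size_t>(n) * npat + p) * blk];
      if (n < ntip) {
        double tp[4];
        tip_partial(tipcode(p, n), tp);
        for (int c = 0; c < ncat; ++c)
          for (int s = 0; s < 4; ++s) d[c * 4 + s] = tp[s];
      } else {
        for (size_t i = 0; i < blk; ++i) d[i] = 1.0;
      }
    }
  }
  for (int e = 0; e < nedge; ++e) {
    const int par = edges(e, 0), ch = edges(e, 1);
    const double* Pe = &P[static_cast<size_t>(e) * ncat * 16];
    for (int p = 0; p < npat; ++p) {
      const double* d = &down[(static_cast<size_t>(ch) * npat + p) * blk];
      double* m = &msg[(static_cast<size_t>(ch) * npat + p) * blk];
      double* dp = &down[(static_cast<size_t>(par) * npat + p) * blk];
      for (int c = 0; c < ncat; ++c) {
        const double* Pc = Pe + c * 16;
        for (int s = 0; s < 4; ++s) {
          double acc = 0.0;
          for (int b = 0; b < 4; ++b) acc += Pc[s * 4 + b] * d[c * 4 + b];
          m[c * 4 + s] = acc;
          dp[c * 4 + s] *= acc;
        }
      }
    }
  }

  // preorder (reverse postorder): up + mup
  for (int e = nedge - 1; e >= 0; --e) {
    const int par = edges(e, 0), ch = edges(e, 1);
    const double* Pe = &P[static_cast<size_t>(e) * ncat * 16];
    for (int p = 0; p < npat; ++p) {
      double* u = &up[(static_cast<size_t>(ch) * npat + p) * blk];
      const double* dpar = &down[(static_cast<size_t>(par) * npat + p) * blk];
      const double* mch = &msg[(static_cast<size_t>(ch) * npat + p) * blk];
      // product over siblings = down[par] / msg[ch], with a safe fallback
      bool safe = true;
      for (size_t i = 0; i < blk; ++i)
        if (mch[i] < 1e-290) { safe = false; break; }
      if (safe) {
        for (size_t i = 0; i < blk; ++i) u[i] = dpar[i] / mch[i];
      } else {
        for (size_t i = 0; i < blk; ++i) u[i] = 1.0;
        for (size_t k = 0; k < kids[par].size(); ++k) {
          int sib = kids[par][k];
          if (sib == ch) continue;
          const double* msib = &msg[(static_cast<size_t>(sib) * npat + p) * blk];
          for (size_t i = 0; i < blk; ++i) u[i] *= msib[i];
        }
      }
      if (par != root) {
        const double* mu = &mup[(static_cast<size_t>(par) * npat + p) * blk];
        for (size_t i = 0; i < blk; ++i) u[i] *= mu[i];
      }
      // mup[ch](a) = sum_b P_e(a,b) * up[ch](b), for ch's own children
      double* muc = &mup[(static_cast<size_t>(ch) * npat + p) * blk];
      for (int c = 0; c < ncat; ++c) {
        const double* Pc = Pe + c * 16;
        for (int s = 0; s < 4; ++s) {
          double acc = 0.0;
          for (int b = 0; b < 4; ++b) acc += Pc[s * 4 + b] * u[c * 4 + b];
          muc[c * 4 + s] = acc;
        }
      }
    }
  }
  return List::create(_["down"] = down, _["up"] = up);
}

// Total weighted log-likelihood when the edge above node v is given length
// parameterisation P (16*ncat flat: [(c*4+s)*4+b]); everything else fixed.
// [[Rcpp::export]]
double cpp_edge_loglik(NumericVector down, NumericVector up, int v, int npat,
                       int ncat, NumericVector P, NumericVector pi,
                       NumericVector w) {
  const size_t blk = static_cast<size_t>(ncat) * 4;
  double tot = 0.0;
  for (int p = 0; p < npat; ++p) {
    if (w[p] == 0.0) continue;
    const double* d = &down[(static_cast<size_t>(v) * npat + p) * blk];
    const double* u = &up[(static_cast<size_t>(v) * npat + p) * blk];
    double L = 0.0;
    for (int c = 0; c < ncat; ++c) {
      const double* Pc = &P[c * 16];
      for (int s = 0; s < 4; ++s) {
        double acc = 0.0;
        for (int b = 0; b < 4; ++b) acc += Pc[s * 4 + b] * d[c * 4 + b];
        L += pi[s] * u[c * 4 + s] * acc;
      }
    }
    L /= ncat;
    if (!(L > 0.0)) return -std::numeric_limits<double>::infinity();
    tot += w[p] * std::log(L);
  }
  return tot;
}

// Log-likelihood after grafting a query tip onto the edge above node v:
// the edge is split into a child-side piece (P1) and a parent-side piece
// (P2); the query hangs by a pendant branch (Pq). qcode gives the query's
// IUPAC bitmask per pattern. Each P* is 16*ncat flat: [(c*4+s)*4+b].
// [[Rcpp::export]]
double cpp_graft_loglik(NumericVector down, NumericVector up, int v, int npat,
                        int ncat, IntegerVector qcode, NumericVector P1,
                        NumericVector P2, NumericVector Pq, NumericVector pi,
                        NumericVector w) {
  const size_t blk = static_cast<size_t>(ncat) * 4;
  // query-side vectors depend only on the 16 possible codes
  std::vector<double> qv(16 * blk);
  for (int code = 0; code < 16; ++code) {
    double tp[4];
    tip_partial(code == 0 ? 15 : code, tp);
    for (int c = 0; c < ncat; ++c) {
      const double* Pc = &Pq[c * 16];
      for (int s = 0; s < 4; ++s) {
        double acc = 0.0;
        for (int b = 0; b < 4; ++b) acc += Pc[s * 4 + b] * tp[b];
        qv[code * blk + c * 4 + s] = acc;
      }
    }
  }
  double tot = 0.0;
  for (int p = 0; p < npat; ++p) {
    if (w[p] == 0.0) continue;
    const double* d = &down[(static_cast<size_t>(v) * npat + p) * blk];
    const double* u = &up[(static_cast<size_t>(v) * npat + p) * blk];
    const double* q = &qv[(qcode[p] & 15) * blk];
    double L = 0.0;
    for (int c = 0; c < ncat; ++c) {
      const double* Pc1 = &P1[c * 16];
      const double* Pc2 = &P2[c * 16];
      for (int s = 0; s < 4; ++s) {
        double a = 0.0, bsum = 0.0;
        for (int b = 0; b < 4; ++b) {
          a += Pc1[s * 4 + b] * d[c * 4 + b];
          bsum += Pc2[s * 4 + b] * u[c * 4 + b];
        }
        L += pi[s] * a * bsum * q[c * 4 + s];
      }
    }
    L /= ncat;
    if (!(L > 0.0)) return -std::numeric_limits<double>::infinity();
    tot += w[p] * std::log(L);
  }
  return tot;
}

// Fixed factor for pendant-length optimization: g[(p*ncat+c)*4+s] =
// pi[s] * (P1 down)[s] * (P2 up)[s]. The pendant likelihood is then the
// inner product with the query-side vector.
// [[Rcpp::export]]
NumericVector cpp_graft_fixed(NumericVector down, NumericVector up, int v,
                              int npat, int ncat, NumericVector P1,
                              NumericVector P2, NumericVector pi) {
  const size_t blk = static_cast<size_t>(ncat) * 4;
  NumericVector g(static_cast<size_t>(npat) * blk);
  for (int p = 0; p < npat; ++p) {
    const double* d = &down[(static_cast<size_t>(v) * npat + p) * blk];
    const double* u = &up[(static_cast<size_t>(v) * npat + p) * blk];
    double* gg = &g[static_cast<size_t>(p) * blk];
    for (int c = 0; c < ncat; ++c) {
      const double* Pc1 = &P1[c * 16];
      const double* Pc2 = &P2[c * 16];
      for (int s = 0; s < 4; ++s) {
        double a = 0.0, bsum = 0.0;
        for (int b = 0; b < 4; ++b) {
          a += Pc1[s * 4 + b] * d[c * 4 + b];
          bsum += Pc2[s * 4 + b] * u[c * 4 + b];
        }
        gg[c * 4 + s] = pi[s] * a * bsum;
      }
    }
  }
  return g;
}

// Pendant-length evaluation against a precomputed fixed factor.
// [[Rcpp::export]]
double cpp_pendant_loglik(NumericVector g, IntegerVector qcode,
                          NumericVector Pq, NumericVector w, int npat,
                          int ncat) {
  const size_t blk = static_cast<size_t>(ncat) * 4;
  std::vector<double> qv(16 * blk);
  for (int code = 0; code < 16; ++code) {
    double tp[4];
    tip_partial(code == 0 ? 15 : code, tp);
    for (int c = 0; c < ncat; ++c) {
      const double* Pc = &Pq[c * 16];
      for (int s = 0; s < 4; ++s) {
        double acc = 0.0;
        for (int b = 0; b < 4; ++b) acc += Pc[s * 4 + b] * tp[b];
        qv[code * blk + c * 4 + s] = acc;
      }
    }
  }
  double tot = 0.0;
  for (int p = 0; p < npat; ++p) {
    if (w[p] == 0.0) continue;
    const double* gg = &g[static_cast<size_t>(p) * blk];
    const double* q = &qv[(qcode[p] & 15) * blk];
    double L = 0.0;
    for (size_t i = 0; i < blk; ++i) L += gg[i] * q[i];
    L /= ncat;
    if (!(L > 0.0)) return -std::numeric_limits<double>::infinity();
    tot += w[p] * std::log(L);
  }
  return tot;
}

// Fixed factor for optimizing one sub-edge: h[(p*ncat+c)*4+s] =
// pi[s] * (Pfix fixed_side)[s] * (Pq qtip)[s], where fixed_side is the down
// or up partial array (selected by the caller) of node v.
// [[Rcpp::export]]
NumericVector cpp_graft_fixed_q(NumericVector side, int v, int npat, int ncat,
                                NumericVector Pfix, IntegerVector qcode,
                                NumericVector Pq, NumericVector pi) {
  const size_t blk = static_cast<size_t>(ncat) * 4;
  std::vector<double> qv(16 * blk);
  for (int code = 0; code < 16; ++code) {
    double tp[4];
    tip_partial(code == 0 ? 15 : code, tp);
    for (int c = 0; c < ncat; ++c) {
      const double* Pc = &Pq[c * 16];
      for (int s = 0; s < 4; ++s) {
        double acc = 0.0;
        for (int b = 0; b < 4; ++b) acc += Pc[s * 4 + b] * tp[b];
        qv[code * blk + c * 4 + s] = acc;
      }
    }
  }
  NumericVector h(static_cast<size_t>(npat) * blk);
  for (int p = 0; p < npat; ++p) {
    const double* x = &side[(static_cast<size_t>(v) * npat + p) * blk];
    const double* q = &qv[(qcode[p] & 15) * blk];
    double* hh = &h[static_cast<size_t>(p) * blk];
    for (int c = 0; c < ncat; ++c) {
      const double* Pc = &Pfix[c * 16];
      for (int s = 0; s < 4; ++s) {
        double acc = 0.0;
        for (int b = 0; b < 4; ++b) acc += Pc[s * 4 + b] * x[c * 4 + b];
        hh[c * 4 + s] = pi[s] * acc * q[c * 4 + s];
      }
    }
  }
  return h;
}

// Sub-edge evaluation against a precomputed fixed factor: the varying side
// partial of node v is pushed through Pvar and dotted with h.
// [[Rcpp::export]]
double cpp_side_loglik(NumericVector h, NumericVector side, int v, int npat,
                       int ncat, NumericVector Pvar, NumericVector w) {
  const size_t blk = static_cast<size_t>(ncat) * 4;
  double tot = 0.0;
  for (int p = 0; p < npat; ++p) {
    if (w[p] == 0.0) continue;
    const double* x = &side[(static_cast<size_t>(v) * npat + p) * blk];
    const double* hh = &h[static_cast<size_t>(p) * blk];
    double L = 0.0;
    for (int c = 0; c < ncat; ++c) {
      const double* Pc = &Pvar[c * 16];
      for (int s = 0; s < 4; ++s) {
        double acc = 0.0;
        for (int b = 0; b < 4; ++b) acc += Pc[s * 4 + b] * x[c * 4 + b];
        L += hh[c * 4 + s] * acc;
      }
    }
    L /= ncat;
    if (!(L > 0.0)) return -std::numeric_limits<double>::infinity();
    tot += w[p] * std::log(L);
  }
  return tot;
}
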