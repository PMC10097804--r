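// Felsenstein pruning over sense-codon states, with per-pattern scaling,
// site-class mixtures, branch-dependent rate matrices (foreground /
// background omega), and an edge-wise branch-length optimizer that reuses
// partial likelihood vectors through the eigendecomposition of the
// reversible generator.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Eigsys {
  mat U, Uinv, Ut, Uinvt; // transposes cached for the edge optimizer
  vec lam;
};

std::vector<Eigsys> parseEig(const Rcpp::List& eig) {
  std::vector<Eigsys> out(eig.size());
  for (int k = 0; k < eig.size(); ++k) {
    Rcpp::List e = eig[k];
    out[k].U = Rcpp::as<mat>(e["U"]);
    out[k].Uinv = Rcpp::as<mat>(e["Uinv"]);
    out[k].lam = Rcpp::as<vec>(e["lam"]);
    out[k].Ut = out[k].U.t();
    out[k].Uinvt = out[k].Uinv.t();
  }
  return out;
}

mat pmat(const Eigsys& E, double t) {
  mat Us = E.U;
  rowvec ex = exp(E.lam.t() * t);
  Us.each_row() %= ex;
  mat P = Us * E.Uinv;
  P.clamp(0.0, datum::inf);
  return P;
}

// contribution of a child along an edge: P * L_child, with tips gathered
// directly from columns of P (missing state -> ones)
mat edgeContribution(const mat& P, int child, int ntip,
                     const imat& tipState,
                     const std::vector<mat>& part) {
  const int npat = tipState.n_cols;
  const int n = P.n_rows;
  if (child < ntip) {
    mat C(n, npat);
    for (int p = 0; p < npat; ++p) {
      int s = tipState(child, p);
      if (s < 0)
        C.col(p).ones();
      else
        C.col(p) = P.col(s);
    }
    return C;
  }
  return P * part[child];
}

// per-class postorder pruning; fills part/scal for internal nodes of one
// class. Sharing: if base >= 0 and a node's entire subtree uses identical
// eigen systems in this class and the base class, partials are copied.
void pruneClass(int c, int base,
                const imat& tipState, const imat& edge, const vec& tvec,
                const vec& rate, const std::vector<Eigsys>& eigs,
                const imat& eidx,
                const std::vector<std::vector<mat> >& basePart,
                const std::vector<std::vector<rowvec> >& baseScal,
                std::vector<mat>& part, std::vector<rowvec>& scal,
                int ntip, int nnode) {
  const int nedge = edge.n_rows;
  const int npat = tipState.n_cols;
  const int n = eigs[0].U.n_rows;

  // nodeEqual: whole subtree of the node uses the same eigen system as base
  std::vector<bool> nodeEqual(nnode, base >= 0);
  if (base >= 0) {
    for (int e = 0; e < nedge; ++e) {
      int pa = edge(e, 0), ch = edge(e, 1);
      bool eq = (eidx(e, c) == eidx(e, base)) && nodeEqual[ch];
      nodeEqual[pa] = nodeEqual[pa] && eq;
    }
  }
  std::vector<bool> ready(nnode, false);
  for (int e = 0; e < nedge; ++e) {
    int pa = edge(e, 0), ch = edge(e, 1);
    if (base >= 0 && nodeEqual[pa]) continue; // parent will be copied
    if (!ready[pa]) {
      part[pa] = mat(n, npat, fill::ones);
      scal[pa] = rowvec(npat, fill::zeros);
      ready[pa] = true;
    }
    mat P = pmat(eigs[eidx(e, c)], tvec(e) * rate(e));
    if (ch >= ntip && base >= 0 && nodeEqual[ch]) {
      part[pa] %= (P * basePart[base][ch]);
      scal[pa] += baseScal[base][ch];
    } else {
      part[pa] %= edgeContribution(P, ch, ntip, tipState, part);
      if (ch >= ntip) scal[pa] += scal[ch];
    }
    rowvec m = max(part[pa], 0);
    for (int p = 0; p < npat; ++p) {
      if (m(p) > 0.0 && (m(p) < 1e-100 || m(p) > 1e100)) {
        part[pa].col(p) /= m(p);
        scal[pa](p) += std::log(m(p));
      }
    }
  }
  // copy shared nodes from base (only those that are actually used later:
  // all of them, for simplicity)
  if (base >= 0) {
    for (int v = ntip; v < nnode; ++v) {
      if (nodeEqual[v]) {
        part[v] = basePart[base][v];
        scal[v] = baseScal[base][v];
      }
    }
  }
}

} // namespace

// Per-pattern, per-class log-likelihoods.
// tipState: ntip x npat, 0-based sense-codon states, -1 = missing
// edge: nedge x 2 (parent, child), 0-based node ids, postorder
// tvec, rate: per-edge branch length and rate multiplier
// eig: list of eigen systems (U, Uinv, lam) of unscaled generators
// eidx: nedge x nclass, 0-based index into eig per edge and class
// shareBase: per class, 0-based index of an earlier class with identical
//   background eigen systems (-1 = none); enables subtree reuse
// [[Rcpp::export]]
arma::mat codon_clik(const arma::imat& tipState, const arma::imat& edge,
                     const arma::vec& tvec, const arma::vec& rate,
                     const Rcpp::List& eig, const arma::imat& eidx,
                     const arma::ivec& shareBase, const arma::vec& pi,
                     int nnode, int root) {
  const int ntip = tipState.n_rows;
  const int npat = tipState.n_cols;
  const int nclass = eidx.n_cols;
  std::vector<Eigsys> eigs = parseEig(eig);

  std::vector<bool> isBase(nclass, false);
  for (int c = 0; c < nclass; ++c)
    if (shareBase(c) >= 0) isBase[shareBase(c)] = true;

  mat out(npat, nclass);
  std::vector<std::vector<mat> > keepPart(nclass);
  std::vector<std::vector<rowvec> > keepScal(nclass);

  for (int c = 0; c < nclass; ++c) {
    std::vector<mat> part(nnode);
    std::vector<rowvec> scal(nnode);
    pruneClass(c, shareBase(c), tipState, edge, tvec, rate, eigs, eidx,
               keepPart, keepScal, part, scal, ntip, nnode);
    rowvec lik = pi.t() * part[root];
    for (int p = 0; p < npat; ++p)
      out(p, c) = (lik(p) > 0.0 ? std::log(lik(p)) + scal[root](p)
                                : -datum::inf);
    if (isBase[c]) {
      keepPart[c] = std::move(part);
      keepScal[c] = std::move(scal);
    }
  }
  return out;
}

namespace {

// mixture log-likelihood of one edge as a function of its length, in the
// eigenbasis: per class, L_c(pat; t) = sum_k coef_c(k,pat) exp(lam_k r t)
struct EdgeObjective {
  std::vector<mat> coef;      // per class: n x npat
  std::vector<rowvec> lscal;  // per class: accumulated log scalers
  std::vector<vec> lam;       // per class
  vec logp;                   // class log proportions
  const vec* w;               // pattern weights
  double rate;

  double eval(double t) const {
    const int nclass = coef.size();
    const int npat = coef[0].n_cols;
    mat g(npat, nclass);
    for (int c = 0; c < nclass; ++c) {
      vec ex = exp(lam[c] * (rate * t));
      rowvec gc = ex.t() * coef[c];
      for (int p = 0; p < npat; ++p)
        g(p, c) = std::max(gc(p), 1e-300);
    }
    double total = 0.0;
    for (int p = 0; p < npat; ++p) {
      double M = -datum::inf;
      for (int c = 0; c < nclass; ++c) {
        double a = logp(c) + lscal[c](p) + std::log(g(p, c));
        if (a > M) M = a;
      }
      double s = 0.0;
      for (int c = 0; c < nclass; ++c)
        s += std::exp(logp(c) + lscal[c](p) + std::log(g(p, c)) - M);
      total += (*w)(p) * (M + std::log(s));
    }
    return total;
  }
};

// bounded golden-section maximization on log(t)
double goldenMax(const EdgeObjective& obj, double lo, double hi,
                 double tol, double init) {
  const double gr = 0.3819660112501051;
  double a = std::log(lo), b = std::log(hi);
  // shrink around the current value first for speed
  double x0 = std::log(std::min(std::max(init, lo), hi));
  double la = std::max(a, x0 - 2.5), lb = std::min(b, x0 + 2.5);
  // widen if the maximum might sit at the boundary of the local window
  double f_la = obj.eval(std::exp(la)), f_lb = obj.eval(std::exp(lb));
  if (la > a && f_la >= f_lb) { la = a; f_la = obj.eval(std::exp(la)); }
  if (lb < b && f_lb > f_la) lb = b;
  a = la; b = lb;
  double x1 = a + gr * (b - a), x2 = b - gr * (b - a);
  double f1 = obj.eval(std::exp(x1)), f2 = obj.eval(std::exp(x2));
  while (b - a > tol) {
    if (f1 < f2) {
      a = x1; x1 = x2; f1 = f2;
      x2 = b - gr * (b - a); f2 = obj.eval(std::exp(x2));
    } else {
      b = x2; x2 = x1; f2 = f1;
      x1 = a + gr * (b - a); f1 = obj.eval(std::exp(x1));
    }
  }
  return std::exp((a + b) / 2.0);
}

} // namespace

// One or more sweeps of edge-wise branch-length optimization.
// Arguments as codon_clik, plus logp (class log proportions), w (pattern
// weights), bounds and sweep control. Returns the updated branch lengths;
// the caller recomputes the final likelihood via codon_clik.
// [[Rcpp::export]]
arma::vec codon_optblens(const arma::imat& tipState, const arma::imat& edge,
                         const arma::vec& tvec0, const arma::vec& rate,
                         const Rcpp::List& eig, const arma::imat& eidx,
                         const arma::vec& pi, const arma::vec& logp,
                         const arma::vec& w, int nnode, int root,
                         double minT, double maxT, int nsweeps,
                         double tol) {
  const int ntip = tipState.n_rows;
  const int nedge = edge.n_rows;
  const int npat = tipState.n_cols;
  const int nclass = eidx.n_cols;
  const int n = pi.n_elem;
  std::vector<Eigsys> eigs = parseEig(eig);
  vec tvec = tvec0;

  // children edge indices per node
  std::vector<std::vector<int> > childEdges(nnode);
  for (int e = 0; e < nedge; ++e) childEdges[edge(e, 0)].push_back(e);

  std::vector<std::vector<mat> > dummyP;
  std::vector<std::vector<rowvec> > dummyS;

  for (int sweep = 0; sweep < nsweeps; ++sweep) {
    // lower partials for every class with current lengths
    std::vector<std::vector<mat> > part(nclass);
    std::vector<std::vector<rowvec> > scal(nclass);
    for (int c = 0; c < nclass; ++c) {
      part[c].assign(nnode, mat());
      scal[c].assign(nnode, rowvec());
      pruneClass(c, -1, tipState, edge, tvec, rate, eigs, eidx,
                 dummyP, dummyS, part[c], scal[c], ntip, nnode);
    }
    // pre-order descent with upper partials
    std::vector<std::vector<mat> > upper(nclass,
        std::vector<mat>(nnode));
    std::vector<std::vector<rowvec> > uscal(nclass,
        std::vector<rowvec>(nnode));
    for (int c = 0; c < nclass; ++c) {
      upper[c][root] = repmat(pi, 1, npat);
      uscal[c][root] = rowvec(npat, fill::zeros);
    }
    std::vector<int> stack;
    stack.push_back(root);
    while (!stack.empty()) {
      int u = stack.back();
      stack.pop_back();
      const std::vector<int>& ce = childEdges[u];
      const int d = ce.size();
      if (d == 0) continue;
      // current child contributions K (per class, per child)
      std::vector<std::vector<mat> > K(nclass, std::vector<mat>(d));
      for (int c = 0; c < nclass; ++c)
        for (int i = 0; i < d; ++i) {
          mat P = pmat(eigs[eidx(ce[i], c)], tvec(ce[i]) * rate(ce[i]));
          K[c][i] = edgeContribution(P, edge(ce[i], 1), ntip, tipState,
                                     part[c]);
        }
      for (int i = 0; i < d; ++i) {
        int e = ce[i], ch = edge(e, 1);
        // A = upper x product of sibling contributions, per class
        std::vector<mat> A(nclass);
        std::vector<rowvec> asc(nclass);
        for (int c = 0; c < nclass; ++c) {
          A[c] = upper[c][u];
          asc[c] = uscal[c][u];
          for (int j = 0; j < d; ++j) {
            if (j == i) continue;
            A[c] %= K[c][j];
            int sib = edge(ce[j], 1);
            if (sib >= ntip) asc[c] += scal[c][sib];
          }
          rowvec m = max(A[c], 0);
          for (int p = 0; p < npat; ++p)
            if (m(p) > 0.0 && (m(p) < 1e-100 || m(p) > 1e100)) {
              A[c].col(p) /= m(p);
              asc[c](p) += std::log(m(p));
            }
        }
        // objective in the eigenbasis
        EdgeObjective obj;
        obj.coef.resize(nclass);
        obj.lscal.resize(nclass);
        obj.lam.resize(nclass);
        obj.logp = logp;
        obj.w = &w;
        obj.rate = rate(e);
        for (int c = 0; c < nclass; ++c) {
          const Eigsys& E = eigs[eidx(e, c)];
          mat bvec;
          if (ch < ntip) {
            bvec.set_size(n, npat);
            for (int p = 0; p < npat; ++p) {
              int s = tipState(ch, p);
              if (s < 0) bvec.col(p) = sum(E.Uinv, 1);
              else bvec.col(p) = E.Uinv.col(s);
            }
          } else {
            bvec = E.Uinv * part[c][ch];
          }
          obj.coef[c] = (E.Ut * A[c]) % bvec;
          obj.lscal[c] = asc[c];
          if (ch >= ntip) obj.lscal[c] += scal[c][ch];
          obj.lam[c] = E.lam;
        }
        tvec(e) = goldenMax(obj, minT, maxT, tol, tvec(e));
        // refresh this child's contribution and push uppers down
        for (int c = 0; c < nclass; ++c) {
          mat P = pmat(eigs[eidx(e, c)], tvec(e) * rate(e));
          K[c][i] = edgeContribution(P, ch, ntip, tipState, part[c]);
          if (ch >= ntip) {
            upper[c][ch] = P.t() * A[c];
            uscal[c][ch] = asc[c];
            rowvec m = max(upper[c][ch], 0);
            for (int p = 0; p < npat; ++p)
              if (m(p) > 0.0 && (m(p) < 1e-100 || m(p) > 1e100)) {
                upper[c][ch].col(p) /= m(p);
                uscal[c][ch](p) += std::log(m(p));
              }
          }
        }
        if (ch >= ntip) stack.push_back(ch);
      }
    }
  }
  return tvec;
}
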