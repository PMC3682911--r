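#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Felsenstein pruning for one data partition under GTR+Gamma.
//
// The tree arrives as a postorder edge list (ape convention, 1-based node
// ids: tips are 1..ntip, internal nodes ntip+1..). Edges must be ordered so
// that every child's subtree is complete before the edge to its parent is
// processed; the root may be multifurcating (unrooted trees are passed with
// a basal trifurcation).
//
// Transition probabilities are built from the eigensystem of the normalized
// rate matrix: P(t) = V diag(exp(lambda * r * t)) Vinv, one set per edge and
// per rate category. Tip states are coded 0..3 (A,C,G,T); 4 means fully
// missing (partial likelihood of ones), which is how gaps, '?' and 'N' in a
// sparse supermatrix are treated.
//
// Numerical underflow is handled by per-node rescaling with log accumulation
// so that thousands of taxa remain feasible.

static inline void edge_pmat(const double* V, const double* Vinv,
                             const double* lambda, double rt, double* P) {
  double e[4];
  for (int i = 0; i < 4; ++i) e[i] = std::exp(lambda[i] * rt);
  for (int i = 0; i < 4; ++i) {
    for (int j = 0; j < 4; ++j) {
      double s = 0.0;
      for (int m = 0; m < 4; ++m) s += V[i + 4 * m] * e[m] * Vinv[m + 4 * j];
      // floor eigen round-off; keeps P strictly positive for t > 0 so the
      // likelihood of any pattern never collapses to exactly zero
      P[i + 4 * j] = s > 1e-300 ? s : 1e-300;
    }
  }
}

// [[Rcpp::export(name = ".cpp_pruning_lnl")]]
List cpp_pruning_lnl(IntegerMatrix edge, NumericVector brlen, int ntip,
                     int nnode_total, IntegerMatrix tipstate,
                     NumericVector weights, NumericVector pi, NumericMatrix V,
                     NumericMatrix Vinv, NumericVector lambda,
                     NumericVector rates) {
  const int nedge = edge.nrow();
  const int npat = tipstate.ncol();
  const int ncat = rates.size();
  const int root = edge(nedge - 1, 0) - 1; // parent of last postorder edge

  std::vector<double> part((size_t)nnode_total * npat * 4);
  std::vector<double> logscale((size_t)nnode_total * npat);
  std::vector<char> seen(nnode_total);
  std::vector<double> P(16);
  // accumulate mixture in likelihood space with a shared per-pattern log offset
  std::vector<double> cat_lnl((size_t)ncat * npat);

  const double* Vp = V.begin();
  const double* Vip = Vinv.begin();
  const double* lam = lambda.begin();

  for (int c = 0; c < ncat; ++c) {
    std::fill(seen.begin(), seen.end(), 0);
    for (int e = 0; e < nedge; ++e) {
      int p = edge(e, 0) - 1, ch = edge(e, 1) - 1;
      edge_pmat(Vp, Vip, lam, rates[c] * brlen[e], &P[0]);
      double* pp = &part[((size_t)p) * npat * 4];
      double* ps = &logscale[((size_t)p) * npat];
      if (!seen[p]) {
        std::fill(pp, pp + (size_t)npat * 4, 1.0);
        std::fill(ps, ps + npat, 0.0);
        seen[p] = 1;
      }
      if (ch < ntip) { // tip child: partial implicit from state
        for (int s = 0; s < npat; ++s) {
          int st = tipstate(ch, s);
          if (st < 4) {
            for (int i = 0; i < 4; ++i) pp[s * 4 + i] *= P[i + 4 * st];
          } // missing: row sums are 1, multiply by 1 -> no-op
        }
      } else {
        const double* cp = &part[((size_t)ch) * npat * 4];
        const double* cs = &logscale[((size_t)ch) * npat];
        for (int s = 0; s < npat; ++s) {
          double mx = 0.0;
          for (int i = 0; i < 4; ++i) {
            double v = P[i + 0] * cp[s * 4 + 0] + P[i + 4] * cp[s * 4 + 1] +
                       P[i + 8] * cp[s * 4 + 2] + P[i + 12] * cp[s * 4 + 3];
            v *= pp[s * 4 + i];
            pp[s * 4 + i] = v;
            if (v > mx) mx = v;
          }
          ps[s] += cs[s];
          if (mx < 1e-200 && mx > 0.0) {
            for (int i = 0; i < 4; ++i) pp[s * 4 + i] /= mx;
            ps[s] += std::log(mx);
          }
        }
      }
    }
    const double* rp = &part[((size_t)root) * npat * 4];
    const double* rs = &logscale[((size_t)root) * npat];
    for (int s = 0; s < npat; ++s) {
      double lik = pi[0] * rp[s * 4 + 0] + pi[1] * rp[s * 4 + 1] +
                   pi[2] * rp[s * 4 + 2] + pi[3] * rp[s * 4 + 3];
      cat_lnl[(size_t)c * npat + s] =
          (lik > 0.0 ? std::log(lik) : -1e308) + rs[s];
    }
  }

  NumericVector site_lnl(npat);
  double total = 0.0;
  for (int s = 0; s < npat; ++s) {
    double mx = -1e308;
    for (int c = 0; c < ncat; ++c)
      if (cat_lnl[(size_t)c * npat + s] > mx) mx = cat_lnl[(size_t)c * npat + s];
    double acc = 0.0;
    for (int c = 0; c < ncat; ++c)
      acc += std::exp(cat_lnl[(size_t)c * npat + s] - mx);
    site_lnl[s] = mx + std::log(acc / ncat);
    total += weights[s] * site_lnl[s];
  }
  return List::create(_["lnL"] = total, _["site_lnl"] = site_lnl);
}

// Fitch parsimony length for unordered 4-state characters with missing data
// treated as wildcards. Tip states arrive as bitmasks (A=1, C=2, G=4, T=8,
// missing=15). Multifurcations are folded in sequentially, which for the
// basal trifurcation of an unrooted binary tree gives the exact length.

// [[Rcpp::export(name = ".cpp_fitch")]]
List cpp_fitch(IntegerMatrix edge, int ntip, int nnode_total,
               IntegerMatrix tipmask, NumericVector weights) {
  const int nedge = edge.nrow();
  const int npat = tipmask.ncol();
  std::vector<int> state((size_t)nnode_total * npat);
  std::vector<int> score((size_t)nnode_total * npat, 0);
  std::vector<char> seen(nnode_total, 0);

  for (int e = 0; e < nedge; ++e) {
    int p = edge(e, 0) - 1, ch = edge(e, 1) - 1;
    int* psV = &state[(size_t)p * npat];
    int* psc = &score[(size_t)p * npat];
    for (int s = 0; s < npat; ++s) {
      int cmask, csc;
      if (ch < ntip) {
        cmask = tipmask(ch, s);
        csc = 0;
      } else {
        cmask = state[(size_t)ch * npat + s];
        csc = score[(size_t)ch * npat + s];
      }
      if (!seen[p]) {
        psV[s] = cmask;
        psc[s] = csc;
      } else {
        int inter = psV[s] & cmask;
        if (inter) {
          psV[s] = inter;
          psc[s] += csc;
        } else {
          psV[s] |= cmask;
          psc[s] += csc + 1;
        }
      }
    }
    if (!seen[p]) seen[p] = 1;
  }
  int root = edge(nedge - 1, 0) - 1;
  double total = 0.0;
  IntegerVector per(npat);
  for (int s = 0; s < npat; ++s) {
    per[s] = score[(size_t)root * npat + s];
    total += weights[s] * per[s];
  }
  return List::create(_["score"] = total, _["site_scores"] = per);
}

// Profile of the likelihood along one edge: with every other branch fixed,
// the tree likelihood as a function of the target edge's length t is
//   L_pat(t) = sum_ij G_i P(t)_ij F_j
// per rate category, where F is the pruning partial of the child's subtree
// and G collects the rest of the tree (including the stationary
// frequencies), computed by walking from the root down to the edge's parent
// while folding in the sibling subtrees. Branch-length optimization then
// costs one pruning pass per edge instead of one per function evaluation.

// [[Rcpp::export(name = ".cpp_edge_profile")]]
List cpp_edge_profile(IntegerMatrix edge, NumericVector brlen, int ntip,
                      int nnode_total, IntegerMatrix tipstate,
                      NumericVector pi, NumericMatrix V, NumericMatrix Vinv,
                      NumericVector lambda, NumericVector rates, int target) {
  const int nedge = edge.nrow();
  const int npat = tipstate.ncol();
  const int ncat = rates.size();
  const int root = edge(nedge - 1, 0) - 1;
  const int t_pa = edge(target - 1, 0) - 1;
  const int t_ch = edge(target - 1, 1) - 1;

  const double* Vp = V.begin();
  const double* Vip = Vinv.begin();
  const double* lam = lambda.begin();

  NumericVector Fout((size_t)ncat * npat * 4);
  NumericVector Gout((size_t)ncat * npat * 4);
  NumericVector Sout((size_t)ncat * npat);

  std::vector<double> part((size_t)nnode_total * npat * 4);
  std::vector<double> logscale((size_t)nnode_total * npat);
  std::vector<char> seen(nnode_total);
  std::vector<double> P(16);
  std::vector<int> parent(nnode_total, -1), parent_edge(nnode_total, -1);
  for (int e = 0; e < nedge; ++e) {
    parent[edge(e, 1) - 1] = edge(e, 0) - 1;
    parent_edge[edge(e, 1) - 1] = e;
  }

  for (int c = 0; c < ncat; ++c) {
    // ---- up-pass (identical to the pruning kernel) ----
    std::fill(seen.begin(), seen.end(), 0);
    for (int e = 0; e < nedge; ++e) {
      int p = edge(e, 0) - 1, ch = edge(e, 1) - 1;
      edge_pmat(Vp, Vip, lam, rates[c] * brlen[e], &P[0]);
      double* pp = &part[((size_t)p) * npat * 4];
      double* ps = &logscale[((size_t)p) * npat];
      if (!seen[p]) {
        std::fill(pp, pp + (size_t)npat * 4, 1.0);
        std::fill(ps, ps + npat, 0.0);
        seen[p] = 1;
      }
      if (ch < ntip) {
        for (int s = 0; s < npat; ++s) {
          int st = tipstate(ch, s);
          if (st < 4) {
            for (int i = 0; i < 4; ++i) pp[s * 4 + i] *= P[i + 4 * st];
          }
        }
      } else {
        const double* cp = &part[((size_t)ch) * npat * 4];
        const double* cs = &logscale[((size_t)ch) * npat];
        for (int s = 0; s < npat; ++s) {
          double mx = 0.0;
          for (int i = 0; i < 4; ++i) {
            double v = P[i + 0] * cp[s * 4 + 0] + P[i + 4] * cp[s * 4 + 1] +
                       P[i + 8] * cp[s * 4 + 2] + P[i + 12] * cp[s * 4 + 3];
            v *= pp[s * 4 + i];
            pp[s * 4 + i] = v;
            if (v > mx) mx = v;
          }
          ps[s] += cs[s];
          if (mx < 1e-200 && mx > 0.0) {
            for (int i = 0; i < 4; ++i) pp[s * 4 + i] /= mx;
            ps[s] += std::log(mx);
          }
        }
      }
    }

    // ---- F: the child's subtree partial ----
    double* F = &Fout[(size_t)c * npat * 4];
    double* S = &Sout[(size_t)c * npat];
    if (t_ch < ntip) {
      for (int s = 0; s < npat; ++s) {
        int st = tipstate(t_ch, s);
        for (int i = 0; i < 4; ++i)
          F[s * 4 + i] = (st >= 4 || st == i) ? 1.0 : 0.0;
        // S accumulates below from G's walk only
      }
    } else {
      const double* cp = &part[((size_t)t_ch) * npat * 4];
      const double* cs = &logscale[((size_t)t_ch) * npat];
      for (int s = 0; s < npat; ++s) {
        for (int i = 0; i < 4; ++i) F[s * 4 + i] = cp[s * 4 + i];
        S[s] += cs[s];
      }
    }

    // ---- G: walk root -> parent of the target edge ----
    std::vector<int> path; // nodes from root down to t_pa
    for (int nd = t_pa; nd != -1; nd = parent[nd]) path.push_back(nd);
    std::reverse(path.begin(), path.end()); // path[0] == root
    std::vector<double> G((size_t)npat * 4);
    for (int s = 0; s < npat; ++s)
      for (int i = 0; i < 4; ++i) G[s * 4 + i] = pi[i];
    for (size_t step = 0; step < path.size(); ++step) {
      int nd = path[step];
      int next = (step + 1 < path.size()) ? path[step + 1] : -1;
      // fold in every child subtree of nd except the path continuation and
      // (at the end) the target child
      for (int e = 0; e < nedge; ++e) {
        if (edge(e, 0) - 1 != nd) continue;
        int ch = edge(e, 1) - 1;
        if (ch == next) continue;
        if (nd == t_pa && ch == t_ch) continue;
        edge_pmat(Vp, Vip, lam, rates[c] * brlen[e], &P[0]);
        if (ch < ntip) {
          for (int s = 0; s < npat; ++s) {
            int st = tipstate(ch, s);
            if (st < 4) {
              for (int i = 0; i < 4; ++i) G[s * 4 + i] *= P[i + 4 * st];
            }
          }
        } else {
          const double* cp = &part[((size_t)ch) * npat * 4];
          const double* cs = &logscale[((size_t)ch) * npat];
          for (int s = 0; s < npat; ++s) {
            for (int i = 0; i < 4; ++i) {
              double v = P[i + 0] * cp[s * 4 + 0] + P[i + 4] * cp[s * 4 + 1] +
                         P[i + 8] * cp[s * 4 + 2] + P[i + 12] * cp[s * 4 + 3];
              G[s * 4 + i] *= v;
            }
            S[s] += cs[s];
          }
        }
      }
      if (next != -1) { // move through the edge nd -> next: G <- P^T G
        int e = parent_edge[next];
        edge_pmat(Vp, Vip, lam, rates[c] * brlen[e], &P[0]);
        for (int s = 0; s < npat; ++s) {
          double g0[4];
          for (int j = 0; j < 4; ++j) {
            g0[j] = P[0 + 4 * j] * G[s * 4 + 0] + P[1 + 4 * j] * G[s * 4 + 1] +
                    P[2 + 4 * j] * G[s * 4 + 2] + P[3 + 4 * j] * G[s * 4 + 3];
          }
          double mx = 0.0;
          for (int j = 0; j < 4; ++j) {
            G[s * 4 + j] = g0[j];
            if (g0[j] > mx) mx = g0[j];
          }
          if (mx < 1e-200 && mx > 0.0) {
            for (int j = 0; j < 4; ++j) G[s * 4 + j] /= mx;
            S[s] += std::log(mx);
          }
        }
      }
    }
    double* Gc = &Gout[(size_t)c * npat * 4];
    for (int s = 0; s < npat * 4; ++s) Gc[s] = G[s];
  }
  Fout.attr("dim") = IntegerVector::create(4, npat, ncat);
  Gout.attr("dim") = IntegerVector::create(4, npat, ncat);
  Sout.attr("dim") = IntegerVector::create(npat, ncat);
  return List::create(_["F"] = Fout, _["G"] = Gout, _["scale"] = Sout);
}

// Evaluate one partition's edge profile at branch length t.
// [[Rcpp::export(name = ".cpp_profile_lnl")]]
double cpp_profile_lnl(NumericVector F, NumericVector G, NumericVector S,
                       NumericVector weights, NumericMatrix V,
                       NumericMatrix Vinv, NumericVector lambda,
                       NumericVector rates, double t) {
  IntegerVector dim = F.attr("dim");
  const int npat = dim[1];
  const int ncat = dim[2];
  std::vector<double> P(16);
  std::vector<double> cl((size_t)ncat * npat);
  for (int c = 0; c < ncat; ++c) {
    edge_pmat(V.begin(), Vinv.begin(), lambda.begin(), rates[c] * t, &P[0]);
    const double* Fc = &F[(size_t)c * npat * 4];
    const double* Gc = &G[(size_t)c * npat * 4];
    const double* Sc = &S[(size_t)c * npat];
    for (int s = 0; s < npat; ++s) {
      double lik = 0.0;
      for (int i = 0; i < 4; ++i) {
        double pf = P[i + 0] * Fc[s * 4 + 0] + P[i + 4] * Fc[s * 4 + 1] +
                    P[i + 8] * Fc[s * 4 + 2] + P[i + 12] * Fc[s * 4 + 3];
        lik += Gc[s * 4 + i] * pf;
      }
      cl[(size_t)c * npat + s] = (lik > 0.0 ? std::log(lik) : -1e308) + Sc[s];
    }
  }
  double total = 0.0;
  for (int s = 0; s < npat; ++s) {
    double mx = -1e308;
    for (int c = 0; c < ncat; ++c)
      if (cl[(size_t)c * npat + s] > mx) mx = cl[(size_t)c * npat + s];
    double acc = 0.0;
    for (int c = 0; c < ncat; ++c)
      acc += std::exp(cl[(size_t)c * npat + s] - mx);
    total += weights[s] * (mx + std::log(acc / ncat));
  }
  return total;
}
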