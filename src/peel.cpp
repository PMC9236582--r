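// Core likelihood kernels: Felsenstein pruning over site patterns with
// per-node scaling, the outer (up) pass, and the coordinate branch-length
// sweep with safeguarded Newton steps in log branch length.
//
// Conventions: node ids are 0-based; tips are 0..ntip-1; the edge matrix is
// in postorder (children before parents); the tree is rooted at an arbitrary
// internal node (virtual root; the model is reversible).  All likelihood
// work is done per gamma category on S x p partial matrices (S states, p
// patterns), with per-pattern log scalers accumulated to avoid underflow.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double TINY = 1e-300;

struct ModelCtx {
  arma::mat L;     // diag(1/sqrt(pi)) U
  arma::mat R;     // t(U) diag(sqrt(pi))
  arma::vec ev;    // eigenvalues of the symmetrized rate matrix
  arma::vec freq;  // stationary frequencies
  arma::vec rates; // gamma category rates
};

static ModelCtx make_ctx(const List& model) {
  ModelCtx M;
  M.L = as<arma::mat>(model["eig_left"]);
  M.R = as<arma::mat>(model["eig_rightT"]);
  M.ev = as<arma::vec>(model["eig_values"]);
  M.freq = as<arma::vec>(model["freq"]);
  M.rates = as<arma::vec>(model["rates"]);
  return M;
}

static arma::mat pmat(const ModelCtx& M, double tr) {
  arma::mat Re = M.R;
  Re.each_col() %= arma::exp(M.ev * tr);
  arma::mat P = M.L * Re;
  P.transform([](double x) { return x < 0 ? 0 : x; });
  return P;
}

struct Peel {
  // per category: down partial and log-scaler per node
  std::vector<std::vector<arma::mat>> down;
  std::vector<std::vector<arma::rowvec>> dlog;
  arma::mat catlogs; // k x p per-category per-pattern log-likelihood
};

// tipp: list of S x p tip partial matrices, one per alignment taxon;
// tipidx[node] maps tree tip node -> taxon index (0-based).
static Peel peel_all(const arma::imat& E, const arma::vec& len, int ntip,
                     int nn, int root, const arma::ivec& tipidx,
                     const std::vector<arma::mat>& tipp, const ModelCtx& M,
                     bool keep) {
  const int k = M.rates.n_elem;
  const int p = tipp[0].n_cols;
  const int S = tipp[0].n_rows;
  Peel out;
  out.catlogs.set_size(k, p);
  out.down.resize(k);
  out.dlog.resize(k);
  for (int ci = 0; ci < k; ++ci) {
    std::vector<arma::mat> down(nn);
    std::vector<arma::rowvec> dlog(nn);
    std::vector<bool> seen(nn, false);
    const double r = M.rates[ci];
    for (arma::uword ei = 0; ei < E.n_rows; ++ei) {
      const int par = E(ei, 0), ch = E(ei, 1);
      arma::mat P = pmat(M, len[ei] * r);
      const arma::mat& chd = (ch < ntip) ? tipp[tipidx[ch]] : down[ch];
      arma::mat T = P * chd;
      arma::rowvec s = arma::sum(T, 0);
      s.transform([](double x) { return x < TINY ? TINY : x; });
      T.each_row() /= s;
      arma::rowvec tl = arma::log(s);
      if (ch >= ntip) tl += dlog[ch];
      if (!seen[par]) {
        down[par] = T; dlog[par] = tl; seen[par] = true;
      } else {
        down[par] %= T; dlog[par] += tl;
      }
    }
    arma::rowvec rootvec = M.freq.t() * down[root];
    rootvec.transform([](double x) { return x < TINY ? TINY : x; });
    out.catlogs.row(ci) = arma::log(rootvec) + dlog[root];
    if (keep) {
      out.down[ci] = std::move(down);
      out.dlog[ci] = std::move(dlog);
    }
  }
  return out;
}

static arma::rowvec mix_categories(const arma::mat& catlogs) {
  arma::rowvec mx = arma::max(catlogs, 0);
  arma::rowvec acc(catlogs.n_cols, arma::fill::zeros);
  for (arma::uword ci = 0; ci < catlogs.n_rows; ++ci)
    acc += arma::exp(catlogs.row(ci) - mx);
  return mx + arma::log(acc / catlogs.n_rows);
}

// [[Rcpp::export(name = ".peel_catlogs_cpp")]]
List peel_catlogs_cpp(const arma::imat& E, const arma::vec& len, int ntip,
                      int nn, int root, const arma::ivec& tipidx,
                      const List& tipp_r, const List& model) {
  ModelCtx M = make_ctx(model);
  std::vector<arma::mat> tipp(tipp_r.size());
  for (int i = 0; i < tipp_r.size(); ++i) tipp[i] = as<arma::mat>(tipp_r[i]);
  Peel pe = peel_all(E, len, ntip, nn, root, tipidx, tipp, M, false);
  return List::create(_["catlogs"] = pe.catlogs,
                      _["pat_ll"] = mix_categories(pe.catlogs));
}

// Outer pass: U[node] = partial likelihood of everything outside the node's
// subtree, indexed by the state of its parent, frequencies folded in at the
// root; Ulog are the matching log scalers.
struct UpPass {
  std::vector<std::vector<arma::mat>> U;
  std::vector<std::vector<arma::rowvec>> Ulog;
};

static UpPass up_all(const arma::imat& E, const arma::vec& len, int ntip,
                     int nn, int root, const arma::ivec& tipidx,
                     const std::vector<arma::mat>& tipp, const ModelCtx& M,
                     const Peel& pe) {
  const int k = M.rates.n_elem;
  const int p = tipp[0].n_cols;
  const int S = tipp[0].n_rows;
  UpPass up;
  up.U.assign(k, std::vector<arma::mat>(nn));
  up.Ulog.assign(k, std::vector<arma::rowvec>(nn));
  // children edges per node
  std::vector<std::vector<int>> kids(nn);
  for (arma::uword ei = 0; ei < E.n_rows; ++ei)
    kids[E(ei, 0)].push_back(ei);
  for (int ci = 0; ci < k; ++ci) {
    const double r = M.rates[ci];
    std::vector<arma::mat> V(nn);
    std::vector<arma::rowvec> Vlog(nn);
    V[root] = arma::repmat(M.freq, 1, p);
    Vlog[root] = arma::rowvec(p, arma::fill::zeros);
    // per-edge transform cache for sibling products
    std::vector<arma::mat> T(E.n_rows);
    std::vector<arma::rowvec> Tl(E.n_rows);
    for (arma::uword ei = 0; ei < E.n_rows; ++ei) {
      const int ch = E(ei, 1);
      arma::mat P = pmat(M, len[ei] * r);
      const arma::mat& chd =
        (ch < ntip) ? tipp[tipidx[ch]] : pe.down[ci][ch];
      T[ei] = P * chd;
      arma::rowvec s = arma::sum(T[ei], 0);
      s.transform([](double x) { return x < TINY ? TINY : x; });
      T[ei].each_row() /= s;
      Tl[ei] = arma::log(s);
      if (ch >= ntip) Tl[ei] += pe.dlog[ci][ch];
    }
    for (int ei = E.n_rows - 1; ei >= 0; --ei) { // preorder
      const int par = E(ei, 0), ch = E(ei, 1);
      arma::mat acc = V[par];
      arma::rowvec alog = Vlog[par];
      for (int b : kids[par]) {
        if (b == ei) continue;
        acc %= T[b];
        alog += Tl[b];
      }
      arma::rowvec s = arma::sum(acc, 0);
      s.transform([](double x) { return x < TINY ? TINY : x; });
      acc.each_row() /= s;
      up.U[ci][ch] = acc;
      up.Ulog[ci][ch] = alog + arma::log(s);
      if (ch >= ntip) {
        arma::mat P = pmat(M, len[ei] * r);
        V[ch] = P.t() * up.U[ci][ch];
        Vlog[ch] = up.Ulog[ci][ch];
      }
    }
  }
  return up;
}

// Weighted total log-likelihood from per-category projected products:
// val_ci(t) = colsum(Upr_ci % exp(ev * rates_ci * t)); obj = sum w * mix.
struct EdgeObj {
  const std::vector<arma::mat>& Upr;
  const std::vector<arma::rowvec>& base;
  const ModelCtx& M;
  const arma::rowvec& w;
  int* evals;  // one-branch objective evaluations (not full passes)

  double obj(double t) const {
    ++*evals;
    const int k = M.rates.n_elem;
    arma::mat lf(k, base[0].n_cols);
    for (int ci = 0; ci < k; ++ci) {
      arma::vec e = arma::exp(M.ev * (t * M.rates[ci]));
      arma::rowvec val = e.t() * Upr[ci];
      val.transform([](double x) { return x < TINY ? TINY : x; });
      lf.row(ci) = arma::log(val) + base[ci];
    }
    return arma::dot(mix_categories(lf), w);
  }

  // objective with first and second derivative w.r.t. t
  arma::vec3 objd(double t) const {
    ++*evals;
    const int k = M.rates.n_elem;
    const int p = base[0].n_cols;
    arma::mat lf(k, p), g(k, p), h(k, p);
    for (int ci = 0; ci < k; ++ci) {
      arma::vec er = M.ev * M.rates[ci];
      arma::vec e = arma::exp(er * t);
      arma::rowvec val = e.t() * Upr[ci];
      arma::rowvec d1 = (er % e).t() * Upr[ci];
      arma::rowvec d2 = (er % er % e).t() * Upr[ci];
      val.transform([](double x) { return x < TINY ? TINY : x; });
      lf.row(ci) = arma::log(val) + base[ci];
      g.row(ci) = d1 / val;
      h.row(ci) = d2 / val;
    }
    arma::rowvec mx = arma::max(lf, 0);
    arma::rowvec tot(p, arma::fill::zeros);
    arma::rowvec pg(p, arma::fill::zeros), ph(p, arma::fill::zeros);
    arma::mat pw(k, p);
    for (int ci = 0; ci < k; ++ci) {
      arma::rowvec pc = arma::exp(lf.row(ci) - mx);
      tot += pc;
      pw.row(ci) = pc;
    }
    for (int ci = 0; ci < k; ++ci) {
      arma::rowvec wc = pw.row(ci) / tot;
      pg += wc % g.row(ci);
      ph += wc % h.row(ci);
    }
    arma::vec3 out;
    out[0] = arma::dot(mx + arma::log(tot / k), w);
    out[1] = arma::dot(pg, w);
    out[2] = arma::dot(ph - pg % pg, w);
    return out;
  }
};

// golden-section fallback (bounded, maximizing)
static double golden_max(const EdgeObj& eo, double lo, double hi,
                         double tol = 1e-5) {
  const double gr = 0.618033988749895;
  double a = lo, b = hi;
  double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
  double f1 = eo.obj(x1), f2 = eo.obj(x2);
  while (b - a > tol) {
    if (f1 < f2) {
      a = x1; x1 = x2; f1 = f2;
      x2 = a + gr * (b - a); f2 = eo.obj(x2);
    } else {
      b = x2; x2 = x1; f2 = f1;
      x1 = b - gr * (b - a); f1 = eo.obj(x1);
    }
  }
  return (a + b) / 2;
}

// Newton in log(t), safeguarded; returns the new length (or t0).
static double optimize_edge(const EdgeObj& eo, double t0, double lo,
                            double hi) {
  const double f0 = eo.obj(t0);
  double t = std::max(t0, lo * 2);
  bool ok = false;
  for (int it = 0; it < 20; ++it) {
    arma::vec3 d = eo.objd(t);
    double u = std::log(t);
    double du1 = d[1] * t;
    double du2 = d[2] * t * t + du1;
    if (!std::isfinite(du1) || !std::isfinite(du2) || du2 >= 0) break;
    double step = std::min(std::max(-du1 / du2, -2.0), 2.0);
    double un = std::min(std::max(u + step, std::log(lo)), std::log(hi));
    if (std::fabs(un - u) < 1e-7) { ok = true; t = std::exp(un); break; }
    t = std::exp(un);
    if (std::fabs(step) < 1e-5) { ok = true; break; }
  }
  if (!ok) {
    double blo = std::max(lo, t0 / 8), bhi = std::min(hi, std::max(t0 * 8, 0.05));
    for (int round = 0; round < 6; ++round) {
      double tb = golden_max(eo, blo, bhi);
      bool at_lo = (tb - blo < 2e-5) && blo > lo;
      bool at_hi = (bhi - tb < 2e-5) && bhi < hi;
      if (at_lo) { blo = std::max(lo, blo / 8); continue; }
      if (at_hi) { bhi = std::min(hi, bhi * 8); continue; }
      t = tb;
      break;
    }
  }
  return (eo.obj(t) > f0) ? t : t0;
}

// One interleaved sweep: optimize every edge in postorder, rebuilding the
// down partials with the new lengths as the sweep proceeds; the up pass is
// from the start of the sweep.
static arma::vec sweep_edges(const arma::imat& E, arma::vec len, int ntip,
                             int nn, const arma::ivec& tipidx,
                             const std::vector<arma::mat>& tipp,
                             const ModelCtx& M, const UpPass& up,
                             const arma::rowvec& w, double lo, double hi,
                             int* evals) {
  const int k = M.rates.n_elem;
  const int p = tipp[0].n_cols;
  std::vector<std::vector<arma::mat>> down(k, std::vector<arma::mat>(nn));
  std::vector<std::vector<arma::rowvec>> dlog(
      k, std::vector<arma::rowvec>(nn));
  std::vector<bool> seen(nn, false);
  const arma::rowvec zero(p, arma::fill::zeros);
  for (arma::uword ei = 0; ei < E.n_rows; ++ei) {
    const int par = E(ei, 0), ch = E(ei, 1);
    std::vector<arma::mat> Dp(k), Upr(k);
    std::vector<arma::rowvec> base(k);
    for (int ci = 0; ci < k; ++ci) {
      const arma::mat& dch =
        (ch < ntip) ? tipp[tipidx[ch]] : down[ci][ch];
      const arma::rowvec& dl = (ch < ntip) ? zero : dlog[ci][ch];
      Dp[ci] = M.R * dch;
      Upr[ci] = (M.L.t() * up.U[ci][ch]) % Dp[ci];
      base[ci] = up.Ulog[ci][ch] + dl;
    }
    EdgeObj eo{Upr, base, M, w, evals};
    len[ei] = optimize_edge(eo, len[ei], lo, hi);
    for (int ci = 0; ci < k; ++ci) {
      const arma::rowvec& dl = (ch < ntip) ? zero : dlog[ci][ch];
      arma::mat De = Dp[ci];
      De.each_col() %= arma::exp(M.ev * (len[ei] * M.rates[ci]));
      arma::mat T = M.L * De;
      T.transform([](double x) { return x < 0 ? 0 : x; });
      arma::rowvec s = arma::sum(T, 0);
      s.transform([](double x) { return x < TINY ? TINY : x; });
      T.each_row() /= s;
      arma::rowvec tl = arma::log(s) + dl;
      if (!seen[par] || down[ci][par].n_elem == 0) {
        down[ci][par] = T; dlog[ci][par] = tl;
      } else {
        down[ci][par] %= T; dlog[ci][par] += tl;
      }
    }
    seen[par] = true;
  }
  return len;
}

static double total_ll(const arma::imat& E, const arma::vec& len, int ntip,
                       int nn, int root, const arma::ivec& tipidx,
                       const std::vector<arma::mat>& tipp, const ModelCtx& M,
                       const arma::rowvec& w) {
  Peel pe = peel_all(E, len, ntip, nn, root, tipidx, tipp, M, false);
  return arma::dot(mix_categories(pe.catlogs), w);
}

// [[Rcpp::export(name = ".optimize_edges_cpp")]]
List optimize_edges_cpp(const arma::imat& E, const arma::vec& len0, int ntip,
                        int nn, int root, const arma::ivec& tipidx,
                        const List& tipp_r, const List& model,
                        const arma::rowvec& pat_w, double tol,
                        int max_sweeps, double lo, double hi) {
  ModelCtx M = make_ctx(model);
  std::vector<arma::mat> tipp(tipp_r.size());
  for (int i = 0; i < tipp_r.size(); ++i) tipp[i] = as<arma::mat>(tipp_r[i]);
  arma::vec len = len0;
  len.transform([lo](double x) { return x < lo ? lo : x; });
  int evals = 0;    // edge-objective evaluations
  int passes = 0;   // complete per-site likelihood passes over the data
  double ll_cur = total_ll(E, len, ntip, nn, root, tipidx, tipp, M, pat_w);
  ++passes;
  bool converged = false;
  int small_gain_run = 0;  // consecutive sweeps below tol; 2 confirm a fixed
                           // point (a single small sweep can precede further
                           // progress on zigzag ridges)
  for (int sw = 0; sw < max_sweeps; ++sw) {
    arma::vec saved = len;
    Peel pe = peel_all(E, len, ntip, nn, root, tipidx, tipp, M, true);
    UpPass up = up_all(E, len, ntip, nn, root, tipidx, tipp, M, pe);
    passes += 2;
    len = sweep_edges(E, len, ntip, nn, tipidx, tipp, M, up, pat_w, lo, hi,
                      &evals);
    double ll_new = total_ll(E, len, ntip, nn, root, tipidx, tipp, M, pat_w);
    ++passes;
    if (ll_new < ll_cur - 1e-9) {
      // interleaved sweep overshot: replay edge by edge with fresh passes
      len = saved;
      for (arma::uword ei = 0; ei < E.n_rows; ++ei) {
        Peel pe2 = peel_all(E, len, ntip, nn, root, tipidx, tipp, M, true);
        UpPass up2 = up_all(E, len, ntip, nn, root, tipidx, tipp, M, pe2);
        passes += 2;
        const int ch = E(ei, 1);
        std::vector<arma::mat> Dp(M.rates.n_elem), Upr(M.rates.n_elem);
        std::vector<arma::rowvec> base(M.rates.n_elem);
        const arma::rowvec zero(pat_w.n_elem, arma::fill::zeros);
        for (arma::uword ci = 0; ci < M.rates.n_elem; ++ci) {
          const arma::mat& dch =
            (ch < ntip) ? tipp[tipidx[ch]] : pe2.down[ci][ch];
          Dp[ci] = M.R * dch;
          Upr[ci] = (M.L.t() * up2.U[ci][ch]) % Dp[ci];
          base[ci] = up2.Ulog[ci][ch] +
            ((ch < ntip) ? zero : pe2.dlog[ci][ch]);
        }
        EdgeObj eo{Upr, base, M, pat_w, &evals};
        len[ei] = optimize_edge(eo, len[ei], lo, hi);
      }
      ll_new = total_ll(E, len, ntip, nn, root, tipidx, tipp, M, pat_w);
      ++passes;
      if (ll_new < ll_cur - 1e-9) { len = saved; ll_new = ll_cur; }
    }
    if (ll_new - ll_cur < tol) {
      ++small_gain_run;
      if (small_gain_run >= 2) {
        ll_cur = std::max(ll_new, ll_cur);
        converged = true;
        break;
      }
    } else {
      small_gain_run = 0;
    }
    ll_cur = std::max(ll_new, ll_cur);
  }
  return List::create(_["len"] = len, _["loglik"] = ll_cur,
                      _["converged"] = converged, _["n_passes"] = passes,
                      _["n_edge_evals"] = evals);
}
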