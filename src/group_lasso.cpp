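// Group-penalized logistic regression on genotype-backed designs.
//
// Every design block is a one-hot indicator matrix of a categorical
// variable: 3 levels for a single SNP, 9 levels for an (ordered) SNP pair.
// Consequently the within-group weighted Gram matrix is diagonal and the
// block update of the penalized weighted least-squares subproblem has an
// exact solution obtained from a one-dimensional root-find on the norm of
// the block coefficient vector.  No design matrix is ever materialized:
// the genotype matrix plus (a, b) group indices define the columns.
//
// Solver layout: proximal-Newton outer loop (IRLS quadratic + step-halving
// line search on the true penalized objective) with block coordinate
// descent on the quadratic, an active working set with full KKT sweeps for
// exactness, and cached per-group level vectors for the working set.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline double log1pexp_(double x) {
  return (x > 0 ? x : 0.0) + std::log1p(std::exp(-std::fabs(x)));
}

// Solve  min_b  0.5 * sum_k m_k b_k^2 - sum_k c_k b_k + lam * ||b||_2
// (diagonal quadratic + group penalty).  b = 0 iff ||c|| <= lam; otherwise
// b_k = c_k / (m_k + lam/t) with t = ||b|| solving
//   sum_k c_k^2 / (m_k + lam/t)^2 = t^2   (unique positive root).
static void group_prox_(const double* c, const double* m, int K,
                        double lam, double* b) {
  double cn2 = 0.0;
  for (int k = 0; k < K; ++k) cn2 += c[k] * c[k];
  const double cn = std::sqrt(cn2);
  if (!(cn > lam)) { std::fill(b, b + K, 0.0); return; }
  if (lam <= 0.0) {
    for (int k = 0; k < K; ++k) b[k] = (m[k] > 0.0) ? c[k] / m[k] : 0.0;
    return;
  }
  double hi = 0.0;
  for (int k = 0; k < K; ++k)
    if (m[k] > 0.0) hi += (c[k] / m[k]) * (c[k] / m[k]);
  hi = std::sqrt(hi) + 1e-12;
  double lo = 0.0;
  for (int it = 0; it < 120; ++it) {
    const double t = 0.5 * (lo + hi);
    double q = 0.0;
    for (int k = 0; k < K; ++k) {
      const double d = m[k] + lam / t;
      q += (c[k] / d) * (c[k] / d);
    }
    if (q > t * t) lo = t; else hi = t;
    if (hi - lo < 1e-15 * (1.0 + hi)) break;
  }
  const double t = 0.5 * (lo + hi);
  for (int k = 0; k < K; ++k) b[k] = c[k] / (m[k] + lam / t);
}

struct Problem {
  const int* G;                // column-major N_all x L genotype codes
  int nrowG;
  const double* y;             // full-length response (0/1)
  std::vector<int> rows;       // 0-based training rows
  const int* ga;               // 0-based SNP index per group
  const int* gb;               // 0-based SNP index or -1 (main)
  int J;
  std::vector<int> K;          // group sizes (3 or 9)
  std::vector<int> off;        // offsets into concatenated beta
  int P;
  const double* w;             // group weights (may be +Inf)
  double tol, ufloor, kkt_tol;
  int maxit_irls, maxit_cd, dfmax;
};

// level vector of group j over the training rows
static void fill_levels_(const Problem& pb, int j, std::vector<uint8_t>& z) {
  const size_t n = pb.rows.size();
  z.resize(n);
  const int* ca = pb.G + (size_t)pb.nrowG * pb.ga[j];
  if (pb.gb[j] < 0) {
    for (size_t r = 0; r < n; ++r) z[r] = (uint8_t)ca[pb.rows[r]];
  } else {
    const int* cb = pb.G + (size_t)pb.nrowG * pb.gb[j];
    for (size_t r = 0; r < n; ++r)
      z[r] = (uint8_t)(3 * ca[pb.rows[r]] + cb[pb.rows[r]]);
  }
}

static double loglik_(const Problem& pb, const std::vector<double>& eta) {
  double ll = 0.0;
  for (size_t r = 0; r < pb.rows.size(); ++r)
    ll += pb.y[pb.rows[r]] * eta[r] - log1pexp_(eta[r]);
  return ll;
}

// ||X_j' resid|| for every group; resid indexed like rows
static void all_grad_norms_(const Problem& pb,
                            const std::vector<double>& resid,
                            std::vector<double>& out) {
  const size_t n = pb.rows.size();
  out.resize(pb.J);
  for (int j = 0; j < pb.J; ++j) {
    double s[9] = {0, 0, 0, 0, 0, 0, 0, 0, 0};
    const int* ca = pb.G + (size_t)pb.nrowG * pb.ga[j];
    if (pb.gb[j] < 0) {
      for (size_t r = 0; r < n; ++r) s[ca[pb.rows[r]]] += resid[r];
    } else {
      const int* cb = pb.G + (size_t)pb.nrowG * pb.gb[j];
      for (size_t r = 0; r < n; ++r)
        s[3 * ca[pb.rows[r]] + cb[pb.rows[r]]] += resid[r];
    }
    double n2 = 0.0;
    for (int k = 0; k < pb.K[j]; ++k) n2 += s[k] * s[k];
    out[j] = std::sqrt(n2);
  }
}

struct FitResult {
  double objective;
  bool converged;
  bool truncated;   // active-set size exceeded dfmax; fit aborted
};

static FitResult fit_at_gamma_(const Problem& pb, double gamma,
                               double& b0, std::vector<double>& beta,
                               std::vector<double>& eta,
                               int& n_irls, int& n_cd) {
  const int J = pb.J;
  const size_t n = pb.rows.size();
  std::vector<double> lam(J);
  for (int j = 0; j < J; ++j) {
    const double l = gamma * pb.w[j] * std::sqrt((double)pb.K[j]);
    lam[j] = (l < 0 ? 0 : l);
  }

  std::vector<char> inws(J, 0);
  std::vector<int> ws;
  std::vector<std::vector<uint8_t> > zc;  // level cache, parallel to ws
  ws.reserve(256); zc.reserve(256);
  for (int j = 0; j < J; ++j) {
    double n2 = 0.0;
    for (int k = 0; k < pb.K[j]; ++k)
      n2 += beta[pb.off[j] + k] * beta[pb.off[j] + k];
    if (n2 > 0.0) {
      inws[j] = 1; ws.push_back(j);
      zc.push_back(std::vector<uint8_t>());
      fill_levels_(pb, j, zc.back());
    }
  }

  std::vector<double> p(n), u(n), e(n), resid(n), norms;
  double c[9], m[9], bnew[9];

  // penalty over the working set (all nonzero groups live there)
  auto ws_penalty = [&](const std::vector<double>& bvec) {
    double pen = 0.0;
    for (size_t q = 0; q < ws.size(); ++q) {
      const int j = ws[q];
      if (!R_finite(lam[j])) continue;
      double n2 = 0.0;
      for (int k = 0; k < pb.K[j]; ++k) {
        const double v = bvec[pb.off[j] + k];
        n2 += v * v;
      }
      if (n2 > 0.0) pen += lam[j] * std::sqrt(n2);
    }
    return pen;
  };

  FitResult fr = {0.0, false, false};
  bool clean = false;
  while (!clean) {
    for (int outer = 0; outer < pb.maxit_irls; ++outer) {
      ++n_irls;
      for (size_t r = 0; r < n; ++r) {
        const double pr = 1.0 / (1.0 + std::exp(-eta[r]));
        p[r] = pr;
        double ur = pr * (1.0 - pr);
        if (ur < pb.ufloor) ur = pb.ufloor;
        u[r] = ur;
        e[r] = (pb.y[pb.rows[r]] - pr) / ur;
      }
      const double f_old = -loglik_(pb, eta) + ws_penalty(beta);
      const double b0_old = b0;
      std::vector<double> beta_old_ws;
      beta_old_ws.reserve(ws.size() * 9);
      for (size_t q = 0; q < ws.size(); ++q)
        for (int k = 0; k < pb.K[ws[q]]; ++k)
          beta_old_ws.push_back(beta[pb.off[ws[q]] + k]);

      double usum = 0.0;
      for (size_t r = 0; r < n; ++r) usum += u[r];

      // CD on the quadratic: cycle over currently-nonzero groups, with a
      // full working-set pass whenever the cycle set stabilizes
      std::vector<char> cyc(ws.size(), 0);
      for (size_t q = 0; q < ws.size(); ++q) {
        const int j = ws[q];
        for (int k = 0; k < pb.K[j]; ++k)
          if (beta[pb.off[j] + k] != 0.0) { cyc[q] = 1; break; }
      }
      bool full_pass = true;  // first pass visits everything
      for (int pass = 0; pass < pb.maxit_cd; ++pass) {
        ++n_cd;
        double maxd = 0.0;
        bool zero_flip = false;
        {  // intercept
          double num = 0.0;
          for (size_t r = 0; r < n; ++r) num += u[r] * e[r];
          const double d0 = num / usum;
          b0 += d0;
          for (size_t r = 0; r < n; ++r) e[r] -= d0;
          if (std::fabs(d0) > maxd) maxd = std::fabs(d0);
        }
        for (size_t q = 0; q < ws.size(); ++q) {
          if (!full_pass && !cyc[q]) continue;
          const int j = ws[q], Kj = pb.K[j];
          if (!R_finite(lam[j])) continue;
          const uint8_t* z = zc[q].data();
          double* bj = &beta[pb.off[j]];
          for (int k = 0; k < Kj; ++k) { c[k] = 0.0; m[k] = 0.0; }
          for (size_t r = 0; r < n; ++r) {
            c[z[r]] += u[r] * e[r];
            m[z[r]] += u[r];
          }
          bool was_zero = true;
          for (int k = 0; k < Kj; ++k) {
            if (bj[k] != 0.0) was_zero = false;
            c[k] += m[k] * bj[k];
          }
          group_prox_(c, m, Kj, lam[j], bnew);
          bool changed = false, is_zero = true;
          for (int k = 0; k < Kj; ++k) {
            if (bnew[k] != 0.0) is_zero = false;
            const double dk = bnew[k] - bj[k];
            if (dk != 0.0) changed = true;
            if (std::fabs(dk) > maxd) maxd = std::fabs(dk);
          }
          if (changed) {
            for (size_t r = 0; r < n; ++r) e[r] -= (bnew[z[r]] - bj[z[r]]);
            for (int k = 0; k < Kj; ++k) bj[k] = bnew[k];
          }
          if (was_zero != is_zero) { cyc[q] = !is_zero; zero_flip = true; }
        }
        if (full_pass) {
          if (maxd < 0.1 * pb.tol && !zero_flip) break;
          full_pass = false;
        } else if (maxd < 0.1 * pb.tol) {
          full_pass = true;  // verify with a full pass before stopping
        }
      }

      // line search on the true objective along the Newton direction
      std::vector<double> deta(n);
      for (size_t r = 0; r < n; ++r) {
        const double z = eta[r] + (pb.y[pb.rows[r]] - p[r]) / u[r];
        deta[r] = (z - e[r]) - eta[r];
      }
      const double b0_new = b0;
      std::vector<double> beta_new_ws;
      beta_new_ws.reserve(beta_old_ws.size());
      for (size_t q = 0; q < ws.size(); ++q)
        for (int k = 0; k < pb.K[ws[q]]; ++k)
          beta_new_ws.push_back(beta[pb.off[ws[q]] + k]);

      double s = 1.0, maxchange = 0.0;
      bool accepted = false;
      for (int h = 0; h < 30; ++h) {
        size_t idx = 0;
        for (size_t q = 0; q < ws.size(); ++q)
          for (int k = 0; k < pb.K[ws[q]]; ++k, ++idx)
            beta[pb.off[ws[q]] + k] =
              beta_old_ws[idx] + s * (beta_new_ws[idx] - beta_old_ws[idx]);
        b0 = b0_old + s * (b0_new - b0_old);
        double ll = 0.0;
        for (size_t r = 0; r < n; ++r) {
          const double et = eta[r] + s * deta[r];
          ll += pb.y[pb.rows[r]] * et - log1pexp_(et);
        }
        const double f_try = -ll + ws_penalty(beta);
        if (f_try <= f_old + 1e-12 * (1.0 + std::fabs(f_old))) {
          for (size_t r = 0; r < n; ++r) eta[r] += s * deta[r];
          maxchange = s * std::fabs(b0_new - b0_old);
          for (size_t q2 = 0; q2 < beta_new_ws.size(); ++q2) {
            const double d = s * std::fabs(beta_new_ws[q2] - beta_old_ws[q2]);
            if (d > maxchange) maxchange = d;
          }
          accepted = true;
          break;
        }
        s *= 0.5;
      }
      if (!accepted) {
        size_t idx = 0;
        for (size_t q = 0; q < ws.size(); ++q)
          for (int k = 0; k < pb.K[ws[q]]; ++k, ++idx)
            beta[pb.off[ws[q]] + k] = beta_old_ws[idx];
        b0 = b0_old;
        break;  // stationary on this working set
      }
      if (maxchange < pb.tol) break;
    }

    // dfmax guard: abort when the model grows beyond what the caller wants
    if (pb.dfmax > 0) {
      int nact = 0;
      for (size_t q = 0; q < ws.size(); ++q) {
        const int j = ws[q];
        for (int k = 0; k < pb.K[j]; ++k)
          if (beta[pb.off[j] + k] != 0.0) { ++nact; break; }
      }
      if (nact > pb.dfmax) {
        fr.truncated = true;
        fr.objective = -loglik_(pb, eta) + ws_penalty(beta);
        return fr;
      }
    }

    // full KKT sweep for exactness
    for (size_t r = 0; r < n; ++r) {
      const double pr = 1.0 / (1.0 + std::exp(-eta[r]));
      resid[r] = pb.y[pb.rows[r]] - pr;
    }
    all_grad_norms_(pb, resid, norms);
    clean = true;
    for (int j = 0; j < J; ++j) {
      if (inws[j] || !R_finite(lam[j])) continue;
      if (norms[j] > lam[j] * (1.0 + pb.kkt_tol)) {
        inws[j] = 1; ws.push_back(j);
        zc.push_back(std::vector<uint8_t>());
        fill_levels_(pb, j, zc.back());
        clean = false;
      }
    }
  }
  fr.converged = true;
  fr.objective = -loglik_(pb, eta) + ws_penalty(beta);
  return fr;
}

static Problem make_problem_(const IntegerMatrix& G, const NumericVector& y,
                             const IntegerVector& ga, const IntegerVector& gb,
                             const NumericVector& w, const IntegerVector& rows,
                             const List& control) {
  Problem pb;
  pb.G = INTEGER(G);
  pb.nrowG = G.nrow();
  pb.y = REAL(y);
  pb.rows.assign(rows.begin(), rows.end());
  pb.ga = INTEGER(ga);
  pb.gb = INTEGER(gb);
  pb.J = ga.size();
  pb.w = REAL(w);
  pb.tol = as<double>(control["tol"]);
  pb.ufloor = as<double>(control["ufloor"]);
  pb.kkt_tol = as<double>(control["kkt_tol"]);
  pb.maxit_irls = as<int>(control["maxit_irls"]);
  pb.maxit_cd = as<int>(control["maxit_cd"]);
  pb.dfmax = control.containsElementNamed("dfmax")
               ? as<int>(control["dfmax"]) : 0;
  pb.K.resize(pb.J); pb.off.resize(pb.J);
  int P = 0;
  for (int j = 0; j < pb.J; ++j) {
    pb.K[j] = (gb[j] < 0) ? 3 : 9;
    pb.off[j] = P;
    P += pb.K[j];
  }
  pb.P = P;
  return pb;
}

static void warm_eta_(const Problem& pb, double b0,
                      const std::vector<double>& beta,
                      std::vector<double>& eta) {
  const size_t n = pb.rows.size();
  eta.assign(n, b0);
  std::vector<uint8_t> z;
  for (int j = 0; j < pb.J; ++j) {
    double n2 = 0.0;
    for (int k = 0; k < pb.K[j]; ++k)
      n2 += beta[pb.off[j] + k] * beta[pb.off[j] + k];
    if (n2 > 0.0) {
      fill_levels_(pb, j, z);
      for (size_t r = 0; r < n; ++r) eta[r] += beta[pb.off[j] + z[r]];
    }
  }
}

static IntegerVector active_of_(const Problem& pb,
                                const std::vector<double>& beta) {
  std::vector<int> act;
  for (int j = 0; j < pb.J; ++j) {
    double n2 = 0.0;
    for (int k = 0; k < pb.K[j]; ++k)
      n2 += beta[pb.off[j] + k] * beta[pb.off[j] + k];
    if (n2 > 0.0) act.push_back(j + 1);
  }
  return IntegerVector(act.begin(), act.end());
}

// [[Rcpp::export(name = ".glfit_cpp")]]
List glfit_cpp(IntegerMatrix G, NumericVector y, IntegerVector ga,
               IntegerVector gb, NumericVector w, double gamma,
               IntegerVector rows, List control, double init_b0,
               NumericVector init_beta) {
  Problem pb = make_problem_(G, y, ga, gb, w, rows, control);
  double b0 = init_b0;
  std::vector<double> beta(pb.P, 0.0);
  if (init_beta.size() == pb.P)
    std::copy(init_beta.begin(), init_beta.end(), beta.begin());
  std::vector<double> eta;
  warm_eta_(pb, b0, beta, eta);
  int n_irls = 0, n_cd = 0;
  FitResult fr = fit_at_gamma_(pb, gamma, b0, beta, eta, n_irls, n_cd);
  return List::create(_["intercept"] = b0,
                      _["beta"] = NumericVector(beta.begin(), beta.end()),
                      _["offsets"] = IntegerVector(pb.off.begin(), pb.off.end()),
                      _["active"] = active_of_(pb, beta),
                      _["objective"] = fr.objective,
                      _["n_irls"] = n_irls, _["n_cd"] = n_cd,
                      _["converged"] = fr.converged,
                      _["truncated"] = fr.truncated);
}

// Warm-started path over a descending gamma grid.  If val_rows is
// non-empty, validation deviance (-2 loglik) and misclassification counts
// are recorded per gamma.  The path stops early (NA from there on) when
// the active-set size exceeds control$dfmax.
// [[Rcpp::export(name = ".glpath_cpp")]]
List glpath_cpp(IntegerMatrix G, NumericVector y, IntegerVector ga,
                IntegerVector gb, NumericVector w, NumericVector gammas,
                IntegerVector rows, IntegerVector val_rows, List control,
                bool keep_last) {
  Problem pb = make_problem_(G, y, ga, gb, w, rows, control);
  const size_t n = pb.rows.size();
  const int ngam = gammas.size();
  double b0 = 0.0;
  {
    double ybar = 0.0;
    for (size_t r = 0; r < n; ++r) ybar += pb.y[pb.rows[r]];
    ybar /= (double)n;
    if (ybar > 0.0 && ybar < 1.0) b0 = std::log(ybar / (1.0 - ybar));
  }
  std::vector<double> beta(pb.P, 0.0), eta(n, b0);
  NumericVector dev(ngam, NA_REAL), cls(ngam, NA_REAL), obj(ngam, NA_REAL);
  IntegerVector nact(ngam, NA_INTEGER);
  List actsets(ngam);
  int n_irls = 0, n_cd = 0, last_done = -1;
  for (int g = 0; g < ngam; ++g) {
    FitResult fr = fit_at_gamma_(pb, gammas[g], b0, beta, eta, n_irls, n_cd);
    if (fr.truncated) break;
    last_done = g;
    obj[g] = fr.objective;
    IntegerVector act = active_of_(pb, beta);
    nact[g] = act.size();
    actsets[g] = act;
    if (val_rows.size() > 0) {
      double d = 0.0, miss = 0.0;
      std::vector<double> veta(val_rows.size(), b0);
      std::vector<uint8_t> z;
      for (int q = 0; q < act.size(); ++q) {
        const int j = act[q] - 1;
        const int* ca = pb.G + (size_t)pb.nrowG * pb.ga[j];
        const int* cb = (pb.gb[j] < 0) ? 0 : pb.G + (size_t)pb.nrowG * pb.gb[j];
        for (int v = 0; v < val_rows.size(); ++v) {
          const int i = val_rows[v];
          const int lev = cb ? 3 * ca[i] + cb[i] : ca[i];
          veta[v] += beta[pb.off[j] + lev];
        }
      }
      for (int v = 0; v < val_rows.size(); ++v) {
        const int i = val_rows[v];
        d += pb.y[i] * veta[v] - log1pexp_(veta[v]);
        if ((veta[v] > 0.0) != (pb.y[i] > 0.5)) miss += 1.0;
      }
      dev[g] = -2.0 * d;
      cls[g] = miss;
    }
  }
  List out = List::create(_["deviance"] = dev, _["misclass"] = cls,
                          _["n_active"] = nact, _["active"] = actsets,
                          _["objective"] = obj, _["n_irls"] = n_irls,
                          _["n_cd"] = n_cd, _["last_done"] = last_done + 1);
  if (keep_last) {
    out["intercept"] = b0;
    out["beta"] = NumericVector(beta.begin(), beta.end());
    out["offsets"] = IntegerVector(pb.off.begin(), pb.off.end());
  }
  return out;
}

// L2 norm of X_j' r per group for a residual vector r (full length,
// subset by rows).  Used for gamma_max and KKT diagnostics.
// [[Rcpp::export(name = ".group_grad_norms_cpp")]]
NumericVector group_grad_norms_cpp(IntegerMatrix G, NumericVector resid,
                                   IntegerVector ga, IntegerVector gb,
                                   IntegerVector rows) {
  const int J = ga.size();
  const int* Gp = INTEGER(G);
  const int nr = G.nrow();
  const double* rs = REAL(resid);
  NumericVector out(J);
  for (int j = 0; j < J; ++j) {
    double s[9] = {0, 0, 0, 0, 0, 0, 0, 0, 0};
    const int* ca = Gp + (size_t)nr * ga[j];
    const int K = (gb[j] < 0) ? 3 : 9;
    if (gb[j] < 0) {
      for (int r = 0; r < rows.size(); ++r) s[ca[rows[r]]] += rs[rows[r]];
    } else {
      const int* cb = Gp + (size_t)nr * gb[j];
      for (int r = 0; r < rows.size(); ++r)
        s[3 * ca[rows[r]] + cb[rows[r]]] += rs[rows[r]];
    }
    double n2 = 0.0;
    for (int k = 0; k < K; ++k) n2 += s[k] * s[k];
    out[j] = std::sqrt(n2);
  }
  return out;
}

// linear predictor eta_i = b0 + sum_j beta_j[level_ij] over given rows
// [[Rcpp::export(name = ".linpred_cpp")]]
NumericVector linpred_cpp(IntegerMatrix G, IntegerVector ga, IntegerVector gb,
                          double b0, NumericVector beta, IntegerVector rows) {
  const int J = ga.size();
  const int* Gp = INTEGER(G);
  const int nr = G.nrow();
  std::vector<int> K(J), off(J);
  int P = 0;
  for (int j = 0; j < J; ++j) { K[j] = (gb[j] < 0) ? 3 : 9; off[j] = P; P += K[j]; }
  NumericVector eta(rows.size(), b0);
  for (int j = 0; j < J; ++j) {
    double n2 = 0.0;
    for (int k = 0; k < K[j]; ++k) n2 += beta[off[j] + k] * beta[off[j] + k];
    if (n2 == 0.0) continue;
    const int* ca = Gp + (size_t)nr * ga[j];
    const int* cb = (gb[j] < 0) ? 0 : Gp + (size_t)nr * gb[j];
    for (int r = 0; r < rows.size(); ++r) {
      const int i = rows[r];
      eta[r] += beta[off[j] + (cb ? 3 * ca[i] + cb[i] : ca[i])];
    }
  }
  return eta;
}
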