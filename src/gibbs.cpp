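// Parameter-expanded Gibbs sampler for the diallel mixed model:
// y = X beta + Z_u u + Z_p v + Z_ps vS + eps,
// u rows ~ N(0, H) with H = diag(alpha) Psi diag(alpha) (working-scale
// expansion), Psi ~ IW(nu_h, V_h I), alpha_c ~ N(alpha_mu, alpha_V),
// v ~ N(0, s2v), vS ~ N(0, s2vs), eps class-heteroskedastic.
//
// Observations sharing a design row (same cross, sex, state, block) enter
// the full conditionals only through their count, sum and sum of squares,
// so the sampler runs on those group-level sufficient statistics: one
// iteration costs O(#groups), independent of replication.
//
// Uses R's RNG throughout so set.seed() gives bit-identical chains.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// W ~ Wishart(df, S) via Bartlett, S supplied as lower Cholesky L (S = LL')
static arma::mat rwishart_chol(double df, const arma::mat& L) {
  const int p = L.n_rows;
  arma::mat A(p, p, arma::fill::zeros);
  for (int i = 0; i < p; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  arma::mat LA = L * A;
  return LA * LA.t();
}

// Psi ~ InverseWishart(df, V): Psi^{-1} ~ Wishart(df, V^{-1})
static arma::mat riwish(double df, const arma::mat& V) {
  arma::mat Vinv = arma::inv_sympd(arma::symmatu(V));
  arma::mat L = arma::chol(arma::symmatu(Vinv), "lower");
  arma::mat W = rwishart_chol(df, L);
  return arma::inv_sympd(arma::symmatu(W));
}

static double rinvgamma(double shape, double rate) {
  double g = R::rgamma(shape, 1.0 / rate);   // R::rgamma takes scale
  return 1.0 / g;
}

// Group-level inputs: ng (replicates), sy (sum of y), syy (sum of y^2),
// one design row per group (X, cls, loadings, pair indices).
// [[Rcpp::export]]
List gibbs_diallel_cpp(const arma::vec& ng, const arma::vec& sy,
                       const arma::vec& syy,
                       const arma::mat& X, const arma::ivec& cls,
                       const arma::ivec& load1, const arma::ivec& load2,
                       const arma::vec& w1, const arma::vec& w2,
                       const arma::ivec& pair, const arma::ivec& pairsex,
                       int n_strain, int n_pair, int n_pairsex,
                       int n_iter, int burn_in, int thin,
                       double V_h, double nu_h,
                       double alpha_mu, double alpha_V,
                       double nu_resid, double V_resid,
                       double nu_pair, double V_pair,
                       double jitter, int max_jitter) {
  const int G = ng.n_elem;
  const int p = X.n_cols;
  const int ns = n_strain;
  const int K = 4;
  const int dimU = ns * K;
  const int n_store = (n_iter - burn_in) / thin;

  std::vector<std::vector<int>> idx_c(K);
  arma::vec n_c(K, arma::fill::zeros);       // observation counts per class
  for (int g = 0; g < G; ++g) {
    idx_c[cls(g)].push_back(g);
    n_c(cls(g)) += ng(g);
  }
  std::vector<arma::mat> XtX_c(K);
  for (int c = 0; c < K; ++c) {
    XtX_c[c] = arma::mat(p, p, arma::fill::zeros);
    if (p > 0)
      for (int g : idx_c[c])
        XtX_c[c] += ng(g) * (X.row(g).t() * X.row(g));
  }
  // A_c(s,s') = sum over class-c groups of ng * loading-weight products
  arma::cube A(ns, ns, K, arma::fill::zeros);
  for (int g = 0; g < G; ++g) {
    int c = cls(g), l1 = load1(g), l2 = load2(g);
    A(l1, l1, c) += ng(g) * w1(g) * w1(g);
    if (l2 >= 0) {
      A(l2, l2, c) += ng(g) * w2(g) * w2(g);
      A(l1, l2, c) += ng(g) * w1(g) * w2(g);
      A(l2, l1, c) += ng(g) * w1(g) * w2(g);
    }
  }

  // state
  arma::vec beta(std::max(p, 1), arma::fill::zeros);
  arma::mat eta(ns, K, arma::fill::zeros);
  arma::vec alpha(K, arma::fill::ones);
  arma::mat Psi = arma::eye(K, K) * 0.1;
  arma::vec v(std::max(n_pair, 1), arma::fill::zeros);
  arma::vec vsx(std::max(n_pairsex, 1), arma::fill::zeros);
  arma::vec s2e(K, arma::fill::ones);
  for (int c = 0; c < K; ++c) {
    if (n_c(c) > 1) {
      double s = 0.0, ss = 0.0;
      for (int g : idx_c[c]) { s += sy(g); ss += syy(g); }
      double vv = (ss - s * s / n_c(c)) / (n_c(c) - 1);
      s2e(c) = (vv > 1e-12) ? vv : 1e-6;
    }
  }
  double s2v = 0.01, s2vs = 0.01;
  double n_tot = arma::accu(ng);
  if (G > 0 && p > 0) beta(0) = arma::accu(sy) / n_tot;  // col 0 = intercept

  // per-group model components
  arma::vec xb(std::max(G, 1), arma::fill::zeros);
  arma::vec ucon(std::max(G, 1), arma::fill::zeros);
  arma::vec vcon(std::max(G, 1), arma::fill::zeros);
  arma::vec vscon(std::max(G, 1), arma::fill::zeros);
  arma::vec winv(std::max(G, 1), arma::fill::zeros);
  auto update_ucon = [&]() {
    for (int g = 0; g < G; ++g) {
      int c = cls(g);
      double s = w1(g) * eta(load1(g), c);
      if (load2(g) >= 0) s += w2(g) * eta(load2(g), c);
      ucon(g) = alpha(c) * s;
    }
  };
  auto update_vcon = [&]() {
    for (int g = 0; g < G; ++g) {
      vcon(g) = (pair(g) >= 0) ? v(pair(g)) : 0.0;
      vscon(g) = (pairsex(g) >= 0) ? vsx(pairsex(g)) : 0.0;
    }
  };

  arma::mat beta_st(n_store, std::max(p, 1), arma::fill::zeros);
  arma::mat U_st(n_store, dimU);
  arma::mat H_st(n_store, K * K);
  arma::mat s2e_st(n_store, K);
  arma::vec s2v_st(n_store), s2vs_st(n_store);
  int jitter_count = 0;

  int store_row = 0;
  for (int it = 1; it <= n_iter; ++it) {
    if (it % 8192 == 0) Rcpp::checkUserInterrupt();
    for (int c = 0; c < K; ++c)
      if (!std::isfinite(s2e(c)) || s2e(c) <= 0.0)
        stop("divergent residual variance in class %d at iteration %d", c + 1, it);
    for (int g = 0; g < G; ++g) winv(g) = 1.0 / s2e(cls(g));

    // --- fixed effects (flat prior) ---
    if (G > 0 && p > 0) {
      update_ucon();
      update_vcon();
      arma::mat B(p, p, arma::fill::zeros);
      for (int c = 0; c < K; ++c)
        if (n_c(c) > 0) B += XtX_c[c] / s2e(c);
      arma::vec rhs(p, arma::fill::zeros);
      for (int g = 0; g < G; ++g) {
        double r = (sy(g) - ng(g) * (ucon(g) + vcon(g) + vscon(g))) * winv(g);
        rhs += r * X.row(g).t();
      }
      arma::mat R;
      if (!arma::chol(R, arma::symmatu(B)))
        stop("singular fixed-effect precision at iteration %d", it);
      arma::vec mu = arma::solve(arma::trimatu(R),
                                 arma::solve(arma::trimatl(R.t()), rhs));
      arma::vec z(p);
      for (int j = 0; j < p; ++j) z(j) = R::norm_rand();
      beta.head(p) = mu + arma::solve(arma::trimatu(R), z);
      xb = X * beta.head(p);
    }

    // --- pair (symmetric epistasis) effects ---
    if (n_pair > 0) {
      update_ucon();
      arma::vec num(n_pair, arma::fill::zeros), prec(n_pair, arma::fill::zeros);
      for (int g = 0; g < G; ++g) {
        if (pair(g) < 0) continue;
        double other = xb(g) + ucon(g) + ((pairsex(g) >= 0) ? vsx(pairsex(g)) : 0.0);
        num(pair(g)) += (sy(g) - ng(g) * other) * winv(g);
        prec(pair(g)) += ng(g) * winv(g);
      }
      for (int q = 0; q < n_pair; ++q) {
        double pr = prec(q) + 1.0 / s2v;
        v(q) = num(q) / pr + R::norm_rand() / std::sqrt(pr);
      }
    }
    if (n_pairsex > 0) {
      update_ucon();
      arma::vec num(n_pairsex, arma::fill::zeros), prec(n_pairsex, arma::fill::zeros);
      for (int g = 0; g < G; ++g) {
        if (pairsex(g) < 0) continue;
        double other = xb(g) + ucon(g) + ((pair(g) >= 0) ? v(pair(g)) : 0.0);
        num(pairsex(g)) += (sy(g) - ng(g) * other) * winv(g);
        prec(pairsex(g)) += ng(g) * winv(g);
      }
      for (int q = 0; q < n_pairsex; ++q) {
        double pr = prec(q) + 1.0 / s2vs;
        vsx(q) = num(q) / pr + R::norm_rand() / std::sqrt(pr);
      }
    }

    // --- strain effects on the working (eta) scale ---
    arma::mat Psi_inv = arma::inv_sympd(arma::symmatu(Psi));
    if (G > 0) {
      update_vcon();
      arma::mat T(ns, K, arma::fill::zeros);
      for (int g = 0; g < G; ++g) {
        int c = cls(g);
        double r = (sy(g) - ng(g) * (xb(g) + vcon(g) + vscon(g))) * winv(g);
        T(load1(g), c) += w1(g) * r;
        if (load2(g) >= 0) T(load2(g), c) += w2(g) * r;
      }
      arma::mat C(dimU, dimU, arma::fill::zeros);
      for (int s = 0; s < ns; ++s)
        C.submat(s * K, s * K, s * K + K - 1, s * K + K - 1) = Psi_inv;
      for (int c = 0; c < K; ++c) {
        if (n_c(c) == 0) continue;
        double f = alpha(c) * alpha(c) / s2e(c);
        for (int s = 0; s < ns; ++s)
          for (int s2 = 0; s2 < ns; ++s2) {
            double a = A(s, s2, c);
            if (a != 0.0) C(s * K + c, s2 * K + c) += f * a;
          }
      }
      arma::vec b(dimU, arma::fill::zeros);
      for (int s = 0; s < ns; ++s)
        for (int c = 0; c < K; ++c)
          b(s * K + c) = alpha(c) * T(s, c);
      arma::mat R;
      int tries = 0;
      while (!arma::chol(R, arma::symmatu(C))) {
        C.diag() += jitter;
        if (++tries > max_jitter)
          stop("strain-effect precision not positive definite after %d jitter attempts (iteration %d)",
               max_jitter, it);
      }
      jitter_count += tries;
      arma::vec mu = arma::solve(arma::trimatu(R),
                                 arma::solve(arma::trimatl(R.t()), b));
      arma::vec z(dimU);
      for (int j = 0; j < dimU; ++j) z(j) = R::norm_rand();
      arma::vec ev = mu + arma::solve(arma::trimatu(R), z);
      for (int s = 0; s < ns; ++s)
        for (int c = 0; c < K; ++c)
          eta(s, c) = ev(s * K + c);
    } else {
      // prior draw: rows of eta ~ N(0, Psi)
      arma::mat Z(ns, K);
      for (int s = 0; s < ns; ++s)
        for (int c = 0; c < K; ++c) Z(s, c) = R::norm_rand();
      eta = Z * arma::chol(arma::symmatu(Psi));
    }

    // --- working scale parameters alpha ---
    update_vcon();
    for (int c = 0; c < K; ++c) {
      if (n_c(c) > 0) {
        double mprec = 0.0, mnum = 0.0;
        for (int g : idx_c[c]) {
          double m = w1(g) * eta(load1(g), c);
          if (load2(g) >= 0) m += w2(g) * eta(load2(g), c);
          double other = xb(g) + vcon(g) + vscon(g);
          mprec += ng(g) * m * m * winv(g);
          mnum += m * (sy(g) - ng(g) * other) * winv(g);
        }
        double pr = mprec + 1.0 / alpha_V;
        double mn = (mnum + alpha_mu / alpha_V) / pr;
        alpha(c) = mn + R::norm_rand() / std::sqrt(pr);
      } else {
        alpha(c) = alpha_mu + std::sqrt(alpha_V) * R::norm_rand();
      }
    }

    // --- Psi from its inverse-Wishart full conditional ---
    arma::mat S = eta.t() * eta;
    Psi = riwish(nu_h + ns, arma::eye(K, K) * V_h + S);

    // --- variance components ---
    if (G > 0) {
      update_ucon();
      for (int c = 0; c < K; ++c) {
        if (n_c(c) == 0) continue;
        double ssr = 0.0;
        for (int g : idx_c[c]) {
          double m = xb(g) + ucon(g) + vcon(g) + vscon(g);
          ssr += syy(g) - 2.0 * m * sy(g) + ng(g) * m * m;
        }
        s2e(c) = rinvgamma((nu_resid + n_c(c)) / 2.0,
                           (nu_resid * V_resid + ssr) / 2.0);
      }
    }
    if (n_pair > 0)
      s2v = rinvgamma((nu_pair + n_pair) / 2.0,
                      (nu_pair * V_pair + arma::dot(v, v)) / 2.0);
    if (n_pairsex > 0)
      s2vs = rinvgamma((nu_pair + n_pairsex) / 2.0,
                       (nu_pair * V_pair + arma::dot(vsx, vsx)) / 2.0);

    // --- store ---
    if (it > burn_in && (it - burn_in) % thin == 0) {
      for (int j = 0; j < p; ++j) beta_st(store_row, j) = beta(j);
      for (int c = 0; c < K; ++c)
        for (int s = 0; s < ns; ++s)
          U_st(store_row, c * ns + s) = alpha(c) * eta(s, c);
      for (int i2 = 0; i2 < K; ++i2)
        for (int j2 = 0; j2 < K; ++j2)
          H_st(store_row, j2 * K + i2) = alpha(i2) * Psi(i2, j2) * alpha(j2);
      for (int c = 0; c < K; ++c)
        s2e_st(store_row, c) = (n_c(c) > 0) ? s2e(c) : NA_REAL;
      s2v_st(store_row) = (n_pair > 0) ? s2v : NA_REAL;
      s2vs_st(store_row) = (n_pairsex > 0) ? s2vs : NA_REAL;
      ++store_row;
    }
  }

  return List::create(_["beta"] = beta_st, _["U"] = U_st, _["H"] = H_st,
                      _["sigma2_e"] = s2e_st, _["sigma2_v"] = s2v_st,
                      _["sigma2_vS"] = s2vs_st,
                      _["jitter_count"] = jitter_count,
                      _["n_store"] = n_store);
}
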