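// Blocked Gibbs samplers for hierarchical Gaussian variance-partitioning
// models.  All random numbers come from R's RNG so set.seed() in R gives
// exact reproducibility.
//
// Univariate model (one behavioral trait):
//   y_j = beta_{g(j)} + u_{i(j)} + p_{pop(j)} + e_j
//   u_i   ~ N(0, vA[g_i])       (vA shared across groups unless het_A)
//   p_k   ~ N(0, vPop)          (optional)
//   e_j   ~ N(0, vW[g_j])       (vW shared across groups unless het_W)
// Priors: beta_g ~ N(0, beta_sd^2); every SD has a half-Student-t(df,
// 0, scale) prior via the inverse-gamma scale-mixture representation
//   sigma^2 | a ~ InvGamma(df/2, df/a),  a ~ InvGamma(1/2, 1/scale^2)
// which keeps every conditional conjugate.
//
// Multivariate model (all traits jointly):
//   y_{jt} = beta_{g,t} + u_{i,t} + p_{pop,t} + e_{jt}
//   u_i ~ MVN(0, Sigma_{g(i)}),  Sigma_g ~ InvWishart(d + 1, I)
//   p_k ~ MVN(0, Sigma_P),       Sigma_P ~ InvWishart(d + 1, I)
//   e_{jt} ~ N(0, vW[g, t]) independent across traits.
// The IW(d + 1, I) prior has marginally uniform correlations.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double rinvgamma(double shape, double rate) {
  return 1.0 / R::rgamma(shape, 1.0 / rate);
}

// sigma^2 update under the half-t scale mixture, given sum of squares
// `ss` over `m` effects and the current auxiliary `a` (updated in place).
static inline double update_variance(double ss, double m, double& a,
                                     double df, double scale) {
  double v = rinvgamma(0.5 * (df + m), df / a + 0.5 * ss);
  a = rinvgamma(0.5 * (df + 1.0), df / v + 1.0 / (scale * scale));
  return v;
}

static const double LOG2PI = 1.837877066409345483560659;

// [[Rcpp::export]]
List gibbs_univariate_cpp(const arma::vec& y,
                          const arma::ivec& g,
                          const arma::ivec& ind,
                          const arma::ivec& pop,
                          const arma::ivec& ind_group,
                          const arma::ivec& pop_group,
                          int n_groups, int n_ind, int n_pop,
                          bool het_A, bool het_W, bool use_pop,
                          int iter, int warmup,
                          double beta_sd, double sd_df, double sd_scale) {
  const int n = y.n_elem;
  const int nA = het_A ? n_groups : 1;
  const int nW = het_W ? n_groups : 1;
  const int S = iter - warmup;

  // index bookkeeping
  arma::vec ng(n_groups, arma::fill::zeros);       // obs per group
  arma::vec ni(n_ind, arma::fill::zeros);          // obs per individual
  arma::vec np(std::max(n_pop, 1), arma::fill::zeros);
  for (int j = 0; j < n; ++j) {
    ng(g(j))   += 1.0;
    ni(ind(j)) += 1.0;
    if (use_pop) np(pop(j)) += 1.0;
  }
  arma::vec mA(nA, arma::fill::zeros);             // individuals per vA block
  for (int i = 0; i < n_ind; ++i) mA(het_A ? ind_group(i) : 0) += 1.0;
  arma::vec mGrp(n_groups, arma::fill::zeros);     // individuals per group
  for (int i = 0; i < n_ind; ++i) mGrp(ind_group(i)) += 1.0;
  arma::vec kGrp(n_groups, arma::fill::zeros);     // populations per group
  if (use_pop) for (int k = 0; k < n_pop; ++k) kGrp(pop_group(k)) += 1.0;
  arma::vec nWcnt(nW, arma::fill::zeros);          // obs per vW block
  for (int j = 0; j < n; ++j) nWcnt(het_W ? g(j) : 0) += 1.0;

  // state
  arma::vec beta(n_groups, arma::fill::zeros);
  arma::vec u(n_ind, arma::fill::zeros);
  arma::vec p(std::max(n_pop, 1), arma::fill::zeros);
  double vy = arma::var(y);
  if (!std::isfinite(vy) || vy <= 0) vy = 1.0;
  arma::vec vA(nA);  vA.fill(0.5 * vy);
  arma::vec vW(nW);  vW.fill(0.5 * vy);
  double vP = 0.25 * vy;
  arma::vec aA(nA, arma::fill::ones), aW(nW, arma::fill::ones);
  double aP = 1.0;
  // init beta at group means
  {
    arma::vec s(n_groups, arma::fill::zeros);
    for (int j = 0; j < n; ++j) s(g(j)) += y(j);
    for (int h = 0; h < n_groups; ++h) beta(h) = ng(h) > 0 ? s(h) / ng(h) : 0.0;
  }

  const int n_par = n_groups + nA + nW + (use_pop ? 1 : 0);
  arma::mat draws(S, n_par);
  arma::mat mu_out(S, n);
  arma::mat ll_out(S, n);

  arma::vec sg(n_groups), si(n_ind), sp(std::max(n_pop, 1));
  const double beta_prec0 = 1.0 / (beta_sd * beta_sd);

  for (int it = 0; it < iter; ++it) {
    // --- beta | rest
    sg.zeros();
    for (int j = 0; j < n; ++j)
      sg(g(j)) += y(j) - u(ind(j)) - (use_pop ? p(pop(j)) : 0.0);
    for (int h = 0; h < n_groups; ++h) {
      double vw = vW(het_W ? h : 0);
      double prec = ng(h) / vw + beta_prec0;
      double mean = (sg(h) / vw) / prec;
      beta(h) = mean + R::rnorm(0.0, 1.0) / std::sqrt(prec);
    }

    // --- u | rest
    si.zeros();
    for (int j = 0; j < n; ++j)
      si(ind(j)) += y(j) - beta(g(j)) - (use_pop ? p(pop(j)) : 0.0);
    for (int i = 0; i < n_ind; ++i) {
      int h = ind_group(i);
      double vw = vW(het_W ? h : 0);
      double va = vA(het_A ? h : 0);
      double prec = ni(i) / vw + 1.0 / va;
      double mean = (si(i) / vw) / prec;
      u(i) = mean + R::rnorm(0.0, 1.0) / std::sqrt(prec);
    }

    // --- p | rest
    if (use_pop) {
      sp.zeros();
      for (int j = 0; j < n; ++j)
        sp(pop(j)) += (y(j) - beta(g(j)) - u(ind(j))) / vW(het_W ? g(j) : 0);
      // populations are nested in groups, so each population has a single vW
      arma::vec pprec(n_pop, arma::fill::zeros);
      for (int j = 0; j < n; ++j) pprec(pop(j)) += 1.0 / vW(het_W ? g(j) : 0);
      for (int k = 0; k < n_pop; ++k) {
        double prec = pprec(k) + 1.0 / vP;
        p(k) = sp(k) / prec + R::rnorm(0.0, 1.0) / std::sqrt(prec);
      }
    }

    // --- interweaving: exchange location mass between beta[g] and its
    // group's random effects (beta and the few population effects per
    // group are strongly correlated; this exact reparameterized Gibbs
    // step removes the resulting slow mixing)
    {
      arma::vec su(n_groups, arma::fill::zeros);
      for (int i = 0; i < n_ind; ++i) su(ind_group(i)) += u(i);
      arma::vec shift(n_groups);
      for (int h = 0; h < n_groups; ++h) {
        double va = vA(het_A ? h : 0);
        double prec = mGrp(h) / va + beta_prec0;
        double mean = (su(h) / va - beta(h) * beta_prec0) / prec;
        shift(h) = mean + R::rnorm(0.0, 1.0) / std::sqrt(prec);
        beta(h) += shift(h);
      }
      for (int i = 0; i < n_ind; ++i) u(i) -= shift(ind_group(i));
      if (use_pop) {
        arma::vec sp2(n_groups, arma::fill::zeros);
        for (int k = 0; k < n_pop; ++k) sp2(pop_group(k)) += p(k);
        for (int h = 0; h < n_groups; ++h) {
          if (kGrp(h) == 0) { shift(h) = 0.0; continue; }
          double prec = kGrp(h) / vP + beta_prec0;
          double mean = (sp2(h) / vP - beta(h) * beta_prec0) / prec;
          shift(h) = mean + R::rnorm(0.0, 1.0) / std::sqrt(prec);
          beta(h) += shift(h);
        }
        for (int k = 0; k < n_pop; ++k) p(k) -= shift(pop_group(k));
      }
    }

    // --- vA | u
    {
      arma::vec ss(nA, arma::fill::zeros);
      for (int i = 0; i < n_ind; ++i) ss(het_A ? ind_group(i) : 0) += u(i) * u(i);
      for (int b = 0; b < nA; ++b)
        vA(b) = update_variance(ss(b), mA(b), aA(b), sd_df, sd_scale);
    }

    // --- vW | residuals
    {
      arma::vec ss(nW, arma::fill::zeros);
      for (int j = 0; j < n; ++j) {
        double e = y(j) - beta(g(j)) - u(ind(j)) - (use_pop ? p(pop(j)) : 0.0);
        ss(het_W ? g(j) : 0) += e * e;
      }
      for (int b = 0; b < nW; ++b)
        vW(b) = update_variance(ss(b), nWcnt(b), aW(b), sd_df, sd_scale);
    }

    // --- vPop | p
    if (use_pop) {
      double ss = arma::dot(p.head(n_pop), p.head(n_pop));
      vP = update_variance(ss, (double)n_pop, aP, sd_df, sd_scale);
    }

    // --- scale interweaving for vA and vPop: rewrite u = s * eta with eta
    // ancillary, draw the signed scale s from its Gaussian conditional
    // (prior t(df, 0, scale) on s via its normal scale mixture, equivalent
    // to the half-t on |s|), and map back. Decorrelates the random-effect
    // block from its variance, which otherwise mixes slowly in small
    // groups.
    {
      arma::vec num(nA, arma::fill::zeros), den(nA, arma::fill::zeros);
      for (int j = 0; j < n; ++j) {
        int b = het_A ? g(j) : 0;
        double eta = u(ind(j)) / std::sqrt(vA(b));
        double r = y(j) - beta(g(j)) - (use_pop ? p(pop(j)) : 0.0);
        double vw = vW(het_W ? g(j) : 0);
        num(b) += eta * r / vw;
        den(b) += eta * eta / vw;
      }
      for (int b = 0; b < nA; ++b) {
        double bmix = rinvgamma(0.5 * (sd_df + 1.0),
                                0.5 * (sd_df * sd_scale * sd_scale + vA(b)));
        double prec = den(b) + 1.0 / bmix;
        double s = num(b) / prec + R::rnorm(0.0, 1.0) / std::sqrt(prec);
        double ratio = std::fabs(s) / std::sqrt(vA(b));
        double sign = s < 0 ? -1.0 : 1.0;
        for (int i = 0; i < n_ind; ++i) {
          if ((het_A ? ind_group(i) : 0) == b) u(i) *= sign * ratio;
        }
        vA(b) = s * s;
      }
      if (use_pop) {
        double pnum = 0.0, pden = 0.0;
        for (int j = 0; j < n; ++j) {
          double eta = p(pop(j)) / std::sqrt(vP);
          double r = y(j) - beta(g(j)) - u(ind(j));
          double vw = vW(het_W ? g(j) : 0);
          pnum += eta * r / vw;
          pden += eta * eta / vw;
        }
        double bmix = rinvgamma(0.5 * (sd_df + 1.0),
                                0.5 * (sd_df * sd_scale * sd_scale + vP));
        double prec = pden + 1.0 / bmix;
        double s = pnum / prec + R::rnorm(0.0, 1.0) / std::sqrt(prec);
        double ratio = std::fabs(s) / std::sqrt(vP);
        double sign = s < 0 ? -1.0 : 1.0;
        for (int k = 0; k < n_pop; ++k) p(k) *= sign * ratio;
        vP = s * s;
      }
    }

    if (it >= warmup) {
      int s = it - warmup;
      int c = 0;
      for (int h = 0; h < n_groups; ++h) draws(s, c++) = beta(h);
      for (int b = 0; b < nA; ++b) draws(s, c++) = std::sqrt(vA(b));
      for (int b = 0; b < nW; ++b) draws(s, c++) = std::sqrt(vW(b));
      if (use_pop) draws(s, c++) = std::sqrt(vP);
      for (int j = 0; j < n; ++j) {
        double m = beta(g(j)) + u(ind(j)) + (use_pop ? p(pop(j)) : 0.0);
        double vw = vW(het_W ? g(j) : 0);
        double e = y(j) - m;
        mu_out(s, j) = m;
        ll_out(s, j) = -0.5 * (LOG2PI + std::log(vw) + e * e / vw);
      }
    }
  }

  return List::create(_["draws"] = draws, _["mu"] = mu_out,
                      _["loglik"] = ll_out);
}

// Draw from InvWishart(df, S) via the Bartlett decomposition of the
// corresponding Wishart(df, S^{-1}).
static arma::mat rinvwishart(double df, const arma::mat& S) {
  const int d = S.n_rows;
  arma::mat Sinv = arma::inv_sympd(arma::symmatu(S));
  arma::mat L = arma::chol(Sinv, "lower");
  arma::mat A(d, d, arma::fill::zeros);
  for (int i = 0; i < d; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::rnorm(0.0, 1.0);
  }
  arma::mat W = L * A;
  W = W * W.t();                       // ~ Wishart(df, S^{-1})
  return arma::inv_sympd(arma::symmatu(W));
}

// [[Rcpp::export]]
List gibbs_multivariate_cpp(const arma::vec& y,
                            const arma::ivec& g,
                            const arma::ivec& ind,
                            const arma::ivec& pop,
                            const arma::ivec& tr,
                            const arma::ivec& ind_group,
                            const arma::ivec& pop_group,
                            int n_groups, int n_ind, int n_pop, int n_traits,
                            bool use_pop, bool het_W,
                            int iter, int warmup,
                            double beta_sd, double sd_df, double sd_scale,
                            bool keep_loglik) {
  const int n = y.n_elem;
  const int d = n_traits;
  const int S = iter - warmup;
  const int nWb = het_W ? n_groups : 1;      // vW blocks are (block, trait)

  arma::mat ngt(n_groups, d, arma::fill::zeros);   // obs per (group, trait)
  arma::mat nit(n_ind, d, arma::fill::zeros);      // obs per (ind, trait)
  arma::mat npt(std::max(n_pop, 1), d, arma::fill::zeros);
  arma::mat nWcnt(nWb, d, arma::fill::zeros);
  arma::vec mG(n_groups, arma::fill::zeros);       // individuals per group
  for (int j = 0; j < n; ++j) {
    ngt(g(j), tr(j)) += 1.0;
    nit(ind(j), tr(j)) += 1.0;
    if (use_pop) npt(pop(j), tr(j)) += 1.0;
    nWcnt(het_W ? g(j) : 0, tr(j)) += 1.0;
  }
  for (int i = 0; i < n_ind; ++i) mG(ind_group(i)) += 1.0;

  // state
  arma::mat beta(n_groups, d, arma::fill::zeros);
  arma::mat u(n_ind, d, arma::fill::zeros);
  arma::mat p(std::max(n_pop, 1), d, arma::fill::zeros);
  arma::cube SigA(d, d, n_groups);
  for (int h = 0; h < n_groups; ++h) SigA.slice(h) = 0.3 * arma::eye(d, d);
  arma::mat SigP = 0.2 * arma::eye(d, d);
  arma::mat vW(nWb, d);  vW.fill(0.5);
  arma::mat aW(nWb, d);  aW.fill(1.0);
  {
    arma::mat s(n_groups, d, arma::fill::zeros);
    for (int j = 0; j < n; ++j) s(g(j), tr(j)) += y(j);
    for (int h = 0; h < n_groups; ++h)
      for (int t = 0; t < d; ++t)
        beta(h, t) = ngt(h, t) > 0 ? s(h, t) / ngt(h, t) : 0.0;
  }

  const double nu0 = d + 1.0;
  const arma::mat S0 = arma::eye(d, d);
  const double beta_prec0 = 1.0 / (beta_sd * beta_sd);
  const int ntri = d * (d + 1) / 2;
  const int n_par = n_groups * d + nWb * d + n_groups * ntri +
                    (use_pop ? ntri : 0);
  arma::mat draws(S, n_par);
  arma::mat mu_out(S, n);
  arma::mat ll_out(keep_loglik ? S : 0, keep_loglik ? n : 0);

  arma::mat sg(n_groups, d), si(n_ind, d), sp(std::max(n_pop, 1), d);
  arma::cube SigAinv(d, d, n_groups);
  arma::mat SigPinv(d, d);

  for (int it = 0; it < iter; ++it) {
    for (int h = 0; h < n_groups; ++h)
      SigAinv.slice(h) = arma::inv_sympd(arma::symmatu(SigA.slice(h)));
    if (use_pop) SigPinv = arma::inv_sympd(arma::symmatu(SigP));

    // --- beta | rest
    sg.zeros();
    for (int j = 0; j < n; ++j)
      sg(g(j), tr(j)) += y(j) - u(ind(j), tr(j)) -
        (use_pop ? p(pop(j), tr(j)) : 0.0);
    for (int h = 0; h < n_groups; ++h)
      for (int t = 0; t < d; ++t) {
        double vw = vW(het_W ? h : 0, t);
        double prec = ngt(h, t) / vw + beta_prec0;
        beta(h, t) = (sg(h, t) / vw) / prec + R::rnorm(0.0, 1.0) / std::sqrt(prec);
      }

    // --- u_i | rest (d-dimensional conjugate normal per individual)
    si.zeros();
    for (int j = 0; j < n; ++j)
      si(ind(j), tr(j)) += (y(j) - beta(g(j), tr(j)) -
        (use_pop ? p(pop(j), tr(j)) : 0.0)) / vW(het_W ? g(j) : 0, tr(j));
    for (int i = 0; i < n_ind; ++i) {
      int h = ind_group(i);
      arma::mat prec = SigAinv.slice(h);
      for (int t = 0; t < d; ++t)
        prec(t, t) += nit(i, t) / vW(het_W ? h : 0, t);
      arma::mat cl = arma::chol(arma::symmatu(prec), "lower");
      arma::vec rhs = si.row(i).t();
      arma::vec z(d);
      for (int t = 0; t < d; ++t) z(t) = R::rnorm(0.0, 1.0);
      // mean = prec^{-1} rhs; draw = mean + chol(prec)^{-T} z
      arma::vec mean = arma::solve(arma::trimatu(cl.t()),
                       arma::solve(arma::trimatl(cl), rhs));
      u.row(i) = (mean + arma::solve(arma::trimatu(cl.t()), z)).t();
    }

    // --- p_k | rest
    if (use_pop) {
      sp.zeros();
      for (int j = 0; j < n; ++j)
        sp(pop(j), tr(j)) += (y(j) - beta(g(j), tr(j)) - u(ind(j), tr(j))) /
          vW(het_W ? g(j) : 0, tr(j));
      // population k sits inside one group; accumulate trait-wise precisions
      arma::mat pprec(n_pop, d, arma::fill::zeros);
      for (int j = 0; j < n; ++j)
        pprec(pop(j), tr(j)) += 1.0 / vW(het_W ? g(j) : 0, tr(j));
      for (int k = 0; k < n_pop; ++k) {
        arma::mat prec = SigPinv;
        for (int t = 0; t < d; ++t) prec(t, t) += pprec(k, t);
        arma::mat cl = arma::chol(arma::symmatu(prec), "lower");
        arma::vec rhs = sp.row(k).t();
        arma::vec z(d);
        for (int t = 0; t < d; ++t) z(t) = R::rnorm(0.0, 1.0);
        arma::vec mean = arma::solve(arma::trimatu(cl.t()),
                         arma::solve(arma::trimatl(cl), rhs));
        p.row(k) = (mean + arma::solve(arma::trimatu(cl.t()), z)).t();
      }
    }

    // --- interweaving: exchange location mass between beta[g, t] and the
    // group's random effects, trait by trait (see univariate sampler)
    {
      arma::mat sumU(n_groups, d, arma::fill::zeros);
      for (int i = 0; i < n_ind; ++i) sumU.row(ind_group(i)) += u.row(i);
      arma::mat shift(n_groups, d, arma::fill::zeros);
      for (int h = 0; h < n_groups; ++h) {
        for (int t = 0; t < d; ++t) {
          arma::vec lin = SigAinv.slice(h) * sumU.row(h).t();
          double prec = mG(h) * SigAinv(t, t, h) + beta_prec0;
          double mean = (lin(t) - beta(h, t) * beta_prec0) / prec;
          double dlt = mean + R::rnorm(0.0, 1.0) / std::sqrt(prec);
          beta(h, t) += dlt;
          shift(h, t) += dlt;
          sumU(h, t) -= mG(h) * dlt;
        }
      }
      for (int i = 0; i < n_ind; ++i) u.row(i) -= shift.row(ind_group(i));
      if (use_pop) {
        arma::mat sumP(n_groups, d, arma::fill::zeros);
        arma::vec kG(n_groups, arma::fill::zeros);
        for (int k = 0; k < n_pop; ++k) {
          sumP.row(pop_group(k)) += p.row(k);
          kG(pop_group(k)) += 1.0;
        }
        shift.zeros();
        for (int h = 0; h < n_groups; ++h) {
          if (kG(h) == 0) continue;
          for (int t = 0; t < d; ++t) {
            arma::vec lin = SigPinv * sumP.row(h).t();
            double prec = kG(h) * SigPinv(t, t) + beta_prec0;
            double mean = (lin(t) - beta(h, t) * beta_prec0) / prec;
            double dlt = mean + R::rnorm(0.0, 1.0) / std::sqrt(prec);
            beta(h, t) += dlt;
            shift(h, t) += dlt;
            sumP(h, t) -= kG(h) * dlt;
          }
        }
        for (int k = 0; k < n_pop; ++k) p.row(k) -= shift.row(pop_group(k));
      }
    }

    // --- Sigma_g | u
    for (int h = 0; h < n_groups; ++h) {
      arma::mat scat = S0;
      for (int i = 0; i < n_ind; ++i)
        if (ind_group(i) == h) scat += u.row(i).t() * u.row(i);
      SigA.slice(h) = rinvwishart(nu0 + mG(h), scat);
    }

    // --- Sigma_P | p
    if (use_pop) {
      arma::mat scat = S0;
      for (int k = 0; k < n_pop; ++k) scat += p.row(k).t() * p.row(k);
      SigP = rinvwishart(nu0 + n_pop, scat);
    }

    // --- vW | residuals
    {
      arma::mat ss(nWb, d, arma::fill::zeros);
      for (int j = 0; j < n; ++j) {
        double e = y(j) - beta(g(j), tr(j)) - u(ind(j), tr(j)) -
          (use_pop ? p(pop(j), tr(j)) : 0.0);
        ss(het_W ? g(j) : 0, tr(j)) += e * e;
      }
      for (int b = 0; b < nWb; ++b)
        for (int t = 0; t < d; ++t)
          vW(b, t) = update_variance(ss(b, t), nWcnt(b, t), aW(b, t),
                                     sd_df, sd_scale);
    }

    if (it >= warmup) {
      int s = it - warmup;
      int c = 0;
      for (int h = 0; h < n_groups; ++h)
        for (int t = 0; t < d; ++t) draws(s, c++) = beta(h, t);
      for (int b = 0; b < nWb; ++b)
        for (int t = 0; t < d; ++t) draws(s, c++) = std::sqrt(vW(b, t));
      for (int h = 0; h < n_groups; ++h)
        for (int t1 = 0; t1 < d; ++t1)
          for (int t2 = t1; t2 < d; ++t2) draws(s, c++) = SigA(t1, t2, h);
      if (use_pop)
        for (int t1 = 0; t1 < d; ++t1)
          for (int t2 = t1; t2 < d; ++t2) draws(s, c++) = SigP(t1, t2);
      for (int j = 0; j < n; ++j) {
        double m = beta(g(j), tr(j)) + u(ind(j), tr(j)) +
          (use_pop ? p(pop(j), tr(j)) : 0.0);
        mu_out(s, j) = m;
        if (keep_loglik) {
          double vw = vW(het_W ? g(j) : 0, tr(j));
          double e = y(j) - m;
          ll_out(s, j) = -0.5 * (LOG2PI + std::log(vw) + e * e / vw);
        }
      }
    }
  }

  return List::create(_["draws"] = draws, _["mu"] = mu_out,
                      _["loglik"] = ll_out);
}
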