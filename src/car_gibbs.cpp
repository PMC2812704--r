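#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Draw a variance component given its sufficient statistics.
// df is the exponent rank (n for the residual variance, K for exchangeable
// effects, K - c for the ICAR component), ss the scale sum of squares.
// prior_type 0: uniform prior on the SD, truncated conjugate draw via the
// precision-scale gamma quantile function (exact, no rejection);
// prior_type 1: gamma prior on the precision (conjugate).
static double draw_variance(int df, double ss, int prior_type,
                            double unif_upper, double g_shape, double g_rate) {
  if (prior_type == 1) {
    double shape = g_shape + 0.5 * df;
    double rate  = g_rate + 0.5 * ss;
    double g = R::rgamma(shape, 1.0 / rate);
    if (g <= 0.0) g = 1e-300;
    return 1.0 / g;
  }
  // uniform on SD over (0, unif_upper)
  if (df == 0 && ss <= 0.0) {         // no information: draw from the prior
    double s = R::runif(0.0, unif_upper);
    return s * s;
  }
  double shape = 0.5 * (df - 1.0);
  if (shape <= 0.0)
    stop("variance update undefined: rank %d too small for a uniform-SD prior", df);
  double scale = 2.0 / ss;            // precision ~ Gamma(shape, rate = ss/2)
  double lo = 1.0 / (unif_upper * unif_upper);
  double plo = R::pgamma(lo, shape, scale, 1, 0);
  double u = R::runif(plo, 1.0);
  if (u >= 1.0) u = 1.0 - 1e-16;
  double g = R::qgamma(u, shape, scale, 1, 0);
  if (g < lo) g = lo;                 // numerical guard at the bound
  return 1.0 / g;
}

// [[Rcpp::export]]
NumericVector draw_variance_cpp(int n, int df, double ss, int prior_type,
                                double unif_upper, double g_shape, double g_rate) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = draw_variance(df, ss, prior_type, unif_upper, g_shape, g_rate);
  return out;
}

// One-block Gibbs sampler for the hierarchical log-DUP models.
//
// State packing (matching the R wrapper): alpha, beta (p), R (K, optional),
// S (K, optional), sigma2_e, sigma2_R (optional), sigma2_S (optional).
// The returned matrix has one retained iteration per row and a trailing
// deviance column (-2 * conditional log-likelihood given all effects).
//
// Update order per sweep: (alpha, beta) jointly, R_i (all wards), S_i
// (sequential scan, then per-component recentring with the observation-
// weighted mean absorbed into alpha), sigma2_e, sigma2_R, sigma2_S.
// [[Rcpp::export]]
arma::mat car_gibbs_cpp(const arma::vec& y, const arma::mat& X,
                        const arma::ivec& ward, const List& nbrs,
                        const arma::ivec& comp,
                        bool use_R, bool use_S,
                        double beta_prior_sd,
                        int var_prior_type, double unif_upper,
                        double g_shape, double g_rate,
                        double fixed_sigma2_e,
                        const arma::vec& init,
                        int n_iter, int burn_in, int thin) {
  const int n = y.n_elem;
  const int p = X.n_cols;
  const int K = nbrs.size();
  const bool sample_s2e = !std::isfinite(fixed_sigma2_e);

  // design with intercept
  arma::mat W(n, p + 1);
  if (n > 0) {
    W.col(0).ones();
    if (p > 0) W.cols(1, p) = X;
  }
  arma::mat WtW = W.t() * W;

  // per-ward observation bookkeeping
  std::vector<std::vector<int> > obs(K);
  arma::vec n_i(K, arma::fill::zeros);
  for (int j = 0; j < n; ++j) {
    obs[ward[j]].push_back(j);
    n_i[ward[j]] += 1.0;
  }

  // neighbour structure and unique edges
  std::vector<arma::uvec> nb(K);
  arma::vec nu(K, arma::fill::zeros);
  std::vector<std::pair<int,int> > edges;
  for (int i = 0; i < K; ++i) {
    IntegerVector v = nbrs[i];
    nb[i].set_size(v.size());
    for (int t = 0; t < v.size(); ++t) {
      nb[i][t] = v[t];
      if (v[t] > i) edges.push_back(std::make_pair(i, (int)v[t]));
    }
    nu[i] = (double)v.size();
  }
  int n_comp = comp.n_elem ? (int)comp.max() + 1 : 0;
  arma::vec comp_nward(std::max(n_comp, 1), arma::fill::zeros);
  arma::vec comp_nobs(std::max(n_comp, 1), arma::fill::zeros);
  for (int i = 0; i < K; ++i) {
    comp_nward[comp[i]] += 1.0;
    comp_nobs[comp[i]] += n_i[i];
  }

  // unpack initial state
  int pos = 0;
  arma::vec theta(p + 1);
  for (int t = 0; t < p + 1; ++t) theta[t] = init[pos++];
  arma::vec Rv(K, arma::fill::zeros), Sv(K, arma::fill::zeros);
  if (use_R) for (int i = 0; i < K; ++i) Rv[i] = init[pos++];
  if (use_S) for (int i = 0; i < K; ++i) Sv[i] = init[pos++];
  double s2e = init[pos++];
  double s2R = use_R ? init[pos++] : 0.0;
  double s2S = use_S ? init[pos++] : 0.0;
  if (!sample_s2e) s2e = fixed_sigma2_e;

  const double tau0_prec = 1.0 / (beta_prior_sd * beta_prior_sd);
  const int n_par = (p + 1) + (use_R ? K + 1 : 0) + (use_S ? K + 1 : 0) + 1;
  const int n_keep = (n_iter - burn_in) / thin;
  arma::mat out(n_keep, n_par + 1);

  arma::vec fit(n), resid0(n), wsum(K), wsum2(K);
  int keep = 0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    // --- (alpha, beta) joint conjugate normal draw ---
    arma::vec r = y;
    if (n > 0) {
      for (int j = 0; j < n; ++j) {
        if (use_R) r[j] -= Rv[ward[j]];
        if (use_S) r[j] -= Sv[ward[j]];
      }
    }
    arma::mat P = WtW / s2e;
    P.diag() += tau0_prec;
    arma::vec b = (n > 0) ? arma::vec(W.t() * r / s2e)
                          : arma::vec(p + 1, arma::fill::zeros);
    arma::mat U = arma::chol(P);                 // upper triangular
    arma::vec mean_th = arma::solve(arma::trimatu(U),
                        arma::solve(arma::trimatl(U.t()), b));
    arma::vec z(p + 1);
    for (int t = 0; t < p + 1; ++t) z[t] = norm_rand();
    theta = mean_th + arma::solve(arma::trimatu(U), z);

    if (n > 0) {
      fit = W * theta;
      resid0 = y - fit;
    }

    // --- unstructured ward effects R_i ---
    if (use_R) {
      wsum.zeros();
      for (int j = 0; j < n; ++j) {
        double e = resid0[j];
        if (use_S) e -= Sv[ward[j]];
        wsum[ward[j]] += e;
      }
      for (int i = 0; i < K; ++i) {
        double prec = n_i[i] / s2e + 1.0 / s2R;
        double m = (wsum[i] / s2e) / prec;
        Rv[i] = m + norm_rand() / std::sqrt(prec);
      }
    }

    // --- ICAR spatial effects S_i: likelihood-tilted sequential scan ---
    if (use_S) {
      wsum2.zeros();
      for (int j = 0; j < n; ++j) {
        double e = resid0[j];
        if (use_R) e -= Rv[ward[j]];
        wsum2[ward[j]] += e;
      }
      for (int i = 0; i < K; ++i) {
        if (nu[i] == 0.0) { Sv[i] = 0.0; continue; }   // island: pinned at zero
        double sbar = 0.0;
        for (unsigned int t = 0; t < nb[i].n_elem; ++t) sbar += Sv[nb[i][t]];
        sbar /= nu[i];
        double prec = n_i[i] / s2e + nu[i] / s2S;
        double m = (wsum2[i] / s2e + (nu[i] / s2S) * sbar) / prec;
        Sv[i] = m + norm_rand() / std::sqrt(prec);
      }
      // sum-to-zero per component; absorb the weighted shift into alpha
      arma::vec m_c(n_comp, arma::fill::zeros);
      for (int i = 0; i < K; ++i) m_c[comp[i]] += Sv[i];
      for (int c = 0; c < n_comp; ++c) m_c[c] /= comp_nward[c];
      double shift = 0.0;
      for (int c = 0; c < n_comp; ++c) shift += comp_nobs[c] * m_c[c];
      if (n > 0) shift /= (double)n; else shift = 0.0;
      for (int i = 0; i < K; ++i) Sv[i] -= m_c[comp[i]];
      theta[0] += shift;
      if (n > 0) { fit = W * theta; resid0 = y - fit; }
    }

    // --- variance components ---
    double ss = 0.0;
    for (int j = 0; j < n; ++j) {
      double e = resid0[j];
      if (use_R) e -= Rv[ward[j]];
      if (use_S) e -= Sv[ward[j]];
      ss += e * e;
    }
    if (sample_s2e)
      s2e = draw_variance(n, ss, var_prior_type, unif_upper, g_shape, g_rate);
    if (use_R) {
      double ssR = arma::dot(Rv, Rv);
      s2R = draw_variance(K, ssR, var_prior_type, unif_upper, g_shape, g_rate);
    }
    if (use_S) {
      double ssS = 0.0;
      for (size_t t = 0; t < edges.size(); ++t) {
        double d = Sv[edges[t].first] - Sv[edges[t].second];
        ssS += d * d;
      }
      s2S = draw_variance(K - n_comp, ssS, var_prior_type, unif_upper,
                          g_shape, g_rate);
    }

    double dev = (n > 0) ? n * std::log(2.0 * M_PI * s2e) + ss / s2e : 0.0;
    if (!std::isfinite(dev) || !std::isfinite(s2e))
      stop("sampler diverged (non-finite deviance) at iteration %d", iter);

    if (iter > burn_in && (iter - burn_in) % thin == 0) {
      int q = 0;
      for (int t = 0; t < p + 1; ++t) out(keep, q++) = theta[t];
      if (use_R) for (int i = 0; i < K; ++i) out(keep, q++) = Rv[i];
      if (use_S) for (int i = 0; i < K; ++i) out(keep, q++) = Sv[i];
      out(keep, q++) = s2e;
      if (use_R) out(keep, q++) = s2R;
      if (use_S) out(keep, q++) = s2S;
      out(keep, q++) = dev;
      ++keep;
    }
  }
  return out;
}
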