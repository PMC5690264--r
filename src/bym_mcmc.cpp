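#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for the Poisson BYM convolution model
//
//   Y_i ~ Poisson(lambda_i),  log lambda_i = log E_i + alpha + x_i'beta + S_i + U_i
//   U_i ~ Normal(0, nu_u)
//   S   ~ intrinsic CAR with symmetric weights w_ij, density
//         prop.to exp( -(1/(2 nu_s)) sum_{i<j} w_ij (S_i - S_j)^2 )
//   1/nu_u, 1/nu_s ~ Gamma(shape, rate); alpha flat; beta_q ~ Normal(0, beta_var)
//
// Scalar random-walk Metropolis for alpha, beta, S_i, U_i with per-parameter
// step sizes adapted toward a target acceptance rate during burn-in only;
// conjugate Gibbs draws for the two precisions.  S is recentred to sum to
// zero after each sweep, the shift being absorbed into alpha (valid under
// the flat prior on alpha).  All randomness comes from R's RNG, so chains
// are bit-reproducible under set.seed().

static inline double sq(double x) { return x * x; }

static double pairwise_sum(const std::vector<double> &S,
                           const IntegerVector &edge_i,
                           const IntegerVector &edge_j,
                           const NumericVector &edge_w) {
  double acc = 0.0;
  const int m = edge_i.size();
  for (int e = 0; e < m; ++e)
    acc += edge_w[e] * sq(S[edge_i[e]] - S[edge_j[e]]);
  return acc;
}

// precision full conditional: Gamma(shape + (n-1)/2, rate + pairsum/2)
static inline double draw_tau_s(double shape, double rate, int n, double pairsum) {
  return R::rgamma(shape + (n - 1) / 2.0, 1.0 / (rate + 0.5 * pairsum));
}

static inline double draw_tau_u(double shape, double rate, int n, double ssq) {
  return R::rgamma(shape + n / 2.0, 1.0 / (rate + 0.5 * ssq));
}

// Exposes the sampler's own tau_s Gibbs update (same code path as the chain)
// so its parameterisation can be checked against closed-form Gamma moments.
// [[Rcpp::export]]
NumericVector tau_s_gibbs_draws(NumericVector S,
                                IntegerVector edge_i, IntegerVector edge_j,
                                NumericVector edge_w,
                                double shape, double rate, int n_draws) {
  std::vector<double> s(S.begin(), S.end());
  const double pairsum = pairwise_sum(s, edge_i, edge_j, edge_w);
  const int n = S.size();
  NumericVector out(n_draws);
  for (int t = 0; t < n_draws; ++t)
    out[t] = draw_tau_s(shape, rate, n, pairsum);
  return out;
}

// [[Rcpp::export]]
List bym_mcmc_chain(IntegerVector Y, NumericVector E, NumericMatrix X,
                    List nbr_index, List nbr_weight, NumericVector w_plus,
                    IntegerVector edge_i, IntegerVector edge_j, NumericVector edge_w,
                    double beta_var, double prior_shape, double prior_rate,
                    int n_burn, int n_keep, int thin,
                    int adapt_window, double target_acc,
                    double init_alpha) {
  const int n = Y.size();
  const int q = X.ncol();
  if (n_keep < 1 || thin < 1 || n_burn < 0) stop("invalid sampler configuration");

  // adjacency in plain C++ containers (0-based)
  std::vector< std::vector<int> > nbrs(n);
  std::vector< std::vector<double> > nbw(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector ni = nbr_index[i];
    NumericVector wi = nbr_weight[i];
    nbrs[i].assign(ni.begin(), ni.end());
    nbw[i].assign(wi.begin(), wi.end());
  }

  // state
  double alpha = init_alpha;
  std::vector<double> beta(q, 0.0), S(n, 0.0), U(n, 0.0), xb(n, 0.0);
  double nu_s = 0.1, nu_u = 0.1;
  std::vector<double> sumYx(q, 0.0);
  double sumY = 0.0;
  for (int i = 0; i < n; ++i) {
    sumY += Y[i];
    for (int k = 0; k < q; ++k) sumYx[k] += Y[i] * X(i, k);
  }

  // adaptive step sizes (log scale) and window acceptance counters
  std::vector<double> ls_S(n, log(0.1)), ls_U(n, log(0.1));
  double ls_a = log(0.1);
  std::vector<double> ls_b(q, log(0.05));
  std::vector<int> acc_S(n, 0), acc_U(n, 0);
  int acc_a = 0;
  std::vector<int> acc_b(q, 0);

  NumericVector out_alpha(n_keep), out_nus(n_keep), out_nuu(n_keep);
  NumericMatrix out_beta(n_keep, q), out_S(n_keep, n), out_U(n_keep, n);
  long long tot_acc_S = 0, tot_prop_S = 0, tot_acc_U = 0;
  const int n_iter = n_burn + n_keep * thin;

  RNGScope scope;
  int kept = 0, window = 0;
  for (int it = 1; it <= n_iter; ++it) {
    const bool adapting = it <= n_burn;

    // --- S updates (pairwise-difference form of the ICAR conditional) ---
    for (int i = 0; i < n; ++i) {
      const double step = exp(ls_S[i]);
      const double cur = S[i];
      const double prop = cur + step * norm_rand();
      double dprior = 0.0;
      for (size_t k = 0; k < nbrs[i].size(); ++k) {
        const double sj = S[nbrs[i][k]];
        dprior += nbw[i][k] * (sq(prop - sj) - sq(cur - sj));
      }
      const double mu = E[i] * exp(alpha + xb[i] + U[i]);
      const double lr = Y[i] * (prop - cur) - mu * (exp(prop) - exp(cur))
                        - dprior / (2.0 * nu_s);
      tot_prop_S++;
      if (log(unif_rand()) < lr) { S[i] = prop; acc_S[i]++; tot_acc_S++; }
    }
    // recentre; shift absorbed into the intercept
    double mS = 0.0;
    for (int i = 0; i < n; ++i) mS += S[i];
    mS /= n;
    for (int i = 0; i < n; ++i) S[i] -= mS;
    alpha += mS;

    // --- U updates ---
    for (int i = 0; i < n; ++i) {
      const double step = exp(ls_U[i]);
      const double cur = U[i];
      const double prop = cur + step * norm_rand();
      const double mu = E[i] * exp(alpha + xb[i] + S[i]);
      const double lr = Y[i] * (prop - cur) - mu * (exp(prop) - exp(cur))
                        - (sq(prop) - sq(cur)) / (2.0 * nu_u);
      if (log(unif_rand()) < lr) { U[i] = prop; acc_U[i]++; tot_acc_U++; }
    }

    // --- alpha (flat prior) ---
    {
      double sumLam = 0.0;
      for (int i = 0; i < n; ++i) sumLam += E[i] * exp(alpha + xb[i] + S[i] + U[i]);
      const double prop = alpha + exp(ls_a) * norm_rand();
      const double lr = sumY * (prop - alpha) - (exp(prop - alpha) - 1.0) * sumLam;
      if (log(unif_rand()) < lr) { alpha = prop; acc_a++; }
    }

    // --- beta (independent Normal(0, beta_var) priors) ---
    for (int k = 0; k < q; ++k) {
      const double cur = beta[k];
      const double prop = cur + exp(ls_b[k]) * norm_rand();
      const double db = prop - cur;
      double dlik = sumYx[k] * db;
      for (int i = 0; i < n; ++i) {
        const double lam = E[i] * exp(alpha + xb[i] + S[i] + U[i]);
        dlik -= lam * (exp(X(i, k) * db) - 1.0);
      }
      const double lr = dlik - (sq(prop) - sq(cur)) / (2.0 * beta_var);
      if (log(unif_rand()) < lr) {
        beta[k] = prop;
        for (int i = 0; i < n; ++i) xb[i] += X(i, k) * db;
        acc_b[k]++;
      }
    }

    // --- conjugate precision updates ---
    double ssqU = 0.0;
    for (int i = 0; i < n; ++i) ssqU += sq(U[i]);
    nu_u = 1.0 / draw_tau_u(prior_shape, prior_rate, n, ssqU);
    const double pairsum = pairwise_sum(S, edge_i, edge_j, edge_w);
    nu_s = 1.0 / draw_tau_s(prior_shape, prior_rate, n, pairsum);

    if (!R_finite(alpha) || !R_finite(nu_s) || !R_finite(nu_u))
      stop("non-finite log-posterior state at iteration %d", it);

    // --- adaptation (burn-in only; frozen afterwards) ---
    if (adapting && it % adapt_window == 0) {
      window++;
      const double gain = 1.0 / sqrt((double) window);
      for (int i = 0; i < n; ++i) {
        ls_S[i] += gain * ((double) acc_S[i] / adapt_window - target_acc);
        ls_U[i] += gain * ((double) acc_U[i] / adapt_window - target_acc);
        if (ls_S[i] < -12) ls_S[i] = -12; if (ls_S[i] > 4) ls_S[i] = 4;
        if (ls_U[i] < -12) ls_U[i] = -12; if (ls_U[i] > 4) ls_U[i] = 4;
        acc_S[i] = 0; acc_U[i] = 0;
      }
      ls_a += gain * ((double) acc_a / adapt_window - target_acc);
      if (ls_a < -12) ls_a = -12; if (ls_a > 4) ls_a = 4;
      acc_a = 0;
      for (int k = 0; k < q; ++k) {
        ls_b[k] += gain * ((double) acc_b[k] / adapt_window - target_acc);
        if (ls_b[k] < -12) ls_b[k] = -12; if (ls_b[k] > 4) ls_b[k] = 4;
        acc_b[k] = 0;
      }
    }

    // --- retention ---
    if (it > n_burn && (it - n_burn) % thin == 0) {
      out_alpha[kept] = alpha;
      out_nus[kept] = nu_s;
      out_nuu[kept] = nu_u;
      for (int k = 0; k < q; ++k) out_beta(kept, k) = beta[k];
      for (int i = 0; i < n; ++i) { out_S(kept, i) = S[i]; out_U(kept, i) = U[i]; }
      kept++;
    }
  }

  return List::create(
    _["alpha"] = out_alpha, _["beta"] = out_beta,
    _["S"] = out_S, _["U"] = out_U,
    _["nu_s"] = out_nus, _["nu_u"] = out_nuu,
    _["accept"] = List::create(
      _["S"] = (double) tot_acc_S / tot_prop_S,
      _["U"] = (double) tot_acc_U / tot_prop_S));
}
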