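#include <Rcpp.h>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for the mating model:
//   pi_ij  = F_j u_ij / sum_k F_k u_ik,   u_ij = exp(-(a d_ij)^b), self -> 0
//   loglik = sum_ij n_ij (theta_j + log u_ij) - sum_i A_i log W_i
// with theta_j = log F_j ~ N(-sigma2/2, sigma2), Gamma priors on a, b and on
// the precision 1/sigma2. Log-scale random walks for a, b and each theta_j;
// sigma2 updated by independence MH with the precision's Gamma conditional at
// the current mean as proposal. Proposal scales adapt towards ~28% acceptance
// during burn-in only. Uses R's RNG so set.seed() governs reproducibility.

struct LikState {
  double S;                // sum over nonzero cells of n_ij log u_ij
  std::vector<double> W;   // per-mother weight totals (only mothers with A>0)
};

static void compute_u(const NumericMatrix& dist, const LogicalMatrix& self,
                      double a, double b, NumericMatrix& u) {
  int M = dist.nrow(), J = dist.ncol();
  for (int j = 0; j < J; ++j)
    for (int i = 0; i < M; ++i)
      u(i, j) = self(i, j) ? 0.0 : std::exp(-std::pow(a * dist(i, j), b));
}

// [[Rcpp::export]]
List mcmc_chain_cpp(IntegerMatrix n, NumericMatrix dist, LogicalMatrix self,
                    int iterations, int burnin, int thin,
                    double a_init, double b_init, double sigma2_init,
                    NumericVector theta_init,
                    double prior_shape, double prior_rate) {
  const int M = n.nrow(), J = n.ncol();
  if (dist.nrow() != M || dist.ncol() != J) stop("dist/n dimension mismatch");

  std::vector<double> A(M, 0.0);
  std::vector<double> colN(J, 0.0);
  std::vector<int> nz_i, nz_j; std::vector<double> nz_n;
  for (int j = 0; j < J; ++j)
    for (int i = 0; i < M; ++i)
      if (n(i, j) > 0) {
        nz_i.push_back(i); nz_j.push_back(j); nz_n.push_back(n(i, j));
        A[i] += n(i, j); colN[j] += n(i, j);
      }

  double a = a_init, b = b_init, sigma2 = sigma2_init;
  std::vector<double> theta(theta_init.begin(), theta_init.end());
  if ((int)theta.size() != J) stop("theta_init length mismatch");
  std::vector<double> F(J);
  for (int j = 0; j < J; ++j) F[j] = std::exp(theta[j]);

  NumericMatrix u(M, J);
  compute_u(dist, self, a, b, u);

  // W_i = sum_j F_j u_ij, only needed for mothers with data
  std::vector<double> W(M, 0.0);
  auto recompute_W = [&]() {
    for (int i = 0; i < M; ++i) {
      double w = 0.0;
      for (int j = 0; j < J; ++j) w += F[j] * u(i, j);
      W[i] = w;
    }
  };
  recompute_W();

  auto loglik_ab = [&](const NumericMatrix& uu) {
    // data part that depends on (a, b): sum n log u - sum A log W(uu)
    double s = 0.0;
    for (size_t t = 0; t < nz_n.size(); ++t) {
      double v = uu(nz_i[t], nz_j[t]);
      if (v <= 0.0) return -std::numeric_limits<double>::infinity();
      s += nz_n[t] * std::log(v);
    }
    for (int i = 0; i < M; ++i) {
      if (A[i] == 0.0) continue;
      double w = 0.0;
      for (int j = 0; j < J; ++j) w += F[j] * uu(i, j);
      if (w <= 0.0) return -std::numeric_limits<double>::infinity();
      s -= A[i] * std::log(w);
    }
    return s;
  };

  // log target for a log-scale kernel parameter x (Gamma prior + Jacobian)
  auto lprior_log = [&](double x) {
    return prior_shape * std::log(x) - prior_rate * x;
  };

  double s_a = 0.3, s_b = 0.3, s_s = 0.5;
  std::vector<double> s_f(J, 0.8);
  double acc_a = 0, acc_b = 0, acc_s = 0, acc_f = 0;
  long n_ab = 0, n_s = 0, n_f = 0;

  double cur_ab = loglik_ab(u);
  if (!std::isfinite(cur_ab)) stop("non-finite likelihood at initial values");

  const int total = burnin + iterations;
  const int keep = iterations / thin;
  NumericMatrix draws(keep, 3 + J);
  int stored = 0;
  NumericMatrix u_prop(M, J);

  for (int it = 0; it < total; ++it) {
    const bool adapting = it < burnin;
    const double gam = 2.0 / std::sqrt((double)it + 10.0);

    // --- a, then b: log random walks ----------------------------------
    for (int par = 0; par < 2; ++par) {
      double cur = par == 0 ? a : b;
      double sc = par == 0 ? s_a : s_b;
      double prop = cur * std::exp(sc * R::norm_rand());
      double a_new = par == 0 ? prop : a;
      double b_new = par == 0 ? b : prop;
      compute_u(dist, self, a_new, b_new, u_prop);
      double ll_new = loglik_ab(u_prop);
      double lr = ll_new - cur_ab + lprior_log(prop) - lprior_log(cur);
      bool ok = std::isfinite(ll_new) && std::log(R::unif_rand()) < lr;
      if (ok) {
        if (par == 0) a = prop; else b = prop;
        std::swap(u, u_prop);
        cur_ab = ll_new;
        recompute_W();
        if (par == 0) acc_a++; else acc_b++;
      }
      if (adapting) {
        double& sc_ref = par == 0 ? s_a : s_b;
        sc_ref *= std::exp(gam * ((ok ? 1.0 : 0.0) - 0.28));
        sc_ref = std::min(std::max(sc_ref, 1e-3), 10.0);
      }
      n_ab++;
    }

    // --- theta_j (log fecundities) ------------------------------------
    for (int j = 0; j < J; ++j) {
      double th_new = theta[j] + s_f[j] * R::norm_rand();
      double F_new = std::exp(th_new);
      double dF = F_new - F[j];
      double dll = colN[j] * (th_new - theta[j]);
      bool fin = true;
      for (int i = 0; i < M; ++i) {
        if (A[i] == 0.0) continue;
        double w_new = W[i] + dF * u(i, j);
        if (w_new <= 0.0) { fin = false; break; }
        dll -= A[i] * (std::log(w_new) - std::log(W[i]));
      }
      double mu = -sigma2 / 2.0;
      double dpr = (-(th_new - mu) * (th_new - mu) + (theta[j] - mu) * (theta[j] - mu)) /
                   (2.0 * sigma2);
      bool ok = fin && std::log(R::unif_rand()) < dll + dpr;
      if (ok) {
        for (int i = 0; i < M; ++i) W[i] += dF * u(i, j);
        // refresh cur_ab? cur_ab depends on W through loglik_ab; recompute lazily
        theta[j] = th_new; F[j] = F_new;
        acc_f++;
      }
      if (adapting) {
        s_f[j] *= std::exp(gam * ((ok ? 1.0 : 0.0) - 0.28));
        s_f[j] = std::min(std::max(s_f[j], 1e-3), 10.0);
      }
      n_f++;
    }
    // keep cached (a,b) data log-likelihood in sync with updated F
    cur_ab = loglik_ab(u);

    // --- sigma2: independence MH via the precision's Gamma conditional -
    {
      double tau = 1.0 / sigma2;
      auto rate_at = [&](double tau_v) {
        double mu = -1.0 / (2.0 * tau_v);
        double ssq = 0.0;
        for (int j = 0; j < J; ++j) ssq += (theta[j] - mu) * (theta[j] - mu);
        return prior_rate + 0.5 * ssq;
      };
      auto ltarget = [&](double tau_v) {
        double mu = -1.0 / (2.0 * tau_v);
        double s = (prior_shape - 1.0) * std::log(tau_v) - prior_rate * tau_v;
        double ssq = 0.0;
        for (int j = 0; j < J; ++j) ssq += (theta[j] - mu) * (theta[j] - mu);
        s += 0.5 * J * std::log(tau_v) - 0.5 * tau_v * ssq;
        return s;
      };
      double sh = prior_shape + 0.5 * J;
      double r_cur = rate_at(tau);
      double tau_new = R::rgamma(sh, 1.0 / r_cur);
      if (tau_new > 0 && std::isfinite(tau_new)) {
        double r_new = rate_at(tau_new);
        double lq_fwd = R::dgamma(tau_new, sh, 1.0 / r_cur, 1);
        double lq_bwd = R::dgamma(tau, sh, 1.0 / r_new, 1);
        double lr = ltarget(tau_new) - ltarget(tau) + lq_bwd - lq_fwd;
        if (std::log(R::unif_rand()) < lr) {
          sigma2 = 1.0 / tau_new;
          acc_s++;
        }
      }
      n_s++;
    }

    // --- store --------------------------------------------------------
    if (it >= burnin && ((it - burnin) % thin == thin - 1) && stored < keep) {
      draws(stored, 0) = a;
      draws(stored, 1) = b;
      draws(stored, 2) = sigma2;
      for (int j = 0; j < J; ++j) draws(stored, 3 + j) = F[j];
      ++stored;
    }
  }

  return List::create(
    _["draws"] = draws,
    _["accept"] = NumericVector::create(
      _["a"] = acc_a / (n_ab / 2.0), _["b"] = acc_b / (n_ab / 2.0),
      _["sigma2"] = n_s ? acc_s / (double)n_s : NA_REAL,
      _["F"] = n_f ? acc_f / (double)n_f : NA_REAL));
}

// Per-draw pollen-cloud functionals: for each posterior draw, the outcross
// mating probabilities pi_ij, the self-pollen share rho_i, and the effective
// numbers of pollen donors (global N_ep with seed-count weights, per-mother
// N_epi). The kernel's normalising constant cancels in every share.
// [[Rcpp::export]]
List derived_cloud_cpp(NumericVector a, NumericVector b, NumericMatrix Fmat,
                       NumericMatrix dist, LogicalMatrix self,
                       NumericVector n_i) {
  const int D = a.size();
  const int M = dist.nrow(), J = dist.ncol();
  if (Fmat.nrow() != D || Fmat.ncol() != J) stop("F draws dimension mismatch");
  double n_tot = 0.0;
  for (int i = 0; i < M; ++i) n_tot += n_i[i];
  NumericVector Nep(D);
  NumericMatrix Nepi(D, M), rho(D, M);
  std::vector<double> pi_row(J), q(J);

  for (int d = 0; d < D; ++d) {
    const double ad = a[d], bd = b[d];
    std::fill(q.begin(), q.end(), 0.0);
    for (int i = 0; i < M; ++i) {
      double tot = 0.0, self_w = 0.0;
      for (int j = 0; j < J; ++j) {
        double u = std::exp(-std::pow(ad * dist(i, j), bd));
        double w = Fmat(d, j) * u;
        if (self(i, j)) { self_w = w; pi_row[j] = 0.0; }
        else pi_row[j] = w;
        tot += w;
      }
      rho(d, i) = tot > 0 ? self_w / tot : NA_REAL;
      double out_tot = tot - self_w;
      double ssq = 0.0;
      if (out_tot > 0) {
        for (int j = 0; j < J; ++j) {
          double p = pi_row[j] / out_tot;
          ssq += p * p;
          if (n_tot > 0) q[j] += (n_i[i] / n_tot) * p;
        }
      }
      Nepi(d, i) = ssq > 0 ? 1.0 / ssq : NA_REAL;
    }
    double qq = 0.0;
    for (int j = 0; j < J; ++j) qq += q[j] * q[j];
    Nep[d] = qq > 0 ? 1.0 / qq : NA_REAL;
  }
  return List::create(_["N_ep"] = Nep, _["N_epi"] = Nepi, _["rho"] = rho);
}
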