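// Joint NB / ZINB model for monthly tick life-stage counts.
//
// Stages j = 0,1,2 (larvae, nymphs, adults). For observation o (one
// location x habitat x year x month cell) the linear predictor is
//
//   eta[o,j] = alpha_j + bsin_j sin(2 pi M/12) + bcos_j cos(2 pi M/12)
//            + bGrass g_o + bWoods w_o
//            + [j==1] blagL log(L_{t-1}+1) + [j==2] blagN log(N_{t-1}+1)
//            + gamma_{year(o)} + u_{loc(o), j} (+ offset)
//
// Y[o,j] ~ NB(mu = exp(eta), size phi_j), Var = mu + mu^2/phi; the ZINB
// family mixes in a structural zero with stage probability pi_j.
// gamma is an RW1 (or iid) year effect with precision tau_year and a
// soft sum-to-zero constraint; u_i is one trivariate normal per location
// with shared covariance Sigma (Cholesky-parameterized).
//
// Priors: Normal(0, beta_sd) on all regression coefficients; Gamma on
// phi_j and tau_year; inverse-Wishart(df, scale) on Sigma with the
// Cholesky-parameterization Jacobian; Beta on pi_j. The objective is the
// negative log joint posterior (up to constants), so the Laplace
// approximation targets the posterior, not the likelihood alone.

#define TMB_LIB_INIT R_init_tickstages
#include <TMB.hpp>

template <class Type>
Type nb_lpmf(Type y, Type mu, Type phi) {
  return lgamma(y + phi) - lgamma(phi) - lgamma(y + Type(1.0)) +
         phi * (log(phi) - log(phi + mu)) + y * (log(mu) - log(phi + mu));
}

template <class Type>
Type objective_function<Type>::operator()() {
  DATA_MATRIX(Y);        // n x 3 counts
  DATA_VECTOR(sin_t);    // n
  DATA_VECTOR(cos_t);    // n
  DATA_VECTOR(grass);    // n, 0/1
  DATA_VECTOR(woods);    // n, 0/1
  DATA_VECTOR(lagL);     // n, log(L_{t-1}+1); 0 where excluded
  DATA_VECTOR(lagN);     // n, log(N_{t-1}+1); 0 where excluded
  DATA_VECTOR(offs);     // n, log-offset (zeros when disabled)
  DATA_IVECTOR(year_i);  // n, 0-based year index
  DATA_IVECTOR(loc_i);   // n, 0-based location index
  DATA_MATRIX(incl);     // n x 3 likelihood inclusion indicators
  DATA_INTEGER(family);     // 0 = NB, 1 = ZINB
  DATA_INTEGER(year_mode);  // 0 = rw1, 1 = iid
  DATA_SCALAR(beta_sd);
  DATA_SCALAR(tau_shape);
  DATA_SCALAR(tau_rate);
  DATA_SCALAR(phi_shape);
  DATA_SCALAR(phi_rate);
  DATA_SCALAR(iw_df);
  DATA_MATRIX(iw_scale);  // 3 x 3
  DATA_SCALAR(pi_a);
  DATA_SCALAR(pi_b);

  PARAMETER_VECTOR(alpha);     // 3 stage intercepts
  PARAMETER_VECTOR(beta_sin);  // 3
  PARAMETER_VECTOR(beta_cos);  // 3
  PARAMETER(beta_grass);
  PARAMETER(beta_woods);
  PARAMETER(beta_lagL);
  PARAMETER(beta_lagN);
  PARAMETER_VECTOR(log_phi);      // 3
  PARAMETER(log_tau_year);
  PARAMETER_VECTOR(chol_diag);    // 3, log of Cholesky diagonal of Sigma
  PARAMETER_VECTOR(chol_off);     // 3, (L21, L31, L32)
  PARAMETER_VECTOR(logit_pi);     // 3, fixed (mapped) for NB
  PARAMETER_VECTOR(gamma);        // n_years, random
  PARAMETER_MATRIX(u);            // n_loc x 3, random

  int n = Y.rows();
  int n_years = gamma.size();
  int n_loc = u.rows();
  int p = 3;

  Type nll = Type(0.0);

  // --- location covariance Sigma = L L' -------------------------------
  matrix<Type> L(p, p);
  L.setZero();
  L(0, 0) = exp(chol_diag(0));
  L(1, 1) = exp(chol_diag(1));
  L(2, 2) = exp(chol_diag(2));
  L(1, 0) = chol_off(0);
  L(2, 0) = chol_off(1);
  L(2, 1) = chol_off(2);
  matrix<Type> Sigma = L * L.transpose();

  density::MVNORM_t<Type> mvn(Sigma);
  for (int i = 0; i < n_loc; i++) {
    vector<Type> ui = u.row(i);
    nll += mvn(ui);
  }

  // --- year effect -----------------------------------------------------
  Type tau_year = exp(log_tau_year);
  Type sd_year = sqrt(Type(1.0) / tau_year);
  if (year_mode == 0) {
    for (int t = 1; t < n_years; t++)
      nll -= dnorm(gamma(t), gamma(t - 1), sd_year, true);
  } else {
    for (int t = 0; t < n_years; t++)
      nll -= dnorm(gamma(t), Type(0.0), sd_year, true);
  }
  // soft sum-to-zero (identifiability with the intercepts)
  nll -= dnorm(gamma.sum(), Type(0.0), Type(1e-3), true);

  // --- observation model ----------------------------------------------
  vector<Type> phi = exp(log_phi);
  vector<Type> pi(p);
  for (int j = 0; j < p; j++) pi(j) = invlogit(logit_pi(j));

  for (int o = 0; o < n; o++) {
    for (int j = 0; j < p; j++) {
      if (incl(o, j) < Type(0.5)) continue;
      Type eta = alpha(j) + beta_sin(j) * sin_t(o) + beta_cos(j) * cos_t(o) +
                 beta_grass * grass(o) + beta_woods * woods(o) +
                 gamma(year_i(o)) + u(loc_i(o), j) + offs(o);
      if (j == 1) eta += beta_lagL * lagL(o);
      if (j == 2) eta += beta_lagN * lagN(o);
      Type mu = exp(eta);
      Type ll = nb_lpmf(Y(o, j), mu, phi(j));
      if (family == 1) {
        if (Y(o, j) < Type(0.5)) {
          ll = logspace_add(log(pi(j)), log(Type(1.0) - pi(j)) + ll);
        } else {
          ll += log(Type(1.0) - pi(j));
        }
      }
      nll -= ll;
    }
  }

  // --- priors ----------------------------------------------------------
  for (int j = 0; j < p; j++) {
    nll -= dnorm(alpha(j), Type(0.0), beta_sd, true);
    nll -= dnorm(beta_sin(j), Type(0.0), beta_sd, true);
    nll -= dnorm(beta_cos(j), Type(0.0), beta_sd, true);
  }
  nll -= dnorm(beta_grass, Type(0.0), beta_sd, true);
  nll -= dnorm(beta_woods, Type(0.0), beta_sd, true);
  nll -= dnorm(beta_lagL, Type(0.0), beta_sd, true);
  nll -= dnorm(beta_lagN, Type(0.0), beta_sd, true);

  // Gamma(shape, rate) priors on phi_j and tau_year, with log-scale Jacobian
  for (int j = 0; j < p; j++)
    nll -= dgamma(phi(j), phi_shape, Type(1.0) / phi_rate, true) + log_phi(j);
  nll -= dgamma(tau_year, tau_shape, Type(1.0) / tau_rate, true) + log_tau_year;

  // inverse-Wishart(df, scale) on Sigma (log density up to a constant):
  //   -((df+p+1)/2) log|Sigma| - 0.5 tr(scale Sigma^-1)
  // plus the Jacobian of Sigma = LL' with log-diagonal Cholesky:
  //   log|J| = p log 2 + sum_j (p + 2 - j) log L_jj   (j = 1..p)
  Type logdetSigma = Type(2.0) * (chol_diag(0) + chol_diag(1) + chol_diag(2));
  matrix<Type> Sigma_inv = atomic::matinv(Sigma);
  matrix<Type> SSi = iw_scale * Sigma_inv;
  Type trSSi = SSi(0, 0) + SSi(1, 1) + SSi(2, 2);
  nll -= -(iw_df + Type(p) + Type(1.0)) / Type(2.0) * logdetSigma -
         Type(0.5) * trSSi;
  nll -= Type(p) * log(Type(2.0)) + Type(4.0) * chol_diag(0) +
         Type(3.0) * chol_diag(1) + Type(2.0) * chol_diag(2);

  if (family == 1) {
    for (int j = 0; j < p; j++)
      nll -= dbeta(pi(j), pi_a, pi_b, true) + log(pi(j)) +
             log(Type(1.0) - pi(j));
  }

  REPORT(Sigma);
  return nll;
}
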