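// Survival-corrected Kalman filter + RTS smoother + M-step expectation
// assembly for one patient.  Mirrors the R reference implementation in
// R/inference.R / R/em.R (patient_stats_r) exactly; kept in C++ because the
// per-patient Newton-Raphson loop dominates EM runtime on cohort fits.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double LOG_HAZ_CLIP = 50.0;

static mat symm(const mat &S) { return 0.5 * (S + S.t()); }

// SPD solve via Cholesky with escalating diagonal jitter
static mat spd_solve(const mat &S, const mat &B, double jitter,
                     double jitter_max) {
  mat Ss = symm(S);
  double jit = 0.0;
  for (;;) {
    mat R;
    if (chol(R, Ss + jit * eye(S.n_rows, S.n_rows))) {
      return solve(trimatu(R), solve(trimatl(R.t()), B));
    }
    jit = (jit == 0.0) ? jitter : jit * 10.0;
    if (jit > jitter_max) {
      Rcpp::stop("matrix not positive definite even after jitter");
    }
  }
}

static double clip_eta(double eta) {
  if (eta > LOG_HAZ_CLIP) return LOG_HAZ_CLIP;
  if (eta < -LOG_HAZ_CLIP) return -LOG_HAZ_CLIP;
  return eta;
}

// [[Rcpp::export]]
Rcpp::List lsdsm_estep_cpp(const arma::mat &y, const arma::vec &omega,
                           const arma::vec &tau, const arma::vec &delta_bar,
                           const arma::mat &A, const arma::mat &W,
                           const arma::mat &C, const arma::mat &V,
                           const arma::vec &x1_bar, const arma::mat &W1_bar,
                           const arma::mat &H, const arma::vec &gamma,
                           const arma::vec &alpha, int nr_max_iter,
                           double nr_tol, int max_halvings, double jitter,
                           double jitter_max) {
  const uword m = y.n_rows, m_y = C.n_rows, m_x = C.n_cols, m_a = H.n_rows;
  const vec a = H.t() * alpha;
  const double g = dot(gamma, omega);
  const bool has_alpha = norm(a, "inf") > 0.0;

  cube P_pred(m_x, m_x, m), P_f(m_x, m_x, m);
  mat mu_pred(m_x, m), mu_f(m_x, m);
  double loglik_y = 0.0;

  vec mu_p = x1_bar;
  mat P_p = W1_bar;
  for (uword j = 0; j < m; ++j) {
    if (j > 0) {
      mu_p = A * mu_f.col(j - 1);
      P_p = symm(A * P_f.slice(j - 1) * A.t() + W);
    }
    mu_pred.col(j) = mu_p;
    P_pred.slice(j) = P_p;

    uvec obs = find_finite(y.row(j).t());
    vec mu_k = mu_p;
    mat P_k = P_p;
    if (obs.n_elem > 0) {
      mat C_o = C.rows(obs);
      mat V_oo = V.submat(obs, obs);
      mat S = symm(C_o * P_p * C_o.t() + V_oo);
      vec yo = y.row(j).t();
      yo = yo.elem(obs);
      vec r = yo - C_o * mu_p;
      double ldet, sign;
      log_det(ldet, sign, S);
      loglik_y += -0.5 * (obs.n_elem * std::log(2.0 * datum::pi) + ldet +
                          dot(r, spd_solve(S, r, jitter, jitter_max)));
      mat K = spd_solve(S, C_o * P_p, jitter, jitter_max).t();
      mu_k = mu_p + K * r;
      mat ImKC = eye(m_x, m_x) - K * C_o;
      P_k = symm(ImKC * P_p * ImKC.t() + K * V_oo * K.t());
    }
    // Laplace correction for the interval survival term.  The negative
    // Hessian is P_k^{-1} + h aa', so Newton steps and the final covariance
    // use the rank-one Sherman-Morrison identity on P_k: only one Cholesky
    // of P_k per grid step.
    if (has_alpha && (tau(j) > 0 || delta_bar(j) == 1)) {
      const mat Ps = symm(P_k);
      mat R;
      {
        double jit = 0.0;
        while (!chol(R, Ps + jit * eye(m_x, m_x))) {
          jit = (jit == 0.0) ? jitter : jit * 10.0;
          if (jit > jitter_max) Rcpp::stop("non-PD filtered covariance");
        }
      }
      const vec pa = Ps * a;
      const double apa = dot(a, pa);
      vec x = mu_k;
      auto pinv_d = [&](const vec &d) {
        return vec(solve(trimatu(R), solve(trimatl(R.t()), d)));
      };
      auto obj = [&](const vec &xx) {
        vec d = xx - mu_k;
        double eta = clip_eta(g + dot(a, xx));
        return -0.5 * dot(d, pinv_d(d)) + delta_bar(j) * dot(a, xx) -
               tau(j) * std::exp(eta);
      };
      double f0 = obj(x);
      for (int it = 0; it < nr_max_iter; ++it) {
        double h = tau(j) * std::exp(clip_eta(g + dot(a, x)));
        vec grad = -pinv_d(x - mu_k) + delta_bar(j) * a - h * a;
        // (P^{-1} + h aa')^{-1} grad = P grad - h/(1 + h a'Pa) pa (pa'grad)
        vec step = Ps * grad - (h / (1.0 + h * apa)) * pa * dot(pa, grad);
        double lam = 1.0, f1 = f0;
        for (int kk = 0; kk <= max_halvings; ++kk) {
          f1 = obj(x + lam * step);
          if (std::isfinite(f1) && f1 >= f0) break;
          lam *= 0.5;
        }
        x += lam * step;
        f0 = f1;
        if (norm(lam * step, "inf") < nr_tol) break;
      }
      double h = tau(j) * std::exp(clip_eta(g + dot(a, x)));
      mu_k = x;
      P_k = symm(Ps - (h / (1.0 + h * apa)) * (pa * pa.t()));
    }
    mu_f.col(j) = mu_k;
    P_f.slice(j) = P_k;
  }

  // RTS backward pass
  mat mu_hat(m_x, m);
  cube S_hat(m_x, m_x, m);
  cube J(m_x, m_x, m);  // J.slice(j) valid for j < m-1
  mu_hat.col(m - 1) = mu_f.col(m - 1);
  S_hat.slice(m - 1) = P_f.slice(m - 1);
  for (uword jj = m - 1; jj-- > 0;) {
    mat Jj = spd_solve(P_pred.slice(jj + 1), A * P_f.slice(jj), jitter,
                       jitter_max).t();
    J.slice(jj) = Jj;
    mu_hat.col(jj) = mu_f.col(jj) +
      Jj * (mu_hat.col(jj + 1) - mu_pred.col(jj + 1));
    S_hat.slice(jj) = symm(P_f.slice(jj) +
      Jj * (S_hat.slice(jj + 1) - P_pred.slice(jj + 1)) * Jj.t());
  }

  // expectation sums
  mat S11(m_x, m_x, fill::zeros), Sxx(m_x, m_x, fill::zeros);
  mat S10s(m_y, m_x, fill::zeros), S00s(m_y, m_y, fill::zeros);
  mat Syy(m_y, m_y, fill::zeros), Syx(m_y, m_x, fill::zeros);
  mat b(m, m_a), s(m, m_a * m_a), b_f(m, m_a), s_f(m, m_a * m_a);
  mat Ex1x1 = S_hat.slice(0) + mu_hat.col(0) * mu_hat.col(0).t();

  for (uword j = 0; j < m; ++j) {
    mat Exx_j = S_hat.slice(j) + mu_hat.col(j) * mu_hat.col(j).t();
    Sxx += Exx_j;
    if (j > 0) {
      S11 += S_hat.slice(j - 1) + mu_hat.col(j - 1) * mu_hat.col(j - 1).t();
      mat lag = S_hat.slice(j) * J.slice(j - 1).t() +
        mu_hat.col(j) * mu_hat.col(j - 1).t();
      S10s += lag.rows(0, m_y - 1);
      S00s += Exx_j.submat(0, 0, m_y - 1, m_y - 1);
    }
    // observation expectations with missing-data corrections
    uvec obs = find_finite(y.row(j).t());
    vec Ey(m_y);
    mat Eyy(m_y, m_y), Eyx(m_y, m_x);
    if (obs.n_elem == m_y) {
      Ey = y.row(j).t();
      Eyy = Ey * Ey.t();
      Eyx = Ey * mu_hat.col(j).t();
    } else {
      vec y0 = y.row(j).t();
      y0.replace(datum::nan, 0.0);
      mat nabla;
      if (obs.n_elem > 0) {
        mat Omega = eye(m_y, m_y);
        Omega = Omega.rows(obs);
        nabla = eye(m_y, m_y) -
          V.cols(obs) * spd_solve(V.submat(obs, obs), Omega, jitter,
                                  jitter_max);
      } else {
        nabla = eye(m_y, m_y);
      }
      vec I_M_diag(m_y, fill::ones);
      I_M_diag.elem(obs).zeros();
      mat I_M = diagmat(I_M_diag);
      Ey = y0 - nabla * (y0 - C * mu_hat.col(j));
      Eyy = I_M * (nabla * V +
                   nabla * C * S_hat.slice(j) * C.t() * nabla.t()) * I_M +
        Ey * Ey.t();
      Eyy = symm(Eyy);
      Eyx = nabla * C * S_hat.slice(j) + Ey * mu_hat.col(j).t();
    }
    Syy += Eyy;
    Syx += Eyx;
    b.row(j) = (H * mu_hat.col(j)).t();
    s.row(j) = vectorise(H * S_hat.slice(j) * H.t()).t();
    b_f.row(j) = (H * mu_f.col(j)).t();
    s_f.row(j) = vectorise(H * P_f.slice(j) * H.t()).t();
  }

  return Rcpp::List::create(
      Rcpp::Named("mu1") = mu_hat.col(0),
      Rcpp::Named("Ex1x1") = Ex1x1,
      Rcpp::Named("S11") = S11, Rcpp::Named("S10s") = S10s,
      Rcpp::Named("S00s") = S00s, Rcpp::Named("Sxx") = Sxx,
      Rcpp::Named("Syy") = Syy, Rcpp::Named("Syx") = Syx,
      Rcpp::Named("b") = b, Rcpp::Named("s") = s,
      Rcpp::Named("b_f") = b_f, Rcpp::Named("s_f") = s_f,
      Rcpp::Named("loglik_y") = loglik_y,
      Rcpp::Named("mu_hat") = mat(mu_hat.t()),
      Rcpp::Named("mu_f") = mat(mu_f.t()));
}
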