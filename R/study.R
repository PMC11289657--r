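#' Tracked trajectories and model survival curves for a cohort
#'
#' Runs the survival-corrected filter (and smoother) for every patient under
#' the supplied parameters and returns the leading-state trajectory estimate
#' together with the corresponding piecewise-exponential survival curve in
#' which each interval's hazard is the model's expected hazard
#' `exp(gamma' omega) E[exp(alpha' H x_j)]`, the expectation taken under the
#' per-step state belief by the Gaussian moment formula.  The default
#' `"filtered"` type tracks online (belief given data up to each step), the
#' quantity the simulation-study tracking tables report; `"smoothed"` uses
#' the full-record posterior instead.
#'
#' @param cohort An `lsdsm_cohort`.
#' @param params An [lsdsm_params()] object (fitted or true).
#' @param control An [fit_control()] (supplies the engine and Newton
#'   settings).
#' @param type `"filtered"` (default) or `"smoothed"` state beliefs.
#' @return List with `mu1` (per-patient matrices of leading-state estimates,
#'   `m` x `m_y`) and `survival` (per-patient survival curves at the ends of
#'   intervals `1..m`).
#' @export
track_cohort <- function(cohort, params, control = fit_control(),
                         type = c("filtered", "smoothed")) {
  type <- match.arg(type)
  m_y <- params$structure$m_y
  m_a <- params$structure$m_alpha
  alpha <- params$alpha
  aa <- as.numeric(outer(alpha, alpha))
  mu1 <- vector("list", length(cohort))
  surv <- vector("list", length(cohort))
  engine <- if (control$engine == "cpp") patient_stats_cpp else patient_stats_r
  for (i in seq_along(cohort)) {
    p <- cohort[[i]]
    ps <- engine(p, params, control$nr)
    mu <- matrix(if (type == "filtered") ps$mu_f else ps$mu_hat, nrow = p$m)
    bb <- matrix(if (type == "filtered") ps$b_f else ps$b, nrow = p$m)
    ss <- matrix(if (type == "filtered") ps$s_f else ps$s, nrow = p$m)
    mu1[[i]] <- mu[, seq_len(m_y), drop = FALSE]
    eta <- clip_log_hazard(
      sum(params$gamma * p$omega) + as.numeric(bb %*% alpha) +
        0.5 * as.numeric(ss %*% aa))
    surv[[i]] <- exp(-cumsum(p$tau * exp(eta)))
  }
  list(mu1 = mu1, survival = surv)
}

#' Replicated simulation study: parameter recovery and tracking RMSE
#'
#' The end-to-end driver behind the simulation-study tables: for each
#' replicate it simulates a training cohort from the default generating
#' model, fits it by EM, records the parameter estimates, and (optionally)
#' computes the pooled RMSE of the smoothed leading state against the true
#' latent state and of the plug-in survival curve against the true survival
#' curve - under both the estimated and the true parameters, the latter
#' isolating the inference machinery from estimation error.
#'
#' @param R Number of replicates.
#' @param n Patients per replicate cohort (default 500).
#' @param missing_pct Missingness fraction (default 0).
#' @param seed Master seed; replicate `r` uses `seed + 104729 * r`.
#' @param control An [fit_control()].
#' @param init `"truth"` (default) starts each EM run at the generating
#'   parameter values, reproducing the published study's convergence
#'   behaviour (convergence in a few tens of iterations; the EM surface has
#'   a very flat ridge along which far-started runs crawl for hundreds of
#'   iterations before the elementwise stopping rule fires); `"default"`
#'   uses the data-driven [initialize_params()] policy.
#' @param rmse Also compute tracking RMSEs (default `TRUE`).
#' @param test Also simulate an equally sized test cohort per replicate and
#'   report its RMSEs under the same fitted parameters (default `FALSE`).
#' @return Data frame with one row per replicate: estimates `A11`, `A12`,
#'   `W_breve`, `V`, `gamma1`, `gamma2`, `alpha1`, fit diagnostics `n_iter`,
#'   `converged`, and (if requested) `rmse_mu1_est`, `rmse_mu1_true`,
#'   `rmse_surv_est`, `rmse_surv_true` (plus `_test` variants).
#' @export
sim_study <- function(R, n = 500L, missing_pct = 0, seed = 1L,
                      control = fit_control(), init = c("truth", "default"),
                      rmse = TRUE, test = FALSE) {
  init <- match.arg(init)
  truth <- true_model()
  st <- truth$structure
  rows <- vector("list", R)
  for (r in seq_len(R)) {
    sc <- sim_config(n = n, missing_pct = missing_pct,
                     seed = seed + 104729L * r)
    cohort <- simulate_cohort(truth, sc)
    fit <- lsdsm_fit(cohort, st, control,
                     init = if (init == "truth") truth else NULL)
    est <- fit$params
    row <- data.frame(replicate = r,
                      A11 = est$A_bar[1L, 1L], A12 = est$A_bar[1L, 2L],
                      W_breve = est$W_breve[1L, 1L], V = est$V[1L, 1L],
                      gamma1 = est$gamma[1L], gamma2 = est$gamma[2L],
                      alpha1 = est$alpha[1L],
                      n_iter = fit$n_iter, converged = fit$converged)
    if (rmse) {
      row <- cbind(row, cohort_rmse(cohort, est, truth, control, ""))
      if (test) {
        tc <- simulate_cohort(truth, sim_config(
          n = n, missing_pct = missing_pct, seed = seed + 104729L * r + 52361L))
        row <- cbind(row, cohort_rmse(tc, est, truth, control, "_test"))
      }
    }
    rows[[r]] <- row
  }
  do.call(rbind, rows)
}

cohort_rmse <- function(cohort, est, truth, control, suffix) {
  latent1 <- lapply(attr(cohort, "latent"), function(x) x[, 1L])
  true_surv <- attr(cohort, "true_survival")
  sm_e <- track_cohort(cohort, est, control)
  sm_t <- track_cohort(cohort, truth, control)
  out <- data.frame(
    a = rmse_trajectory(sm_e$mu1, latent1),
    b = rmse_trajectory(sm_t$mu1, latent1),
    c = rmse_survival(sm_e$survival, true_surv),
    d = rmse_survival(sm_t$survival, true_surv))
  names(out) <- paste0(c("rmse_mu1_est", "rmse_mu1_true",
                         "rmse_surv_est", "rmse_surv_true"), suffix)
  out
}
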