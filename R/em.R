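#' EM fitting controls
#'
#' @param tol Convergence threshold: maximum absolute elementwise change
#'   across all parameter arrays between successive EM iterations
#'   (default 5e-4).
#' @param max_iter EM iteration cap (default 600); reaching it without
#'   meeting `tol` is reported as failure to converge.
#' @param nr Inner Newton-Raphson settings, an [nr_control()] list (shared by
#'   the state-posterior Laplace approximation and the survival M-step).
#' @param update_survival Update `gamma`/`alpha` in the M-step (default
#'   `TRUE`).  With `FALSE` they stay at their initial values; combined with
#'   `alpha = 0` this makes the whole fit an exact linear-Gaussian EM.
#' @param engine `"cpp"` (compiled per-patient E-step, default) or `"r"`
#'   (reference implementation); both produce identical results to numerical
#'   precision.
#' @param verbose Print one line per EM iteration.
#' @return A list of class `lsdsm_fit_control`.
#' @export
fit_control <- function(tol = 5e-4, max_iter = 600L, nr = nr_control(),
                        update_survival = TRUE, engine = c("cpp", "r"),
                        verbose = FALSE) {
  stopifnot(tol >= 0, max_iter >= 1)
  structure(list(tol = tol, max_iter = as.integer(max_iter), nr = nr,
                 update_survival = isTRUE(update_survival),
                 engine = match.arg(engine), verbose = isTRUE(verbose)),
            class = "lsdsm_fit_control")
}

# per-patient sufficient statistics (R reference engine)
patient_stats_r <- function(patient, params, ctrl) {
  sm <- lsdsm_smooth(patient, params, ctrl)
  m <- patient$m
  m_y <- params$structure$m_y
  m_x <- params$structure$m_x
  H <- params$structure$H
  C <- params$structure$C
  S11 <- matrix(0, m_x, m_x)
  S10s <- matrix(0, m_y, m_x)
  S00s <- matrix(0, m_y, m_y)
  Sxx <- matrix(0, m_x, m_x)
  Syy <- matrix(0, m_y, m_y)
  Syx <- matrix(0, m_y, m_x)
  b <- matrix(0, m, nrow(H))
  s <- matrix(0, m, nrow(H)^2)
  b_f <- matrix(0, m, nrow(H))
  s_f <- matrix(0, m, nrow(H)^2)
  filtered <- attr(sm, "filtered")
  for (j in seq_len(m)) {
    Exx_j <- sm$Exx[[j]]
    Sxx <- Sxx + Exx_j
    if (j > 1L) {
      S11 <- S11 + sm$Exx[[j - 1L]]
      S10s <- S10s + sm$Exx_lag[[j]][seq_len(m_y), , drop = FALSE]
      S00s <- S00s + Exx_j[seq_len(m_y), seq_len(m_y), drop = FALSE]
    }
    ob <- expected_observation_moments(
      patient$y[j, ], list(mu = sm$mu_hat[j, ], Sigma = sm$Sigma_hat[[j]]),
      params)
    Syy <- Syy + ob$Eyy
    Syx <- Syx + ob$Eyx
    b[j, ] <- as.numeric(H %*% sm$mu_hat[j, ])
    s[j, ] <- as.numeric(H %*% sm$Sigma_hat[[j]] %*% t(H))
    b_f[j, ] <- as.numeric(H %*% filtered[[j]]$mu)
    s_f[j, ] <- as.numeric(H %*% filtered[[j]]$Sigma %*% t(H))
  }
  list(mu1 = sm$mu_hat[1L, ], Ex1x1 = sm$Exx[[1L]],
       S11 = S11, S10s = S10s, S00s = S00s,
       Sxx = Sxx, Syy = Syy, Syx = Syx, m = m,
       b = b, s = s, b_f = b_f, s_f = s_f,
       loglik_y = attr(sm, "loglik_y"),
       mu_hat = sm$mu_hat,
       mu_f = matrix(unlist(lapply(filtered, `[[`, "mu")),
                     ncol = m_x, byrow = TRUE))
}

patient_stats_cpp <- function(patient, params, ctrl) {
  out <- lsdsm_estep_cpp(
    patient$y, patient$omega, patient$tau, as.numeric(patient$delta_bar),
    assemble_A(params), assemble_W(params), params$structure$C, params$V,
    params$x1_bar, params$W1_bar, params$structure$H, params$gamma,
    params$alpha, ctrl$max_iter, ctrl$tol, ctrl$max_halvings,
    ctrl$jitter, ctrl$jitter_max)
  out
}

#' E-step: pooled sufficient statistics over a cohort
#'
#' Runs the survival-corrected filter, the RTS smoother and the
#' missing-observation expectation formulas for every patient and pools the
#' sums the closed-form M-step and the survival objective need.  Per-patient
#' failures abort with the patient id attached.
#'
#' @param cohort An `lsdsm_cohort` (or plain list of `lsdsm_patient`s).
#' @param params Current parameter iterate, an [lsdsm_params()] object.
#' @param control An [fit_control()] list.
#' @return A list of class `lsdsm_suffstats` holding the pooled sums
#'   (`sum_mu1`, `sum_Ex1x1`, `S11`, `S10s`, `S00s`, `Sxx`, `Syy`, `Syx`,
#'   counts `n`, `N_steps`, `N_trans`) and the stacked per-step survival
#'   pieces (`B`, `Sflat`, `tau`, `dbar`, `Omega`) plus `loglik_y`.
#' @export
e_step <- function(cohort, params, control = fit_control()) {
  n <- length(cohort)
  if (!n) stop("empty cohort", call. = FALSE)
  m_y <- params$structure$m_y
  m_x <- params$structure$m_x
  m_a <- params$structure$m_alpha
  engine <- if (control$engine == "cpp") patient_stats_cpp else patient_stats_r
  acc <- list(sum_mu1 = numeric(m_x), sum_Ex1x1 = matrix(0, m_x, m_x),
              S11 = matrix(0, m_x, m_x), S10s = matrix(0, m_y, m_x),
              S00s = matrix(0, m_y, m_y), Sxx = matrix(0, m_x, m_x),
              Syy = matrix(0, m_y, m_y), Syx = matrix(0, m_y, m_x))
  N_steps <- 0L
  B <- vector("list", n); Sf <- vector("list", n)
  tau <- vector("list", n); dbar <- vector("list", n); Om <- vector("list", n)
  loglik_y <- 0
  for (i in seq_len(n)) {
    ps <- tryCatch(engine(cohort[[i]], params, control$nr), error = function(e)
      stop(sprintf("E-step failed for patient '%s': %s",
                   as.character(cohort[[i]]$patient_id),
                   conditionMessage(e)), call. = FALSE))
    acc$sum_mu1 <- acc$sum_mu1 + as.numeric(ps$mu1)
    acc$sum_Ex1x1 <- acc$sum_Ex1x1 + ps$Ex1x1
    acc$S11 <- acc$S11 + ps$S11
    acc$S10s <- acc$S10s + ps$S10s
    acc$S00s <- acc$S00s + ps$S00s
    acc$Sxx <- acc$Sxx + ps$Sxx
    acc$Syy <- acc$Syy + ps$Syy
    acc$Syx <- acc$Syx + ps$Syx
    N_steps <- N_steps + cohort[[i]]$m
    B[[i]] <- matrix(ps$b, ncol = m_a)
    Sf[[i]] <- matrix(ps$s, ncol = m_a * m_a)
    tau[[i]] <- cohort[[i]]$tau
    dbar[[i]] <- as.numeric(cohort[[i]]$delta_bar)
    Om[[i]] <- matrix(cohort[[i]]$omega, nrow = cohort[[i]]$m,
                      ncol = length(cohort[[i]]$omega), byrow = TRUE)
    loglik_y <- loglik_y + ps$loglik_y
  }
  structure(c(acc, list(n = n, N_steps = N_steps, N_trans = N_steps - n,
                        B = do.call(rbind, B), Sflat = do.call(rbind, Sf),
                        tau = unlist(tau), dbar = unlist(dbar),
                        Omega = do.call(rbind, Om), loglik_y = loglik_y)),
            class = "lsdsm_suffstats")
}

# survival objective f(gamma, alpha), its gradient and Hessian, on pooled
# per-step moments: f = sum_j dbar_j eta_j - tau_j exp(eta_j + q_j/2) with
# eta_j = gamma'omega_j + alpha'b_j and q_j = alpha'S_j alpha
survival_objective <- function(theta_sv, stats, m_omega, m_alpha,
                               want = c("f", "grad", "hess"), clip = 50) {
  gamma <- theta_sv[seq_len(m_omega)]
  alpha <- theta_sv[m_omega + seq_len(m_alpha)]
  lin <- as.numeric(stats$Omega %*% gamma) + as.numeric(stats$B %*% alpha)
  quad <- as.numeric(stats$Sflat %*% as.numeric(outer(alpha, alpha)))
  eta <- pmin(pmax(lin + 0.5 * quad, -clip), clip)
  e <- exp(eta)
  out <- list(f = sum(stats$dbar * lin) - sum(stats$tau * e))
  if (any(c("grad", "hess") %in% want)) {
    # S_j alpha per step
    SA <- matrix(0, length(e), m_alpha)
    for (r in seq_len(m_alpha)) {
      idx <- (seq_len(m_alpha) - 1L) * m_alpha + r
      SA[, r] <- stats$Sflat[, idx, drop = FALSE] %*% alpha
    }
    u <- stats$B + SA
    w <- stats$tau * e
    out$grad <- c(colSums(stats$dbar * stats$Omega) - colSums(w * stats$Omega),
                  colSums(stats$dbar * stats$B) - colSums(w * u))
    if ("hess" %in% want) {
      Hgg <- -crossprod(stats$Omega, w * stats$Omega)
      Hga <- -crossprod(stats$Omega, w * u)
      Haa <- -crossprod(u, w * u) -
        matrix(colSums(w * stats$Sflat), m_alpha, m_alpha)
      out$hess <- rbind(cbind(Hgg, Hga), cbind(t(Hga), Haa))
    }
  }
  out
}

#' Closed-form M-step for the state-space parameters
#'
#' Implements the five closed-form updates: initial mean and covariance from
#' the first-step smoothed moments, the free transition block from the
#' lag-one/starred cross moments, the reduced disturbance covariance from the
#' transition residual moments (using the freshly updated transition block),
#' and the measurement covariance from the observation expectations.  The
#' lagged-state Gram matrix is ridge-regularized by `1e-10 I` when its
#' condition number exceeds `1e12`.
#'
#' @param stats An `lsdsm_suffstats` from [e_step()].
#' @param params The current parameters (supplies the structure).
#' @return An [lsdsm_params()] object with updated state-space fields and the
#'   survival coefficients carried over unchanged.
#' @export
update_state_params <- function(stats, params) {
  n <- stats$n
  x1_bar <- stats$sum_mu1 / n
  W1_bar <- sym(stats$sum_Ex1x1 / n - tcrossprod(x1_bar))
  if (stats$N_trans >= 1L) {
    Gram <- sym(stats$S11)
    ev <- eigen(Gram, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0 || max(ev) / min(ev) > 1e12) {
      Gram <- Gram + diag(1e-10, nrow(Gram))
    }
    A_bar <- t(solve(Gram, t(stats$S10s)))
    W_breve <- sym((stats$S00s - stats$S10s %*% t(A_bar) -
                      A_bar %*% t(stats$S10s) +
                      A_bar %*% stats$S11 %*% t(A_bar)) / stats$N_trans)
  } else {
    # no transitions anywhere: the dynamics are not informed by the data
    A_bar <- params$A_bar
    W_breve <- params$W_breve
  }
  C <- params$structure$C
  V <- sym((stats$Syy - stats$Syx %*% t(C) - C %*% t(stats$Syx) +
              C %*% stats$Sxx %*% t(C)) / stats$N_steps)
  lsdsm_params(params$structure, A_bar, W_breve, V, x1_bar, W1_bar,
               params$gamma, params$alpha)
}

#' Newton-Raphson M-step for the survival coefficients
#'
#' Maximizes the expected survival log-likelihood
#' `sum_j dbar_j (gamma'omega + alpha'H mu_hat_j) - tau_j exp(gamma'omega)
#' E[exp(alpha'H x_j)]` (the expectation by the Gaussian moment formula) by
#' damped Newton-Raphson with analytic gradient and Hessian.  The Hessian is
#' negative semi-definite everywhere, so full Newton steps with backtracking
#' halving give a monotone ascent; iteration stops when the gradient
#' infinity-norm drops below `grad_tol`.  Degenerate data with no events
#' drive the linear predictor to `-Inf`; this is guarded by the iteration cap
#' and a magnitude bound, with a warning.
#'
#' @param stats An `lsdsm_suffstats` from [e_step()].
#' @param gamma0,alpha0 Starting values (typically the previous EM iterate).
#' @param ctrl An [nr_control()] list.
#' @param grad_tol Stationarity tolerance on the gradient infinity-norm
#'   (default 1e-6).
#' @return List with `gamma`, `alpha`, `converged`, `n_iter`.
#' @export
update_survival_params <- function(stats, gamma0, alpha0,
                                   ctrl = nr_control(), grad_tol = 1e-6) {
  m_omega <- length(gamma0)
  m_alpha <- length(alpha0)
  theta <- c(gamma0, alpha0)
  if (sum(stats$dbar) == 0) {
    warning("no events in the cohort; survival coefficients not estimable",
            call. = FALSE)
    return(list(gamma = gamma0, alpha = alpha0, converged = FALSE,
                n_iter = 0L))
  }
  ob <- survival_objective(theta, stats, m_omega, m_alpha,
                           want = c("f", "grad", "hess"))
  converged <- FALSE
  iter <- 0L
  while (iter < ctrl$max_iter) {
    iter <- iter + 1L
    if (max(abs(ob$grad)) < grad_tol) { converged <- TRUE; break }
    neg_hess <- sym(-ob$hess)
    step <- tryCatch(as.numeric(chol_solve(neg_hess, ob$grad, ctrl)),
                     error = function(e) ob$grad)  # gradient ascent fallback
    lam <- 1
    for (k in seq_len(ctrl$max_halvings + 1L)) {
      cand <- survival_objective(theta + lam * step, stats, m_omega, m_alpha,
                                 want = c("f", "grad", "hess"))
      if (is.finite(cand$f) && cand$f >= ob$f) break
      lam <- lam / 2
    }
    theta <- theta + lam * step
    ob <- cand
    if (max(abs(theta)) > 50) {
      warning("survival coefficients diverging (|coef| > 50); data may be degenerate",
              call. = FALSE)
      break
    }
  }
  if (!converged && max(abs(ob$grad)) < grad_tol) converged <- TRUE
  if (!converged) {
    warning("survival Newton-Raphson did not reach stationarity", call. = FALSE)
  }
  list(gamma = theta[seq_len(m_omega)], alpha = theta[m_omega + seq_len(m_alpha)],
       converged = converged, n_iter = iter)
}

#' Expected complete-data log-likelihood Q
#'
#' Evaluates the four blocks of the EM objective (survival, measurement,
#' initial state, transition) at `params`, under expectations held in
#' `stats` (computed at some previous iterate).  Additive constants not
#' involving the parameters are dropped.  The transition block is the
#' canonical-form one, over the leading `m_y` states driven by the
#' disturbance.
#'
#' @param stats An `lsdsm_suffstats` from [e_step()].
#' @param params An [lsdsm_params()] object.
#' @return Scalar Q value.
#' @export
expected_complete_loglik <- function(stats, params) {
  st <- params$structure
  C <- st$C
  f_surv <- survival_objective(c(params$gamma, params$alpha), stats,
                               length(params$gamma), st$m_alpha,
                               want = "f")$f
  quad <- function(Sinv, M) sum(diag(Sinv %*% M))
  ld <- function(S) as.numeric(determinant(S, logarithm = TRUE)$modulus)
  V <- params$V
  Mv <- stats$Syy - stats$Syx %*% t(C) - C %*% t(stats$Syx) +
    C %*% stats$Sxx %*% t(C)
  q_meas <- -0.5 * (stats$N_steps * ld(V) + quad(solve(V), Mv))
  W1 <- params$W1_bar
  x1 <- params$x1_bar
  M1 <- stats$sum_Ex1x1 - tcrossprod(stats$sum_mu1, x1) -
    tcrossprod(x1, stats$sum_mu1) + stats$n * tcrossprod(x1)
  q_init <- -0.5 * (stats$n * ld(W1) + quad(solve(W1), M1))
  Ab <- params$A_bar
  Mw <- stats$S00s - stats$S10s %*% t(Ab) - Ab %*% t(stats$S10s) +
    Ab %*% stats$S11 %*% t(Ab)
  q_trans <- -0.5 * (stats$N_trans * ld(params$W_breve) +
                       quad(solve(params$W_breve), Mw))
  f_surv + q_meas + q_init + q_trans
}

#' Default parameter initialization
#'
#' A documented default policy (the originating estimation procedure leaves
#' initialization unspecified): the initial state mean is the cohort mean of
#' each patient's first observed measurement, replicated across the lag
#' blocks; the initial covariance replicates the (diagonally loaded)
#' covariance of those first measurements across the diagonal lag blocks;
#' the free transition block comes from a pooled least-squares regression of
#' each observed measurement on its `M` fully observed predecessors (shrunk,
#' if needed, until the assembled transition matrix has spectral radius
#' below one; a stable persistence form 0.9/0.05 is the fallback when too
#' few complete lag windows exist); the disturbance and measurement
#' covariances each take half the pooled variance of first differences of
#' observed measurements; the hazard coefficients start at zero.
#'
#' @param cohort An `lsdsm_cohort`.
#' @param structure An [canonical_structure()] object.
#' @return An [lsdsm_params()] object.
#' @export
initialize_params <- function(cohort, structure) {
  m_y <- structure$m_y
  M <- structure$M
  m_x <- structure$m_x
  firsts <- t(vapply(cohort, function(p) {
    apply(p$y, 2L, function(col) {
      ok <- which(!is.na(col))
      if (length(ok)) col[ok[1L]] else NA_real_
    })
  }, numeric(m_y)))
  firsts <- matrix(firsts, ncol = m_y)
  if (all(is.na(firsts))) {
    stop("no observed measurements anywhere in the cohort", call. = FALSE)
  }
  mu0 <- colMeans(firsts, na.rm = TRUE)
  x1_bar <- rep(mu0, M)
  S0 <- stats::var(firsts, na.rm = TRUE)
  if (any(!is.finite(S0))) S0 <- diag(m_y)
  S0 <- sym(S0) + diag(1e-2 * max(1, mean(diag(S0))), m_y)
  W1_bar <- kronecker(diag(M), S0)
  A_bar <- init_A_bar(cohort, m_y, M)
  # pooled variance of first differences of successively observed values
  dvar <- vapply(seq_len(m_y), function(k) {
    d <- unlist(lapply(cohort, function(p) {
      v <- p$y[, k]
      diff(v[!is.na(v)])
    }))
    if (length(d) > 1L) stats::var(d) else 1
  }, numeric(1))
  dvar[!is.finite(dvar) | dvar <= 0] <- 1
  W_breve <- diag(dvar / 2, m_y)
  V <- diag(dvar / 2, m_y)
  m_omega <- attr(cohort, "m_omega")
  if (is.null(m_omega)) m_omega <- length(cohort[[1L]]$omega)
  lsdsm_params(structure, A_bar, W_breve, V, x1_bar, W1_bar,
               gamma = rep(0, m_omega), alpha = rep(0, structure$m_alpha))
}

# pooled least-squares AR(M) start for the free transition block, with a
# stable persistence fallback
init_A_bar <- function(cohort, m_y, M) {
  m_x <- M * m_y
  fallback <- cbind(0.9 * diag(m_y),
                    if (M > 1L) 0.05 * diag(m_y) else NULL,
                    matrix(0, m_y, max(0L, m_x - 2L * m_y)))
  X <- list(); Y <- list()
  for (p in cohort) {
    if (p$m < M + 1L) next
    for (j in seq.int(M + 1L, p$m)) {
      win <- p$y[j - seq_len(M), , drop = FALSE]  # lags 1..M
      if (all(!is.na(p$y[j, ])) && all(!is.na(win))) {
        Y[[length(Y) + 1L]] <- p$y[j, ]
        X[[length(X) + 1L]] <- as.numeric(t(win))
      }
    }
  }
  if (length(Y) < 5L * m_x) return(fallback)
  Xm <- do.call(rbind, X)
  Ym <- do.call(rbind, Y)
  G <- crossprod(Xm) + diag(1e-8, m_x)
  A_bar <- t(solve(G, crossprod(Xm, Ym)))
  for (k in 1:20) {
    A_full <- rbind(A_bar, if (M > 1L)
      cbind(diag((M - 1L) * m_y), matrix(0, (M - 1L) * m_y, m_y)) else NULL)
    rho <- max(Mod(eigen(A_full, only.values = TRUE)$values))
    if (rho < 1) return(A_bar)
    A_bar <- A_bar * (0.98 / rho)
  }
  fallback
}

#' Fit the state-space survival model by EM
#'
#' Alternates the E-step (survival-corrected filtering, RTS smoothing,
#' expectation assembly) with the closed-form state-space M-step and the
#' Newton-Raphson survival M-step until the maximum absolute elementwise
#' change across all parameter arrays falls below `control$tol`, or
#' `control$max_iter` is reached.  The survival Newton-Raphson is warm
#' started from the previous EM iterate.
#'
#' @param cohort An `lsdsm_cohort` from [grid_cohort()] or
#'   [simulate_cohort()].
#' @param structure An [canonical_structure()]; defaults to a single-biomarker
#'   AR(2) model when the cohort has one biomarker.
#' @param control An [fit_control()] list.
#' @param init Optional starting [lsdsm_params()]; defaults to
#'   [initialize_params()].
#' @return An object of class `lsdsm_fit` with elements `params` (the
#'   estimate), `n_iter`, `converged`, `q_trace` (expected complete-data
#'   log-likelihood per iteration), `max_change_trace`, `loglik_y_trace`, and
#'   `control`.
#' @export
lsdsm_fit <- function(cohort, structure = NULL, control = fit_control(),
                      init = NULL) {
  if (!length(cohort)) stop("empty cohort", call. = FALSE)
  if (is.null(structure)) {
    m_y <- attr(cohort, "m_y")
    if (is.null(m_y)) m_y <- ncol(cohort[[1L]]$y)
    structure <- canonical_structure(m_y, 2L)
  }
  params <- if (is.null(init)) initialize_params(cohort, structure) else init
  q_trace <- numeric(0)
  mc_trace <- numeric(0)
  ll_trace <- numeric(0)
  sv_iters <- integer(0)
  converged <- FALSE
  iter <- 0L
  while (iter < control$max_iter) {
    iter <- iter + 1L
    stats <- tryCatch(e_step(cohort, params, control), error = function(e)
      stop(sprintf("EM iteration %d: %s", iter, conditionMessage(e)),
           call. = FALSE))
    new_params <- update_state_params(stats, params)
    if (control$update_survival) {
      sv <- update_survival_params(stats, params$gamma, params$alpha,
                                   control$nr)
      new_params$gamma <- sv$gamma
      new_params$alpha <- sv$alpha
      sv_iters <- c(sv_iters, sv$n_iter)
    }
    q_trace <- c(q_trace, expected_complete_loglik(stats, new_params))
    ll_trace <- c(ll_trace, stats$loglik_y)
    max_change <- max(abs(params_to_vector(new_params) -
                            params_to_vector(params)))
    mc_trace <- c(mc_trace, max_change)
    if (control$verbose) {
      message(sprintf("EM iter %3d: max |d theta| = %.3e, Q = %.4f",
                      iter, max_change, q_trace[iter]))
    }
    params <- new_params
    if (max_change < control$tol) { converged <- TRUE; break }
  }
  structure(list(params = params, n_iter = iter, converged = converged,
                 q_trace = q_trace, max_change_trace = mc_trace,
                 loglik_y_trace = ll_trace,
                 diagnostics = list(survival_nr_iter = sv_iters),
                 control = control),
            class = "lsdsm_fit")
}

#' @export
print.lsdsm_fit <- function(x, ...) {
  cat(sprintf("State-space survival model fit: %d EM iteration(s), %s\n",
              x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  print(x$params)
  invisible(x)
}

#' @export
coef.lsdsm_fit <- function(object, ...) {
  params_to_vector(object$params)
}
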