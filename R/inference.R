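#' Newton-Raphson / filtering numerical controls
#'
#' Settings for the inner Newton-Raphson search used by the Laplace
#' approximation of survival-corrected state posteriors.
#'
#' @param max_iter Maximum Newton iterations (default 100).
#' @param tol Convergence threshold on the step infinity-norm (default 1e-8).
#' @param max_halvings Maximum backtracking halvings per iteration (default 10).
#' @param jitter Initial diagonal jitter added to a numerically non-PD
#'   Hessian, escalated tenfold up to `jitter_max` before failing.
#' @param jitter_max Largest jitter tried (default 1e-2).
#' @return A list of class `lsdsm_nr_control`.
#' @export
nr_control <- function(max_iter = 100L, tol = 1e-8, max_halvings = 10L,
                       jitter = 1e-8, jitter_max = 1e-2) {
  stopifnot(max_iter >= 1, tol > 0)
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 max_halvings = as.integer(max_halvings),
                 jitter = jitter, jitter_max = jitter_max),
            class = "lsdsm_nr_control")
}

sym <- function(S) (S + t(S)) / 2

# SPD solve via Cholesky with escalating jitter; never forms an explicit
# inverse of an ill-conditioned block
chol_solve <- function(S, B, ctrl = nr_control()) {
  S <- sym(S)
  jit <- 0
  repeat {
    ch <- tryCatch(chol(S + diag(jit, nrow(S))), error = function(e) NULL)
    if (!is.null(ch)) {
      return(backsolve(ch, backsolve(ch, B, transpose = TRUE)))
    }
    jit <- if (jit == 0) ctrl$jitter else jit * 10
    if (jit > ctrl$jitter_max) {
      stop("matrix not positive definite even after jitter", call. = FALSE)
    }
  }
}

#' One-step time update (prediction) of a Gaussian state belief
#'
#' Propagates mean and covariance through the linear dynamics:
#' `mu' = A mu`, `Sigma' = A Sigma A' + G W_breve G'`.
#'
#' @param belief List with elements `mu` and `Sigma`.
#' @param params An [lsdsm_params()] object.
#' @return The predicted belief (same shape).
#' @export
time_update <- function(belief, params) {
  A <- assemble_A(params)
  list(mu = as.numeric(A %*% belief$mu),
       Sigma = sym(A %*% belief$Sigma %*% t(A) + assemble_W(params)))
}

#' Survival-corrected measurement update (Laplace approximation)
#'
#' Corrects a predicted state belief with the evidence of one grid interval:
#' the observed biomarker components (exact Gaussian conditioning) and the
#' interval survival term `exp(delta_bar * eta - tau * exp(eta))` with
#' `eta = gamma' omega + alpha' H x`.  The posterior is approximated as a
#' Gaussian centred at the mode of the log-posterior - located by damped
#' Newton-Raphson started at the Gaussian-conditioned mean - with covariance
#' the inverse negative Hessian there.  When `alpha = 0` (or `tau = 0` and no
#' event) the survival factor does not depend on the state and the update
#' reduces exactly to the standard Kalman measurement update; unobserved
#' biomarker components contribute nothing.
#'
#' @param pred Predicted belief: list with `mu`, `Sigma`.
#' @param y_j Measurement vector (length `m_y`), `NA` where missing.
#' @param omega Baseline covariates.
#' @param tau_j Exposure time in the interval (>= 0).
#' @param delta_bar_j Interval event indicator (0/1).
#' @param params An [lsdsm_params()] object.
#' @param ctrl An [nr_control()] list.
#' @return The corrected belief: list with `mu`, `Sigma`, and `nr_iter`, the
#'   number of Newton iterations used (0 when the update was closed-form).
#' @export
survival_measurement_update <- function(pred, y_j, omega, tau_j, delta_bar_j,
                                        params, ctrl = nr_control()) {
  stopifnot(tau_j >= 0)
  C <- params$structure$C
  V <- params$V
  obs <- which(!is.na(y_j))
  # exact Gaussian conditioning on the observed components (Joseph form)
  if (length(obs)) {
    C_o <- C[obs, , drop = FALSE]
    V_oo <- V[obs, obs, drop = FALSE]
    S <- sym(C_o %*% pred$Sigma %*% t(C_o) + V_oo)
    K <- t(chol_solve(S, C_o %*% pred$Sigma, ctrl))
    mu_k <- pred$mu + as.numeric(K %*% (y_j[obs] - C_o %*% pred$mu))
    ImKC <- diag(length(pred$mu)) - K %*% C_o
    P_k <- sym(ImKC %*% pred$Sigma %*% t(ImKC) + K %*% V_oo %*% t(K))
  } else {
    mu_k <- pred$mu
    P_k <- pred$Sigma
  }
  a <- as.numeric(t(params$structure$H) %*% params$alpha)
  g <- sum(params$gamma * omega)
  no_surv <- (tau_j == 0 && delta_bar_j == 0) || all(a == 0)
  if (no_surv && delta_bar_j == 0) {
    return(list(mu = mu_k, Sigma = P_k, nr_iter = 0L))
  }
  # Newton-Raphson on the log posterior
  #   l(x) = -(x-mu_k)' P_k^{-1} (x-mu_k)/2 + delta_bar a'x - tau e^{g+a'x}
  P_inv <- chol_solve(P_k, diag(nrow(P_k)), ctrl)
  haz <- function(x) exp(clip_log_hazard(g + sum(a * x)))
  obj <- function(x) {
    d <- x - mu_k
    -0.5 * sum(d * (P_inv %*% d)) + delta_bar_j * sum(a * x) - tau_j * haz(x)
  }
  x <- mu_k
  f0 <- obj(x)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    h <- tau_j * haz(x)
    grad <- -as.numeric(P_inv %*% (x - mu_k)) + delta_bar_j * a - h * a
    neg_hess <- P_inv + h * tcrossprod(a)
    step <- as.numeric(chol_solve(neg_hess, grad, ctrl))
    # backtracking halving until the objective increases
    lam <- 1
    for (k in seq_len(ctrl$max_halvings + 1L)) {
      f1 <- obj(x + lam * step)
      if (is.finite(f1) && f1 >= f0) break
      lam <- lam / 2
    }
    x <- x + lam * step
    f0 <- f1
    if (max(abs(lam * step)) < ctrl$tol) break
    if (iter >= ctrl$max_iter) {
      warning("Newton-Raphson state correction did not converge", call. = FALSE)
      break
    }
  }
  h <- tau_j * haz(x)
  Sigma <- chol_solve(P_inv + h * tcrossprod(a), diag(length(x)), ctrl)
  list(mu = as.numeric(x), Sigma = sym(Sigma), nr_iter = iter)
}

#' Survival-corrected forward filter for one patient
#'
#' Runs the modified Kalman filter over the patient's grid: at every interval
#' the state is predicted through the dynamics, then corrected with the
#' observed biomarker components and the interval survival information
#' ([survival_measurement_update()]).  The final partial interval uses the
#' patient's shortened exposure; survival information beyond `T` contributes
#' nothing.
#'
#' @param patient An `lsdsm_patient` from [grid_patient()].
#' @param params An [lsdsm_params()] object.
#' @param ctrl An [nr_control()] list.
#' @return A list with per-step `predicted` and `filtered` beliefs (lists of
#'   `mu`/`Sigma`), `loglik_y` (the Gaussian measurement log-likelihood by
#'   prediction-error decomposition, exact for the observed-data likelihood
#'   only when `alpha = 0`), and `nr_iter` per step.
#' @export
lsdsm_filter <- function(patient, params, ctrl = nr_control()) {
  m <- patient$m
  C <- params$structure$C
  V <- params$V
  predicted <- vector("list", m)
  filtered <- vector("list", m)
  nr_iter <- integer(m)
  loglik_y <- 0
  belief <- list(mu = params$x1_bar, Sigma = params$W1_bar)
  for (j in seq_len(m)) {
    if (j > 1L) belief <- time_update(belief, params)
    predicted[[j]] <- belief
    y_j <- patient$y[j, ]
    obs <- which(!is.na(y_j))
    if (length(obs)) {
      C_o <- C[obs, , drop = FALSE]
      S <- sym(C_o %*% belief$Sigma %*% t(C_o) + V[obs, obs, drop = FALSE])
      r <- y_j[obs] - as.numeric(C_o %*% belief$mu)
      loglik_y <- loglik_y - 0.5 * (length(obs) * log(2 * pi) +
        determinant(S, logarithm = TRUE)$modulus +
        sum(r * chol_solve(S, r, ctrl)))
    }
    belief <- survival_measurement_update(belief, y_j, patient$omega,
                                          patient$tau[j], patient$delta_bar[j],
                                          params, ctrl)
    nr_iter[j] <- belief$nr_iter
    belief <- belief[c("mu", "Sigma")]
    filtered[[j]] <- belief
  }
  list(predicted = predicted, filtered = filtered,
       loglik_y = as.numeric(loglik_y), nr_iter = nr_iter)
}

#' Rauch-Tung-Striebel backward smoothing pass
#'
#' Standard fixed-interval RTS recursion run from the survival-corrected
#' filtered beliefs; the backward pass itself is unchanged by the survival
#' correction.  Also assembles every posterior expectation the M-step needs:
#' `E[x]`, `E[xx']`, the lag-one cross moments `E[x_j x_{j-1}']` built from
#' the smoother gains, and their "starred" reductions to the leading `m_y`
#' states used by the canonical-form parameter updates.
#'
#' @param filtered,predicted Aligned per-step belief lists from
#'   [lsdsm_filter()].
#' @param params An [lsdsm_params()] object.
#' @return A list of class `lsdsm_smoothed` with per-step `mu_hat`
#'   (`m` x `m_x` matrix), `Sigma_hat` (list), smoother gains `J` (list,
#'   `J[[j]]` maps step `j+1` corrections to step `j`), `lag_one` (list,
#'   entry `j` holding `E`-free `Cov(x_j, x_{j-1})`), and expectation arrays
#'   `Ex`, `Exx`, `Exx_lag`.
#' @export
rts_backward <- function(filtered, predicted, params, ctrl = nr_control()) {
  m <- length(filtered)
  stopifnot(m >= 1L, length(predicted) == m)
  A <- assemble_A(params)
  m_x <- length(filtered[[1L]]$mu)
  mu_hat <- matrix(0, m, m_x)
  Sigma_hat <- vector("list", m)
  J <- vector("list", m)
  mu_hat[m, ] <- filtered[[m]]$mu
  Sigma_hat[[m]] <- filtered[[m]]$Sigma
  if (m > 1L) {
    for (j in (m - 1L):1L) {
      # J_j = Sigma_f,j A' (Sigma_pred,j+1)^{-1}
      J[[j]] <- t(chol_solve(predicted[[j + 1L]]$Sigma,
                             A %*% filtered[[j]]$Sigma, ctrl))
      mu_hat[j, ] <- filtered[[j]]$mu +
        as.numeric(J[[j]] %*% (mu_hat[j + 1L, ] - predicted[[j + 1L]]$mu))
      Sigma_hat[[j]] <- sym(filtered[[j]]$Sigma +
        J[[j]] %*% (Sigma_hat[[j + 1L]] - predicted[[j + 1L]]$Sigma) %*%
          t(J[[j]]))
    }
  }
  lag_one <- vector("list", m)  # entry j (j >= 2): Cov(x_j, x_{j-1})
  Exx <- vector("list", m)
  Exx_lag <- vector("list", m)
  for (j in seq_len(m)) {
    Exx[[j]] <- Sigma_hat[[j]] + tcrossprod(mu_hat[j, ])
    if (j > 1L) {
      lag_one[[j]] <- Sigma_hat[[j]] %*% t(J[[j - 1L]])
      Exx_lag[[j]] <- lag_one[[j]] + tcrossprod(mu_hat[j, ], mu_hat[j - 1L, ])
    }
  }
  structure(list(mu_hat = mu_hat, Sigma_hat = Sigma_hat, J = J,
                 lag_one = lag_one, Ex = mu_hat, Exx = Exx,
                 Exx_lag = Exx_lag),
            class = "lsdsm_smoothed")
}

#' Expectations of a (possibly partially missing) observation vector
#'
#' Computes `E[y]`, `E[yy']` and `E[yx']` for one grid step under the
#' smoothed state posterior, filling missing biomarker components by
#' Gaussian conditioning on the observed ones and on the state.  Uses the
#' correction operator `nabla = I - V O' (V_oo)^{-1} O` with `O` the
#' observed-row selector: `nabla` vanishes on fully observed steps (the
#' expectations collapse to the data) and is the identity on fully missing
#' steps (`E[y] = C E[x]`).
#'
#' @param y_j Measurement vector with `NA` at missing components.
#' @param smoothed_j Smoothed belief for the step: list with `mu`, `Sigma`.
#' @param params An [lsdsm_params()] object.
#' @return List with `Ey`, `Eyy`, `Eyx` and the operator `nabla`.
#' @export
expected_observation_moments <- function(y_j, smoothed_j, params) {
  C <- params$structure$C
  V <- params$V
  m_y <- nrow(C)
  obs <- which(!is.na(y_j))
  mu <- smoothed_j$mu
  Sig <- smoothed_j$Sigma
  if (length(obs) == m_y) {
    Ey <- as.numeric(y_j)
    return(list(Ey = Ey, Eyy = tcrossprod(Ey),
                Eyx = tcrossprod(Ey, mu), nabla = matrix(0, m_y, m_y)))
  }
  y0 <- ifelse(is.na(y_j), 0, y_j)  # placeholder cancels inside nabla
  if (length(obs)) {
    Omega <- diag(m_y)[obs, , drop = FALSE]
    nabla <- diag(m_y) -
      V %*% t(Omega) %*% solve(V[obs, obs, drop = FALSE]) %*% Omega
  } else {
    nabla <- diag(m_y)
  }
  I_M <- diag(as.numeric(is.na(y_j)), m_y)
  Ey <- as.numeric(y0 - nabla %*% (y0 - C %*% mu))
  Eyy <- I_M %*% (nabla %*% V + nabla %*% C %*% Sig %*% t(C) %*% t(nabla)) %*%
    I_M + tcrossprod(Ey)
  Eyx <- nabla %*% C %*% Sig + tcrossprod(Ey, mu)
  list(Ey = Ey, Eyy = sym(Eyy), Eyx = Eyx, nabla = nabla)
}

#' Filter and smooth one patient in a single call
#'
#' Convenience wrapper chaining [lsdsm_filter()] and [rts_backward()].
#'
#' @inheritParams lsdsm_filter
#' @return The `lsdsm_smoothed` object with the filter output attached as
#'   attributes `filtered`, `predicted` and `loglik_y`.
#' @export
lsdsm_smooth <- function(patient, params, ctrl = nr_control()) {
  fl <- lsdsm_filter(patient, params, ctrl)
  sm <- rts_backward(fl$filtered, fl$predicted, params, ctrl)
  attr(sm, "filtered") <- fl$filtered
  attr(sm, "predicted") <- fl$predicted
  attr(sm, "loglik_y") <- fl$loglik_y
  sm
}
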