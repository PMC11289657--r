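#' Log-hazard of the proportional hazards sub-model
#'
#' The hazard is `exp(gamma' omega + alpha' H x)`: a constant baseline level
#' modulated by baseline covariates and by a linear functional `H x` of the
#' hidden states (by default the current true biomarker values).  Computed and
#' returned in the log domain; [exp()] of the result is the hazard.  The
#' linear predictor is clipped at `+/- clip` to survive transient extreme
#' coefficients during Newton-Raphson exploration.
#'
#' @param x Hidden state vector (length `m_x`).
#' @param omega Baseline covariate vector.
#' @param params An [lsdsm_params()] object.
#' @param clip Symmetric bound on the returned log-hazard (default 50).
#' @return Scalar log-hazard.
#' @export
log_hazard <- function(x, omega, params, clip = 50) {
  eta <- sum(params$gamma * omega) +
    sum(params$alpha * (params$structure$H %*% x))
  if (!is.finite(eta)) stop("non-finite log-hazard", call. = FALSE)
  clip_log_hazard(eta, clip)
}

clip_log_hazard <- function(eta, clip = 50) {
  if (any(abs(eta) > clip)) {
    warning(sprintf("log-hazard clipped at +/-%g", clip), call. = FALSE)
    eta <- pmin(pmax(eta, -clip), clip)
  }
  eta
}

#' Log-likelihood contribution of one survival interval
#'
#' Under the piecewise-constant-hazard assumption, the probability of the
#' survival information in grid interval `j` given the state there is
#' `exp(delta_bar_j * eta - tau_j * exp(eta))` with
#' `eta = gamma' omega + alpha' H x_j`: the event term if the event fell in
#' this interval, minus the cumulative hazard accrued over the `tau_j` time
#' units at risk.
#'
#' @param x_j State vector for the interval.
#' @param omega Baseline covariates.
#' @param tau_j Exposure time in the interval (>= 0).
#' @param delta_bar_j Interval event indicator (0 or 1).
#' @param params An [lsdsm_params()] object.
#' @return Scalar log-probability contribution.
#' @export
interval_survival_logpdf <- function(x_j, omega, tau_j, delta_bar_j, params) {
  stopifnot(tau_j >= 0, delta_bar_j %in% c(0, 1))
  eta <- log_hazard(x_j, omega, params)
  delta_bar_j * eta - tau_j * exp(eta)
}

#' Piecewise-exponential survival probability along a state path
#'
#' Evaluates `S(T) = exp(-sum_j tau_j * exp(gamma' omega + alpha' H x_j))`,
#' the survival function of a hazard held constant within each grid interval
#' at the level implied by that interval's hidden state.
#'
#' @param x_path Matrix of per-interval states (one row per interval, `m_x`
#'   columns) or a vector when `m_x = 1`.
#' @param omega Baseline covariates.
#' @param tau Per-interval exposures (same length as rows of `x_path`).
#' @param params An [lsdsm_params()] object.
#' @return Survival probability in `(0, 1]`.
#' @export
piecewise_survival <- function(x_path, omega, tau, params) {
  x_path <- if (is.null(dim(x_path))) matrix(x_path, ncol = params$structure$m_x)
    else as.matrix(x_path)
  if (nrow(x_path) != length(tau)) {
    stop("'x_path' and 'tau' must have the same length", call. = FALSE)
  }
  if (any(tau < 0)) stop("negative exposure 'tau'", call. = FALSE)
  if (!length(tau)) return(1)
  eta <- clip_log_hazard(
    sum(params$gamma * omega) +
      as.numeric(x_path %*% t(params$structure$H) %*% params$alpha))
  exp(-sum(tau * exp(eta)))
}

#' Expectation of exp(a'x) under a Gaussian
#'
#' For `x ~ N(mu, Sigma)` this is the moment-generating function
#' `exp(a' mu + a' Sigma a / 2)` - exact for Gaussian inputs.  It is the
#' closed form behind the Laplace treatment of the expected exponential
#' hazard term in the estimation objective.
#'
#' @param mu Mean vector.
#' @param Sigma Covariance matrix (symmetric PSD).
#' @param a Linear functional (same length as `mu`).
#' @param log Return the log of the moment instead.
#' @return Scalar `E[exp(a'x)]` (or its log).
#' @export
gaussian_exp_moment <- function(mu, Sigma, a, log = FALSE) {
  Sigma <- as.matrix(Sigma)
  if (max(abs(Sigma - t(Sigma))) > 1e-8 * max(1, max(abs(Sigma)))) {
    stop("'Sigma' must be symmetric", call. = FALSE)
  }
  lm <- sum(a * mu) + 0.5 * sum(a * (Sigma %*% a))
  if (log) lm else exp(lm)
}
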