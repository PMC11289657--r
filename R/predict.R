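# one prediction step: propagate, correct for having survived the step, and
# accumulate the one-step conditional survival increment.
# The increment integral  int N(x; mu_p, P_p) exp{-tau c e^{a'x}} dx  is
# approximated by Laplace around the mode x_hat of the integrand's exponent:
#   exp{phi(x_hat)} / sqrt(1 + h a' P_p a),  h = tau c e^{g + a' x_hat},
# a rank-one determinant identity; exact when alpha = 0.
survive_step <- function(pred, omega, tau_k, params, ctrl) {
  belief <- survival_measurement_update(
    pred, rep(NA_real_, params$structure$m_y), omega, tau_k, 0L, params, ctrl)
  a <- as.numeric(t(params$structure$H) %*% params$alpha)
  g <- sum(params$gamma * omega)
  x_hat <- belief$mu
  haz <- exp(clip_log_hazard(g + sum(a * x_hat)))
  d <- x_hat - pred$mu
  phi <- -0.5 * sum(d * chol_solve(pred$Sigma, d, ctrl)) - tau_k * haz
  quad <- tau_k * haz * sum(a * (pred$Sigma %*% a))
  list(belief = belief[c("mu", "Sigma")],
       log_increment = phi - 0.5 * log1p(quad))
}

#' Individualized dynamic survival prediction
#'
#' Predicts a patient's conditional survival curve from a landmark time
#' `t_s` out to a horizon `t_h`, given the longitudinal record up to the
#' landmark and survival through it.  The recursion initializes from the
#' survival-corrected filter run over the landmark record and then repeats
#' three steps per future grid interval: (1) one-step state prediction
#' through the dynamics, (2) Gaussian (Laplace) re-approximation of the
#' state conditioned on surviving the step, and (3) the one-step conditional
#' survival increment by Laplace approximation of the Gaussian-weighted
#' survival integral.  Increments multiply into a non-increasing curve.
#'
#' @param patient An `lsdsm_patient`; its record is truncated at the
#'   landmark, which must not exceed the patient's follow-up.
#' @param params An [lsdsm_params()] object (fitted or true).
#' @param landmark Landmark time `t_s` (>= 0); must be a grid multiple of
#'   `patient$dt` - off-grid landmarks are floored to the grid with a
#'   warning.
#' @param horizon Horizon span `t_h` (>= 0) beyond the landmark; a final
#'   partial step uses a shortened exposure.
#' @param ctrl An [nr_control()] list.
#' @param init_belief Optional state belief at the landmark (list with `mu`,
#'   `Sigma`, conditional on survival to the landmark); bypasses the
#'   filtering pass, allowing a saved recursion to be continued.
#' @return A data frame of class `lsdsm_survcurve` with columns
#'   `patient_id`, `landmark`, `horizon_time` and `survival` (the first row
#'   is the landmark itself with survival 1), and attribute `final_belief`,
#'   the carried state belief at the horizon.
#' @export
predict_survival <- function(patient, params, landmark, horizon,
                             ctrl = nr_control(), init_belief = NULL) {
  dt <- patient$dt
  stopifnot(landmark >= 0, horizon >= 0)
  m_s <- floor(landmark / dt + 1e-9)
  if (abs(landmark - m_s * dt) > 1e-8 * max(1, dt)) {
    warning(sprintf("landmark %g is not a grid multiple of dt = %g; floored to %g",
                    landmark, dt, m_s * dt), call. = FALSE)
    landmark <- m_s * dt
  }
  if (is.null(init_belief)) {
    if (landmark > patient$T + 1e-9) {
      stop("landmark exceeds the patient's observed follow-up", call. = FALSE)
    }
    if (patient$delta == 1 && patient$T <= landmark + 1e-9) {
      stop("patient experienced the event before the landmark", call. = FALSE)
    }
  }
  at_state_one <- FALSE
  if (is.null(init_belief)) {
    if (m_s >= 1L) {
      trunc <- patient
      trunc$y <- patient$y[seq_len(m_s), , drop = FALSE]
      trunc$observed_mask <- patient$observed_mask[seq_len(m_s), , drop = FALSE]
      trunc$m <- as.integer(m_s)
      trunc$tau <- rep(dt, m_s)          # survived every landmark interval
      trunc$delta_bar <- rep(0L, m_s)
      fl <- lsdsm_filter(trunc, params, ctrl)
      belief <- fl$filtered[[m_s]]
    } else {
      belief <- list(mu = params$x1_bar, Sigma = params$W1_bar)
      # no data and no elapsed exposure: the prior over x_1 is the landmark
      # belief, and interval 1 is governed by x_1 itself (no propagation)
      at_state_one <- TRUE
    }
  } else {
    belief <- init_belief
  }
  n_h <- if (horizon > 0) as.integer(ceiling(horizon / dt - 1e-9)) else 0L
  times <- landmark
  surv <- 1
  log_s <- 0
  if (n_h > 0L) {
    tau_k <- rep(dt, n_h)
    tau_k[n_h] <- horizon - (n_h - 1L) * dt
    for (k in seq_len(n_h)) {
      pred <- if (k == 1L && at_state_one) belief else
        time_update(belief, params)
      stp <- survive_step(pred, patient$omega, tau_k[k], params, ctrl)
      belief <- stp$belief
      log_s <- log_s + stp$log_increment
      times <- c(times, landmark + sum(tau_k[seq_len(k)]))
      surv <- c(surv, exp(log_s))
    }
  }
  out <- data.frame(patient_id = patient$patient_id, landmark = landmark,
                    horizon_time = times, survival = surv)
  class(out) <- c("lsdsm_survcurve", "data.frame")
  attr(out, "final_belief") <- belief
  out
}
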