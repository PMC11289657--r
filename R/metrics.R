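# Kaplan-Meier estimate of the censoring survivor function among the at-risk
# set, as a step function evaluable at arbitrary times (left limit via eps)
censoring_km <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  function(t) {
    s <- summary(fit, times = pmax(t, 0), extend = TRUE)$surv
    pmax(s, .Machine$double.eps)
  }
}

#' Dynamic (cumulative/dynamic) AUC with IPCW
#'
#' Discrimination of risk scores for events occurring in the window
#' `(t_s, t_s + t_h]` among patients still at risk at the landmark `t_s`.
#' Cases are patients with an observed event inside the window; controls are
#' patients still event-free beyond it.  Censoring is handled with
#' inverse-probability-of-censoring weights from a Kaplan-Meier estimate of
#' the censoring distribution fitted on the at-risk set (time measured from
#' the landmark): case `i` gets weight `1/G(T_i-)`, controls `1/G(t_h)`.
#' Tied scores contribute one half.
#'
#' @param risk_scores Numeric risk scores (higher = higher predicted risk)
#'   for all patients; typically 1 minus the predicted conditional survival
#'   at the horizon.
#' @param T_i Event/censoring times.
#' @param delta Event indicators (1 event, 0 censored).
#' @param t_s Landmark time.
#' @param t_h Horizon span beyond the landmark.
#' @param weighting `"km"` (IPCW, default) or `"none"` (unweighted; only
#'   appropriate without censoring before `t_s + t_h`).
#' @return Scalar AUC in `[0, 1]`.
#' @export
dynamic_auc <- function(risk_scores, T_i, delta, t_s, t_h,
                        weighting = c("km", "none")) {
  weighting <- match.arg(weighting)
  stopifnot(length(risk_scores) == length(T_i), length(T_i) == length(delta),
            t_h > 0)
  at_risk <- T_i > t_s
  r <- risk_scores[at_risk]
  tt <- T_i[at_risk] - t_s
  dd <- delta[at_risk]
  case <- tt <= t_h & dd == 1
  control <- tt > t_h
  if (!any(case)) stop("no events in the prediction window", call. = FALSE)
  if (!any(control)) stop("no controls beyond the horizon", call. = FALSE)
  if (weighting == "km") {
    G <- censoring_km(tt, dd)
    w_case <- 1 / G(tt[case] - 1e-9)
    w_ctrl <- rep(1 / G(t_h), sum(control))
  } else {
    w_case <- rep(1, sum(case))
    w_ctrl <- rep(1, sum(control))
  }
  rc <- r[case]
  rq <- r[control]
  conc <- outer(rc, rq, ">") + 0.5 * outer(rc, rq, "==")
  num <- as.numeric(t(w_case) %*% conc %*% w_ctrl)
  num / (sum(w_case) * sum(w_ctrl))
}

#' Time-dependent Brier score with IPCW
#'
#' Mean squared difference between the survival status indicator at
#' `t_s + t_h` and the predicted conditional survival probability, over
#' patients at risk at the landmark, with inverse-probability-of-censoring
#' weights: patients with an event inside the window weigh `1/G(T_i-)`,
#' survivors `1/G(t_h)`, and patients censored inside the window drop out
#' (weight 0).
#'
#' @param predicted_survival Predicted conditional survival probabilities at
#'   `t_s + t_h` given survival to `t_s`, for all patients.
#' @inheritParams dynamic_auc
#' @return Scalar Brier score in `[0, 1]`.
#' @export
brier_score <- function(predicted_survival, T_i, delta, t_s, t_h,
                        weighting = c("km", "none")) {
  weighting <- match.arg(weighting)
  stopifnot(length(predicted_survival) == length(T_i), t_h > 0)
  at_risk <- T_i > t_s
  p <- predicted_survival[at_risk]
  tt <- T_i[at_risk] - t_s
  dd <- delta[at_risk]
  case <- tt <= t_h & dd == 1
  control <- tt > t_h
  if (weighting == "km") {
    G <- censoring_km(tt, dd)
    w <- numeric(length(tt))
    w[case] <- 1 / G(tt[case] - 1e-9)
    w[control] <- 1 / G(t_h)
  } else {
    w <- as.numeric(case | control)
  }
  err <- numeric(length(tt))
  err[case] <- p[case]^2          # status 0 at the horizon
  err[control] <- (1 - p[control])^2
  sum(w * err) / length(tt)
}

#' RMSE between estimated and true latent trajectories
#'
#' Pools the squared deviation of the (leading) smoothed state from the true
#' latent state over all patients and grid steps, then takes the root.
#'
#' @param estimated,true Lists (one entry per patient) of numeric vectors or
#'   single-column matrices on aligned grids, or plain numeric vectors.
#' @return Scalar RMSE.
#' @export
rmse_trajectory <- function(estimated, true) {
  if (!is.list(estimated)) estimated <- list(estimated)
  if (!is.list(true)) true <- list(true)
  stopifnot(length(estimated) == length(true))
  sq <- unlist(mapply(function(e, t) {
    e <- as.numeric(e); t <- as.numeric(t)
    if (length(e) != length(t)) stop("trajectory shape mismatch", call. = FALSE)
    (e - t)^2
  }, estimated, true, SIMPLIFY = FALSE))
  sqrt(mean(sq))
}

#' RMSE between estimated and true survival curves
#'
#' Pools squared survival-probability differences over all patients and their
#' own follow-up grid points (pooling across patient-time points; a
#' per-patient-average variant is available).
#'
#' @param estimated,true Lists of per-patient survival-probability vectors on
#'   matching grids.
#' @param pool `"points"` (default): pool all patient-time points before the
#'   root-mean; `"patients"`: RMSE per patient first, then average.
#' @return Scalar RMSE.
#' @export
rmse_survival <- function(estimated, true, pool = c("points", "patients")) {
  pool <- match.arg(pool)
  if (!is.list(estimated)) estimated <- list(estimated)
  if (!is.list(true)) true <- list(true)
  stopifnot(length(estimated) == length(true))
  per <- mapply(function(e, t) {
    e <- as.numeric(e); t <- as.numeric(t)
    if (length(e) != length(t)) stop("curve shape mismatch", call. = FALSE)
    (e - t)^2
  }, estimated, true, SIMPLIFY = FALSE)
  if (pool == "points") sqrt(mean(unlist(per)))
  else mean(vapply(per, function(s) sqrt(mean(s)), numeric(1)))
}

#' Landmark/horizon evaluation report
#'
#' Computes the dynamic AUC and time-dependent Brier score for every
#' landmark/horizon pair on supplied predictions.
#'
#' @param predictions Data frame with columns `patient_id`, `landmark`,
#'   `horizon_time`, `survival_probability` (as written by [cmd_predict()]).
#' @param survival Data frame with columns `patient_id`, `time`, `event`.
#' @param landmarks,horizons Numeric vectors of landmark times and horizon
#'   spans.
#' @return Data frame with columns `landmark`, `horizon`, `n_at_risk`,
#'   `auc`, `brier`.
#' @export
evaluate_predictions <- function(predictions, survival, landmarks, horizons) {
  rows <- list()
  for (t_s in landmarks) {
    for (t_h in horizons) {
      pr <- predictions[abs(predictions$landmark - t_s) < 1e-9 &
                          abs(predictions$horizon_time - (t_s + t_h)) < 1e-9, ]
      idx <- match(pr$patient_id, survival$patient_id)
      if (any(is.na(idx))) {
        stop("predictions refer to patients absent from the survival table",
             call. = FALSE)
      }
      T_i <- survival$time[idx]
      delta <- survival$event[idx]
      if (!any(T_i > t_s)) {
        stop(sprintf("no patients at risk at landmark %g", t_s), call. = FALSE)
      }
      auc <- tryCatch(
        dynamic_auc(1 - pr$survival_probability, T_i, delta, t_s, t_h),
        error = function(e) NA_real_)
      bs <- brier_score(pr$survival_probability, T_i, delta, t_s, t_h)
      rows[[length(rows) + 1L]] <- data.frame(
        landmark = t_s, horizon = t_h, n_at_risk = sum(T_i > t_s),
        auc = auc, brier = bs)
    }
  }
  do.call(rbind, rows)
}
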