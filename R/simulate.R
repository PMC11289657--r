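#' Default "true model" for the simulation study
#'
#' The single-biomarker AR(2) generating model used throughout the
#' simulation study: free transition block `[1.46 -0.48]`, disturbance
#' variance 0.04 (sd 0.2), measurement-error variance 0.25 (sd 0.5), hazard
#' coefficients `gamma = (2.5, -0.75)` - an intercept and one
#' standard-normal baseline covariate - and current-value association
#' `alpha = -1.25`.  Fixed quantities: `C = [1 0]`, `H = [1 0]`,
#' `x1_bar = (10, 10)`, `W1_bar = I`.
#'
#' @return An [lsdsm_params()] object.
#' @export
#' @examples
#' true_model()
true_model <- function() {
  st <- canonical_structure(1L, 2L)
  lsdsm_params(st,
               A_bar = matrix(c(1.46, -0.48), 1L, 2L),
               W_breve = matrix(0.04), V = matrix(0.25),
               x1_bar = c(10, 10), W1_bar = diag(2),
               gamma = c(2.5, -0.75), alpha = -1.25)
}

#' Simulation configuration
#'
#' @param n Cohort size (default 500).
#' @param missing_pct Fraction of longitudinal measurements removed
#'   completely at random, in `[0, 1)` (default 0).
#' @param censor_low,censor_high Support of the uniform censoring draw
#'   (defaults 10 and 50 time units).
#' @param max_steps Administrative follow-up cap applied to the censoring
#'   time, `C_i = min(max_steps, C*_i)` (default 30).
#' @param dt Grid step (default 1 simulated time unit).
#' @param seed RNG seed (default 1).
#' @return A list of class `lsdsm_sim_config`.
#' @export
sim_config <- function(n = 500L, missing_pct = 0, censor_low = 10,
                       censor_high = 50, max_steps = 30L, dt = 1,
                       seed = 1L) {
  stopifnot(n >= 1, missing_pct >= 0, missing_pct < 1,
            censor_low < censor_high, max_steps >= 1, dt > 0)
  structure(list(n = as.integer(n), missing_pct = missing_pct,
                 censor_low = censor_low, censor_high = censor_high,
                 max_steps = as.integer(max_steps), dt = dt,
                 seed = as.integer(seed)),
            class = "lsdsm_sim_config")
}

#' Sample an event time by inverse-transform sampling
#'
#' Under the piecewise-constant-hazard assumption the survival function along
#' a latent state path is a product of interval-wise exponentials.  Given a
#' uniform draw `u`, the event time solves `S(T) = u`: cumulative hazard is
#' walked interval by interval and the crossing interval is solved with the
#' exponential closed form.  If the target is not reached within the supplied
#' path, `Inf` is returned (the event falls beyond the covered window and the
#' caller censors).
#'
#' @param x_path Matrix of per-interval latent states (rows = intervals).
#' @param omega Baseline covariates.
#' @param params An [lsdsm_params()] object.
#' @param u Uniform(0,1) draw.
#' @param dt Interval width (default 1).
#' @return Event time `T >= 0` (possibly `Inf`).
#' @export
sample_event_time <- function(x_path, omega, params, u, dt = 1) {
  if (u <= 0 || u >= 1) {
    if (u == 1) return(0)
    stop("'u' must lie in (0, 1)", call. = FALSE)
  }
  x_path <- if (is.null(dim(x_path)))
    matrix(x_path, ncol = params$structure$m_x) else as.matrix(x_path)
  eta <- clip_log_hazard(
    sum(params$gamma * omega) +
      as.numeric(x_path %*% t(params$structure$H) %*% params$alpha))
  h <- exp(eta)
  target <- -log(u)
  cum <- 0
  for (j in seq_along(h)) {
    inc <- dt * h[j]
    if (cum + inc >= target) {
      return((j - 1) * dt + (target - cum) / h[j])
    }
    cum <- cum + inc
  }
  Inf
}

#' Simulate a synthetic cohort from the generating model
#'
#' Reproduces the simulation-study world: each patient draws a baseline
#' covariate from N(0,1) (alongside a constant intercept column), an initial
#' state from `N(x1_bar, W1_bar)`, then iterates the linear dynamics with
#' Gaussian disturbances and emits noisy observations of the leading state at
#' every grid step.  The event time comes from [sample_event_time()] on the
#' latent path; censoring is `min(max_steps, Uniform(censor_low,
#' censor_high))`, with ties resolved as censored.  Follow-up is truncated at
#' `T = min(event, censoring)` and each longitudinal measurement is then
#' removed independently with probability `missing_pct` (the survival outcome
#' is never removed).  Separate RNG substreams are used for initial states,
#' disturbances, measurement errors, event uniforms, censoring and
#' missingness so that changing one leaves the others reproducible.
#'
#' @param model An [lsdsm_params()] "true model" (default [true_model()]).
#' @param config A [sim_config()] list.
#' @return An `lsdsm_cohort` (list of `lsdsm_patient`) with extra attributes:
#'   `latent` (list of true state paths, one `m x m_x` matrix per patient),
#'   `true_survival` (list of true survival curves over each patient's grid,
#'   evaluated at the ends of intervals `1..m`), `model` and `config`.
#' @export
simulate_cohort <- function(model = true_model(), config = sim_config()) {
  st <- model$structure
  m_x <- st$m_x
  m_y <- st$m_y
  n <- config$n
  dt <- config$dt
  max_m <- as.integer(ceiling(config$max_steps / dt))
  A <- assemble_A(model)
  G <- st$G
  C <- st$C
  cw <- chol(sym(model$W_breve) + diag(1e-12, m_y))
  cv <- chol(sym(model$V) + diag(1e-12, m_y))
  c1 <- chol(sym(model$W1_bar) + diag(1e-12, m_x))
  # named substreams derived from the master seed
  sub_seed <- function(k) {
    set.seed(config$seed)
    as.integer(sample.int(.Machine$integer.max - 1L, 7L)[k])
  }
  draw <- function(k, fn) { set.seed(sub_seed(k)); fn() }
  x1 <- draw(1L, function()
    matrix(stats::rnorm(n * m_x), n, m_x) %*% c1 +
      matrix(model$x1_bar, n, m_x, byrow = TRUE))
  w <- draw(2L, function()
    array(stats::rnorm(n * max_m * m_y), c(n, max_m, m_y)))
  v <- draw(3L, function()
    array(stats::rnorm(n * max_m * m_y), c(n, max_m, m_y)))
  u_event <- draw(4L, function() stats::runif(n))
  cens <- draw(5L, function()
    pmin(config$max_steps,
         stats::runif(n, config$censor_low, config$censor_high)))
  miss <- draw(6L, function() matrix(stats::runif(n * max_m), n, max_m))
  omega_draw <- draw(7L, function() stats::rnorm(n))

  patients <- vector("list", n)
  latent <- vector("list", n)
  true_surv <- vector("list", n)
  for (i in seq_len(n)) {
    x <- matrix(0, max_m, m_x)
    x[1L, ] <- x1[i, ]
    for (j in seq_len(max_m - 1L)) {
      x[j + 1L, ] <- A %*% x[j, ] + G %*% (t(cw) %*% w[i, j, ])
    }
    omega <- c(1, omega_draw[i])
    T_event <- sample_event_time(x, omega, model, u_event[i], dt)
    delta <- as.integer(T_event < cens[i])  # ties resolved as censored
    T_i <- min(T_event, cens[i])
    m <- as.integer(ceiling(T_i / dt))
    y <- x[seq_len(m), , drop = FALSE] %*% t(C) +
      matrix(v[i, seq_len(m), ], m, m_y) %*% cv
    keep <- miss[i, seq_len(m)] >= config$missing_pct
    times <- (seq_len(m) - 1L) * dt
    p <- grid_patient(paste0("sim", i), times[keep],
                      y[keep, , drop = FALSE], omega, T_i, delta, dt)
    patients[[i]] <- p
    latent[[i]] <- x[seq_len(m), , drop = FALSE]
    eta <- clip_log_hazard(
      sum(model$gamma * omega) +
        as.numeric(x[seq_len(m), , drop = FALSE] %*% t(st$H) %*% model$alpha))
    true_surv[[i]] <- exp(-cumsum(p$tau * exp(eta)))
  }
  structure(patients, class = "lsdsm_cohort", dt = dt, m_y = m_y,
            m_omega = length(model$gamma),
            biomarkers = paste0("y", seq_len(m_y)),
            covariates = c("intercept", "z"),
            latent = latent, true_survival = true_surv,
            model = model, config = config)
}
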