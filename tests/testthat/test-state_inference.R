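rand_params <- function(seed, alpha = -1.25) {
  set.seed(seed)
  st <- canonical_structure(1, 2)
  lsdsm_params(st, A_bar = matrix(c(runif(1, 0.8, 1.4), runif(1, -0.5, -0.1)),
                                  1, 2),
               W_breve = matrix(runif(1, 0.02, 0.3)),
               V = matrix(runif(1, 0.1, 0.6)),
               x1_bar = rnorm(2, 5), W1_bar = diag(runif(2, 0.5, 2)),
               gamma = c(rnorm(1), rnorm(1, sd = 0.3)), alpha = alpha)
}

test_that("time update matches the textbook Kalman predict step", {
  pr <- rand_params(1)
  A <- assemble_A(pr); W <- assemble_W(pr)
  # identity dynamics, no disturbance (AR(1) form): belief unchanged
  st1 <- canonical_structure(1, 1)
  id <- lsdsm_params(st1, A_bar = matrix(1), W_breve = matrix(0),
                     V = matrix(1), x1_bar = 0, W1_bar = matrix(1),
                     gamma = 0, alpha = 0)
  b <- list(mu = 1.3, Sigma = matrix(2))
  expect_equal(time_update(b, id), b)
  # zero covariance: pure disturbance remains
  b0 <- list(mu = c(2, -1), Sigma = matrix(0, 2, 2))
  expect_equal(time_update(b0, pr)$Sigma, W)
  # random instance vs independently coded predict
  set.seed(2)
  S <- crossprod(matrix(rnorm(4), 2))
  b1 <- list(mu = rnorm(2), Sigma = S)
  ora <- kalman_predict_oracle(b1$mu, b1$Sigma, A, W)
  out <- time_update(b1, pr)
  expect_equal(out$mu, ora$mu, tolerance = 1e-12)
  expect_equal(out$Sigma, (ora$Sigma + t(ora$Sigma)) / 2, tolerance = 1e-12)
})

test_that("survival correction reduces to the Kalman update when alpha = 0", {
  pr <- rand_params(3, alpha = 0)
  set.seed(4)
  pred <- list(mu = rnorm(2, 5), Sigma = crossprod(matrix(rnorm(4), 2)) + diag(2))
  y <- 4.7
  out <- survival_measurement_update(pred, y, c(1, 0.5), tau_j = 1,
                                     delta_bar_j = 0, pr)
  ora <- kalman_update_oracle(pred$mu, pred$Sigma, y, pr$structure$C, pr$V)
  expect_equal(out$mu, ora$mu, tolerance = 1e-10)
  expect_equal(out$Sigma, ora$Sigma, tolerance = 1e-10)

  # no measurement and no exposure: posterior equals the prediction
  out2 <- survival_measurement_update(pred, NA_real_, c(1, 0.5), 0, 0,
                                      rand_params(3))
  expect_equal(out2$mu, pred$mu)
  expect_equal(out2$Sigma, pred$Sigma)
})

test_that("1-D survival-corrected posterior matches the quadrature oracle", {
  st <- canonical_structure(1, 1)
  for (case in list(list(y = 1.2, tau = 1, dbar = 0),
                    list(y = 1.2, tau = 0.6, dbar = 1),
                    list(y = NA_real_, tau = 1, dbar = 1))) {
    pr <- lsdsm_params(st, A_bar = matrix(0.9), W_breve = matrix(0.2),
                       V = matrix(0.3), x1_bar = 1, W1_bar = matrix(0.8),
                       gamma = -0.5, alpha = 0.8)
    pred <- list(mu = 1.5, Sigma = matrix(0.6))
    out <- survival_measurement_update(pred, case$y, omega = 1, case$tau,
                                       case$dbar, pr)
    ora <- quadrature_posterior_oracle(1.5, 0.6, case$y, 0.3, g = -0.5,
                                       a = 0.8, tau = case$tau,
                                       dbar = case$dbar)
    # the Laplace approximation is defined by the mode and the inverse
    # negative curvature there
    expect_equal(out$mu, ora$mode, tolerance = 1e-6)
    expect_equal(out$Sigma[1, 1], ora$laplace_var, tolerance = 1e-6)
    # and it should stay close to the exact normalized posterior moments
    # (largest deviation: unobserved event interval, where the posterior is
    # visibly skewed)
    expect_equal(out$mu, ora$mean, tolerance = 0.06)
    expect_equal(out$Sigma[1, 1], ora$var, tolerance = 0.06)
  }
})

test_that("an event shifts the posterior towards higher hazard", {
  st <- canonical_structure(1, 1)
  pr <- lsdsm_params(st, A_bar = matrix(0.9), W_breve = matrix(0.2),
                     V = matrix(0.3), x1_bar = 0, W1_bar = matrix(1),
                     gamma = -1, alpha = 0.8)
  pred <- list(mu = 0.5, Sigma = matrix(0.7))
  no_ev <- survival_measurement_update(pred, NA_real_, 1, 1, 0, pr)
  ev <- survival_measurement_update(pred, NA_real_, 1, 1, 1, pr)
  # alpha > 0: the event pulls the state up (direction of H'alpha)
  expect_gt(ev$mu, no_ev$mu)
})

test_that("with alpha = 0 the whole forward pass is a textbook Kalman filter", {
  for (seed in 1:5) {
    pr <- rand_params(seed, alpha = 0)
    set.seed(seed + 100)
    m <- sample(2:6, 1)
    y <- matrix(rnorm(m, 5), m, 1)
    y[sample(m, 1), 1] <- NA  # one missing step
    p <- make_patient(y, omega = c(1, 0.3), T_i = m - runif(1, 0, 0.9),
                      delta = 1)
    fl <- lsdsm_filter(p, pr)
    A <- assemble_A(pr); W <- assemble_W(pr)
    mu <- pr$x1_bar; Sg <- pr$W1_bar
    for (j in 1:p$m) {
      if (j > 1) {
        o <- kalman_predict_oracle(mu, Sg, A, W); mu <- o$mu; Sg <- o$Sigma
      }
      expect_equal(fl$predicted[[j]]$mu, mu, tolerance = 1e-10)
      expect_equal(fl$predicted[[j]]$Sigma, (Sg + t(Sg)) / 2,
                   tolerance = 1e-10)
      if (!is.na(y[j, 1])) {
        o <- kalman_update_oracle(mu, Sg, y[j, 1], pr$structure$C, pr$V)
        mu <- o$mu; Sg <- o$Sigma
      }
      expect_equal(fl$filtered[[j]]$mu, mu, tolerance = 1e-10)
      expect_equal(fl$filtered[[j]]$Sigma, (Sg + t(Sg)) / 2,
                   tolerance = 1e-10)
    }
  }
})

test_that("RTS smoothing matches batch joint-Gaussian conditioning (alpha = 0)", {
  for (seed in 1:4) {
    pr <- rand_params(seed + 10, alpha = 0)
    set.seed(seed + 200)
    m <- sample(3:5, 1)
    y <- matrix(rnorm(m, 4), m, 1)
    p <- make_patient(y, omega = c(1, 0), T_i = m, delta = 0)
    sm <- lsdsm_smooth(p, pr)
    ora <- batch_smoother_oracle(y, assemble_A(pr), assemble_W(pr),
                                 pr$structure$C, pr$V, pr$x1_bar, pr$W1_bar)
    for (j in 1:m) {
      idx <- (j - 1) * 2 + 1:2
      expect_equal(sm$mu_hat[j, ], ora$mu[idx], tolerance = 1e-8)
      expect_equal(sm$Sigma_hat[[j]], (ora$P[idx, idx] + t(ora$P[idx, idx])) / 2,
                   tolerance = 1e-8)
      if (j > 1) {
        idx0 <- (j - 2) * 2 + 1:2
        # lag-one cross covariance against the batch joint
        expect_equal(sm$lag_one[[j]], ora$P[idx, idx0], tolerance = 1e-8)
        # definitional identity
        expect_equal(sm$lag_one[[j]],
                     sm$Sigma_hat[[j]] %*% t(sm$J[[j - 1]]), tolerance = 1e-12)
      }
    }
  }
})

test_that("single-step smoothing returns the filtered belief", {
  pr <- rand_params(42)
  p <- make_patient(matrix(5.1), omega = c(1, 0), T_i = 0.7, delta = 1)
  fl <- lsdsm_filter(p, pr)
  sm <- rts_backward(fl$filtered, fl$predicted, pr)
  expect_equal(sm$mu_hat[1, ], fl$filtered[[1]]$mu)
  expect_equal(sm$Sigma_hat[[1]], fl$filtered[[1]]$Sigma)
})

test_that("posterior covariances stay symmetric PSD and smoothing shrinks them", {
  pr <- rand_params(7)
  set.seed(70)
  y <- matrix(rnorm(8, 4), 8, 1); y[c(2, 5), 1] <- NA
  p <- make_patient(y, omega = c(1, 1), T_i = 7.4, delta = 1)
  fl <- lsdsm_filter(p, pr)
  sm <- rts_backward(fl$filtered, fl$predicted, pr)
  for (j in 1:p$m) {
    S <- sm$Sigma_hat[[j]]
    expect_lt(max(abs(S - t(S))), 1e-8)
    expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values),
              -1e-10)
  }
  expect_equal(sm$Sigma_hat[[p$m]], fl$filtered[[p$m]]$Sigma)
  # smoothing never increases the final-state marginal variance
  expect_lte(sm$Sigma_hat[[p$m]][1, 1], fl$filtered[[p$m]]$Sigma[1, 1] + 1e-12)
})

test_that("missing-observation expectations match conditional-Gaussian logic", {
  st <- canonical_structure(2, 1)
  V <- matrix(c(0.4, 0.15, 0.15, 0.3), 2, 2)
  pr <- lsdsm_params(st, A_bar = diag(2) * 0.9, W_breve = diag(2) * 0.1,
                     V = V, x1_bar = c(0, 0), W1_bar = diag(2),
                     gamma = 0, alpha = c(0, 0))
  mu <- c(1.2, -0.4)
  Sg <- matrix(c(0.5, 0.1, 0.1, 0.7), 2, 2)
  bel <- list(mu = mu, Sigma = Sg)

  # fully observed
  y_full <- c(1.0, -0.2)
  ob <- expected_observation_moments(y_full, bel, pr)
  expect_equal(ob$Ey, y_full)
  expect_equal(ob$Eyy, tcrossprod(y_full))
  expect_equal(ob$Eyx, tcrossprod(y_full, mu))

  # fully missing
  ob2 <- expected_observation_moments(c(NA, NA), bel, pr)
  expect_equal(ob2$Ey, mu)  # C = I here
  expect_equal(ob2$Eyy, V + Sg + tcrossprod(mu), tolerance = 1e-12)

  # one component missing: conditional-Gaussian oracle for E[y2 | y1, x-belief]
  y_part <- c(1.0, NA)
  ob3 <- expected_observation_moments(y_part, bel, pr)
  # y = x + v; E[y2|y1,x] = x2 + V21/V11 (y1 - x1); then average over belief
  cond <- mu[2] + V[2, 1] / V[1, 1] * (y_part[1] - mu[1])
  expect_equal(ob3$Ey[2], cond, tolerance = 1e-12)
  expect_equal(ob3$Ey[1], y_part[1])
  # Monte-Carlo check of E[y2^2] and E[y2 x'] under the joint belief
  set.seed(99)
  n_mc <- 4e5
  xs <- matrix(rnorm(2 * n_mc), ncol = 2) %*% chol(Sg) +
    matrix(mu, n_mc, 2, byrow = TRUE)
  # the belief already conditions on the observed data, so plain draws apply
  mu_c <- xs[, 2] + V[2, 1] / V[1, 1] * (y_part[1] - xs[, 1])
  v_c <- V[2, 2] - V[2, 1]^2 / V[1, 1]
  expect_equal(ob3$Eyy[2, 2], mean(mu_c^2) + v_c, tolerance = 0.02)
  expect_equal(ob3$Eyx[2, ], colMeans(mu_c * xs), tolerance = 0.02)
})

test_that("compiled and reference E-step engines agree", {
  pr <- rand_params(77)
  set.seed(78)
  y <- matrix(rnorm(9, 5), 9, 1); y[c(3, 6), 1] <- NA
  p <- make_patient(y, omega = c(1, -0.4), T_i = 8.3, delta = 1)
  a <- lsdsm:::patient_stats_r(p, pr, nr_control())
  b <- lsdsm:::patient_stats_cpp(p, pr, nr_control())
  for (nm in c("mu1", "Ex1x1", "S11", "S10s", "S00s", "Sxx", "Syy", "Syx",
               "b", "s", "b_f", "s_f", "loglik_y", "mu_hat", "mu_f")) {
    expect_equal(as.numeric(a[[nm]]), as.numeric(b[[nm]]), tolerance = 1e-6,
                 label = nm)
  }
})
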