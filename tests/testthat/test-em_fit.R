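ar1_params <- function(a = 0.8, w = 0.3, v = 0.4, mu1 = 2, p1 = 1,
                       gamma = 0, alpha = 0) {
  st <- canonical_structure(1, 1)
  lsdsm_params(st, A_bar = matrix(a), W_breve = matrix(w), V = matrix(v),
               x1_bar = mu1, W1_bar = matrix(p1), gamma = gamma,
               alpha = alpha)
}

sim_ar1_cohort <- function(n, m, pars, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    x <- numeric(m)
    x[1] <- rnorm(1, pars$x1_bar, sqrt(pars$W1_bar[1, 1]))
    for (j in seq_len(m - 1)) {
      x[j + 1] <- pars$A_bar[1, 1] * x[j] +
        rnorm(1, 0, sqrt(pars$W_breve[1, 1]))
    }
    y <- matrix(x + rnorm(m, 0, sqrt(pars$V[1, 1])), m, 1)
    make_patient(y, omega = 0, T_i = m, delta = 0, id = paste0("p", i))
  })
}

test_that("E-step with alpha = 0 matches an independent linear-Gaussian E-step", {
  pr <- ar1_params()
  co <- sim_ar1_cohort(3, 6, pr, seed = 15)
  stats <- e_step(co, pr, fit_control(engine = "r"))
  # oracle: batch joint-Gaussian smoother per patient, moments summed
  S11 <- S10 <- S00 <- sum_mu1 <- sum_E11 <- Sxx <- Syx <- 0
  for (p in co) {
    ora <- batch_smoother_oracle(p$y, matrix(pr$A_bar), matrix(pr$W_breve),
                                 matrix(1), matrix(pr$V[1, 1]),
                                 pr$x1_bar, matrix(pr$W1_bar))
    m <- p$m
    Exx <- diag(ora$P)[1:m] + ora$mu^2
    sum_mu1 <- sum_mu1 + ora$mu[1]
    sum_E11 <- sum_E11 + Exx[1]
    S11 <- S11 + sum(Exx[1:(m - 1)])
    S00 <- S00 + sum(Exx[2:m])
    lag <- vapply(2:m, function(j) ora$P[j, j - 1] + ora$mu[j] * ora$mu[j - 1],
                  numeric(1))
    S10 <- S10 + sum(lag)
    Sxx <- Sxx + sum(Exx)
    Syx <- Syx + sum(p$y[, 1] * ora$mu)
  }
  expect_equal(stats$sum_mu1, sum_mu1, tolerance = 1e-8)
  expect_equal(stats$sum_Ex1x1[1, 1], sum_E11, tolerance = 1e-8)
  expect_equal(stats$S11[1, 1], S11, tolerance = 1e-8)
  expect_equal(stats$S10s[1, 1], S10, tolerance = 1e-8)
  expect_equal(stats$S00s[1, 1], S00, tolerance = 1e-8)
  expect_equal(stats$Sxx[1, 1], Sxx, tolerance = 1e-8)
  expect_equal(stats$Syx[1, 1], Syx, tolerance = 1e-8)

  expect_error(e_step(list(), pr), "empty cohort")
})

test_that("m = 1 cohorts populate only initial-state terms", {
  pr <- ar1_params()
  p <- make_patient(matrix(1.7), omega = 0, T_i = 1, delta = 0)
  stats <- e_step(list(p), pr, fit_control(engine = "r"))
  expect_equal(stats$N_trans, 0L)
  expect_equal(stats$S11[1, 1], 0)
  expect_equal(stats$S10s[1, 1], 0)
  up <- update_state_params(stats, pr)
  sm <- lsdsm_smooth(p, pr)
  expect_equal(up$x1_bar, sm$mu_hat[1, ])
  expect_equal(up$W1_bar[1, 1], sm$Sigma_hat[[1]][1, 1], tolerance = 1e-10)
  # dynamics untouched without transitions
  expect_equal(up$A_bar, pr$A_bar)
})

test_that("noise-free transition update is the least-squares regression", {
  # craft sufficient statistics from a deterministic state sequence
  set.seed(33)
  m <- 40
  x <- matrix(0, m, 2)
  x[1, ] <- c(5, 4)
  A <- matrix(c(1.2, -0.3, 1, 0), 2, 2, byrow = TRUE)
  for (j in 2:m) x[j, ] <- A %*% x[j - 1, ] + c(rnorm(1, 0, 0.2), 0)
  stats <- list(n = 1, N_steps = m, N_trans = m - 1,
                sum_mu1 = x[1, ], sum_Ex1x1 = tcrossprod(x[1, ]),
                S11 = crossprod(x[-m, ]),
                S10s = t(x[-1, 1, drop = FALSE]) %*% x[-m, ],
                S00s = crossprod(x[-1, 1, drop = FALSE]),
                Sxx = crossprod(x), Syy = matrix(crossprod(x[, 1]), 1, 1),
                Syx = t(x[, 1, drop = FALSE]) %*% x)
  st <- canonical_structure(1, 2)
  pr0 <- lsdsm_params(st, A_bar = matrix(c(0, 0), 1, 2),
                      W_breve = matrix(1), V = matrix(1), x1_bar = c(0, 0),
                      W1_bar = diag(2), gamma = 0, alpha = 0)
  up <- update_state_params(stats, pr0)
  ls_fit <- lm.fit(x[-m, ], x[-1, 1])
  expect_equal(as.numeric(up$A_bar), unname(ls_fit$coefficients),
               tolerance = 1e-10)
})

test_that("Q is stationary at the closed-form state updates", {
  pr <- ar1_params()
  co <- sim_ar1_cohort(4, 7, pr, seed = 44)
  stats <- e_step(co, pr, fit_control(engine = "r"))
  up <- update_state_params(stats, pr)
  q0 <- expected_complete_loglik(stats, up)
  eps <- 1e-5
  for (field in c("A_bar", "W_breve", "V", "x1_bar", "W1_bar")) {
    th <- up
    th[[field]][1] <- th[[field]][1] + eps
    q_plus <- expected_complete_loglik(stats, th)
    th[[field]][1] <- th[[field]][1] - 2 * eps
    q_minus <- expected_complete_loglik(stats, th)
    grad <- (q_plus - q_minus) / (2 * eps)
    expect_lt(abs(grad) / max(1, abs(q0)), 1e-5)
  }
  # additivity: duplicating the cohort doubles Q (constants dropped)
  stats2 <- e_step(c(co, co), pr, fit_control(engine = "r"))
  expect_equal(expected_complete_loglik(stats2, up), 2 * q0, tolerance = 1e-8)
})

test_that("survival M-step matches a derivative-free optimizer when states are exact", {
  # degenerate smoothed moments (Sigma_hat = 0) reduce the objective to a
  # piecewise-exponential PH log-likelihood
  set.seed(55)
  n_steps <- 300
  stats <- list(B = matrix(rnorm(n_steps, 1, 0.7), ncol = 1),
                Sflat = matrix(0, n_steps, 1),
                Omega = cbind(1, rnorm(n_steps)),
                tau = runif(n_steps, 0.3, 1),
                dbar = rbinom(n_steps, 1, 0.25))
  sv <- update_survival_params(stats, c(0, 0), 0, nr_control())
  ph_loglik <- function(th) {
    eta <- stats$Omega %*% th[1:2] + stats$B * th[3]
    -sum(stats$dbar * eta - stats$tau * exp(eta))
  }
  o <- optim(c(0, 0, 0), ph_loglik, method = "Nelder-Mead",
             control = list(maxit = 5000, reltol = 1e-12))
  expect_equal(c(sv$gamma, sv$alpha), o$par, tolerance = 1e-4)
  # stationarity of the analytic gradient
  ob <- lsdsm:::survival_objective(c(sv$gamma, sv$alpha), stats, 2, 1,
                                   want = c("f", "grad"))
  expect_lt(max(abs(ob$grad)), 1e-5)

  # gradient and Hessian agree with finite differences (Sigma_hat > 0 case)
  stats$Sflat <- matrix(runif(n_steps, 0, 0.4), ncol = 1)
  th0 <- c(0.3, -0.2, -0.5)
  ob0 <- lsdsm:::survival_objective(th0, stats, 2, 1,
                                    want = c("f", "grad", "hess"))
  eps <- 1e-6
  for (k in 1:3) {
    e <- numeric(3); e[k] <- eps
    fp <- lsdsm:::survival_objective(th0 + e, stats, 2, 1, want = "f")$f
    fm <- lsdsm:::survival_objective(th0 - e, stats, 2, 1, want = "f")$f
    expect_equal(ob0$grad[k], (fp - fm) / (2 * eps),
                 tolerance = 1e-5)
    gp <- lsdsm:::survival_objective(th0 + e, stats, 2, 1, want = "grad")$grad
    gm <- lsdsm:::survival_objective(th0 - e, stats, 2, 1, want = "grad")$grad
    expect_equal(ob0$hess[, k], (gp - gm) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("degenerate no-event data are guarded and reported", {
  stats <- list(B = matrix(rnorm(50), ncol = 1), Sflat = matrix(0, 50, 1),
                Omega = matrix(1, 50, 1), tau = rep(1, 50),
                dbar = rep(0, 50))
  expect_warning(sv <- update_survival_params(stats, 0, 0, nr_control()),
                 "no events")
  expect_false(sv$converged)
  expect_equal(sv$gamma, 0)
})

test_that("initialization is stable and anchored at the data", {
  co <- lapply(1:6, function(i)
    make_patient(matrix(rep(3, 5), 5, 1), omega = 0, T_i = 5, delta = 0,
                 id = i))
  st <- canonical_structure(1, 2)
  init <- initialize_params(co, st)
  expect_equal(init$x1_bar, c(3, 3))
  A <- assemble_A(init)
  expect_lt(max(Mod(eigen(A, only.values = TRUE)$values)), 1)
  expect_equal(init$gamma, 0)
  expect_equal(init$alpha, 0)
  # no observations anywhere -> error
  co_na <- lapply(co, function(p) { p$y[] <- NA; p$observed_mask[] <- FALSE; p })
  expect_error(initialize_params(co_na, st), "no observed measurements")
})

test_that("EM with survival switched off matches an independent SSM EM", {
  pr_true <- ar1_params(a = 0.7, w = 0.25, v = 0.5, mu1 = 1.5, p1 = 0.8)
  co <- sim_ar1_cohort(25, 10, pr_true, seed = 66)
  init <- ar1_params(a = 0.5, w = 0.5, v = 0.5, mu1 = 0, p1 = 1)
  n_it <- 15
  ctl <- fit_control(tol = 0, max_iter = n_it, update_survival = FALSE,
                     engine = "r")
  fit <- suppressWarnings(lsdsm_fit(co, pr_true$structure, ctl, init = init))
  ys <- lapply(co, function(p) p$y[, 1])
  ora <- shumway_stoffer_em(ys, n_it, a0 = 0.5, w0 = 0.5, v0 = 0.5,
                            mu0 = 0, p0 = 1)
  expect_equal(fit$params$A_bar[1, 1], ora$a, tolerance = 1e-6)
  expect_equal(fit$params$W_breve[1, 1], ora$w, tolerance = 1e-6)
  expect_equal(fit$params$V[1, 1], ora$v, tolerance = 1e-6)
  expect_equal(fit$params$x1_bar, ora$mu1, tolerance = 1e-6)
  # exact-Gaussian case: observed-data log-likelihood is monotone across EM
  expect_true(all(diff(fit$loglik_y_trace) > -1e-8))
})

test_that("fit loop honours iteration and tolerance boundaries", {
  pr_true <- ar1_params(a = 0.7, w = 0.25, v = 0.5)
  co <- sim_ar1_cohort(10, 8, pr_true, seed = 88)
  fit1 <- lsdsm_fit(co, pr_true$structure,
                    fit_control(tol = 1e9, max_iter = 5, engine = "r",
                                update_survival = FALSE))
  expect_equal(fit1$n_iter, 1L)
  expect_true(fit1$converged)
  fit2 <- lsdsm_fit(co, pr_true$structure,
                    fit_control(tol = 0, max_iter = 3, engine = "r",
                                update_survival = FALSE))
  expect_equal(fit2$n_iter, 3L)
  expect_false(fit2$converged)
  expect_length(fit2$q_trace, 3L)
})

test_that("pooled statistics are invariant to patient order", {
  pr <- ar1_params(gamma = c(-1), alpha = 0.6)
  co <- sim_ar1_cohort(5, 6, pr, seed = 91)
  co <- lapply(co, function(p) { p$omega <- 1; p })
  s1 <- e_step(co, pr, fit_control())
  s2 <- e_step(rev(co), pr, fit_control())
  for (nm in c("sum_mu1", "sum_Ex1x1", "S11", "S10s", "S00s", "Sxx", "Syy",
               "Syx")) {
    expect_equal(s1[[nm]], s2[[nm]], tolerance = 1e-10)
  }
})
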