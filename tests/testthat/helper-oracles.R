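# Independent oracles, written from textbook definitions and kept free of the
# package's own filtering/EM code paths.

# --- textbook Kalman predict/update (joseph-free, straightforward algebra) ---
kalman_predict_oracle <- function(mu, Sigma, A, W) {
  list(mu = as.numeric(A %*% mu), Sigma = A %*% Sigma %*% t(A) + W)
}

kalman_update_oracle <- function(mu, Sigma, y, C, V) {
  S <- C %*% Sigma %*% t(C) + V
  K <- Sigma %*% t(C) %*% solve(S)
  list(mu = as.numeric(mu + K %*% (y - C %*% mu)),
       Sigma = Sigma - K %*% C %*% Sigma)
}

# --- batch joint-Gaussian smoother: stack all states, condition on observed
# measurements directly (exact for the linear-Gaussian model, alpha = 0) ---
batch_smoother_oracle <- function(y, A, W, C, V, x1_bar, W1_bar) {
  m <- nrow(y)
  m_x <- ncol(A)
  m_y <- nrow(C)
  # joint prior over (x_1, ..., x_m)
  mu <- numeric(m * m_x)
  mu[1:m_x] <- x1_bar
  for (j in 2:m) mu[(j - 1) * m_x + 1:m_x] <- A %*% mu[(j - 2) * m_x + 1:m_x]
  P <- matrix(0, m * m_x, m * m_x)
  P[1:m_x, 1:m_x] <- W1_bar
  for (j in 2:m) {
    i2 <- (j - 1) * m_x + 1:m_x
    i1 <- (j - 2) * m_x + 1:m_x
    P[i2, i2] <- A %*% P[i1, i1] %*% t(A) + W
    for (k in 1:(j - 1)) {           # cross-covariances propagate linearly
      ik <- (k - 1) * m_x + 1:m_x
      P[i2, ik] <- A %*% P[i1, ik]
      P[ik, i2] <- t(P[i2, ik])
    }
  }
  # observation operator over observed cells only
  rows <- list(); obs_y <- c()
  for (j in 1:m) {
    for (k in 1:m_y) {
      if (!is.na(y[j, k])) {
        r <- numeric(m * m_x)
        r[(j - 1) * m_x + 1:m_x] <- C[k, ]
        rows[[length(rows) + 1]] <- r
        obs_y <- c(obs_y, y[j, k])
      }
    }
  }
  Hm <- do.call(rbind, rows)
  Vfull <- diag(0, length(obs_y))
  # measurement noise: independent across time, V across biomarkers
  idx <- 0
  for (j in 1:m) {
    ks <- which(!is.na(y[j, ]))
    if (length(ks)) {
      Vfull[idx + seq_along(ks), idx + seq_along(ks)] <-
        V[ks, ks, drop = FALSE]
      idx <- idx + length(ks)
    }
  }
  S <- Hm %*% P %*% t(Hm) + Vfull
  K <- P %*% t(Hm) %*% solve(S)
  mu_post <- mu + as.numeric(K %*% (obs_y - Hm %*% mu))
  P_post <- P - K %*% Hm %*% P
  list(mu = mu_post, P = P_post, m_x = m_x)
}

# --- 1-D oracle for the survival-corrected posterior ---
# unnormalized log posterior: log N(x; mu_p, P) + log N(y; x, V) (if observed)
#   + dbar*(g+ax) - tau*exp(g+ax).
# Mode found by generic 1-D optimization; the Laplace variance is the inverse
# negative curvature at the mode, taken by central finite differences; the
# exact normalized mean/variance come from dense-grid quadrature.
quadrature_posterior_oracle <- function(mu_p, P, y, V, g, a, tau, dbar,
                                        span = 12, n_grid = 40001) {
  sd0 <- sqrt(P)
  logpost <- function(x) {
    lp <- dnorm(x, mu_p, sd0, log = TRUE)
    if (!is.na(y)) lp <- lp + dnorm(y, x, sqrt(V), log = TRUE)
    eta <- g + a * x
    lp + dbar * eta - tau * exp(eta)
  }
  opt <- optimize(logpost, c(mu_p - span * sd0, mu_p + span * sd0),
                  maximum = TRUE, tol = 1e-12)
  h <- 1e-4 * sd0
  curv <- (logpost(opt$maximum + h) - 2 * logpost(opt$maximum) +
             logpost(opt$maximum - h)) / h^2
  xs <- seq(mu_p - span * sd0, mu_p + span * sd0, length.out = n_grid)
  w <- exp(logpost(xs) - opt$objective)
  w <- w / sum(w)
  mo <- sum(w * xs)
  list(mode = opt$maximum, laplace_var = -1 / curv,
       mean = mo, var = sum(w * (xs - mo)^2))
}

# --- independent EM for the plain linear-Gaussian SSM (no survival),
# Shumway-Stoffer style, scalar state (AR(1), m_x = m_y = 1) ---
shumway_stoffer_em <- function(ys, n_iter, a0, w0, v0, mu0, p0) {
  a <- a0; w <- w0; v <- v0; mu1 <- mu0; p1 <- p0
  n <- length(ys)
  for (it in 1:n_iter) {
    m <- vapply(ys, length, integer(1))
    # E-step per series: filter + smooth (textbook scalar recursions)
    S11 <- S10 <- S00 <- Sxx <- Syy <- Syx <- 0
    sm1 <- 0; sm1sq <- 0
    Nst <- 0
    for (s in ys) {
      mm <- length(s)
      mp <- numeric(mm); pp <- numeric(mm)
      mf <- numeric(mm); pf <- numeric(mm)
      for (j in 1:mm) {
        mp[j] <- if (j == 1) mu1 else a * mf[j - 1]
        pp[j] <- if (j == 1) p1 else a^2 * pf[j - 1] + w
        k <- pp[j] / (pp[j] + v)
        mf[j] <- mp[j] + k * (s[j] - mp[j])
        pf[j] <- (1 - k) * pp[j]
      }
      mh <- numeric(mm); ph <- numeric(mm); J <- numeric(mm)
      mh[mm] <- mf[mm]; ph[mm] <- pf[mm]
      if (mm > 1) for (j in (mm - 1):1) {
        J[j] <- pf[j] * a / pp[j + 1]
        mh[j] <- mf[j] + J[j] * (mh[j + 1] - mp[j + 1])
        ph[j] <- pf[j] + J[j]^2 * (ph[j + 1] - pp[j + 1])
      }
      lag1 <- numeric(mm)
      if (mm > 1) for (j in 2:mm) lag1[j] <- ph[j] * J[j - 1]
      Exx <- ph + mh^2
      sm1 <- sm1 + mh[1]; sm1sq <- sm1sq + Exx[1]
      if (mm > 1) {
        S11 <- S11 + sum(Exx[1:(mm - 1)])
        S10 <- S10 + sum(lag1[2:mm] + mh[2:mm] * mh[1:(mm - 1)])
        S00 <- S00 + sum(Exx[2:mm])
      }
      Sxx <- Sxx + sum(Exx)
      Syy <- Syy + sum(s^2)
      Syx <- Syx + sum(s * mh)
      Nst <- Nst + mm
    }
    ns <- length(ys)
    mu1 <- sm1 / ns
    p1 <- sm1sq / ns - mu1^2
    a <- S10 / S11
    w <- (S00 - 2 * a * S10 + a^2 * S11) / (Nst - ns)
    v <- (Syy - 2 * Syx + Sxx) / Nst
  }
  list(a = a, w = w, v = v, mu1 = mu1, p1 = p1)
}

# --- brute-force AUC over case/control pairs (no censoring) ---
pair_auc_oracle <- function(score, is_case, is_control) {
  num <- 0; den <- 0
  for (i in which(is_case)) {
    for (j in which(is_control)) {
      num <- num + (score[i] > score[j]) + 0.5 * (score[i] == score[j])
      den <- den + 1
    }
  }
  num / den
}

# small helper: build a gridded patient directly from already-binned values
make_patient <- function(y, omega, T_i, delta, dt = 1, id = "p") {
  y <- if (is.null(dim(y))) matrix(y, ncol = 1) else y
  m <- as.integer(ceiling(T_i / dt))
  stopifnot(nrow(y) == m)
  tau <- rep(dt, m); tau[m] <- T_i - (m - 1) * dt
  db <- rep(0L, m); if (delta == 1) db[m] <- 1L
  structure(list(patient_id = id, omega = omega, dt = dt, y = y,
                 observed_mask = !is.na(y), T = T_i,
                 delta = as.integer(delta), m = m, tau = tau,
                 delta_bar = db),
            class = "lsdsm_patient")
}
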