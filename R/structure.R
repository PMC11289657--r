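#' Canonical state-space structure for an AR(M) biomarker model
#'
#' Builds the fixed structural matrices of the canonical state-space form used
#' throughout the package.  With `m_y` observed biomarkers tracked by an
#' autoregressive process of order `M`, the hidden state stacks the current
#' and `M - 1` lagged true biomarker vectors, giving `m_x = M * m_y` states.
#' Identifiability is enforced by fixing the observation matrix to
#' `C = [I 0]`, loading the process disturbance only on the leading block via
#' `G = [I 0]'`, and constraining the transition matrix to companion form
#' `A = rbind(A_bar, [I 0])` so that only its first `m_y` rows are free.
#'
#' @param m_y Number of observed biomarkers (>= 1).
#' @param M Autoregressive order (>= 1).
#' @param H Optional hazard-association matrix with `m_x` columns selecting
#'   which linear combinations of the hidden states enter the log-hazard.
#'   Defaults to `[I 0]`, the current-value association.
#'
#' @return An object of class `lsdsm_structure`: a list with elements
#'   `m_y`, `M`, `m_x`, `m_alpha`, `C`, `G`, `H` and `A_lower` (the fixed
#'   lower block of the transition matrix).
#' @export
#' @examples
#' canonical_structure(1, 2)
canonical_structure <- function(m_y, M, H = NULL) {
  stopifnot(length(m_y) == 1L, length(M) == 1L)
  m_y <- as.integer(m_y)
  M <- as.integer(M)
  if (m_y < 1L || M < 1L) {
    stop("'m_y' and 'M' must both be >= 1", call. = FALSE)
  }
  m_x <- M * m_y
  I_y <- diag(m_y)
  C <- cbind(I_y, matrix(0, m_y, m_x - m_y))
  G <- t(C)
  if (is.null(H)) {
    H <- C
  } else {
    H <- rbind(H)
    if (ncol(H) != m_x) {
      stop(sprintf("'H' must have %d columns, got %d", m_x, ncol(H)),
           call. = FALSE)
    }
  }
  # lower companion block [I 0] (absent when M = 1)
  A_lower <- if (M > 1L) {
    cbind(diag((M - 1L) * m_y), matrix(0, (M - 1L) * m_y, m_y))
  } else {
    matrix(0, 0L, m_x)
  }
  structure(list(m_y = m_y, M = M, m_x = m_x, m_alpha = nrow(H),
                 C = C, G = G, H = H, A_lower = A_lower),
            class = "lsdsm_structure")
}

#' @export
print.lsdsm_structure <- function(x, ...) {
  cat(sprintf(
    "Canonical AR(%d) state-space structure: %d biomarker(s), %d hidden state(s)\n",
    x$M, x$m_y, x$m_x))
  cat(sprintf("  C = [I 0] (%d x %d), G = [I 0]', H (%d x %d)\n",
              x$m_y, x$m_x, x$m_alpha, x$m_x))
  invisible(x)
}

#' Model parameters of the state-space survival model
#'
#' Bundles every estimable parameter: the free transition block `A_bar`
#' (`m_y` x `m_x`), the reduced disturbance covariance `W_breve`
#' (`m_y` x `m_y`), the measurement-error covariance `V` (`m_y` x `m_y`),
#' the initial state mean `x1_bar` (`m_x`) and covariance `W1_bar`
#' (`m_x` x `m_x`), the baseline-covariate log-hazard coefficients `gamma`
#' and the state-association log-hazard coefficients `alpha`.
#'
#' @param structure An [canonical_structure()] object.
#' @param A_bar Free transition block, `m_y` x `m_x`.
#' @param W_breve Reduced disturbance covariance, `m_y` x `m_y`, symmetric PSD.
#' @param V Measurement-error covariance, `m_y` x `m_y`, symmetric PSD.
#' @param x1_bar Initial state mean, length `m_x`.
#' @param W1_bar Initial state covariance, `m_x` x `m_x`, symmetric PSD.
#' @param gamma Baseline-covariate coefficients (length sets `m_omega`).
#' @param alpha State-association coefficients, length `m_alpha`.
#'
#' @return An object of class `lsdsm_params`.
#' @export
lsdsm_params <- function(structure, A_bar, W_breve, V, x1_bar, W1_bar,
                         gamma, alpha) {
  stopifnot(inherits(structure, "lsdsm_structure"))
  m_y <- structure$m_y
  m_x <- structure$m_x
  A_bar <- rbind(A_bar)
  W_breve <- as_cov(W_breve, m_y, "W_breve")
  V <- as_cov(V, m_y, "V")
  W1_bar <- as_cov(W1_bar, m_x, "W1_bar")
  x1_bar <- as.numeric(x1_bar)
  gamma <- as.numeric(gamma)
  alpha <- as.numeric(alpha)
  if (!identical(dim(A_bar), c(m_y, m_x))) {
    stop(sprintf("'A_bar' must be %d x %d", m_y, m_x), call. = FALSE)
  }
  if (length(x1_bar) != m_x) {
    stop(sprintf("'x1_bar' must have length %d", m_x), call. = FALSE)
  }
  if (length(alpha) != structure$m_alpha) {
    stop(sprintf("'alpha' must have length %d", structure$m_alpha),
         call. = FALSE)
  }
  structure(list(structure = structure, A_bar = A_bar, W_breve = W_breve,
                 V = V, x1_bar = x1_bar, W1_bar = W1_bar,
                 gamma = gamma, alpha = alpha,
                 m_omega = length(gamma)),
            class = "lsdsm_params")
}

# validate / coerce a covariance argument
as_cov <- function(S, d, name) {
  S <- as.matrix(S)
  if (!identical(dim(S), c(d, d))) {
    stop(sprintf("'%s' must be %d x %d", name, d, d), call. = FALSE)
  }
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S)))) {
    stop(sprintf("'%s' must be symmetric", name), call. = FALSE)
  }
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(1, max(abs(ev)))) {
    stop(sprintf("'%s' must be positive semi-definite", name), call. = FALSE)
  }
  S
}

#' Assemble the full transition matrix A
#'
#' Stacks the free block over the fixed companion block `[I 0]`, so the
#' lower `(M-1)*m_y` rows of the result always satisfy the canonical mask.
#'
#' @param params An [lsdsm_params()] object.
#' @return The `m_x` x `m_x` transition matrix.
#' @export
assemble_A <- function(params) {
  rbind(params$A_bar, params$structure$A_lower)
}

#' Assemble the full disturbance covariance W = G W_breve G'
#'
#' The result has rank at most `m_y`: in the canonical form the disturbance
#' acts only on the leading biomarker block, the lagged states being
#' deterministic copies.
#'
#' @param params An [lsdsm_params()] object.
#' @return The `m_x` x `m_x` (singular for `M > 1`) disturbance covariance.
#' @export
assemble_W <- function(params) {
  G <- params$structure$G
  G %*% params$W_breve %*% t(G)
}

#' @export
print.lsdsm_params <- function(x, ...) {
  s <- x$structure
  cat(sprintf("State-space survival model parameters (m_y = %d, M = %d, m_x = %d)\n",
              s$m_y, s$M, s$m_x))
  cat("A_bar:\n"); print(x$A_bar)
  cat("W_breve:\n"); print(x$W_breve)
  cat("V:\n"); print(x$V)
  cat("x1_bar:", format(x$x1_bar), "\n")
  cat("gamma: ", format(x$gamma), "\n")
  cat("alpha: ", format(x$alpha), "\n")
  invisible(x)
}

# flatten all free parameters to one named numeric vector (for convergence
# checks and serialization)
params_to_vector <- function(params) {
  c(x1_bar = params$x1_bar,
    W1_bar = as.numeric(params$W1_bar),
    A_bar = as.numeric(params$A_bar),
    W_breve = as.numeric(params$W_breve),
    V = as.numeric(params$V),
    gamma = params$gamma,
    alpha = params$alpha)
}
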