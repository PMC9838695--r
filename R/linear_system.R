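#' Linear stochastic (Ornstein-Uhlenbeck) network system
#'
#' Container for the uncontrolled dynamics `dx = A x dt + C dw`, parameterized
#' by the drift matrix `A` (units 1/time) and the noise covariance rate
#' `S_C = C C'` (signal^2/time). Only `S_C` is stored: it is sufficient for
#' every cost computation, and is what the estimation pipeline identifies.
#'
#' @param A n x n drift matrix.
#' @param S_C n x n symmetric positive-definite noise covariance rate.
#' @return An object of class `linear_system` with fields `A`, `S_C`, `n`.
#' @examples
#' sys <- linear_system(A = -diag(2), S_C = diag(2))
#' steady_state(sys)
#' @export
linear_system <- function(A, S_C) {
  if (!is_square_numeric(A) || !is_square_numeric(S_C) || nrow(A) != nrow(S_C)) {
    cb_stop("A and S_C must be square numeric matrices of equal dimension",
            "ctrlbridge_invalid_argument")
  }
  check_finite(A, "A"); check_finite(S_C, "S_C")
  nS <- norm(S_C, "F")
  if (nS > 0 && norm(S_C - t(S_C), "F") / nS > 1e-10) {
    cb_stop("S_C is not symmetric within tolerance 1e-10",
            "ctrlbridge_invalid_argument")
  }
  S_C <- (S_C + t(S_C)) / 2
  ev <- eigen(S_C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev)) {
    cb_stop("S_C must be positive definite (noise of full rank)",
            "ctrlbridge_singular_noise_error")
  }
  structure(list(A = unname(A), S_C = unname(S_C), n = nrow(A)),
            class = "linear_system")
}

#' @export
print.linear_system <- function(x, ...) {
  lam <- eigen(x$A, only.values = TRUE)$values
  cat(sprintf("<linear_system> n = %d, max Re(eigen(A)) = %.4g\n",
              x$n, max(Re(lam))))
  invisible(x)
}

#' Gaussian state distribution
#'
#' A brain-state distribution N(mu, sigma): the marginal law of activity
#' across the n network nodes at one moment.
#'
#' @param mu Mean vector (signal units).
#' @param sigma Covariance matrix (signal^2), symmetric positive semidefinite.
#' @return An object of class `gaussian_state` with fields `mu`, `sigma`.
#' @export
gaussian_state <- function(mu, sigma) {
  mu <- as.numeric(mu)
  if (!is_square_numeric(sigma) || nrow(sigma) != length(mu)) {
    cb_stop("sigma must be a square matrix conformable with mu",
            "ctrlbridge_invalid_argument")
  }
  check_finite(mu, "mu"); check_finite(sigma, "sigma")
  ns <- norm(sigma, "F")
  if (ns > 0 && norm(sigma - t(sigma), "F") / ns > 1e-10) {
    cb_stop("sigma is not symmetric within tolerance 1e-10",
            "ctrlbridge_invalid_argument")
  }
  sigma <- (sigma + t(sigma)) / 2
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (length(ev) && min(ev) < -1e-12 * max(abs(ev), 1)) {
    cb_stop("sigma must be positive semidefinite", "ctrlbridge_invalid_argument")
  }
  structure(list(mu = mu, sigma = unname(sigma)), class = "gaussian_state")
}

#' @export
print.gaussian_state <- function(x, ...) {
  cat(sprintf("<gaussian_state> n = %d, |mu| = %.4g, tr(sigma) = %.4g\n",
              length(x$mu), sqrt(sum(x$mu^2)), sum(diag(x$sigma))))
  invisible(x)
}

#' State transition matrix Phi(dt) = exp(A dt)
#'
#' @param system A [linear_system()].
#' @param dt Time offset; may be zero or negative.
#' @return The n x n matrix exponential of `A * dt`.
#' @export
transition_matrix <- function(system, dt) {
  stopifnot(inherits(system, "linear_system"))
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt)) {
    cb_stop("dt must be a single finite number", "ctrlbridge_invalid_argument")
  }
  if (dt == 0) return(diag(system$n))
  expm_dense(system$A * dt)
}

#' Steady-state distribution of the uncontrolled dynamics
#'
#' Solves the continuous Lyapunov equation `A S + S A' + S_C = 0` for the
#' stationary covariance; the stationary mean is zero. Requires `A` stable
#' (all eigenvalues with real part below -1e-10).
#'
#' @param system A [linear_system()].
#' @return A [gaussian_state()] with `mu = 0` and the stationary covariance.
#' @export
steady_state <- function(system) {
  stopifnot(inherits(system, "linear_system"))
  lam <- eigen(system$A, only.values = TRUE)$values
  worst <- lam[which.max(Re(lam))]
  if (max(Re(lam)) >= -1e-10) {
    cb_stop(sprintf("drift matrix is not stable: eigenvalue %s has Re >= -1e-10",
                    format(worst, digits = 6)),
            "ctrlbridge_stability_error")
  }
  Sigma <- solve_lyapunov(system$A, system$S_C)
  gaussian_state(rep(0, system$n), Sigma)
}

#' Propagate a Gaussian state under the uncontrolled dynamics
#'
#' Moment propagation over a horizon `T`:
#' `m_T = e^{AT} mu0`, `S_T = e^{AT} Sigma0 e^{A'T} + int_0^T e^{As} S_C e^{A's} ds`.
#'
#' @param system A [linear_system()].
#' @param state Initial [gaussian_state()].
#' @param T Nonnegative horizon.
#' @return The [gaussian_state()] at time `T`.
#' @export
propagate_uncontrolled <- function(system, state, T) {
  stopifnot(inherits(system, "linear_system"), inherits(state, "gaussian_state"))
  if (!is.numeric(T) || length(T) != 1L || !is.finite(T) || T < 0) {
    cb_stop("T must be a single finite nonnegative number",
            "ctrlbridge_invalid_argument")
  }
  if (T == 0) return(state)
  Phi <- transition_matrix(system, T)
  M <- van_loan_integral(system$A, system$S_C, T)
  gaussian_state(drop(Phi %*% state$mu),
                 symmetrize(Phi %*% state$sigma %*% t(Phi) + M, warn = FALSE))
}

#' Controllability Gramian of the stochastic system
#'
#' `M(T) = int_0^T Phi(T, tau) S_C Phi(T, tau)' dtau`, symmetric positive
#' definite for positive-definite `S_C`. Its eigenvectors indicate directions
#' in which steering the mean is cheap or expensive.
#'
#' @param system A [linear_system()].
#' @param T Positive horizon.
#' @return The n x n Gramian matrix.
#' @export
gramian <- function(system, T) {
  stopifnot(inherits(system, "linear_system"))
  if (!is.numeric(T) || length(T) != 1L || !is.finite(T) || T <= 0) {
    cb_stop("T must be a single positive number", "ctrlbridge_invalid_argument")
  }
  van_loan_integral(system$A, system$S_C, T)
}

#' Exact discretization of the OU dynamics at a sampling interval
#'
#' Returns the VAR(1) pair `(a, Sigma_dt)` with `a = e^{A dt}` and
#' `Sigma_dt = int_0^dt e^{As} S_C e^{A's} ds`, so that sampling
#' `x[t+dt] = a x[t] + eps`, `eps ~ N(0, Sigma_dt)` has exactly the law of the
#' continuous process on the grid.
#'
#' @param system A [linear_system()].
#' @param dt Positive sampling interval.
#' @return A list with elements `a` and `Sigma_dt`.
#' @export
exact_discretization <- function(system, dt) {
  stopifnot(inherits(system, "linear_system"))
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    cb_stop("dt must be a single positive number", "ctrlbridge_invalid_argument")
  }
  list(a = expm_dense(system$A * dt),
       Sigma_dt = van_loan_integral(system$A, system$S_C, dt))
}

#' Write / read a linear system as a plain JSON document
#'
#' The document stores `{n, A, S_C}` with matrices as row-major lists, so a
#' fitted system can be exchanged with other tools.
#'
#' @param system A [linear_system()].
#' @param path File path.
#' @return `write_linear_system` returns `path` invisibly;
#'   `read_linear_system` returns a [linear_system()].
#' @export
write_linear_system <- function(system, path) {
  stopifnot(inherits(system, "linear_system"))
  doc <- list(n = system$n,
              A = as.vector(t(system$A)),
              S_C = as.vector(t(system$S_C)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_linear_system
#' @export
read_linear_system <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- as.integer(doc$n)
  linear_system(matrix(doc$A, n, n, byrow = TRUE),
                matrix(doc$S_C, n, n, byrow = TRUE))
}

#' Write / read a numeric matrix as TSV
#'
#' @param X Numeric matrix.
#' @param path File path.
#' @export
write_matrix_tsv <- function(X, path) {
  # %.17g so doubles round-trip through text exactly
  Xc <- matrix(sprintf("%.17g", X), nrow(X), ncol(X))
  utils::write.table(Xc, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
}
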