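# Internal numerical helpers: symmetrization, matrix functions, Lyapunov and
# Van Loan integrals, seeded evaluation. None of these are exported.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
cb_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "ctrlbridge_error"), call = call))
}

#' @noRd
cb_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "ctrlbridge_warning")))
}

# Symmetrize, warning when the asymmetry is beyond tolerance (relative).
#' @noRd
symmetrize <- function(X, tol = 1e-8, warn = TRUE) {
  S <- (X + t(X)) / 2
  nx <- norm(X, "F")
  if (warn && nx > 0 && norm(X - t(X), "F") / nx > tol) {
    cb_warn(sprintf("matrix asymmetry %.3e exceeds tolerance %.1e; symmetrized",
                    norm(X - t(X), "F") / nx, tol),
            "ctrlbridge_asymmetry_warning")
  }
  S
}

#' @noRd
expm_dense <- function(X) {
  n <- nrow(X)
  if (n == 1L) return(matrix(exp(X[1, 1]), 1, 1))
  unname(as.matrix(Matrix::expm(Matrix::Matrix(X))))
}

# Symmetric PSD square root via eigendecomposition; negative ripple clipped.
#' @noRd
sqrtm_sym <- function(X) {
  e <- eigen((X + t(X)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

# Principal matrix logarithm through the (complex) eigendecomposition.
# Errors if an eigenvalue lies on the closed negative real axis (no real
# principal branch) or if the eigenbasis is too ill-conditioned to trust.
#' @noRd
logm_principal <- function(X, imag_tol = 1e-6) {
  if (nrow(X) == 1L) {
    x <- X[1, 1]
    if (x <= 0) {
      cb_stop(sprintf("matrix logarithm undefined: eigenvalue %.6g on the closed negative real axis; a smaller sampling interval is needed", x),
              "ctrlbridge_branch_error")
    }
    return(matrix(log(x), 1, 1))
  }
  e <- eigen(X)
  lam <- e$values
  on_cut <- Re(lam) <= 0 & abs(Im(lam)) <= 1e-12 * max(Mod(lam))
  if (any(on_cut)) {
    cb_stop(sprintf("matrix logarithm undefined: eigenvalue %s on the closed negative real axis; refit with a smaller sampling interval", format(lam[on_cut][1])),
            "ctrlbridge_branch_error")
  }
  V <- e$vectors
  Vi <- tryCatch(solve(V), error = function(e) NULL)
  if (is.null(Vi) || max(Mod(V)) * max(Mod(Vi)) > 1e13) {
    cb_stop("matrix logarithm failed: eigenvector basis numerically singular",
            "ctrlbridge_branch_error")
  }
  L <- V %*% (log(lam) * Vi)
  imag_res <- max(abs(Im(L))) / max(1, max(abs(Re(L))))
  if (imag_res > imag_tol) {
    cb_stop(sprintf("matrix logarithm imaginary residual %.3e exceeds %.1e; refit with a smaller sampling interval", imag_res, imag_tol),
            "ctrlbridge_branch_error")
  }
  Re(L)
}

# Continuous Lyapunov equation A X + X A' + Q = 0, solved in the eigenbasis of
# A (O(n^3)); falls back to the Kronecker linear system for defective A.
#' @noRd
solve_lyapunov <- function(A, Q) {
  n <- nrow(A)
  e <- eigen(A)
  V <- e$vectors
  ok <- tryCatch(rcond(Mod(V)) > 1e-12 || n == 1L, error = function(e) FALSE)
  if (ok) {
    Vi <- solve(V)
    Qt <- Vi %*% Q %*% t(Vi)  # transformed -Qdot
    denom <- outer(e$values, e$values, `+`)
    X <- V %*% (-Qt / denom) %*% t(V)
    X <- Re(X)
  } else {
    K <- kronecker(diag(n), A) + kronecker(A, diag(n))
    X <- matrix(solve(K, -as.vector(Q)), n, n)
  }
  (X + t(X)) / 2
}

# Van Loan block-exponential evaluation of int_0^T e^{A s} Q e^{A' s} ds.
# For long horizons the block exponential overflows (it contains e^{-A'T}),
# so the base interval is kept short and extended by the exact doubling
# recurrence M(2t) = Phi(t) M(t) Phi(t)' + M(t).
#' @noRd
van_loan_integral <- function(A, Q, T) {
  n <- nrow(A)
  k <- max(0, ceiling(log2(max(norm(A, "F") * T, 1e-300) / 2)))
  h <- T / 2^k
  H <- rbind(cbind(A, Q), cbind(matrix(0, n, n), -t(A)))
  E <- expm_dense(H * h)
  E12 <- E[seq_len(n), n + seq_len(n), drop = FALSE]
  E11 <- E[seq_len(n), seq_len(n), drop = FALSE]
  M <- E12 %*% t(E11)
  M <- (M + t(M)) / 2
  Phi <- E11
  for (i in seq_len(k)) {
    M <- Phi %*% M %*% t(Phi) + M
    M <- (M + t(M)) / 2
    Phi <- Phi %*% Phi
  }
  M
}

# Composite Simpson weights on a uniform grid with npts points (npts odd).
#' @noRd
simpson_weights <- function(npts, h) {
  stopifnot(npts >= 3L, npts %% 2L == 1L)
  w <- c(1, rep(c(4, 2), length.out = npts - 2L), 1)
  w[npts] <- 1
  w * h / 3
}

# Evaluate code with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards. All seeded generators in the package use this.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    cb_stop("seed must be a single finite number", "ctrlbridge_invalid_argument")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Draw m samples from N(mu, Sigma) via the symmetric eigen square root
# (PSD-safe, unlike Cholesky). Returns an n x m matrix.
#' @noRd
rmvn_cols <- function(m, mu, Sigma) {
  n <- length(mu)
  L <- sqrtm_sym(Sigma)
  sweep(L %*% matrix(stats::rnorm(n * m), n, m), 1, mu, `+`)
}

#' @noRd
is_square_numeric <- function(X) {
  is.matrix(X) && is.numeric(X) && nrow(X) == ncol(X)
}

#' @noRd
check_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    cb_stop(sprintf("%s contains non-finite entries", what),
            "ctrlbridge_invalid_argument")
  }
  invisible(TRUE)
}
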