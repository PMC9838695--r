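# Shared fixtures and independent oracles used across the suite. Oracles are
# deliberately naive (quadrature, enumeration, root-finding, path simulation)
# so they stay independent of the analytic code paths they check.

expm_ref <- function(X) unname(as.matrix(Matrix::expm(Matrix::Matrix(X))))

rand_pd <- function(n, jitter = 0.3) {
  X <- matrix(rnorm(n * n), n)
  (X %*% t(X)) / n + jitter * diag(n)
}

rand_state <- function(n, mean_scale = 1) {
  gaussian_state(rnorm(n, sd = mean_scale), rand_pd(n))
}

# Composite-Simpson quadrature of int_0^T e^{A s} Q e^{A' s} ds, built from
# one-step matrix-exponential powers (independent of the Van Loan evaluation).
quad_gramian <- function(A, Q, T, K = 2000L) {
  if (K %% 2L == 1L) K <- K + 1L
  h <- T / K
  E <- expm_ref(A * h)
  w <- c(1, rep(c(4, 2), length.out = K - 1), 1)
  w[K + 1] <- 1
  acc <- matrix(0, nrow(A), ncol(A))
  P <- diag(nrow(A))
  for (k in 0:K) {
    acc <- acc + w[k + 1] * (P %*% Q %*% t(P))
    P <- E %*% P
  }
  acc * h / 3
}

# Scalar Schroedinger boundary system solved by root finding on Pi(0), using
# the linear representations Q(t) = phi^2 Q(0) - M(t), P(t) = phi^2 P(0) + M(t)
# written pole-free as Pi(T) = x / (phi^2 - M x), H(T) = h0 / (phi^2 + M h0).
# Pi(0) is negative when the target is more dispersed than the uncontrolled
# endpoint, so the root is searched on both sides of zero.
scalar_bridge_oracle <- function(a, c2, S0, ST, T) {
  phi2 <- exp(2 * a * T)
  M <- if (abs(a) < 1e-14) c2 * T else c2 * (exp(2 * a * T) - 1) / (2 * a)
  f <- function(x) {  # x = Pi(0)
    h0 <- 1 / S0 - x
    x / (phi2 - M * x) + h0 / (phi2 + M * h0) - 1 / ST
  }
  hi <- min(1 / S0, phi2 / M) - 1e-10
  lo <- -1000 / M
  xs <- seq(lo, hi, length.out = 20000L)
  fs <- vapply(xs, f, 0.0)
  j <- which(diff(sign(fs)) != 0)[1]
  stopifnot(is.finite(j))
  x <- uniroot(f, c(xs[j], xs[j + 1]), tol = 1e-14)$root
  list(Pi0 = x, H0 = 1 / S0 - x)
}

# Discretized minimum-energy deterministic control cost with input matrix
# equal to a noise loading C (C C' = S_C): Euler dynamics
# x[k+1] = x[k] + h (A x[k] + C v[k]), cost sum ||v||^2 h; least-norm value.
min_energy_oracle <- function(A, S_C, mu0, muT, T, h = 1e-3) {
  n <- nrow(A)
  K <- round(T / h)
  Ad <- diag(n) + h * A
  G <- matrix(0, n, n)
  P <- diag(n)
  for (j in 0:(K - 1)) {   # P = Ad^j
    G <- G + P %*% S_C %*% t(P) * h
    P <- Ad %*% P
  }
  d <- muT - P %*% mu0     # P = Ad^K after the loop
  drop(t(d) %*% solve(G, d))
}

# Euler-Maruyama OU simulation (independent of the exact-discretization path).
euler_ou_endpoints <- function(system, x0, T, h, n_paths) {
  n <- system$n
  K <- round(T / h)
  L <- t(chol(system$S_C))
  X <- matrix(x0, n, n_paths)
  for (k in seq_len(K)) {
    X <- X + system$A %*% X * h + sqrt(h) * (L %*% matrix(rnorm(n * n_paths), n))
  }
  X
}

# Small labeled task series: steady-state OU run with alternating blocks,
# performing blocks remapped to mean `delta` and covariance L Sigma L'.
make_task_series <- function(system, n_steps, block, delta, Lmod, dt, seed) {
  ss <- steady_state(system)
  run <- simulate_ou_series(system, ss, dt, n_steps - 1L, seed = seed)
  block_id <- (seq_len(n_steps) - 1L) %/% block
  labels <- ifelse(block_id %% 2L == 0L, "task_free", "task_performing")
  perf <- labels == "task_performing"
  vals <- run$values
  vals[perf, ] <- vals[perf, , drop = FALSE] %*% t(Lmod) +
    matrix(delta, sum(perf), system$n, byrow = TRUE)
  ts_data(vals, dt, labels = labels)
}

# Cohort used by the directional end-to-end tests: the generating system is
# rescaled so its steady-state covariance has unit trace, matching the units
# the estimation pipeline produces after trace normalization.
directional_cohort <- function(task_delta, task_L, n_subjects = 20L,
                               n_rois = 6L, seed = 77L) {
  sys0 <- make_random_stable_system(n_rois, sparsity = 0.5, seed = seed)
  tr0 <- sum(diag(steady_state(sys0)$sigma))
  sys <- linear_system(sys0$A, sys0$S_C / tr0)
  spec <- cohort_spec(
    n_subjects = n_subjects, n_rois = n_rois, rest_length = 800L,
    task_length = 400L, dt = 0.72, block_length = 40L,
    mean_offsets = list(task = task_delta),
    cov_modulators = list(task = task_L),
    subject_scales = exp(seq(-0.3, 0.3, length.out = n_subjects)),
    seed = seed + 1L)
  list(system = sys, cohort = generate_cohort(spec, sys))
}
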