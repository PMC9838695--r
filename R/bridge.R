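#' Gaussian Schroedinger bridge problem
#'
#' Describes the optimal steering problem: move the network from an initial
#' Gaussian state to a target Gaussian state over a horizon `T`, staying as
#' close as possible (in path-space KL divergence) to the uncontrolled OU
#' dynamics. Both marginal covariances must be strictly positive definite.
#'
#' @param system A [linear_system()] giving the uncontrolled dynamics.
#' @param initial Initial [gaussian_state()] (`mu0`, `Sigma0`).
#' @param target Target [gaussian_state()] (`muT`, `SigmaT`).
#' @param horizon Positive transition horizon `T` (default 1 time unit).
#' @param grid_points Number of time grid points on `[0, T]` (odd, >= 51;
#'   default 201). The grid is uniform; quadrature is composite Simpson.
#' @return An object of class `bridge_problem`.
#' @export
bridge_problem <- function(system, initial, target, horizon = 1.0,
                           grid_points = 201L) {
  stopifnot(inherits(system, "linear_system"),
            inherits(initial, "gaussian_state"),
            inherits(target, "gaussian_state"))
  if (length(initial$mu) != system$n || length(target$mu) != system$n) {
    cb_stop("marginal dimensions must match the system dimension",
            "ctrlbridge_invalid_argument")
  }
  if (!is.numeric(horizon) || length(horizon) != 1L || !is.finite(horizon) ||
      horizon <= 0) {
    cb_stop("horizon must be a single positive number",
            "ctrlbridge_invalid_argument")
  }
  grid_points <- as.integer(grid_points)
  if (grid_points < 51L) {
    cb_stop("grid_points must be at least 51", "ctrlbridge_invalid_argument")
  }
  if (grid_points %% 2L == 0L) grid_points <- grid_points + 1L
  for (nm in c("initial", "target")) {
    S <- get(nm)$sigma
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10 * max(ev)) {
      cb_stop(sprintf("%s covariance is near-singular (smallest eigenvalue %.3e of largest %.3e); shrink it before solving", nm, min(ev), max(ev)),
              "ctrlbridge_conditioning_error")
    }
  }
  structure(list(system = system, initial = initial, target = target,
                 horizon = horizon, grid_points = grid_points),
            class = "bridge_problem")
}

# Boundary potentials Pi(0), H(0) of the Schroedinger system, by the
# closed-form static construction: pull the terminal state back through the
# deterministic flow, whiten by the pulled-back Gramian, solve the static
# Gaussian entropic coupling, and read the terminal log-potential off the
# conditional precision. Returns the zero matrix for Pi when the target
# covariance already equals the uncontrolled endpoint.
#' @noRd
.bridge_boundary <- function(system, initial, target, horizon) {
  n <- system$n
  Phi <- expm_dense(system$A * horizon)
  M <- van_loan_integral(system$A, system$S_C, horizon)
  S0 <- initial$sigma
  ST <- target$sigma
  S_unc <- symmetrize(Phi %*% S0 %*% t(Phi) + M, warn = FALSE)
  zero_cov <- norm(ST - S_unc, "F") <= 1e-10 * norm(S_unc, "F")
  if (zero_cov) {
    Pi0 <- matrix(0, n, n)
  } else {
    Phii <- solve(Phi)
    N <- symmetrize(Phii %*% M %*% t(Phii), warn = FALSE)
    R <- sqrtm_sym(N)
    Ri <- solve(R)
    s0 <- symmetrize(Ri %*% S0 %*% Ri, warn = FALSE)
    s1 <- symmetrize(Ri %*% Phii %*% ST %*% t(Phii) %*% Ri, warn = FALSE)
    s0h <- sqrtm_sym(s0)
    s0hi <- solve(s0h)
    D <- sqrtm_sym(4 * s0h %*% s1 %*% s0h + diag(n))
    Cu <- 0.5 * (s0h %*% D %*% s0hi - diag(n))   # cross-covariance Cov(u0, u1)
    cond_cov <- symmetrize(s1 - t(Cu) %*% solve(s0, Cu), warn = FALSE)
    Gam <- symmetrize(solve(cond_cov) - diag(n), warn = FALSE)
    Pi0 <- symmetrize(Ri %*% Gam %*% solve(diag(n) + Gam) %*% Ri, warn = FALSE)
  }
  H0 <- symmetrize(solve(S0) - Pi0, warn = FALSE)
  list(Pi0 = Pi0, H0 = H0, Phi_T = Phi, M_T = M, S_unc = S_unc,
       zero_cov = zero_cov)
}

# Gridded flow quantities and Riccati paths on a uniform grid. Phi_k and M_k
# follow the exact one-step recurrences; Pi(t), H(t) use the inverse-free
# linear representations, which remain valid for singular Pi(0).
#' @noRd
.bridge_grid_fields <- function(system, Pi0, H0, horizon, npts) {
  n <- system$n
  K <- npts - 1L
  h <- horizon / K
  Phi_h <- expm_dense(system$A * h)
  M_h <- van_loan_integral(system$A, system$S_C, h)
  I_n <- diag(n)
  Phi <- array(0, c(n, n, npts)); Mt <- array(0, c(n, n, npts))
  Pi <- array(0, c(n, n, npts)); H <- array(0, c(n, n, npts))
  Sigma <- array(0, c(n, n, npts))
  Phi[, , 1] <- I_n
  for (k in seq_len(K)) {
    Phi[, , k + 1] <- Phi_h %*% Phi[, , k]
    Mt[, , k + 1] <- symmetrize(Phi_h %*% Mt[, , k] %*% t(Phi_h) + M_h,
                                warn = FALSE)
  }
  for (k in seq_len(npts)) {
    Pk <- matrix(Phi[, , k], n, n)
    Pki <- solve(Pk)
    Nk <- symmetrize(Pki %*% matrix(Mt[, , k], n, n) %*% t(Pki), warn = FALSE)
    Pi[, , k] <- symmetrize(t(Pki) %*% Pi0 %*% solve(I_n - Nk %*% Pi0) %*% Pki,
                            warn = FALSE)
    H[, , k] <- symmetrize(t(Pki) %*% H0 %*% solve(I_n + Nk %*% H0) %*% Pki,
                           warn = FALSE)
    Sigma[, , k] <- symmetrize(solve(matrix(Pi[, , k] + H[, , k], n, n)),
                               warn = FALSE)
  }
  list(time = seq(0, horizon, length.out = npts), Phi = Phi, M = Mt,
       Pi = Pi, H = H, Sigma = Sigma, h = h)
}

# Mean path and feedforward on the grid. mu(t) follows the Gramian
# interpolation formula; w(t) = Pi(t) mu(t) - m(t) is the deterministic part
# of the optimal input, and m(t) the feedforward offset.
#' @noRd
.bridge_mean_fields <- function(grids, Pi, mu0, muT, Phi_T, M_T) {
  npts <- length(grids$time)
  n <- length(mu0)
  mud <- muT - drop(Phi_T %*% mu0)
  alpha <- drop(solve(M_T, mud))     # M(T)^{-1} (muT - Phi muT0)
  mu_t <- matrix(0, n, npts); m_t <- matrix(0, n, npts); w_t <- matrix(0, n, npts)
  for (k in seq_len(npts)) {
    Phi_k <- matrix(grids$Phi[, , k], n, n)
    # Phi(T, t_k) = Phi(T) Phi(t_k)^{-1}; on the uniform grid this equals the
    # transition matrix over the remaining time, Phi[, , npts - k + 1].
    Phi_Tt <- matrix(grids$Phi[, , npts - k + 1], n, n)
    mu_t[, k] <- drop(Phi_k %*% mu0 +
                        matrix(grids$M[, , k], n, n) %*% t(Phi_Tt) %*% alpha)
    w_t[, k] <- drop(-t(Phi_Tt) %*% alpha)
    m_t[, k] <- drop(matrix(Pi[, , k], n, n) %*% mu_t[, k]) - w_t[, k]
  }
  list(mu_t = mu_t, m_t = m_t, w_t = w_t, mud = mud)
}

#' @noRd
.bridge_cov_cost <- function(system, grids, Pi0, Pi, Sigma, S0, ST) {
  npts <- length(grids$time)
  n <- system$n
  w <- simpson_weights(npts, grids$h)
  Pi_T <- matrix(Pi[, , npts], n, n)
  f_tr <- vapply(seq_len(npts), function(k)
    sum(diag(system$S_C %*% matrix(Pi[, , k], n, n))), 0.0)
  f_quad <- vapply(seq_len(npts), function(k) {
    Pk <- matrix(Pi[, , k], n, n)
    sum(diag(Pk %*% system$S_C %*% Pk %*% matrix(Sigma[, , k], n, n)))
  }, 0.0)
  J_printed <- sum(w * f_tr) - sum(diag(Pi_T %*% ST)) + sum(diag(Pi0 %*% S0))
  J_quadform <- sum(w * f_quad)
  list(printed = J_printed, quadform = J_quadform)
}

#' Solve the Gaussian Schroedinger bridge
#'
#' Computes the optimal controlled process between the problem's marginals:
#' the feedback potential `Pi(t)`, the auxiliary potential `H(t)`, the bridge
#' covariance `Sigma(t) = (Pi(t) + H(t))^{-1}`, the bridge mean `mu(t)`, the
#' feedforward offset `m(t)`, and the cost decomposition `J_total = J_mean +
#' J_cov` (the total equals twice the path KL divergence). The optimal input
#' is `v*(x, t) = -S_C (Pi(t) x - m(t))`.
#'
#' The time grid is refined (doubled) until the covariance cost changes by
#' less than `1e-6` relative, up to three refinements.
#'
#' @param problem A [bridge_problem()].
#' @return An object of class `bridge_solution`: gridded fields `time`, `Pi`,
#'   `H`, `Sigma_t` (n x n x npts arrays), `mu_t`, `m_t` (n x npts), costs
#'   `J_mean`, `J_cov`, `J_total`, `KL = J_total / 2`, and `diagnostics`
#'   (boundary residuals and the two-form covariance-cost identity gap).
#' @export
solve_schrodinger_bridge <- function(problem) {
  stopifnot(inherits(problem, "bridge_problem"))
  sys <- problem$system
  n <- sys$n
  bnd <- .bridge_boundary(sys, problem$initial, problem$target, problem$horizon)
  S0 <- problem$initial$sigma
  ST <- problem$target$sigma

  npts <- problem$grid_points
  grids <- .bridge_grid_fields(sys, bnd$Pi0, bnd$H0, problem$horizon, npts)
  cc <- .bridge_cov_cost(sys, grids, bnd$Pi0, grids$Pi, grids$Sigma, S0, ST)
  J_cov <- cc$printed
  if (!bnd$zero_cov) {
    # refine by doubling until the covariance cost is quadrature-converged
    for (refine in 1:3) {
      npts2 <- 2L * (npts - 1L) + 1L
      grids2 <- .bridge_grid_fields(sys, bnd$Pi0, bnd$H0, problem$horizon, npts2)
      cc2 <- .bridge_cov_cost(sys, grids2, bnd$Pi0, grids2$Pi, grids2$Sigma,
                              S0, ST)
      converged <- abs(cc2$printed - J_cov) <=
        1e-6 * max(abs(cc2$printed), 1e-12)
      if (converged) break
      grids <- grids2; cc <- cc2; J_cov <- cc2$printed; npts <- npts2
    }
  }
  mf <- .bridge_mean_fields(grids, grids$Pi, problem$initial$mu,
                            problem$target$mu, bnd$Phi_T, bnd$M_T)
  ev <- eigen(bnd$M_T, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) / min(ev) > 1e12) {
    cb_warn(sprintf("Gramian condition number %.3e exceeds 1e12; mean cost may be inaccurate", max(ev) / min(ev)),
            "ctrlbridge_conditioning_warning")
  }
  J_mean <- drop(t(mf$mud) %*% solve(bnd$M_T, mf$mud))
  if (bnd$zero_cov) J_cov <- 0

  # boundary residual diagnostics (relative Frobenius)
  npts_f <- length(grids$time)
  res0 <- norm(bnd$Pi0 + bnd$H0 - solve(S0), "F") / norm(solve(S0), "F")
  resT <- norm(matrix(grids$Pi[, , npts_f] + grids$H[, , npts_f], n, n) -
                 solve(ST), "F") / norm(solve(ST), "F")
  two_form_gap <- if (bnd$zero_cov) 0 else
    abs(cc$printed - cc$quadform) / max(abs(cc$quadform), 1e-12)

  structure(list(
    time = grids$time,
    Pi = grids$Pi, H = grids$H, Sigma_t = grids$Sigma,
    mu_t = mf$mu_t, m_t = mf$m_t,
    J_mean = max(J_mean, 0), J_cov = max(J_cov, 0),
    J_total = max(J_mean, 0) + max(J_cov, 0),
    KL = (max(J_mean, 0) + max(J_cov, 0)) / 2,
    Pi0 = bnd$Pi0, H0 = bnd$H0, Phi_T = bnd$Phi_T, M_T = bnd$M_T,
    diagnostics = list(residual_0 = res0, residual_T = resT,
                       two_form_gap = two_form_gap,
                       grid_points = npts_f, zero_cov = bnd$zero_cov),
    problem = problem
  ), class = "bridge_solution")
}

#' @export
print.bridge_solution <- function(x, ...) {
  cat(sprintf(paste0("<bridge_solution> n = %d, T = %.3g, grid = %d\n",
                     "  J_mean = %.6g, J_cov = %.6g, J_total = %.6g (KL = %.6g)\n",
                     "  boundary residuals: %.2e (t=0), %.2e (t=T)\n"),
              x$problem$system$n, x$problem$horizon,
              x$diagnostics$grid_points, x$J_mean, x$J_cov, x$J_total, x$KL,
              x$diagnostics$residual_0, x$diagnostics$residual_T))
  invisible(x)
}

#' Mean control cost via the Gramian form
#'
#' `J_mean = (muT - Phi(T) mu0)' M(T)^{-1} (muT - Phi(T) mu0)`: the cost of
#' steering the distribution mean, independent of the marginal covariances and
#' equal to the deterministic minimum-energy control cost when the input
#' matrix equals the noise loading.
#'
#' @param system A [linear_system()].
#' @param mu0,muT Initial and target mean vectors.
#' @param T Positive horizon.
#' @return Nonnegative scalar cost.
#' @export
mean_cost <- function(system, mu0, muT, T) {
  stopifnot(inherits(system, "linear_system"))
  mu0 <- as.numeric(mu0); muT <- as.numeric(muT)
  if (length(mu0) != system$n || length(muT) != system$n) {
    cb_stop("mean vectors must have length n", "ctrlbridge_invalid_argument")
  }
  M <- gramian(system, T)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) / min(ev) > 1e12) {
    cb_warn(sprintf("Gramian condition number %.3e exceeds 1e12", max(ev) / min(ev)),
            "ctrlbridge_conditioning_warning")
  }
  mud <- muT - drop(transition_matrix(system, T) %*% mu0)
  max(drop(t(mud) %*% solve(M, mud)), 0)
}

#' Covariance control cost with internal two-form cross-check
#'
#' Evaluates the covariance cost both as
#' `int tr(S_C Pi) dt - tr(Pi(T) SigmaT - Pi(0) Sigma0)` and as the
#' integration-by-parts equivalent `int tr(Pi S_C Pi Sigma) dt`, errors if the
#' two disagree beyond `1e-4` relative, and returns the former.
#'
#' @param solution A [solve_schrodinger_bridge()] result.
#' @param problem The [bridge_problem()] it solves.
#' @return Nonnegative scalar cost.
#' @export
covariance_cost <- function(solution, problem) {
  stopifnot(inherits(solution, "bridge_solution"),
            inherits(problem, "bridge_problem"))
  if (max(solution$diagnostics$residual_0, solution$diagnostics$residual_T) >
      1e-8) {
    cb_stop("bridge boundary residuals exceed 1e-8; solution unusable",
            "ctrlbridge_convergence_error")
  }
  if (solution$diagnostics$zero_cov) return(0)
  grids <- list(time = solution$time,
                h = diff(solution$time[1:2]))
  cc <- .bridge_cov_cost(problem$system, grids, solution$Pi0, solution$Pi,
                         solution$Sigma_t, problem$initial$sigma,
                         problem$target$sigma)
  gap <- abs(cc$printed - cc$quadform) / max(abs(cc$quadform), 1e-12)
  if (gap > 1e-4) {
    cb_stop(sprintf("covariance-cost identity mismatch %.3e exceeds 1e-4", gap),
            "ctrlbridge_internal_consistency_error")
  }
  max(cc$printed, 0)
}

#' Total stochastic control cost and its decomposition
#'
#' @param problem A [bridge_problem()].
#' @return A list with `J_mean`, `J_cov`, `J_total` (their sum, equal to twice
#'   the path KL divergence) and `KL = J_total / 2`.
#' @export
total_cost <- function(problem) {
  sol <- solve_schrodinger_bridge(problem)
  list(J_mean = sol$J_mean, J_cov = sol$J_cov, J_total = sol$J_total,
       KL = sol$KL)
}

#' Optimal mean path and feedforward control offset
#'
#' Returns the bridge mean `mu(t)` and the feedforward offset `m(t)` of the
#' optimal input `v*(x, t) = -S_C (Pi(t) x - m(t))` on the solution grid, and
#' verifies by Runge-Kutta integration of the closed-loop mean dynamics
#' `mu' = A mu - S_C (Pi mu - m)` that the path hits the target mean.
#'
#' @param problem A [bridge_problem()].
#' @param solution Optional pre-computed [solve_schrodinger_bridge()] result.
#' @return A list with `time`, `mu_t`, `m_t` and the closed-loop terminal
#'   error `closed_loop_error`.
#' @export
mean_path_and_feedforward <- function(problem, solution = NULL) {
  if (is.null(solution)) solution <- solve_schrodinger_bridge(problem)
  sys <- problem$system
  n <- sys$n
  time <- solution$time
  npts <- length(time)
  # closed-loop RK4 on the coarse grid, with exact coefficients at midpoints:
  # rebuild Pi and m on the doubled grid so no interpolation error enters.
  fine <- .bridge_grid_fields(sys, solution$Pi0, solution$H0, problem$horizon,
                              2L * (npts - 1L) + 1L)
  mff <- .bridge_mean_fields(fine, fine$Pi, problem$initial$mu,
                             problem$target$mu, solution$Phi_T, solution$M_T)
  h <- time[2] - time[1]
  mu <- problem$initial$mu
  rhs <- function(j, mu) {  # j indexes the fine grid
    drop(sys$A %*% mu - sys$S_C %*%
           (matrix(fine$Pi[, , j], n, n) %*% mu - mff$m_t[, j]))
  }
  for (k in seq_len(npts - 1L)) {
    j <- 2L * k - 1L
    k1 <- rhs(j, mu)
    k2 <- rhs(j + 1L, mu + h / 2 * k1)
    k3 <- rhs(j + 1L, mu + h / 2 * k2)
    k4 <- rhs(j + 2L, mu + h * k3)
    mu <- mu + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  err <- sqrt(sum((mu - problem$target$mu)^2)) /
    max(1, sqrt(sum(problem$target$mu^2)))
  if (err > 1e-4) {
    cb_stop(sprintf("closed-loop mean error %.3e exceeds 1e-4; grid too coarse", err),
            "ctrlbridge_resolution_error")
  }
  list(time = time, mu_t = solution$mu_t, m_t = solution$m_t,
       closed_loop_error = err)
}

#' Per-node control inputs (input map)
#'
#' Expected total squared optimal input at each node,
#' `I(k) = E int ||v_k*||^2 dt`, decomposed into the mean input
#' `I_mean(k) = (S_C int (Pi mu - m)(Pi mu - m)' dt S_C)_kk` and the
#' covariance input `I_cov(k) = (S_C int Pi Sigma Pi dt S_C)_kk`. When
#' `S_C = I` the inputs sum to `J_total`.
#'
#' @param problem A [bridge_problem()].
#' @param solution A [solve_schrodinger_bridge()] result for `problem`.
#' @param roi_names Optional node labels (default `roi_1 ... roi_n`).
#' @return A data frame of class `input_map` with columns `roi`, `I_mean`,
#'   `I_cov`, `I_total` (`I_total = I_mean + I_cov` exactly).
#' @export
node_inputs <- function(problem, solution, roi_names = NULL) {
  stopifnot(inherits(solution, "bridge_solution"))
  sys <- problem$system
  n <- sys$n
  npts <- length(solution$time)
  w <- simpson_weights(npts, diff(solution$time[1:2]))
  W_mu <- matrix(0, n, n); W_cov <- matrix(0, n, n)
  for (k in seq_len(npts)) {
    Pk <- matrix(solution$Pi[, , k], n, n)
    wk <- drop(Pk %*% solution$mu_t[, k]) - solution$m_t[, k]
    W_mu <- W_mu + w[k] * tcrossprod(wk)
    W_cov <- W_cov + w[k] * Pk %*% matrix(solution$Sigma_t[, , k], n, n) %*% Pk
  }
  I_mean <- pmax(diag(sys$S_C %*% W_mu %*% sys$S_C), 0)
  I_cov <- pmax(diag(sys$S_C %*% W_cov %*% sys$S_C), 0)
  if (is.null(roi_names)) roi_names <- paste0("roi_", seq_len(n))
  out <- data.frame(roi = roi_names, I_mean = I_mean, I_cov = I_cov,
                    I_total = I_mean + I_cov, stringsAsFactors = FALSE)
  class(out) <- c("input_map", "data.frame")
  out
}

#' Export a bridge solution as a directory of TSV matrices plus a cost summary
#'
#' Writes `grid.tsv`, `Pi.tsv`, `Sigma.tsv` (gridpoint-stacked n x n blocks),
#' `mu.tsv`, `m.tsv` and `costs.json` (`J_mean`, `J_cov`, `J_total`, `KL`).
#'
#' @param solution A [solve_schrodinger_bridge()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
export_bridge_solution <- function(solution, dir) {
  stopifnot(inherits(solution, "bridge_solution"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- dim(solution$Pi)[1]
  npts <- length(solution$time)
  stack <- function(arr) do.call(rbind, lapply(seq_len(npts), function(k)
    matrix(arr[, , k], n, n)))
  write_matrix_tsv(matrix(solution$time, ncol = 1), file.path(dir, "grid.tsv"))
  write_matrix_tsv(stack(solution$Pi), file.path(dir, "Pi.tsv"))
  write_matrix_tsv(stack(solution$Sigma_t), file.path(dir, "Sigma.tsv"))
  write_matrix_tsv(t(solution$mu_t), file.path(dir, "mu.tsv"))
  write_matrix_tsv(t(solution$m_t), file.path(dir, "m.tsv"))
  jsonlite::write_json(list(J_mean = solution$J_mean, J_cov = solution$J_cov,
                            J_total = solution$J_total, KL = solution$KL),
                       file.path(dir, "costs.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
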