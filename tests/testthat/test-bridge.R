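# Gaussian Schroedinger bridge: boundary system, costs, decomposition,
# per-node inputs.

test_that("uncontrolled target gives the zero-control bridge", {
  sys <- make_random_stable_system(3, sparsity = 0.2, seed = 201)
  set.seed(201)
  init <- gaussian_state(rep(0, 3), rand_pd(3))
  tgt <- propagate_uncontrolled(sys, init, 1.0)
  prob <- bridge_problem(sys, init, tgt, horizon = 1.0)
  sol <- solve_schrodinger_bridge(prob)

  expect_lt(sol$J_total, 1e-8)
  expect_equal(sol$J_cov, 0)
  expect_lt(max(abs(sol$Pi)), 1e-10)
  # H(t) must then be the inverse uncontrolled covariance along the path
  for (k in c(1L, 51L, 101L, 201L)) {
    S_unc <- propagate_uncontrolled(sys, init, sol$time[k])$sigma
    expect_lt(norm(matrix(sol$H[, , k], 3, 3) - solve(S_unc), "F") /
                norm(solve(S_unc), "F"), 1e-8)
  }
})

test_that("scalar bridge matches an independent boundary-system root-finder", {
  a <- -0.8; c2 <- 1.4; S0 <- 0.6; ST <- 1.9; T <- 1.0
  sys <- linear_system(matrix(a, 1, 1), matrix(c2, 1, 1))
  prob <- bridge_problem(sys, gaussian_state(0, matrix(S0, 1, 1)),
                         gaussian_state(0.4, matrix(ST, 1, 1)), horizon = T)
  sol <- solve_schrodinger_bridge(prob)
  orc <- scalar_bridge_oracle(a, c2, S0, ST, T)
  expect_equal(sol$Pi0[1, 1], orc$Pi0, tolerance = 1e-8)
  expect_equal(sol$H0[1, 1], orc$H0, tolerance = 1e-8)
})

test_that("bridge marginals and boundary residuals hold on random problems", {
  for (i in 1:10) {
    n <- 1 + (i %% 8)
    sys <- make_random_stable_system(n, sparsity = 0.2, seed = 300 + i)
    set.seed(300 + i)
    prob <- bridge_problem(sys, rand_state(n), rand_state(n), horizon = 1.0)
    sol <- solve_schrodinger_bridge(prob)
    expect_lt(sol$diagnostics$residual_0, 1e-8)
    expect_lt(sol$diagnostics$residual_T, 1e-8)
    npts <- length(sol$time)
    expect_lt(norm(matrix(sol$Sigma_t[, , 1], n, n) - prob$initial$sigma, "F") /
                norm(prob$initial$sigma, "F"), 1e-6)
    expect_lt(norm(matrix(sol$Sigma_t[, , npts], n, n) - prob$target$sigma, "F") /
                norm(prob$target$sigma, "F"), 1e-6)
    expect_lt(max(abs(sol$mu_t[, 1] - prob$initial$mu)), 1e-8)
    expect_lt(max(abs(sol$mu_t[, npts] - prob$target$mu)), 1e-8)
    # Pi + H positive definite along the whole grid
    min_eigs <- vapply(seq_len(npts), function(k)
      min(eigen(matrix(sol$Pi[, , k] + sol$H[, , k], n, n), symmetric = TRUE,
                only.values = TRUE)$values), 0.0)
    expect_gt(min(min_eigs), 0)
  }
})

test_that("mean cost: zero at free drift, Gramian identity, min-energy oracle", {
  sys <- make_random_stable_system(4, sparsity = 0.2, seed = 401)
  set.seed(401)
  mu0 <- rnorm(4)
  muT_free <- drop(transition_matrix(sys, 1.3) %*% mu0)
  expect_equal(mean_cost(sys, mu0, muT_free, 1.3), 0, tolerance = 1e-20)

  sysI <- linear_system(matrix(0, 3, 3), diag(3))
  expect_equal(mean_cost(sysI, rep(0, 3), c(1, 0, 0), 1), 1, tolerance = 1e-10)

  muT <- rnorm(4)
  got <- mean_cost(sys, mu0, muT, 1.0)
  orc <- min_energy_oracle(sys$A, sys$S_C, mu0, muT, 1.0, h = 1e-3)
  expect_lt(abs(got - orc) / orc, 0.005)
})

test_that("covariance cost: zero at uncontrolled target, identity, monotone probes", {
  sys <- make_random_stable_system(3, sparsity = 0, seed = 501)
  set.seed(501)
  init <- rand_state(3)
  tgt_free <- propagate_uncontrolled(sys, init, 1.0)
  prob0 <- bridge_problem(sys, init, tgt_free, horizon = 1.0)
  sol0 <- solve_schrodinger_bridge(prob0)
  expect_lt(abs(covariance_cost(sol0, prob0)), 1e-8 * 3)

  prob <- bridge_problem(sys, init, rand_state(3), horizon = 1.0)
  sol <- solve_schrodinger_bridge(prob)
  expect_lt(sol$diagnostics$two_form_gap, 1e-6)
  expect_gte(covariance_cost(sol, prob), 0)

  # scalar probes: inflating the target covariance costs strictly more, and
  # halving the horizon does not make the transition cheaper
  a <- -0.6; c2 <- 1.1; T <- 1.0
  ssys <- linear_system(matrix(a, 1, 1), matrix(c2, 1, 1))
  s_init <- gaussian_state(0, matrix(0.8, 1, 1))
  S_unc <- propagate_uncontrolled(ssys, s_init, T)$sigma
  probe <- function(ST, Th) {
    p <- bridge_problem(ssys, s_init, gaussian_state(0, matrix(ST, 1, 1)),
                        horizon = Th)
    solve_schrodinger_bridge(p)$J_cov
  }
  J_double <- probe(2 * S_unc[1, 1], T)
  expect_gt(J_double, 1e-4)
  orc <- scalar_bridge_oracle(a, c2, 0.8, 2 * S_unc[1, 1], T)
  expect_gt(abs(orc$Pi0), 1e-6)  # oracle agrees the control is active
  expect_gte(probe(2 * S_unc[1, 1], T / 2), J_double - 1e-10)
})

test_that("total cost decomposes orthogonally into mean and covariance parts", {
  sys <- make_random_stable_system(4, sparsity = 0.3, seed = 601)
  set.seed(601)
  mu0 <- rnorm(4); muT <- rnorm(4)
  S0a <- rand_pd(4); STa <- rand_pd(4)
  S0b <- rand_pd(4); STb <- rand_pd(4)

  tc <- function(m0, mT, S0, ST) {
    total_cost(bridge_problem(sys, gaussian_state(m0, S0),
                              gaussian_state(mT, ST), horizon = 1.0))
  }
  ca <- tc(mu0, muT, S0a, STa)
  cb <- tc(mu0, muT, S0b, STb)
  expect_equal(ca$J_mean, cb$J_mean, tolerance = 1e-9)

  cc1 <- tc(rnorm(4), rnorm(4), S0a, STa)
  expect_equal(ca$J_cov, cc1$J_cov, tolerance = 1e-9)

  expect_identical(ca$J_total, ca$J_mean + ca$J_cov)
  expect_identical(ca$KL, ca$J_total / 2)

  # uncontrolled target in both moments: vanishing total cost
  init <- gaussian_state(mu0, S0a)
  free <- propagate_uncontrolled(sys, init, 1.0)
  cf <- tc(mu0, free$mu, S0a, free$sigma)
  expect_lt(cf$J_total, 1e-8)
})

test_that("mean path and feedforward: degenerate cases and closed loop", {
  sys <- make_random_stable_system(3, sparsity = 0, seed = 701)
  set.seed(701)
  S0 <- rand_pd(3); ST <- rand_pd(3)

  p0 <- bridge_problem(sys, gaussian_state(rep(0, 3), S0),
                       gaussian_state(rep(0, 3), ST), horizon = 1.0)
  mp0 <- mean_path_and_feedforward(p0)
  expect_lt(max(abs(mp0$mu_t)), 1e-12)
  expect_lt(max(abs(mp0$m_t)), 1e-12)

  mu0 <- rnorm(3)
  muT_free <- drop(transition_matrix(sys, 1.0) %*% mu0)
  p1 <- bridge_problem(sys, gaussian_state(mu0, S0),
                       gaussian_state(muT_free, ST), horizon = 1.0)
  s1 <- solve_schrodinger_bridge(p1)
  mp1 <- mean_path_and_feedforward(p1, s1)
  # with a free-drift mean the feedforward reduces to m = Pi mu
  np1 <- length(s1$time)
  for (k in c(1L, (np1 + 1L) %/% 2L, np1)) {
    expect_lt(max(abs(mp1$m_t[, k] -
                        drop(matrix(s1$Pi[, , k], 3, 3) %*% mp1$mu_t[, k]))),
              1e-8)
  }

  p2 <- bridge_problem(sys, gaussian_state(mu0, S0),
                       gaussian_state(rnorm(3), ST), horizon = 1.0)
  mp2 <- mean_path_and_feedforward(p2)
  expect_lt(mp2$closed_loop_error, 1e-6)
})

test_that("node inputs: zero control, additivity, unit-noise sum identity", {
  sys <- make_random_stable_system(3, sparsity = 0, seed = 801)
  set.seed(801)
  init <- gaussian_state(rep(0, 3), rand_pd(3))
  free <- propagate_uncontrolled(sys, init, 1.0)
  p0 <- bridge_problem(sys, init, free, horizon = 1.0)
  im0 <- node_inputs(p0, solve_schrodinger_bridge(p0))
  expect_lt(max(im0$I_total), 1e-10)

  sysI <- linear_system(make_random_stable_system(4, 0.2, seed = 802)$A,
                        diag(4))
  set.seed(802)
  pI <- bridge_problem(sysI, rand_state(4), rand_state(4), horizon = 1.0)
  sI <- solve_schrodinger_bridge(pI)
  imI <- node_inputs(pI, sI)
  expect_true(all(imI$I_mean >= 0) && all(imI$I_cov >= 0))
  expect_identical(imI$I_total, imI$I_mean + imI$I_cov)
  expect_lt(abs(sum(imI$I_total) - sI$J_total) / sI$J_total, 1e-6)
})

test_that("grid refinement reports a converged covariance cost", {
  sys <- make_random_stable_system(3, sparsity = 0, seed = 901)
  set.seed(901)
  prob_coarse <- bridge_problem(sys, rand_state(3), rand_state(3),
                                horizon = 1.0, grid_points = 51)
  prob_fine <- bridge_problem(sys, prob_coarse$initial, prob_coarse$target,
                              horizon = 1.0, grid_points = 401)
  J_c <- solve_schrodinger_bridge(prob_coarse)$J_cov
  J_f <- solve_schrodinger_bridge(prob_fine)$J_cov
  expect_equal(J_c, J_f, tolerance = 1e-5)
})
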