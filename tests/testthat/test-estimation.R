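# Estimation pipeline: normalization, VAR(1) fit, continuous-time
# conversion, state estimation, bootstrap resampling.

test_that("trace normalization rescales to unit reference trace and is idempotent", {
  set.seed(1001)
  vals <- matrix(rnorm(600 * 3), 600, 3) %*% diag(c(1, 1.2, 0.9))
  s <- ts_data(vals, dt = 0.5)
  tr <- sum(diag(cov(vals)))
  norm1 <- trace_normalize(s)
  expect_equal(unname(norm1$values), vals / sqrt(tr), tolerance = 1e-12)
  expect_equal(sum(diag(cov(norm1$values))), 1, tolerance = 1e-10)
  norm2 <- trace_normalize(norm1)
  expect_equal(norm2$values, norm1$values, tolerance = 1e-10)

  # a doubled series normalizes to the same result (scale invariance)
  s2 <- ts_data(2 * vals, dt = 0.5)
  expect_equal(trace_normalize(s2)$values, norm1$values, tolerance = 1e-12)

  # reference trace 4 -> scale by 1/2
  v4 <- matrix(rnorm(2000 * 2), 2000, 2)
  v4 <- 2 * v4 %*% solve(chol(cov(v4))) / sqrt(2)  # empirical trace exactly 4
  s4 <- ts_data(v4, dt = 1)
  expect_equal(unname(trace_normalize(s4)$values), v4 / 2, tolerance = 1e-10)

  lab <- ts_data(vals, 0.5, labels = rep("task_performing", 600))
  expect_error(trace_normalize(lab), class = "ctrlbridge_labeling_error")
})

test_that("VAR fit: exact on noiseless data, OLS recovery on simulated OU", {
  x <- 2 * 0.5^(0:200)
  s <- ts_data(matrix(x, ncol = 1), dt = 1)
  fit <- suppressWarnings(fit_var_lasso(s, lambda = 0))
  expect_equal(fit$a_hat[1, 1], 0.5, tolerance = 1e-10)
  expect_lt(fit$S_eps[1, 1], 1e-20)

  sys <- make_random_stable_system(5, sparsity = 0.4, seed = 1101)
  ss <- steady_state(sys)
  dt <- 0.3
  run <- simulate_ou_series(sys, ss, dt, 50000L, seed = 1102)
  fit5 <- fit_var_lasso(run, lambda = 0)
  a_true <- exact_discretization(sys, dt)$a
  expect_lt(norm(fit5$a_hat - a_true, "F") / norm(a_true, "F"), 0.05)

  # rank-deficient design errors under OLS
  const <- ts_data(matrix(1, 50, 2), dt = 1)
  expect_error(suppressWarnings(fit_var_lasso(const, lambda = 0)),
               class = "ctrlbridge_singularity_error")
})

test_that("lasso path: off-diagonal support shrinks as the penalty grows", {
  sys <- make_random_stable_system(5, sparsity = 0.6, seed = 1201)
  run <- simulate_ou_series(sys, steady_state(sys), 0.3, 20000L, seed = 1202)
  nnz <- vapply(c(1e-4, 1e-3, 1e-2, 5e-2), function(lam) {
    f <- fit_var_lasso(run, lambda = lam)
    sum(f$a_hat[row(f$a_hat) != col(f$a_hat)] != 0)
  }, 0L)
  expect_true(all(diff(nnz) <= 0))
})

test_that("regression pairs never span segment boundaries", {
  # two exactly geometric segments starting from opposite signs: both satisfy
  # x[t+1] = 0.5 x[t] exactly, so a boundary-respecting OLS fit is exact,
  # while a seam-spanning pair (x ~ 0 -> y = -10) would blow up the residual
  seg <- function(x0) ts_data(matrix(x0 * 0.5^(0:19), ncol = 1), dt = 1)
  fit <- suppressWarnings(fit_var_lasso(list(seg(10), seg(-10)), lambda = 0))
  expect_equal(fit$n_pairs, 2L * 19L)
  expect_equal(fit$a_hat[1, 1], 0.5, tolerance = 1e-8)
  expect_lt(fit$S_eps[1, 1], 1e-10)
})

test_that("continuous-time conversion: scalar closed forms and exactness", {
  # scalar drift
  fit1 <- structure(list(a_hat = matrix(exp(-0.5), 1, 1), intercept = 0,
                         S_eps = matrix(0.1, 1, 1), lambda = 0, n_pairs = 100L),
                    class = "var_fit")
  expect_equal(to_continuous_system(fit1, 1)$A[1, 1], -0.5, tolerance = 1e-12)

  # scalar noise-rate cancellation: exact discrete moments return S_C exactly
  alpha <- 0.5; c2 <- 2; dt <- 0.72
  fit2 <- structure(list(a_hat = matrix(exp(-alpha * dt), 1, 1), intercept = 0,
                         S_eps = matrix(c2 * (1 - exp(-2 * alpha * dt)) /
                                          (2 * alpha), 1, 1),
                         lambda = 0, n_pairs = 100L),
                    class = "var_fit")
  sysr <- to_continuous_system(fit2, dt)
  expect_equal(sysr$S_C[1, 1], 2, tolerance = 1e-10)
  expect_equal(sysr$A[1, 1], -alpha, tolerance = 1e-12)

  # non-stationary and branch errors
  fit3 <- structure(list(a_hat = matrix(1.01, 1, 1), intercept = 0,
                         S_eps = matrix(1, 1, 1), lambda = 0, n_pairs = 100L),
                    class = "var_fit")
  expect_error(to_continuous_system(fit3, 1),
               class = "ctrlbridge_nonstationary_error")
  fit4 <- structure(list(a_hat = matrix(-0.5, 1, 1), intercept = 0,
                         S_eps = matrix(1, 1, 1), lambda = 0, n_pairs = 100L),
                    class = "var_fit")
  expect_error(to_continuous_system(fit4, 1),
               class = "ctrlbridge_branch_error")
})

test_that("rest state: empirical moments match the generating steady state", {
  sys <- make_random_stable_system(4, sparsity = 0.2, seed = 1401)
  ss <- steady_state(sys)
  run <- simulate_ou_series(sys, ss, 0.3, 100000L, seed = 1402,
                            labels = rep("rest", 100001L))
  est <- estimate_rest_state(run)
  expect_lt(norm(est$sigma - ss$sigma, "F") / norm(ss$sigma, "F"), 0.05)
  expect_lt(max(abs(est$mu)), 0.05)

  # pooling over subjects equals moments of the row-bound data
  r1 <- simulate_ou_series(sys, ss, 0.3, 500L, seed = 1403)
  r2 <- simulate_ou_series(sys, ss, 0.3, 700L, seed = 1404)
  pooled <- estimate_rest_state(list(r1, r2))
  all_rows <- rbind(r1$values, r2$values)
  expect_equal(pooled$mu, unname(colMeans(all_rows)), tolerance = 1e-12)
  expect_equal(pooled$sigma, unname(cov(all_rows)), tolerance = 1e-12)

  expect_warning(estimate_rest_state(ts_data(matrix(0, 10, 2), dt = 1)),
                 class = "ctrlbridge_degenerate_warning")
})

test_that("task state: offset and covariance modulation are recovered", {
  sys <- make_random_stable_system(3, sparsity = 0, seed = 1501)
  ss <- steady_state(sys)
  delta <- c(0.8, -0.4, 0.2)
  Lmod <- diag(3) + 0.2
  run <- make_task_series(sys, 50000L, block = 50L, delta = delta,
                          Lmod = Lmod, dt = 0.3, seed = 1502)
  est <- estimate_task_state(run)
  n_perf <- sum(run$labels == "task_performing")
  se <- sqrt(diag(ss$sigma) / n_perf) * 3
  # autocorrelation inflates the naive SE; allow a generous factor
  expect_true(all(abs(est$mu - delta) < 10 * se + 0.02))
  ST_true <- Lmod %*% ss$sigma %*% t(Lmod)
  expect_lt(norm(est$sigma - ST_true, "F") / norm(ST_true, "F"), 0.05)

  # identical statistics in both segments: zero mean shift
  null_run <- make_task_series(sys, 20000L, block = 50L, delta = rep(0, 3),
                               Lmod = diag(3), dt = 0.3, seed = 1503)
  est0 <- estimate_task_state(null_run)
  expect_lt(max(abs(est0$mu)), 0.1)

  rest_only <- ts_data(matrix(rnorm(20), 10, 2), dt = 1,
                       labels = rep("rest", 10))
  expect_error(estimate_task_state(rest_only),
               class = "ctrlbridge_labeling_error")
})

test_that("bootstrap resampling is seeded, exhaustive at k = n, unbiased", {
  set.seed(1601)
  subjects <- lapply(1:352, function(i)
    ts_data(matrix(rnorm(40), 20, 2), dt = 1, subject_id = i))

  all_in <- bootstrap_concatenate(subjects[1:5], k = 5, reps = 1, seed = 9)
  expect_identical(all_in[[1]]$indices, 1:5)

  d1 <- bootstrap_concatenate(subjects, k = 100, reps = 5, seed = 42)
  d2 <- bootstrap_concatenate(subjects, k = 100, reps = 5, seed = 42)
  expect_identical(lapply(d1, `[[`, "indices"), lapply(d2, `[[`, "indices"))

  reps <- 100
  draws <- bootstrap_concatenate(subjects, k = 100, reps = reps, seed = 7)
  counts <- tabulate(unlist(lapply(draws, `[[`, "indices")), nbins = 352)
  p <- 100 / 352
  se <- sqrt(reps * p * (1 - p))
  expect_equal(sum(counts), reps * 100)
  expect_true(mean(abs(counts - reps * p) <= 3 * se) > 0.98)

  expect_error(bootstrap_concatenate(subjects, k = 400, reps = 1, seed = 1),
               class = "ctrlbridge_invalid_argument")
})

test_that("full recovery: normalized series through lasso and conversion", {
  # moderate-size end-to-end check (the acceptance suite runs the larger one)
  sys0 <- make_random_stable_system(5, sparsity = 0.5, seed = 1701)
  tr0 <- sum(diag(steady_state(sys0)$sigma))
  sys <- linear_system(sys0$A, sys0$S_C / tr0)  # unit-trace steady state
  run <- simulate_ou_series(sys, steady_state(sys), 0.72, 40000L, seed = 1702)
  run$labels <- rep("rest", nrow(run$values))
  fit <- fit_var_lasso(trace_normalize(run), lambda = 1e-4)
  est <- to_continuous_system(fit, 0.72)
  expect_lt(norm(est$A - sys$A, "F") / norm(sys$A, "F"), 0.15)
  expect_lt(norm(est$S_C - sys$S_C, "F") / norm(sys$S_C, "F"), 0.15)
})

test_that("covariance shrinkage reaches the conditioning target", {
  set.seed(1801)
  X <- matrix(rnorm(12 * 4), 12, 4)
  S <- cov(cbind(X, X[, 1] + 1e-9 * rnorm(12)))  # nearly singular
  Sh <- shrink_covariance(S, target_cond = 1e6)
  ev <- eigen(Sh, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(max(ev) / min(ev), 1e6 * 1.01)
  well <- diag(4)
  expect_identical(shrink_covariance(well, 1e8), well)
})
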