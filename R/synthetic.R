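#' Random stable OU system generator
#'
#' Draws a drift matrix with a prescribed off-diagonal zero fraction and
#' stability margin `max Re(eigen(A)) <= -0.1`, and a random symmetric
#' positive-definite noise rate with condition number at most 100.
#' Deterministic given the seed.
#'
#' @param n Dimension (number of nodes).
#' @param sparsity Fraction of off-diagonal entries of `A` set to zero
#'   (`0 <= sparsity < 1`).
#' @param seed Integer seed.
#' @return A [linear_system()].
#' @export
make_random_stable_system <- function(n, sparsity = 0, seed) {
  if (!is.numeric(sparsity) || sparsity < 0 || sparsity >= 1) {
    cb_stop("sparsity must be in [0, 1)", "ctrlbridge_invalid_argument")
  }
  with_seed(seed, {
    A <- matrix(stats::rnorm(n * n, sd = 1 / sqrt(max(n, 2))), n, n)
    if (n > 1L) {
      off <- which(row(A) != col(A))
      n_zero <- floor(sparsity * length(off))
      if (n_zero > 0) A[sample(off, n_zero)] <- 0
    }
    shift <- max(Re(eigen(A, only.values = TRUE)$values))
    diag(A) <- diag(A) - shift - 0.1 - stats::runif(1, 0, 0.4)
    # noise rate: random orthogonal basis, eigenvalues log-spaced within cond 100
    Q <- qr.Q(qr(matrix(stats::rnorm(n * n), n, n)))
    ev <- exp(stats::runif(n, log(0.05), log(0.05 * 100)))
    S_C <- symmetrize(Q %*% (ev * t(Q)), warn = FALSE)
    linear_system(A, S_C)
  })
}

#' Simulate an OU trajectory by exact discretization
#'
#' Samples the process exactly in law on the grid using the one-step VAR(1)
#' pair from [exact_discretization()]; no integration error is introduced.
#'
#' @param system A [linear_system()].
#' @param x0_state Initial [gaussian_state()] (use [steady_state()] for a
#'   stationary run).
#' @param dt Sampling interval.
#' @param n_steps Number of steps (the series has `n_steps + 1` rows).
#' @param seed Integer seed.
#' @param labels Optional labels passed to [ts_data()].
#' @param subject_id Optional subject identifier.
#' @return A [ts_data()].
#' @export
simulate_ou_series <- function(system, x0_state, dt, n_steps, seed,
                               labels = NULL, subject_id = NULL) {
  stopifnot(inherits(system, "linear_system"),
            inherits(x0_state, "gaussian_state"))
  if (n_steps < 1L) {
    cb_stop("n_steps must be at least 1", "ctrlbridge_invalid_argument")
  }
  disc <- exact_discretization(system, dt)
  L <- sqrtm_sym(disc$Sigma_dt)
  n <- system$n
  with_seed(seed, {
    X <- matrix(0, n_steps + 1L, n)
    X[1, ] <- drop(rmvn_cols(1, x0_state$mu, x0_state$sigma))
    eps <- L %*% matrix(stats::rnorm(n * n_steps), n, n_steps)
    for (k in seq_len(n_steps)) {
      X[k + 1L, ] <- drop(disc$a %*% X[k, ]) + eps[, k]
    }
    ts_data(X, dt, labels = labels, subject_id = subject_id)
  })
}

#' Monte-Carlo simulation of the optimally controlled process
#'
#' Euler-Maruyama integration of `dx = (A x + v*) dt + C dw` with the
#' feedback `v*(x, t) = -S_C (Pi(t) x - m(t))` interpolated linearly in time
#' from the bridge solution grid. Serves as the independent oracle for the
#' analytic costs: returns per-path endpoints, the per-path quadratic cost
#' `int ||v||^2_{S_C^{-1}} dt`, and per-node costs `int v_k^2 dt`.
#'
#' @param problem A [bridge_problem()].
#' @param solution Its [solve_schrodinger_bridge()] solution.
#' @param n_paths Number of simulated paths.
#' @param euler_dt Euler step; must be at most `horizon / 500`.
#' @param seed Integer seed.
#' @return A list with `endpoints` (n x n_paths), `cost` (length n_paths),
#'   `node_cost` (n x n_paths), and a `summary` list of means and standard
#'   errors.
#' @export
simulate_controlled_paths <- function(problem, solution, n_paths,
                                      euler_dt = problem$horizon / 500,
                                      seed = 1L) {
  stopifnot(inherits(problem, "bridge_problem"),
            inherits(solution, "bridge_solution"))
  if (euler_dt > problem$horizon / 500 + 1e-15) {
    cb_stop("euler_dt must be at most horizon / 500",
            "ctrlbridge_resolution_error")
  }
  sys <- problem$system
  n <- sys$n
  K <- ceiling(problem$horizon / euler_dt)
  h <- problem$horizon / K
  L <- sqrtm_sym(sys$S_C)
  S_Ci <- solve(sys$S_C)
  tgrid <- solution$time
  interp_idx <- function(t) {
    # linear interpolation weights on the solution grid
    j <- findInterval(t, tgrid, rightmost.closed = TRUE)
    j <- min(max(j, 1L), length(tgrid) - 1L)
    w <- (t - tgrid[j]) / (tgrid[j + 1L] - tgrid[j])
    list(j = j, w = w)
  }
  with_seed(seed, {
    X <- rmvn_cols(n_paths, problem$initial$mu, problem$initial$sigma)
    cost <- numeric(n_paths)
    node_cost <- matrix(0, n, n_paths)
    for (k in seq_len(K)) {
      t_k <- (k - 1L) * h
      iw <- interp_idx(t_k)
      Pi_k <- (1 - iw$w) * matrix(solution$Pi[, , iw$j], n, n) +
        iw$w * matrix(solution$Pi[, , iw$j + 1L], n, n)
      m_k <- (1 - iw$w) * solution$m_t[, iw$j] +
        iw$w * solution$m_t[, iw$j + 1L]
      v <- -sys$S_C %*% (Pi_k %*% X - m_k)
      cost <- cost + colSums(v * (S_Ci %*% v)) * h
      node_cost <- node_cost + v^2 * h
      X <- X + (sys$A %*% X + v) * h +
        sqrt(h) * (L %*% matrix(stats::rnorm(n * n_paths), n, n_paths))
    }
    summary <- list(
      cost_mean = mean(cost), cost_se = stats::sd(cost) / sqrt(n_paths),
      endpoint_mean = rowMeans(X),
      endpoint_mean_se = apply(X, 1, stats::sd) / sqrt(n_paths),
      endpoint_cov = stats::cov(t(X)),
      node_cost_mean = rowMeans(node_cost),
      node_cost_se = apply(node_cost, 1, stats::sd) / sqrt(n_paths))
    list(endpoints = X, cost = cost, node_cost = node_cost, summary = summary)
  })
}

#' Specification of a synthetic multi-subject rest/task cohort
#'
#' Defines the study conditions the generator emulates: per-subject resting
#' and task runs sampled from a known stable OU system, with task-performing
#' blocks given a mean offset `delta` and a modulated covariance
#' `L Sigma0 L'`, and subject-specific BOLD-like scale factors.
#'
#' @param n_subjects Number of subjects.
#' @param n_rois Number of ROIs (must match the generating system).
#' @param rest_length,task_length Timepoints per resting / task run.
#' @param dt Sampling interval (default 0.72 time units, an fMRI-like TR).
#' @param block_length Timepoints per task block (task-free and
#'   task-performing blocks alternate, task-free first).
#' @param mean_offsets Named list (one per task) of length-`n_rois` offset
#'   vectors `delta`.
#' @param cov_modulators Named list (same names) of nonsingular `n_rois` x
#'   `n_rois` mixing matrices `L`.
#' @param subject_scales Positive per-subject scale factors (length
#'   `n_subjects`), emulating subject-specific signal magnitude.
#' @param seed Integer seed; the cohort is fully reproducible.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, n_rois, rest_length = 800L,
                        task_length = 400L, dt = 0.72, block_length = 40L,
                        mean_offsets, cov_modulators,
                        subject_scales = rep(1, n_subjects), seed = 1L) {
  if (n_subjects < 1L || n_rois < 1L || rest_length < 2L || task_length < 2L ||
      block_length < 1L) {
    cb_stop("all counts must be positive", "ctrlbridge_invalid_argument")
  }
  if (block_length > task_length) {
    cb_stop("block_length exceeds task_length", "ctrlbridge_invalid_argument")
  }
  if (!is.list(mean_offsets) || !is.list(cov_modulators) ||
      !identical(names(mean_offsets), names(cov_modulators)) ||
      is.null(names(mean_offsets))) {
    cb_stop("mean_offsets and cov_modulators must be named lists over the same tasks",
            "ctrlbridge_invalid_argument")
  }
  for (nm in names(cov_modulators)) {
    Lm <- cov_modulators[[nm]]
    if (!is_square_numeric(Lm) || nrow(Lm) != n_rois ||
        abs(det(Lm)) < 1e-12) {
      cb_stop(sprintf("cov_modulator for task %s must be a nonsingular %d x %d matrix", nm, n_rois, n_rois),
              "ctrlbridge_invalid_argument")
    }
    if (length(mean_offsets[[nm]]) != n_rois) {
      cb_stop(sprintf("mean_offset for task %s must have length %d", nm, n_rois),
              "ctrlbridge_invalid_argument")
    }
  }
  if (length(subject_scales) != n_subjects || any(subject_scales <= 0)) {
    cb_stop("subject_scales must be positive and one per subject",
            "ctrlbridge_invalid_argument")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_rois = as.integer(n_rois),
                 rest_length = as.integer(rest_length),
                 task_length = as.integer(task_length), dt = dt,
                 block_length = as.integer(block_length),
                 mean_offsets = mean_offsets,
                 cov_modulators = cov_modulators,
                 subject_scales = subject_scales,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic multi-subject cohort
#'
#' Per subject: a stationary resting run, and per task a run of alternating
#' task-free blocks (steady-state OU samples) and task-performing blocks (the
#' same OU samples pushed through the affine map `x -> L x + delta`, so the
#' performing blocks have mean `delta` and covariance `L Sigma0 L'` exactly
#' in law). The whole subject is multiplied by its scale factor.
#'
#' @param spec A [cohort_spec()].
#' @param system A stable [linear_system()] with `n = spec$n_rois`.
#' @return A list of subjects; each subject is a list with `rest` (a
#'   [ts_data()]) and `tasks` (named list of labeled [ts_data()]).
#' @export
generate_cohort <- function(spec, system) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(system, "linear_system"))
  if (system$n != spec$n_rois) {
    cb_stop("system dimension must equal n_rois", "ctrlbridge_invalid_argument")
  }
  ss <- steady_state(system)
  tasks <- names(spec$mean_offsets)
  lapply(seq_len(spec$n_subjects), function(s) {
    scale_s <- spec$subject_scales[s]
    sid <- sprintf("sub%03d", s)
    rest <- simulate_ou_series(system, ss, spec$dt, spec$rest_length - 1L,
                               seed = spec$seed + 1000L * s,
                               labels = rep("rest", spec$rest_length),
                               subject_id = sid)
    rest$values <- rest$values * scale_s
    task_runs <- lapply(seq_along(tasks), function(j) {
      tk <- tasks[j]
      run <- simulate_ou_series(system, ss, spec$dt, spec$task_length - 1L,
                                seed = spec$seed + 1000L * s + j)
      # alternate blocks: task_free first, then task_performing
      block_id <- ((seq_len(spec$task_length) - 1L) %/% spec$block_length)
      labels <- ifelse(block_id %% 2L == 0L, "task_free", "task_performing")
      perf <- labels == "task_performing"
      vals <- run$values
      vals[perf, ] <- vals[perf, , drop = FALSE] %*%
        t(spec$cov_modulators[[tk]]) +
        matrix(spec$mean_offsets[[tk]], sum(perf), spec$n_rois, byrow = TRUE)
      ts_data(vals * scale_s, spec$dt, labels = labels, subject_id = sid)
    })
    names(task_runs) <- tasks
    list(rest = rest, tasks = task_runs, subject_id = sid)
  })
}
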