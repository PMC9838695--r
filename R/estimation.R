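#' ROI time-series container
#'
#' @param values timepoints x n numeric matrix of ROI activity.
#' @param dt Sampling interval (time units).
#' @param labels Optional per-timepoint character labels from
#'   `{"rest", "task_free", "task_performing"}`.
#' @param subject_id Optional subject identifier.
#' @return An object of class `ts_data`.
#' @export
ts_data <- function(values, dt, labels = NULL, subject_id = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values) || nrow(values) < 2L) {
    cb_stop("values must be a numeric matrix with at least 2 timepoints",
            "ctrlbridge_invalid_argument")
  }
  check_finite(values, "values")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    cb_stop("dt must be a single positive number", "ctrlbridge_invalid_argument")
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(values)) {
      cb_stop("labels length must equal the number of timepoints",
              "ctrlbridge_labeling_error")
    }
    bad <- setdiff(unique(labels), c("rest", "task_free", "task_performing"))
    if (length(bad)) {
      cb_stop(sprintf("unknown labels: %s", paste(bad, collapse = ", ")),
              "ctrlbridge_labeling_error")
    }
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("roi_", seq_len(ncol(values)))
  }
  structure(list(values = values, dt = dt, labels = labels,
                 subject_id = subject_id), class = "ts_data")
}

#' @export
print.ts_data <- function(x, ...) {
  cat(sprintf("<ts_data> %d timepoints x %d ROIs, dt = %.4g%s%s\n",
              nrow(x$values), ncol(x$values), x$dt,
              if (is.null(x$labels)) "" else
                sprintf(", labels: %s", paste(unique(x$labels), collapse = "/")),
              if (is.null(x$subject_id)) "" else
                sprintf(", subject %s", x$subject_id)))
  invisible(x)
}

#' @noRd
.reference_rows <- function(series, reference_labels) {
  if (is.null(series$labels)) return(seq_len(nrow(series$values)))
  which(series$labels %in% reference_labels)
}

#' Trace normalization of a subject's series
#'
#' Divides the whole series by the square root of the trace of the empirical
#' covariance of the reference segment (the resting run, or the task-free
#' moments of a task run), so that the reference covariance has unit trace.
#' This removes subject-specific BOLD scale and makes series concatenable
#' across subjects.
#'
#' @param series A [ts_data()].
#' @param reference_labels Labels defining the reference segment (default
#'   `c("rest", "task_free")`); a series without labels is its own reference.
#' @return The normalized [ts_data()].
#' @export
trace_normalize <- function(series, reference_labels = c("rest", "task_free")) {
  stopifnot(inherits(series, "ts_data"))
  rows <- .reference_rows(series, reference_labels)
  n <- ncol(series$values)
  if (length(rows) == 0L) {
    cb_stop("reference segment is empty; check the labels",
            "ctrlbridge_labeling_error")
  }
  if (length(rows) < n + 1L) {
    cb_stop(sprintf("reference segment has %d timepoints; need at least n + 1 = %d", length(rows), n + 1L),
            "ctrlbridge_labeling_error")
  }
  tr <- sum(diag(stats::cov(series$values[rows, , drop = FALSE])))
  if (tr <= 0) {
    cb_stop("reference segment has zero variance", "ctrlbridge_labeling_error")
  }
  out <- series
  out$values <- series$values / sqrt(tr)
  out
}

#' VAR(1) fit of discretized OU dynamics
#'
#' Row-wise L1-penalized regression of `x(t + dt)` on `x(t)` with intercept.
#' Regression pairs never span segment boundaries, so a list of series
#' (e.g. concatenated subjects) is fitted jointly without contaminating
#' transitions.
#'
#' @param series A [ts_data()] or a list of them (segments).
#' @param lambda L1 penalty: a nonnegative number, or `"cv"` (default) for
#'   5-fold cross-validation of the one-step-ahead error via
#'   [glmnet::cv.glmnet()]. `lambda = 0` is exact ordinary least squares.
#' @return An object of class `var_fit` with `a_hat` (n x n coefficient
#'   matrix, rows = response ROI), `intercept`, `S_eps` (residual covariance)
#'   and `lambda` (per-row penalties actually used).
#' @export
fit_var_lasso <- function(series, lambda = "cv") {
  if (inherits(series, "ts_data")) series <- list(series)
  stopifnot(all(vapply(series, inherits, TRUE, "ts_data")))
  n <- ncol(series[[1]]$values)
  X <- do.call(rbind, lapply(series, function(s)
    s$values[-nrow(s$values), , drop = FALSE]))
  Y <- do.call(rbind, lapply(series, function(s)
    s$values[-1, , drop = FALSE]))
  if (nrow(X) < 10L * n) {
    cb_warn(sprintf("only %d regression pairs for n = %d ROIs; at least %d recommended", nrow(X), n, 10L * n),
            "ctrlbridge_data_warning")
  }
  a_hat <- matrix(0, n, n, dimnames = list(colnames(series[[1]]$values),
                                           colnames(series[[1]]$values)))
  intercept <- numeric(n)
  lambdas <- numeric(n)
  if (identical(lambda, 0) || identical(lambda, 0L)) {
    Xd <- cbind(1, X)
    qrX <- qr(Xd)
    if (qrX$rank < ncol(Xd)) {
      cb_stop("design matrix is rank deficient; OLS (lambda = 0) undefined",
              "ctrlbridge_singularity_error")
    }
    B <- qr.coef(qrX, Y)
    intercept <- B[1, ]
    a_hat[] <- t(B[-1, , drop = FALSE])
  } else if (identical(lambda, "cv")) {
    for (i in seq_len(n)) {
      cv <- glmnet::cv.glmnet(X, Y[, i], alpha = 1, nfolds = 5,
                              standardize = FALSE)
      lambdas[i] <- cv$lambda.min
      cf <- as.numeric(stats::coef(cv, s = "lambda.min"))
      intercept[i] <- cf[1]
      a_hat[i, ] <- cf[-1]
    }
  } else if (is.numeric(lambda) && length(lambda) == 1L && lambda > 0) {
    for (i in seq_len(n)) {
      fit <- glmnet::glmnet(X, Y[, i], alpha = 1, lambda = lambda,
                            standardize = FALSE)
      cf <- as.numeric(stats::coef(fit, s = lambda))
      intercept[i] <- cf[1]
      a_hat[i, ] <- cf[-1]
      lambdas[i] <- lambda
    }
  } else {
    cb_stop("lambda must be a nonnegative number or \"cv\"",
            "ctrlbridge_invalid_argument")
  }
  resid <- Y - (X %*% t(a_hat) + matrix(intercept, nrow(X), n, byrow = TRUE))
  S_eps <- symmetrize(stats::cov(resid), warn = FALSE)
  structure(list(a_hat = a_hat, intercept = intercept, S_eps = S_eps,
                 lambda = lambdas, n_pairs = nrow(X)),
            class = "var_fit")
}

#' @export
print.var_fit <- function(x, ...) {
  cat(sprintf("<var_fit> n = %d, %d regression pairs, mean lambda = %.4g, spectral radius(a_hat) = %.4g\n",
              nrow(x$a_hat), x$n_pairs, mean(x$lambda),
              max(Mod(eigen(x$a_hat, only.values = TRUE)$values))))
  invisible(x)
}

#' Convert a discrete VAR(1) fit to continuous-time OU dynamics
#'
#' Drift: `A = log(a_hat) / dt` (principal matrix logarithm). Noise rate:
#' `S_C = -(1/dt) vec^{-1}[(I - a (x) a)^{-1} log(a (x) a) vec(S_eps)]`, the
#' inverse of the exact-discretization integral; `(x)` is the Kronecker
#' product. The principal logarithm requires all eigenvalues of `a_hat`
#' inside the open unit disk and off the closed negative real axis.
#'
#' @param fit A [fit_var_lasso()] result.
#' @param dt Sampling interval used for the fit.
#' @return A [linear_system()].
#' @export
to_continuous_system <- function(fit, dt) {
  stopifnot(inherits(fit, "var_fit"))
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    cb_stop("dt must be a single positive number", "ctrlbridge_invalid_argument")
  }
  a <- unname(fit$a_hat)
  n <- nrow(a)
  mods <- Mod(eigen(a, only.values = TRUE)$values)
  if (max(mods) >= 1) {
    cb_stop(sprintf("a_hat has eigenvalue of modulus %.6g >= 1: discrete dynamics non-stationary", max(mods)),
            "ctrlbridge_nonstationary_error")
  }
  A <- logm_principal(a, imag_tol = 1e-6) / dt
  # log(a (x) a) = log(a) (x) I + I (x) log(a) for the principal branch here
  la <- A * dt
  L_kron <- kronecker(la, diag(n)) + kronecker(diag(n), la)
  I_aa <- diag(n * n) - kronecker(a, a)
  S_C <- matrix(-solve(I_aa, L_kron %*% as.vector(fit$S_eps)) / dt, n, n)
  S_C <- symmetrize(S_C, warn = FALSE)
  linear_system(A, S_C)
}

#' Empirical resting-state distribution
#'
#' Pools all rest-labeled rows (or all rows of unlabeled series) and returns
#' their empirical mean and covariance.
#'
#' @param series A [ts_data()] or list of them.
#' @return A [gaussian_state()]. A zero covariance is flagged with a warning.
#' @export
estimate_rest_state <- function(series) {
  if (inherits(series, "ts_data")) series <- list(series)
  rows <- do.call(rbind, lapply(series, function(s) {
    idx <- .reference_rows(s, "rest")
    s$values[idx, , drop = FALSE]
  }))
  if (is.null(rows) || nrow(rows) < 2L) {
    cb_stop("need at least 2 rest timepoints", "ctrlbridge_insufficient_data_error")
  }
  S <- symmetrize(stats::cov(rows), warn = FALSE)
  if (sum(diag(S)) == 0) {
    cb_warn("rest covariance is identically zero (degenerate state)",
            "ctrlbridge_degenerate_warning")
  }
  gaussian_state(colMeans(rows), S)
}

#' Empirical task-state distribution
#'
#' Mean: average during task-performing moments minus average during
#' task-free moments (the task-free baseline plays the role of the resting
#' mean). Covariance: empirical covariance of the task-performing moments.
#'
#' @param series A [ts_data()] (with both labels present) or list of them.
#' @return A [gaussian_state()].
#' @export
estimate_task_state <- function(series) {
  if (inherits(series, "ts_data")) series <- list(series)
  grab <- function(lbl) do.call(rbind, lapply(series, function(s) {
    if (is.null(s$labels)) return(NULL)
    s$values[s$labels == lbl, , drop = FALSE]
  }))
  perf <- grab("task_performing")
  free <- grab("task_free")
  if (is.null(perf) || nrow(perf) < 2L || is.null(free) || nrow(free) < 1L) {
    cb_stop("need both task_performing and task_free labeled timepoints",
            "ctrlbridge_labeling_error")
  }
  gaussian_state(colMeans(perf) - colMeans(free),
                 symmetrize(stats::cov(perf), warn = FALSE))
}

#' Bootstrap subject resampling with per-subject normalization
#'
#' Each replicate draws `k` subjects uniformly without replacement,
#' trace-normalizes each drawn subject, and records the concatenation (as a
#' list of segments, so downstream regression respects boundaries).
#'
#' @param subjects A list of [ts_data()] (one element per subject, or a list
#'   of runs per subject).
#' @param k Subjects per replicate.
#' @param reps Number of replicates.
#' @param seed Integer seed; identical seeds give identical replicates.
#' @return A list of `reps` replicates, each a list with `indices` (drawn
#'   subject positions) and `segments` (normalized [ts_data()] list).
#' @export
bootstrap_concatenate <- function(subjects, k, reps, seed) {
  if (k > length(subjects)) {
    cb_stop(sprintf("k = %d exceeds the %d available subjects", k,
                    length(subjects)),
            "ctrlbridge_invalid_argument")
  }
  with_seed(seed, {
    lapply(seq_len(reps), function(r) {
      idx <- sort(sample.int(length(subjects), k, replace = FALSE))
      segs <- lapply(subjects[idx], function(s) {
        if (inherits(s, "ts_data")) trace_normalize(s)
        else lapply(s, trace_normalize)
      })
      list(indices = idx, segments = segs)
    })
  })
}

#' Diagonal shrinkage of a covariance matrix to a conditioning floor
#'
#' Convex shrinkage `(1 - w) S + w diag(S)` with the smallest `w` making the
#' condition number at most `target_cond`; needed because bridge marginals
#' must be strictly positive definite.
#'
#' @param sigma Symmetric covariance matrix.
#' @param target_cond Maximum acceptable condition number (default 1e8).
#' @return The shrunk covariance matrix.
#' @export
shrink_covariance <- function(sigma, target_cond = 1e8) {
  S <- symmetrize(sigma, warn = FALSE)
  cond_of <- function(w) {
    ev <- eigen((1 - w) * S + w * diag(diag(S), nrow(S)), symmetric = TRUE,
                only.values = TRUE)$values
    if (min(ev) <= 0) Inf else max(ev) / min(ev)
  }
  if (cond_of(0) <= target_cond) return(S)
  if (cond_of(1) > target_cond) {
    # even the diagonal is too ill-conditioned: add a ridge instead
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    return(S + diag(max(ev) / target_cond, nrow(S)))
  }
  w <- stats::uniroot(function(w) log(cond_of(w)) - log(target_cond),
                      c(0, 1), tol = 1e-6)$root
  symmetrize((1 - w) * S + w * diag(diag(S), nrow(S)), warn = FALSE)
}
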