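#' Entropy of an input map
#'
#' Shannon entropy (natural log) of the normalized input shares
#' `S = -sum_l (I_l / I_sum) log(I_l / I_sum)`; zero entries contribute 0.
#' Maximal (`log n`) for a uniform map, 0 for a single-node map. Large values
#' mean the control input is dispersed over many regions.
#'
#' @param map_vector Nonnegative numeric vector with at least one positive
#'   entry.
#' @return Scalar entropy in `[0, log(n)]`.
#' @export
input_map_entropy <- function(map_vector) {
  v <- as.numeric(map_vector)
  if (any(v < 0) || !all(is.finite(v))) {
    cb_stop("input map entries must be finite and nonnegative",
            "ctrlbridge_invalid_argument")
  }
  s <- sum(v)
  if (s <= 0) {
    cb_stop("input map is all zero; entropy undefined",
            "ctrlbridge_invalid_argument")
  }
  p <- v / s
  p <- p[p > 0]
  -sum(p * log(p))
}

# descending value, ties broken by ascending ROI index
#' @noRd
.rank_order <- function(v) order(-v, seq_along(v))

#' Top-k membership counts across tasks
#'
#' For each of the mean, covariance and total input maps, counts for every
#' ROI in how many tasks it ranks among the `k` largest inputs. Ties are
#' broken by descending value then ascending ROI index.
#'
#' @param maps List of per-task `input_map` data frames (as returned by
#'   [node_inputs()]), sharing the same `roi` labels.
#' @param k Rank cutoff (`k <= n`).
#' @return A data frame with columns `roi`, `count_mean`, `count_cov`,
#'   `count_total`; counts lie in `[0, length(maps)]`.
#' @export
top_k_membership_counts <- function(maps, k) {
  stopifnot(length(maps) >= 1L)
  rois <- maps[[1]]$roi
  for (m in maps) {
    if (!identical(m$roi, rois)) {
      cb_stop("all input maps must share the same ROI names in the same order",
              "ctrlbridge_schema_error")
    }
  }
  if (k > length(rois)) {
    cb_stop("k exceeds the number of ROIs", "ctrlbridge_invalid_argument")
  }
  count_for <- function(col) {
    cnt <- integer(length(rois))
    for (m in maps) {
      top <- .rank_order(m[[col]])[seq_len(k)]
      cnt[top] <- cnt[top] + 1L
    }
    cnt
  }
  data.frame(roi = rois,
             count_mean = count_for("I_mean"),
             count_cov = count_for("I_cov"),
             count_total = count_for("I_total"),
             stringsAsFactors = FALSE)
}

#' Minimal ROI subset covering a fraction of the total input
#'
#' ROIs sorted by descending input; returns the smallest prefix whose
#' cumulative share of the total reaches `fraction` (e.g. 0.30 reproduces a
#' "regions accounting for 30% of the whole input" selection).
#'
#' @param map_vector Nonnegative input map.
#' @param fraction Target cumulative share in `(0, 1]`.
#' @return Integer vector of selected ROI indices, in descending input order.
#' @export
coverage_selection <- function(map_vector, fraction) {
  v <- as.numeric(map_vector)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    cb_stop("fraction must be in (0, 1]", "ctrlbridge_invalid_argument")
  }
  if (sum(v) <= 0) {
    cb_stop("input map is all zero", "ctrlbridge_invalid_argument")
  }
  ord <- .rank_order(v)
  shares <- cumsum(v[ord]) / sum(v)
  m <- which(shares >= fraction - 1e-12)[1]
  if (fraction == 1) m <- sum(v[ord] > 0)
  ord[seq_len(m)]
}

#' Correlation between an input map and activation strength
#'
#' Pearson correlation between a per-ROI input map and the absolute t values
#' of the task-vs-baseline activation change.
#'
#' @param input_map Per-ROI input vector (length >= 3).
#' @param activation_t Per-ROI t values (absolute values are taken).
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
activation_correlation <- function(input_map, activation_t) {
  x <- as.numeric(input_map)
  y <- abs(as.numeric(activation_t))
  if (length(x) != length(y) || length(x) < 3L) {
    cb_stop("vectors must have equal length >= 3", "ctrlbridge_invalid_argument")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    cb_stop("zero variance: correlation undefined",
            "ctrlbridge_undefined_correlation_error")
  }
  stats::cor(x, y)
}

#' Per-ROI activation t values of a task run
#'
#' Welch two-sample t statistic per ROI between task-performing and task-free
#' samples; pooled across a list of runs.
#'
#' @param series A labeled [ts_data()] or list of them.
#' @return Numeric vector of t values (one per ROI).
#' @export
activation_tvalues <- function(series) {
  if (inherits(series, "ts_data")) series <- list(series)
  pool <- function(lbl) do.call(rbind, lapply(series, function(s)
    s$values[s$labels == lbl, , drop = FALSE]))
  perf <- pool("task_performing")
  free <- pool("task_free")
  if (is.null(perf) || is.null(free) || nrow(perf) < 2L || nrow(free) < 2L) {
    cb_stop("need task_performing and task_free samples",
            "ctrlbridge_labeling_error")
  }
  vapply(seq_len(ncol(perf)), function(j)
    stats::t.test(perf[, j], free[, j])$statistic, 0.0)
}

#' @noRd
.default_config <- function(config) {
  defaults <- list(T = 1.0, grid_points = 201L, dt = NULL,
                   lambda = list(mode = "cv", value = NULL),
                   bootstrap = list(k = 10L, reps = 10L, seed = 1L),
                   shrink_target_cond = 1e8)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  if (is.null(config$lambda$mode)) config$lambda$mode <- "cv"
  config
}

#' Bootstrap transition-cost analysis pipeline
#'
#' Reproduces the full analysis on a cohort: for each bootstrap replicate it
#' draws `k` subjects, trace-normalizes them, fits the resting dynamics
#' (sparse VAR(1) then continuous-time conversion), estimates the rest state
#' and each task state, solves the rest-to-task Schroedinger bridge, and
#' records the cost decomposition and per-node input maps. The
#' covariance/mean cost ratio is computed per replicate and then averaged.
#'
#' @param subjects A cohort: list of subjects, each a list with `rest` (a
#'   [ts_data()]) and `tasks` (named list of labeled [ts_data()]).
#' @param config List of settings: `T` (horizon, default 1), `grid_points`
#'   (default 201), `lambda` (`list(mode = "cv")` or
#'   `list(mode = "fixed", value = x)`), `bootstrap` (`list(k, reps, seed)`),
#'   `shrink_target_cond` (PD floor for estimated covariances, default 1e8).
#' @return An object of class `cost_report`: `costs` (data frame: task,
#'   replicate, J_mean, J_cov, J_total, ratio), `summary` (per-task mean and
#'   SD across replicates), `input_maps` (per task, replicate-averaged
#'   [node_inputs()] maps), `failures`, and the resolved `config`.
#' @export
run_transition_analysis <- function(subjects, config = list()) {
  config <- .default_config(config)
  tasks <- names(subjects[[1]]$tasks)
  reps <- config$bootstrap$reps
  draws <- bootstrap_concatenate(lapply(subjects, function(s) s$rest),
                                 k = config$bootstrap$k, reps = reps,
                                 seed = config$bootstrap$seed)
  lam <- if (identical(config$lambda$mode, "fixed")) config$lambda$value else "cv"
  rows <- list(); map_acc <- list(); failures <- list()
  # seeded block: cross-validation fold draws inside the loop must be
  # reproducible for the determinism contract, not only the subject draws
  with_seed(config$bootstrap$seed + 1L, for (r in seq_len(reps)) {
    res <- tryCatch({
      idx <- draws[[r]]$indices
      rest_segs <- draws[[r]]$segments
      fit <- fit_var_lasso(rest_segs, lambda = lam)
      sys <- to_continuous_system(fit, rest_segs[[1]]$dt)
      rest_state <- estimate_rest_state(rest_segs)
      rest_state <- gaussian_state(
        rest_state$mu,
        shrink_covariance(rest_state$sigma, config$shrink_target_cond))
      rep_rows <- list(); rep_maps <- list()
      for (tk in tasks) {
        task_runs <- lapply(subjects[idx], function(s)
          trace_normalize(s$tasks[[tk]], reference_labels = "task_free"))
        task_state <- estimate_task_state(task_runs)
        task_state <- gaussian_state(
          task_state$mu,
          shrink_covariance(task_state$sigma, config$shrink_target_cond))
        prob <- bridge_problem(sys, rest_state, task_state,
                               horizon = config$T,
                               grid_points = config$grid_points)
        sol <- solve_schrodinger_bridge(prob)
        rep_rows[[tk]] <- data.frame(
          task = tk, replicate = r, J_mean = sol$J_mean, J_cov = sol$J_cov,
          J_total = sol$J_total,
          ratio = if (sol$J_mean > 0) sol$J_cov / sol$J_mean else NA_real_,
          residual_T = sol$diagnostics$residual_T,
          stringsAsFactors = FALSE)
        rep_maps[[tk]] <- node_inputs(prob, sol,
                                      roi_names = colnames(rest_segs[[1]]$values))
      }
      list(rows = rep_rows, maps = rep_maps)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- list(replicate = r,
                                                reason = conditionMessage(res))
      if (length(failures) > 0.1 * reps) {
        cb_stop(sprintf("more than 10%% of replicates failed (last: %s)",
                        conditionMessage(res)),
                "ctrlbridge_pipeline_error")
      }
    } else {
      rows <- c(rows, res$rows)
      map_acc[[length(map_acc) + 1L]] <- res$maps
    }
  })
  costs <- do.call(rbind, rows)
  rownames(costs) <- NULL
  agg <- function(f) stats::aggregate(
    costs[c("J_mean", "J_cov", "J_total", "ratio")],
    by = list(task = costs$task), FUN = f)
  mu <- agg(mean); sdv <- agg(stats::sd)
  summary <- data.frame(task = mu$task,
                        J_mean = mu$J_mean, J_mean_sd = sdv$J_mean,
                        J_cov = mu$J_cov, J_cov_sd = sdv$J_cov,
                        J_total = mu$J_total, J_total_sd = sdv$J_total,
                        ratio = mu$ratio, ratio_sd = sdv$ratio,
                        stringsAsFactors = FALSE)
  input_maps <- lapply(tasks, function(tk) {
    ms <- lapply(map_acc, function(m) m[[tk]])
    out <- ms[[1]]
    out$I_mean <- rowMeans(sapply(ms, function(m) m$I_mean))
    out$I_cov <- rowMeans(sapply(ms, function(m) m$I_cov))
    out$I_total <- out$I_mean + out$I_cov
    out
  })
  names(input_maps) <- tasks
  structure(list(costs = costs, summary = summary, input_maps = input_maps,
                 failures = failures, config = config),
            class = "cost_report")
}

#' @export
print.cost_report <- function(x, ...) {
  cat(sprintf("<cost_report> %d replicates, %d failed\n",
              length(unique(x$costs$replicate)), length(x$failures)))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Cross-task average of input maps
#'
#' Normalizes each task's maps by that task's total input over all ROIs
#' (`sum_k I(k)`) and averages the normalized maps across tasks, so every
#' task contributes equally regardless of its absolute cost.
#'
#' @param maps Named list of per-task `input_map` data frames.
#' @return A single `input_map` data frame of task-averaged shares.
#' @export
average_input_maps <- function(maps) {
  stopifnot(length(maps) >= 1L)
  rois <- maps[[1]]$roi
  norm_one <- function(m) {
    tot <- sum(m$I_total)
    cbind(m$I_mean / tot, m$I_cov / tot, m$I_total / tot)
  }
  acc <- Reduce(`+`, lapply(maps, norm_one)) / length(maps)
  out <- data.frame(roi = rois, I_mean = acc[, 1], I_cov = acc[, 2],
                    I_total = acc[, 3], stringsAsFactors = FALSE)
  class(out) <- c("input_map", "data.frame")
  out
}
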