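# Delimited-text interfaces: time series, labels, cohort manifests, run
# configuration, and report writers.

#' Write / read ROI time series as TSV
#'
#' Values: rows = timepoints, columns = ROIs, with a header row of ROI names.
#' Labels (when present) go to a companion TSV with columns
#' `timepoint_index`, `label`.
#'
#' @param series A [ts_data()].
#' @param path Values file path.
#' @param labels_path Optional labels file path.
#' @export
write_ts_data <- function(series, path, labels_path = NULL) {
  stopifnot(inherits(series, "ts_data"))
  vals <- matrix(sprintf("%.17g", series$values), nrow(series$values),
                 dimnames = dimnames(series$values))
  utils::write.table(vals, path, sep = "\t", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  if (!is.null(series$labels) && !is.null(labels_path)) {
    utils::write.table(
      data.frame(timepoint_index = seq_along(series$labels),
                 label = series$labels),
      labels_path, sep = "\t", row.names = FALSE, col.names = TRUE,
      quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_ts_data
#' @param dt Sampling interval to attach on read.
#' @param subject_id Optional subject identifier to attach.
#' @export
read_ts_data <- function(path, dt, labels_path = NULL, subject_id = NULL) {
  vals <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                      check.names = FALSE))
  labels <- NULL
  if (!is.null(labels_path) && file.exists(labels_path)) {
    lab <- utils::read.table(labels_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    labels <- lab$label[order(lab$timepoint_index)]
  }
  ts_data(vals, dt, labels = labels, subject_id = subject_id)
}

#' Write a cohort to a directory with a JSON manifest
#'
#' Each subject's rest run and task runs are written as TSV value/label
#' files; `manifest.json` lists per-subject files and the sampling interval,
#' and is what [read_cohort()] consumes.
#'
#' @param subjects A cohort as produced by [generate_cohort()].
#' @param dir Output directory.
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(subjects, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- lapply(subjects, function(s) {
    sid <- s$subject_id
    rest_file <- file.path(dir, paste0(sid, "_rest.tsv"))
    write_ts_data(s$rest, rest_file)
    tasks <- lapply(names(s$tasks), function(tk) {
      vf <- file.path(dir, sprintf("%s_task_%s.tsv", sid, tk))
      lf <- file.path(dir, sprintf("%s_task_%s_labels.tsv", sid, tk))
      write_ts_data(s$tasks[[tk]], vf, lf)
      list(task = tk, values = basename(vf), labels = basename(lf))
    })
    list(subject_id = sid, dt = s$rest$dt, rest = basename(rest_file),
         tasks = tasks)
  })
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(subjects = manifest), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_cohort
#' @param manifest_path Path to a `manifest.json` written by [write_cohort()].
#' @export
read_cohort <- function(manifest_path) {
  doc <- jsonlite::read_json(manifest_path)
  base <- dirname(manifest_path)
  lapply(doc$subjects, function(s) {
    rest <- read_ts_data(file.path(base, s$rest), dt = s$dt,
                         subject_id = s$subject_id)
    rest$labels <- rep("rest", nrow(rest$values))
    tasks <- lapply(s$tasks, function(tk)
      read_ts_data(file.path(base, tk$values), dt = s$dt,
                   labels_path = file.path(base, tk$labels),
                   subject_id = s$subject_id))
    names(tasks) <- vapply(s$tasks, function(tk) tk$task, "")
    list(rest = rest, tasks = tasks, subject_id = s$subject_id)
  })
}

#' Read a YAML run configuration
#'
#' Keys: `T`, `dt`, `grid_points`, `lambda` (`mode`: `cv` or `fixed`,
#' `value`), `bootstrap` (`k`, `reps`, `seed`), `shrink_target_cond`.
#' Missing keys take package defaults.
#'
#' @param path YAML file path.
#' @return A config list for [run_transition_analysis()].
#' @export
read_run_config <- function(path) {
  .default_config(yaml::read_yaml(path))
}

#' Write a cost report to a directory
#'
#' Emits `costs.tsv` (task, replicate, J_mean, J_cov, J_total, ratio),
#' `input_maps.tsv` (task, roi, I_mean, I_cov, I_total) and `summary.json`
#' (per-task means and SDs plus failure count). Values are stored at full
#' double precision.
#'
#' @param report A [run_transition_analysis()] result.
#' @param dir Output directory.
#' @export
write_cost_report <- function(report, dir) {
  stopifnot(inherits(report, "cost_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$costs, file.path(dir, "costs.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  maps <- do.call(rbind, lapply(names(report$input_maps), function(tk)
    cbind(task = tk, as.data.frame(report$input_maps[[tk]]))))
  utils::write.table(maps, file.path(dir, "input_maps.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(summary = report$summary, n_failures = length(report$failures),
         config = report$config),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(dir)
}
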