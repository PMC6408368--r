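#' Read and validate a pipeline configuration
#'
#' The configuration is a single declarative YAML file; every tolerance the
#' run uses is taken from it (or from the documented defaults echoed into the
#' run log), so reruns are auditable. Structure:
#'
#' ```yaml
#' seed: 1
#' output_dir: results
#' metadata: metadata.csv
#' measurements: measurements.csv   # required only for linear jobs
#' plots: true
#' gpa: {tol: 1.0e-8, max_iter: 100, criterion: bending_energy}
#' blr: {max_prefix: 10, max_iter: 100, tol: 1.0e-8}
#' jobs:
#'   - {name: trochlear, mode: landmark, tps: trochlear.tps,
#'      sliders: trochlear_sliders.txt, scheme: trochlear}
#'   - {name: linear, mode: linear}
#' ```
#'
#' Relative paths are resolved against the config file's directory. Missing
#' input files or unknown schemes are fatal before any job runs.
#'
#' @param path Path to the YAML config.
#' @return A validated config list of class `analysis_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (startsWith(p, "/")) p else file.path(base, p)
  }
  defaults <- list(seed = 1L, output_dir = "locomorph_out", plots = TRUE,
                   gpa = list(), blr = list())
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  gpa_def <- list(tol = 1e-8, max_iter = 100L, criterion = "bending_energy")
  blr_def <- list(max_prefix = 10L, max_iter = 100L, tol = 1e-8)
  for (nm in names(gpa_def)) if (is.null(cfg$gpa[[nm]])) cfg$gpa[[nm]] <- gpa_def[[nm]]
  for (nm in names(blr_def)) if (is.null(cfg$blr[[nm]])) cfg$blr[[nm]] <- blr_def[[nm]]

  if (is.null(cfg$jobs) || length(cfg$jobs) == 0L) stop("config lists no jobs")
  if (is.null(cfg$metadata)) stop("config must name a metadata file")
  cfg$metadata <- resolve(cfg$metadata)
  if (!file.exists(cfg$metadata)) stop("metadata file not found: ", cfg$metadata)
  cfg$measurements <- resolve(cfg$measurements)
  if (!startsWith(cfg$output_dir, "/")) cfg$output_dir <- file.path(base, cfg$output_dir)

  for (i in seq_along(cfg$jobs)) {
    job <- cfg$jobs[[i]]
    if (is.null(job$name)) stop(sprintf("job %d has no name", i))
    job$mode <- if (is.null(job$mode)) "landmark" else job$mode
    if (!job$mode %in% c("landmark", "linear")) {
      stop(sprintf("job '%s': unknown mode '%s'", job$name, job$mode))
    }
    if (job$mode == "landmark") {
      if (is.null(job$tps)) stop(sprintf("job '%s': landmark job needs a tps path", job$name))
      job$tps <- resolve(job$tps)
      if (!file.exists(job$tps)) stop(sprintf("job '%s': tps file not found: %s", job$name, job$tps))
      if (!is.null(job$sliders)) {
        job$sliders <- resolve(job$sliders)
        if (!file.exists(job$sliders)) {
          stop(sprintf("job '%s': slider file not found: %s", job$name, job$sliders))
        }
      }
      if (is.null(job$scheme)) job$scheme <- job$name
      # scheme must be resolvable now, not mid-run
      builtin_scheme(job$scheme)
    } else {
      if (is.null(cfg$measurements)) stop("linear job requires a measurements file in the config")
      if (!file.exists(cfg$measurements)) {
        stop("measurements file not found: ", cfg$measurements)
      }
    }
    cfg$jobs[[i]] <- job
  }
  class(cfg) <- "analysis_config"
  cfg
}

log_line <- function(con, fmt, ...) {
  msg <- sprintf(fmt, ...)
  if (!is.null(con)) writeLines(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg), con)
  invisible(msg)
}

# deterministic fingerprint of an input file for the run log
file_fingerprint <- function(path) {
  sz <- file.info(path)$size
  sprintf("%s (%d bytes, sum %.0f)", basename(path), sz,
          sum(as.integer(readBin(path, "raw", n = min(sz, 1e6)))))
}

search_log_df <- function(search) {
  do.call(rbind, lapply(search$attempts, function(f) {
    data.frame(pcs = paste(range(f$pc_indices), collapse = "-"),
               n_pcs = length(f$pc_indices), converged = f$converged,
               separation = f$separation_detected, aic = f$aic,
               null_deviance = f$null_deviance,
               residual_deviance = f$residual_deviance)
  }))
}

open_plot_device <- function(path_stem) {
  if (isTRUE(unname(capabilities("cairo")))) {
    grDevices::svg(paste0(path_stem, ".svg"), width = 7, height = 6)
  } else {
    grDevices::pdf(paste0(path_stem, ".pdf"), width = 7, height = 6)
  }
}

#' Run one view (or the linear measurement) analysis
#'
#' Landmark jobs: read the TPS file and optional sliders, superimpose by
#' [gpa()], project to tangent space, run [pca_covariance()] and
#' [pc_search()]; write aligned coordinates (TPS), PCA scores (CSV), the
#' search log (CSV), a morphospace plot and PC1/PC2-extreme deformation grids
#' into `output_dir/<job name>/`. Linear jobs: [log10_measurements()] then
#' PCA and the linear-mode search (starting at PC2). The returned report row
#' carries the preferred model's PCs, the cumulative variance fraction of
#' those PCs, AIC, null and residual deviance; a failed search yields status
#' `"no convergent model"` and no predictions.
#'
#' @param job One entry of `config$jobs`.
#' @param config An [read_config()] result (or equivalent list).
#' @return List with `row` (one-row data.frame), `predictions` (data.frame),
#'   `pca`, `search`, and for landmark jobs `aligned`.
#' @export
run_view_analysis <- function(job, config) {
  out_dir <- file.path(config$output_dir, job$name)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(out_dir, "run.log"), "wt")
  on.exit(close(log_con))
  metadata <- read_metadata(config$metadata)
  log_line(log_con, "job '%s' mode=%s", job$name, job$mode)
  log_line(log_con, "metadata: %s", file_fingerprint(config$metadata))
  log_line(log_con, "settings: gpa tol=%g max_iter=%d criterion=%s | blr max_prefix=%d max_iter=%d tol=%g",
           config$gpa$tol, config$gpa$max_iter, config$gpa$criterion,
           config$blr$max_prefix, config$blr$max_iter, config$blr$tol)

  aligned <- NULL
  if (job$mode == "landmark") {
    shapes <- read_tps(job$tps, view = job$scheme)
    log_line(log_con, "tps: %s -> %d shapes", file_fingerprint(job$tps), length(shapes))
    sliders <- NULL
    if (!is.null(job$sliders)) {
      sliders <- read_sliders(job$sliders, n_landmarks = nrow(shapes[[1]]$points))
      log_line(log_con, "sliders: %s -> %d rows", file_fingerprint(job$sliders), nrow(sliders))
    }
    report <- validate_dataset(shapes, metadata, builtin_scheme(job$scheme))
    if (nrow(report$issues)) {
      utils::write.csv(report$issues, file.path(out_dir, "validation_issues.csv"),
                       row.names = FALSE)
      stop(sprintf("job '%s': %d validation issue(s); see validation_issues.csv",
                   job$name, nrow(report$issues)))
    }
    aligned <- gpa(shapes, sliders = sliders, max_iter = config$gpa$max_iter,
                   tol = config$gpa$tol, criterion = config$gpa$criterion)
    log_line(log_con, "gpa: %d iterations, converged=%s", aligned$n_iterations,
             aligned$converged)
    aligned_shapes <- lapply(seq_along(aligned$ids), function(i) {
      specimen_shape(aligned$ids[i], job$scheme, aligned$coords[, , i])
    })
    write_tps(aligned_shapes, file.path(out_dir, "aligned.tps"))
    utils::write.csv(
      data.frame(iteration = seq_along(aligned$objective_trace),
                 procrustes_ss = aligned$objective_trace),
      file.path(out_dir, "gpa_trace.csv"), row.names = FALSE
    )
    dat <- tangent_projection(aligned)
    mode <- "landmark"
  } else {
    mm <- read_measurements(config$measurements)
    log_line(log_con, "measurements: %s -> %d specimens",
             file_fingerprint(config$measurements), nrow(mm))
    dat <- log10_measurements(mm)
    mode <- "linear"
  }

  pca <- pca_covariance(dat)
  utils::write.csv(data.frame(specimen_id = pca$ids, pca$scores),
                   file.path(out_dir, "scores.csv"), row.names = FALSE)
  search <- pc_search(pca, metadata, mode = mode,
                      max_prefix = config$blr$max_prefix,
                      max_iter = config$blr$max_iter, tol = config$blr$tol)
  utils::write.csv(search_log_df(search), file.path(out_dir, "blr_search.csv"),
                   row.names = FALSE)

  if (isTRUE(config$plots)) {
    tryCatch({
      open_plot_device(file.path(out_dir, "morphospace"))
      plot_morphospace(pca, metadata)
      grDevices::dev.off()
      if (mode == "landmark") {
        for (ax in 1:2) {
          open_plot_device(file.path(out_dir, sprintf("deformation_PC%d", ax)))
          graphics::par(mfrow = c(1, 2))
          for (s in range(pca$scores[, ax])) {
            plot(deformation_grid(aligned$mean_shape, pca, ax, s))
          }
          grDevices::dev.off()
        }
      }
    }, error = function(e) {
      log_line(log_con, "plotting skipped: %s", conditionMessage(e))
      while (grDevices::dev.cur() > 1) grDevices::dev.off()
    })
  }

  if (is.null(search$preferred)) {
    log_line(log_con, "search: %s", search$failure_reason)
    row <- data.frame(dataset = job$name, mode = mode,
                      status = search$failure_reason, pcs = NA_character_,
                      n_pcs = NA_integer_, cum_variance_pct = NA_real_,
                      aic = NA_real_, null_deviance = NA_real_,
                      residual_deviance = NA_real_, stringsAsFactors = FALSE)
    preds <- data.frame(dataset = character(), specimen_id = character(),
                        probability = numeric())
  } else {
    pf <- search$preferred
    cumvar <- 100 * sum(pca$variance_fraction[pf$pc_indices])
    log_line(log_con, "search: preferred PCs %s, AIC %.3f",
             paste(range(pf$pc_indices), collapse = "-"), pf$aic)
    row <- data.frame(dataset = job$name, mode = mode, status = "ok",
                      pcs = paste(range(pf$pc_indices), collapse = "-"),
                      n_pcs = length(pf$pc_indices),
                      cum_variance_pct = cumvar, aic = pf$aic,
                      null_deviance = pf$null_deviance,
                      residual_deviance = pf$residual_deviance,
                      stringsAsFactors = FALSE)
    preds <- if (nrow(search$predictions)) {
      cbind(dataset = job$name, search$predictions)
    } else {
      data.frame(dataset = character(), specimen_id = character(),
                 probability = numeric())
    }
    utils::write.csv(search$predictions, file.path(out_dir, "predictions.csv"),
                     row.names = FALSE)
  }
  list(row = row, predictions = preds, pca = pca, search = search,
       aligned = aligned)
}

#' Run every job in a configuration
#'
#' Validates the whole config up front (missing input files are fatal before
#' any job runs), then executes each job; a job-level failure is logged in
#' its report row (`status`) and the remaining jobs continue. Writes
#' `report.csv` (one row per job, fixed column order: dataset, mode, status,
#' pcs, n_pcs, cum_variance_pct, aic, null_deviance, residual_deviance) and
#' `predictions.csv` (long format: dataset, specimen_id, probability, 1 =
#' terrestrial/bipedal saltating) under `output_dir`. Identical config +
#' inputs + seed give identical outputs.
#'
#' @param config Path to a YAML config or an [read_config()] result.
#' @return List of class `pipeline_result`: `report`, `predictions`,
#'   `results` (per-job detail), `n_failed`.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "analysis_config") || is.list(config))
  set.seed(config$seed)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  rows <- list(); preds <- list(); results <- list()
  for (job in config$jobs) {
    res <- tryCatch(run_view_analysis(job, config), error = function(e) e)
    if (inherits(res, "error")) {
      rows[[job$name]] <- data.frame(
        dataset = job$name, mode = job$mode %||% "landmark",
        status = paste("error:", conditionMessage(res)), pcs = NA_character_,
        n_pcs = NA_integer_, cum_variance_pct = NA_real_, aic = NA_real_,
        null_deviance = NA_real_, residual_deviance = NA_real_,
        stringsAsFactors = FALSE
      )
    } else {
      rows[[job$name]] <- res$row
      preds[[job$name]] <- res$predictions
      results[[job$name]] <- res
    }
  }
  report <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  predictions <- if (length(preds)) {
    do.call(rbind, c(preds, list(make.row.names = FALSE)))
  } else {
    data.frame(dataset = character(), specimen_id = character(),
               probability = numeric())
  }
  utils::write.csv(report, file.path(config$output_dir, "report.csv"),
                   row.names = FALSE)
  utils::write.csv(predictions, file.path(config$output_dir, "predictions.csv"),
                   row.names = FALSE)
  structure(
    list(report = report, predictions = predictions, results = results,
         n_failed = sum(startsWith(report$status, "error"))),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d job(s), %d failed\n", nrow(x$report), x$n_failed))
  print(x$report, row.names = FALSE, digits = 4)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
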