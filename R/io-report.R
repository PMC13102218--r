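config_keys <- c("n_values", "J_values", "K_values", "R", "base_seed",
                 "quad_points", "quad_width", "tol", "max_cycles", "D",
                 "correction", "a_scale", "workers", "checkpoint_dir", "preset")

#' Load a study configuration from a YAML file
#'
#' Unspecified fields take the reference-design defaults (full grid,
#' `R = 100`, seed 123, `D = 1.701`). Unknown keys raise an error listing
#' them; out-of-domain values raise a validation error naming the field. An
#' empty file yields the default configuration.
#'
#' @param path Path to a YAML file.
#' @return A [study_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path),
          class = "grmsim_validation_error")
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), config_keys)
  if (length(unknown)) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "grmsim_validation_error")
  }
  do.call(study_config, cfg)
}

#' Write a study configuration to YAML
#'
#' Fields are emitted in a fixed canonical order at full precision, so
#' writing, re-loading and writing again is byte-identical.
#'
#' @param config A [study_config()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  out <- unclass(config)[config_keys]
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Write study result tables and manifest to a directory
#'
#' Emits `per_replication.csv`, `per_condition.csv` and `manifest.json`.
#'
#' @param study A `grm_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_result <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(study$per_replication, file.path(dir, "per_replication.csv"),
            row.names = FALSE)
  write.csv(study$per_condition, file.path(dir, "per_condition.csv"),
            row.names = FALSE)
  jsonlite::write_json(study$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Render a plain-text report of a study
#'
#' One line per condition cell with the metric means, the Fisher-mean
#' correlation and its agreement band, and a flag marking cells whose
#' corrected latent-trait RMSE meets the 0.30 sufficient-accuracy reference
#' (the error level at which about 68% of estimation errors fall within
#' +/- 0.30 under a standard-normal error). A saturation summary of the
#' smallest `J` with diminishing returns is appended when the grid covers
#' at least three `J` values.
#'
#' @param study A `grm_study`.
#' @param rmse_reference Accuracy reference point; default 0.30.
#' @param saturation_tol Tolerance passed to [summarize_saturation()].
#' @return A character vector of report lines, invisibly; also printed.
#' @export
render_report <- function(study, rmse_reference = 0.30, saturation_tol = 0.01) {
  pc <- study$per_condition
  if (nrow(pc) == 0) abort("Empty study result.", class = "grmsim_invalid_request")
  lines <- c(
    "GRM parameter-recovery study",
    sprintf("  cells: %d, replications per cell: %d, base seed: %d",
            nrow(pc), study$config$R, study$config$base_seed),
    "",
    sprintf("%6s %4s %3s | %8s %12s %10s %14s | %7s %-9s %s",
            "n", "J", "K", "rmse_a", "rmse_a_stdF", "rmse_th", "rmse_th_fpc",
            "r_bar", "agreement", "meets_0.30")
  )
  for (i in seq_len(nrow(pc))) {
    row <- pc[i, ]
    if (row$status != "ok") {
      lines <- c(lines, sprintf("%6d %4d %3d | all replications failed",
                                row$n, row$J, row$K))
      next
    }
    lines <- c(lines, sprintf(
      "%6d %4d %3d | %8.3f %12.3f %10.3f %14.3f | %7.3f %-9s %s",
      row$n, row$J, row$K, row$rmse_a, row$rmse_a_std_fpc, row$rmse_theta,
      row$rmse_theta_fpc, row$r_bar, row$agreement,
      ifelse(row$rmse_theta_fpc < rmse_reference, "yes", "no")))
  }
  if (length(unique(pc$J)) >= 3) {
    sat <- summarize_saturation(study, tol = saturation_tol)
    lines <- c(lines, "", "Saturation J (first J with < 0.01 improvement in rmse_theta_fpc):")
    lines <- c(lines, sprintf("  n=%d K=%d: %s", sat$n, sat$K,
                              ifelse(is.na(sat$saturation_J), "none in range",
                                     as.character(sat$saturation_J))))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
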