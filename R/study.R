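#' Configure a parameter-recovery study
#'
#' A study runs the full Cartesian grid of sample sizes, item counts and
#' category counts, with `R` replications per cell. Defaults reproduce the
#' reference design: `n` 500-1500 in steps of 100, `J` 5-50 in steps of 5,
#' `K` 4-7, `R = 100`, base seed 123. A reduced desk-scale preset is
#' available via `preset = "desk"` (R = 20, corner subset of the grid).
#'
#' @param n_values,J_values,K_values Grid values.
#' @param R Replications per condition cell.
#' @param base_seed Base seed for the hierarchical stream derivation.
#' @param quad_points,quad_width Quadrature settings (see
#'   [make_quadrature()]).
#' @param tol,max_cycles EM settings (see [fit_grm()]).
#' @param D Scaling constant.
#' @param correction `"sqrt"` or `"raw"` finite-population-correction form.
#' @param a_scale Scale for discrimination RMSE, `"slope"` (default) or
#'   `"classic"`; see [replication_metrics()].
#' @param workers Parallel workers for [run_grid()] (forked, condition cells
#'   only; replications stay serial within a cell so random streams never
#'   interleave).
#' @param checkpoint_dir Optional directory for per-cell checkpoints.
#' @param preset `"paper"` (full grid defaults) or `"desk"` (reduced scale).
#' @return A list of class `study_config`.
#' @examples
#' study_config(n_values = 500, J_values = 10, K_values = 5, R = 2)
#' @export
study_config <- function(n_values = seq(500L, 1500L, by = 100L),
                         J_values = seq(5L, 50L, by = 5L),
                         K_values = 4:7,
                         R = 100L, base_seed = 123L,
                         quad_points = 61L, quad_width = 6,
                         tol = 1e-4, max_cycles = 500L, D = 1.701,
                         correction = "sqrt", a_scale = "slope", workers = 1L,
                         checkpoint_dir = NULL,
                         preset = c("paper", "desk")) {
  preset <- match.arg(preset)
  if (preset == "desk" && missing(n_values) && missing(J_values) &&
      missing(K_values) && missing(R)) {
    n_values <- c(500L, 1500L)
    J_values <- c(10L, 50L)
    K_values <- c(4L, 7L)
    R <- 20L
  }
  check_pos <- function(x, nm, lo) {
    if (length(x) < 1 || any(!is.finite(x)) || any(x < lo)) {
      abort(sprintf("Invalid `%s`: values must be >= %d.", nm, lo),
            class = "grmsim_validation_error")
    }
  }
  check_pos(n_values, "n_values", 1L)
  check_pos(J_values, "J_values", 2L)
  check_pos(K_values, "K_values", 2L)
  check_pos(R, "R", 1L)
  if (!correction %in% c("sqrt", "raw")) {
    abort("Invalid `correction`: must be \"sqrt\" or \"raw\".",
          class = "grmsim_validation_error")
  }
  if (!a_scale %in% c("slope", "classic")) {
    abort("Invalid `a_scale`: must be \"slope\" or \"classic\".",
          class = "grmsim_validation_error")
  }
  structure(
    list(n_values = as.integer(sort(n_values)),
         J_values = as.integer(sort(J_values)),
         K_values = as.integer(sort(K_values)),
         R = as.integer(R), base_seed = as.integer(base_seed),
         quad_points = as.integer(quad_points), quad_width = as.numeric(quad_width),
         tol = as.numeric(tol), max_cycles = as.integer(max_cycles),
         D = as.numeric(D), correction = correction, a_scale = a_scale,
         workers = as.integer(workers), checkpoint_dir = checkpoint_dir,
         preset = preset),
    class = "study_config"
  )
}

na_metrics_row <- function() {
  tibble::tibble(rmse_a = NA_real_, fpc_a = NA_real_, rmse_a_fpc = NA_real_,
                 rmse_a_std = NA_real_, rmse_a_std_fpc = NA_real_,
                 rmse_theta = NA_real_, fpc_theta = NA_real_,
                 rmse_theta_fpc = NA_real_, r = NA_real_,
                 converged = NA, n_warnings = NA_integer_)
}

#' Run one replication of a condition
#'
#' Draws a sample from the condition's fixed population, fits the GRM by
#' MML-EM, scores respondents by EAP (inside the fit) and computes the full
#' metric set. Deterministic given `(base_seed, n, J, K, rep_index)`.
#' Degenerate-sample fitting errors are caught and recorded as a failed
#' replication rather than raised.
#'
#' @param pop A [generate_population()] result.
#' @param rep_index Replication index (1-based).
#' @param config A [study_config()].
#' @return A one-row tibble keyed by `(n, J, K, rep)` with `status`,
#'   `reason`, and the metric columns.
#' @export
run_replication <- function(pop, rep_index, config = study_config()) {
  cond <- pop$condition
  quad <- make_quadrature(config$quad_points, config$quad_width)
  s <- draw_sample(pop, rep_index = rep_index)
  res <- tryCatch({
    fit <- fit_grm(s$responses, K = cond$K, quad = quad, tol = config$tol,
                   max_cycles = config$max_cycles, D = config$D)
    list(metrics = replication_metrics(fit, s$theta_true, pop$bank$a,
                                       pop$N_pop, config$correction,
                                       config$a_scale),
         status = "ok", reason = NA_character_)
  }, grmsim_degenerate_item = function(e) {
    list(metrics = na_metrics_row(), status = "failed",
         reason = conditionMessage(e))
  })
  dplyr::bind_cols(
    tibble::tibble(n = cond$n, J = cond$J, K = cond$K, rep = as.integer(rep_index),
                   status = res$status, reason = res$reason),
    res$metrics
  )
}

metric_cols <- c("rmse_a", "fpc_a", "rmse_a_fpc", "rmse_a_std",
                 "rmse_a_std_fpc", "rmse_theta", "fpc_theta",
                 "rmse_theta_fpc", "r")

aggregate_condition <- function(per_rep) {
  ok <- dplyr::filter(per_rep, .data$status == "ok")
  base <- dplyr::distinct(per_rep, .data$n, .data$J, .data$K)
  base$R <- nrow(per_rep)
  base$n_ok <- nrow(ok)
  base$conv_rate <- if (nrow(ok)) mean(ok$converged) else NA_real_
  base$status <- if (nrow(ok)) "ok" else "failed"
  if (nrow(ok)) {
    means <- dplyr::summarise(ok, dplyr::across(dplyr::all_of(metric_cols), mean))
    base <- dplyr::bind_cols(base, means)
    base$r_bar <- fisher_mean_r(ok$r)
  } else {
    base <- dplyr::bind_cols(base, dplyr::summarise(
      per_rep, dplyr::across(dplyr::all_of(metric_cols), ~NA_real_)))
    base$r_bar <- NA_real_
  }
  base$agreement <- classify_agreement(base$r_bar)
  base
}

#' Run all replications of one condition cell
#'
#' Builds the condition's population once, executes the `R` replications
#' serially, and aggregates: arithmetic means across replications for the
#' RMSE metrics and the Fisher-z mean for the correlation. Non-converged
#' replications are retained in the aggregates (flagged via `conv_rate`);
#' failed replications are excluded from means but counted.
#'
#' @param condition A [grm_condition()].
#' @param config A [study_config()].
#' @return A list with tibbles `per_replication` (R rows) and
#'   `per_condition` (one row, including `r_bar` and its agreement label).
#' @examples
#' cfg <- study_config(R = 2, max_cycles = 50)
#' run_condition(grm_condition(100, 5, 4, R = 2), cfg)$per_condition
#' @export
run_condition <- function(condition, config = study_config()) {
  pop <- generate_population(condition, D = config$D)
  per_rep <- purrr::map_dfr(seq_len(condition$R),
                            ~run_replication(pop, .x, config))
  list(per_replication = per_rep, per_condition = aggregate_condition(per_rep))
}

#' Run the full condition grid of a study
#'
#' Iterates the Cartesian grid of the configured `n`, `J` and `K` values,
#' optionally in parallel over condition cells (forked workers). Results are
#' identical regardless of worker count because every random stream is
#' derived from the cell coordinates, never from execution order. When a
#' checkpoint directory is set, each finished cell is written to disk and
#' re-used on resume.
#'
#' @param config A [study_config()].
#' @param progress Emit a progress line per condition cell.
#' @return An object of class `grm_study`: tibbles `per_replication` and
#'   `per_condition`, the `config`, and a run `manifest` (grid dimensions,
#'   seed, per-cell status, package version, timestamps).
#' @examples
#' cfg <- study_config(n_values = 100, J_values = 5, K_values = 4, R = 2)
#' study <- run_grid(cfg, progress = FALSE)
#' study$per_condition
#' @export
run_grid <- function(config = study_config(), progress = TRUE) {
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  cells <- tidyr::expand_grid(n = config$n_values, J = config$J_values,
                              K = config$K_values)
  run_cell <- function(i) {
    cell <- cells[i, ]
    ckpt <- NULL
    if (!is.null(config$checkpoint_dir)) {
      ckpt <- file.path(config$checkpoint_dir,
                        sprintf("cell_n%d_J%d_K%d.csv", cell$n, cell$J, cell$K))
    }
    if (!is.null(ckpt) && file.exists(ckpt)) {
      per_rep <- tibble::as_tibble(read.csv(ckpt))
      per_rep$reason <- as.character(per_rep$reason)
      return(list(per_replication = per_rep,
                  per_condition = aggregate_condition(per_rep)))
    }
    res <- run_condition(grm_condition(cell$n, cell$J, cell$K, R = config$R,
                                       base_seed = config$base_seed),
                         config)
    if (!is.null(ckpt)) {
      dir.create(dirname(ckpt), showWarnings = FALSE, recursive = TRUE)
      write.csv(res$per_replication, ckpt, row.names = FALSE)
    }
    if (progress) {
      message(sprintf("condition n=%d J=%d K=%d done (%d/%d ok)",
                      cell$n, cell$J, cell$K,
                      res$per_condition$n_ok, config$R))
    }
    res
  }
  results <- if (config$workers > 1L &&
                 requireNamespace("parallel", quietly = TRUE) &&
                 .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(nrow(cells)), run_cell,
                       mc.cores = config$workers)
  } else {
    lapply(seq_len(nrow(cells)), run_cell)
  }
  per_rep <- purrr::map_dfr(results, "per_replication")
  per_cond <- purrr::map_dfr(results, "per_condition")
  manifest <- list(
    base_seed = config$base_seed,
    grid = list(n_values = config$n_values, J_values = config$J_values,
                K_values = config$K_values, R = config$R),
    n_cells = nrow(cells),
    cell_status = per_cond[c("n", "J", "K", "status")],
    package_version = as.character(packageVersion("grmsim")),
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  structure(list(per_replication = per_rep, per_condition = per_cond,
                 config = config, manifest = manifest),
            class = "grm_study")
}

#' Smallest item count beyond which a metric stops improving
#'
#' For each `(n, K)` pair, scans the condition means of a metric across
#' ascending `J` and reports the first `J` at which the improvement over the
#' previous `J` falls below `tol` — the point of diminishing returns from
#' adding items. `NA` means the metric was still improving by more than
#' `tol` at the largest `J` tested.
#'
#' @param study A `grm_study` (or a per-condition tibble).
#' @param metric Name of a per-condition metric column; default
#'   `"rmse_theta_fpc"`.
#' @param tol Absolute improvement threshold; default 0.01.
#' @return A tibble with columns `n`, `K`, `saturation_J`.
#' @export
summarize_saturation <- function(study, metric = "rmse_theta_fpc", tol = 0.01) {
  pc <- if (inherits(study, "grm_study")) study$per_condition else study
  if (length(unique(pc$J)) < 3) {
    abort("Saturation needs at least 3 distinct J values.",
          class = "grmsim_invalid_request")
  }
  if (!metric %in% names(pc)) {
    abort(sprintf("Unknown metric `%s`.", metric), class = "grmsim_invalid_request")
  }
  pc |>
    dplyr::group_by(.data$n, .data$K) |>
    dplyr::arrange(.data$J, .by_group = TRUE) |>
    dplyr::summarise(saturation_J = {
      v <- .data[[metric]]
      imp <- -diff(v)
      hit <- which(imp < tol)
      if (length(hit)) .data$J[hit[1] + 1L] else NA_integer_
    }, .groups = "drop")
}

#' @export
print.grm_study <- function(x, ...) {
  cat(sprintf("GRM recovery study: %d condition cells x %d replications\n",
              nrow(x$per_condition), x$config$R))
  print(x$per_condition)
  invisible(x)
}

#' Per-condition summary table of a study
#'
#' @param x A `grm_study`.
#' @param ... Unused.
#' @return The per-condition tibble (one row per grid cell).
#' @export
tidy.grm_study <- function(x, ...) x$per_condition

#' One-row summary of a study run
#'
#' @param x A `grm_study`.
#' @param ... Unused.
#' @return A tibble with cell counts, total replications, overall
#'   convergence rate and the range of the Fisher-mean correlations.
#' @export
glance.grm_study <- function(x, ...) {
  ok <- dplyr::filter(x$per_replication, .data$status == "ok")
  tibble::tibble(
    n_cells = nrow(x$per_condition),
    n_replications = nrow(x$per_replication),
    n_failed = sum(x$per_replication$status != "ok"),
    conv_rate = if (nrow(ok)) mean(ok$converged) else NA_real_,
    min_r_bar = suppressWarnings(min(x$per_condition$r_bar, na.rm = TRUE)),
    max_r_bar = suppressWarnings(max(x$per_condition$r_bar, na.rm = TRUE))
  )
}
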