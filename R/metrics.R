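#' Recovery metrics for discrimination and latent-trait estimates
#'
#' Root-mean-squared error between estimated and true parameter vectors,
#' finite-population corrections, range-standardized RMSE, Pearson
#' correlation, and Fisher-z averaging of correlations across replications.
#'
#' The finite-population corrections address two different finiteness
#' effects: `fpc_a()` corrects the item-level RMSE for the small number of
#' items `J` (factor `sqrt(J / (J - 1))`, > 1), while `fpc_theta()` corrects
#' the person-level RMSE for sampling a non-negligible fraction of a finite
#' latent-trait pool (factor `sqrt(1 - n / N_pop)`, <= 1). Both are also
#' available without the square root via `correction = "raw"`.
#'
#' @param a_hat,a_true Estimated and true discriminations (equal length).
#' @param theta_hat,theta_true Estimated and true latent traits (equal length).
#' @param J Item count (>= 2).
#' @param n,N_pop Sample and population sizes, `1 <= n <= N_pop`.
#' @param rmse An RMSE value to standardize or correct.
#' @param correction `"sqrt"` (default) or `"raw"` form of the correction
#'   factor.
#' @return A single numeric value.
#' @examples
#' rmse_a(c(1.0, 2.0), c(1.3, 1.6)) # sqrt(0.125)
#' fpc_a(10)                        # sqrt(10/9)
#' fpc_theta(500, 500000)           # sqrt(0.999)
#' @name recovery-metrics
NULL

#' @rdname recovery-metrics
#' @export
rmse_a <- function(a_hat, a_true) {
  if (length(a_hat) != length(a_true) || length(a_hat) < 1) {
    abort("`a_hat` and `a_true` must be non-empty and of equal length.",
          class = "grmsim_invalid_argument")
  }
  sqrt(mean((a_hat - a_true)^2))
}

#' @rdname recovery-metrics
#' @export
fpc_a <- function(J, correction = c("sqrt", "raw")) {
  correction <- match.arg(correction)
  if (J < 2) abort("`J` must be at least 2.", class = "grmsim_invalid_argument")
  f <- J / (J - 1)
  if (correction == "sqrt") sqrt(f) else f
}

#' @rdname recovery-metrics
#' @export
rmse_a_standardized <- function(rmse, a_hat) {
  rng <- max(a_hat) - min(a_hat)
  if (length(a_hat) < 2 || rng <= 0) {
    abort("Standardization undefined: `a_hat` has zero range.",
          class = "grmsim_undefined_standardization")
  }
  rmse / rng
}

#' @rdname recovery-metrics
#' @export
rmse_theta <- function(theta_hat, theta_true) {
  if (length(theta_hat) != length(theta_true) || length(theta_hat) < 1) {
    abort("`theta_hat` and `theta_true` must be non-empty and of equal length.",
          class = "grmsim_invalid_argument")
  }
  sqrt(mean((theta_hat - theta_true)^2))
}

#' @rdname recovery-metrics
#' @export
fpc_theta <- function(n, N_pop, correction = c("sqrt", "raw")) {
  correction <- match.arg(correction)
  if (n < 1 || n > N_pop) {
    abort("Need 1 <= n <= N_pop.", class = "grmsim_invalid_argument")
  }
  f <- 1 - n / N_pop
  if (correction == "sqrt") sqrt(f) else f
}

#' @rdname recovery-metrics
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("Need at least 3 paired observations.", class = "grmsim_invalid_argument")
  }
  if (var(x) == 0 || var(y) == 0) {
    abort("Correlation undefined for a constant vector.",
          class = "grmsim_undefined_correlation")
  }
  cor(x, y)
}

#' Fisher-z averaged correlation across replications
#'
#' Applies the variance-stabilizing transformation `z = artanh(r)`, averages,
#' and back-transforms: `tanh(mean(artanh(r)))`. All correlations must be
#' strictly inside (-1, 1).
#'
#' @param rs Vector of per-replication correlations.
#' @return The averaged correlation.
#' @examples
#' fisher_mean_r(c(0.5, 0.9))
#' @export
fisher_mean_r <- function(rs) {
  if (length(rs) < 1) {
    abort("`rs` must be non-empty.", class = "grmsim_invalid_argument")
  }
  if (any(abs(rs) >= 1)) {
    abort("Correlations of |r| = 1 have infinite Fisher z.",
          class = "grmsim_infinite_z")
  }
  tanh(mean(atanh(rs)))
}

#' Classify an averaged correlation against agreement benchmarks
#'
#' Cohen-style bands: above `high` is "high" agreement, between `low` and
#' `high` (inclusive) "moderate", below `low` "low". The upper boundary is
#' strict: exactly 0.70 is "moderate".
#'
#' @param r_bar Averaged correlation in `[-1, 1]`.
#' @param high,low Band cutpoints; defaults 0.70 and 0.50.
#' @return One of `"high"`, `"moderate"`, `"low"` (vectorized over `r_bar`).
#' @examples
#' classify_agreement(c(0.75, 0.60, 0.30))
#' @export
classify_agreement <- function(r_bar, high = 0.70, low = 0.50) {
  ifelse(r_bar > high, "high", ifelse(r_bar >= low, "moderate", "low"))
}

#' Per-replication recovery metrics from a fitted model
#'
#' Computes the full metric set for one replication: RMSE of discrimination
#' on the classic scale, its item-count correction and range standardization,
#' RMSE of the EAP trait estimates with the sampling-fraction correction, and
#' the Pearson correlation between true and estimated traits.
#'
#' Discrimination recovery is evaluated on the logistic slope metric by
#' default (`a_scale = "slope"`: estimated slope `a1_hat` against the true
#' slope `D * a_true`) — the metric on which estimation is performed and on
#' which IRT software reports slopes. `a_scale = "classic"` divides both
#' sides by `D`. The range-standardized RMSE is identical under either
#' choice.
#'
#' @param fit A `grm_fit`.
#' @param theta_true True latent traits of the sampled respondents.
#' @param a_true True discriminations (classic scale).
#' @param N_pop Population size behind the sample.
#' @param correction Correction form passed to [fpc_a()] and [fpc_theta()].
#' @param a_scale Scale on which discrimination RMSE is computed: `"slope"`
#'   (default) or `"classic"`.
#' @return A one-row tibble with columns `rmse_a`, `fpc_a`, `rmse_a_fpc`,
#'   `rmse_a_std`, `rmse_a_std_fpc`, `rmse_theta`, `fpc_theta`,
#'   `rmse_theta_fpc`, `r`, `converged`, `n_warnings`.
#' @export
replication_metrics <- function(fit, theta_true, a_true, N_pop,
                                correction = "sqrt",
                                a_scale = c("slope", "classic")) {
  a_scale <- match.arg(a_scale)
  if (a_scale == "slope") {
    ra <- rmse_a(fit$a1_hat, fit$D * a_true)
    rs <- rmse_a_standardized(ra, fit$a1_hat)
  } else {
    ra <- rmse_a(fit$a_hat, a_true)
    rs <- rmse_a_standardized(ra, fit$a_hat)
  }
  fa <- fpc_a(fit$J, correction)
  rt <- rmse_theta(fit$theta_eap, theta_true)
  ft <- fpc_theta(fit$n, N_pop, correction)
  tibble::tibble(
    rmse_a = ra, fpc_a = fa, rmse_a_fpc = ra * fa,
    rmse_a_std = rs, rmse_a_std_fpc = rs * fa,
    rmse_theta = rt, fpc_theta = ft, rmse_theta_fpc = rt * ft,
    r = pearson_r(fit$theta_eap, theta_true),
    converged = fit$converged, n_warnings = length(fit$warnings)
  )
}
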