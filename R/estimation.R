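#' Fixed-grid quadrature over the latent trait
#'
#' Equally spaced nodes on `[-half_width, half_width]` with weights
#' proportional to the standard-normal density, renormalized to sum to one.
#' This discretized N(0, 1) prior is used both for marginalizing the latent
#' trait in the EM algorithm and for EAP scoring.
#'
#' @param n_points Number of nodes (>= 11); default 61.
#' @param half_width Half-width of the grid in theta units; default 6.
#' @return A tibble of class `quadrature` with columns `node` and `weight`.
#' @examples
#' q <- make_quadrature()
#' sum(q$weight)
#' @export
make_quadrature <- function(n_points = 61L, half_width = 6) {
  if (n_points < 11 || half_width <= 0) {
    abort("Need `n_points` >= 11 and `half_width` > 0.",
          class = "grmsim_invalid_argument")
  }
  nodes <- seq(-half_width, half_width, length.out = n_points)
  w <- dnorm(nodes)
  out <- tibble::tibble(node = nodes, weight = w / sum(w))
  class(out) <- c("quadrature", class(out))
  out
}

# Log category probabilities at the quadrature nodes for every item, as the
# Q x K x J cube the C++ E-step consumes. Probabilities are clipped at 1e-300
# so pattern log-likelihoods stay finite at extreme nodes.
build_logP <- function(a1, d, nodes) {
  J <- length(a1)
  K <- ncol(d) + 1L
  out <- array(0, c(length(nodes), K, J))
  for (j in seq_len(J)) {
    out[, , j] <- log(pmax(category_prob_internal(nodes, a1[j], d[j, ]), 1e-300))
  }
  out
}

# eta = (log a1, d_1, log successive gaps of d): the ordered parametrization
# used by the M-step, which keeps the implied category locations ascending by
# construction.
eta_to_par <- function(eta, K) {
  a1 <- exp(eta[1])
  if (K == 2L) {
    d <- eta[2]
  } else {
    d <- eta[2] - cumsum(c(0, exp(eta[3:K])))
  }
  list(a1 = a1, d = d)
}

par_to_eta <- function(a1, d) {
  K <- length(d) + 1L
  if (K == 2L) return(c(log(a1), d))
  gaps <- pmax(-diff(d), 1e-8)
  c(log(a1), d[1], log(gaps))
}

# Vectorized conversions for the concatenated eta of all items (K entries
# per item, columns of a K x J matrix).
etas_to_pars <- function(eta, J, K) {
  em <- matrix(eta, nrow = K)
  a1 <- exp(em[1, ])
  if (K == 2L) {
    d <- matrix(em[2, ], J, 1L)
  } else {
    d <- t(apply(em, 2, function(e) e[2] - cumsum(c(0, exp(e[3:K])))))
  }
  list(a1 = a1, d = d)
}

pars_to_etas <- function(a1, d) {
  K <- ncol(d) + 1L
  as.numeric(vapply(seq_along(a1),
                    function(j) par_to_eta(a1[j], d[j, ]), numeric(K)))
}

# Expected complete-data negative log-likelihood over all items (block
# separable); evaluation and gradient are computed in C++.
mstep_fn <- function(eta, counts, nodes, K) {
  grm_mstep_eval(eta, counts, nodes, K)$value
}

mstep_gr <- function(eta, counts, nodes, K) {
  grm_mstep_eval(eta, counts, nodes, K)$gradient
}

# Starting intercepts from the inverse logit of the observed cumulative
# category proportions (the theta = 0 cross-section), floored away from 0/1
# and forced strictly decreasing.
start_intercepts <- function(responses, K) {
  n <- nrow(responses)
  J <- ncol(responses)
  d0 <- matrix(0, J, K - 1L)
  for (j in seq_len(J)) {
    pstar <- vapply(seq_len(K - 1L), function(t) mean(responses[, j] >= t),
                    numeric(1))
    pstar <- pmin(pmax(pstar, 1 / (2 * n)), 1 - 1 / (2 * n))
    d <- qlogis(pstar)
    for (t in seq_along(d)[-1]) d[t] <- min(d[t], d[t - 1] - 1e-3)
    d0[j, ] <- d
  }
  d0
}

#' Fit the graded response model by marginal maximum likelihood EM
#'
#' Fits a unidimensional GRM with a fixed `N(0, 1)` latent distribution. The
#' E-step accumulates each respondent's posterior mass over the quadrature
#' nodes; the M-step maximizes, item by item, the expected complete-data
#' log-likelihood over `(log a1, d_1, log gaps of d)` so the implied category
#' locations stay ordered. Cycles stop when the largest absolute change in
#' any item parameter falls below `tol` or at `max_cycles` (the model is then
#' returned with `converged = FALSE`, not an error). EAP trait estimates and
#' posterior standard deviations are computed at the final parameters.
#'
#' Internally the logistic slope is `a1 = D * a`; estimates are reported on
#' both scales (`a_hat = a1_hat / D`) with implied locations
#' `b_hat = -d_hat / a1_hat`.
#'
#' @param responses Integer matrix or data frame (`n x J`) of 0-based
#'   categories. At least 50 respondents are required.
#' @param K Number of categories; defaults to `max(responses) + 1`.
#' @param quad A [make_quadrature()] grid.
#' @param tol Convergence threshold on the maximum absolute parameter change;
#'   default 1e-4.
#' @param max_cycles Maximum EM cycles; default 500.
#' @param D Scaling constant used to report the classic discrimination scale.
#' @param d_bound Absolute bound on intercepts, applied when a sample leaves
#'   categories unobserved; default 30 (a warning is recorded on the fit).
#' @return An object of class `grm_fit`: estimated parameters (`a1_hat`,
#'   `a_hat`, `d_hat`, `b_hat`), `theta_eap` and `theta_psd`, the marginal
#'   log-likelihood trace, cycle count, convergence flag and recorded
#'   warnings.
#' @examples
#' bank <- item_bank(a = c(1, 1.5, 2), b = rbind(c(-1, 1), c(0, 0.5), c(-0.5, 0)))
#' set.seed(7)
#' resp <- simulate_responses(rnorm(300), bank)
#' fit <- fit_grm(resp, K = 3)
#' glance(fit)
#' @export
fit_grm <- function(responses, K = NULL, quad = make_quadrature(),
                    tol = 1e-4, max_cycles = 500L, D = 1.701, d_bound = 30) {
  responses <- as.matrix(responses)
  storage.mode(responses) <- "integer"
  n <- nrow(responses)
  J <- ncol(responses)
  if (n < 50) {
    abort("At least 50 respondents are required.", class = "grmsim_invalid_argument")
  }
  if (is.null(K)) K <- max(responses) + 1L
  if (K < 2 || any(responses < 0) || any(responses >= K)) {
    abort("Responses must be integers in 0..K-1 with K >= 2.",
          class = "grmsim_invalid_argument")
  }
  degenerate <- which(apply(responses, 2, function(x) length(unique(x))) == 1L)
  if (length(degenerate)) {
    abort(paste0("Degenerate item(s) with a single observed category: ",
                 paste(degenerate, collapse = ", ")),
          class = "grmsim_degenerate_item")
  }

  nodes <- quad$node
  logw <- log(quad$weight)
  a1 <- rep(1.701, J)
  d <- start_intercepts(responses, K)
  warnings <- character(0)

  # items where some category is unobserved: intercepts are bounded there
  obs <- apply(responses, 2, function(x) tabulate(x + 1L, K))
  partial <- which(apply(obs, 2, function(ct) any(ct == 0L)))
  if (length(partial)) {
    warnings <- c(warnings, paste0("unobserved categories in item(s): ",
                                   paste(partial, collapse = ", ")))
  }

  loglik_trace <- numeric(0)
  converged <- FALSE
  cycle <- 0L
  eta <- pars_to_etas(a1, d)
  safe_eta <- eta
  prev_step <- NULL
  accelerated <- FALSE
  last_ll <- -Inf

  # EM with safeguarded extrapolation: each cycle takes the plain EM step
  # (E-step + one joint quasi-Newton M-step), then extrapolates along the
  # step direction with a Ramsay-style multiplier estimated from the linear
  # convergence rate. If an extrapolated point ever lowers the marginal
  # log-likelihood, the iteration falls back to the last plain EM point, so
  # the recorded trace is nondecreasing.
  while (cycle < max_cycles) {
    cycle <- cycle + 1L
    es <- grm_estep_cpp(responses, build_logP(a1, d, nodes), logw)
    if (accelerated && es$loglik < last_ll - 1e-10) {
      eta <- safe_eta
      pd <- etas_to_pars(eta, J, K)
      a1 <- pd$a1
      d <- pd$d
      prev_step <- NULL
      accelerated <- FALSE
      es <- grm_estep_cpp(responses, build_logP(a1, d, nodes), logw)
    }
    last_ll <- es$loglik
    loglik_trace <- c(loglik_trace, es$loglik)

    eta_em <- grm_mstep_opt(eta, es$counts, nodes, K)
    pd <- etas_to_pars(eta_em, J, K)
    if (any(abs(pd$d) > d_bound)) {
      pd$d <- pmin(pmax(pd$d, -d_bound), d_bound)
      eta_cl <- pars_to_etas(pd$a1, pd$d)
      # keep the bound without ever decreasing the expected log-likelihood
      if (mstep_fn(eta_cl, es$counts, nodes, K) <=
          mstep_fn(eta, es$counts, nodes, K)) {
        eta_em <- eta_cl
      } else {
        eta_em <- eta
      }
      pd <- etas_to_pars(eta_em, J, K)
      if (!any(grepl("intercepts bounded", warnings))) {
        warnings <- c(warnings, sprintf("intercepts bounded at |d| <= %g", d_bound))
      }
    }

    delta <- max(abs(c(pd$a1 - a1, pd$d - d)))
    if (delta < tol) {
      a1 <- pd$a1
      d <- pd$d
      converged <- TRUE
      break
    }

    step <- eta_em - eta
    mult <- 0
    if (!is.null(prev_step)) {
      rate <- sqrt(sum(step^2) / sum(prev_step^2))
      if (is.finite(rate) && rate > 0.01 && rate < 1) {
        mult <- min(rate / (1 - rate), 4)
      }
    }
    prev_step <- step
    safe_eta <- eta_em
    eta <- eta_em + mult * step
    accelerated <- mult > 0
    pd2 <- etas_to_pars(eta, J, K)
    a1 <- pd2$a1
    d <- pd2$d
  }

  if (!converged) {
    pd <- etas_to_pars(safe_eta, J, K)
    a1 <- pd$a1
    d <- pd$d
  }

  es <- grm_estep_cpp(responses, build_logP(a1, d, nodes), logw)
  eap <- drop(es$post %*% nodes)
  psd <- sqrt(pmax(drop(es$post %*% nodes^2) - eap^2, 0))

  structure(
    list(a1_hat = a1, a_hat = a1 / D, d_hat = d, b_hat = -d / a1,
         theta_eap = eap, theta_psd = psd,
         loglik_trace = loglik_trace, loglik = es$loglik,
         n_cycles = cycle, converged = converged, warnings = warnings,
         n = n, J = J, K = K, D = D, quad = quad),
    class = "grm_fit"
  )
}

#' EAP latent-trait scores for a response matrix
#'
#' Expected a posteriori estimates under a discretized `N(0, 1)` prior:
#' `theta_eap[i]` is the posterior mean of the quadrature nodes weighted by
#' the respondent's response-pattern likelihood, and `theta_psd` the matching
#' posterior standard deviation. Likelihood contributions are clipped at
#' 1e-300 so a score is always defined.
#'
#' @param responses Integer matrix (`n x J`) of 0-based categories.
#' @param params A `grm_fit` or an [item_bank()] supplying item parameters.
#' @param quad A [make_quadrature()] grid.
#' @return A tibble with columns `theta_eap` and `theta_psd`.
#' @examples
#' bank <- item_bank(a = c(1, 2), b = rbind(c(-1, 0, 1), c(-0.5, 0, 0.5)))
#' eap_scores(rbind(c(0L, 0L), c(3L, 3L)), bank)
#' @export
eap_scores <- function(responses, params, quad = make_quadrature()) {
  responses <- as.matrix(responses)
  storage.mode(responses) <- "integer"
  if (inherits(params, "grm_fit")) {
    a1 <- params$a1_hat
    d <- params$d_hat
  } else if (inherits(params, "item_bank")) {
    a1 <- attr(params, "D") * params$a
    d <- bank_d(params)
  } else {
    abort("`params` must be a `grm_fit` or an `item_bank`.",
          class = "grmsim_invalid_argument")
  }
  if (ncol(responses) != length(a1)) {
    abort("`responses` has a different item count than `params`.",
          class = "grmsim_invalid_argument")
  }
  es <- grm_estep_cpp(responses, build_logP(a1, d, quad$node), log(quad$weight))
  eap <- drop(es$post %*% quad$node)
  tibble::tibble(theta_eap = eap,
                 theta_psd = sqrt(pmax(drop(es$post %*% quad$node^2) - eap^2, 0)))
}

#' @export
print.grm_fit <- function(x, ...) {
  cat(sprintf("GRM fit: %d items, %d categories, n = %d\n", x$J, x$K, x$n))
  cat(sprintf("  EM cycles: %d (%s), marginal logLik = %.3f\n", x$n_cycles,
              if (x$converged) "converged" else "NOT converged", x$loglik))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Tidy item-parameter estimates of a GRM fit
#'
#' @param x A `grm_fit`.
#' @param ... Unused.
#' @return A tibble with one row per item and parameter: columns `item`,
#'   `term` (`a`, `b_1`, ..., `d_1`, ...) and `estimate` (classic scale for
#'   `a`).
#' @export
tidy.grm_fit <- function(x, ...) {
  K <- x$K
  est <- cbind(a = x$a_hat, x$b_hat, x$d_hat)
  colnames(est) <- c("a", paste0("b_", seq_len(K - 1L)), paste0("d_", seq_len(K - 1L)))
  tibble::tibble(item = rep(seq_len(x$J), times = ncol(est)),
                 term = rep(colnames(est), each = x$J),
                 estimate = as.numeric(est)) |>
    dplyr::arrange(.data$item, .data$term)
}

#' One-row summary of a GRM fit
#'
#' @param x A `grm_fit`.
#' @param ... Unused.
#' @return A tibble with log-likelihood, cycle count, convergence flag and
#'   the design dimensions.
#' @export
glance.grm_fit <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, n_cycles = x$n_cycles,
                 converged = x$converged, n = x$n, J = x$J, K = x$K,
                 n_warnings = length(x$warnings))
}
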