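#' Plot condition-level recovery trends of a study
#'
#' Line plot of a per-condition metric against sample size, coloured by item
#' count and faceted by category count — the standard view of how design
#' factors trade off against recovery accuracy.
#'
#' @param object A `grm_study`.
#' @param metric Per-condition metric column to plot; default `"rmse_a"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.grm_study <- function(object, metric = "rmse_a", ...) {
  pc <- dplyr::filter(object$per_condition, .data$status == "ok")
  ggplot2::ggplot(pc, ggplot2::aes(x = .data$n, y = .data[[metric]],
                                   colour = factor(.data$J),
                                   group = factor(.data$J))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$K), labeller = ggplot2::label_both) +
    ggplot2::labs(x = "sample size n", y = metric, colour = "J")
}

#' Plot category response curves of a fitted model
#'
#' Category probability curves over the latent trait for a subset of items,
#' computed from the fitted slope-intercept parameters.
#'
#' @param object A `grm_fit`.
#' @param items Item indices to draw; defaults to the first four.
#' @param theta_range Range of the latent-trait axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.grm_fit <- function(object, items = seq_len(min(4L, object$J)),
                             theta_range = c(-4, 4), ...) {
  theta <- seq(theta_range[1], theta_range[2], length.out = 101)
  df <- purrr::map_dfr(items, function(j) {
    P <- category_prob_internal(theta, object$a1_hat[j], object$d_hat[j, ])
    tibble::tibble(item = j, theta = rep(theta, times = object$K),
                   category = factor(rep(0:(object$K - 1L), each = length(theta))),
                   prob = as.numeric(P))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$theta, y = .data$prob,
                                   colour = .data$category)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$item), labeller = ggplot2::label_both) +
    ggplot2::labs(x = expression(theta), y = "category probability")
}

#' Scatter plot of estimated against true discriminations
#'
#' @param fit A `grm_fit`.
#' @param bank The generating [item_bank()].
#' @return A ggplot object with the identity line.
#' @export
plot_recovery <- function(fit, bank) {
  df <- tibble::tibble(a_true = bank$a, a_hat = fit$a_hat)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a_true, y = .data$a_hat)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "true a", y = "estimated a")
}
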