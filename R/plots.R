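# ggplot2 autoplot methods for the result objects.

#' Plot an adaptation run
#'
#' Connectivity `<K>`, branching parameter `lambda` (running mean), and
#' activating-link ratio `r+` against the rewiring epoch, with the critical
#' value `lambda = 1` marked.
#'
#' @param object a `socnet_evolution` (or `socnet_stimulant`) object.
#' @param smooth plot the running-mean `lambda` instead of the instantaneous
#'   per-epoch value.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.socnet_evolution <- function(object, smooth = TRUE, ...) {
  tr <- object$trace
  tr$lambda_plot <- if (smooth) tr$lambda_smooth else tr$lambda
  long <- tidyr::pivot_longer(
    tr[c("epoch", "K", "lambda_plot", "r_plus")],
    cols = c("K", "lambda_plot", "r_plus"),
    names_to = "quantity", values_to = "value"
  )
  long$quantity <- factor(long$quantity,
    levels = c("K", "lambda_plot", "r_plus"),
    labels = c("<K>", "lambda", "r+")
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value, colour = .data$quantity)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "rewiring epoch", y = NULL, colour = NULL,
      title = "Self-organization towards the critical branching state"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.socnet_evolution
#' @export
autoplot.socnet_stimulant <- function(object, smooth = TRUE, ...) {
  p <- autoplot.socnet_evolution(object, smooth = smooth, ...)
  p + ggplot2::geom_vline(
    xintercept = object$switch_epoch,
    linetype = "dotted", colour = "black"
  ) +
    ggplot2::labs(title = "Rewiring response to a sudden threshold decrease")
}

#' Plot avalanche size and duration distributions
#'
#' Complementary cumulative distributions of avalanche size `S` and duration
#' `T` on log-log axes; power-law scaling appears as a straight line.
#'
#' @param object an `avalanche_ensemble`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.avalanche_ensemble <- function(object, ...) {
  ccdf_tbl <- function(x, what) {
    ux <- sort(unique(x))
    tibble::tibble(
      x = ux,
      ccdf = vapply(ux, function(u) mean(x >= u), numeric(1)),
      quantity = what
    )
  }
  df <- dplyr::bind_rows(
    ccdf_tbl(object$S, "size S"),
    ccdf_tbl(object$T, "duration T")
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$ccdf)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~quantity, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "P(X >= x)") +
    ggplot2::theme_minimal()
}

#' Plot an avalanche-shape collapse
#'
#' Mean temporal profiles of the chosen duration classes after rescaling time
#' to the unit interval and amplitude by `T^(gamma - 1)`; at criticality the
#' curves fall onto a single universal shape.
#'
#' @param object a `collapse_result`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.collapse_result <- function(object, ...) {
  df <- object$profiles
  df$duration <- factor(df$duration)
  ggplot2::ggplot(df, ggplot2::aes(.data$phase, .data$value, colour = .data$duration)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "t / T", y = "activity / T^(gamma - 1)", colour = "T",
      title = sprintf("Avalanche shape collapse (gamma = %.2f)", object$gamma_shape)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the mean size versus duration scaling
#'
#' `<S>(T)` on log-log axes with the fitted power law `T^gamma`.
#'
#' @param object a `scaling_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.scaling_fit <- function(object, ...) {
  df <- object$st_fit$data
  ggplot2::ggplot(df, ggplot2::aes(.data$T, .data$mean_S)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(
      method = "lm", formula = y ~ x, se = FALSE,
      linewidth = 0.4, colour = "firebrick"
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "duration T", y = "<S>(T)",
      title = sprintf("Mean size scaling, gamma = %.2f", object$gamma)
    ) +
    ggplot2::theme_minimal()
}
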