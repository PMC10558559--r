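#' Plot a PSD estimate
#'
#' One line per channel on a log power scale, with the four canonical
#' band ranges shaded.
#'
#' @param object a [compute_psd()] estimate.
#' @param channels optional subset of channel labels.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.psd_estimate <- function(object, channels = NULL, ...) {
  keep <- if (is.null(channels)) object$channels else channels
  df <- as_tibble(t(object$power))
  colnames(df) <- object$channels
  df$freq <- object$freqs
  long <- tidyr::pivot_longer(df, -"freq",
    names_to = "channel", values_to = "power"
  ) %>% filter(.data$channel %in% keep, .data$freq > 0)
  bands <- eeg_bands()
  ggplot2::ggplot(long, ggplot2::aes(.data$freq, .data$power)) +
    ggplot2::geom_rect(
      data = bands, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$lo, xmax = .data$hi, ymin = -Inf, ymax = Inf),
      alpha = 0.08
    ) +
    ggplot2::geom_line(ggplot2::aes(group = .data$channel), alpha = 0.5) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Frequency (Hz)", y = expression(PSD ~ (mu * V^2 / Hz))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a module allegiance matrix
#'
#' Heatmap of the probability that channel pairs share a community.
#'
#' @param object an [module_allegiance()] matrix.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.allegiance_matrix <- function(object, ...) {
  P <- unclass(object)
  labs <- rownames(P)
  if (is.null(labs)) labs <- as.character(seq_len(nrow(P)))
  df <- tidyr::expand_grid(i = labs, j = labs)
  df$p <- as.vector(t(P))
  ggplot2::ggplot(df, ggplot2::aes(
    factor(.data$j, labs), factor(.data$i, rev(labs)),
    fill = .data$p
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "P(same\ncommunity)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Plot a partition matrix
#'
#' Community assignment of every channel across time windows; label
#' changes along a row are what temporal flexibility counts.
#'
#' @param object a [build_partition_matrix()] object.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.partition_matrix <- function(object, ...) {
  A <- object$A
  df <- tidyr::expand_grid(
    channel = rownames(A), window = seq_len(ncol(A))
  )
  df$community <- factor(as.vector(t(A)))
  ggplot2::ggplot(df, ggplot2::aes(
    .data$window, factor(.data$channel, rev(rownames(A))),
    fill = .data$community
  )) +
    ggplot2::geom_tile(color = "white", linewidth = 0.2) +
    ggplot2::labs(x = "Window (s)", y = NULL, fill = "Community") +
    ggplot2::theme_minimal()
}

#' Plot a fitted workload/performance model
#'
#' Fixed-effect estimates with 95% Wald intervals.
#'
#' @param object a [fit_random_intercept()] or [glmm_lasso()] fit.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.workload_fit <- function(object, ...) {
  co <- tidy(object) %>% filter(.data$term != "(Intercept)")
  ggplot2::ggplot(co, ggplot2::aes(
    .data$estimate, stats::reorder(.data$term, .data$estimate)
  )) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - 1.96 * .data$std.error,
      xmax = .data$estimate + 1.96 * .data$std.error
    )) +
    ggplot2::labs(x = "Estimate (95% Wald CI)", y = NULL) +
    ggplot2::theme_minimal()
}
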