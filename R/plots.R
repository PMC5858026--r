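#' Plot a type 2 ROC curve
#'
#' Draws the response-collapsed type 2 ROC of one or more subjects'
#' confidence counts, with the chance diagonal for reference.
#'
#' @param counts Counts in any form accepted by [as_counts_list()].
#' @return A ggplot object.
#' @export
plot_type2_roc <- function(counts) {
  cl <- as_counts_list(counts)
  df <- purrr::imap(cl, function(cc, nm) {
    dplyr::mutate(type2_roc(cc), subject = nm)
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$far2, y = .data$hr2,
                                   group = .data$subject)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "P(conf ≥ y | incorrect)",
                  y = "P(conf ≥ y | correct)",
                  title = "Type 2 ROC") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Trace and posterior plots for a hierarchical fit
#'
#' Shows the MCMC trace of the group-level efficiency parameter per chain
#' (left) and the pooled posterior histogram of meta-d'/d' (right-style
#' faceting), the standard visual convergence check.
#'
#' @param object A `metad_group_fit`.
#' @param parameter Column of `object$samples` to display. Default
#'   `"mu_logMratio"`, shown on the meta-d'/d' scale.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metad_group_fit <- function(object, parameter = "mu_logMratio",
                                     ...) {
  df <- object$samples
  v <- df[[parameter]]
  if (parameter == "mu_logMratio") {
    v <- exp(v)
    lab <- "meta-d'/d'"
  } else {
    lab <- parameter
  }
  df$value <- v
  trace <- ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration,
                                            y = .data$value,
                                            colour = factor(.data$chain))) +
    ggplot2::geom_line(alpha = 0.6, linewidth = 0.2) +
    ggplot2::labs(x = "iteration", y = lab, colour = "chain") +
    ggplot2::theme_minimal()
  hist <- ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 60, fill = "steelblue",
                            colour = "white") +
    ggplot2::labs(x = lab, y = "samples") +
    ggplot2::theme_minimal()
  if (requireNamespace("patchwork", quietly = TRUE)) {
    return(patchwork::wrap_plots(trace, hist, ncol = 2))
  }
  trace
}

#' Posterior histogram of the cross-domain correlation
#'
#' @param object A `metad_corr_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metad_corr_fit <- function(object, ...) {
  ci <- calc_ci(object$samples$rho)
  ggplot2::ggplot(object$samples, ggplot2::aes(x = .data$rho)) +
    ggplot2::geom_histogram(bins = 60, fill = "steelblue",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = c(ci$lo, ci$hi), linetype = "dashed") +
    ggplot2::labs(x = expression(rho), y = "samples",
                  title = "Cross-domain correlation of log(meta-d'/d')") +
    ggplot2::theme_minimal()
}
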