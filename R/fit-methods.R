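#' @export
tidy.unpbn_fit <- function(x, ...) {
  tibble::tibble(
    sample = seq_along(x$samples),
    iteration = vapply(x$samples, `[[`, 1L, "iteration"),
    n_components = vapply(x$samples, `[[`, 1L, "n_components"),
    log_posterior = vapply(x$samples, `[[`, 1, "log_posterior"))
}

#' @export
glance.unpbn_fit <- function(x, ...) {
  nc <- vapply(x$samples, `[[`, 1L, "n_components")
  tab <- table(nc)
  tibble::tibble(
    n = x$n, d = x$d, n_samples = length(x$samples),
    modal_n_components = as.integer(names(tab)[which.max(tab)]),
    mean_n_components = mean(nc),
    mean_log_posterior = mean(vapply(x$samples, `[[`, 1, "log_posterior")),
    edge_acceptance = x$acceptance$rate[x$acceptance$move == "edge"],
    eject_acceptance = x$acceptance$rate[x$acceptance$move == "eject"],
    absorb_acceptance = x$acceptance$rate[x$acceptance$move == "absorb"])
}

#' Trace plots for a mixture-of-networks fit
#'
#' Shows the retained-sample trace of the number of components together
#' with its posterior frequencies.
#'
#' @param object An `unpbn_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.unpbn_fit <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$iteration,
                                   y = .data$n_components)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "MCMC iteration", y = "Number of components N",
                  title = "Posterior trace of the number of components") +
    ggplot2::theme_minimal()
}

#' Heatmap of posterior edge probabilities
#'
#' @param pep_tbl Output of [posterior_edge_probabilities()].
#' @return A ggplot object, faceted by consensus component when present.
#' @export
plot_edge_probabilities <- function(pep_tbl) {
  p <- ggplot2::ggplot(pep_tbl,
                       ggplot2::aes(x = .data$to, y = .data$from,
                                    fill = .data$pep)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "child", y = "parent",
                  fill = "posterior\nedge prob.") +
    ggplot2::theme_minimal()
  if (!all(is.na(pep_tbl$component)))
    p <- p + ggplot2::facet_wrap(~component, labeller = ggplot2::label_both)
  p
}

#' Boxplot of benchmark accuracy by noise level and method
#'
#' @param results Tidy benchmark tibble from [run_benchmark()].
#' @return A ggplot object.
#' @export
plot_benchmark <- function(results) {
  ggplot2::ggplot(results,
                  ggplot2::aes(x = factor(.data$fd), y = .data$pco,
                               fill = .data$method)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "noise level (fractional deviation)",
                  y = "correctly allocated observations [%]") +
    ggplot2::theme_minimal()
}
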