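#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a training run
#'
#' @param x A `plasticity_fit` from [train()].
#' @param ... Unused.
#' @return The metrics tibble: one row per recorded step with `step`,
#'   `n_responsive`, `n_divergent`, `mean_di_prime`, `fisher_opt`,
#'   `mean_degree`.
#' @exportS3Method generics::tidy
tidy.plasticity_fit <- function(x, ...) x$metrics

#' One-row summary of a training run
#'
#' @param x A `plasticity_fit` from [train()].
#' @param ... Unused.
#' @return A one-row tibble with the run setup and the initial/final
#'   discriminability metrics.
#' @exportS3Method generics::glance
glance.plasticity_fit <- function(x, ...) {
  first <- x$metrics[1, ]
  last <- x$metrics[nrow(x$metrics), ]
  tibble::tibble(variant = x$variant, n_steps = max(x$steps),
                 n_responsive_start = first$n_responsive,
                 n_responsive_end = last$n_responsive,
                 n_divergent_start = first$n_divergent,
                 n_divergent_end = last$n_divergent,
                 mean_di_prime_start = first$mean_di_prime,
                 mean_di_prime_end = last$mean_di_prime,
                 fisher_opt_start = first$fisher_opt,
                 fisher_opt_end = last$fisher_opt,
                 mean_degree_end = last$mean_degree)
}

#' Plot the metric time courses of a training run
#'
#' @param object A `plasticity_fit` from [train()].
#' @param ... Unused.
#' @return A ggplot with one facet per metric.
#' @exportS3Method ggplot2::autoplot
autoplot.plasticity_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$metrics, -"step",
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "training trial", y = NULL,
                  title = paste0("training run (", object$variant, ")"))
}

#' Heatmap of the effective MC-MC connectivity
#'
#' Visualizes the number of GCs mediating mutual disynaptic inhibition
#' between every pair of MCs (diagonal suppressed).
#'
#' @param W Binary connectivity matrix.
#' @return A ggplot heatmap.
#' @export
plot_effective_connectivity <- function(W) {
  wmm <- effective_connectivity(W)
  diag(wmm) <- NA
  df <- tibble::tibble(mc_i = rep(seq_len(nrow(wmm)), ncol(wmm)),
                       mc_j = rep(seq_len(ncol(wmm)), each = nrow(wmm)),
                       shared_gcs = as.vector(wmm))
  ggplot2::ggplot(df, ggplot2::aes(.data$mc_i, .data$mc_j,
                                   fill = .data$shared_gcs)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "MC", y = "MC", fill = "shared GCs")
}
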