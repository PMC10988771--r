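#' Tidy and glance methods
#'
#' Broom-style accessors for the package's result objects: `tidy()` returns
#' one row per estimated quantity, `glance()` a one-row model summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name glio-tidiers
NULL

#' @rdname glio-tidiers
#' @export
tidy.contrast_result <- function(x, ...) {
  as_tibble(x)[, c("channel_id", "band", "contrast", "psc", "p",
                   "significant", "degenerate")]
}

#' @rdname glio-tidiers
#' @export
tidy.spin_test_result <- function(x, ...) as_tibble(x)

#' @rdname glio-tidiers
#' @export
tidy.glio_model_report <- function(x, ...) x$terms

#' @rdname glio-tidiers
#' @export
glance.glio_model_report <- function(x, ...) {
  s <- summary(x$fit)
  tibble(response = x$response, n = x$n, r_squared = s$r.squared,
         adj_r_squared = s$adj.r.squared, sigma = s$sigma)
}

#' @rdname glio-tidiers
#' @export
tidy.psc_fc_grid <- function(x, ...) as_tibble(x)

#' @rdname glio-tidiers
#' @export
tidy.tumour_network_result <- function(x, ...) x$voxels

#' @rdname glio-tidiers
#' @export
glance.tumour_network_result <- function(x, ...) {
  tibble(mean_connectivity = x$mean_connectivity,
         n_survivors = x$n_survivors, n_tested = x$n_tested,
         n_overlap_excluded = x$n_overlap_excluded)
}

#' Plot per-electrode contrast results
#'
#' Percentage signal change per channel, filled by two-tailed significance.
#'
#' @param object A `contrast_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.contrast_result <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$channel_id, y = .data$psc,
                               fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(.data$band ~ .data$contrast) +
    ggplot2::labs(x = NULL, y = "signal change (%)",
                  fill = "p < alpha") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot spin-test medians against their nulls
#'
#' @param object A `spin_test_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spin_test_result <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$network, y = .data$observed_median,
                               colour = .data$direction)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = "network", y = "observed median (z)",
                  colour = "direction") +
    ggplot2::theme_minimal()
}

#' Plot the mixed-model association grid
#'
#' @param object A `psc_fc_grid`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.psc_fc_grid <- function(object, ...) {
  d <- mutate(as_tibble(object), sig = .data$p < 0.05)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$network, y = .data$contrast,
                                  fill = .data$chisq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$sig, "*", "")),
                       size = 6) +
    ggplot2::labs(x = "network", y = "contrast", fill = "Wald chi-sq") +
    ggplot2::theme_minimal()
}
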