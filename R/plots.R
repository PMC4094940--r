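#' Plot a TSS-distance profile
#'
#' Bar histogram of the fraction of sites per distance bin, one panel
#' colouring per dataset.
#'
#' @param object A [tss_profile()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tss_profile
#' @export
autoplot.tss_profile <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$bin_mid, y = 100 * .data$fraction, fill = .data$dataset)
  ) +
    ggplot2::geom_col(position = "identity", alpha = 0.6) +
    ggplot2::labs(
      x = "Distance from TSS (bp)", y = "Sites (%)",
      fill = "Dataset"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a ChIP-fragment density profile
#'
#' Mean fragment coverage per bin as a function of the offset from the
#' integration site.
#'
#' @param object A [chip_density()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot chip_profile
#' @export
autoplot.chip_profile <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$offset_mid, y = .data$density)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Offset from integration site (bp)",
      y = "Mean fragment coverage"
    ) +
    ggplot2::theme_minimal()
}

#' Plot chromatin-state composition per dataset
#'
#' Stacked-bar view of the fraction of sites per epigenetic state,
#' including the unassigned fraction.
#'
#' @param states A [state_summary()] tibble.
#' @return A ggplot object.
#' @export
plot_state_summary <- function(states) {
  ggplot2::ggplot(
    states,
    ggplot2::aes(x = .data$dataset, y = 100 * .data$fraction, fill = .data$state)
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Sites (%)", fill = "Chromatin state") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
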