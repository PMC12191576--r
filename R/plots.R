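#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the diagonal power spectra of one or more spectral grids
#'
#' @param object A `cg_spectrum`.
#' @param ... Further `cg_spectrum` objects to overlay (e.g. empirical vs
#'   theoretical).
#' @return A ggplot: power spectral density per component, overlaid by
#'   label.
#' @export
autoplot.cg_spectrum <- function(object, ...) {
  specs <- c(list(object), list(...))
  df <- dplyr::bind_rows(lapply(specs, tidy))
  df <- dplyr::filter(df, .data$i == .data$j)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$omega, y = .data$re,
                                   colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ .data$i, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "frequency (rad/bin)", y = "power spectral density",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a coarse-grained kernel sequence
#'
#' @param object A `coarse_kernel`.
#' @param ... Unused.
#' @export
autoplot.coarse_kernel <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag, y = .data$value)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::facet_grid(.data$i ~ .data$j, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "lag (bins)", y = expression(Phi[k])) +
    ggplot2::theme_minimal()
}

#' Boxplots of a parameter-recovery study
#'
#' One panel per parameter, estimates by method, ground truth as a line.
#'
#' @param object A `recovery_study`.
#' @param ... Unused.
#' @export
autoplot.recovery_study <- function(object, ...) {
  df <- dplyr::inner_join(object$results, object$truth, by = "term")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$estimate)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$truth),
                        colour = "darkgreen") +
    ggplot2::facet_wrap(~ .data$term, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "estimate") +
    ggplot2::theme_minimal()
}
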