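## ggplot2 autoplot methods for the package's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a Survival-Yield curve
#'
#' @param object An `sy_curve` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sy_curve
#' @export
autoplot.sy_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$voltage, y = .data$sy,
                                       colour = .data$peptide_id)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "acceleration voltage (V)", y = "Survival Yield",
                  colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot breakdown curves
#'
#' One panel per target m/z, one curve per peptide.
#'
#' @param object A `breakdown_curve` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot breakdown_curve
#' @export
autoplot.breakdown_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$voltage, y = .data$fraction,
                                       colour = .data$peptide_id)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~ round(target_mz, 2)) +
    ggplot2::labs(x = "acceleration voltage (V)", y = "fraction of TIC",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Score or loading plot of a NIPALS PCA fit
#'
#' @param object A `nipals_pca` object.
#' @param type `"scores"` (default) or `"loadings"`.
#' @param components Two components to display.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot nipals_pca
#' @export
autoplot.nipals_pca <- function(object, type = c("scores", "loadings"),
                                components = c(1L, 2L), ...) {
  type <- match.arg(type)
  ev <- object$explained_variance_pct
  labs <- sprintf("PC%d (%.2f%%)", components, ev[components])
  if (type == "scores") {
    df <- tibble::tibble(x = object$scores[, components[1]],
                         y = object$scores[, components[2]])
    if (!is.null(object$meta) && "peptide_id" %in% names(object$meta)) {
      df$peptide_id <- object$meta$peptide_id
      p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                            colour = .data$peptide_id))
    } else {
      p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y))
    }
    return(p + ggplot2::geom_point(size = 2) +
             ggplot2::labs(x = labs[1], y = labs[2], colour = NULL) +
             ggplot2::theme_minimal())
  }
  df <- tibble::tibble(x = object$loadings[, components[1]],
                       y = object$loadings[, components[2]],
                       mz = object$variable_mzs %||%
                         seq_len(nrow(object$loadings)))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = 0),
                          colour = "grey70", linewidth = 0.2) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = round(.data$mz, 2)),
                       vjust = -0.6, size = 2.6) +
    ggplot2::labs(x = labs[1], y = labs[2]) +
    ggplot2::theme_minimal()
}

#' Plot an annotated spectrum
#'
#' Stick spectrum with annotation labels over the matched peaks.
#'
#' @param spectrum Peak tibble of one spectrum.
#' @param annotations Annotation tibble from [annotate_spectrum()].
#' @param top_n Label at most this many matched peaks (by intensity).
#' @return A ggplot.
#' @export
plot_annotated_spectrum <- function(spectrum, annotations, top_n = 12L) {
  lab <- dplyr::slice_max(annotations, .data$intensity, n = top_n)
  ggplot2::ggplot(spectrum, ggplot2::aes(x = .data$mz, xend = .data$mz,
                                         y = 0, yend = .data$intensity)) +
    ggplot2::geom_segment(linewidth = 0.3) +
    ggplot2::geom_text(data = lab,
                       ggplot2::aes(x = .data$observed_mz,
                                    y = .data$intensity,
                                    label = .data$label),
                       inherit.aes = FALSE, angle = 90, hjust = -0.05,
                       size = 2.4) +
    ggplot2::labs(x = "m/z", y = "intensity") +
    ggplot2::theme_minimal()
}
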