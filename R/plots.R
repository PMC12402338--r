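# ggplot2 helpers for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a metagene TSS profile
#'
#' Aggregated mark signal as a function of distance to the TSS.
#'
#' @param object A `tss_profile` from [tss_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tss_profile <- function(object, ...) {
  df <- tibble(position = object$position, signal = object$mean)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "distance to TSS (bp)", y = "mean fragments per gene") +
    ggplot2::theme_minimal()
}

#' Plot cells in an embedding
#'
#' @param object A `pt_embedding` from [reduce_dims()].
#' @param colour Optional named vector (cell -> group) used to colour points.
#' @param dims Which two components to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pt_embedding <- function(object, colour = NULL, dims = c(1L, 2L), ...) {
  df <- as_tibble(object$coords[, dims, drop = FALSE], rownames = "cell")
  names(df)[2:3] <- c("dim1", "dim2")
  if (!is.null(colour)) df$group <- unname(colour[df$cell])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2)) +
    ggplot2::labs(x = colnames(object$coords)[dims[1]],
                  y = colnames(object$coords)[dims[2]]) +
    ggplot2::theme_minimal()
  if (is.null(colour)) p + ggplot2::geom_point(size = 0.6, alpha = 0.7)
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$group),
                               size = 0.6, alpha = 0.7)
}

#' Volcano plot of a differential result
#'
#' @param results Tibble from [find_markers()] or [differential_bins()].
#' @param label_threshold q-value line to draw.
#' @return A ggplot object.
#' @export
plot_volcano <- function(results, label_threshold = 0.01) {
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$log2fc, y = -log10(.data$p_value),
                               colour = .data$significant)) +
    ggplot2::geom_point(size = 0.7, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' Bar plot of genic annotation fractions
#'
#' @param summary Tibble from [summarize_annotation()].
#' @return A ggplot object.
#' @export
plot_annotation_summary <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$category, y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "fraction of peaks") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
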