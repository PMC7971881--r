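# Plotting ---------------------------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ROC curve
#'
#' Barcode-strict recovery as a solid line, detection-only ("total hit
#' rate") dashed.
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$curve, c("tpr_strict", "tpr_detection"),
                            names_to = "kind", values_to = "tpr")
  df$kind <- factor(df$kind, c("tpr_strict", "tpr_detection"),
                    c("correct barcode", "any detection"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   linetype = .data$kind)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "false positive rate", y = "1 - FNR",
                  linetype = NULL,
                  title = sprintf("AUROC = %.3f", object$auroc)) +
    ggplot2::theme_minimal()
}

#' Plot a spot-quality histogram
#'
#' @param object A `quality_histogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot quality_histogram
#' @export
autoplot.quality_histogram <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = (.data$bin_lower + .data$bin_upper) / 2,
                               y = .data$count)) +
    ggplot2::geom_col(width = object$bin_upper[1] - object$bin_lower[1],
                      fill = "grey30") +
    ggplot2::labs(x = expression(R^2 ~ "of rank-one approximation"),
                  y = "spots") +
    ggplot2::theme_minimal()
}

#' Plot the optimization trajectory of a fit
#'
#' @param object A `density_fit`.
#' @param ... Unused.
#' @return A ggplot of reconstruction and sparsity losses per iteration.
#' @method autoplot density_fit
#' @export
autoplot.density_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$trajectory,
                            c("reconstruction_loss", "sparsity_loss"),
                            names_to = "loss", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~loss, scales = "free_y") +
    ggplot2::labs(x = "outer iteration", y = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of one barcode's density image
#'
#' @param F Density matrix or `density_fit`.
#' @param j Barcode index (1-based).
#' @param spatial_shape Grid extents (defaulted from a fit).
#' @param blur Render the PSF-blurred density (easier to see; default
#'   `FALSE`).
#' @param psf `psf` used when `blur = TRUE`.
#' @return A ggplot raster.
#' @export
plot_density <- function(F, j, spatial_shape = NULL, blur = FALSE, psf = NULL) {
  if (inherits(F, "density_fit")) {
    fit <- F
    spatial_shape <- spatial_shape %||% fit$spatial_shape
    psf <- psf %||% fit$psf
    F <- fit$params$F
  }
  stopifnot(length(spatial_shape) == 2L)
  col <- F[, j]
  if (blur) {
    stopifnot(!is.null(psf))
    col <- convolve_density(matrix(col, ncol = 1L), spatial_shape,
                            psf_operators(psf, spatial_shape))[, 1L]
  }
  coords <- voxel_to_coords(seq_along(col) - 1L, spatial_shape)
  df <- tibble::tibble(y = coords[, 1L], x = coords[, 2L], density = col)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
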