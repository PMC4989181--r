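# Optional ggplot2-based figures.

#' Plot an area-contribution curve
#'
#' Bar height is the per-worm area contribution of each size class; the sum
#' of the bars is the mean total accumulation area per worm.
#'
#' @param curve An `area_contribution_curve` from [area_contribution()].
#' @return A ggplot object.
#' @export
plot_area_contribution <- function(curve) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  ggplot2::ggplot(as.data.frame(curve),
                  ggplot2::aes(x = bin_mid,
                               y = contribution_per_worm)) +
    ggplot2::geom_col(width = attr(curve, "bin_width") * 0.9,
                      fill = "firebrick", alpha = 0.8) +
    ggplot2::labs(x = expression(paste("accumulation size (", mu, m^2, ")")),
                  y = expression(paste("area contribution (", mu, m^2,
                                       " per worm)")))
}

#' Scatter plot of carrier versus lipid signal offsets
#'
#' @param delta_gfp,delta_cars Position-mean offsets.
#' @param fit Optional `carrier_lipid_fit` to overlay.
#' @return A ggplot object.
#' @export
plot_carrier_lipid <- function(delta_gfp, delta_cars, fit = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- data.frame(delta_gfp = delta_gfp, delta_cars = delta_cars)
  p <- ggplot2::ggplot(df, ggplot2::aes(delta_gfp, delta_cars)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = expression(Delta * " integrated GFP signal"),
                  y = expression(Delta * " integrated CARS signal"))
  if (!is.null(fit))
    p <- p + ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept,
                                  colour = "red")
  p
}

utils::globalVariables(c("bin_mid", "contribution_per_worm", "delta_gfp",
                         "delta_cars"))
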