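# ggplot2 visualisations for the result types

#' Plot a tri-class PET/CT result
#'
#' Bar chart of the PET+/CT-, PET+/CT+ and PET-/CT+ percentages, coloured as
#' is conventional (magenta / blue / green).
#'
#' @param object A `tri_class_result`.
#' @param ... Unused.
#' @export
autoplot.tri_class_result <- function(object, ...) {
  labs <- c(pet_only = "PET+/CT-", both = "PET+/CT+", ct_only = "PET-/CT+")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = labs[as.character(.data$class)],
                               y = .data$percentage,
                               fill = as.character(.data$class))) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(pet_only = "magenta3",
                                          both = "blue3",
                                          ct_only = "green4")) +
    ggplot2::labs(x = NULL, y = "% of PET or CT positive voxels") +
    ggplot2::theme_minimal()
}

#' Plot a PET/CT transect profile
#'
#' PET activity and CT density along the transect, each scaled to its own
#' maximum so rim/core structure of both signals can be compared on one axis.
#'
#' @param object A `transect_profile`.
#' @param ... Unused.
#' @export
autoplot.transect_profile <- function(object, ...) {
  d <- tidyr::pivot_longer(
    dplyr::mutate(
      object,
      PET = .data$pet_value / max(abs(.data$pet_value), 1e-300),
      CT = .data$ct_hu / max(abs(.data$ct_hu), 1e-300)
    )[, c("position_mm", "PET", "CT")],
    cols = c("PET", "CT"), names_to = "modality", values_to = "relative"
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$position_mm, .data$relative,
                                  colour = .data$modality)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position along transect (mm)",
                  y = "signal / max signal", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a Patlak fit
#'
#' Normalized-tissue vs normalized-integrated-plasma coordinates with the
#' fitted regression line over the points past the equilibration cutoff.
#'
#' @param object A `patlak_fit`.
#' @param ... Unused.
#' @export
autoplot.patlak_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$used)) +
    ggplot2::geom_abline(slope = object$Ki, intercept = object$V,
                         colour = "red3") +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                guide = "none") +
    ggplot2::labs(
      x = "integral(Cb) / Cb (min)",
      y = "Ct / Cb",
      title = sprintf("Patlak: Ki = %.4g ml cm^-3 min^-1, V = %.3g",
                      object$Ki, object$V)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a kinetic association/dissociation fit
#'
#' Observed points with the fitted one-site curve.
#'
#' @param object A `kinetic_fit`.
#' @param ... Unused.
#' @export
autoplot.kinetic_fit <- function(object, ...) {
  d <- object$data
  tt <- seq(min(d$time_min), max(d$time_min), length.out = 200)
  pred <- stats::predict(object$fit, newdata = tibble(time_min = tt))
  ggplot2::ggplot(d, ggplot2::aes(.data$time_min, .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = tibble(time_min = tt, value = pred),
                       colour = "red3") +
    ggplot2::labs(x = "time (min)", y = "bound activity",
                  title = paste0("one-site ", object$kind, " fit")) +
    ggplot2::theme_minimal()
}

#' Heat-map of a phantom, activity map or rendered image
#'
#' @param x A `plaque_phantom`, `activity_map` or `image_volume` (2D, or a 3D
#'   object with `slice` given).
#' @param slice Slice index along the third axis for 3D inputs.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_grid_field <- function(x, slice = NULL, ...) {
  g <- x$grid
  if (length(dim(g)) == 3) {
    slice <- slice %||% ceiling(dim(g)[3] / 2)
    g <- g[, , slice]
  }
  d <- expand.grid(x_um = (seq_len(nrow(g)) - 0.5) * x$voxel_size,
                   y_um = (seq_len(ncol(g)) - 0.5) * x$voxel_size)
  d$value <- as.vector(g)
  ggplot2::ggplot(d, ggplot2::aes(.data$x_um, .data$y_um,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
}
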