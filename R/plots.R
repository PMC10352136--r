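#' Plot a neighborhood cloud as a 2D density image
#'
#' @param object A `coat_cloud` from [relative_poses()].
#' @param plane `"tangent"` or `"axial"` (see [neighborhood_histogram()]).
#' @param bin_A Bin width in Angstrom.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coat_cloud <- function(object, plane = "tangent", bin_A = 2, ...) {
  hg <- neighborhood_histogram(object, plane = plane, bin_A = bin_A)
  lab <- if (plane == "tangent") c("dx (along strand, Å)", "dy (lateral, Å)")
         else c("dx (along strand, Å)", "dz (radial, Å)")
  ggplot2::ggplot(hg, ggplot2::aes(x = .data$x_A, y = .data$y_A,
                                   fill = .data$count)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = lab[1], y = lab[2], fill = "poses",
                  title = "Neighborhood plot") +
    ggplot2::theme_minimal()
}

#' Unrolled-surface scatter of a tube's particles
#'
#' Shows the helical strands as oblique point rows in the (s, u) plane.
#'
#' @param particles Particle tibble (single or multiple tubes).
#' @param axes Axis table or list of [tube_axis()] objects.
#' @return A ggplot object, faceted by tube.
#' @export
plot_unrolled <- function(particles, axes) {
  unr <- if (all(c("s_A", "u_A") %in% names(particles))) particles
         else unroll_particles(particles, axes)
  ggplot2::ggplot(unr, ggplot2::aes(x = .data$s_A, y = .data$u_A)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::facet_wrap(~tube_id, scales = "free") +
    ggplot2::labs(x = "arc length s (Å)", y = "circumferential u (Å)",
                  title = "Unrolled tube surface") +
    ggplot2::theme_minimal()
}

#' Start-number histogram of a set of helix fits
#'
#' @param object A `coat_helix_fit` tibble from [fit_helix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coat_helix_fit <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = factor(.data$n_starts))) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "helical starts", y = "tubes",
                  title = "Start-number distribution") +
    ggplot2::theme_minimal()
}
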