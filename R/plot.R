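# ggplot2 helpers for the tabular diagnostics (ggplot2 is suggested, not
# required by the geometry pipeline).

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
}

#' Plot the per-pore diameter profile along the path
#'
#' Reproduces the pore-uniformity diagnostic: effective pore diameter
#' against arc-length position, coloured by the pore's vertical normal
#' orientation (side vs top/bottom pores).
#'
#' @param pore_table output of \code{\link{pore_size_profile}}.
#' @return A ggplot object.
#' @export
plot_pore_profile <- function(pore_table) {
  need_ggplot()
  pore_table$facing <- ifelse(abs(pore_table$normal_z) <= 0.5,
                              "side", "top/bottom")
  ggplot2::ggplot(pore_table,
                  ggplot2::aes(x = s, y = diameter_um,
                               colour = facing)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::labs(x = "arc length s (um)",
                  y = "effective pore diameter (um)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot bead tracks
#'
#' @param tracks a \code{bead_tracks} tibble.
#' @return A ggplot object.
#' @export
plot_tracks <- function(tracks) {
  need_ggplot()
  ggplot2::ggplot(tracks, ggplot2::aes(x = x, y = y,
                                       group = track,
                                       colour = factor(track))) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "x (px)", y = "y (px)", colour = "track") +
    ggplot2::theme_minimal()
}
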