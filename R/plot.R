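#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

frames_to_tibble <- function(z, frames, value_name = "value") {
  d <- dim(z)
  out <- lapply(frames, function(k) {
    tibble::tibble(x = rep(grid_coords(d[1]), times = d[2]),
                   y = rep(grid_coords(d[2]), each = d[1]),
                   frame = k, value = as.vector(z[, , k]))
  })
  do.call(rbind, out)
}

#' Plot frames of a denoised sequence
#'
#' Raster panels of selected frames of the denoised array, or of the
#' per-voxel decision map (`what = "decision"`), which shows where the
#' one-sided (edge) fits were triggered.
#'
#' @param object A `jpllk_denoise` object.
#' @param frames Integer vector of frame indices (default: 4 equally spaced).
#' @param what `"fhat"` or `"decision"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.jpllk_denoise <- function(object, frames = NULL, what = c("fhat", "decision"), ...) {
  what <- match.arg(what)
  d <- dim(object$fhat)
  if (is.null(frames)) frames <- unique(round(seq(1, d[3], length.out = min(4, d[3]))))
  if (what == "fhat") {
    df <- frames_to_tibble(object$fhat, frames)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$y, y = .data$x, fill = .data$value)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c(name = "intensity")
  } else {
    df <- frames_to_tibble(object$decision, frames)
    df$value <- factor(decision_labels[df$value + 1], levels = decision_labels)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$y, y = .data$x, fill = .data$value)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_d(name = "decision")
  }
  p + ggplot2::facet_wrap(~frame, labeller = ggplot2::label_both) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "y", y = "x") +
    ggplot2::theme_minimal()
}

#' Plot frames of a simulated replicate
#'
#' @param object A `jpllk_replicate` object.
#' @param frames Integer vector of frame indices.
#' @param what `"observed"` or `"truth"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.jpllk_replicate <- function(object, frames = NULL,
                                     what = c("observed", "truth"), ...) {
  what <- match.arg(what)
  z <- object[[what]]
  d <- dim(z)
  if (is.null(frames)) frames <- unique(round(seq(1, d[3], length.out = min(4, d[3]))))
  df <- frames_to_tibble(z, frames)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$y, y = .data$x, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = what) +
    ggplot2::facet_wrap(~frame, labeller = ggplot2::label_both) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Plot a cross-validation score surface
#'
#' Tile plot of the modified CV score over the `(hx, ht)` grid, faceted by
#' the threshold `u`, with the selected triple marked.
#'
#' @param object A `jpllk_cv` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom rlang .data
#' @export
autoplot.jpllk_cv <- function(object, ...) {
  tab <- object$score_table
  b <- object$best_params
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$ht, y = .data$hx, fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = tab[tab$hx == b$hx & tab$ht == b$ht & tab$u == b$u, ],
                        colour = "red", size = 2) +
    ggplot2::scale_fill_viridis_c(name = "CV score") +
    ggplot2::facet_wrap(~u, labeller = ggplot2::label_both) +
    ggplot2::theme_minimal()
}
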