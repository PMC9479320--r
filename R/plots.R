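#' Plot a persistence diagram
#'
#' Birth/death scatter with the diagonal reference line; essential
#' intervals are drawn as triangles at the cap value. Points near the
#' diagonal are short-lived features ("many small holes"); points far from
#' it are prominent structure.
#'
#' @param object A `persistence_diagram`.
#' @param cap Finite plotting value replacing `+Inf` deaths; defaults to
#'   1.05 times the largest finite value.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.persistence_diagram <- function(object, cap = NULL, ...) {
  d <- tibble::as_tibble(object)
  finite <- c(d$birth[is.finite(d$birth)], d$death[is.finite(d$death)])
  if (is.null(cap)) cap <- if (length(finite)) 1.05 * max(finite, 1e-9) else 1
  d$essential <- !is.finite(d$death)
  d$death[d$essential] <- cap
  ggplot2::ggplot(d, ggplot2::aes(x = .data$birth, y = .data$death,
                                  colour = factor(.data$dim),
                                  shape = .data$essential)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17),
                                guide = "none") +
    ggplot2::labs(x = "birth", y = "death", colour = "dim",
                  title = attr(object, "source_label")) +
    ggplot2::theme_minimal()
}

#' Barcode rendering of a persistence diagram
#'
#' One horizontal bar per interval, grouped by dimension; essential bars
#' run to the cap.
#'
#' @param diagram A `persistence_diagram`.
#' @param cap Finite plotting value replacing `+Inf` deaths.
#' @return A ggplot object.
#' @export
plot_barcode <- function(diagram, cap = NULL) {
  d <- tibble::as_tibble(diagram)
  finite <- c(d$birth[is.finite(d$birth)], d$death[is.finite(d$death)])
  if (is.null(cap)) cap <- if (length(finite)) 1.05 * max(finite, 1e-9) else 1
  d$death[!is.finite(d$death)] <- cap
  d <- dplyr::arrange(d, .data$dim, .data$birth)
  d$bar <- seq_len(nrow(d))
  ggplot2::ggplot(d, ggplot2::aes(y = .data$bar, yend = .data$bar,
                                  x = .data$birth, xend = .data$death,
                                  colour = factor(.data$dim))) +
    ggplot2::geom_segment(linewidth = 0.8) +
    ggplot2::labs(x = "filtration value", y = NULL, colour = "dim",
                  title = attr(diagram, "source_label")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot a Betti curve
#'
#' @param object A `betti_curve`.
#' @param ... Unused.
#' @return A ggplot object (step plot of `beta_k` against threshold).
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.betti_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$threshold, y = .data$betti)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "threshold",
                  y = sprintf("beta[%s]", attr(object, "k"))) +
    ggplot2::theme_minimal()
}
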