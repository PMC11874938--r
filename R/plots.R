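# Plot methods for the main result types.

#' @export
autoplot.expression_table <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$query,
                                     y = .data$archive,
                                     fill = log10(.data$n_spots + 1))) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_spots), size = 3) +
    ggplot2::scale_fill_viridis_c(name = "log10(spots + 1)") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Supporting spots per query and archive") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.absence_calibration <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$coverage)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo,
                                      ymax = .data$ci_hi),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted),
                       colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed)) +
    ggplot2::labs(x = "coverage (x)", y = "fraction of targets missed",
                  title = "Absence bound: simulation vs exp(-lambda)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.spot_hit_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$query_id,
                                       y = .data$n_spots)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "supporting spots") +
    ggplot2::theme_minimal()
}

#' Plot a Dollo loss report on the tree
#'
#' Draws the species tree with the loss branches highlighted and tip
#' states annotated (ape base graphics, the field idiom for trees).
#'
#' @param x A `loss_report`.
#' @param ... Passed to [ape::plot.phylo()].
#' @method plot loss_report
#' @export
plot.loss_report <- function(x, ...) {
  tree <- x$tree
  edge_col <- rep("black", nrow(tree$edge))
  edge_lwd <- rep(1, nrow(tree$edge))
  for (e in x$loss_branches$edge) {
    if (!is.na(e)) {
      edge_col[e] <- "red"
      edge_lwd[e] <- 3
    }
  }
  ape::plot.phylo(tree, edge.color = edge_col, edge.width = edge_lwd,
                  ...)
  st <- x$states[tree$tip.label]
  pch <- ifelse(st == "present", 19, ifelse(st == "absent", 4, 1))
  ape::tiplabels(pch = pch, adj = 0.5, offset = 0.1)
  graphics::legend("bottomleft",
                   legend = c("present", "absent", "unknown", "loss"),
                   pch = c(19, 4, 1, NA), lty = c(NA, NA, NA, 1),
                   lwd = c(NA, NA, NA, 3),
                   col = c("black", "black", "black", "red"),
                   bty = "n", cex = 0.8)
  invisible(x)
}
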