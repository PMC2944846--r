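#' @describeIn fit_cda `autoplot()` scatter of the first two canonical
#'   variables coloured by cluster.
#' @param object The fitted object.
#' @exportS3Method ggplot2::autoplot
autoplot.cda_fit <- function(object, ...) {
  s <- object$scores
  if (is.null(s) || !all(c("can1", "can2") %in% names(s))) {
    abort("need at least two canonical axes with stored scores to plot")
  }
  ggplot2::ggplot(s, ggplot2::aes(.data$can1, .data$can2,
                                  colour = factor(.data$cluster))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "canonical variable 1", y = "canonical variable 2",
                  colour = "cluster") +
    ggplot2::theme_minimal()
}

#' @describeIn cluster_flow `autoplot()` band diagram: cluster boxes of the
#'   two models joined by bands with width proportional to shared
#'   individuals.
#' @param object A `cluster_flow`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.cluster_flow <- function(object, ...) {
  long <- tidy(object)
  long <- dplyr::filter(long, .data$n > 0)
  # stack clusters of each model on [0, n]
  pos <- function(labels, n_vec) {
    ends <- cumsum(n_vec)
    tibble(label = labels, y0 = c(0, head(ends, -1)), y1 = ends)
  }
  from_sizes <- rowSums(object$counts)
  to_sizes <- colSums(object$counts)
  pf <- pos(rownames(object$counts), from_sizes)
  pt <- pos(colnames(object$counts), to_sizes)
  # band offsets within each box
  long <- long %>%
    arrange(.data$from, .data$to) %>%
    group_by(.data$from) %>%
    mutate(f1 = cumsum(.data$n), f0 = .data$f1 - .data$n) %>%
    dplyr::ungroup() %>%
    arrange(.data$to, .data$from) %>%
    group_by(.data$to) %>%
    mutate(t1 = cumsum(.data$n), t0 = .data$t1 - .data$n) %>%
    dplyr::ungroup()
  long <- long %>%
    dplyr::left_join(pf, by = c(from = "label")) %>%
    dplyr::rename(fy0 = "y0", fy1 = "y1") %>%
    dplyr::left_join(pt, by = c(to = "label")) %>%
    dplyr::rename(ty0 = "y0", ty1 = "y1")
  ribbons <- dplyr::bind_rows(
    dplyr::transmute(long, band = paste(.data$from, .data$to), x = 0.05,
                     ymin = .data$fy0 + .data$f0, ymax = .data$fy0 + .data$f1),
    dplyr::transmute(long, band = paste(.data$from, .data$to), x = 0.95,
                     ymin = .data$ty0 + .data$t0, ymax = .data$ty0 + .data$t1))
  boxes <- dplyr::bind_rows(
    dplyr::mutate(pf, x0 = 0, x1 = 0.05),
    dplyr::mutate(pt, x0 = 0.95, x1 = 1))
  ggplot2::ggplot() +
    ggplot2::geom_ribbon(data = ribbons,
                         ggplot2::aes(x = .data$x, ymin = .data$ymin,
                                      ymax = .data$ymax, group = .data$band),
                         fill = "grey80", colour = "grey50", alpha = 0.8) +
    ggplot2::geom_rect(data = boxes,
                       ggplot2::aes(xmin = .data$x0, xmax = .data$x1,
                                    ymin = .data$y0, ymax = .data$y1),
                       fill = "steelblue", colour = "black") +
    ggplot2::geom_text(data = boxes,
                       ggplot2::aes(x = (.data$x0 + .data$x1) / 2,
                                    y = (.data$y0 + .data$y1) / 2,
                                    label = .data$label), colour = "white") +
    ggplot2::labs(x = NULL, y = "individuals") +
    ggplot2::theme_void()
}

#' @describeIn lca_fit `autoplot()` tile map of fitted genotype-category
#'   probabilities per class.
#' @param object An `lca_model`.
#' @exportS3Method ggplot2::autoplot
autoplot.lca_model <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(.data$snp_id, factor(.data$genotype),
                                   fill = .data$estimate)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~class, ncol = 1,
                        labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "genotype", fill = "probability") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @describeIn fit_forest `autoplot()` dot plot of both importance measures.
#' @param object A `forest_report`.
#' @exportS3Method ggplot2::autoplot
autoplot.forest_report <- function(object, ...) {
  td <- tidyr::pivot_longer(object$importance, c("mda", "gini"),
                            names_to = "measure", values_to = "importance")
  ggplot2::ggplot(td, ggplot2::aes(.data$importance,
                                   stats::reorder(.data$feature,
                                                  .data$importance))) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~measure, scales = "free_x") +
    ggplot2::labs(y = NULL) +
    ggplot2::theme_minimal()
}
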