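#' Plot a contig mosaic
#'
#' Renders the per-gene taxonomic track of a contig: one coloured block per
#' ORF (colour = class), grey intergenic gaps.
#'
#' @param object An `lgt_mosaic` tibble from [contig_mosaic()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lgt_mosaic
#' @export
autoplot.lgt_mosaic <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object))
  df$fill <- ifelse(df$feature == "intergenic", "intergenic",
                    dplyr::coalesce(df$class, "unclassified"))
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start, xmax = .data$end, ymin = 0, ymax = 1,
      fill = .data$fill)) +
    ggplot2::scale_fill_brewer(palette = "Set2", na.value = "grey80") +
    ggplot2::facet_wrap(~contig_id, ncol = 1) +
    ggplot2::labs(x = "position (nt)", fill = "class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.title.y = ggplot2::element_blank())
}

#' Plot a genetic-exchange network
#'
#' Classes are laid out on a circle; directed edges (discordance calls) are
#' drawn as arrows from donor to recipient, undirected edges (phylogenetic
#' calls) as plain segments; width encodes multiplicity.
#'
#' @param object An `lgt_exchange_network` tibble.
#' @param ... Unused.
#' @return A ggplot object (facetted by pathway).
#' @method autoplot lgt_exchange_network
#' @export
autoplot.lgt_exchange_network <- function(object, ...) {
  net <- tibble::as_tibble(unclass(object))
  if (!nrow(net)) stop("empty exchange network")
  nodes <- sort(unique(c(net$from, net$to)))
  ang <- seq(0, 2 * pi, length.out = length(nodes) + 1L)[seq_along(nodes)]
  pos <- tibble::tibble(node = nodes, x = cos(ang), y = sin(ang))
  net <- net |>
    dplyr::left_join(pos, by = c(from = "node")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(pos, by = c(to = "node"))
  ggplot2::ggplot(net) +
    ggplot2::geom_segment(
      data = ~dplyr::filter(.x, .data$directed),
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x,
                   yend = .data$y, linewidth = .data$multiplicity),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.12, "inches")),
      colour = "steelblue") +
    ggplot2::geom_segment(
      data = ~dplyr::filter(.x, !.data$directed),
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x,
                   yend = .data$y, linewidth = .data$multiplicity),
      colour = "grey50", linetype = "dashed") +
    ggplot2::geom_label(data = pos,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     label = .data$node), size = 3) +
    ggplot2::scale_linewidth(range = c(0.4, 2)) +
    ggplot2::facet_wrap(~pathway) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(linewidth = "transfers")
}
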