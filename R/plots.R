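#' Plot a Bayesian skyline
#'
#' Median scaled population size (fNe*mu) against time before present
#' (substitutions/site), with the 95% HPD ribbon.
#'
#' @param object a `skyline_fit`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.skyline_fit <- function(object, ...) {
  sk <- object$skyline
  ggplot2::ggplot(sk, ggplot2::aes(x = .data$time, y = .data$median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$hpd_lower,
                                      ymax = .data$hpd_upper),
                         fill = "grey80") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time before present (substitutions/site)",
                  y = "scaled population size (fNeμ)",
                  title = "Bayesian skyline")
}

#' Plot a haplotype network
#'
#' Simple force-free layout: sampled haplotypes as circles scaled by count,
#' inferred intermediates as small points. Coordinates come from a
#' deterministic radial embedding per component (hub-centred), adequate for
#' inspecting star-likeness.
#'
#' @param object a `haplotype_network`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.haplotype_network <- function(object, ...) {
  lay <- network_layout(object)
  edges <- object$edges %>%
    dplyr::left_join(lay, by = c(node_a = "node")) %>%
    dplyr::rename(xa = "x", ya = "y") %>%
    dplyr::left_join(lay, by = c(node_b = "node")) %>%
    dplyr::rename(xb = "x", yb = "y")
  nodes <- dplyr::left_join(tidy(object), lay, by = "node")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$xa, y = .data$ya,
                                       xend = .data$xb, yend = .data$yb),
                          colour = "grey50") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$count,
                                     shape = .data$is_inferred)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1)) +
    ggplot2::theme_void() +
    ggplot2::labs(title = sprintf("haplotype network (star score %.2f)",
                                  star_score(object)))
}

# deterministic radial layout: BFS rings around each component's hub
network_layout <- function(net) {
  deg <- network_degrees(net)
  out <- NULL
  for (comp in unique(net$nodes$component)) {
    ids <- net$nodes$node[net$nodes$component == comp]
    dsub <- deg[deg$node %in% ids, ]
    hub <- dsub$node[which.max(dsub$degree)]
    depth <- setNames(rep(NA_integer_, length(ids)), ids)
    depth[hub] <- 0L
    frontier <- hub
    while (length(frontier)) {
      nxt <- unique(c(
        net$edges$node_b[net$edges$node_a %in% frontier],
        net$edges$node_a[net$edges$node_b %in% frontier]))
      nxt <- nxt[nxt %in% ids & is.na(depth[nxt])]
      if (!length(nxt)) break
      depth[nxt] <- depth[frontier[1]] + 1L
      frontier <- nxt
    }
    depth[is.na(depth)] <- max(depth, na.rm = TRUE) + 1L
    xoff <- (comp - 1) * (2 * max(depth) + 3)
    pos <- purrr::map_dfr(ids, function(id) {
      ring <- depth[[id]]
      ring_ids <- names(depth)[depth == ring]
      i <- match(id, ring_ids)
      ang <- 2 * pi * i / length(ring_ids)
      tibble(node = id, x = xoff + ring * cos(ang), y = ring * sin(ang))
    })
    out <- dplyr::bind_rows(out, pos)
  }
  out
}

#' Plot a genetic landscape surface
#'
#' @param object a `landscape_surface` from [interpolate_surface()].
#' @param ... unused.
#' @return A ggplot raster of interpolated residual genetic distance.
#' @export
autoplot.landscape_surface <- function(object, ...) {
  ggplot2::ggplot(object[!object$masked, ],
                  ggplot2::aes(x = .data$lon, y = .data$lat,
                               fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "residual\ngenetic distance") +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "longitude", y = "latitude",
                  title = "genetic landscape shape interpolation")
}
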