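#' Plot zone-scale occurrence counts
#'
#' Boxplots of per-plot occurrence counts by guild and tree zone — the
#' descriptive companion of [zone_contrasts()].
#'
#' @param ds A `forest_dataset`.
#' @return A ggplot.
#' @export
plot_zone_occurrences <- function(ds) {
  zone_occurrences(ds) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$zone, y = .data$n,
                                 fill = .data$guild)) +
    ggplot2::geom_boxplot(position = "dodge") +
    ggplot2::labs(x = "tree zone", y = "occurrences per plot", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_zone_occurrences
#' @param object A `forest_dataset`.
#' @param ... Unused.
#' @export
autoplot.forest_dataset <- function(object, ...) plot_zone_occurrences(object)

#' Ring-K envelope plot
#'
#' Observed ring-differenced cross-K with the Monte Carlo envelope;
#' radii where the observed curve leaves the band are highlighted.
#'
#' @param object A `ring_k_envelope`.
#' @param ... Unused.
#' @export
autoplot.ring_k_envelope <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "firebrick", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed)) +
    ggplot2::geom_point(data = df[df$exceed, ],
                        ggplot2::aes(y = .data$observed), colour = "firebrick") +
    ggplot2::labs(
      x = "radius r (m)",
      y = sprintf("ring K(r) (width %g m)", attr(object, "ring_width")),
      title = sprintf("%s-host to %s-host association vs covariate-adjusted null",
                      attr(object, "from_mark"), attr(object, "to_mark"))) +
    ggplot2::theme_minimal()
}

#' Bipartite interaction web plot
#'
#' Two-column web: row species left, column species right, link width
#' proportional to interaction weight.
#'
#' @param object A `bipartite_matrix`.
#' @param ... Unused.
#' @export
autoplot.bipartite_matrix <- function(object, ...) {
  rep_ <- network_report(object, top_k = nrow(object))
  rw <- setNames(seq_len(nrow(rep_$rows)), rep_$rows$species)
  cl <- setNames(seq_len(nrow(rep_$cols)), rep_$cols$species)
  links <- as_tibble(as.data.frame.table(unclass(object),
                                         stringsAsFactors = FALSE))
  names(links) <- c("row_species", "col_species", "weight")
  links <- filter(links, .data$weight > 0) %>%
    mutate(y0 = rw[.data$row_species] * (max(cl) / max(rw)),
           y1 = cl[.data$col_species])
  ggplot2::ggplot(links) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = 1, y = .data$y0,
                                       yend = .data$y1,
                                       linewidth = .data$weight),
                          alpha = 0.5, colour = "grey40") +
    ggplot2::geom_text(data = distinct(links, .data$row_species, .data$y0),
                       ggplot2::aes(x = -0.02, y = .data$y0,
                                    label = .data$row_species), hjust = 1,
                       size = 3) +
    ggplot2::geom_text(data = distinct(links, .data$col_species, .data$y1),
                       ggplot2::aes(x = 1.02, y = .data$y1,
                                    label = .data$col_species), hjust = 0,
                       size = 3) +
    ggplot2::scale_linewidth(range = c(0.2, 3)) +
    ggplot2::xlim(-0.6, 1.6) +
    ggplot2::theme_void() +
    ggplot2::labs(linewidth = attr(object, "weight_kind"))
}

#' Marginal response curves plot
#'
#' Posterior expected response over dbh per forest type, from
#' [marginal_curves()].
#'
#' @param object A `host_model_fit`.
#' @param ... Passed to [marginal_curves()].
#' @export
autoplot.host_model_fit <- function(object, ...) {
  marginal_curves(object, ...) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$dbh, y = .data$mean,
                                 colour = .data$forest_type,
                                 fill = .data$forest_type)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                      ymax = .data$conf.high),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "dbh (cm)", y = object$spec$response,
                  colour = "forest type", fill = "forest type") +
    ggplot2::theme_minimal()
}
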