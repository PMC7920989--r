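#' Heatmap of a host-range table
#'
#' Tile heatmap of the lysis scores (or 0/1 cells) with bacteria on rows and
#' phages on columns, in the table's current order.
#'
#' @param data host-range tibble.
#' @return a ggplot object.
#' @export
plot_host_range <- function(data) {
  m <- hr_matrix(data)
  df <- as_tibble(as.data.frame.table(m, responseName = "score",
                                      stringsAsFactors = FALSE)) |>
    rename(bacterium = "Var1", phage = "Var2") |>
    mutate(bacterium = factor(.data$bacterium, levels = rev(rownames(m))),
           phage = factor(.data$phage, levels = colnames(m)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phage, y = .data$bacterium,
                                   fill = .data$score)) +
    ggplot2::geom_tile(colour = "grey85", linewidth = 0.1) +
    ggplot2::scale_fill_gradient(low = "white", high = "#8A0F62") +
    ggplot2::labs(x = "phage", y = "bacterium", fill = "lysis") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot a packed matrix with its isocline of perfect order
#'
#' Tiles of the packed binary matrix with the isocline overlaid; unexpected
#' cells (presences beyond the isocline, absences inside it) are outlined.
#'
#' @param object a `pbin_nestedness` object.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pbin_nestedness <- function(object, ...) {
  m <- hr_matrix(object$packed)
  R <- nrow(m); C <- ncol(m)
  df <- as_tibble(as.data.frame.table(m, responseName = "cell",
                                      stringsAsFactors = FALSE)) |>
    rename(bacterium = "Var1", phage = "Var2") |>
    mutate(col = match(.data$phage, colnames(m)),
           row = match(.data$bacterium, rownames(m)))
  xs <- seq(1e-3, 1 - 1e-3, length.out = 200)
  iso_df <- tibble(x = xs * C + 0.5 - 0.5,
                   y = isocline_y(object$isocline, xs) * R + 0.5 - 0.5)
  unexp <- object$unexpected
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_tile(ggplot2::aes(fill = factor(.data$cell)),
                       colour = "grey85", linewidth = 0.1) +
    ggplot2::geom_line(data = iso_df,
                       ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "#2166AC", linewidth = 0.8,
                       inherit.aes = FALSE) +
    ggplot2::scale_fill_manual(values = c(`0` = "white", `1` = "#8A0F62")) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "phage (packed order)", y = "bacterium (packed order)",
                  fill = "lysis",
                  title = sprintf("T = %.3g, f = %.3g%% (%s)",
                                  object$temperature, object$fill,
                                  object$method)) +
    ggplot2::theme_minimal()
  if (nrow(unexp) > 0L) {
    p <- p + ggplot2::geom_tile(data = unexp,
                                ggplot2::aes(x = .data$col, y = .data$row),
                                fill = NA, colour = "#E08214",
                                linewidth = 0.5, inherit.aes = FALSE)
  }
  p
}

#' Elbow plot for a phage clustering
#'
#' Within-cluster sum of squares against k, with the elbow-selected k marked.
#'
#' @param object a `phage_clusters` object.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.phage_clusters <- function(object, ...) {
  df <- tibble(k = seq_along(object$wss), wss = object$wss)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$wss)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k, linetype = "dashed",
                        colour = "#2166AC") +
    ggplot2::labs(x = "number of clusters k",
                  y = "total within-cluster sum of squares",
                  title = sprintf("elbow at k = %d", object$k)) +
    ggplot2::theme_minimal()
}

#' Per-strain expected virulence of a cocktail
#'
#' @param object a `cocktail_design` object.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cocktail_design <- function(object, ...) {
  df <- object$virulence |>
    mutate(bacterium = factor(.data$bacterium, levels = .data$bacterium))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bacterium,
                                   y = .data$virulence_max)) +
    ggplot2::geom_col(fill = "#8A0F62") +
    ggplot2::labs(x = "bacterium", y = "expected virulence (best phage)",
                  title = sprintf("cocktail of %d phages, coverage %.3g%%",
                                  object$phi, object$coverage)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
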