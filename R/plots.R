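#' Heatmap of DT-Hybrid recommendation scores
#'
#' Tiles drugs by targets, colouring by score; validated interactions are
#' outlined so novel high-scoring cells stand out.
#'
#' @param object A `dthybrid_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dthybrid_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$target_id, y = .data$drug_id)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$score)) +
    ggplot2::geom_tile(
      data = df[df$known, ], fill = NA,
      colour = "white", linewidth = 0.4
    ) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "target", y = "drug", fill = "score",
                  title = "DT-Hybrid recommendation scores",
                  subtitle = "validated interactions outlined") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Per-drug score profile of top predictions
#'
#' @param predictions Output of [rank_predictions()] or
#'   [score_significance()].
#' @param drugs Optional drug identifiers to show (default: first 6).
#' @return A ggplot object.
#' @export
plot_prediction_scores <- function(predictions, drugs = NULL) {
  predictions <- as_tibble(predictions)
  drugs <- drugs %||% head(unique(predictions$drug_id), 6)
  df <- predictions[predictions$drug_id %in% drugs, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$target_id, .data$score),
    y = .data$score
  ))
  if ("in_best_subset" %in% names(df)) {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = .data$in_best_subset)) +
      ggplot2::labs(fill = "in best subset")
  } else {
    p <- p + ggplot2::geom_col()
  }
  p +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~drug_id, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "DT-Hybrid score",
                  title = "Top predicted targets per drug") +
    ggplot2::theme_minimal()
}

#' Gene-coverage map of a combination query
#'
#' Shows which candidate target reaches which user gene and at what
#' distance; members of the greedy minimal set are marked.
#'
#' @param object A `combination_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.combination_result <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::distinct(.data$target_id, .data$gene, .data$distance,
                    .data$in_minimal_set)
  if (nrow(df) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0, label = object$status) +
             ggplot2::theme_void())
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$target_id)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$distance)) +
    ggplot2::geom_point(data = df[df$in_minimal_set, ], size = 1,
                        colour = "red") +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = "user gene", y = "candidate target",
                  fill = "distance (edges)",
                  title = "Candidate targets covering the gene list",
                  subtitle = "red dot = greedy minimal set") +
    ggplot2::theme_minimal()
}
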