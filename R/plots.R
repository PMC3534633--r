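#' Precision/Recall curve of a pipeline report
#'
#' One curve per ternary threshold (baseline drawn dashed), points along the
#' inflation grid; finer granularity (higher inflation) moves points toward
#' high precision / low recall.
#'
#' @param report A [run_pipeline()] report with metrics columns.
#' @return A ggplot object.
#' @export
plot_pr_curve <- function(report) {
  stopifnot(all(c("recall", "precision") %in% names(report)))
  df <- dplyr::mutate(
    report,
    reduction = dplyr::if_else(
      is.na(.data$t), "none", sprintf("T = %.2f", .data$t)
    )
  )
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data$recall, y = .data$precision,
      colour = .data$reduction,
      linetype = is.na(.data$t)
    )
  ) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_linetype_manual(
      values = c(`TRUE` = "dashed", `FALSE` = "solid"), guide = "none"
    ) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Recall", y = "Precision", colour = "Ternary threshold",
      title = "Precision/Recall across the inflation grid"
    ) +
    ggplot2::theme_minimal()
}

#' Clustering granularity against inflation
#'
#' Largest cluster size as a function of the MCL inflation parameter, one
#' curve per ternary threshold (baseline dashed).
#'
#' @param profile A [granularity_profile()] (or pipeline report) tibble.
#' @return A ggplot object.
#' @export
plot_granularity <- function(profile) {
  df <- dplyr::mutate(
    profile,
    reduction = dplyr::if_else(
      is.na(.data$t), "none", sprintf("T = %.2f", .data$t)
    )
  )
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data$inflation, y = .data$max_cluster_size,
      colour = .data$reduction, linetype = is.na(.data$t)
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(
      values = c(`TRUE` = "dashed", `FALSE` = "solid"), guide = "none"
    ) +
    ggplot2::labs(
      x = "Inflation I", y = "Largest cluster size",
      colour = "Ternary threshold",
      title = "Clustering granularity"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the reduction trace
#'
#' Remaining marked line-graph edges after each greedy iteration, annotated
#' with the batch degree.
#'
#' @param object A `tern_reduction`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tern_reduction <- function(object, ...) {
  tr <- tidy(object)
  ggplot2::ggplot(
    tr, ggplot2::aes(x = .data$iteration, y = .data$n_marked_remaining)
  ) +
    ggplot2::geom_step() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_removed)) +
    ggplot2::labs(
      x = "Iteration", y = "Marked edges remaining", size = "Edges removed",
      title = sprintf("Greedy ternary reduction (t = %s)", format(object$t))
    ) +
    ggplot2::theme_minimal()
}

#' Plot cluster sizes of a partition
#'
#' @param object A `tern_partition`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tern_partition <- function(object, ...) {
  sizes <- dplyr::count(tibble::as_tibble(object), .data$cluster, name = "size")
  ggplot2::ggplot(
    sizes,
    ggplot2::aes(x = stats::reorder(.data$cluster, -.data$size), y = .data$size)
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Cluster", y = "Items", title = "Cluster sizes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
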