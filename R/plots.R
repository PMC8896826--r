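# ggplot2 views of the main result types.

#' Overlaid patristic-distance distributions: full set vs selected subset
#'
#' The visual representativeness check: density of distances from the focal
#' leaf for all orthologs against the same density for the selected subset.
#'
#' @param matrix Patristic matrix or `phylo` tree.
#' @param focal Focal leaf label.
#' @param selected Selected leaves (`representative_set`, data frame with a
#'   `leaf` column, or character vector).
#' @return A ggplot object.
#' @export
plot_distance_distributions <- function(matrix, focal, selected) {
  m <- as_patristic(matrix)
  full <- distances_from(m, focal)
  sel <- setdiff(selected_leaves(selected), focal)
  df <- dplyr::bind_rows(
    dplyr::mutate(full, set = "full"),
    dplyr::mutate(full[full$leaf %in% sel, ], set = "selected")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance, colour = .data$set)) +
    ggplot2::geom_density() +
    ggplot2::labs(
      x = paste0("patristic distance from ", focal, " (subst./site)"),
      y = "density", colour = NULL,
      title = "Distance distribution: full ortholog set vs selected subset"
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_distance_distributions Density view of a computed
#'   representativeness report.
#' @param object A `representativeness_report`.
#' @param ... Unused.
#' @export
autoplot.representativeness_report <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(distance = object$full, set = "full"),
    tibble::tibble(distance = object$selected, set = "selected")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance, colour = .data$set)) +
    ggplot2::geom_density() +
    ggplot2::labs(
      x = paste0("patristic distance from ", object$focal, " (subst./site)"),
      y = "density", colour = NULL,
      subtitle = paste0("two-sided rank-sum p = ",
                        signif(object$p_two_sided, 4))
    ) +
    ggplot2::theme_minimal()
}

#' Plot an outcome vs distance association
#'
#' Distances from the focal leaf by binarized outcome group, with the
#' correlation ratio in the subtitle.
#'
#' @param object An `outcome_association`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.outcome_association <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$outcome, y = .data$distance)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.6) +
    ggplot2::labs(
      x = object$outcome_column,
      y = paste0("patristic distance from ", object$focal),
      subtitle = paste0("eta = ", signif(object$eta$eta, 3),
                        ", rank-sum p = ", signif(object$rank_test$p_value, 3))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a permutation null for eta
#'
#' Histogram of permuted eta values with the observed eta marked.
#'
#' @param object An `eta_null`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eta_null <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(eta = object$null), ggplot2::aes(x = .data$eta)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(
      x = "eta under label permutation", y = "count",
      subtitle = paste0("observed eta = ", signif(object$observed, 3),
                        " (percentile ", signif(object$percentile, 3), ")")
    ) +
    ggplot2::theme_minimal()
}
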