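#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an rf_experiment: the serial feature-addition curve
#'
#' @param x An `rf_experiment`.
#' @param ... Unused.
#' @return Tibble `k`, `feature`, `cv_accuracy`, `optimal` (logical marker
#'   of the selected k).
#' @export
tidy.rf_experiment <- function(x, ...) {
  dplyr::mutate(tibble::as_tibble(x$curve), optimal = .data$k == x$optimal_k)
}

#' One-row summary of an rf_experiment
#'
#' @inheritParams tidy.rf_experiment
#' @return Tibble `ref_pop`, `target_pop`, `mode`, `n_subjects`,
#'   `n_features`, `optimal_k`, `accuracy`, `max_accuracy`, `seed`.
#' @export
glance.rf_experiment <- function(x, ...) {
  tibble::tibble(ref_pop = x$ref_pop, target_pop = x$target_pop, mode = x$mode,
                 n_subjects = x$n_subjects, n_features = nrow(x$curve),
                 optimal_k = x$optimal_k, accuracy = x$accuracy,
                 max_accuracy = max(x$curve$cv_accuracy), seed = x$seed)
}

#' Tidy an fst_result
#'
#' @param x An `fst_result`.
#' @param ... Unused.
#' @return One-row tibble `gene`, `pop_a`, `pop_b`, `theta`, `p_value`,
#'   `n_perm`.
#' @export
tidy.fst_result <- function(x, ...) {
  tibble::tibble(gene = x$gene, pop_a = x$pop_a, pop_b = x$pop_b,
                 theta = x$theta, p_value = x$p_value,
                 n_perm = length(x$perm_values))
}

#' Tidy a dapc_result: subject coordinates on the discriminant axes
#'
#' @param x A `dapc_result`.
#' @param ... Unused.
#' @export
tidy.dapc_result <- function(x, ...) x$coords

#' One-row summary of a dapc_result
#'
#' @inheritParams tidy.dapc_result
#' @return Tibble `n_pca`, `var_explained`, `n_axes`, `mean_centroid_dist`.
#' @export
glance.dapc_result <- function(x, ...) {
  tibble::tibble(n_pca = x$n_pca, var_explained = x$var_explained,
                 n_axes = sum(startsWith(names(x$coords), "LD")),
                 mean_centroid_dist = mean(x$centroid_dist$distance))
}

#' Plot the serial feature-addition accuracy curve
#'
#' @param object An `rf_experiment`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rf_experiment <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$cv_accuracy)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$optimal), size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::labs(
      x = "number of top-ranked features",
      y = "10-fold CV accuracy",
      title = sprintf("%s (ref) vs %s (target), %s mode",
                      object$ref_pop, object$target_pop, object$mode)
    ) +
    ggplot2::theme_minimal()
}

#' Plot subjects on the first two discriminant axes
#'
#' @param object A `dapc_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dapc_result <- function(object, ...) {
  df <- object$coords
  if (!"LD2" %in% names(df)) df$LD2 <- 0
  cen <- object$centroids
  if (!"LD2" %in% names(cen)) cen$LD2 <- 0
  ggplot2::ggplot(df, ggplot2::aes(x = .data$LD1, y = .data$LD2,
                                   colour = .data$population)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_point(data = cen, shape = 4, size = 4, stroke = 2) +
    ggplot2::labs(x = "discriminant axis 1", y = "discriminant axis 2") +
    ggplot2::theme_minimal()
}

#' Heatmap-style plot of an accuracy matrix
#'
#' @param acc Tibble from [accuracy_matrix()].
#' @return A ggplot with reference populations as rows, targets as columns,
#'   tiles labelled `accuracy (optimal_k)`.
#' @export
plot_accuracy_matrix <- function(acc) {
  ggplot2::ggplot(acc, ggplot2::aes(x = .data$target_pop, y = .data$ref_pop,
                                    fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f (%d)", .data$accuracy, .data$optimal_k))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0.5, 1)) +
    ggplot2::facet_wrap(~mode) +
    ggplot2::labs(x = "target population", y = "reference population") +
    ggplot2::theme_minimal()
}
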