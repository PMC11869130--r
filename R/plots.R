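# ggplot2 displays for the result objects.

#' Plot generation metrics
#'
#' Bar chart of validity, uniqueness and novelty.
#'
#' @param object A `fluogen_metrics` row from [generation_metrics()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fluogen_metrics <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object[, c("validity", "uniqueness", "novelty")],
    dplyr::everything(), names_to = "metric", values_to = "fraction")
  df$metric <- factor(df$metric, levels = c("validity", "uniqueness",
                                            "novelty"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$fraction)) +
    ggplot2::geom_col(fill = "#4477aa") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "fraction") +
    ggplot2::theme_minimal()
}

#' Plot a chemical-space map
#'
#' Reference molecules in gray, database molecules matching the target in
#' blue, generated molecules in red.
#'
#' @param object A `fluogen_chemspace` tibble from [chemical_space_map()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fluogen_chemspace <- function(object, ...) {
  cols <- c(reference = "gray70", matched = "#4477aa", generated = "#cc3311")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$x, y = .data$y,
                               color = .data$group)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.2) +
    ggplot2::scale_color_manual(values = cols) +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2", color = NULL) +
    ggplot2::theme_minimal()
}

#' Property distributions of generated molecules against a target
#'
#' Histograms of oracle-scored properties of a generated set, with the
#' target values as dashed vertical lines; optionally overlaid on the
#' distribution of a reference database.
#'
#' @param scored A tibble with the seven property columns (e.g. oracle
#'   scores of generated molecules).
#' @param target The target condition.
#' @param reference Optional reference tibble with the same columns.
#' @return A ggplot object (faceted by property).
#' @export
plot_property_distributions <- function(scored, target = NULL,
                                        reference = NULL) {
  pick <- function(df, lab) {
    tidyr::pivot_longer(df[, intersect(PROPERTY_NAMES, names(df))],
                        dplyr::everything(), names_to = "property",
                        values_to = "value") |>
      dplyr::mutate(set = lab)
  }
  df <- pick(scored, "generated")
  if (!is.null(reference)) df <- dplyr::bind_rows(df, pick(reference,
                                                           "reference"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$value,
                                        fill = .data$set)) +
    ggplot2::geom_histogram(position = "identity", alpha = 0.55, bins = 30) +
    ggplot2::facet_wrap(~property, scales = "free") +
    ggplot2::scale_fill_manual(values = c(generated = "#cc3311",
                                          reference = "gray60")) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = "count", fill = NULL)
  if (!is.null(target)) {
    tv <- tibble::tibble(property = PROPERTY_NAMES,
                         value = unlist(as_condition(target)[PROPERTY_NAMES]))
    p <- p + ggplot2::geom_vline(data = tv,
                                 ggplot2::aes(xintercept = .data$value),
                                 linetype = "dashed")
  }
  p
}
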