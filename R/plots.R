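#' Volcano plot of differential results
#'
#' Plots `-log10(p)` against `log2` fold change, one panel per channel,
#' highlighting variables below the significance limit.
#'
#' @param results A differential-results tibble (from
#'   [test_compartments()] or [test_motility_groups()]) or a table from
#'   [volcano_table()].
#' @param alpha Significance limit drawn as a horizontal reference line.
#' @return A ggplot object.
#' @export
plot_volcano <- function(results, alpha = 0.001) {
  pts <- if ("neg_log10_p" %in% names(results)) results
         else volcano_table(results)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$log2fc, y = .data$neg_log10_p,
                                    colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$channel), scales = "free") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  title = unique(pts$comparison)[1]) +
    ggplot2::theme_minimal()
}

#' Stacked-bar plot of lipid-class composition
#'
#' Shows the mean per-mille abundance of each lipid class, stacked, one
#' bar per compartment (if a design is supplied) or per sample, faceted
#' by channel.
#'
#' @param class_table Output of [aggregate_by_class()].
#' @param design Optional design table (`sample_id`, `compartment`) used
#'   to average samples within compartments.
#' @return A ggplot object.
#' @export
plot_class_abundance <- function(class_table, design = NULL) {
  d <- class_table
  if (!is.null(design)) {
    d <- d |>
      dplyr::inner_join(dplyr::distinct(design, .data$sample_id,
                                        .data$compartment),
                        by = "sample_id") |>
      dplyr::group_by(.data$compartment, .data$channel, .data$class) |>
      dplyr::summarise(per_mille = mean(.data$per_mille), .groups = "drop") |>
      dplyr::rename(unit = "compartment")
  } else {
    d <- dplyr::rename(d, unit = "sample_id")
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$unit, y = .data$per_mille,
                                  fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = NULL, y = "abundance (per mille)", fill = "class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
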