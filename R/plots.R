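# ggplot2 views of the result objects.

#' Plot log2 fold changes per cell line
#'
#' Bar chart of log2 fold change vs the control line, faceted by cell
#' line, filled by significance tier. Non-detectable miRs and the control
#' line's self-comparison are omitted.
#'
#' @param object A [quantify()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mir_quant
#' @export
autoplot.mir_quant <- function(object, ...) {
  s <- attr(object, "settings")
  df <- tidy(object) |>
    dplyr::filter(
      .data$cell_line != s$control_cell_line,
      !is.na(.data$log2_fc)
    ) |>
    dplyr::mutate(
      tier = factor(.data$tier, levels = c("ns", "*", "**", "***"))
    )
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$mir, y = .data$log2_fc, fill = .data$tier)
  ) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$cell_line)) +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL,
      y = paste0("log2 fold change vs ", s$control_cell_line),
      fill = "tier"
    ) +
    ggplot2::theme_minimal()
}

#' Plot 5p/3p arm preference
#'
#' Relative 3p expression (5p = 1) per family and cell line on a log2
#' scale; bars below 1 mean the 5p arm dominates. Not-applicable and
#' non-evaluable families are omitted.
#'
#' @param object An [arm_preference()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot arm_comparison
#' @export
autoplot.arm_comparison <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::filter(.data$evaluable, !is.na(.data$rel_expr_3p_vs_5p))
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data$family, y = .data$rel_expr_3p_vs_5p,
      fill = .data$preferred_arm
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linewidth = 0.3) +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::facet_wrap(ggplot2::vars(.data$cell_line)) +
    ggplot2::labs(
      x = NULL, y = "3p expression relative to 5p (fold)",
      fill = "preferred arm"
    ) +
    ggplot2::theme_minimal()
}

#' Plot stage-stratified alteration sets
#'
#' Gene-by-stage presence tiles from [stage_alteration_sets()].
#'
#' @param sets Output of [stage_alteration_sets()].
#' @return A ggplot object.
#' @export
plot_stage_sets <- function(sets) {
  df <- sets |>
    dplyr::mutate(
      stage_lab = paste0(.data$stage, " (N=", .data$n_patients, ")")
    ) |>
    tidyr::unnest_longer("genes", values_to = "gene")
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$stage_lab, y = .data$gene)
  ) +
    ggplot2::geom_tile(fill = "grey30") +
    ggplot2::labs(x = "stage", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the candidate-identification funnel
#'
#' Bar chart of gene counts surviving each funnel stage.
#'
#' @param object A [run_lead_identification()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lead_funnel
#' @export
autoplot.lead_funnel <- function(object, ...) {
  df <- object$stages |>
    dplyr::mutate(stage = factor(.data$stage, levels = .data$stage))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$n_out)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::geom_text(
      ggplot2::aes(label = .data$n_out), vjust = -0.4, size = 3
    ) +
    ggplot2::labs(x = NULL, y = "genes remaining") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
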