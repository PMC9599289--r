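# broom-style accessors for the fitted result objects.

#' Tidy a quantification result
#'
#' @param x A [quantify()] result.
#' @param ... Unused.
#' @return A plain tibble of the per-(cell line, miR) results.
#' @method tidy mir_quant
#' @export
tidy.mir_quant <- function(x, ...) {
  out <- x
  attr(out, "settings") <- NULL
  attr(out, "detectability") <- NULL
  attr(out, "dropped_samples") <- NULL
  attr(out, "control_failed_samples") <- NULL
  class(out) <- class(tibble::tibble())
  out
}

#' Summarize a quantification result in one row
#'
#' @param x A [quantify()] result.
#' @param ... Unused.
#' @return A one-row tibble: `control_cell_line`, `n_cell_lines`,
#'   `n_mirs`, `n_detectable`, `n_significant` (p <= 0.05 in any
#'   non-control line), `n_dropped_samples`.
#' @method glance mir_quant
#' @export
glance.mir_quant <- function(x, ...) {
  s <- attr(x, "settings")
  tibble::tibble(
    control_cell_line = s$control_cell_line,
    n_cell_lines = dplyr::n_distinct(x$cell_line),
    n_mirs = dplyr::n_distinct(x$mir),
    n_detectable = sum(x$detectable, na.rm = TRUE),
    n_significant = nrow(collate_significant(x)),
    n_dropped_samples = length(attr(x, "dropped_samples"))
  )
}

#' Tidy an arm-preference result
#'
#' @param x An [arm_preference()] result.
#' @param ... Unused.
#' @return A plain tibble.
#' @method tidy arm_comparison
#' @export
tidy.arm_comparison <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  out
}

#' Tidy a lead-identification funnel
#'
#' @param x A [run_lead_identification()] result.
#' @param ... Unused.
#' @return The stage-count tibble (`stage`, `n_in`, `n_out`).
#' @method tidy lead_funnel
#' @export
tidy.lead_funnel <- function(x, ...) {
  x$stages
}

#' Summarize a lead-identification funnel in one row
#'
#' @param x A [run_lead_identification()] result.
#' @param ... Unused.
#' @return A one-row tibble: `n_input_genes`, `n_panel`,
#'   `n_differential`, `n_mature`, `coverage`.
#' @method glance lead_funnel
#' @export
glance.lead_funnel <- function(x, ...) {
  tibble::tibble(
    n_input_genes = length(x$genes$input),
    n_panel = length(x$genes$panel_optimization),
    n_differential = length(x$genes$disease_differential),
    n_mature = length(x$mature),
    coverage = x$panel$coverage
  )
}
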