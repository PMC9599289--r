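# Stage-stratified alteration sets: which panel genes are altered in at
# least one patient of each tumor stage, and how the stage sets intersect.

#' Stage-stratified alteration sets
#'
#' For each tumor stage (I-IV), the set of panel genes altered in at least
#' one patient with that stage label. Patients with `stage = "unknown"` are
#' counted in overall coverage elsewhere but excluded from every stage set;
#' a stage with no patients maps to the empty set.
#'
#' @inheritParams alteration_frequency
#' @param panel Genes to stratify; defaults to all genes in the matrix.
#' @return A tibble with one row per stage I-IV: `stage`, `n_patients`,
#'   `genes` (list column, in panel order), `n_genes`.
#' @examples
#' sets <- stage_alteration_sets(pdac_stage_matrix())
#' sets
#' @export
stage_alteration_sets <- function(data, panel = NULL) {
  genes <- check_alteration_matrix(data)
  panel <- check_panel(as.character(panel %||% genes), genes)
  staged <- data[data$stage != "unknown", , drop = FALSE]
  purrr::map_dfr(c("I", "II", "III", "IV"), function(s) {
    rows <- staged[staged$stage == s, panel, drop = FALSE]
    present <- if (nrow(rows) > 0 && length(panel) > 0) {
      panel[colSums(rows) > 0]
    } else {
      character(0)
    }
    tibble::tibble(
      stage = s,
      n_patients = nrow(rows),
      genes = list(present),
      n_genes = length(present)
    )
  })
}

#' Genes altered in both of two stages
#'
#' Exact intersection of two stage alteration sets, returned sorted.
#'
#' @param sets Output of [stage_alteration_sets()].
#' @param stage_a,stage_b Stage labels present in `sets`.
#' @return Sorted character vector of shared gene symbols.
#' @examples
#' sets <- stage_alteration_sets(pdac_stage_matrix())
#' stage_overlap(sets, "I", "IV")
#' @export
stage_overlap <- function(sets, stage_a, stage_b) {
  if (!is.data.frame(sets) || !all(c("stage", "genes") %in% names(sets))) {
    abort("`sets` must be the output of stage_alteration_sets().")
  }
  for (s in c(stage_a, stage_b)) {
    if (length(s) != 1 || !s %in% sets$stage) {
      abort(paste0(
        "Unknown stage label '", s, "'. Available: ", toString(sets$stage)
      ))
    }
  }
  a <- sets$genes[[match(stage_a, sets$stage)]]
  b <- sets$genes[[match(stage_b, sets$stage)]]
  sort(intersect(a, b))
}

#' Serialize stage sets to JSON
#'
#' @param sets Output of [stage_alteration_sets()].
#' @return A JSON string: per stage, the patient count and the sorted gene
#'   set.
#' @export
stage_sets_json <- function(sets) {
  payload <- purrr::map(seq_len(nrow(sets)), function(i) {
    list(
      n_patients = sets$n_patients[[i]],
      genes = sort(sets$genes[[i]])
    )
  })
  names(payload) <- sets$stage
  jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE)
}

#' Serialize a panel evaluation to JSON
#'
#' @param evaluation One-row tibble from [panel_coverage()] or
#'   [select_panel()] (panel order is preserved).
#' @return A JSON string.
#' @export
panel_json <- function(evaluation) {
  stopifnot(is.data.frame(evaluation), nrow(evaluation) == 1)
  payload <- list(
    panel = evaluation$panel[[1]],
    n_genes = evaluation$n_genes[[1]],
    n_covered = evaluation$n_covered[[1]],
    n_patients = evaluation$n_patients[[1]],
    coverage = evaluation$coverage[[1]]
  )
  if ("method" %in% names(evaluation)) payload$method <- evaluation$method[[1]]
  jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE, digits = NA)
}
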