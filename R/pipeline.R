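# End-to-end orchestration: the candidate-identification funnel
# (alteration frequency -> exosomal -> coverage-optimized panel ->
# disease differential -> mature expansion) and the quantification
# workflow (censor -> filters -> ddCq -> tiers -> collation -> arm
# preference), plus schema validation for the three input file types.

empty_stage_error <- function(stage_name) {
  abort(
    paste0("Candidate funnel stage '", stage_name, "' produced zero genes."),
    class = "exomir_empty_result"
  )
}

#' Run the candidate-identification funnel
#'
#' Applies, in order: alteration-frequency filter, exosomal filter,
#' patient-coverage panel optimization, disease-differential filter, and
#' gene-to-mature-arm expansion. Every stage's input and output counts are
#' tracked; a stage yielding zero candidates is an error of class
#' `"exomir_empty_result"`.
#'
#' @param alteration Alteration matrix tibble (see
#'   [read_alteration_matrix()]).
#' @param annotation Annotation tibble covering every gene that reaches
#'   the exosomal stage.
#' @param min_fraction Minimum alteration frequency (default 0.10).
#' @param panel_size Coverage-optimized panel size `k` (default 18). If at
#'   least the number of exosomal candidates, the whole candidate set is
#'   kept.
#' @param exhaustive_limit Passed to [select_panel()].
#' @return An object of class `"lead_funnel"`: a list with `stages`
#'   (tibble: `stage`, `n_in`, `n_out`), `genes` (list of gene vectors per
#'   stage), `panel` (the [select_panel()] evaluation row), `mature`
#'   (final mature miR vector) and `params`.
#' @examples
#' \donttest{
#' demo <- demo_lead_dataset()
#' funnel <- run_lead_identification(demo$alteration, demo$annotation)
#' funnel$stages
#' }
#' @export
run_lead_identification <- function(alteration,
                                    annotation,
                                    min_fraction = 0.10,
                                    panel_size = 18,
                                    exhaustive_limit = 1e5) {
  all_genes <- check_alteration_matrix(alteration)
  if (length(all_genes) == 0) empty_stage_error("input")

  frequent <- filter_genes_by_frequency(alteration, min_fraction)$gene
  if (length(frequent) == 0) empty_stage_error("alteration_frequency")

  exosomal <- filter_exosomal(annotation, frequent)
  if (length(exosomal) == 0) empty_stage_error("exosomal")

  panel_eval <- select_panel(
    alteration,
    k = panel_size, candidates = exosomal,
    exhaustive_limit = exhaustive_limit
  )
  panel <- panel_eval$panel[[1]]
  if (length(panel) == 0) empty_stage_error("panel_optimization")

  differential <- filter_disease_differential(annotation, panel)
  if (length(differential) == 0) empty_stage_error("disease_differential")

  mature <- expand_to_mature(annotation, differential)
  if (length(mature) == 0) empty_stage_error("mature_expansion")

  genes <- list(
    input = all_genes,
    alteration_frequency = frequent,
    exosomal = exosomal,
    panel_optimization = panel,
    disease_differential = differential,
    mature_expansion = mature
  )
  n <- lengths(genes)
  stages <- tibble::tibble(
    stage = names(genes)[-1],
    n_in = unname(n[-length(n)]),
    n_out = unname(n[-1])
  )
  structure(
    list(
      stages = stages,
      genes = genes,
      panel = panel_eval,
      mature = mature,
      params = list(
        min_fraction = min_fraction,
        panel_size = panel_size,
        exhaustive_limit = exhaustive_limit,
        n_patients = nrow(alteration)
      )
    ),
    class = "lead_funnel"
  )
}

#' @export
print.lead_funnel <- function(x, ...) {
  p <- x$params
  cat(
    "<lead_funnel> ", p$n_patients, " patients; min alteration frequency ",
    p$min_fraction, "; panel size ", p$panel_size, "\n", sep = ""
  )
  for (i in seq_len(nrow(x$stages))) {
    cat(sprintf(
      "  %-22s %4d -> %4d\n",
      x$stages$stage[i], x$stages$n_in[i], x$stages$n_out[i]
    ))
  }
  cat(
    "  panel coverage: ", x$panel$n_covered, "/", x$panel$n_patients,
    " patients (", sprintf("%.1f%%", 100 * x$panel$coverage), ")\n",
    sep = ""
  )
  cat("  mature miRs:", toString(x$mature), "\n")
  invisible(x)
}

#' Run the quantification workflow
#'
#' Censoring, sample/assay filters, delta-delta-Cq quantification against
#' the control cell line, significance tiers and collation, and 5p/3p arm
#' preference, in one call. Deterministic for fixed inputs.
#'
#' @inheritParams quantify
#' @param alpha Significance level for collation and arm preference.
#' @param paired_arms Use the paired arm-preference test.
#' @return An object of class `"quant_report"`: a list with `quant` (the
#'   [quantify()] result), `significant` ([collate_significant()]), `arms`
#'   ([arm_preference()]), `arm_families` ([collate_arm_preferences()],
#'   control line excluded) and `settings`.
#' @export
run_quantification <- function(data,
                               control_cell_line,
                               control_assays = control_assay_names(),
                               cq_ceiling = 35,
                               cq_imputed = 36,
                               min_detected_fraction = 0.20,
                               alpha = 0.05,
                               remove_outliers = TRUE,
                               var_equal = TRUE,
                               paired_arms = FALSE) {
  quant <- quantify(
    data,
    control_cell_line = control_cell_line,
    control_assays = control_assays,
    cq_ceiling = cq_ceiling,
    cq_imputed = cq_imputed,
    min_detected_fraction = min_detected_fraction,
    remove_outliers = remove_outliers,
    var_equal = var_equal
  )
  significant <- collate_significant(quant, alpha = alpha)
  arms <- arm_preference(
    data,
    control_assays = control_assays,
    cq_ceiling = cq_ceiling,
    cq_imputed = cq_imputed,
    min_detected_fraction = min_detected_fraction,
    var_equal = var_equal,
    paired = paired_arms,
    alpha = alpha
  )
  arm_families <- collate_arm_preferences(
    arms,
    alpha = alpha, exclude_cell_lines = control_cell_line
  )
  structure(
    list(
      quant = quant,
      significant = significant,
      arms = arms,
      arm_families = arm_families,
      settings = attr(quant, "settings")
    ),
    class = "quant_report"
  )
}

#' @export
print.quant_report <- function(x, ...) {
  s <- x$settings
  cat(
    "<quant_report> vs '", s$control_cell_line, "'; ",
    nrow(x$quant), " (cell line, miR) comparisons\n", sep = ""
  )
  cat(
    "  significant miRs (any line):",
    if (nrow(x$significant) > 0) toString(x$significant$mir) else "none",
    "\n"
  )
  cat(
    "  arm-preference families:",
    if (nrow(x$arm_families) > 0) toString(x$arm_families$family) else "none",
    "\n"
  )
  invisible(x)
}

finding <- function(file, line, message) {
  tibble::tibble(file = file, line = as.integer(line), message = message)
}

validate_matrix_file <- function(path) {
  out <- finding(character(), integer(), character())
  raw <- readr::read_delim(
    path,
    delim = delim_for(path),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  miss <- setdiff(c("patient_id", "stage"), names(raw))
  if (length(miss) > 0) {
    return(finding(path, 1L, paste0("missing column(s): ", toString(miss))))
  }
  dup <- which(duplicated(raw$patient_id))
  for (i in dup) {
    out <- dplyr::bind_rows(out, finding(
      path, i + 1L, paste0("duplicated patient_id '", raw$patient_id[i], "'")
    ))
  }
  bad_stage <- which(!raw$stage %in% stage_labels())
  for (i in bad_stage) {
    out <- dplyr::bind_rows(out, finding(
      path, i + 1L,
      paste0(
        "invalid stage '", raw$stage[i], "'; allowed: ",
        toString(stage_labels())
      )
    ))
  }
  genes <- setdiff(names(raw), c("patient_id", "stage"))
  for (g in genes) {
    bad <- which(!raw[[g]] %in% c("0", "1"))
    for (i in bad) {
      out <- dplyr::bind_rows(out, finding(
        path, i + 1L,
        paste0("gene '", g, "' has non-0/1 entry '", raw[[g]][i], "'")
      ))
    }
  }
  out
}

validate_annotation_file <- function(path) {
  out <- finding(character(), integer(), character())
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  need <- c(
    "symbol", "exosomal", "dir_pancreatitis_vs_healthy",
    "dir_pdac_vs_pancreatitis", "mature_arms"
  )
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    return(finding(path, 1L, paste0("missing column(s): ", toString(miss))))
  }
  dup <- which(duplicated(raw$symbol))
  for (i in dup) {
    out <- dplyr::bind_rows(out, finding(
      path, i + 1L, paste0("duplicated symbol '", raw$symbol[i], "'")
    ))
  }
  bad_exo <- which(!raw$exosomal %in% c("0", "1"))
  for (i in bad_exo) {
    out <- dplyr::bind_rows(out, finding(
      path, i + 1L, paste0("exosomal must be 0/1, got '", raw$exosomal[i], "'")
    ))
  }
  for (col in c("dir_pancreatitis_vs_healthy", "dir_pdac_vs_pancreatitis")) {
    bad <- which(!raw[[col]] %in% direction_levels())
    for (i in bad) {
      out <- dplyr::bind_rows(out, finding(
        path, i + 1L,
        paste0(
          col, " must be one of ", toString(direction_levels()),
          ", got '", raw[[col]][i], "'"
        )
      ))
    }
  }
  out
}

validate_cq_file <- function(path) {
  out <- finding(character(), integer(), character())
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  need <- c(
    "sample_id", "cell_line", "biological_replicate",
    "technical_replicate", "assay", "cq"
  )
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    return(finding(path, 1L, paste0("missing column(s): ", toString(miss))))
  }
  key <- paste(raw$sample_id, raw$assay, raw$technical_replicate, sep = "\r")
  dup <- which(duplicated(key))
  for (i in dup) {
    out <- dplyr::bind_rows(out, finding(
      path, i + 1L,
      paste0(
        "duplicated well (", raw$sample_id[i], ", ", raw$assay[i],
        ", technical_replicate ", raw$technical_replicate[i], ")"
      )
    ))
  }
  chr <- trimws(ifelse(is.na(raw$cq), "", raw$cq))
  nd <- chr == "" | tolower(chr) == "undetermined"
  val <- suppressWarnings(as.numeric(chr))
  bad <- which(!nd & (is.na(val) | val <= 0 | !is.finite(val)))
  for (i in bad) {
    out <- dplyr::bind_rows(out, finding(
      path, i + 1L,
      paste0(
        "cq must be a positive number, empty, or 'Undetermined', got '",
        raw$cq[i], "'"
      )
    ))
  }
  out
}

#' Validate input files
#'
#' Schema, uniqueness and range checks for the three file types, with
#' line-numbered findings (line 1 is the header). Zero rows means every
#' supplied file is valid.
#'
#' @param alteration,annotation,cq Optional file paths; only supplied
#'   files are checked.
#' @return A tibble of findings: `file`, `line`, `message`.
#' @export
validate_inputs <- function(alteration = NULL, annotation = NULL, cq = NULL) {
  supplied <- c(alteration = alteration, annotation = annotation, cq = cq)
  for (path in supplied) {
    if (!file.exists(path)) {
      abort(paste0("Cannot read file: ", path))
    }
  }
  out <- finding(character(), integer(), character())
  if (!is.null(alteration)) {
    out <- dplyr::bind_rows(out, validate_matrix_file(alteration))
  }
  if (!is.null(annotation)) {
    out <- dplyr::bind_rows(out, validate_annotation_file(annotation))
  }
  if (!is.null(cq)) {
    out <- dplyr::bind_rows(out, validate_cq_file(cq))
  }
  out
}
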