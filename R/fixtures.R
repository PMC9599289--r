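# Deterministic fixtures encoding the published PDAC exosomal-miRNA study
# facts: the 18-gene and 10-gene panels, the stage-wise alteration pattern
# of the 109-patient UTSW cBioPortal cohort, the printed per-cell-line
# p-values, and a fully synthetic demonstration dataset calibrated to the
# published candidate-identification funnel.

#' The PDAC copy-number-alteration miRNA panels
#'
#' `"full"`: the 18 MIR genes altered in at least 10% of the UTSW PDAC
#' cohort, exosomal, and jointly covering 90% of patients. `"core"`: the
#' 10-gene subset carried into RT-qPCR validation.
#'
#' @param which `"full"` (18 genes) or `"core"` (10 genes).
#' @return Character vector of gene symbols.
#' @export
pdac_mir_panel <- function(which = c("full", "core")) {
  which <- match.arg(which)
  full <- c(
    "MIR27A", "MIR31", "MIR93", "MIR96", "MIR122", "MIR130B",
    "MIR133A1", "MIR203A", "MIR210", "MIR330", "MIR339", "MIR425",
    "MIR429", "MIR522", "MIR590", "MIR664A", "MIR1208", "MIR3620"
  )
  core <- c(
    "MIR31", "MIR93", "MIR133A1", "MIR210", "MIR330", "MIR339",
    "MIR425", "MIR429", "MIR1208", "MIR3620"
  )
  if (which == "full") full else core
}

#' Mature miRs encoded by the core 10-gene panel
#'
#' The 18 mature forms (5p/3p arms, plus the single-form miR-429 and
#' miR-1208) assayed in the cell-line validation.
#'
#' @return Character vector of 18 mature miR names.
#' @export
pdac_mature_mirs <- function() {
  c(
    "miR-31-5p", "miR-31-3p", "miR-93-5p", "miR-93-3p",
    "miR-133a-5p", "miR-133a-3p", "miR-210-5p", "miR-210-3p",
    "miR-330-5p", "miR-330-3p", "miR-339-5p", "miR-339-3p",
    "miR-425-5p", "miR-425-3p", "miR-429", "miR-1208",
    "miR-3620-5p", "miR-3620-3p"
  )
}

pdac_stage_gene_sets <- function() {
  list(
    I = c(
      "MIR27A", "MIR31", "MIR93", "MIR96", "MIR122", "MIR130B",
      "MIR203A", "MIR210", "MIR330", "MIR339", "MIR425", "MIR429",
      "MIR3620"
    ),
    II = pdac_mir_panel("full"),
    III = c(
      "MIR31", "MIR93", "MIR96", "MIR130B", "MIR133A1", "MIR210",
      "MIR330", "MIR429", "MIR522", "MIR590", "MIR1208"
    ),
    IV = c("MIR27A", "MIR203A", "MIR210", "MIR429", "MIR664A", "MIR1208")
  )
}

#' Deterministic stage-incidence alteration matrix (UTSW marginals)
#'
#' A minimal 109-patient alteration matrix over the 18-gene panel that
#' exactly reproduces the published stage-wise alteration pattern of the
#' UTSW PDAC cBioPortal cohort: stage populations 7/94/6/2 and, per stage,
#' the published set of altered genes (13 genes in stage I, all 18 in
#' stage II, 11 in stage III, 6 in stage IV). Each stage's alterations are
#' distributed round-robin over its patients, one altered gene per
#' patient-gene incidence; individual patient profiles are synthetic --
#' only the stage marginals and stage-wise gene sets are faithful.
#'
#' @return An alteration matrix tibble (109 patients x 18 genes).
#' @examples
#' stage_alteration_sets(pdac_stage_matrix())
#' @export
pdac_stage_matrix <- function() {
  genes <- pdac_mir_panel("full")
  sets <- pdac_stage_gene_sets()
  counts <- c(I = 7L, II = 94L, III = 6L, IV = 2L)
  rows <- purrr::map_dfr(names(counts), function(s) {
    n <- counts[[s]]
    alt <- matrix(0L, nrow = n, ncol = length(genes),
                  dimnames = list(NULL, genes))
    stage_genes <- sets[[s]]
    for (j in seq_along(stage_genes)) {
      alt[((j - 1L) %% n) + 1L, stage_genes[j]] <- 1L
    }
    dplyr::bind_cols(
      tibble::tibble(
        patient_id = sprintf("UTSW_%s_%03d", s, seq_len(n)),
        stage = s
      ),
      tibble::as_tibble(alt)
    )
  })
  rows
}

#' Annotation table for the 18-gene PDAC panel
#'
#' One row per panel gene, with the published facts: exosomal evidence
#' (all 18 passed the exosome-encyclopedia screen), expression direction
#' in chronic pancreatitis vs healthy tissue (8 genes down) and in PDAC vs
#' chronic pancreatitis (5 genes up), the annotated mature arms, and a
#' `panel10` flag marking the 10-gene core panel. Genes without a reported
#' direction in a contrast carry `"none"`.
#'
#' @return An annotation tibble (see [as_gene_annotation()]) with the
#'   extra `panel10` logical column.
#' @export
pdac_mir_annotation <- function() {
  down_pancreatitis <- c(
    "MIR31", "MIR96", "MIR130B", "MIR210", "MIR339", "MIR429",
    "MIR590", "MIR1208"
  )
  up_pdac <- c("MIR27A", "MIR31", "MIR93", "MIR130B", "MIR330")
  arms <- list(
    MIR27A = c("miR-27a-5p", "miR-27a-3p"),
    MIR31 = c("miR-31-5p", "miR-31-3p"),
    MIR93 = c("miR-93-5p", "miR-93-3p"),
    MIR96 = c("miR-96-5p", "miR-96-3p"),
    MIR122 = c("miR-122-5p", "miR-122-3p"),
    MIR130B = c("miR-130b-5p", "miR-130b-3p"),
    MIR133A1 = c("miR-133a-5p", "miR-133a-3p"),
    MIR203A = c("miR-203a-5p", "miR-203a-3p"),
    MIR210 = c("miR-210-5p", "miR-210-3p"),
    MIR330 = c("miR-330-5p", "miR-330-3p"),
    MIR339 = c("miR-339-5p", "miR-339-3p"),
    MIR425 = c("miR-425-5p", "miR-425-3p"),
    MIR429 = "miR-429",
    MIR522 = c("miR-522-5p", "miR-522-3p"),
    MIR590 = c("miR-590-5p", "miR-590-3p"),
    MIR664A = c("miR-664a-5p", "miR-664a-3p"),
    MIR1208 = "miR-1208",
    MIR3620 = c("miR-3620-5p", "miR-3620-3p")
  )
  genes <- pdac_mir_panel("full")
  tibble::tibble(
    symbol = genes,
    exosomal = TRUE,
    dir_pancreatitis_vs_healthy = ifelse(
      genes %in% down_pancreatitis, "down", "none"
    ),
    dir_pdac_vs_pancreatitis = ifelse(genes %in% up_pdac, "up", "none"),
    mature_arms = unname(arms[genes]),
    panel10 = genes %in% pdac_mir_panel("core")
  )
}

#' Published per-cell-line p-values of the 18 mature miRs
#'
#' The RT-qPCR significance results of the three PDAC cell lines (PANC1,
#' BXPC3, CAPAN2) vs the HPNE control: exact p-values where printed,
#' the printed significance bound (0.05 / 0.01 / 0.001) where only a tier
#' was reported, and `NA` with `detectable = FALSE` where the miR was not
#' detected in that line.
#'
#' @return A tibble with one row per (cell line, mature miR): `cell_line`,
#'   `mir`, `p_value`, `detectable`.
#' @examples
#' collate_significant(pdac_mir_pvalues())
#' @export
pdac_mir_pvalues <- function() {
  p <- list(
    # mir, PANC1, BXPC3, CAPAN2 (NA = not detected in that line)
    list("miR-31-5p", 0.05, 0.05, 0.001),
    list("miR-31-3p", 0.01, 0.05, 0.001),
    list("miR-93-5p", 0.0691, 0.0770, 0.2412),
    list("miR-93-3p", 0.7759, NA, NA),
    list("miR-133a-5p", NA, NA, NA),
    list("miR-133a-3p", 0.3000, NA, NA),
    list("miR-210-5p", NA, NA, NA),
    list("miR-210-3p", 0.05, 0.05, 0.9928),
    list("miR-330-5p", NA, NA, NA),
    list("miR-330-3p", NA, NA, NA),
    list("miR-339-5p", 0.1412, 0.001, 0.1499),
    list("miR-339-3p", 0.1416, NA, 0.9769),
    list("miR-425-5p", 0.001, 0.05, 0.05),
    list("miR-425-3p", 0.380, 0.05, 0.381),
    list("miR-429", NA, 0.01, 0.01),
    list("miR-1208", NA, NA, NA),
    list("miR-3620-5p", NA, NA, NA),
    list("miR-3620-3p", NA, NA, NA)
  )
  purrr::map_dfr(p, function(row) {
    tibble::tibble(
      cell_line = c("PANC1", "BXPC3", "CAPAN2"),
      mir = row[[1]],
      p_value = as.numeric(row[2:4])
    )
  }) |>
    dplyr::mutate(detectable = !is.na(.data$p_value)) |>
    dplyr::arrange(.data$cell_line, .data$mir)
}

#' Published 5p/3p arm-preference comparisons
#'
#' The reported arm-preference tests per (family, PDAC cell line): the
#' printed significance bound and preferred arm for the six significant
#' comparisons; `NA` p-values for family/line combinations not reported
#' as significant (exact values were not published).
#'
#' @return A tibble: `family`, `cell_line`, `p_value`, `preferred_arm`.
#' @examples
#' collate_arm_preferences(pdac_arm_pvalues())
#' @export
pdac_arm_pvalues <- function() {
  sig <- tibble::tribble(
    ~family, ~cell_line, ~p_value, ~preferred_arm,
    "miR-93", "PANC1", 0.01, "5p",
    "miR-93", "CAPAN2", 0.01, "5p",
    "miR-210", "PANC1", 0.01, "3p",
    "miR-339", "CAPAN2", 0.05, "5p",
    "miR-425", "PANC1", 0.05, "5p",
    "miR-425", "CAPAN2", 0.01, "5p"
  )
  two_arm <- c("miR-31", "miR-93", "miR-133a", "miR-210", "miR-330",
               "miR-339", "miR-425", "miR-3620")
  grid <- tidyr::expand_grid(
    family = two_arm,
    cell_line = c("PANC1", "BXPC3", "CAPAN2")
  )
  grid |>
    dplyr::left_join(sig, by = c("family", "cell_line")) |>
    dplyr::mutate(
      preferred_arm = dplyr::if_else(
        is.na(.data$p_value), NA_character_, .data$preferred_arm
      )
    ) |>
    dplyr::arrange(.data$family, .data$cell_line)
}

#' Synthetic demonstration dataset for the lead-identification funnel
#'
#' A fully synthetic alteration matrix (2000 patients x 383 ncRNA genes)
#' and matching annotation table, calibrated so the candidate funnel
#' reproduces the published stage counts: 383 genes, 72 at or above 10%
#' alteration frequency, 50 of those exosomal, an 18-gene
#' coverage-optimized panel, 10 genes with a disease-contrast signal, and
#' 18 mature miRs. The 18-gene panel and the mature-arm table use the
#' real panel symbols; every other gene, all patient profiles and the
#' differential flags of the annotation are synthetic (in particular, the
#' annotation marks exactly the core-10 genes as differential, which is a
#' calibration, not a published fact). Deterministic: no RNG involved.
#'
#' @return A list: `alteration` (matrix tibble), `annotation` (annotation
#'   tibble).
#' @examples
#' \donttest{
#' demo <- demo_lead_dataset()
#' run_lead_identification(demo$alteration, demo$annotation)
#' }
#' @export
demo_lead_dataset <- function() {
  n_patients <- 2000L
  panel <- sort(pdac_mir_panel("full"))
  exo_extra <- sprintf("MIR%04d", 7001:7032) # exosomal, frequent, redundant
  nonexo_freq <- sprintf("MIR%04d", 7101:7122) # frequent but not exosomal
  rare <- sprintf("MIR%04d", 7201:7511) # below the 10% threshold
  genes <- c(panel, exo_extra, nonexo_freq, rare)

  shared <- 1:200 # 10% shared block: every frequent gene alters it
  marginals <- 89L - seq_along(panel) + 1L # distinct marginal gains 89..72
  alt <- matrix(0L, nrow = n_patients, ncol = length(genes),
                dimnames = list(NULL, genes))
  offset <- 200L
  for (j in seq_along(panel)) {
    block <- (offset + 1L):(offset + marginals[j])
    alt[c(shared, block), panel[j]] <- 1L
    offset <- offset + marginals[j]
  }
  alt[shared, c(exo_extra, nonexo_freq)] <- 1L
  alt[1:50, rare] <- 1L

  alteration <- dplyr::bind_cols(
    tibble::tibble(
      patient_id = sprintf("SYN_%04d", seq_len(n_patients)),
      stage = rep(c("I", "II", "III", "IV"), length.out = n_patients)
    ),
    tibble::as_tibble(alt)
  )

  real_ann <- pdac_mir_annotation()
  core <- pdac_mir_panel("core")
  synth_arms <- function(sym) {
    id <- tolower(sub("^MIR", "", sym))
    purrr::map(id, function(i) paste0("miR-", i, c("-5p", "-3p")))
  }
  synth <- tibble::tibble(
    symbol = c(exo_extra, nonexo_freq, rare),
    exosomal = c(
      rep(TRUE, length(exo_extra)),
      rep(FALSE, length(nonexo_freq) + length(rare))
    ),
    dir_pancreatitis_vs_healthy = "none",
    dir_pdac_vs_pancreatitis = "none",
    mature_arms = synth_arms(c(exo_extra, nonexo_freq, rare))
  )
  panel_ann <- real_ann |>
    dplyr::select(-"panel10") |>
    dplyr::mutate(
      # calibration: exactly the core-10 genes carry a differential signal
      dir_pancreatitis_vs_healthy = dplyr::if_else(
        .data$symbol %in% core, .data$dir_pancreatitis_vs_healthy, "none"
      ),
      dir_pdac_vs_pancreatitis = dplyr::if_else(
        .data$symbol %in% core, .data$dir_pdac_vs_pancreatitis, "none"
      ),
      dir_pancreatitis_vs_healthy = dplyr::if_else(
        .data$symbol %in% core &
          .data$dir_pancreatitis_vs_healthy == "none" &
          .data$dir_pdac_vs_pancreatitis == "none",
        "up",
        .data$dir_pancreatitis_vs_healthy
      )
    )
  annotation <- dplyr::bind_rows(panel_ann, synth)
  list(alteration = alteration, annotation = annotation)
}
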