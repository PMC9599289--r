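# Synthetic-data generators with known ground truth. Defaults emulate the
# study conditions the rest of the package is designed around: a 109-patient
# PDAC cohort with stage marginals 7/94/6/2, and an RT-qPCR design with two
# stable controls, 3 biological x 3 technical replicates, Cq noise sd 0.3
# and censoring at Cq 35.

default_gene_freqs <- function() {
  freqs <- stats::setNames(rep(0.15, 18), pdac_mir_panel("full"))
  # MIR31 carries deep deletions in roughly a quarter of patients
  freqs["MIR31"] <- 0.25
  freqs
}

#' Simulate a patient x gene alteration matrix
#'
#' Each patient's alteration indicator for gene *g* is drawn independently
#' Bernoulli(`gene_freqs[g]`); the stage label is drawn from `stage_probs`.
#' Defaults emulate a 109-patient PDAC cohort (stage counts 7/94/6/2) over
#' the 18-gene panel, with per-gene alteration frequency 0.15 (0.25 for
#' MIR31). Identical seeds give identical matrices.
#'
#' @param n_patients Number of patients.
#' @param gene_freqs Named vector of per-gene alteration probabilities in
#'   `[0, 1]`.
#' @param stage_probs Named probabilities over stages I-IV (may include
#'   `unknown`), summing to 1.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return An alteration matrix tibble (`patient_id`, `stage`, one 0/1
#'   column per gene).
#' @examples
#' simulate_alteration_matrix(n_patients = 10, seed = 1)
#' @export
simulate_alteration_matrix <- function(n_patients = 109,
                                       gene_freqs = default_gene_freqs(),
                                       stage_probs = c(I = 7, II = 94, III = 6, IV = 2) / 109,
                                       seed = NULL) {
  if (!is.numeric(n_patients) || length(n_patients) != 1 || n_patients < 1) {
    abort("`n_patients` must be a positive integer.")
  }
  if (is.null(names(gene_freqs)) || any(!nzchar(names(gene_freqs)))) {
    abort("`gene_freqs` must be a named vector (gene -> probability).")
  }
  if (any(is.na(gene_freqs)) || any(gene_freqs < 0) || any(gene_freqs > 1)) {
    abort("`gene_freqs` must lie in [0, 1].")
  }
  bad_stage <- setdiff(names(stage_probs), stage_labels())
  if (length(bad_stage) > 0 || is.null(names(stage_probs))) {
    abort(paste0(
      "`stage_probs` names must be among ", toString(stage_labels())
    ))
  }
  if (any(stage_probs < 0) || abs(sum(stage_probs) - 1) > 1e-9) {
    abort("`stage_probs` must be non-negative and sum to 1 (within 1e-9).")
  }

  draw <- function() {
    stage <- sample(names(stage_probs), n_patients, replace = TRUE, prob = stage_probs)
    alt <- vapply(
      unname(gene_freqs),
      function(p) stats::rbinom(n_patients, 1L, p),
      integer(n_patients)
    )
    alt <- matrix(alt, nrow = n_patients, dimnames = list(NULL, names(gene_freqs)))
    dplyr::bind_cols(
      tibble::tibble(
        patient_id = sprintf("P%04d", seq_len(n_patients)),
        stage = stage
      ),
      tibble::as_tibble(alt)
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate a replicate-level Cq table with known ground truth
#'
#' Emulates the measurement design of a dual-control RT-qPCR experiment.
#' The true well Cq of miR *m* in cell line *L* is
#' `base_cq[m] - true_log2_fc[L, m] + sample_effect + N(0, noise_sd)`,
#' where the sample effect (shared by every assay of a biological sample,
#' controls included) models per-sample extraction/pipetting efficiency --
#' exactly the nuisance the dual controls exist to cancel. Control wells
#' use `control_assays` means plus the same sample effect. Wells whose
#' true Cq exceeds `detection_limit` read as non-detect (deterministic
#' dropout in true Cq); `dropout_prob` adds optional random dropout on
#' top. Identical seeds give identical tables.
#'
#' @param cell_lines Cell line names; must include `control_cell_line`.
#' @param control_cell_line The reference line; its injected fold changes
#'   are 0 by definition.
#' @param mirs Target assay (mature miR) names.
#' @param base_cq Named mean Cq per miR in the control line; default
#'   spreads the targets over Cq 26-31.
#' @param true_log2_fc Data frame (`cell_line`, `mir`, `log2_fc`) of
#'   injected effects; missing combinations default to 0.
#' @param control_assays Named vector: control assay -> mean Cq.
#' @param control_cq_sd Technical noise sd of control wells (Cq units).
#' @param noise_sd Technical noise sd of target wells (Cq units).
#' @param sample_effect_sd Sd of the per-sample global shift (Cq units).
#' @param detection_limit True Cq above which a well reads non-detect.
#' @param dropout_prob Extra per-well Bernoulli dropout probability.
#' @param n_bio,n_tech Biological and technical replicates per line.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A list: `cq` (long-format Cq table; non-detect wells have
#'   `cq = NA`) and `truth` (the complete injected `log2_fc` grid).
#' @examples
#' sim <- simulate_cq_table(seed = 1)
#' head(sim$cq)
#' @export
simulate_cq_table <- function(cell_lines = c("HPNE", "PANC1", "BXPC3", "CAPAN2"),
                              control_cell_line = "HPNE",
                              mirs = pdac_mature_mirs(),
                              base_cq = NULL,
                              true_log2_fc = NULL,
                              control_assays = c("miR-16-5p" = 21, "cel-miR-2-3p" = 23),
                              control_cq_sd = 0.15,
                              noise_sd = 0.3,
                              sample_effect_sd = 0.2,
                              detection_limit = 35,
                              dropout_prob = 0,
                              n_bio = 3,
                              n_tech = 3,
                              seed = NULL) {
  if (!control_cell_line %in% cell_lines) {
    abort("`control_cell_line` must be listed in `cell_lines`.")
  }
  if (noise_sd < 0 || control_cq_sd < 0 || sample_effect_sd < 0) {
    abort("Noise standard deviations must be non-negative.")
  }
  if (!is.numeric(detection_limit) || detection_limit <= 0) {
    abort("`detection_limit` must be positive.")
  }
  if (n_bio < 1 || n_tech < 1) abort("`n_bio` and `n_tech` must be >= 1.")
  if (dropout_prob < 0 || dropout_prob > 1) {
    abort("`dropout_prob` must lie in [0, 1].")
  }
  if (is.null(base_cq)) {
    base_cq <- stats::setNames(
      seq(26, 31, length.out = length(mirs)), mirs
    )
  }
  missing_base <- setdiff(mirs, names(base_cq))
  if (length(missing_base) > 0) {
    abort(paste0("`base_cq` missing miR(s): ", toString(missing_base)))
  }
  if (is.null(names(control_assays)) || any(!nzchar(names(control_assays)))) {
    abort("`control_assays` must be a named vector (assay -> mean Cq).")
  }

  truth <- tidyr::expand_grid(cell_line = cell_lines, mir = mirs) |>
    dplyr::mutate(log2_fc = 0)
  if (!is.null(true_log2_fc)) {
    fc <- tibble::as_tibble(true_log2_fc)
    miss <- setdiff(c("cell_line", "mir", "log2_fc"), names(fc))
    if (length(miss) > 0) {
      abort(paste0("`true_log2_fc` is missing column(s): ", toString(miss)))
    }
    if (any(fc$log2_fc[fc$cell_line == control_cell_line] != 0)) {
      abort("Injected fold changes for the control cell line must be 0.")
    }
    truth <- truth |>
      dplyr::left_join(fc, by = c("cell_line", "mir"), suffix = c("", ".inj")) |>
      dplyr::mutate(log2_fc = dplyr::coalesce(.data$log2_fc.inj, .data$log2_fc)) |>
      dplyr::select(-"log2_fc.inj")
  }

  draw <- function() {
    wells <- tidyr::expand_grid(
      cell_line = cell_lines,
      biological_replicate = seq_len(n_bio),
      assay = c(mirs, names(control_assays)),
      technical_replicate = seq_len(n_tech)
    ) |>
      dplyr::mutate(
        sample_id = paste0(.data$cell_line, "_b", .data$biological_replicate)
      )
    effects <- wells |>
      dplyr::distinct(.data$sample_id) |>
      dplyr::mutate(sample_effect = stats::rnorm(dplyr::n(), 0, sample_effect_sd))
    wells <- wells |>
      dplyr::left_join(effects, by = "sample_id") |>
      dplyr::left_join(truth, by = c("cell_line", "assay" = "mir")) |>
      dplyr::mutate(
        is_control = .data$assay %in% names(control_assays),
        mu = dplyr::if_else(
          .data$is_control,
          unname(control_assays[.data$assay]),
          unname(base_cq[.data$assay]) - .data$log2_fc
        ),
        true_cq = .data$mu + .data$sample_effect +
          stats::rnorm(dplyr::n(), 0, 1) *
            dplyr::if_else(.data$is_control, control_cq_sd, noise_sd),
        dropout = .data$true_cq > detection_limit |
          (dropout_prob > 0 & stats::rbinom(dplyr::n(), 1L, dropout_prob) == 1L),
        cq = dplyr::if_else(.data$dropout, NA_real_, .data$true_cq)
      ) |>
      dplyr::select(
        "sample_id", "cell_line", "biological_replicate",
        "technical_replicate", "assay", "cq"
      ) |>
      dplyr::arrange(
        .data$cell_line, .data$biological_replicate,
        .data$assay, .data$technical_replicate
      )
    wells
  }
  cq <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  list(cq = cq, truth = truth)
}
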