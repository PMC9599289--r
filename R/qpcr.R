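# Replicate-level RT-qPCR Cq handling: validation, non-detect censoring,
# detectability filtering and dual-control normalization.
#
# A Cq table is long format, one row per well:
#   sample_id, cell_line, biological_replicate, technical_replicate,
#   assay (mature miR or control assay name), cq (positive Cq or NA for a
#   non-detect well).
# Validation adds a `non_detect` logical; censor_cq() adds `censored`.

#' Default control assay names
#'
#' The dual normalization controls: the endogenous control miR-16-5p and
#' the exogenous spike-in cel-miR-2-3p (added before RNA extraction to
#' track extraction efficiency).
#'
#' @return Character vector of the two control assay names.
#' @export
control_assay_names <- function() c("miR-16-5p", "cel-miR-2-3p")

# Validates a Cq table and normalizes the non_detect flag.
check_cq <- function(data) {
  if (!is.data.frame(data)) abort("`data` must be a long-format Cq data frame.")
  need <- c(
    "sample_id", "cell_line", "biological_replicate",
    "technical_replicate", "assay", "cq"
  )
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    abort(paste0("Cq table is missing column(s): ", toString(miss)))
  }
  out <- tibble::as_tibble(data)
  if (!is.numeric(out$cq)) {
    abort("`cq` must be numeric (NA for non-detect wells); see read_cq().")
  }
  bad <- !is.na(out$cq) & (!is.finite(out$cq) | out$cq <= 0)
  if (any(bad)) {
    abort(paste0(
      "Cq values must be finite and positive (or NA for non-detects); ",
      sum(bad), " offending well(s)."
    ))
  }
  key <- paste(out$sample_id, out$assay, out$technical_replicate, sep = "\r")
  if (anyDuplicated(key) > 0) {
    dup <- out[duplicated(key), c("sample_id", "assay", "technical_replicate")]
    abort(paste0(
      "Duplicated (sample_id, assay, technical_replicate) well(s), e.g. ",
      paste(dup$sample_id[1], dup$assay[1], dup$technical_replicate[1])
    ))
  }
  if (!"non_detect" %in% names(out)) out$non_detect <- is.na(out$cq)
  out$non_detect <- as.logical(out$non_detect) | is.na(out$cq)
  out
}

#' Censor high and non-detect Cq values
#'
#' Wells beyond the reliable detection range carry information (the target
#' is absent or extremely dilute) that would be lost if they were dropped.
#' Every well with `cq` strictly above `ceiling`, and every non-detect
#' well, is assigned the fixed imputed value and flagged `censored = TRUE`;
#' wells at or below the ceiling are untouched (so a well at exactly 35 is
#' kept). The operation is idempotent.
#'
#' @param data Long-format Cq table.
#' @param ceiling Largest Cq treated as a real measurement (default 35).
#' @param imputed Value assigned to censored wells (default 36); must
#'   exceed `ceiling`.
#' @return The table with `cq` imputed where censored and logical columns
#'   `non_detect` and `censored`.
#' @export
censor_cq <- function(data, ceiling = 35, imputed = 36) {
  if (!is.numeric(ceiling) || !is.numeric(imputed) ||
      length(ceiling) != 1 || length(imputed) != 1 ||
      !is.finite(ceiling) || !is.finite(imputed) || ceiling >= imputed) {
    abort("`ceiling` must be a finite number strictly below `imputed`.")
  }
  out <- check_cq(data)
  cens <- out$non_detect | (!is.na(out$cq) & out$cq > ceiling)
  out$censored <- cens
  out$cq <- ifelse(cens, imputed, out$cq)
  out
}

#' Flag undetectable assays and drop empty samples
#'
#' Two-step quality filter. First, samples with no numeric Cq on any assay
#' (every well non-detect, controls included) are dropped. Then, within
#' each (cell line, assay) group, the assay is `detectable` when the
#' fraction of wells with `cq <= ceiling` reaches `min_detected_fraction`
#' (default: at least 20% of wells). Non-detectable groups are reported,
#' not silently removed; [quantify()] uses the flags downstream. A group
#' with zero wells is flagged not-evaluable (`NA`), not an error.
#'
#' @inheritParams censor_cq
#' @param min_detected_fraction Minimum detected fraction in `[0, 1]`.
#' @return A list: `data` (table minus dropped samples), `detectability`
#'   (per cell line and assay: `n_wells`, `n_detected`,
#'   `detected_fraction`, `detectable`), `dropped_samples`.
#' @export
detectability_filter <- function(data, min_detected_fraction = 0.20, ceiling = 35) {
  if (!is.numeric(min_detected_fraction) || length(min_detected_fraction) != 1 ||
      is.na(min_detected_fraction) ||
      min_detected_fraction < 0 || min_detected_fraction > 1) {
    abort("`min_detected_fraction` must be a single number in [0, 1].")
  }
  out <- check_cq(data)
  with_value <- unique(out$sample_id[!out$non_detect])
  dropped <- sort(setdiff(unique(out$sample_id), with_value))
  kept <- out[!out$sample_id %in% dropped, , drop = FALSE]
  det <- kept |>
    dplyr::mutate(.detected = !.data$non_detect & !is.na(.data$cq) & .data$cq <= ceiling) |>
    dplyr::group_by(.data$cell_line, .data$assay) |>
    dplyr::summarise(
      n_wells = dplyr::n(),
      n_detected = sum(.data$.detected),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      detected_fraction = .data$n_detected / .data$n_wells,
      detectable = dplyr::if_else(
        .data$n_wells == 0L,
        NA,
        .data$detected_fraction >= min_detected_fraction
      )
    )
  list(data = kept, detectability = det, dropped_samples = dropped)
}

#' Per-sample control Cq
#'
#' Averages the two control assays into one stable per-sample normalizer:
#' the arithmetic mean of the two per-assay technical-replicate means.
#' A sample whose control assay is entirely non-detect cannot be
#' normalized; it is flagged `control_failed` (with a warning) and must be
#' excluded downstream.
#'
#' @inheritParams censor_cq
#' @param control_assays Names of the two control assays.
#' @return A tibble with one row per sample: `sample_id`, `cell_line`,
#'   `biological_replicate`, `control_cq`, `control_failed`.
#' @export
control_cq <- function(data, control_assays = control_assay_names()) {
  out <- check_cq(data)
  samples <- dplyr::distinct(
    out, .data$sample_id, .data$cell_line, .data$biological_replicate
  )
  per_assay <- out |>
    dplyr::filter(.data$assay %in% control_assays, !.data$non_detect) |>
    dplyr::group_by(.data$sample_id, .data$assay) |>
    dplyr::summarise(assay_mean = mean(.data$cq), .groups = "drop")
  grid <- tidyr::expand_grid(
    sample_id = samples$sample_id,
    assay = control_assays
  ) |>
    dplyr::left_join(per_assay, by = c("sample_id", "assay")) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      control_failed = anyNA(.data$assay_mean),
      control_cq = mean(.data$assay_mean),
      .groups = "drop"
    )
  res <- dplyr::left_join(samples, grid, by = "sample_id") |>
    dplyr::select(
      "sample_id", "cell_line", "biological_replicate",
      "control_cq", "control_failed"
    )
  if (any(res$control_failed)) {
    warn(paste0(
      "Control assay entirely non-detect; sample(s) flagged control-failed ",
      "and excluded from quantification: ",
      toString(res$sample_id[res$control_failed])
    ))
  }
  res
}

#' Per-sample, per-assay delta-Cq
#'
#' For every target assay in every sample: the technical-replicate mean Cq
#' minus the sample's control Cq (see [control_cq()]). Censored wells enter
#' the mean at their imputed value, so run [censor_cq()] first; otherwise
#' non-detect wells propagate `NA`. Control-failed samples carry the flag
#' through (quantification drops them).
#'
#' @inheritParams control_cq
#' @return A tibble with one row per (sample, target assay): `sample_id`,
#'   `cell_line`, `biological_replicate`, `assay`, `n_wells`, `mean_cq`,
#'   `control_cq`, `control_failed`, `delta_cq`.
#' @export
delta_cq <- function(data, control_assays = control_assay_names()) {
  out <- check_cq(data)
  cc <- control_cq(out, control_assays)
  out |>
    dplyr::filter(!.data$assay %in% control_assays) |>
    dplyr::group_by(
      .data$sample_id, .data$cell_line, .data$biological_replicate, .data$assay
    ) |>
    dplyr::summarise(
      n_wells = dplyr::n(),
      mean_cq = mean(.data$cq),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      cc[, c("sample_id", "control_cq", "control_failed")],
      by = "sample_id"
    ) |>
    dplyr::mutate(delta_cq = .data$mean_cq - .data$control_cq) |>
    dplyr::arrange(.data$cell_line, .data$assay, .data$sample_id)
}
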