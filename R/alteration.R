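# Patient x gene copy-number alteration matrices and panel-coverage
# optimization. An alteration matrix is an ordinary tibble: `patient_id`,
# `stage` (I/II/III/IV/unknown), then one 0/1 column per gene symbol, 1
# meaning the gene is amplified or deleted in that patient.

stage_labels <- function() c("I", "II", "III", "IV", "unknown")

# Validates the matrix layout and returns the gene columns, in column order.
check_alteration_matrix <- function(data) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame (patient x gene alteration matrix).")
  }
  miss <- setdiff(c("patient_id", "stage"), names(data))
  if (length(miss) > 0) {
    abort(paste0("Alteration matrix is missing column(s): ", toString(miss)))
  }
  genes <- setdiff(names(data), c("patient_id", "stage"))
  if (anyDuplicated(data$patient_id) > 0) {
    dup <- unique(data$patient_id[duplicated(data$patient_id)])
    abort(paste0("Duplicated patient_id value(s): ", toString(utils::head(dup, 5))))
  }
  if (anyDuplicated(genes) > 0) {
    abort("Duplicated gene columns in alteration matrix.")
  }
  bad_stage <- setdiff(unique(as.character(data$stage)), stage_labels())
  if (length(bad_stage) > 0) {
    abort(paste0(
      "Invalid stage label(s): ", toString(bad_stage),
      ". Allowed: ", toString(stage_labels())
    ))
  }
  if (length(genes) > 0) {
    vals <- unlist(data[genes], use.names = FALSE)
    if (anyNA(vals) || !all(vals %in% c(0, 1))) {
      abort("Alteration entries must all be 0 or 1 (1 = amplification or deletion).")
    }
  }
  invisible(genes)
}

check_panel <- function(panel, genes) {
  panel <- as.character(panel)
  if (anyDuplicated(panel) > 0) {
    dup <- unique(panel[duplicated(panel)])
    abort(paste0("Duplicated gene(s) in panel: ", toString(dup)))
  }
  missing <- setdiff(panel, genes)
  if (length(missing) > 0) {
    abort(paste0("Panel gene(s) absent from matrix: ", toString(missing)))
  }
  panel
}

#' Per-gene copy-number alteration frequency
#'
#' Fraction of patients in which each gene carries a copy-number alteration
#' (amplification or deletion, binarized upstream to 0/1).
#'
#' @param data Alteration matrix: a data frame with `patient_id`, `stage`,
#'   then one 0/1 column per gene symbol.
#' @param genes Genes to report. Defaults to every gene column, in column
#'   order. Unknown symbols are an error.
#' @return A tibble with one row per gene: `gene`, `n_altered`,
#'   `n_patients`, `frequency` (`n_altered / n_patients`).
#' @examples
#' m <- simulate_alteration_matrix(n_patients = 20, seed = 1)
#' alteration_frequency(m)
#' @export
alteration_frequency <- function(data, genes = NULL) {
  all_genes <- check_alteration_matrix(data)
  if (nrow(data) == 0) {
    abort("Alteration matrix has no patients; frequencies are undefined.")
  }
  genes <- as.character(genes %||% all_genes)
  unknown <- setdiff(genes, all_genes)
  if (length(unknown) > 0) {
    abort(paste0("Unknown gene symbol(s): ", toString(unknown)))
  }
  n_alt <- vapply(genes, function(g) sum(data[[g]]), numeric(1))
  tibble::tibble(
    gene = genes,
    n_altered = as.integer(n_alt),
    n_patients = nrow(data),
    frequency = unname(n_alt) / nrow(data)
  )
}

#' Filter genes by minimum alteration frequency
#'
#' Keeps genes altered in at least `min_fraction` of patients (inclusive:
#' a gene at exactly the threshold is retained). The conventional screening
#' threshold is 10% of the cohort.
#'
#' @inheritParams alteration_frequency
#' @param min_fraction Minimum alteration fraction in `[0, 1]`.
#' @return A tibble (as [alteration_frequency()]) restricted to retained
#'   genes, in matrix column order.
#' @export
filter_genes_by_frequency <- function(data, min_fraction = 0.10) {
  if (!is.numeric(min_fraction) || length(min_fraction) != 1 ||
      is.na(min_fraction) || min_fraction < 0 || min_fraction > 1) {
    abort("`min_fraction` must be a single number in [0, 1].")
  }
  freq <- alteration_frequency(data)
  dplyr::filter(freq, .data$frequency >= min_fraction)
}

#' Patient coverage of a gene panel
#'
#' A patient is covered when at least one panel gene is altered in that
#' patient; coverage is the covered fraction of the cohort. This is the
#' figure of merit for a copy-number-based diagnostic panel.
#'
#' @inheritParams alteration_frequency
#' @param panel Character vector of gene symbols, all present in the matrix
#'   and without duplicates. An empty panel has coverage 0.
#' @return A one-row tibble: `panel` (list column, order preserved),
#'   `n_genes`, `n_covered`, `n_patients`, `coverage`.
#' @examples
#' m <- simulate_alteration_matrix(n_patients = 50, seed = 1)
#' panel_coverage(m, c("MIR31", "MIR210"))
#' @export
panel_coverage <- function(data, panel) {
  genes <- check_alteration_matrix(data)
  if (nrow(data) == 0) {
    abort("Alteration matrix has no patients; coverage is undefined.")
  }
  panel <- check_panel(panel, genes)
  covered <- if (length(panel) == 0) {
    rep(FALSE, nrow(data))
  } else {
    rowSums(data[panel]) > 0
  }
  tibble::tibble(
    panel = list(panel),
    n_genes = length(panel),
    n_covered = as.integer(sum(covered)),
    n_patients = nrow(data),
    coverage = sum(covered) / nrow(data)
  )
}

#' Select a gene panel maximizing patient coverage
#'
#' Chooses `k` genes from `candidates` to maximize [panel_coverage()].
#' When the number of k-subsets is at most `exhaustive_limit` the optimum
#' is found by exhaustive enumeration; above it a greedy set-cover heuristic
#' is used (repeatedly add the gene covering the most still-uncovered
#' patients), which guarantees at least `1 - 1/e` of the optimal coverage.
#' Ties at every choice point are broken by lexicographic gene symbol, so
#' the result is deterministic.
#'
#' @inheritParams alteration_frequency
#' @param k Panel size (positive integer). If `k >= length(candidates)` the
#'   whole candidate set is returned.
#' @param candidates Genes eligible for the panel; defaults to all genes.
#' @param exhaustive_limit Largest subset count still enumerated exhaustively.
#' @return A one-row tibble as [panel_coverage()], plus `method`
#'   (`"all"`, `"exhaustive"` or `"greedy"`).
#' @examples
#' m <- simulate_alteration_matrix(n_patients = 60, seed = 7)
#' select_panel(m, k = 3)
#' @export
select_panel <- function(data, k, candidates = NULL, exhaustive_limit = 1e5) {
  genes <- check_alteration_matrix(data)
  if (nrow(data) == 0) {
    abort("Alteration matrix has no patients; panel selection is undefined.")
  }
  candidates <- as.character(candidates %||% genes)
  if (length(candidates) == 0) {
    abort("`candidates` must contain at least one gene.")
  }
  candidates <- check_panel(candidates, genes)
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 1 || k != floor(k)) {
    abort("`k` must be a single positive integer.")
  }

  if (k >= length(candidates)) {
    panel <- candidates
    method <- "all"
  } else if (choose(length(candidates), k) <= exhaustive_limit) {
    cand <- sort(candidates)
    alt <- as.matrix(data[cand]) == 1
    subsets <- utils::combn(length(cand), k)
    cover <- apply(subsets, 2, function(ix) {
      sum(rowSums(alt[, ix, drop = FALSE]) > 0)
    })
    # combn enumerates sorted candidates in lexicographic order, so the
    # first maximum is the lexicographically smallest optimal panel.
    panel <- cand[subsets[, which.max(cover)]]
    method <- "exhaustive"
  } else {
    remaining <- sort(candidates)
    alt <- as.matrix(data[remaining]) == 1
    uncovered <- rep(TRUE, nrow(data))
    panel <- character(0)
    for (i in seq_len(k)) {
      gains <- colSums(alt[uncovered, remaining, drop = FALSE])
      pick <- remaining[which.max(gains)] # remaining is sorted: ties lexicographic
      panel <- c(panel, pick)
      uncovered <- uncovered & !(data[[pick]] == 1)
      remaining <- setdiff(remaining, pick)
    }
    method <- "greedy"
  }

  dplyr::mutate(panel_coverage(data, panel), method = method)
}
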