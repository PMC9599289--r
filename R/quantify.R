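# Censored delta-delta-Cq relative quantification against a control cell
# line, significance tiers, collation across cell lines, and 5p/3p arm
# preference.

# Two-sample t-test that degrades gracefully: returns NA for undersized
# groups and handles (numerically) constant groups -- where stats::t.test
# refuses with "data are essentially constant" -- by the limit case:
# equal means -> t = 0, p = 1; unequal means with no spread -> p = 0.
safe_t_test <- function(x, y, var_equal = TRUE, paired = FALSE) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2 || (paired && length(x) != length(y))) {
    return(list(t = NA_real_, p = NA_real_))
  }
  tryCatch(
    {
      tt <- stats::t.test(x, y, var.equal = var_equal, paired = paired)
      list(t = unname(tt$statistic), p = tt$p.value)
    },
    error = function(e) {
      eq <- isTRUE(all.equal(mean(x), mean(y)))
      list(
        t = if (eq) 0 else Inf * sign(mean(x) - mean(y)),
        p = if (eq) 1 else 0
      )
    }
  )
}

# Median +/- 1.5 IQR trim. Quartile fences are not identifiable from
# fewer than 4 points (the fences are essentially the data themselves and
# the rule misfires, inflating the false-positive rate), so groups of
# fewer than 4 values are kept whole; trimming also never reduces a group
# below 2 values.
inlier_mask <- function(x) {
  if (length(x) < 4) return(rep(TRUE, length(x)))
  med <- stats::median(x)
  iqr <- stats::IQR(x)
  keep <- x >= med - 1.5 * iqr & x <= med + 1.5 * iqr
  if (sum(keep) < 2) rep(TRUE, length(x)) else keep
}

#' Map p-values to significance tiers
#'
#' `***` for p <= 0.001, `**` for p <= 0.01, `*` for p <= 0.05, `ns`
#' otherwise. Boundaries are inclusive and the strongest tier wins; `NA`
#' p-values give `NA` tiers.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Character vector of tiers.
#' @examples
#' significance_tier(c(0.0005, 0.04, 0.0691))
#' @export
significance_tier <- function(p) {
  if (!is.numeric(p)) abort("`p` must be numeric.")
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) {
    abort(paste0("p-values must lie in [0, 1]; offending: ", toString(p[bad])))
  }
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p <= 0.001 ~ "***",
    p <= 0.01 ~ "**",
    p <= 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Relative quantification by censored delta-delta-Cq
#'
#' Runs the full quantification engine per (cell line, miR): censor
#' non-detect and high-Cq wells ([censor_cq()]), drop all-non-detect
#' samples and flag undetectable assays ([detectability_filter()]),
#' normalize each sample by the dual-control mean ([control_cq()],
#' [delta_cq()]), optionally trim outlying per-sample delta-Cq values
#' (median +/- 1.5 IQR within each group; only groups of at least 4
#' values are trimmed, and never below 2 values), then
#' compute `ddCq = mean dCq(cell line) - mean dCq(control line)` and
#' `log2_fc = -ddCq`, with a two-sided Student's t-test on the per-sample
#' delta-Cq values (cell line vs control line).
#'
#' The biological sample is the unit of replication: technical replicates
#' are averaged within a sample before any statistics. A miR detectable in
#' neither line of a comparison gets `detectable = FALSE` and `NA`
#' estimates; detectable in exactly one line, it is quantified with the
#' censored (imputed) values on the silent side and flagged
#' `one_sided_detection`. The control line compared with itself has
#' `log2_fc = 0` and no p-value.
#'
#' @inheritParams censor_cq
#' @inheritParams control_cq
#' @param control_cell_line Reference cell line; must be present with at
#'   least two usable samples.
#' @param cq_ceiling,cq_imputed Censoring parameters (see [censor_cq()]).
#' @param min_detected_fraction Detectability threshold (see
#'   [detectability_filter()]).
#' @param remove_outliers Trim per-sample delta-Cq outliers before testing.
#' @param var_equal Equal-variance Student's t-test (`TRUE`, default) or
#'   Welch (`FALSE`).
#' @param p_adjust_method Optional multiple-testing correction applied
#'   across all comparisons (e.g. `"BH"`). The default `"none"` reports
#'   raw p-values; when set, tiers are computed from `p_adjusted`.
#' @return A tibble of class `"mir_quant"` with one row per (cell line,
#'   miR): `cell_line`, `mir`, `n_line`, `n_control`, `mean_delta_cq`,
#'   `mean_delta_cq_control`, `delta_delta_cq`, `log2_fc`, `t_statistic`,
#'   `p_value`, `tier`, `detectable`, `one_sided_detection`,
#'   `n_outliers_removed`. Attributes carry the settings, the per-group
#'   detectability table, dropped samples and control-failed samples.
#' @examples
#' sim <- simulate_cq_table(
#'   cell_lines = c("HPNE", "PANC1"),
#'   mirs = c("miR-31-5p", "miR-429"),
#'   true_log2_fc = data.frame(
#'     cell_line = "PANC1", mir = c("miR-31-5p", "miR-429"),
#'     log2_fc = c(3, -1)
#'   ),
#'   seed = 42
#' )
#' quantify(sim$cq, control_cell_line = "HPNE")
#' @export
quantify <- function(data,
                     control_cell_line,
                     control_assays = control_assay_names(),
                     cq_ceiling = 35,
                     cq_imputed = 36,
                     min_detected_fraction = 0.20,
                     remove_outliers = TRUE,
                     var_equal = TRUE,
                     p_adjust_method = "none") {
  out <- check_cq(data)
  if (length(control_cell_line) != 1 || !control_cell_line %in% out$cell_line) {
    abort(paste0(
      "Control cell line '", control_cell_line, "' not present in the data."
    ))
  }
  cens <- censor_cq(out, ceiling = cq_ceiling, imputed = cq_imputed)
  flt <- detectability_filter(
    cens,
    min_detected_fraction = min_detected_fraction, ceiling = cq_ceiling
  )
  dcq <- delta_cq(flt$data, control_assays)
  control_failed <- sort(unique(dcq$sample_id[dcq$control_failed]))
  dcq <- dcq[!dcq$control_failed, , drop = FALSE]

  settings <- list(
    control_cell_line = control_cell_line,
    control_assays = control_assays,
    cq_ceiling = cq_ceiling,
    cq_imputed = cq_imputed,
    min_detected_fraction = min_detected_fraction,
    remove_outliers = remove_outliers,
    var_equal = var_equal,
    p_adjust_method = p_adjust_method
  )

  if (nrow(dcq) == 0) {
    warn("No target assays left after filtering; returning empty result.")
    return(new_mir_quant(empty_quant_rows(), settings, flt, control_failed))
  }

  n_ctrl_samples <- dplyr::n_distinct(
    dcq$sample_id[dcq$cell_line == control_cell_line]
  )
  if (n_ctrl_samples < 2) {
    abort(paste0(
      "Control cell line '", control_cell_line,
      "' has fewer than 2 usable samples."
    ))
  }

  if (remove_outliers) {
    dcq <- dcq |>
      dplyr::group_by(.data$cell_line, .data$assay) |>
      dplyr::mutate(.inlier = inlier_mask(.data$delta_cq)) |>
      dplyr::ungroup()
  } else {
    dcq$.inlier <- TRUE
  }

  groups <- dcq |>
    dplyr::group_by(.data$cell_line, .data$assay) |>
    dplyr::summarise(
      dcq_values = list(.data$delta_cq[.data$.inlier]),
      mean_dcq = mean(.data$delta_cq[.data$.inlier]),
      n_used = sum(.data$.inlier),
      n_outliers_removed = sum(!.data$.inlier),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      flt$detectability[, c("cell_line", "assay", "detectable")],
      by = c("cell_line", "assay")
    )

  ctrl <- groups[groups$cell_line == control_cell_line, , drop = FALSE]

  rows <- purrr::map_dfr(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    ci <- match(g$assay, ctrl$assay)
    det_line <- isTRUE(g$detectable)
    det_ctrl <- !is.na(ci) && isTRUE(ctrl$detectable[ci])
    base <- tibble::tibble(
      cell_line = g$cell_line,
      mir = g$assay,
      n_line = g$n_used,
      n_control = if (is.na(ci)) 0L else ctrl$n_used[ci],
      mean_delta_cq = g$mean_dcq,
      mean_delta_cq_control = if (is.na(ci)) NA_real_ else ctrl$mean_dcq[ci],
      delta_delta_cq = NA_real_,
      log2_fc = NA_real_,
      t_statistic = NA_real_,
      p_value = NA_real_,
      detectable = det_line || det_ctrl,
      one_sided_detection = xor(det_line, det_ctrl),
      n_outliers_removed = g$n_outliers_removed
    )
    if (g$cell_line == control_cell_line) {
      base$detectable <- det_line
      base$one_sided_detection <- FALSE
      if (det_line) {
        base$delta_delta_cq <- 0
        base$log2_fc <- 0
      }
      return(base)
    }
    if (is.na(ci) || !(det_line || det_ctrl)) {
      # measured in neither or detectable in neither line: not quantifiable
      base$detectable <- FALSE
      base$one_sided_detection <- FALSE
      return(base)
    }
    base$delta_delta_cq <- g$mean_dcq - ctrl$mean_dcq[ci]
    base$log2_fc <- -base$delta_delta_cq
    tt <- safe_t_test(
      g$dcq_values[[1]], ctrl$dcq_values[[ci]],
      var_equal = var_equal
    )
    base$t_statistic <- tt$t
    base$p_value <- tt$p
    base
  })

  if (!identical(p_adjust_method, "none")) {
    rows$p_adjusted <- stats::p.adjust(rows$p_value, method = p_adjust_method)
    rows$tier <- significance_tier(rows$p_adjusted)
  } else {
    rows$tier <- significance_tier(rows$p_value)
  }
  rows <- rows |>
    dplyr::relocate("tier", .after = "p_value") |>
    dplyr::arrange(.data$cell_line, .data$mir)

  new_mir_quant(rows, settings, flt, control_failed)
}

empty_quant_rows <- function() {
  tibble::tibble(
    cell_line = character(), mir = character(),
    n_line = integer(), n_control = integer(),
    mean_delta_cq = double(), mean_delta_cq_control = double(),
    delta_delta_cq = double(), log2_fc = double(),
    t_statistic = double(), p_value = double(), tier = character(),
    detectable = logical(), one_sided_detection = logical(),
    n_outliers_removed = integer()
  )
}

new_mir_quant <- function(rows, settings, flt, control_failed) {
  structure(
    rows,
    class = c("mir_quant", class(tibble::tibble())),
    settings = settings,
    detectability = flt$detectability,
    dropped_samples = flt$dropped_samples,
    control_failed_samples = control_failed
  )
}

#' @export
print.mir_quant <- function(x, ...) {
  s <- attr(x, "settings")
  cat(
    "<mir_quant> censored ddCq quantification vs '",
    s$control_cell_line, "'\n",
    "  censoring: Cq > ", s$cq_ceiling, " or non-detect -> ", s$cq_imputed,
    "; detectability >= ", 100 * s$min_detected_fraction, "% of wells\n",
    sep = ""
  )
  dropped <- attr(x, "dropped_samples")
  failed <- attr(x, "control_failed_samples")
  if (length(dropped) > 0) cat("  dropped samples:", toString(dropped), "\n")
  if (length(failed) > 0) cat("  control-failed samples:", toString(failed), "\n")
  NextMethod()
}

#' Collate significant miRs across cell lines
#'
#' Lists the miRs reaching significance in at least one (non-control) cell
#' line, with the membership map saying which lines each passed in.
#'
#' @param results A [quantify()] result, or any data frame with columns
#'   `cell_line`, `mir` (or `assay`) and `p_value`.
#' @param alpha Significance level (inclusive), default 0.05.
#' @param exclude_cell_lines Cell lines to ignore (e.g. the control line;
#'   [quantify()] already leaves its control rows without p-values).
#' @return A tibble sorted by miR: `mir`, `n_cell_lines`, `cell_lines`
#'   (list column of sorted line names).
#' @examples
#' collate_significant(pdac_mir_pvalues())
#' @export
collate_significant <- function(results, alpha = 0.05, exclude_cell_lines = NULL) {
  df <- tibble::as_tibble(results)
  if (!"mir" %in% names(df) && "assay" %in% names(df)) {
    df <- dplyr::rename(df, mir = "assay")
  }
  need <- c("cell_line", "mir", "p_value")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(paste0("`results` is missing column(s): ", toString(miss)))
  }
  df |>
    dplyr::filter(
      !is.na(.data$p_value),
      .data$p_value <= alpha,
      !.data$cell_line %in% exclude_cell_lines
    ) |>
    dplyr::group_by(.data$mir) |>
    dplyr::summarise(
      n_cell_lines = dplyr::n_distinct(.data$cell_line),
      cell_lines = list(sort(unique(.data$cell_line))),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$mir)
}

# "miR-31-5p" -> family "miR-31", arm "5p"; single-form names (miR-429)
# have arm NA.
split_arm <- function(assay) {
  arm <- dplyr::case_when(
    grepl("-5p$", assay) ~ "5p",
    grepl("-3p$", assay) ~ "3p",
    TRUE ~ NA_character_
  )
  tibble::tibble(family = sub("-[53]p$", "", assay), arm = arm)
}

#' 5p vs 3p arm preference within miRNA families
#'
#' The two mature arms processed from one hairpin are often expressed
#' unequally in tumors. For each (cell line, family) with both a 5p and a
#' 3p assay, this compares the per-sample delta-Cq of the arms:
#' `rel_expr_3p_vs_5p = 2^(mean dCq_5p - mean dCq_3p)` (5p = 1; values
#' below 1 mean the 5p arm dominates), with a two-sided Student's t-test
#' across samples (unpaired by default; `paired = TRUE` pairs arms within
#' a sample). The preferred arm is the one with the lower mean delta-Cq
#' when `p <= alpha`, otherwise `"none"`. An arm that is entirely
#' undetectable contributes its censored (imputed) values and the
#' comparison is flagged `one_arm_undetected`; families lacking one of the
#' two assays (e.g. miR-429) are returned flagged `not_applicable`.
#'
#' @inheritParams quantify
#' @param families Families to compare; default: every family in the data
#'   with at least one target assay.
#' @param cell_lines Cell lines to compare; default: all.
#' @param alpha Significance level for declaring a preference.
#' @param paired Pair arms within samples instead of the unpaired test.
#' @return A tibble of class `"arm_comparison"`: `cell_line`, `family`,
#'   `n_5p`, `n_3p`, `mean_dcq_5p`, `mean_dcq_3p`, `rel_expr_3p_vs_5p`,
#'   `t_statistic`, `p_value`, `preferred_arm`, `one_arm_undetected`,
#'   `evaluable`, `not_applicable`.
#' @export
arm_preference <- function(data,
                           families = NULL,
                           cell_lines = NULL,
                           control_assays = control_assay_names(),
                           cq_ceiling = 35,
                           cq_imputed = 36,
                           min_detected_fraction = 0.20,
                           var_equal = TRUE,
                           paired = FALSE,
                           alpha = 0.05) {
  out <- check_cq(data)
  cens <- censor_cq(out, ceiling = cq_ceiling, imputed = cq_imputed)
  flt <- detectability_filter(
    cens,
    min_detected_fraction = min_detected_fraction, ceiling = cq_ceiling
  )
  dcq <- delta_cq(flt$data, control_assays)
  dcq <- dcq[!dcq$control_failed, , drop = FALSE]
  dcq <- dplyr::bind_cols(dcq, split_arm(dcq$assay))

  families <- families %||% sort(unique(dcq$family))
  cell_lines <- cell_lines %||% sort(unique(dcq$cell_line))
  det <- flt$detectability

  grid <- tidyr::expand_grid(cell_line = cell_lines, family = families)
  res <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    cl <- grid$cell_line[i]
    fam <- grid$family[i]
    sub <- dcq[dcq$cell_line == cl & dcq$family == fam, , drop = FALSE]
    row <- tibble::tibble(
      cell_line = cl, family = fam,
      n_5p = NA_integer_, n_3p = NA_integer_,
      mean_dcq_5p = NA_real_, mean_dcq_3p = NA_real_,
      rel_expr_3p_vs_5p = NA_real_,
      t_statistic = NA_real_, p_value = NA_real_,
      preferred_arm = NA_character_,
      one_arm_undetected = NA,
      evaluable = FALSE,
      not_applicable = FALSE
    )
    arms_present <- unique(sub$arm[!is.na(sub$arm)])
    if (!all(c("5p", "3p") %in% arms_present)) {
      row$not_applicable <- TRUE
      return(row)
    }
    a5 <- sub[sub$arm == "5p", , drop = FALSE]
    a3 <- sub[sub$arm == "3p", , drop = FALSE]
    det_of <- function(assay) {
      j <- which(det$cell_line == cl & det$assay == assay)
      length(j) == 1 && isTRUE(det$detectable[j])
    }
    det5 <- any(vapply(unique(a5$assay), det_of, logical(1)))
    det3 <- any(vapply(unique(a3$assay), det_of, logical(1)))
    row$n_5p <- nrow(a5)
    row$n_3p <- nrow(a3)
    row$one_arm_undetected <- xor(det5, det3)
    if (!det5 && !det3) {
      return(row) # neither arm detectable: not evaluable
    }
    row$evaluable <- TRUE
    row$mean_dcq_5p <- mean(a5$delta_cq)
    row$mean_dcq_3p <- mean(a3$delta_cq)
    row$rel_expr_3p_vs_5p <- 2^(row$mean_dcq_5p - row$mean_dcq_3p)
    if (paired) {
      pairs <- dplyr::inner_join(
        a5[, c("sample_id", "delta_cq")],
        a3[, c("sample_id", "delta_cq")],
        by = "sample_id", suffix = c("_5p", "_3p")
      )
      tt <- safe_t_test(
        pairs$delta_cq_5p, pairs$delta_cq_3p,
        var_equal = var_equal, paired = TRUE
      )
    } else {
      tt <- safe_t_test(a5$delta_cq, a3$delta_cq, var_equal = var_equal)
    }
    row$t_statistic <- tt$t
    row$p_value <- tt$p
    row$preferred_arm <- if (!is.na(tt$p) && tt$p <= alpha) {
      if (row$mean_dcq_5p <= row$mean_dcq_3p) "5p" else "3p"
    } else {
      "none"
    }
    row
  })

  res <- dplyr::arrange(res, .data$cell_line, .data$family)
  structure(res, class = c("arm_comparison", class(tibble::tibble())))
}

#' Collate families with a significant arm preference
#'
#' @param arms An [arm_preference()] result, or any data frame with
#'   `family`, `cell_line` and `p_value` columns.
#' @param alpha Significance level (inclusive).
#' @param exclude_cell_lines Cell lines to ignore (e.g. the control line).
#' @return A tibble sorted by family: `family`, `n_cell_lines`,
#'   `cell_lines` (list column).
#' @examples
#' collate_arm_preferences(pdac_arm_pvalues())
#' @export
collate_arm_preferences <- function(arms, alpha = 0.05, exclude_cell_lines = NULL) {
  df <- tibble::as_tibble(arms)
  need <- c("family", "cell_line", "p_value")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(paste0("`arms` is missing column(s): ", toString(miss)))
  }
  df |>
    dplyr::filter(
      !is.na(.data$p_value),
      .data$p_value <= alpha,
      !.data$cell_line %in% exclude_cell_lines
    ) |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(
      n_cell_lines = dplyr::n_distinct(.data$cell_line),
      cell_lines = list(sort(unique(.data$cell_line))),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$family)
}
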