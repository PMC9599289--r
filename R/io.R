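# File dialects.
#
# Alteration matrix: CSV or TSV (by extension), header mandatory; first
# column patient_id, second stage, remaining columns gene symbols with 0/1
# entries.
# Annotation: TSV with columns symbol, exosomal (0/1),
# dir_pancreatitis_vs_healthy, dir_pdac_vs_pancreatitis, mature_arms
# (comma-joined).
# Cq table: long-format CSV (sample_id, cell_line, biological_replicate,
# technical_replicate, assay, cq); non-detect wells are an empty field or
# "Undetermined". A wide per-plate dialect (one column per assay) is also
# supported.

delim_for <- function(path) {
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read / write a patient x gene alteration matrix
#'
#' @param path CSV or TSV file (dialect chosen by extension).
#' @return `read_alteration_matrix()`: a validated alteration matrix
#'   tibble.
#' @export
read_alteration_matrix <- function(path) {
  raw <- readr::read_delim(
    path,
    delim = delim_for(path),
    col_types = readr::cols(
      patient_id = readr::col_character(),
      stage = readr::col_character(),
      .default = readr::col_integer()
    ),
    progress = FALSE
  )
  check_alteration_matrix(raw)
  raw
}

#' @rdname read_alteration_matrix
#' @param data Alteration matrix tibble.
#' @export
write_alteration_matrix <- function(data, path) {
  check_alteration_matrix(data)
  readr::write_delim(data, path, delim = delim_for(path))
  invisible(path)
}

#' Read / write a gene annotation table
#'
#' @param path TSV file.
#' @return `read_annotation()`: a validated annotation tibble with
#'   `mature_arms` as a list column.
#' @export
read_annotation <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  as_gene_annotation(raw)
}

#' @rdname read_annotation
#' @param data Annotation tibble.
#' @export
write_annotation <- function(data, path) {
  ann <- as_gene_annotation(data)
  flat <- ann |>
    dplyr::mutate(
      exosomal = as.integer(.data$exosomal),
      mature_arms = purrr::map_chr(
        .data$mature_arms, paste, collapse = ","
      )
    )
  readr::write_tsv(flat, path)
  invisible(path)
}

parse_cq_column <- function(x) {
  chr <- trimws(as.character(x))
  nd <- is.na(chr) | chr == "" | tolower(chr) == "undetermined"
  val <- suppressWarnings(as.numeric(chr))
  bad <- !nd & is.na(val)
  if (any(bad)) {
    abort(paste0(
      "Unparseable Cq value(s): ", toString(unique(chr[bad])),
      ". Use a positive number, an empty field, or 'Undetermined'."
    ))
  }
  val[nd] <- NA_real_
  val
}

#' Read / write a long-format Cq table
#'
#' Non-detect wells may be encoded as an empty field or as
#' `"Undetermined"` (case-insensitive); both read as `NA` with
#' `non_detect = TRUE`.
#'
#' @param path CSV file.
#' @return `read_cq()`: a validated long-format Cq tibble.
#' @export
read_cq <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      cell_line = readr::col_character(),
      biological_replicate = readr::col_integer(),
      technical_replicate = readr::col_integer(),
      assay = readr::col_character(),
      cq = readr::col_character()
    ),
    progress = FALSE
  )
  raw$cq <- parse_cq_column(raw$cq)
  check_cq(raw)
}

#' @rdname read_cq
#' @param data Long-format Cq tibble.
#' @export
write_cq <- function(data, path) {
  out <- check_cq(data)
  flat <- out |>
    dplyr::mutate(
      cq = dplyr::if_else(
        .data$non_detect, "Undetermined", format(.data$cq, trim = TRUE)
      )
    ) |>
    dplyr::select(
      "sample_id", "cell_line", "biological_replicate",
      "technical_replicate", "assay", "cq"
    )
  readr::write_csv(flat, path)
  invisible(path)
}

#' Read a wide per-plate Cq export
#'
#' One row per (sample, technical replicate), one column per assay;
#' pivots to the long dialect of [read_cq()].
#'
#' @param path CSV file with columns `sample_id`, `cell_line`,
#'   `biological_replicate`, `technical_replicate`, then one column per
#'   assay.
#' @return A validated long-format Cq tibble.
#' @export
read_cq_wide <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  id_cols <- c(
    "sample_id", "cell_line", "biological_replicate", "technical_replicate"
  )
  miss <- setdiff(id_cols, names(raw))
  if (length(miss) > 0) {
    abort(paste0("Wide Cq file is missing column(s): ", toString(miss)))
  }
  long <- raw |>
    tidyr::pivot_longer(
      cols = -dplyr::all_of(id_cols),
      names_to = "assay", values_to = "cq"
    ) |>
    dplyr::mutate(
      biological_replicate = as.integer(.data$biological_replicate),
      technical_replicate = as.integer(.data$technical_replicate),
      cq = parse_cq_column(.data$cq)
    )
  check_cq(long)
}
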