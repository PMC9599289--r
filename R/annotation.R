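# Offline gene annotation: exosomal presence, disease-contrast expression
# direction, and gene -> mature-arm expansion. Replaces live database
# lookups (ExoCarta, expression databases) with a flat table so analyses
# are reproducible offline.
#
# An annotation table has one row per gene symbol:
#   symbol                      uppercase gene symbol (e.g. MIR31)
#   exosomal                    logical: evidence of exosomal presence
#   dir_pancreatitis_vs_healthy "up"/"down"/"none"/"unknown"
#   dir_pdac_vs_pancreatitis    "up"/"down"/"none"/"unknown"
#   mature_arms                 list column of mature miR names
# "none" means assessed with no differential signal; "unknown" means never
# assessed. The two are deliberately distinct states.

direction_levels <- function() c("up", "down", "none", "unknown")

#' Normalize and validate a gene annotation table
#'
#' Accepts `mature_arms` either as a list column or as comma-joined
#' strings (the TSV dialect) and `exosomal` as logical or 0/1, and returns
#' a validated tibble with a list column and logical flag.
#'
#' @param data Annotation data frame (see [read_annotation()] for the file
#'   dialect).
#' @return A validated annotation tibble.
#' @export
as_gene_annotation <- function(data) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  need <- c(
    "symbol", "exosomal", "dir_pancreatitis_vs_healthy",
    "dir_pdac_vs_pancreatitis", "mature_arms"
  )
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    abort(paste0("Annotation table is missing column(s): ", toString(miss)))
  }
  out <- tibble::as_tibble(data)
  if (anyDuplicated(out$symbol) > 0) {
    dup <- unique(out$symbol[duplicated(out$symbol)])
    abort(paste0("Duplicated annotation symbol(s): ", toString(dup)))
  }
  if (!is.logical(out$exosomal)) {
    if (all(out$exosomal %in% c(0, 1, "0", "1"))) {
      out$exosomal <- as.integer(out$exosomal) == 1L
    } else {
      abort("`exosomal` must be logical or 0/1.")
    }
  }
  for (col in c("dir_pancreatitis_vs_healthy", "dir_pdac_vs_pancreatitis")) {
    bad <- setdiff(unique(as.character(out[[col]])), direction_levels())
    if (length(bad) > 0) {
      abort(paste0(
        "Invalid value(s) in `", col, "`: ", toString(bad),
        ". Allowed: ", toString(direction_levels())
      ))
    }
  }
  if (!is.list(out$mature_arms)) {
    out$mature_arms <- purrr::map(
      as.character(out$mature_arms),
      function(x) {
        if (is.na(x) || !nzchar(trimws(x))) character(0) else trimws(strsplit(x, ",")[[1]])
      }
    )
  }
  out
}

# Index of `genes` into the annotation table; unannotated genes are an error.
annotation_index <- function(annotations, genes) {
  idx <- match(genes, annotations$symbol)
  if (anyNA(idx)) {
    abort(paste0(
      "Gene(s) without annotation: ", toString(genes[is.na(idx)])
    ))
  }
  idx
}

#' Keep genes with evidence of exosomal presence
#'
#' @param annotations Annotation table (see [as_gene_annotation()]).
#' @param genes Genes to filter; defaults to every annotated gene. Every
#'   gene must be annotated. Input order is preserved.
#' @return Character vector of genes flagged exosomal.
#' @examples
#' ann <- pdac_mir_annotation()
#' filter_exosomal(ann, c("MIR31", "MIR210"))
#' @export
filter_exosomal <- function(annotations, genes = NULL) {
  ann <- as_gene_annotation(annotations)
  genes <- as.character(genes %||% ann$symbol)
  idx <- annotation_index(ann, genes)
  genes[ann$exosomal[idx]]
}

#' Keep genes with a known disease-contrast expression signal
#'
#' Retains genes whose expression direction is known (`"up"` or `"down"`)
#' in either contrast: chronic pancreatitis vs healthy tissue, or PDAC vs
#' chronic pancreatitis. Genes assessed with no signal in both contrasts
#' (`"none"`) are dropped silently; genes never assessed in either contrast
#' (`"unknown"` twice) are dropped with a warning, because absence of
#' evidence is not evidence of absence.
#'
#' @inheritParams filter_exosomal
#' @return Character vector of retained genes, input order preserved.
#' @export
filter_disease_differential <- function(annotations, genes = NULL) {
  ann <- as_gene_annotation(annotations)
  genes <- as.character(genes %||% ann$symbol)
  idx <- annotation_index(ann, genes)
  d1 <- as.character(ann$dir_pancreatitis_vs_healthy[idx])
  d2 <- as.character(ann$dir_pdac_vs_pancreatitis[idx])
  known <- d1 %in% c("up", "down") | d2 %in% c("up", "down")
  unassessed <- d1 == "unknown" & d2 == "unknown"
  if (any(unassessed)) {
    warn(paste0(
      "Dropping gene(s) never assessed in either disease contrast ",
      "(direction 'unknown', which is distinct from 'none'): ",
      toString(genes[unassessed])
    ))
  }
  genes[known]
}

#' Expand gene symbols to mature miRNA arms
#'
#' Concatenates the annotated mature arms of each gene, in input gene
#' order, with the 5p arm before the 3p arm within a gene. Single-form
#' miRNAs (e.g. miR-429) contribute one name. Duplicates are removed.
#'
#' @inheritParams filter_exosomal
#' @return Character vector of mature miR names.
#' @examples
#' expand_to_mature(pdac_mir_annotation(), pdac_mir_panel("core"))
#' @export
expand_to_mature <- function(annotations, genes = NULL) {
  ann <- as_gene_annotation(annotations)
  genes <- as.character(genes %||% ann$symbol)
  if (length(genes) == 0) return(character(0))
  idx <- annotation_index(ann, genes)
  arms <- ann$mature_arms[idx]
  empty <- lengths(arms) == 0
  if (any(empty)) {
    abort(paste0(
      "Gene(s) with no annotated mature arm: ", toString(genes[empty])
    ))
  }
  ordered <- purrr::map(arms, function(a) {
    rank <- ifelse(grepl("-5p$", a), 1L, ifelse(grepl("-3p$", a), 3L, 2L))
    a[order(rank)]
  })
  unique(unlist(ordered))
}

#' Canonicalize a miRNA name and classify its processing tier
#'
#' miRNA nomenclature encodes the processing level in the prefix casing:
#' `MIR` is the gene, `mir` the precursor/primary transcript, and `miR`
#' the mature form. Separators and suffix casing are canonicalized
#' (gene symbols keep no separators, e.g. `MIR133A1`; precursor and mature
#' names are lowercase and hyphenated after the prefix, e.g. `mir-133a`,
#' `miR-425-5p`). An optional three-letter species prefix (e.g. `cel-`) is
#' kept on precursor/mature names. Canonical names round-trip unchanged;
#' unparseable names are an error, never silently coerced.
#'
#' @param name Character vector of miRNA names.
#' @return A tibble with one row per input: `input`, `name` (canonical
#'   form), `tier` (`"gene"`, `"precursor"` or `"mature"`).
#' @examples
#' normalize_mir_name(c("MIR31", "miR-425-5p", "mir-133a"))
#' @export
normalize_mir_name <- function(name) {
  if (!is.character(name) || length(name) == 0) {
    abort("`name` must be a non-empty character vector.")
  }
  purrr::map_dfr(name, normalize_one_mir)
}

normalize_one_mir <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) {
    abort("miRNA names must be non-empty.")
  }
  x0 <- trimws(x)
  m <- regexec(
    "^([A-Za-z]{3}-)?(MIR|miR|mir)[-_ ]?([0-9][0-9A-Za-z]*(?:[-_ ][0-9A-Za-z]+)*)$",
    x0,
    perl = TRUE
  )
  g <- regmatches(x0, m)[[1]]
  if (length(g) == 0) {
    abort(paste0(
      "Cannot parse miRNA name '", x, "'. Expected MIR<id> (gene), ",
      "mir-<id> (precursor) or miR-<id> (mature), optionally with a ",
      "species prefix such as 'cel-'."
    ))
  }
  prefix <- g[2]
  tier <- c(MIR = "gene", mir = "precursor", miR = "mature")[[g[3]]]
  rest <- gsub("[-_ ]+", "-", g[4])
  if (tier == "gene") {
    if (nzchar(prefix)) {
      abort(paste0(
        "Species prefixes apply to precursor/mature names, not gene ",
        "symbols: '", x, "'"
      ))
    }
    canonical <- paste0("MIR", toupper(gsub("-", "", rest)))
  } else {
    stem <- if (tier == "precursor") "mir-" else "miR-"
    canonical <- paste0(tolower(prefix), stem, tolower(rest))
  }
  tibble::tibble(input = x, name = canonical, tier = tier)
}
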