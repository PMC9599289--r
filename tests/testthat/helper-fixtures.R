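# Shared in-code fixtures and independent oracles.

# 4-patient toy: g1 alters {p1, p2}, g2 {p3, p4}, g3 {p2, p3}.
toy_matrix <- function() {
  tibble::tibble(
    patient_id = paste0("p", 1:4),
    stage = c("I", "II", "II", "IV"),
    g1 = c(1L, 1L, 0L, 0L),
    g2 = c(0L, 0L, 1L, 1L),
    g3 = c(0L, 1L, 1L, 0L)
  )
}

# Random alteration matrix with gene columns G01, G02, ...
random_matrix <- function(n_patients, n_genes, density = 0.3) {
  alt <- matrix(
    rbinom(n_patients * n_genes, 1L, density),
    nrow = n_patients,
    dimnames = list(NULL, sprintf("G%02d", seq_len(n_genes)))
  )
  dplyr::bind_cols(
    tibble::tibble(
      patient_id = sprintf("p%03d", seq_len(n_patients)),
      stage = sample(c("I", "II", "III", "IV", "unknown"), n_patients, TRUE)
    ),
    tibble::as_tibble(alt)
  )
}

# Independent brute-force panel oracle: enumerates every k-subset of the
# (sorted) candidates and computes coverage per patient with any(),
# returning the maximal coverage and the lexicographically first argmax.
brute_force_best_panel <- function(data, k, candidates) {
  cand <- sort(candidates)
  subsets <- utils::combn(cand, k, simplify = FALSE)
  cov <- vapply(subsets, function(p) {
    covered <- apply(data[, p, drop = FALSE] == 1, 1, any)
    sum(covered) / nrow(data)
  }, numeric(1))
  best <- which.max(cov)
  list(coverage = cov[best], panel = subsets[[best]])
}

# Long-format Cq rows for one sample: each assay gets `n_tech` wells at
# the given Cq values (recycled). NA encodes a non-detect well.
cq_sample <- function(sample_id, cell_line, bio, assays) {
  purrr::imap_dfr(assays, function(values, assay) {
    tibble::tibble(
      sample_id = sample_id,
      cell_line = cell_line,
      biological_replicate = bio,
      technical_replicate = seq_along(values),
      assay = assay,
      cq = as.numeric(values)
    )
  })
}

# A 2-line Cq table with both controls at fixed values and the given
# per-sample target-assay means (list: cell_line -> list of per-sample
# named assay vectors).
cq_table_from_means <- function(design, controls = c("miR-16-5p" = 20, "cel-miR-2-3p" = 22)) {
  purrr::imap_dfr(design, function(samples, line) {
    purrr::imap_dfr(samples, function(assays, i) {
      all_assays <- c(
        assays,
        purrr::map(as.list(controls), function(v) rep(v, 3))
      )
      cq_sample(paste0(line, "_b", i), line, as.integer(i), all_assays)
    })
  })
}

# Textbook pooled-variance two-sample t statistic and p-value.
pooled_t_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  list(t = t, p = 2 * pt(-abs(t), df))
}
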