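# Annotation filters, mature-arm expansion and nomenclature.

test_that("exosomal filter preserves order and errors on unannotated genes", {
  ann <- tibble::tibble(
    symbol = c("MIRA", "MIRB", "MIRC"),
    exosomal = c(TRUE, FALSE, TRUE),
    dir_pancreatitis_vs_healthy = "none",
    dir_pdac_vs_pancreatitis = "none",
    mature_arms = list("miR-a-5p", "miR-b-5p", "miR-c-5p")
  )
  expect_identical(filter_exosomal(ann, c("MIRC", "MIRA")), c("MIRC", "MIRA"))
  expect_identical(filter_exosomal(ann, "MIRB"), character(0))
  all_exo <- dplyr::mutate(ann, exosomal = TRUE)
  expect_identical(filter_exosomal(all_exo, ann$symbol), ann$symbol)
  expect_error(filter_exosomal(ann, c("MIRA", "MIRX")), "MIRX")
})

test_that("the demo funnel annotation flags 50 of the 72 frequent genes exosomal", {
  demo <- demo_lead_dataset()
  frequent <- filter_genes_by_frequency(demo$alteration, 0.10)$gene
  expect_length(frequent, 72)
  expect_length(filter_exosomal(demo$annotation, frequent), 50)
})

test_that("disease-differential filter distinguishes none from unknown", {
  ann <- tibble::tibble(
    symbol = c("MIR31", "MIRNONE", "MIRUNK", "MIRHALF"),
    exosomal = TRUE,
    dir_pancreatitis_vs_healthy = c("down", "none", "unknown", "none"),
    dir_pdac_vs_pancreatitis = c("up", "none", "unknown", "unknown"),
    mature_arms = list("x-5p", "x-5p", "x-5p", "x-5p")
  )
  # assessed-differential kept, assessed-flat dropped silently
  expect_identical(
    filter_disease_differential(ann, c("MIR31", "MIRNONE")),
    "MIR31"
  )
  # fully unassessed drops with a warning; mixed none/unknown drops silently
  expect_warning(
    out <- filter_disease_differential(ann, c("MIR31", "MIRUNK", "MIRHALF")),
    "MIRUNK"
  )
  expect_identical(out, "MIR31")
})

test_that("annotation filters are order-preserving and idempotent", {
  ann <- pdac_mir_annotation()
  genes <- rev(ann$symbol)
  once <- filter_disease_differential(ann, genes)
  expect_identical(filter_disease_differential(ann, once), once)
  expect_identical(once, genes[genes %in% once]) # order preserved
  exo <- filter_exosomal(ann, genes)
  expect_identical(filter_exosomal(ann, exo), exo)
})

test_that("mature expansion yields 18 miRs for the core panel, 5p before 3p", {
  ann <- pdac_mir_annotation()
  mature <- expand_to_mature(ann, pdac_mir_panel("core"))
  expect_length(mature, 18)
  expect_setequal(mature, pdac_mature_mirs())
  # 5p precedes 3p within each gene
  expect_lt(match("miR-31-5p", mature), match("miR-31-3p", mature))
  expect_lt(match("miR-425-5p", mature), match("miR-425-3p", mature))
  # single-form genes contribute one name
  expect_identical(expand_to_mature(ann, "MIR429"), "miR-429")
  expect_identical(expand_to_mature(ann, character(0)), character(0))
  # expansion length is the sum of per-gene arm counts
  expect_length(expand_to_mature(ann, c("MIR31", "MIR429")), 3)

  broken <- ann
  broken$mature_arms[broken$symbol == "MIR429"] <- list(character(0))
  expect_error(expand_to_mature(broken, "MIR429"), "MIR429")
})

test_that("miRNA names canonicalize by prefix casing and round-trip", {
  out <- normalize_mir_name(c("MIR31", "miR-425-5p", "mir-133a"))
  expect_identical(out$name, c("MIR31", "miR-425-5p", "mir-133a"))
  expect_identical(out$tier, c("gene", "mature", "precursor"))
  # separators and case are canonicalized
  messy <- normalize_mir_name(c("MIR 133a1", "miR_425 5P", "cel-miR-2-3p"))
  expect_identical(messy$name, c("MIR133A1", "miR-425-5p", "cel-miR-2-3p"))
  # idempotent on its own outputs
  again <- normalize_mir_name(messy$name)
  expect_identical(again$name, messy$name)
  expect_identical(again$tier, messy$tier)
  expect_error(normalize_mir_name("Mir31"), "Cannot parse")
  expect_error(normalize_mir_name("totally-wrong"), "Cannot parse")
})

test_that("annotation tables round-trip through the TSV dialect", {
  path <- withr::local_tempfile(fileext = ".tsv")
  ann <- pdac_mir_annotation()[, -6] # drop the panel10 convenience column
  write_annotation(ann, path)
  back <- read_annotation(path)
  expect_identical(back$symbol, ann$symbol)
  expect_identical(back$mature_arms, ann$mature_arms)
  expect_identical(back$exosomal, ann$exosomal)
})
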