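# Alteration frequencies, panel coverage and panel optimization.

test_that("alteration_frequency matches direct division, including edge cases", {
  m <- simulate_alteration_matrix(
    n_patients = 109,
    gene_freqs = c(GZERO = 0, GALL = 1, GSOME = 0.2),
    seed = 11
  )
  # force an exact 11/109 column
  m$GSOME <- c(rep(1L, 11), rep(0L, 98))
  freq <- alteration_frequency(m)
  expect_equal(freq$frequency[freq$gene == "GZERO"], 0)
  expect_equal(freq$frequency[freq$gene == "GALL"], 1)
  expect_equal(freq$frequency[freq$gene == "GSOME"], 11 / 109)
  expect_equal(freq$n_patients, rep(109L, 3))

  expect_error(alteration_frequency(m, "NOPE"), "Unknown gene")
  expect_error(alteration_frequency(m[0, ]), "no patients")
})

test_that("frequency filter is inclusive at the threshold", {
  m <- toy_matrix()[rep(1, 109), ]
  m$patient_id <- sprintf("p%03d", 1:109)
  m$g1 <- c(rep(1L, 11), rep(0L, 98)) # 11/109 ~ 0.1009: kept
  m$g2 <- c(rep(1L, 10), rep(0L, 99)) # 10/109 ~ 0.0917: dropped
  m$g3 <- rep(0L, 109)
  kept <- filter_genes_by_frequency(m, min_fraction = 0.10)
  expect_identical(kept$gene, "g1")
  # vacuous threshold keeps everything, in column order
  expect_identical(
    filter_genes_by_frequency(m, min_fraction = 0)$gene,
    c("g1", "g2", "g3")
  )
  expect_error(filter_genes_by_frequency(m, min_fraction = 1.2), "0, 1")
})

test_that("panel_coverage counts patients with >= 1 altered panel gene", {
  m <- toy_matrix()
  expect_equal(panel_coverage(m, character(0))$coverage, 0)
  g3 <- panel_coverage(m, "g3")
  expect_equal(g3$n_covered, 2L)
  expect_equal(g3$coverage, 0.5)
  both <- panel_coverage(m, c("g1", "g2"))
  expect_equal(both$n_covered, 4L)
  expect_equal(both$coverage, 1)

  expect_error(panel_coverage(m, c("g1", "g1")), "Duplicated")
  expect_error(panel_coverage(m, c("g1", "gX")), "gX")
})

test_that("single-gene coverage equals alteration frequency", {
  withr::with_seed(21, {
    m <- random_matrix(30, 8)
    freq <- alteration_frequency(m)
    for (g in freq$gene) {
      expect_equal(panel_coverage(m, g)$coverage, freq$frequency[freq$gene == g])
    }
  })
})

test_that("coverage is monotone in panel inclusion", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      m <- random_matrix(sample(5:30, 1), sample(3:10, 1), runif(1, 0.1, 0.5))
      genes <- setdiff(names(m), c("patient_id", "stage"))
      big <- sample(genes, sample(2:length(genes), 1))
      small <- sample(big, sample(seq_len(length(big) - 1), 1))
      expect_lte(
        panel_coverage(m, small)$coverage,
        panel_coverage(m, big)$coverage
      )
    }
  })
})

test_that("select_panel solves the toy exactly and ties break lexicographically", {
  m <- toy_matrix()
  k2 <- select_panel(m, k = 2)
  expect_identical(k2$panel[[1]], c("g1", "g2"))
  expect_equal(k2$coverage, 1)
  expect_identical(k2$method, "exhaustive")
  # g1, g2, g3 each cover 2 patients; lexicographic tie-break picks g1
  k1 <- select_panel(m, k = 1)
  expect_identical(k1$panel[[1]], "g1")
  # k >= |candidates| returns the whole candidate set
  all3 <- select_panel(m, k = 5)
  expect_identical(all3$panel[[1]], c("g1", "g2", "g3"))
  expect_identical(all3$method, "all")

  expect_error(select_panel(m, k = 0), "positive integer")
  expect_error(select_panel(m, k = 2, candidates = character(0)), "at least one")
})

test_that("exhaustive path equals the brute-force oracle; greedy is near-optimal", {
  withr::with_seed(41, {
    for (rep in 1:40) {
      m <- random_matrix(sample(8:30, 1), sample(4:12, 1), runif(1, 0.1, 0.4))
      genes <- setdiff(names(m), c("patient_id", "stage"))
      k <- sample(2:(length(genes) - 1), 1)
      oracle <- brute_force_best_panel(m, k, genes)
      exact <- select_panel(m, k = k, candidates = genes)
      expect_equal(exact$coverage, oracle$coverage)
      expect_identical(exact$panel[[1]], oracle$panel)
      greedy <- select_panel(m, k = k, candidates = genes, exhaustive_limit = 0)
      expect_identical(greedy$method, "greedy")
      expect_gte(greedy$coverage, (1 - exp(-1)) * oracle$coverage)
    }
  })
})

test_that("select_panel is deterministic", {
  withr::with_seed(51, m <- random_matrix(25, 10))
  genes <- setdiff(names(m), c("patient_id", "stage"))
  a <- select_panel(m, k = 4, candidates = genes)
  b <- select_panel(m[sample(nrow(m)), ], k = 4, candidates = genes)
  expect_identical(a$panel, b$panel)
  g1 <- select_panel(m, k = 4, candidates = genes, exhaustive_limit = 0)
  g2 <- select_panel(m, k = 4, candidates = rev(genes), exhaustive_limit = 0)
  expect_identical(g1$panel, g2$panel)
})

test_that("panel evaluations serialize to JSON with panel order preserved", {
  ev <- select_panel(toy_matrix(), k = 2)
  parsed <- jsonlite::fromJSON(panel_json(ev))
  expect_identical(parsed$panel, c("g1", "g2"))
  expect_equal(parsed$coverage, 1)
  expect_identical(parsed$method, "exhaustive")
})
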