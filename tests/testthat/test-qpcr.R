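# Censoring, detectability, control averaging and delta-Cq.

test_that("censoring imputes non-detects and Cq above the ceiling, idempotently", {
  tab <- cq_sample("s1", "A", 1L, list(
    "m-1-5p" = c(35.6, NA, 34.2, 35.0)
  ))
  out <- censor_cq(tab)
  expect_equal(out$cq, c(36, 36, 34.2, 35.0))
  expect_identical(out$censored, c(TRUE, TRUE, FALSE, FALSE))
  # a well at exactly the ceiling is a real measurement
  expect_false(out$censored[4])
  # idempotent, non_detect provenance preserved
  again <- censor_cq(out)
  expect_identical(again$cq, out$cq)
  expect_identical(again$censored, out$censored)
  expect_identical(again$non_detect, c(FALSE, TRUE, FALSE, FALSE))

  expect_error(censor_cq(tab, ceiling = 36, imputed = 36), "strictly below")
  bad <- tab
  bad$cq[1] <- -3
  expect_error(censor_cq(bad), "positive")
})

test_that("detectability applies the 20% well rule and drops empty samples", {
  wells <- function(n_det) c(rep(30, n_det), rep(NA, 9 - n_det))
  tab <- dplyr::bind_rows(
    cq_sample("s1", "A", 1L, list(
      "m-0" = wells(0), "m-1" = wells(1), "m-2" = wells(2),
      "miR-16-5p" = rep(20, 3), "cel-miR-2-3p" = rep(22, 3)
    )),
    cq_sample("s2", "A", 2L, list("m-0" = rep(NA_real_, 3)))
  )
  res <- detectability_filter(censor_cq(tab))
  # s2 has no numeric Cq on any assay
  expect_identical(res$dropped_samples, "s2")
  expect_false("s2" %in% res$data$sample_id)
  det <- res$detectability
  flag <- function(a) det$detectable[det$assay == a & det$cell_line == "A"]
  expect_false(flag("m-0")) # 0/9
  expect_false(flag("m-1")) # 1/9 ~ 11% < 20%
  expect_true(flag("m-2")) # 2/9 ~ 22% >= 20%
  frac <- function(a) det$detected_fraction[det$assay == a & det$cell_line == "A"]
  expect_equal(frac("m-1"), 1 / 9)
  expect_equal(frac("m-2"), 2 / 9)
})

test_that("control Cq averages the two per-assay means and flags failures", {
  tab <- cq_sample("s1", "A", 1L, list(
    "miR-16-5p" = c(20, 20, 20),
    "cel-miR-2-3p" = c(22, 22, 22),
    "m-1" = c(25, 25, 25)
  ))
  cc <- control_cq(tab)
  expect_equal(cc$control_cq, 21)
  expect_false(cc$control_failed)

  same <- cq_sample("s1", "A", 1L, list(
    "miR-16-5p" = c(19, 21), "cel-miR-2-3p" = c(20, 20)
  ))
  expect_equal(control_cq(same)$control_cq, 20)

  failed <- cq_sample("s1", "A", 1L, list(
    "miR-16-5p" = c(20, 20), "cel-miR-2-3p" = c(NA_real_, NA_real_)
  ))
  expect_warning(cc2 <- control_cq(failed), "control-failed")
  expect_true(cc2$control_failed)
  expect_true(is.na(cc2$control_cq))
})

test_that("delta-Cq subtracts the control mean; censored wells participate", {
  tab <- cq_sample("s1", "A", 1L, list(
    "miR-16-5p" = c(20, 20, 20),
    "cel-miR-2-3p" = c(22, 22, 22),
    "m-1" = c(24, 24, 24),
    "m-2" = c(21, 21, 21),
    "m-3" = c(36, 36, NA) # high + non-detect wells
  ))
  dcq <- delta_cq(censor_cq(tab))
  val <- function(a) dcq$delta_cq[dcq$assay == a]
  expect_equal(val("m-1"), 3)
  expect_equal(val("m-2"), 0)
  # censored wells enter the mean at the imputed 36
  expect_equal(val("m-3"), 36 - 21)
  # control assays never appear as targets
  expect_false(any(control_assay_names() %in% dcq$assay))
})

test_that("Cq tables round-trip through both CSV dialects", {
  tab <- dplyr::bind_rows(
    cq_sample("s1", "A", 1L, list("m-1" = c(30, NA), "miR-16-5p" = c(20, 20))),
    cq_sample("s2", "B", 1L, list("m-1" = c(28, 29), "miR-16-5p" = c(20, 21)))
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_cq(tab, path)
  expect_true(any(grepl("Undetermined", readLines(path))))
  back <- read_cq(path)
  expect_equal(back$cq, tab$cq)
  expect_identical(back$non_detect, is.na(tab$cq))

  wide <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "sample_id,cell_line,biological_replicate,technical_replicate,m-1,miR-16-5p",
    "s1,A,1,1,30.5,20",
    "s1,A,1,2,Undetermined,20.2"
  ), wide)
  long <- read_cq_wide(wide)
  expect_equal(nrow(long), 4L)
  expect_equal(sum(long$non_detect), 1L)
  expect_equal(long$cq[long$assay == "m-1" & long$technical_replicate == 1], 30.5)
})

test_that("malformed Cq tables are rejected with explicit errors", {
  tab <- cq_sample("s1", "A", 1L, list("m-1" = c(30, 31)))
  dup <- dplyr::bind_rows(tab, tab[1, ])
  expect_error(censor_cq(dup), "Duplicated")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "sample_id,cell_line,biological_replicate,technical_replicate,assay,cq",
    "s1,A,1,1,m-1,oops"
  ), path)
  expect_error(read_cq(path), "Unparseable")
})
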