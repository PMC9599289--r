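# Delta-delta-Cq quantification, significance tiers, collation and
# arm preference.

# Two lines, 3 samples each; target m-1 shifted by -3 Cq in line B
# (log2 fold change +3) with a little within-line spread.
two_line_table <- function() {
  cq_table_from_means(list(
    A = list(
      `1` = list("m-1" = rep(28.0, 3), "m-2" = rep(26.0, 3)),
      `2` = list("m-1" = rep(28.2, 3), "m-2" = rep(26.1, 3)),
      `3` = list("m-1" = rep(27.8, 3), "m-2" = rep(25.9, 3))
    ),
    B = list(
      `1` = list("m-1" = rep(25.0, 3), "m-2" = rep(26.1, 3)),
      `2` = list("m-1" = rep(25.2, 3), "m-2" = rep(25.9, 3)),
      `3` = list("m-1" = rep(24.8, 3), "m-2" = rep(26.0, 3))
    )
  ))
}

test_that("quantify recovers the ddCq definition and the control self-comparison", {
  q <- quantify(two_line_table(), control_cell_line = "A")
  b1 <- q[q$cell_line == "B" & q$mir == "m-1", ]
  expect_equal(b1$delta_delta_cq, -3)
  expect_equal(b1$log2_fc, 3)
  expect_equal(2^b1$log2_fc, 8)
  # control line vs itself: zero fold change, no test
  a_rows <- q[q$cell_line == "A", ]
  expect_true(all(a_rows$log2_fc == 0))
  expect_true(all(is.na(a_rows$p_value)))
  # identical delta-Cq vectors in both lines: t = 0, p = 1, ns
  b2 <- q[q$cell_line == "B" & q$mir == "m-2", ]
  expect_equal(b2$p_value, 1, tolerance = 1e-12)
  expect_identical(b2$tier, "ns")

  expect_error(quantify(two_line_table(), "NOPE"), "not present")
})

test_that("adding a per-sample constant to every Cq leaves results unchanged", {
  tab <- two_line_table()
  shifted <- tab |>
    dplyr::group_by(sample_id) |>
    dplyr::mutate(cq = cq + 1.5 * dplyr::cur_group_id()) |>
    dplyr::ungroup()
  q0 <- tidy(quantify(tab, "A"))
  q1 <- tidy(quantify(shifted, "A"))
  expect_equal(q1$log2_fc, q0$log2_fc)
  expect_equal(q1$p_value, q0$p_value)
  expect_equal(q1$mean_delta_cq, q0$mean_delta_cq)
})

test_that("swapping target and control cell lines negates log2 fold changes", {
  tab <- two_line_table()
  ab <- tidy(quantify(tab, "A"))
  ba <- tidy(quantify(tab, "B"))
  m <- ab[ab$cell_line == "B", c("mir", "log2_fc", "p_value")]
  w <- ba[ba$cell_line == "A", c("mir", "log2_fc", "p_value")]
  expect_equal(w$log2_fc[match(m$mir, w$mir)], -m$log2_fc)
  expect_equal(w$p_value[match(m$mir, w$mir)], m$p_value)
})

test_that("quantify is invariant to record order", {
  tab <- two_line_table()
  withr::with_seed(71, shuffled <- tab[sample(nrow(tab)), ])
  expect_equal(tidy(quantify(tab, "A")), tidy(quantify(shuffled, "A")))
})

test_that("one-sided and two-sided non-detection are flagged correctly", {
  tab <- cq_table_from_means(list(
    A = list(
      `1` = list("m-gone" = rep(NA_real_, 3), "m-dead" = rep(NA_real_, 3)),
      `2` = list("m-gone" = rep(NA_real_, 3), "m-dead" = rep(NA_real_, 3)),
      `3` = list("m-gone" = rep(NA_real_, 3), "m-dead" = rep(NA_real_, 3))
    ),
    B = list(
      `1` = list("m-gone" = rep(27, 3), "m-dead" = rep(NA_real_, 3)),
      `2` = list("m-gone" = rep(27.2, 3), "m-dead" = rep(NA_real_, 3)),
      `3` = list("m-gone" = rep(26.8, 3), "m-dead" = rep(NA_real_, 3))
    )
  ))
  q <- quantify(tab, "A")
  gone <- q[q$cell_line == "B" & q$mir == "m-gone", ]
  # detectable in B only: quantified against the censored 36s in A
  expect_true(gone$detectable)
  expect_true(gone$one_sided_detection)
  expect_equal(gone$log2_fc, (36 - 21) - (27 - 21), tolerance = 0.2)
  dead <- q[q$cell_line == "B" & q$mir == "m-dead", ]
  expect_false(dead$detectable)
  expect_true(is.na(dead$log2_fc) && is.na(dead$p_value))
})

test_that("t statistics match the textbook pooled-variance formula", {
  withr::with_seed(81, {
    for (rep in 1:50) {
      x <- rnorm(sample(3:8, 1))
      y <- rnorm(sample(3:8, 1), mean = runif(1, -1, 1))
      ours <- exomir:::safe_t_test(x, y)
      oracle <- pooled_t_oracle(x, y)
      expect_equal(ours$t, oracle$t, tolerance = 1e-10)
      expect_equal(ours$p, oracle$p, tolerance = 1e-10)
    }
  })
})

test_that("significance tiers use inclusive boundaries", {
  expect_identical(
    significance_tier(c(0.0005, 0.001, 0.01, 0.04, 0.05, 0.0691, NA)),
    c("***", "***", "**", "*", "*", "ns", NA)
  )
  expect_error(significance_tier(1.2), "\\[0, 1\\]")
  expect_error(significance_tier(-0.1), "\\[0, 1\\]")
})

test_that("collation reports each miR's cell-line membership", {
  res <- tibble::tibble(
    cell_line = c("X", "Y", "X", "Y"),
    mir = c("m-a", "m-a", "m-b", "m-c"),
    p_value = c(0.01, 0.04, 0.2, NA)
  )
  out <- collate_significant(res)
  expect_identical(out$mir, "m-a")
  expect_identical(out$cell_lines[[1]], c("X", "Y"))
  expect_equal(nrow(collate_significant(dplyr::mutate(res, p_value = 1))), 0L)
})

test_that("arm preference follows the relative-expression definition", {
  tab <- cq_table_from_means(list(
    A = list(
      `1` = list("m-7-5p" = rep(25.0, 3), "m-7-3p" = rep(28.0, 3),
                 "m-8-5p" = rep(26, 3), "m-8-3p" = rep(26, 3)),
      `2` = list("m-7-5p" = rep(25.1, 3), "m-7-3p" = rep(28.1, 3),
                 "m-8-5p" = rep(26.1, 3), "m-8-3p" = rep(26.1, 3)),
      `3` = list("m-7-5p" = rep(24.9, 3), "m-7-3p" = rep(27.9, 3),
                 "m-8-5p" = rep(25.9, 3), "m-8-3p" = rep(25.9, 3))
    )
  ))
  arms <- arm_preference(tab)
  m7 <- arms[arms$family == "m-7", ]
  # dCq_5p mean 20-ish below dCq_3p: 2^(m5 - m3) = 2^-3
  expect_equal(m7$rel_expr_3p_vs_5p, 2^(-3), tolerance = 1e-12)
  expect_identical(m7$preferred_arm, "5p")
  expect_lte(m7$p_value, 0.05)
  # identical arms: ratio 1, no preference
  m8 <- arms[arms$family == "m-8", ]
  expect_equal(m8$rel_expr_3p_vs_5p, 1)
  expect_identical(m8$preferred_arm, "none")
})

test_that("single-arm families and fully undetected arms are flagged", {
  tab <- cq_table_from_means(list(
    A = list(
      `1` = list("m-9" = rep(27, 3),
                 "m-10-5p" = rep(26, 3), "m-10-3p" = rep(NA_real_, 3)),
      `2` = list("m-9" = rep(27.1, 3),
                 "m-10-5p" = rep(26.2, 3), "m-10-3p" = rep(NA_real_, 3)),
      `3` = list("m-9" = rep(26.9, 3),
                 "m-10-5p" = rep(25.8, 3), "m-10-3p" = rep(NA_real_, 3))
    )
  ))
  arms <- arm_preference(tab)
  m9 <- arms[arms$family == "m-9", ]
  expect_true(m9$not_applicable)
  m10 <- arms[arms$family == "m-10", ]
  expect_true(m10$one_arm_undetected)
  expect_true(m10$evaluable)
  # the undetected 3p arm enters at the censored 36
  expect_equal(m10$mean_dcq_3p, 36 - 21)
  expect_identical(m10$preferred_arm, "5p")
})

test_that("run_quantification assembles a deterministic report", {
  sim <- simulate_cq_table(
    cell_lines = c("HPNE", "PANC1"),
    mirs = c("miR-31-5p", "miR-31-3p"),
    base_cq = c("miR-31-5p" = 27, "miR-31-3p" = 29),
    true_log2_fc = data.frame(
      cell_line = "PANC1", mir = c("miR-31-5p", "miR-31-3p"),
      log2_fc = c(4, 4)
    ),
    seed = 91
  )
  r1 <- run_quantification(sim$cq, "HPNE")
  r2 <- run_quantification(sim$cq, "HPNE")
  expect_equal(tidy(r1$quant), tidy(r2$quant))
  expect_identical(r1$significant$mir, c("miR-31-3p", "miR-31-5p"))
  expect_s3_class(r1$arms, "arm_comparison")

  controls_only <- cq_table_from_means(list(
    A = list(`1` = list(), `2` = list()),
    B = list(`1` = list(), `2` = list())
  ))
  expect_warning(
    empty <- quantify(controls_only, "A"),
    "No target assays"
  )
  expect_equal(nrow(empty), 0L)
})

test_that("tidy, glance and autoplot views work on fitted objects", {
  q <- quantify(two_line_table(), "A")
  td <- tidy(q)
  expect_false(inherits(td, "mir_quant"))
  g <- glance(q)
  expect_equal(g$n_mirs, 2L)
  expect_identical(g$control_cell_line, "A")
  expect_s3_class(autoplot(q), "ggplot")
  arms <- arm_preference(two_line_table())
  expect_s3_class(autoplot(arms), "ggplot")
})
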