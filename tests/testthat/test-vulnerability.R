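test_that("outcome sequence helper detects interleaving", {
  ordered <- c("NO_PROPAGATION", "NO_PROPAGATION", "BZ_BLOCK",
               "FULL_PROPAGATION")
  expect_true(alternansim:::.scan_ordered(ordered))
  expect_true(alternansim:::.scan_ordered(c("NO_PROPAGATION",
                                            "FULL_PROPAGATION")))
  expect_false(alternansim:::.scan_ordered(rev(ordered)))
  expect_false(alternansim:::.scan_ordered(c("NO_PROPAGATION", "BZ_BLOCK",
                                             "NO_PROPAGATION")))
})

test_that("outcome classification agrees with a whole-fiber activation oracle", {
  pp <- std_sim("pp0")
  seg <- alternansim:::.block_segment(pp$config)
  for (ci in c(195, 213, 235)) {
    rec <- apply_s2(pp, seg, ci, after = "long")
    out <- classify_outcome(rec)
    act <- s2_activation_times(rec)
    n <- pp$config$n_cells
    # brute force: inspect every cell, not just the sentinels
    if (out$category == "FULL_PROPAGATION") {
      expect_true(all(is.finite(act)))
    } else if (out$category == "NO_PROPAGATION") {
      far <- setdiff(seq_len(n), (min(seg) - 8):(max(seg) + 8))
      expect_false(any(is.finite(act[far])))
    } else {
      # one side reached, the other not: the far end stays silent
      expect_true(xor(is.finite(act[5]), is.finite(act[n - 4])))
    }
  }
})

test_that("classification covers the three scenarios along the block scan", {
  scan <- std_sim("block0")$scan
  expect_setequal(unique(scan$category),
                  c("NO_PROPAGATION", "BZ_BLOCK", "FULL_PROPAGATION"))
  # refractory end of the scan fails, recovered end conducts fully
  expect_equal(scan$category[1], "NO_PROPAGATION")
  expect_equal(scan$category[nrow(scan)], "FULL_PROPAGATION")
})

test_that("outcomes are invariant to extending the post-stimulus recording", {
  pp <- std_sim("pp0")
  seg <- alternansim:::.block_segment(pp$config)
  for (ci in c(213, 235)) {
    c1 <- classify_outcome(apply_s2(pp, seg, ci, after = "long",
                                    tail_ms = 500))$category
    c2 <- classify_outcome(apply_s2(pp, seg, ci, after = "long",
                                    tail_ms = 800))$category
    expect_identical(c1, c2)
  }
})

test_that("premature-complex scan returns the sentinel when nothing conducts", {
  pp <- std_sim("pp0")
  res <- min_propagating_ci(pp, ci_range = c(150, 160), step = 5)
  expect_identical(res$min_full_ci, Inf)
  expect_true(res$scan_truncated)
})

test_that("the fiber table reports the standard configurations and rejects bad ids", {
  expect_error(table2_harness(fibers = c("A", "Z")), "valid ids")
  tb <- std_sim("table2")
  expect_equal(tb$fiber_id, c("A", "B", "C", "D", "E"))
  expect_equal(tb$bcl_ms, c(300, 300, 400, 400, 300))
  expect_equal(tb$composition, c("NZ-BZ-NZ", "NZ only", "NZ-BZ-NZ",
                                 "NZ only", "NZ-BZ-NZ"))
  expect_equal(tb$bar_level, c(0, 0, 0, 0, 1))
  expect_true(all(is.finite(tb$min_ci_ms)))
})

test_that("scan results land on the requested coupling-interval grid", {
  scan <- std_sim("block0")$scan
  expect_equal(scan$ci_ms, seq(190, 240, by = 1))
  expect_true(all(scan$ci_ms == round(scan$ci_ms)))
})
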