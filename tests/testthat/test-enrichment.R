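test_that("one-sided Fisher P matches the hypergeometric tail oracle on worked examples", {
  # no protein counts anywhere: the tail holds all the mass
  expect_equal(fisher_onesided(0, 0, 100, 100), 1)

  # frozen from the enumeration oracle (sum over x >= a of the pmf)
  expect_equal(fisher_onesided(5, 0, 95, 100),
               hyper_tail_oracle(5, 0, 95, 100), tolerance = 1e-12)
  expect_equal(fisher_onesided(1, 1, 1, 1),
               hyper_tail_oracle(1, 1, 1, 1), tolerance = 1e-12)
  # the 1/1/1/1 oracle value by hand: 1 - C(2,0)C(2,2)/C(4,2) = 5/6
  expect_equal(fisher_onesided(1, 1, 1, 1), 5 / 6, tolerance = 1e-12)

  expect_error(fisher_onesided(0, 0, 0, 0), "all four")
  expect_error(fisher_onesided(1.5, 0, 3, 4), "non-negative integers")
  expect_error(fisher_onesided(-1, 0, 3, 4), "non-negative integers")
})

test_that("one-sided Fisher P agrees with stats::fisher.test on random tables", {
  set.seed(7)
  for (i in 1:40) {
    cells <- rpois(4, 15)
    if (sum(cells) == 0) next
    expected <- stats::fisher.test(matrix(cells, 2, byrow = TRUE),
                                   alternative = "greater")$p.value
    expect_equal(fisher_onesided(cells[1], cells[2], cells[3], cells[4]),
                 expected, tolerance = 1e-10)
  }
})

test_that("BH adjustment reproduces hand-computed step-up values", {
  expect_equal(bh_adjust(0.04), 0.04)                   # m = 1 leaves P unchanged
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),    # p(i)*m/i with cummin from top
               rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 6)), rep(0.2, 6))     # p*m/m = p
  expect_error(bh_adjust(numeric()), "empty")
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(1.2), "0, 1")
})

test_that("log2 fold change uses the pseudocounted ratio", {
  expect_equal(log2_fold_change(10, 10), 0)
  expect_equal(log2_fold_change(400, 100, 0.5), log2(400.5 / 100.5))
  expect_equal(log2_fold_change(8, 0, 0.5), log2(17))
  expect_error(log2_fold_change(-1, 2), "non-negative")
  expect_error(log2_fold_change(1, 2, pseudocount = 0), "positive")
})

test_that("score_bait calls a clean planted prey significant and leaves flat background alone", {
  toy <- make_toy_experiment()
  rec <- score_bait(toy$counts, toy$sheet, "TK0001", TRUE, TRUE)
  expect_s3_class(rec, "enrichment_records")

  prey <- rec[rec$protein_id == "TK0002", ]
  expect_true(prey$significant)
  expect_equal(prey$n_detected, 3L)
  expect_gt(prey$log2fc, 4)
  # pooled 2x2 must match the oracle exactly
  X <- unclass(toy$counts)[, 1:3]; Y <- unclass(toy$counts)[, 4:7]
  a <- sum(X["TK0002", ]); b <- sum(Y["TK0002", ])
  expect_equal(prey$p_raw, hyper_tail_oracle(a, b, sum(X) - a, sum(Y) - b),
               tolerance = 1e-12)

  # identical pooled proportions on both sides: not significant
  flat <- rec[rec$protein_id == "TK0004", ]
  expect_false(flat$significant)
  expect_lt(abs(flat$log2fc), 0.5)

  # the sticky binder, elevated equally everywhere, is rejected too
  expect_false(rec[rec$protein_id == "TK0006", "significant"])
})

test_that("proteins absent from all experimental runs are not tested", {
  toy <- make_toy_experiment()
  counts <- unclass(toy$counts)
  counts["TK0005", 1:3] <- 0L   # present only in controls
  rec <- score_bait(spectral_counts(counts), toy$sheet, "TK0001", TRUE, TRUE)
  expect_false("TK0005" %in% rec$protein_id)
})

test_that("a high-count prey absent from controls is significant against deep background", {
  # counts (10, 12, 9) in three experimental runs, 0 in four controls,
  # ~1e4 background counts per run on both sides
  proteins <- c("TK0010", sprintf("TK%04d", 100:119))
  runs <- c(paste0("B_pSpP_E", 1:3), paste0("TS559_pSpP_C", 1:4))
  counts <- matrix(500L, nrow = length(proteins), ncol = 7,
                   dimnames = list(proteins, runs))
  counts["TK0010", ] <- c(10L, 12L, 9L, 0L, 0L, 0L, 0L)
  sheet <- sample_sheet(data.frame(
    run_id = runs, strain = c(rep("B", 3), rep("PARENTAL", 4)),
    role = c(rep("experimental", 3), rep("control", 4)),
    sulfur = TRUE, pyruvate = TRUE, replicate = c(1:3, 1:4)
  ))
  rec <- score_bait(spectral_counts(counts), sheet, "B", TRUE, TRUE)
  prey <- rec[rec$protein_id == "TK0010", ]
  expect_true(prey$significant)
  expect_gt(prey$log2fc, 4)
  a <- 31; tot_e <- sum(counts[, 1:3]); tot_c <- sum(counts[, 4:7])
  expect_equal(prey$p_raw, hyper_tail_oracle(a, 0, tot_e - a, tot_c),
               tolerance = 1e-8)
})

test_that("bait rescue lowers the fold-change threshold only when warranted", {
  base <- make_records(
    protein_id = c("TK0001", "TK0002", "TK0003", "TK0004"),
    log2fc = c(1.8, 1.9, 1.5, 0.5),
    p_adj = c(0.01, 0.02, 0.03, 0.2), p_raw = c(0.01, 0.02, 0.03, 0.2),
    significant = FALSE
  )

  # bait at log2fc 1.8 with adjusted P < 0.05: threshold drops to 1.8 and
  # every protein passing P with log2fc >= 1.8 comes along
  expect_message(out <- rescue_bait(base), "rescued bait TK0001")
  expect_true(all(out$significant[1:2]))
  expect_true(all(out$rescued[1:2]))
  expect_false(out$significant[3])  # log2fc 1.5 below the adjusted range
  expect_false(out$significant[4])  # fails the P criterion
  expect_equal(attr(out, "rescue")$threshold, 1.8)

  # bait already passing: unchanged
  ok <- make_records(protein_id = c("TK0001", "TK0002"),
                     log2fc = c(3.0, 1.9), p_adj = 0.01, p_raw = 0.01,
                     significant = c(TRUE, FALSE))
  expect_identical(rescue_bait(ok)$significant, c(TRUE, FALSE))

  # bait failing the P criterion: no rescue
  bad_p <- make_records(protein_id = c("TK0001", "TK0002"),
                        log2fc = c(1.8, 1.9), p_adj = 0.2, p_raw = 0.2,
                        significant = FALSE)
  expect_identical(rescue_bait(bad_p)$significant, c(FALSE, FALSE))

  # bait below the rescue floor: a failed purification cannot drag the threshold
  low <- make_records(protein_id = c("TK0001", "TK0002"),
                      log2fc = c(0.4, 1.9), p_adj = 0.01, p_raw = 0.01,
                      significant = FALSE)
  expect_identical(rescue_bait(low)$significant, c(FALSE, FALSE))

  # bait not detected at all: warning, records unchanged
  absent <- make_records(protein_id = "TK0002", significant = FALSE)
  expect_warning(out2 <- rescue_bait(absent), "not detected")
  expect_identical(out2$significant, FALSE)
})
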