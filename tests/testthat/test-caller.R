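test_that("global error estimation pools low-MAF evidence", {
  # forced by construction: 1 alt in 1000 depth everywhere
  cc <- do.call(rbind, lapply(1:20, function(i) {
    counts_row(i, "A", "G", 1000, 1, 0)
  }))
  expect_equal(estimate_global_error(cc), 0.001)

  # all-zero alt counts clamp to the floor
  zero <- counts_row(1:10, "A", ".", 100, 0, 0)
  expect_equal(estimate_global_error(zero), 1e-6)

  # sites at or above the ceiling are excluded from the estimate
  mixed <- rbind(counts_row(1, "A", "G", 100, 50, 0),
                 counts_row(2, "A", "G", 1000, 1, 1))
  expect_equal(estimate_global_error(mixed), 0.002)

  expect_error(estimate_global_error(counts_row(1, "A", "G", 100, 99, 0)),
               "no sites below")
  expect_error(estimate_global_error(counts_row(1, "A", "G", 100, 1, 0)[0, ]),
               "empty")
})

test_that("simulated pools recover the injected error rate", {
  # deep sites so the MAF ceiling does not truncate integer evidence
  genome <- bare_genome(strrep("A", 500))  # ~2e5 qualifying bases
  clones <- list(make_clone("c1"), make_clone("c2"))
  cc <- sample_pool_counts(clones, genome, mean_depth = 400,
                           seq_error = 0.002, seed = 11, all_sites = TRUE)
  est <- estimate_global_error(cc)
  n_bases <- 500 * 400
  se <- sqrt(0.002 * (1 - 0.002) / n_bases)
  expect_lt(abs(est - 0.002), 3 * se)
})

test_that("the likelihood-ratio test matches a direct binomial oracle", {
  expect_equal(likelihood_ratio_call(150, 0, 0.001),
               data.frame(lrt_stat = 0, lrt_p = 1))
  # boundary: observed fraction equals the error rate exactly
  expect_equal(likelihood_ratio_call(100, 1, 0.01)$lrt_stat, 0)

  got <- likelihood_ratio_call(150, 15, 0.001)
  expect_equal(got$lrt_stat, oracle_lrt(150, 15, 0.001), tolerance = 1e-12)
  expect_equal(got$lrt_p,
               pchisq(oracle_lrt(150, 15, 0.001), 1, lower.tail = FALSE))

  expect_error(likelihood_ratio_call(0, 0, 0.001), "depth")
})

test_that("strand-bias p-values are exact and two-sided", {
  expect_equal(strand_bias_test(10, 10), 1)
  expect_equal(strand_bias_test(20, 0), 2 * 0.5^20, tolerance = 1e-12)
  expect_equal(strand_bias_test(20, 0), 1.9073486e-06, tolerance = 1e-7)
  expect_equal(strand_bias_test(1, 0), 1)   # n = 1: no power
  expect_equal(strand_bias_test(0, 0), 1)   # nothing to test, by contract
  # asymmetric expected fraction against the enumeration oracle
  for (case in list(c(7, 3, 0.3), c(2, 18, 0.5), c(50, 40, 0.45))) {
    expect_equal(strand_bias_test(case[1], case[2], case[3]),
                 oracle_binom_two_sided(case[1], case[1] + case[2], case[3]),
                 tolerance = 1e-12)
  }
})

test_that("calling applies the depth and MAF gates at the stated cut-offs", {
  p <- caller_params()
  cc <- rbind(
    counts_row(10, "A", "G", 40, 5, 5),    # depth 40 < 50: never called
    counts_row(20, "A", "G", 150, 4, 4),   # maf 5.3%: low only
    counts_row(30, "A", "G", 150, 8, 7),   # maf 10%: low + standard
    counts_row(40, "A", "G", 150, 2, 2),   # maf 2.7%: below 3%
    counts_row(50, "A", "G", 150, 30, 0),  # strand-biased: filtered
    counts_row(60, "A", ".", 150, 0, 0)    # no alt allele: dropped
  )
  calls <- call_variants(cc, p, error = 0.001, keep_all = TRUE)
  expect_false(60 %in% calls$pos)
  gate <- function(pos, col) calls[calls$pos == pos, col]
  expect_false(gate(10, "passes_low"))
  expect_true(gate(20, "passes_low"))
  expect_false(gate(20, "passes_standard"))
  expect_true(gate(30, "passes_low"))
  expect_true(gate(30, "passes_standard"))
  expect_false(gate(40, "passes_low"))
  expect_false(gate(50, "passes_low"))
  expect_lt(gate(50, "strand_p"), 0.01)

  # maf column is exactly (alt_fwd + alt_rev)/depth
  expect_equal(calls$maf, (calls$alt_fwd + calls$alt_rev) / calls$depth)
  # passes_standard implies passes_low
  expect_true(all(!calls$passes_standard | calls$passes_low))
  # default return keeps only low-stringency passes
  kept <- call_variants(cc, p, error = 0.001)
  expect_setequal(kept$pos, c(20, 30))
})

test_that("boundary MAFs are inclusive, matching the >= phrasing", {
  cc <- rbind(
    counts_row(1, "A", "G", 100, 7, 0),   # exactly 7%
    counts_row(2, "A", "G", 100, 3, 0),   # exactly 3%
    counts_row(3, "A", "G", 50, 5, 0)     # exactly depth 50
  )
  # balanced-strand variants would pass; use one-sided counts with
  # small n so the strand gate stays open
  calls <- call_variants(cc, caller_params(strand_alpha = 1e-4),
                         error = 1e-4, keep_all = TRUE)
  expect_true(calls$passes_standard[calls$pos == 1])
  expect_true(calls$passes_low[calls$pos == 2])
  expect_true(calls$passes_low[calls$pos == 3])
})

test_that("control subtraction is allele-aware", {
  t <- rbind(counts_row(5, "A", "G", 100, 5, 5),
             counts_row(9, "C", "T", 100, 6, 6),
             counts_row(9, "C", "A", 100, 6, 6))
  t$maf <- 0.1; t$passes_low <- TRUE; t$in_control <- FALSE
  ctl_same <- t
  res <- subtract_control(t, ctl_same)
  expect_equal(nrow(res$calls), 0L)
  expect_equal(nrow(res$removed), 3L)
  expect_true(all(res$removed$in_control))

  ctl <- t[2, , drop = FALSE]
  res2 <- subtract_control(t, ctl)
  expect_equal(nrow(res2$calls), 2L)
  # same position, different alt base is retained
  expect_true(any(res2$calls$pos == 9 & res2$calls$alt == "A"))
  expect_true(any(res2$calls$pos == 5))

  other <- t; other$contig <- "chr9"
  expect_error(subtract_control(t, other), "contigs")
})

test_that("caller parameters enforce their invariants", {
  expect_error(caller_params(maf_low = 0.1, maf_standard = 0.05),
               "maf_low")
  expect_error(caller_params(min_depth = 0), "min_depth")
  expect_error(caller_params(lrt_alpha = 0), "alphas")
  p <- caller_params(maf_low = 0.05, maf_standard = 0.05)
  expect_equal(p$maf_low, p$maf_standard)
})

test_that("call probability grows with depth and allele fraction", {
  set.seed(42)
  p <- caller_params(lrt_alpha = 1e-3, strand_alpha = 1e-6)
  rate <- function(depth, maf, n = 300) {
    alt <- rbinom(n, depth, maf)
    fwd <- rbinom(n, alt, 0.5)
    cc <- counts_row(seq_len(n), "A", "G", depth, fwd, alt - fwd)
    mean(call_variants(cc, p, error = 0.001, keep_all = TRUE)$passes_low)
  }
  r_by_maf <- c(rate(150, 0.03), rate(150, 0.06), rate(150, 0.12))
  expect_true(all(diff(r_by_maf) >= 0))
  r_by_depth <- c(rate(50, 0.06), rate(120, 0.06), rate(250, 0.06))
  expect_true(all(diff(r_by_depth) >= 0))
})
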