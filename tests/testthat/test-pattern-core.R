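test_that("site discovery dedupes, sorts, and respects the trimmed interval", {
  amp <- make_config(start = 100L, end = 160L)
  calls <- make_calls(c("a", "b", "c", "d"), pos = c(110L, 110L, 130L, 150L),
                      methylated = TRUE)
  idx <- build_site_index(calls, amp)
  expect_equal(idx$sites, c(110L, 130L, 150L))

  # boundary exclusion: position below trim_start ignored and tallied
  amp2 <- make_config(start = 90L, end = 170L, fwd = 10L, rev = 10L)  # trimmed [100,160)
  calls2 <- make_calls(c("a", "b"), pos = c(95L, 110L), methylated = TRUE)
  idx2 <- build_site_index(calls2, amp2)
  expect_equal(idx2$sites, 110L)
  expect_equal(attr(idx2, "n_outside"), 1L)

  # no-CpG control: only non-CpG calls -> empty site set, not an error
  calls3 <- make_calls("a", pos = 120L, methylated = FALSE, context = "CHH")
  idx3 <- build_site_index(calls3, amp)
  expect_length(idx3$sites, 0L)
})

test_that("pattern strings encode call states and missing sites", {
  amp <- make_config(start = 100L, end = 200L)
  sites <- c(110L, 120L, 130L)
  calls <- rbind(
    make_calls("full", pos = sites, methylated = c(TRUE, FALSE, TRUE)),
    make_calls("half", pos = 120L, methylated = TRUE)
  )
  idx <- build_site_index(calls, amp)
  expect_equal(idx$sites, sites)
  pats <- assemble_patterns(calls, idx)
  expect_equal(pats$pattern[pats$read_id == "full"], "101")
  expect_equal(pats$pattern[pats$read_id == "half"], "-1-")
})

test_that("a mixed five-read fixture yields exactly three distinct patterns", {
  amp <- make_config()
  sites <- c(110L, 130L)
  calls <- rbind(
    make_calls("m1", pos = sites, methylated = TRUE),
    make_calls("m2", pos = sites, methylated = TRUE),
    make_calls("u1", pos = sites, methylated = FALSE),
    make_calls("u2", pos = sites, methylated = FALSE),
    make_calls("h1", pos = 110L, methylated = TRUE)
  )
  idx <- build_site_index(calls, amp)
  pats <- assemble_patterns(calls, idx)
  expect_equal(nrow(pats), 5L)
  expect_setequal(unique(pats$pattern), c("11", "00", "1-"))
})

test_that("duplicate calls resolve first-seen-wins and conflicts are counted", {
  amp <- make_config()
  calls <- rbind(
    make_calls("r1", pos = 110L, methylated = TRUE),
    make_calls("r1", pos = 110L, methylated = FALSE),  # conflicting duplicate
    make_calls("r1", pos = 110L, methylated = TRUE),   # agreeing duplicate
    make_calls("r1", pos = 130L, methylated = FALSE)
  )
  idx <- build_site_index(calls, amp)
  pats <- assemble_patterns(calls, idx)
  expect_equal(pats$pattern, "10")
  expect_equal(attr(pats, "conflicts"), 1L)
})

test_that("counting ranks by count with lexicographic tie-break", {
  amp <- make_config()
  calls <- rbind(
    make_calls("a", pos = c(110L, 130L), methylated = c(TRUE, TRUE)),
    make_calls("b", pos = c(110L, 130L), methylated = c(TRUE, TRUE)),
    make_calls("c", pos = c(110L, 130L), methylated = c(TRUE, FALSE))
  )
  idx <- build_site_index(calls, amp)
  s <- count_patterns(assemble_patterns(calls, idx), idx, 0, "s1")
  expect_equal(s$rows$pattern, c("11", "10"))
  expect_equal(s$rows$count, c(2L, 1L))
  expect_equal(s$rows$fraction, c(2 / 3, 1 / 3))
  expect_equal(s$site_meth_fraction, c(1, 2 / 3))

  # equal counts: lexicographic ascending on the pattern string
  calls2 <- rbind(
    make_calls("a", pos = c(110L, 130L), methylated = c(TRUE, FALSE)),
    make_calls("b", pos = c(110L, 130L), methylated = c(FALSE, TRUE))
  )
  idx2 <- build_site_index(calls2, amp)
  s2 <- count_patterns(assemble_patterns(calls2, idx2), idx2, 0)
  expect_equal(s2$rows$pattern, c("01", "10"))
})

test_that("the coverage filter drops partial reads and reports them", {
  amp <- make_config()
  calls <- rbind(
    make_calls("p", pos = 110L, methylated = TRUE),                 # "1-"
    make_calls("f", pos = c(110L, 130L), methylated = TRUE)         # "11"
  )
  idx <- build_site_index(calls, amp)
  pats <- assemble_patterns(calls, idx)
  s <- count_patterns(pats, idx, min_coverage_fraction = 1)
  expect_equal(s$rows$pattern, "11")
  expect_equal(s$total_reads, 1L)
  expect_equal(s$dropped, 1L)
  # threshold 0 keeps the partial pattern as a distinct string
  s0 <- count_patterns(pats, idx, min_coverage_fraction = 0)
  expect_setequal(s0$rows$pattern, c("11", "1-"))
  # everything filtered out is a valid empty summary, not an error
  only_partial <- pats[pats$read_id == "p", , drop = FALSE]
  attr(only_partial, "conflicts") <- 0L
  s_empty <- count_patterns(only_partial, idx, min_coverage_fraction = 1)
  expect_equal(s_empty$total_reads, 0L)
  expect_equal(nrow(s_empty$rows), 0L)
})

test_that("summaries are invariant to input record order", {
  fx <- random_call_fixture(101)
  amp <- make_config(start = 90L, end = 700L)
  idx <- build_site_index(fx$calls, amp)
  base <- count_patterns(assemble_patterns(fx$calls, idx), idx, 0.5)
  set.seed(9)
  for (i in 1:5) {
    shuffled <- fx$calls[sample.int(nrow(fx$calls)), , drop = FALSE]
    idx_s <- build_site_index(shuffled, amp)
    s <- count_patterns(assemble_patterns(shuffled, idx_s), idx_s, 0.5)
    expect_equal(s$rows, base$rows)
    expect_equal(s$sites, base$sites)
    expect_equal(s$site_meth_fraction, base$site_meth_fraction)
  }
})

test_that("counting agrees exactly with the brute-force oracle on random fixtures", {
  amp <- make_config(start = 90L, end = 700L)
  for (seed in 1:40) {
    fx <- random_call_fixture(seed)
    mcf <- sample(c(0, 0.25, 0.5, 1), 1L)
    idx <- build_site_index(fx$calls, amp)
    pats <- assemble_patterns(fx$calls, idx)
    s <- count_patterns(pats, idx, min_coverage_fraction = mcf)
    ref_p <- brute_force_patterns(fx$calls, idx$sites)
    ref <- brute_force_count(ref_p$pattern, length(idx$sites), mcf)
    expect_identical(s$rows$pattern, ref$pattern)
    expect_identical(s$rows$count, ref$count)
    expect_identical(s$dropped, ref$dropped)
    expect_identical(s$total_reads, ref$total)
    expect_equal(s$site_meth_fraction, ref$site_meth_fraction)
    # independent assembly agrees too
    expect_identical(sort(pats$pattern), sort(ref_p$pattern))
  }
})

test_that("pattern counts conserve reads", {
  amp <- make_config(start = 90L, end = 700L)
  for (seed in 41:60) {
    fx <- random_call_fixture(seed)
    idx <- build_site_index(fx$calls, amp)
    pats <- assemble_patterns(fx$calls, idx)
    s <- count_patterns(pats, idx, min_coverage_fraction = 0.75)
    expect_equal(sum(s$rows$count), s$total_reads)
    expect_equal(s$total_reads + s$dropped,
                 length(unique(fx$calls$read_id)))
    expect_equal(abs(sum(s$rows$fraction) - 1) < 1e-9 || nrow(s$rows) == 0, TRUE)
  }
})

test_that("a fully methylated sample gives one pattern and unit site fractions", {
  amp <- make_config()
  sites <- c(105L, 115L, 125L, 135L)
  calls <- do.call(rbind, lapply(sprintf("r%02d", 1:30), function(r)
    make_calls(r, pos = sites, methylated = TRUE)))
  idx <- build_site_index(calls, amp)
  s <- count_patterns(assemble_patterns(calls, idx), idx, 1)
  expect_equal(nrow(s$rows), 1L)
  expect_equal(s$rows$pattern, "1111")
  expect_true(all(s$site_meth_fraction == 1))
})

test_that("estimated epiallele frequencies recover the generating mixture", {
  amp <- make_config(name = "mix", start = 100L, end = 200L)
  sites <- c(110L, 130L, 150L)
  freqs <- c("111" = 0.7, "000" = 0.3)
  spec <- sim_spec(amp, sites = list(mix = sites),
                   epiallele_freqs = list(mix = freqs),
                   n_reads = 1000L, dropout_rate = 0,
                   conversion_error = 0, n_noncpg = 0L, seed = 2024L)
  res <- simulate_extractor_file(spec, tempdir(), "mix")
  calls <- read_bismark_calls(res$calls_path, strand = "forward")
  idx <- build_site_index(calls, amp)
  s <- count_patterns(assemble_patterns(calls, idx), idx, 1)
  est <- setNames(s$rows$fraction, s$rows$pattern)
  for (p in names(freqs)) {
    se <- sqrt(freqs[[p]] * (1 - freqs[[p]]) / 1000)
    expect_lt(abs(est[[p]] - freqs[[p]]), 3 * se)
  }
  # with no dropout the counts match the truth table exactly
  truth <- setNames(res$truth$true_count, res$truth$pattern)
  expect_equal(setNames(s$rows$count, s$rows$pattern)[names(truth)], truth)
})

test_that("conversion QC computes the stated ratios and flags degenerate input", {
  chh <- make_calls(sprintf("r%03d", 1:100), pos = 200L, context = "CHH",
                    methylated = c(rep(TRUE, 2), rep(FALSE, 98)))
  qc <- compute_qc(chh, "s")
  expect_equal(qc$conversion_rate, 0.98)
  expect_true(qc$conversion_defined)

  all_u <- make_calls(sprintf("r%02d", 1:50), pos = 200L, context = "CHG",
                      methylated = FALSE)
  expect_equal(compute_qc(all_u)$conversion_rate, 1.0)

  cpg_only <- make_calls("r1", pos = 100L, methylated = TRUE, context = "CpG")
  qc0 <- compute_qc(cpg_only)
  expect_false(qc0$conversion_defined)
  expect_true(is.na(qc0$conversion_rate))
})

test_that("QC conversion estimate is consistent with the generating error rate", {
  amp <- make_config(name = "a", start = 100L, end = 5000L)
  spec <- sim_spec(amp, sites = list(a = 200L),
                   epiallele_freqs = list(a = c("1" = 1)),
                   n_reads = 1L, dropout_rate = 0,
                   conversion_error = 0.01, n_noncpg = 10000L, seed = 5L)
  res <- simulate_extractor_file(spec, tempdir(), "qc")
  calls <- read_bismark_calls(res$calls_path, strand = "forward")
  qc <- compute_qc(calls)
  se <- sqrt(0.99 * 0.01 / 10000)
  expect_lt(abs(qc$conversion_rate - 0.99), 3 * se)
})
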