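test_that("primer sites are found on both strands with exact matching", {
  hits <- find_primer_sites("ACGT", "TTACGTTT", max_mismatch = 0, anchor_len = 0)
  plus <- hits[hits$strand == "+", ]
  expect_equal(plus$position, 2L)
  expect_equal(plus$mismatches, 0L)
  # ACGT is its own reverse complement, so the same window is a minus site too
  expect_equal(hits$position[hits$strand == "-"], 2L)

  # a primer equal to the reverse complement of a window is a minus-strand site
  set.seed(42)
  ref <- random_dna(400)
  window <- substring(ref, 101, 130)
  primer <- revcomp_chr(window)
  hits <- find_primer_sites(primer, ref, max_mismatch = 0, anchor_len = 3)
  minus <- hits[hits$strand == "-", ]
  expect_true(100 %in% minus$position)

  # primer longer than the reference: empty result, not an error
  expect_equal(nrow(find_primer_sites("ACGTACGTAC", "ACGT", 0, 0)), 0L)
  expect_error(find_primer_sites("ACXT", "ACGTACGT", 0, 0), "non-IUPAC")
})

test_that("IUPAC ambiguity codes in the primer match their base sets", {
  # R = A/G; the anchor must still match exactly
  hits <- find_primer_sites("ACRT", "GGACGTGGACAT", max_mismatch = 0,
                            anchor_len = 0)
  plus <- hits[hits$strand == "+", ]
  expect_setequal(plus$position, c(2L, 8L))
})

test_that("site search agrees with the exhaustive scan on random instances", {
  set.seed(101)
  for (i in 1:100) {
    L <- sample(300:2000, 1)
    k <- sample(15:30, 1)
    mm <- sample(0:2, 1)
    anchor <- sample(0:3, 1)
    ref <- random_dna(L)
    # half the time plant a mutated copy of a real window to force hits
    if (i %% 2 == 0) {
      s <- sample(L - k, 1)
      primer <- substring(ref, s + 1, s + k)
      flip <- sample(k - anchor, min(mm, k - anchor))
      pc <- strsplit(primer, "")[[1]]
      pc[flip] <- sample(c("A", "C", "G", "T"), length(flip), replace = TRUE)
      primer <- paste(pc, collapse = "")
    } else {
      primer <- random_dna(k)
    }
    got <- as.data.frame(find_primer_sites(primer, ref, mm, anchor))
    want <- brute_force_sites(primer, ref, mm, anchor)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want,
                 info = sprintf("instance %d (L=%d k=%d mm=%d anchor=%d)",
                                i, L, k, mm, anchor))
  }
})

test_that("a 30-mer against a 20 kb reference matches the exhaustive scan", {
  set.seed(7)
  ref <- random_dna(20000)
  s <- 12345
  primer <- substring(ref, s + 1, s + 30)
  got <- as.data.frame(find_primer_sites(primer, ref, 2, 3))
  want <- brute_force_sites(primer, ref, 2, 3)
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
  expect_true(s %in% got$position)
})

test_that("amplicons are enumerated from compatible site pairs within the size range", {
  set.seed(11)
  ref <- random_dna(2500)
  fwd <- substring(ref, 1, 20)
  rev <- revcomp_chr(substring(ref, 1981, 2000))
  pairs <- tibble::tibble(name = "p1", fwd_seq = fwd, rev_seq = rev)
  amp <- enumerate_amplicons(pairs, ref, min_len = 1000, max_len = 3000)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$start, 0L)
  expect_equal(amp$end, 2000L)
  expect_equal(amp$length, 2000L)

  # empty size range: warning plus empty result
  expect_warning(
    none <- enumerate_amplicons(pairs, ref, min_len = 3000, max_len = 1000),
    "min_len exceeds max_len"
  )
  expect_equal(nrow(none), 0L)

  # a pair with no in-range product is a recorded design failure, not an error
  amp2 <- enumerate_amplicons(pairs, ref, min_len = 2400, max_len = 5000)
  expect_equal(nrow(amp2), 0L)
  expect_equal(attr(amp2, "design_failures"), "p1")
})

test_that("coverage fractions follow half-open interval arithmetic", {
  amp <- tibble::tibble(pair = "a", contig = "c", start = 0L, end = 5000L,
                        length = 5000L)
  tg <- tibble::tibble(contig = "c", start = c(100L, 4000L), end = c(200L, 4100L))
  cov <- coverage_report(amp, tg)
  expect_equal(cov$covered_fraction, c(1, 1))
  expect_true(attr(cov, "complete"))

  amp2 <- tibble::tibble(pair = "a", contig = "c", start = 0L, end = 150L,
                         length = 150L)
  cov2 <- coverage_report(amp2, tibble::tibble(contig = "c", start = 100L, end = 200L))
  expect_equal(cov2$covered_fraction, 0.5)
  expect_false(attr(cov2, "complete"))

  cov3 <- coverage_report(amp2[0, ], tg)
  expect_equal(cov3$covered_fraction, c(0, 0))
  expect_equal(cov3$n_amplicons, c(0L, 0L))
})

test_that("coverage is monotone non-decreasing as amplicons are added", {
  set.seed(3)
  tg <- tibble::tibble(contig = "c", start = c(0L, 500L, 900L),
                       end = c(300L, 800L, 1200L))
  amps <- tibble::tibble(
    pair = paste0("a", 1:6), contig = "c",
    start = as.integer(sample(0:900, 6)), length = 250L
  )
  amps$end <- amps$start + amps$length
  prev <- rep(0, nrow(tg))
  for (i in seq_len(nrow(amps))) {
    cov <- coverage_report(amps[1:i, ], tg)
    expect_true(all(cov$covered_fraction >= prev - 1e-12))
    expect_true(all(cov$covered_fraction >= 0 & cov$covered_fraction <= 1))
    prev <- cov$covered_fraction
  }
})

test_that("pool assignment separates overlapping amplicons and detects infeasibility", {
  two <- tibble::tibble(pair = c("a", "b"), contig = "c",
                        start = c(0L, 500L), end = c(1000L, 1500L),
                        length = 1000L)
  pools <- assign_pools(two, n_pools = 2)
  expect_setequal(pools$pool, c(1L, 2L))

  three <- tibble::tibble(pair = c("a", "b", "c"), contig = "c",
                          start = c(0L, 100L, 200L), end = c(1000L, 1100L, 1200L),
                          length = 1000L)
  expect_error(assign_pools(three, n_pools = 2), "mutually overlapping")
  ok <- assign_pools(three, n_pools = 3)
  expect_equal(sort(unique(ok$pool)), 1:3)
})

test_that("the shipped toy panel satisfies all design constraints", {
  ref <- toy_ref()
  panel <- toy_panel(ref)
  expect_equal(nrow(panel), 9L)
  expect_true(all(nchar(panel$fwd_seq) >= 15 & nchar(panel$fwd_seq) <= 35))
  expect_true(all(grepl("^[ACGT]+$", c(panel$fwd_seq, panel$rev_seq))))

  tg <- toy_targets(ref)
  amp <- enumerate_amplicons(panel, ref, targets = tg)
  expect_equal(nrow(amp), 9L)
  expect_equal(length(attr(amp, "design_failures")), 0L)
  expect_true(all(amp$length >= 1500 & amp$length <= 5000))
  expect_true(all(amp$on_target))

  # complete coverage, confirmed by an independent interval-union sweep
  cov <- coverage_report(amp, tg)
  expect_true(attr(cov, "complete"))
  oracle <- vapply(seq_len(nrow(tg)), function(i) {
    union_covered_fraction(amp$start, amp$end, tg$start[i], tg$end[i])
  }, numeric(1))
  expect_equal(cov$covered_fraction, oracle)
  expect_true(all(oracle == 1))

  # two pools, each internally non-overlapping by brute-force pairwise check
  pools <- assign_pools(amp, n_pools = 2)
  expect_setequal(unique(pools$pool), 1:2)
  for (p in 1:2) {
    sub <- pools[pools$pool == p, ]
    if (nrow(sub) > 1) {
      combs <- utils::combn(nrow(sub), 2)
      for (j in seq_len(ncol(combs))) {
        a <- combs[1, j]; b <- combs[2, j]
        expect_false(sub$start[a] < sub$end[b] && sub$start[b] < sub$end[a])
      }
    }
  }
})
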