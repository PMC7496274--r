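test_that("recombinants are exactly the individuals whose origin changes", {
  f <- make_founders(12, 60e6, seed = 75)
  pop <- simulate_population(
    f, cross_plan(crosses = list(c("C085", "R104")), generation = "F2",
                  n_per_cross = 150), seed = 76)
  region <- qtl_region("ch01", 1, 60e6)
  rec <- find_recombinants(pop, region)
  # tracked-origin oracle: recompute breakpoints from the truth record
  M <- encode_parental_dosage(pop)
  inf <- which(M$informative["C085xR104", ])
  pa <- match("C085", f$founder_ids)
  truth <- parental_counts_truth(pop)
  for (i in seq_along(pop$ids)) {
    a <- truth[i, inf, pa]
    ch <- which(diff(a) != 0)
    got <- rec[rec$individual == pop$ids[i], , drop = FALSE]
    expect_equal(nrow(got), length(ch))
    if (length(ch)) {
      expect_equal(got$left_pos_bp, f$map$pos_bp[inf[ch]])
      expect_equal(got$right_pos_bp, f$map$pos_bp[inf[ch + 1L]])
    }
  }
  # non-recombinant at zero recombination rate
  pop0 <- simulate_population(
    f, cross_plan(crosses = list(c("C085", "R104")), generation = "F2",
                  n_per_cross = 30), recomb_rate_cM_per_Mbp = 0, seed = 77)
  rec0 <- find_recombinants(pop0, region)
  expect_equal(nrow(rec0), 0L)
  expect_error(find_recombinants(
    pop, qtl_region("ch01", 1, 2)), "fewer than 2")
})

test_that("family contrasts separate planted class differences and stay calibrated", {
  set.seed(78)
  # strong separation: 5 SD at n = 10 per class
  power_hits <- sum(replicate(60, {
    contrast_family(rnorm(10, 0, 1), rnorm(10, 5, 1))$significant
  }))
  expect_gte(power_hits, 59)
  # identical distributions: about 5% significant
  null_hits <- mean(replicate(400, {
    contrast_family(rnorm(10), rnorm(10))$significant
  }))
  expect_gt(null_hits, 0.02)
  expect_lt(null_hits, 0.09)
  # degenerate equal constants
  cc <- contrast_family(rep(1, 3), rep(1, 4))
  expect_false(cc$significant)
  expect_equal(cc$P, 1)
  expect_error(contrast_family(1, c(2, 3)), "two observations")
  # rank-based alternative agrees on a strong contrast
  expect_true(contrast_family(1:6, 101:106, test = "kw")$significant)
})

test_that("substitution mapping reproduces the printed interval refinement", {
  parent <- region_from_mbp("ch4", 51.8, 56.8, "PHEV")
  sig <- recombinant_family("famA", region_from_mbp("ch4", 54.52, 54.85),
                            TRUE)
  expect_equal(interval_width_kbp(sig$segment), 330)
  ref1 <- refine_interval(list(sig), parent)
  expect_equal(c(ref1$start_bp, ref1$end_bp), c(54.52e6, 54.85e6))
  nonsig <- recombinant_family("famB",
                               region_from_mbp("ch4", 54.63, 54.85), FALSE)
  ref2 <- refine_interval(list(sig, nonsig), parent)
  expect_equal(c(ref2$start_bp, ref2$end_bp), c(54.52e6, 54.63e6))
  expect_equal(interval_width_kbp(ref2), 110)
  # order independence and monotone shrinkage
  ref2b <- refine_interval(list(nonsig, sig), parent)
  expect_equal(ref2b[c("start_bp", "end_bp")], ref2[c("start_bp", "end_bp")])
  expect_lte(interval_width_kbp(ref2), interval_width_kbp(ref1))
  # contradictions are errors, not guesses
  sig2 <- recombinant_family("famC", region_from_mbp("ch4", 55.5, 56.0),
                             TRUE)
  expect_error(refine_interval(list(sig, sig2), parent), "disjoint")
  swallow <- recombinant_family("famD",
                                region_from_mbp("ch4", 54.4, 54.9), FALSE)
  expect_error(refine_interval(list(sig, swallow), parent), "whole")
  splitter <- recombinant_family("famE",
                                 region_from_mbp("ch4", 54.6, 54.7), FALSE)
  expect_error(refine_interval(list(sig, splitter), parent), "splits")
  expect_error(refine_interval(list(nonsig), parent), "no significant")
})

test_that("interval widths follow the exact Mbp-endpoint convention", {
  expect_equal(interval_width_kbp(region_from_mbp("ch4", 54.52, 54.85)), 330)
  expect_equal(interval_width_kbp(region_from_mbp("ch4", 54.52, 54.63)), 110)
  expect_equal(interval_width_kbp(qtl_region("ch1", 5, 5)), 0)
  expect_error(qtl_region("ch1", 10, 2), "end before start")
})

test_that("gene lookup applies the any-overlap rule and matches a quadratic scan", {
  gff <- tempfile(fileext = ".gff3")
  set.seed(79)
  n <- 1000
  starts <- sort(sample.int(60e6, n))
  ends <- starts + sample.int(20000, n)
  lines <- sprintf("ch4\tsynth\tgene\t%d\t%d\t.\t+\t.\tID=gene%04d", starts,
                   ends, seq_len(n))
  writeLines(c("##gff-version 3", lines), gff)
  region <- region_from_mbp("ch4", 30.0, 30.8)
  genes <- genes_in_interval(gff, region)
  brute <- which(starts <= region$end_bp & ends >= region$start_bp)
  expect_equal(nrow(genes), length(brute))
  expect_equal(genes$start, starts[brute])
  expect_false(is.unsorted(genes$start))
  # straddling gene is included
  straddle <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "ch4\tsynth\tgene\t29900000\t30100000\t.\t+\t.\tID=gx"),
             straddle)
  expect_equal(nrow(genes_in_interval(straddle, region)), 1L)
  # empty annotation
  empty <- tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", empty)
  expect_equal(nrow(suppressWarnings(
    genes_in_interval(empty, region))), 0L)
})
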