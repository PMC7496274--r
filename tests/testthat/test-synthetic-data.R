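test_that("founder sets have the required shape, homozygosity and determinism", {
  f <- make_founders(10, 50e6, seed = 7)
  expect_equal(nrow(f$map), 10L)
  expect_true(all(diff(f$map$pos_bp) > 0))
  expect_equal(dim(f$haplotypes), c(4L, 10L))
  expect_true(all(f$haplotypes %in% 0:1))  # homozygous binary alleles
  expect_identical(f, make_founders(10, 50e6, seed = 7))
  expect_false(identical(f$haplotypes,
                         make_founders(10, 50e6, seed = 8)$haplotypes))
  expect_error(make_founders(0, 50e6, seed = 1), ">= 1 marker")
  expect_error(make_founders(10, -1, seed = 1), "> 0")
})

test_that("founder pairwise difference tracks the requested fraction", {
  f <- make_founders(2000, 80e6, seed = 3, diff_fraction = 0.4)
  pair_diff <- combn(4, 2, function(p)
    mean(f$haplotypes[p[1], ] != f$haplotypes[p[2], ]))
  expect_true(all(abs(pair_diff - 0.4) < 0.05))
  # the maximal-polymorphism regime: every marker a balanced 2/2 split,
  # so every marker segregates and every pair differs at 2/3 of markers
  f1 <- make_founders(1500, 80e6, seed = 4, diff_fraction = 1)
  expect_true(all(colSums(f1$haplotypes) == 2L))
  pair_diff1 <- combn(4, 2, function(p)
    mean(f1$haplotypes[p[1], ] != f1$haplotypes[p[2], ]))
  expect_true(all(abs(pair_diff1 - 2 / 3) < 0.05))
})

test_that("zero recombination yields intact founder chromosomes", {
  f <- small_founders()
  pop <- simulate_population(f, cross_plan(generation = "F2",
                                           n_per_cross = 8),
                             recomb_rate_cM_per_Mbp = 0, seed = 4)
  for (ch in unique(f$map$chrom)) {
    idx <- which(f$map$chrom == ch)
    expect_true(all(apply(pop$origins1[, idx], 1,
                          function(o) length(unique(o))) == 1))
    expect_true(all(apply(pop$origins2[, idx], 1,
                          function(o) length(unique(o))) == 1))
  }
})

test_that("F2 segregation at an informative marker is 1:2:1", {
  f <- make_founders(5, 50e6, seed = 9)
  pop <- simulate_population(
    f, cross_plan(crosses = list(c("C074", "C085")), generation = "F2",
                  n_per_cross = 2000), seed = 10)
  j <- which(f$haplotypes["C074", ] != f$haplotypes["C085", ])[1]
  cnt <- table(factor(genotype_dosage(pop)[, f$map$marker[j]],
                      levels = 0:2))
  # exact multinomial expectation oracle: (1/4, 1/2, 1/4)
  chi <- sum((cnt - 2000 * c(.25, .5, .25))^2 / (2000 * c(.25, .5, .25)))
  expect_lt(chi, qchisq(0.99, df = 2))
})

test_that("Mendelian consistency: every offspring allele traces to a parent", {
  f <- small_founders(seed = 31)
  pop <- simulate_population(f, cross_plan(generation = "F2",
                                           n_per_cross = 6), seed = 12)
  for (i in seq_along(pop$ids)) {
    parents <- match(pop$crosses[[pop$cross[i]]], f$founder_ids)
    expect_true(all(pop$origins1[i, ] %in% parents))
    expect_true(all(pop$origins2[i, ] %in% parents))
  }
})

test_that("same plan and seed reproduce a population bit-identically", {
  f <- small_founders()
  plan <- cross_plan(generation = "F6", n_per_cross = 5)
  p1 <- simulate_population(f, plan, seed = 42)
  p2 <- simulate_population(f, plan, seed = 42)
  expect_identical(p1, p2)
  expect_error(simulate_population(
    f, cross_plan(crosses = list(c("C074", "NOPE"))), seed = 1),
    "unknown parent")
  expect_error(simulate_population(f, plan, recomb_rate_cM_per_Mbp = -1),
               ">= 0")
})

test_that("rin selection leaves no mutant carriers among F6 RILs", {
  f <- make_founders(rep(11, 5), rep(50e6, 5), seed = 21)
  pop <- simulate_population(
    f, cross_plan(crosses = list(c("C085", "R075"), c("R075", "R104")),
                  generation = "F6", n_per_cross = 40,
                  rin_selection = TRUE), seed = 22)
  expect_true(all(rin_dosage_truth(pop) == 0))
  # without selection the mutant allele still segregates
  pop_ns <- simulate_population(
    f, cross_plan(crosses = list(c("C085", "R075")), generation = "F6",
                  n_per_cross = 40), seed = 23)
  expect_gt(sum(rin_dosage_truth(pop_ns)), 0)
})

test_that("trait simulation: deterministic structure and planted moments", {
  fx <- hd_fixture()
  # all effects and SDs zero: trait equals baseline exactly
  arch0 <- trait_architecture(list(trait_spec("flat", baseline = 3.5)))
  tt0 <- simulate_traits(fx$pop, arch0, seed = 1)
  expect_true(all(tt0$flat == 3.5))
  # single C085 QTL, no noise: affine in the C085 allele count
  qmk <- fx$founders$map$marker[100]
  arch1 <- trait_architecture(list(trait_spec(
    "aff", baseline = 1,
    qtls = data.frame(marker = qmk, C074 = 0, C085 = 1.5, R075 = 0,
                      R104 = 0))))
  tt1 <- simulate_traits(fx$pop, arch1, seed = 2)
  cnt <- diallelQTL:::founder_counts_at(fx$pop, qmk)[, 2]
  expect_equal(tt1$aff, 1 + 1.5 * cnt)
  expect_error(simulate_traits(fx$pop, trait_architecture(list(trait_spec(
    "bad", qtls = data.frame(marker = "nope", C085 = 1)))), seed = 1),
    "absent from map")
})

test_that("planted per-cross background SDs are recovered at large n", {
  f <- make_founders(rep(6, 2), rep(50e6, 2), seed = 41)
  crosses <- list(c("C074", "C085"), c("C074", "R075"), c("C085", "R104"))
  pop <- simulate_population(f, cross_plan(crosses = crosses,
                                           generation = "F2",
                                           n_per_cross = 500), seed = 42)
  sds <- c(0.5, 1, 2)
  names(sds) <- vapply(crosses, paste, "", collapse = "x")
  arch <- trait_architecture(list(trait_spec(
    "y", cross_background_sd = sds, residual_sd = 0)))
  tt <- simulate_traits(pop, arch, seed = 43)
  got <- tapply(tt$y, tt$cross, sd)[names(sds)]
  expect_true(all(abs(got - sds) / sds < 0.15))
})

test_that("sensory attributes follow their weighted log2 drivers", {
  fx <- hd_fixture()
  arch <- trait_architecture(list(trait_spec(
    "PHET", type = "metabolite", baseline = 4,
    cross_background_sd = 0.5, residual_sd = 0.5)))
  tt <- simulate_traits(fx$pop, arch, seed = 3)
  smap <- sensory_map(list(
    a_ros = list(weights = c(PHET = 1), noise_sd = 0)))
  ts <- simulate_sensory(tt, smap, seed = 4)
  expect_equal(order(ts$a_ros), order(log2(ts$PHET)))
  # all-zero weights with noise: attribute uncorrelated with the compound
  smap0 <- sensory_map(list(
    a_null = list(weights = c(PHET = 0), noise_sd = 1)))
  ts0 <- simulate_sensory(tt, smap0, seed = 5)
  expect_lt(abs(cor(ts0$a_null, log2(ts0$PHET))), 0.15)
  # determinism and missing-compound error
  expect_identical(simulate_sensory(tt, smap, seed = 4), ts)
  expect_error(simulate_sensory(
    tt, sensory_map(list(a = list(weights = c(NOPE = 1), noise_sd = 0))),
    seed = 1), "missing compound")
})

test_that("germplasm mixture proportions hit their planted extremes", {
  f <- small_founders(seed = 51)
  regions <- list(qtl_region("ch01", 1, 40e6, "r1"),
                  qtl_region("ch02", 1, 40e6, "r2"))
  p1 <- simulate_germplasm(f, regions, founder_mixture = 1,
                           n_accessions = 60, seed = 52)
  fr1 <- representation_frequencies(
    call_region_haplotypes(p1$genotypes, f$map, regions, f))
  expect_equal(fr1$per_region$represented_pct, c(100, 100))
  p0 <- simulate_germplasm(f, regions, founder_mixture = 0,
                           n_accessions = 60, seed = 53)
  fr0 <- representation_frequencies(
    call_region_haplotypes(p0$genotypes, f$map, regions, f))
  expect_equal(fr0$per_region$represented_pct, c(0, 0))
  expect_error(simulate_germplasm(f, regions, founder_mixture = 1.2),
               "founder_mixture")
})

test_that("pairwise recombinant fraction follows the Haldane map function", {
  f <- make_founders(c(12), c(60e6), seed = 61)
  pop <- simulate_population(
    f, cross_plan(crosses = list(c("C074", "C085")), generation = "F2",
                  n_per_cross = 1500), seed = 62,
    recomb_rate_cM_per_Mbp = 2)
  # gametes transmitted by the F1: recombination between marker pairs on
  # each transmitted haplotype, compared with Haldane r = (1-exp(-2d))/2
  idx <- seq_len(nrow(f$map))
  pick <- cbind(idx[1], idx[c(4, 8, 12)])
  for (k in seq_len(nrow(pick))) {
    i <- pick[k, 1]; j <- pick[k, 2]
    d_morgan <- 2 * (f$map$pos_bp[j] - f$map$pos_bp[i]) / 1e6 / 100
    r_exp <- 0.5 * (1 - exp(-2 * d_morgan))
    r_obs <- mean(c(pop$origins1[, i] != pop$origins1[, j],
                    pop$origins2[, i] != pop$origins2[, j]))
    se <- sqrt(r_exp * (1 - r_exp) / (2 * length(pop$ids)))
    expect_lt(abs(r_obs - r_exp), 4 * se)
  }
})
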