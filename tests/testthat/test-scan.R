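make_dp_panel <- function(n = 60, m = 12, seed = 90) {
  set.seed(seed)
  G <- matrix(rbinom(n * m, 2, 0.4), n, m,
              dimnames = list(sprintf("dp%03d", 1:n),
                              sprintf("mk%02d", 1:m)))
  map <- marker_map(colnames(G), rep("ch01", m),
                    sort(sample.int(60e6, m)))
  G <- G[, map$marker]
  traits <- data.frame(genotype_id = rownames(G),
                       fruit_type = sample(c("cherry", "round", "beef"),
                                           n, TRUE),
                       stringsAsFactors = FALSE)
  list(G = G, map = map, traits = traits)
}

test_that("diversity-panel scan recovers an exact linear signal and skips monomorphic markers", {
  dp <- make_dp_panel()
  dp$G[, 3] <- 1L  # monomorphic
  dp$traits$y <- 2 * dp$G[, 5]  # exact, noiseless
  res <- scan_dp(dp$traits, dp$G, dp$map, trait_cols = "y")
  row5 <- res[res$marker == colnames(dp$G)[5], ]
  expect_equal(row5$effect, 2, tolerance = 1e-10)
  expect_equal(row5$logP, 300)  # machine-zero P reported at the cap
  expect_equal(res$note[res$marker == colnames(dp$G)[3]], "monomorphic")
  expect_error(scan_dp(dp$traits[, -2], dp$G, dp$map, trait_cols = "y"),
               "fruit_type")
})

test_that("diversity-panel t statistic equals the textbook OLS formula", {
  set.seed(91)
  g <- c(0, 0, 1, 1, 1, 2, 2, 2)
  type <- rep(c("cherry", "round"), 4)
  y <- 1 + 0.5 * g + (type == "round") * 2 + rnorm(8, 0, 0.3)
  G <- matrix(g, 8, 1, dimnames = list(paste0("s", 1:8), "mk1"))
  map <- marker_map("mk1", "ch01", 100)
  traits <- data.frame(genotype_id = paste0("s", 1:8), fruit_type = type,
                       y = y, stringsAsFactors = FALSE)
  res <- scan_dp(traits, G, map, scan_config(min_informative_n = 5),
                 trait_cols = "y")
  # hand computation: t = beta / se from the normal equations
  X <- cbind(1, type == "round", g)
  XtXi <- solve(crossprod(X))
  beta <- XtXi %*% crossprod(X, y)
  sig2 <- sum((y - X %*% beta)^2) / (8 - 3)
  t_hand <- beta[3] / sqrt(sig2 * XtXi[3, 3])
  expect_equal(res$statistic, t_hand, tolerance = 1e-10)
  expect_equal(res$P, 2 * pt(abs(t_hand), 5, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("F6 per-cross scans report R2 = squared correlation and never pool crosses", {
  f <- small_founders(seed = 93)
  pop <- simulate_population(
    f, cross_plan(crosses = list(c("C074", "C085"), c("R075", "R104")),
                  generation = "F6", n_per_cross = 40), seed = 94)
  G <- genotype_dosage(pop)
  arch <- trait_architecture(list(trait_spec(
    "y", qtls = data.frame(marker = f$map$marker[3], C074 = 0, C085 = 1,
                           R075 = 0, R104 = 0),
    cross_background_sd = 0.3, residual_sd = 0.6)))
  tt <- simulate_traits(pop, arch, seed = 95)
  res <- scan_f6(tt, G, f$map, trait_cols = "y")
  cl <- "C074xC085"
  rows <- tt$cross == cl
  for (j in c(1, 3, 7)) {
    rr <- res[res$cross == cl & res$marker == f$map$marker[j], ]
    if (nrow(rr) == 1L && is.na(rr$note)) {
      expect_equal(rr$r2, cor(tt$y[rows], G[rows, j])^2, tolerance = 1e-10)
    }
  }
  # permuting trait values of cross 2 leaves cross-1 rows bit-identical
  tt2 <- tt
  i2 <- which(tt2$cross == "R075xR104")
  set.seed(96)
  tt2$y[i2] <- sample(tt2$y[i2])
  res2 <- scan_f6(tt2, G, f$map, trait_cols = "y")
  expect_identical(res[res$cross == cl, ], res2[res2$cross == cl, ])
})

test_that("F6 scan recovers a planted fraction of explained variance", {
  # single cross, marker explaining ~30% of variance, n = 100 RILs.
  # The sampling SD of R^2 at rho^2 = 0.3, n = 100 is ~0.073, so
  # individual estimates land in [0.2, 0.4] about 80% of the time; the
  # estimator is checked by its mean and that in-band rate.
  f <- make_founders(10, 60e6, seed = 97)
  r2s <- numeric(20)
  for (s in 1:20) {
    pop <- simulate_population(
      f, cross_plan(crosses = list(c("C074", "R075")), generation = "F6",
                    n_per_cross = 100), seed = 200 + s)
    j <- which(f$haplotypes["C074", ] != f$haplotypes["R075", ])[1]
    G <- genotype_dosage(pop)
    # RIL dosages are ~binary; scale the effect for var ~ 0.3 of total
    g <- G[, j]
    b <- sqrt(0.3 / 0.7 / var(g))
    set.seed(300 + s)
    y <- b * g + rnorm(100)
    traits <- data.frame(genotype_id = pop$ids, cross = pop$cross, y = y,
                         stringsAsFactors = FALSE)
    res <- scan_f6(traits, G, f$map, trait_cols = "y")
    r2s[s] <- res$r2[res$marker == f$map$marker[j]]
  }
  expect_lt(abs(mean(r2s) - 0.3), 0.05)
  expect_gte(mean(r2s > 0.2 & r2s < 0.4), 0.7)
})

test_that("Kruskal-Wallis matches the rank-sum formula and a permutation oracle", {
  r <- kruskal_wallis_assoc(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  # hand computation: 12/(N(N+1)) * sum R_g^2/n_g - 3(N+1), no ties
  expect_equal(r$statistic, 12 / (6 * 7) * (6^2 / 3 + 15^2 / 3) - 3 * 7,
               tolerance = 1e-12)
  tied <- kruskal_wallis_assoc(rep(7, 6), rep(c("a", "b"), 3))
  expect_equal(tied$statistic, 0)
  expect_equal(tied$P, 1)
  expect_error(kruskal_wallis_assoc(1:5, rep("a", 5)), "two non-empty")
  # permutation oracle: with two groups of 8 the chi-square reference is
  # already close to the permutation distribution
  set.seed(98)
  y <- rnorm(16) + rep(c(0, 1), each = 8)
  cls <- rep(c("a", "b"), each = 8)
  obs <- kruskal_wallis_assoc(y, cls)
  perm_stats <- replicate(4000, kruskal_wallis_assoc(y, sample(cls))$statistic)
  p_perm <- mean(perm_stats >= obs$statistic - 1e-12)
  expect_lt(abs(obs$P - p_perm), 0.05)
})

test_that("QTL map binning respects the threshold boundary and 5-Mbp bins", {
  res <- rbind(
    diallelQTL:::assoc_row("t1", "m1", "ch4", 52660000, "F2-diallel",
                           P = 10^-3.51, cross = "CC"),
    diallelQTL:::assoc_row("t1", "m2", "ch4", 52670000, "F2-diallel",
                           P = 10^-3.49, cross = "RR"),
    diallelQTL:::assoc_row("t1", "m3", "ch4", 54990000, "F2-diallel",
                           P = 10^-6, cross = "CR"))
  qm <- summarize_qtl_map(res)
  expect_equal(nrow(qm), 1L)  # 3.49 excluded; both others in [50,55) Mbp
  expect_equal(qm$bin_start_bp, 50e6)
  expect_equal(qm$bin_end_bp, 55e6)
  expect_equal(qm$peak_marker, "m3")
  expect_equal(qm$n_markers, 2L)
  expect_true(grepl("CC", qm$crosses) && grepl("CR", qm$crosses))
  empty <- summarize_qtl_map(diallelQTL:::empty_assoc())
  expect_equal(nrow(empty), 0L)
})

test_that("the F2 Wald statistic is invariant to the founder contrast basis", {
  fx <- hd_fixture()
  arch <- trait_architecture(list(trait_spec(
    "y", qtls = data.frame(marker = fx$founders$map$marker[40], C074 = 0,
                           C085 = 0.8, R075 = 0, R104 = 0),
    cross_background_sd = 0.5, residual_sd = 1)))
  tt <- simulate_traits(fx$pop, arch, seed = 40)
  mks <- fx$founders$map$marker[c(38, 40, 42, 100)]
  r_sum <- scan_f2(tt, fx$M, fx$rin, trait_cols = "y", markers = mks,
                   contrast_type = "sum")
  r_hel <- scan_f2(tt, fx$M, fx$rin, trait_cols = "y", markers = mks,
                   contrast_type = "helmert")
  ok <- !is.na(r_sum$statistic)
  expect_equal(r_sum$statistic[ok], r_hel$statistic[ok], tolerance = 1e-8)
  expect_equal(r_sum$P[ok], r_hel$P[ok], tolerance = 1e-8)
})

test_that("doubling a planted QTL effect does not decrease the median peak logP", {
  fx <- hd_fixture()
  j <- which(colSums(fx$M$informative) > 0)[50]
  qmk <- fx$founders$map$marker[j]
  logp_at <- function(effect, seeds) vapply(seeds, function(s) {
    arch <- trait_architecture(list(trait_spec(
      "y", qtls = data.frame(marker = qmk, C074 = 0, C085 = effect,
                             R075 = 0, R104 = 0),
      cross_background_sd = 0.5, residual_sd = 1)))
    tt <- simulate_traits(fx$pop, arch, seed = s)
    scan_f2(tt, fx$M, fx$rin, trait_cols = "y", markers = qmk)$logP
  }, 1)
  seeds <- 501:512
  expect_gte(median(logp_at(1, seeds)), median(logp_at(0.5, seeds)))
})

test_that("markers uninformative everywhere are skipped with a reason", {
  fx <- hd_fixture()
  j <- which(colSums(fx$M$informative) == 0)[1]
  arch <- trait_architecture(list(trait_spec("y", residual_sd = 1)))
  tt <- simulate_traits(fx$pop, arch, seed = 50)
  res <- scan_f2(tt, fx$M, fx$rin, trait_cols = "y",
                 markers = fx$founders$map$marker[j])
  expect_equal(res$note, "uninformative in all crosses")
  expect_true(is.na(res$P))
})
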