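test_that("sitewise pi matches hand-enumerated pairs", {
  # {0/0, 1/1}: 4 alleles, counts 2/2 -> 4/6
  vt <- make_vt(matrix(c("0/0", "1/1"), 1))
  expect_equal(sitewise_pi(vt)$pi, 4 / 6)
  # {0/1, ./.}: single called pair differs
  vt2 <- make_vt(matrix(c("0/1", "./."), 1))
  expect_equal(sitewise_pi(vt2)$pi, 1.0)
  # monomorphic -> 0; single allele -> dropped
  vt3 <- make_vt(rbind(c("0/0", "0/0"), c("./.", "./.")))
  tr3 <- sitewise_pi(vt3)
  expect_equal(nrow(tr3), 1L)
  expect_equal(tr3$pi, 0)
})

test_that("windowed pi divides by full window length", {
  track <- data.frame(chrom = "chr1", pos = 5L, pi = 4 / 6, n_called = 4L)
  w <- windowed_pi(track, window = 10L, step = 10L)
  expect_equal(w$pi[1], (4 / 6) / 10)
  # empty window -> 0
  track2 <- data.frame(chrom = "chr1", pos = 25L, pi = 0.5, n_called = 4L)
  w2 <- windowed_pi(track2, window = 10L, step = 10L)
  expect_equal(w2$pi[w2$start == 1], 0)
  # abutting step-windows share a site that falls in both
  track3 <- data.frame(chrom = "chr1", pos = 15L, pi = 0.5, n_called = 4L)
  w3 <- windowed_pi(track3, window = 20L, step = 10L)
  expect_equal(w3$n_sites[w3$start %in% c(1, 11)], c(1L, 1L))
})

test_that("Tajima's D reproduces the worked value and the null identity", {
  # n = 4 haplotypes, 3 segregating sites, allele counts (1,3),(2,2),(1,3)
  vt <- make_vt(rbind(c("0/1", "0/0"), c("0/1", "0/1"), c("1/0", "0/0")))
  d <- tajimas_d(vt)
  expect_equal(attr(d, "theta_pi"), 1.6667, tolerance = 1e-4)
  expect_equal(attr(d, "theta_w"), 1.6364, tolerance = 1e-4)
  expect_equal(as.numeric(d), 0.168, tolerance = 1e-2)
  # no segregating sites -> undefined, not 0
  expect_true(is.na(tajimas_d(make_vt(matrix("0/0", 2, 3)))))
})

test_that("pi/Tajima/Fst/r2 match brute-force oracles on random toys", {
  set.seed(1234)
  for (rep in 1:25) {
    vt <- random_vt(12, sample(4:10, 1), miss = 0.15)
    expect_equal(sitewise_pi(vt)$pi,
                 oracle_pi_track(vt)[!is.na(oracle_pi_track(vt))],
                 tolerance = 1e-12)
    vtc <- random_vt(10, sample(3:10, 1))    # complete data for D
    d <- tajimas_d(vtc)
    if (!is.na(d))
      expect_equal(as.numeric(d),
                   oracle_tajima(2 * n_samples(vtc), oracle_pi_track(vtc)),
                   tolerance = 1e-12)
    ns <- sample(6:10, 1)
    vtf <- random_vt(30, 2 * ns, miss = 0.1)
    pops <- list(p1 = vtf$samples[1:ns], p2 = vtf$samples[(ns + 1):(2 * ns)])
    expect_equal(weir_cockerham_fst(vtf, pops)$global,
                 oracle_wc_global(vtf, pops), tolerance = 1e-12)
    dos <- vt_dosage(random_vt(2, 12))
    r <- suppressWarnings(cor(dos[1, ], dos[2, ],
                              use = "pairwise.complete.obs"))
    if (!is.na(r))
      expect_equal(r^2, oracle_r2(dos[1, ], dos[2, ]), tolerance = 1e-12)
  }
})

test_that("pi_n/pi_s reproduces the hand-computed toy exactly", {
  # 2 nonsynonymous sites with pi 0.5 inside an HQ model (positions 12, 15),
  # 4 intergenic sites with pi 0.5 each (summed diversity 2.0)
  gt <- matrix(rep(c("0/0", "0/1"), 6), nrow = 6, byrow = TRUE)  # pi = 0.5
  vt <- make_vt(gt, pos = c(12L, 15L, 1000L, 1100L, 1200L, 1300L))
  models <- toy_model("g1", "chr1", 10L, 30L)
  calls <- data.frame(chrom = "chr1",
                      pos = vt$sites$pos,
                      ref = "A", alt = "T",
                      gene_id = c("g1", "g1", NA, NA, NA, NA),
                      impact = c("HIGH", "MODERATE", rep("MODIFIER", 4)),
                      stringsAsFactors = FALSE)
  res <- pin_pis(vt, calls, models,
                 called = called_site_counts(300, 1000))
  expect_equal(res$sum_diversity_nonsyn, 1.0)
  expect_equal(res$pi_n, 1.0 / (300 * 2 / 3))      # = 0.005
  expect_equal(res$pi_n, 0.005)
  expect_equal(res$pi_s, 2.0 / 1000)               # = 0.002
  expect_equal(res$ratio, 2.5)
  # no variants anywhere: both zero, ratio undefined
  res0 <- pin_pis(vt_subset(vt, sites = 0L), calls[0, ], models,
                  called = called_site_counts(300, 1000))
  expect_equal(res0$pi_n, 0)
  expect_equal(res0$pi_s, 0)
  expect_true(is.na(res0$ratio))
  # zero intergenic called positions: pi_s and ratio undefined
  resz <- pin_pis(vt, calls, models, called = called_site_counts(300, 0))
  expect_true(is.na(resz$pi_s) && is.na(resz$ratio))
})

test_that("pi_n is monotone in numerator diversity at fixed denominators", {
  models <- toy_model("g1", "chr1", 10L, 30L)
  base_calls <- data.frame(chrom = "chr1", pos = 12L, ref = "A", alt = "T",
                           gene_id = "g1", impact = "HIGH",
                           stringsAsFactors = FALSE)
  pis <- sapply(list(c("0/0", "0/1"), c("0/0", "1/1")), function(g) {
    vt <- make_vt(matrix(g, 1), pos = 12L)
    pin_pis(vt, base_calls, models,
            called = called_site_counts(300, 1000))$pi_n
  })
  expect_gt(pis[2], pis[1])   # site pi 2/3 beats 1/2 at fixed denominators
  expect_equal(pis, c(0.5, 2 / 3) / 200)
})

test_that("Weir-Cockerham F_ST hits the fixed-difference and null limits", {
  vt <- make_vt(matrix(c(rep("0/0", 5), rep("1/1", 5)), 1))
  pops <- list(p1 = vt$samples[1:5], p2 = vt$samples[6:10])
  expect_equal(weir_cockerham_fst(vt, pops)$global, 1.0)
  # identical genotype vectors in both populations
  set.seed(7)
  g <- matrix(sample(c("0/0", "0/1", "1/1"), 40, replace = TRUE), nrow = 4)
  vt2 <- make_vt(cbind(g, g))
  pops2 <- list(p1 = vt2$samples[1:10], p2 = vt2$samples[11:20])
  th <- weir_cockerham_fst(vt2, pops2)$global
  expect_lte(th, 0)
  expect_lt(abs(th), 0.2)
})

test_that("LD decay fit inverts to the closed-form half-decay distance", {
  curve <- list(beta0 = 0.6, beta1 = -0.1, r0 = 0.5, d_min = 10)
  expect_equal(half_decay(curve), 10^3.5, tolerance = 1e-9)
  curve_up <- list(beta0 = 0.1, beta1 = 0.05, r0 = 0.2)
  expect_true(is.na(half_decay(curve_up)))
  # identical dosage vectors give r2 = 1
  gt <- matrix(rep(c("0/0", "0/1", "1/1", "0/1", "1/1", "0/0",
                     "0/1", "1/1", "0/0", "0/1", "1/1", "0/1"), 2),
               nrow = 2, byrow = TRUE)
  vt <- make_vt(gt, pos = c(100L, 200L))
  curve2 <- ld_decay(vt, mac_min = 4L)
  expect_equal(curve2$pairs$r2, 1)
  expect_equal(curve2$pairs$distance, 100)
})

test_that("LD pruning keeps one of each correlated set", {
  set.seed(11)
  base <- sample(c("0/0", "0/1", "1/1"), 30, replace = TRUE)
  gt <- rbind(base, base, base)    # 3 perfectly correlated SNPs
  vt <- make_vt(gt, pos = c(10L, 20L, 30L))
  pruned <- ld_prune(vt, window = 50L, step = 10L, r2_max = 0.1)
  expect_equal(n_sites(pruned), 1L)
  # independent sites survive
  vt2 <- random_vt(30, 40, seed = 3)
  pruned2 <- ld_prune(vt2, r2_max = 0.9)
  expect_equal(n_sites(pruned2), 30L)
  # duplicated site: exactly one copy removed, the larger coordinate
  vt3 <- make_vt(rbind(base, base), pos = c(10L, 20L))
  pruned3 <- ld_prune(vt3)
  expect_equal(pruned3$sites$pos, 10L)
})

test_that("f3 is zero when target equals a source and negative for admixture", {
  set.seed(21)
  g <- matrix(sample(c("0/0", "0/1", "1/1"), 200 * 6, replace = TRUE), 200)
  vt <- make_vt(cbind(g[, 1:3], g[, 1:3], g[, 4:6]))
  f3 <- f3_statistic(vt, target = vt$samples[4:6],
                     source_a = vt$samples[1:3],
                     source_b = vt$samples[7:9],
                     block_size = 50L, correction = FALSE)
  expect_equal(f3$f3, 0)
  p <- simulation_params(8000, c(15, 15), n_admixed = 10,
                         divergence_F = 0.2, seed = 77)
  sim <- simulate_two_population_genotypes(p)
  sm <- sim$vt$samples
  f3m <- f3_statistic(sim$vt, target = grep("F1", sm, value = TRUE),
                      source_a = grep("pop1", sm, value = TRUE),
                      source_b = grep("pop2", sm, value = TRUE),
                      block_size = 500L)
  expect_lt(f3m$f3, 0)
  expect_lt(f3m$z, -3)
  # identical source populations: no admixture signal
  f3n <- f3_statistic(sim$vt, target = grep("pop1", sm, value = TRUE)[1:7],
                      source_a = grep("pop1", sm, value = TRUE)[8:15],
                      source_b = grep("pop2", sm, value = TRUE),
                      block_size = 500L)
  expect_gt(f3n$z, -3)
})

test_that("inbreeding coefficient hits its fixed points", {
  set.seed(5)
  vt <- random_vt(4000, 12)
  f <- inbreeding_coefficient(vt)
  expect_lt(abs(mean(f)), 0.05)               # outbred: near 0
  hom <- vt
  hom$geno_b <- hom$geno_a                     # fully homozygous sample set
  fh <- inbreeding_coefficient(hom, samples = "s1")
  expect_equal(unname(fh), 1, tolerance = 1e-9)
})
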