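test_that("mapping-fraction classes follow the observed group ranges", {
  res <- classify_mapping_fraction(c(80, 30, 50), c(20, 70, 50))
  expect_equal(res$class, c("HY-dominant", "HH-dominant", "admixed"))
  expect_equal(res$f_hy, c(0.8, 0.3, 0.5))
})

test_that("DEA calls gate on depth and use the exact binomial test", {
  res <- call_dea(list(a = c(g1 = 50, g2 = 90, g3 = 4),
                       b = c(g1 = 50, g2 = 10, g3 = 3)))
  expect_equal(res$p[1], 1)                       # 50/50 exact null
  expect_false(res$dea[1])
  expect_equal(res$p[2], binom.test(90, 100)$p.value)  # ~3.1e-17
  expect_lt(res$p[2], 1e-16)
  expect_true(res$dea[2])
  expect_false(res$tested[3])                     # 7 reads < min_depth
  expect_true(is.na(res$p[3]))
  # q monotone in p within the library
  set.seed(3)
  a <- rbinom(60, 100, runif(60, 0.4, 0.9)); b <- 100 - a
  r <- call_dea(list(a = setNames(a, paste0("g", 1:60)),
                     b = setNames(b, paste0("g", 1:60))))
  ord <- order(r$p)
  expect_true(all(diff(r$q[ord]) >= -1e-12))
})

test_that("null allelic ratios yield calls at about the FDR level", {
  sim <- simulate_allelic_counts(paste0("g", 1:600), 4, depth_mean = 100,
                                 dea_fraction = 0, seed = 44)
  calls <- call_dea_all(sim$counts)
  frac <- mean(vapply(calls, function(cs) mean(cs$dea[cs$tested]),
                      numeric(1)))
  expect_lte(frac, 0.05 * 1.5)   # V/m under complete null is below alpha
})

test_that("saturation curve is exact on the 3-library toy and monotone", {
  sc <- saturation_curve(list(c("a", "b"), c("b", "c"), c("c")),
                         k_values = 0:3, reps = 500, seed = 1)
  expect_equal(sc$mean_union, c(0, 5 / 3, 8 / 3, 3))
  expect_true(all(sc$exhaustive))
  expect_equal(sc$sd_union[sc$k == 3], 0)          # full union: no variance
  expect_true(all(diff(sc$mean_union) >= 0))
  # monotone on simulated call sets too
  sim <- simulate_allelic_counts(paste0("g", 1:200), 8, dea_fraction = 0.2,
                                 seed = 12)
  calls <- call_dea_all(sim$counts)
  sc2 <- saturation_curve(calls, k_values = c(1, 2, 4, 8), reps = 100,
                          seed = 2)
  expect_true(all(diff(sc2$mean_union) >= 0))
})

test_that("NG86 Ka/Ks matches the path-enumeration oracle", {
  for (s in 1:20) {
    pair <- random_cds_pair(100, n_mut = 8, seed = 1000 + s)
    got <- allelic_kaks(pair$a, pair$b)
    want <- oracle_ng86(pair$a, pair$b)
    expect_equal(got$ka, want$ka, tolerance = 1e-9)
    expect_equal(got$ks, want$ks, tolerance = 1e-9)
    expect_equal(got$s_sites, want$S, tolerance = 1e-9)
    # symmetric under order swap
    swap <- allelic_kaks(pair$b, pair$a)
    expect_equal(swap$ka, got$ka, tolerance = 1e-12)
    expect_equal(swap$ks, got$ks, tolerance = 1e-12)
  }
})

test_that("Ka/Ks edge cases: identity, pure synonymous change, errors", {
  cds <- "ATGCTTCTCGAAGGGTGGTAA"
  same <- allelic_kaks(cds, cds)
  expect_equal(same$ka, 0)
  expect_equal(same$ks, 0)
  expect_true(is.na(same$ratio))
  # one GAA -> GAG synonymous difference: Ka = 0, Ks > 0, ratio 0
  mut <- sub("GAAGGG", "GAGGGG", cds)
  r <- allelic_kaks(cds, mut)
  expect_equal(r$ka, 0)
  expect_gt(r$ks, 0)
  expect_equal(r$ratio, 0)
  expect_error(allelic_kaks("ATGAAA", "ATGAAATTT"), "length mismatch")
  expect_error(allelic_kaks("ATGTAAAAA", "ATGTACAAA"), "internal stop")
})

test_that("SNP density per feature is count over length times 100", {
  # plus-strand gene: exons [101,160] & [261,320], CDS [121,160] & [261,300]
  m <- list(g1 = list(gene_id = "g1", chrom = "chr1", strand = "+",
                      exons = cbind(start = c(101L, 261L),
                                    end = c(160L, 320L)),
                      cds = cbind(start = c(121L, 261L),
                                  end = c(160L, 300L)),
                      tss = 101L))
  class(m) <- "gene_model_set"
  snps <- data.frame(chrom = "chr1",
                     pos = c(50L, 105L, 130L, 200L, 310L, 400L))
  res <- snp_feature_density(snps, m)
  pg <- res$per_gene
  g <- function(f) pg[pg$feature == f, ]
  expect_equal(g("promoter")$length, 100L)   # clipped at chromosome start
  expect_equal(g("promoter")$n_snps, 1L)     # pos 50
  expect_equal(g("promoter")$density, 1.0)
  expect_equal(g("utr5")$n_snps, 1L)         # pos 105 in [101,120]
  expect_equal(g("exon")$n_snps, 3L)         # 105, 130, 310
  expect_equal(g("intron")$n_snps, 1L)       # pos 200 in [161,260]
  expect_equal(g("utr3")$n_snps, 1L)         # pos 310 in [301,320]
  expect_equal(g("downstream2kb")$n_snps, 1L)  # pos 400
  expect_equal(g("downstream2kb")$density, 100 * 1 / 2000)
  expect_equal(res$aggregate$density[res$aggregate$feature == "exon"],
               100 * 3 / 120)
})

test_that("feature assignment is strand-aware", {
  m <- list(g1 = list(gene_id = "g1", chrom = "chr1", strand = "-",
                      exons = cbind(start = 101L, end = 160L),
                      cds = cbind(start = 121L, end = 140L),
                      tss = 160L))
  class(m) <- "gene_model_set"
  snps <- data.frame(chrom = "chr1", pos = c(110L, 150L, 170L, 90L))
  pg <- snp_feature_density(snps, m, promoter_len = 50L,
                            downstream_len = 50L)$per_gene
  g <- function(f) pg[pg$feature == f, ]
  expect_equal(g("utr3")$n_snps, 1L)       # pos 110: left of CDS = 3' on minus
  expect_equal(g("utr5")$n_snps, 1L)       # pos 150
  expect_equal(g("promoter")$n_snps, 1L)   # pos 170: upstream of minus TSS
  expect_equal(g("downstream2kb")$n_snps, 1L)  # pos 90
})
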