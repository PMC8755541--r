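test_that("generators are deterministic under a fixed seed", {
  p <- simulation_params(500, c(5, 5), n_admixed = 2, seed = 11)
  s1 <- simulate_two_population_genotypes(p)
  s2 <- simulate_two_population_genotypes(p)
  expect_identical(s1$vt$geno_a, s2$vt$geno_a)
  expect_identical(s1$truth$p_population, s2$truth$p_population)
  f1 <- tempfile(); f2 <- tempfile()
  write_vcf(s1$vt, f1); write_vcf(s2$vt, f2)
  expect_identical(readLines(f1), readLines(f2))   # byte-identical VCF

  g1 <- generate_genome_with_annotation(n_genes = 5, seed = 3)
  g2 <- generate_genome_with_annotation(n_genes = 5, seed = 3)
  expect_identical(as.character(g1$genomes$hap2[[1]]),
                   as.character(g2$genomes$hap2[[1]]))
})

test_that("zero divergence makes the populations exchangeable", {
  p <- simulation_params(4000, c(15, 15), divergence_F = 0, seed = 21)
  sim <- simulate_two_population_genotypes(p)
  expect_identical(sim$truth$p_population[, 1], sim$truth$p_population[, 2])
  pops <- split(sim$vt$samples, sub("_.*", "", sim$vt$samples))
  fst <- weir_cockerham_fst(sim$vt, pops)
  expect_lt(abs(fst$global), 0.02)
})

test_that("allele-frequency conservation: population mean tracks ancestral mean", {
  p <- simulation_params(20000, c(2, 2), divergence_F = 0.2, seed = 5)
  sim <- simulate_two_population_genotypes(p)
  # E[p_k] = p_anc under Balding-Nichols; CLT bound on the mean difference
  for (k in 1:2) {
    d <- sim$truth$p_population[, k] - sim$truth$p_ancestral
    se <- sd(d) / sqrt(length(d))
    expect_lt(abs(mean(d)), 5 * se)
  }
})

test_that("within-population inbreeding produces the expected het deficit", {
  p <- simulation_params(20000, c(25, 0), divergence_F = 0.01,
                         inbreeding_F_within = c(0.4, 0), seed = 8)
  sim <- simulate_two_population_genotypes(p)
  vt <- vt_subset(sim$vt, samples = grep("pop1", sim$vt$samples, value = TRUE))
  f <- mean(inbreeding_coefficient(vt))
  expect_lt(abs(f - 0.4), 0.05)
})

test_that("pedigree truth encodes definitional degrees", {
  p <- simulation_params(800, c(6, 0), divergence_F = 0.02, seed = 2)
  founders <- vt_subset(simulate_two_population_genotypes(p)$vt,
                        samples = paste0("pop1_0", 1:6))
  ped <- data.frame(child = c("cl", "kid", "gkid"),
                    parent_a = c("pop1_01", "pop1_01", "kid"),
                    parent_b = c(NA, "pop1_02", "pop1_03"))
  sim <- simulate_pedigree_genotypes(founders, ped, seed = 4)
  deg <- sim$truth$degree
  expect_equal(deg["cl", "pop1_01"], "duplicate")
  expect_equal(deg["kid", "pop1_01"], "1")          # parent-offspring
  expect_equal(deg["gkid", "pop1_01"], "2")         # grandparent
  expect_equal(deg["pop1_05", "pop1_06"], "unrelated")
  # clone genotypes are copied verbatim
  expect_identical(sim$vt$geno_a[, "cl"], sim$vt$geno_a[, "pop1_01"])
  expect_error(simulate_pedigree_genotypes(
    founders, data.frame(child = "x", parent_a = "nope", parent_b = "pop1_01"),
    seed = 1), "unknown parent")
})

test_that("genome generator plants the requested deletion and defects", {
  g <- generate_genome_with_annotation(n_genes = 10, deletion_length = 3781L,
                                       malformed_fraction = 0, seed = 13)
  expect_equal(g$truth$deletion$end - g$truth$deletion$start + 1L, 3781L)
  hq <- filter_high_quality_models(g$models, g$genomes$hap1)
  expect_equal(nrow(hq$rejected), 0L)   # all models pass with no defects
  expect_equal(length(hq$kept), 10L)

  gm <- generate_genome_with_annotation(n_genes = 40,
                                        malformed_fraction = 0.5, seed = 19)
  hqm <- filter_high_quality_models(gm$models, gm$genomes$hap1)
  # the HQ filter rejects exactly the planted malformed set
  expect_setequal(hqm$rejected$gene_id, gm$truth$malformed_gene_ids)
  # seed-fixed binomial draw around 20 of 40
  expect_gt(nrow(hqm$rejected), 10)
  expect_lt(nrow(hqm$rejected), 30)
})

test_that("allelic count generator respects dea_fraction and theta", {
  s0 <- simulate_allelic_counts(paste0("g", 1:50), 5, dea_fraction = 0,
                                seed = 31)
  expect_length(s0$truth$dea_genes, 0)
  s <- simulate_allelic_counts(paste0("g", 1:400), 8, depth_mean = 100,
                               dea_fraction = 0.25, theta_dea = 0.8, seed = 32)
  expect_length(s$truth$dea_genes, 100)
  dea <- rownames(s$counts$a) %in% s$truth$dea_genes
  frac_a <- rowSums(s$counts$a) / (rowSums(s$counts$a) + rowSums(s$counts$b))
  expect_lt(abs(mean(frac_a[!dea]) - 0.5), 0.01)
  expect_gt(mean(abs(frac_a[dea] - 0.5)), 0.25)    # near 0.8 or 0.2
})

test_that("coverage generator scales depth by deleted copies", {
  cov <- simulate_coverage(12000, list(start = 4001, end = 7000),
                           c(g0 = 0L, g1 = 1L, g2 = 2L),
                           mean_depth = 40, seed = 6)
  inside <- 4001:7000; outside <- c(1:4000, 7001:12000)
  m_in <- colMeans(cov$depth[inside, ])
  m_out <- colMeans(cov$depth[outside, ])
  expect_lt(m_in[["g2"]], 1)                      # near zero
  expect_lt(abs(m_in[["g1"]] / m_out[["g1"]] - 0.5), 0.05)
  expect_lt(abs(m_in[["g0"]] / m_out[["g0"]] - 1), 0.05)
})
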