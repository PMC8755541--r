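test_that("HQ filter rejects non-ATG starts and broken frames with reasons", {
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(
    "NNNNNNNNN",
    "GTGAAAGAATAA",          # gene at 10..21: GTG start
    "ATGAAAGAAT",            # gene at 22..31: length 10, not %% 3
    "ATGGAAAAGTGGCCCTAA")))  # gene at 32..49: clean
  models <- c(toy_model("gGTG", "chr1", 10L, 12L),
              toy_model("gLEN", "chr1", 22L, 10L),
              toy_model("gOK", "chr1", 32L, 18L))
  class(models) <- "gene_model_set"
  res <- filter_high_quality_models(models, genome)
  expect_named(res$kept, "gOK")
  expect_equal(res$rejected$reason[res$rejected$gene_id == "gGTG"],
               "non-ATG start")
  expect_equal(res$rejected$reason[res$rejected$gene_id == "gLEN"],
               "length not divisible by three")
  expect_error(filter_high_quality_models(models,
                 Biostrings::DNAStringSet(c(chr9 = "ACGT"))), "chr1")
})

test_that("coding SNPs are classified through the genetic code", {
  # CDS at 11..28 on +: ATG GAA TGG ATG CCC TAA
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(
    "AAAAAAAAAA", "ATGGAATGGATGCCCTAA", "AAAAAAAAAA")))
  models <- toy_model("g1", "chr1", 11L, 18L)
  v <- data.frame(chrom = "chr1",
                  pos = c(19L, 16L, 22L, 5L),
                  ref = c("G", "A", "G", "A"),
                  alt = c("A", "G", "T", "T"))
  calls <- classify_variant_effects(v, models, genome)
  # TGG -> TGA at codon position 3? pos 19 is TGG's G2: TGG->TAG stop
  expect_equal(calls$consequence[1], "stop_gained")
  expect_equal(calls$impact[1], "HIGH")
  expect_equal(calls$consequence[2], "synonymous")   # GAA -> GAG
  expect_equal(calls$impact[2], "LOW")
  expect_equal(calls$consequence[3], "missense")     # ATG -> ATT (Met->Ile)
  expect_equal(calls$impact[3], "MODERATE")
  expect_equal(calls$impact[4], "MODIFIER")          # intergenic
  expect_true(is.na(calls$gene_id[4]))
})

test_that("CDS indels split into in-frame MODERATE and frameshift HIGH", {
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(
    "AAAAAAAAAA", "ATGGAAGGGCCCTTTTAA", "AAAAAAAAAA")))
  models <- toy_model("g1", "chr1", 11L, 18L)
  v <- data.frame(chrom = "chr1", pos = c(14L, 14L),
                  ref = c("GAAG", "GA"), alt = c("G", "G"))
  calls <- classify_variant_effects(v, models, genome)
  expect_equal(calls$consequence, c("inframe_indel", "frameshift"))
  expect_equal(calls$impact, c("MODERATE", "HIGH"))
})

test_that("classification agrees with full-CDS translation brute force", {
  g <- generate_genome_with_annotation(n_genes = 15, malformed_fraction = 0,
                                       seed = 42)
  hq <- filter_high_quality_models(g$models, g$genomes$hap1)$kept
  genome <- g$genomes$hap1
  set.seed(99)
  # random SNPs inside CDS of random HQ genes
  n_checked <- 0
  for (rep in seq_len(1000)) {
    gid <- sample(names(hq), 1)
    m <- hq[[gid]]
    iv <- m$cds[sample(nrow(m$cds), 1), , drop = FALSE]
    pos <- sample(iv[1, 1]:iv[1, 2], 1)
    ref <- substr(as.character(genome[[m$chrom]]), pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    call <- classify_variant_effects(
      data.frame(chrom = m$chrom, pos = pos, ref = ref, alt = alt),
      hq[gid], genome)
    # oracle: translate the whole CDS before and after the substitution
    mut_genome <- genome
    s <- as.character(mut_genome[[m$chrom]])
    substr(s, pos, pos) <- alt
    mut_genome[[m$chrom]] <- Biostrings::DNAString(s)
    aa_ref <- as.character(Biostrings::translate(
      Biostrings::DNAString(cds_sequence(m, genome)), no.init.codon = TRUE))
    aa_alt <- as.character(Biostrings::translate(
      Biostrings::DNAString(cds_sequence(m, mut_genome)),
      no.init.codon = TRUE))
    expected <- if (aa_ref == aa_alt) "LOW"
      else {
        d <- which(strsplit(aa_ref, "")[[1]] != strsplit(aa_alt, "")[[1]])
        ra <- substr(aa_ref, d, d); ma <- substr(aa_alt, d, d)
        if (ma == "*" || ra == "*") "HIGH" else "MODERATE"
      }
    expect_equal(call$impact, expected,
                 info = sprintf("%s pos %d %s>%s", gid, pos, ref, alt))
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 1000)
})

test_that("impact calls are invariant under strand flip of the genome", {
  g <- generate_genome_with_annotation(n_genes = 6, seed = 77)
  genome <- g$genomes$hap1
  L <- g$truth$genome_length
  snps <- g$variants[nchar(g$variants$ref) == 1 &
                       nchar(g$variants$alt) == 1, ][1:40, ]
  fwd <- classify_variant_effects(snps, g$models, genome)
  # reverse-complement the chromosome, flip model strands and coordinates
  rc <- Biostrings::DNAStringSet(
    setNames(Biostrings::reverseComplement(genome[[1]]), NULL))
  names(rc) <- "chr1"
  flip_iv <- function(m) cbind(start = L - m[, 2] + 1L, end = L - m[, 1] + 1L)
  flipped <- lapply(g$models, function(m) {
    m2 <- m
    m2$strand <- if (m$strand == "+") "-" else "+"
    m2$exons <- flip_iv(m$exons)[rev(seq_len(nrow(m$exons))), , drop = FALSE]
    m2$cds <- flip_iv(m$cds)[rev(seq_len(nrow(m$cds))), , drop = FALSE]
    m2$tss <- L - m$tss + 1L
    m2
  })
  class(flipped) <- "gene_model_set"
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  snps_rc <- data.frame(chrom = "chr1", pos = L - snps$pos + 1L,
                        ref = comp[snps$ref], alt = comp[snps$alt])
  rev_calls <- classify_variant_effects(snps_rc, flipped, rc)
  expect_equal(rev_calls$impact, fwd$impact)
  expect_equal(rev_calls$consequence, fwd$consequence)
})

test_that("divergence summary computes internally consistent percentages", {
  g <- generate_genome_with_annotation(n_genes = 15, seed = 55)
  calls <- classify_variant_effects(g$variants, g$models, g$genomes$hap1)
  ds <- summarize_haplotype_divergence(calls, g$models)
  expect_lte(ds$n_genes_with_aa_change, ds$n_genes_with_variant)
  expect_lte(ds$n_genes_with_variant, ds$n_genes_total)
  expect_equal(ds$pct_genes_with_variant,
               round(100 * ds$n_genes_with_variant / ds$n_genes_total, 1))
  # undefined on a zero denominator, not 0
  empty <- summarize_haplotype_divergence(
    classify_variant_effects(g$variants[0, ], g$models, g$genomes$hap1),
    structure(list(), class = "gene_model_set"))
  expect_true(is.na(empty$pct_genes_with_variant))
  # stop-gain-only restriction can only shrink the nonsense gene set
  ds2 <- summarize_haplotype_divergence(calls, g$models,
                                        nonsense_includes_frameshift = FALSE)
  expect_lte(ds2$n_genes_with_nonsense, ds$n_genes_with_nonsense)
})

test_that("per-individual impact counts follow carried alternate alleles", {
  vt <- make_vt(rbind(c("0/1", "0/0", "1/1"),
                      c("0/0", "0/0", "0/1"),
                      c("0/1", "0/0", "./.")))
  calls <- data.frame(impact = c("HIGH", "HIGH", "HIGH"))
  res <- count_impact_per_individual(vt, calls)
  expect_equal(unname(res$counts[, "HIGH"]), c(2, 0, 2))
  # identical groups: ANOVA cannot reject the null
  vt2 <- make_vt(matrix(rep(c("0/1", "0/0"), each = 4), nrow = 2,
                        byrow = TRUE))
  calls2 <- data.frame(impact = c("HIGH", "MODERATE"))
  res2 <- count_impact_per_individual(vt2, calls2,
                                      groups = rep(c("a", "b"), 2))
  expect_true(is.na(res2$anova[["HIGH"]]) || res2$anova[["HIGH"]] > 0.9)
})
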