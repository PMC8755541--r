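# Fixtures are built in code; nothing is read from disk except what a test
# itself writes to a tempfile.

# quick variant_table from genotype strings like "0/1", "./."
make_vt <- function(gt, pos = NULL, chrom = "chr1", ref = "A", alt = "T",
                    ann = NULL) {
  gt <- as.matrix(gt)
  n <- nrow(gt)
  if (is.null(pos)) pos <- seq_len(n) * 10L
  a <- apply(gt, c(1, 2), function(g) {
    x <- strsplit(g, "[/|]")[[1]][1]
    if (x == ".") NA_integer_ else as.integer(x)
  })
  b <- apply(gt, c(1, 2), function(g) {
    x <- strsplit(g, "[/|]")[[1]][2]
    if (x == ".") NA_integer_ else as.integer(x)
  })
  sites <- data.frame(chrom = chrom, pos = pos,
                      ref = rep_len(ref, n), alt = rep_len(alt, n),
                      stringsAsFactors = FALSE)
  if (!is.null(ann)) sites <- cbind(sites, ann)
  samples <- colnames(gt)
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(gt)))
  variant_table(sites, a, b, samples)
}

# random biallelic variant_table with optional missingness
random_vt <- function(n_sites, n_samples, miss = 0, maf_min = 0.05,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- runif(n_sites, maf_min, 1 - maf_min)
  a <- matrix(rbinom(n_sites * n_samples, 1, rep(p, n_samples)),
              nrow = n_sites)
  b <- matrix(rbinom(n_sites * n_samples, 1, rep(p, n_samples)),
              nrow = n_sites)
  if (miss > 0) {
    drop <- matrix(runif(n_sites * n_samples) < miss, nrow = n_sites)
    a[drop] <- NA; b[drop] <- NA
  }
  sites <- data.frame(chrom = "chr1", pos = seq_len(n_sites) * 10L,
                      ref = "A", alt = "T", stringsAsFactors = FALSE)
  variant_table(sites, a, b, paste0("s", seq_len(n_samples)))
}

# a hand-made single-exon plus-strand gene model
toy_model <- function(gene_id, chrom, start, cds_len, strand = "+") {
  cds <- matrix(c(start, start + cds_len - 1L), ncol = 2,
                dimnames = list(NULL, c("start", "end")))
  structure(list(setNames(list(gene_id, chrom, strand, cds, cds,
                               if (strand == "-") start + cds_len - 1L
                               else start),
                          c("gene_id", "chrom", "strand", "exons", "cds",
                            "tss"))),
            names = gene_id, class = "gene_model_set")
}
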