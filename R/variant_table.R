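#' Variant table: multi-sample genotypes plus site annotations
#'
#' The central container of the package. A `variant_table` holds one row per
#' variant site (chromosome, 1-based position, REF, ALT alleles and the usual
#' hard-filter site annotations such as QD, FS, MQ, SOR, DP, MQRankSum and
#' ReadPosRankSum) together with two integer allele matrices giving, for every
#' site and sample, the pair of allele indices (0 = REF, 1 = first ALT, ...).
#' Missing genotypes are `NA` in both matrices.
#'
#' @param sites data.frame with at least columns `chrom`, `pos`, `ref`, `alt`.
#'   `alt` is a comma-separated string of alternate alleles. Any further
#'   numeric columns are treated as site annotations.
#' @param geno_a,geno_b integer matrices (sites x samples) of allele indices;
#'   `NA` marks a missing genotype. Unphased: the pair is unordered.
#' @param samples character vector of unique sample ids naming the columns.
#'
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(sites, geno_a, geno_b, samples) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  if (nrow(sites) > 0) {
    stopifnot(all(sites$pos >= 1), all(nzchar(sites$ref)))
  }
  if (anyDuplicated(samples)) stop("sample ids must be unique")
  geno_a <- as.matrix(geno_a); geno_b <- as.matrix(geno_b)
  storage.mode(geno_a) <- "integer"; storage.mode(geno_b) <- "integer"
  if (!all(dim(geno_a) == c(nrow(sites), length(samples))) ||
      !all(dim(geno_b) == c(nrow(sites), length(samples))))
    stop("genotype matrix dimensions must be n_sites x n_samples")
  # allele index must stay inside the site's allele set
  if (nrow(sites) > 0) {
    n_alleles <- 1L + ifelse(nzchar(sites$alt) & sites$alt != ".",
                             lengths(strsplit(sites$alt, ",", fixed = TRUE)), 0L)
    mx <- pmax(suppressWarnings(apply(geno_a, 1, max, na.rm = TRUE)),
               suppressWarnings(apply(geno_b, 1, max, na.rm = TRUE)))
    mx[!is.finite(mx)] <- 0
    if (any(mx > n_alleles - 1L))
      stop("genotype allele index exceeds 1 + number of ALT alleles")
  }
  colnames(geno_a) <- colnames(geno_b) <- samples
  rownames(sites) <- NULL
  structure(list(sites = sites, geno_a = geno_a, geno_b = geno_b,
                 samples = as.character(samples)),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d sites x %d samples\n",
              nrow(x$sites), length(x$samples)))
  ann <- setdiff(names(x$sites), c("chrom", "pos", "id", "ref", "alt", "qual"))
  if (length(ann)) cat("annotations:", paste(ann, collapse = ", "), "\n")
  invisible(x)
}

#' Number of variant sites
#' @param vt a `variant_table`
#' @export
n_sites <- function(vt) nrow(vt$sites)

#' Number of samples
#' @param vt a `variant_table`
#' @export
n_samples <- function(vt) length(vt$samples)

#' Subset a variant table by site index and/or sample id
#'
#' @param vt a `variant_table`
#' @param sites logical or integer index over rows
#' @param samples character vector of sample ids (or integer index)
#' @return a `variant_table`
#' @export
vt_subset <- function(vt, sites = NULL, samples = NULL) {
  if (!is.null(sites)) {
    vt$sites <- vt$sites[sites, , drop = FALSE]
    rownames(vt$sites) <- NULL
    vt$geno_a <- vt$geno_a[sites, , drop = FALSE]
    vt$geno_b <- vt$geno_b[sites, , drop = FALSE]
  }
  if (!is.null(samples)) {
    if (is.character(samples)) {
      idx <- match(samples, vt$samples)
      if (anyNA(idx)) stop("unknown sample id: ",
                           paste(samples[is.na(idx)], collapse = ", "))
    } else idx <- samples
    vt$geno_a <- vt$geno_a[, idx, drop = FALSE]
    vt$geno_b <- vt$geno_b[, idx, drop = FALSE]
    vt$samples <- vt$samples[idx]
  }
  vt
}

#' Genotype dosage matrix
#'
#' Counts of the first alternate allele per sample (0/1/2 for a biallelic
#' site); `NA` where the genotype is missing. This is the representation the
#' LD, kinship and F_ST machinery works on.
#'
#' @param vt a `variant_table`
#' @return integer matrix, sites x samples
#' @export
vt_dosage <- function(vt) {
  d <- (vt$geno_a == 1L) + (vt$geno_b == 1L)
  storage.mode(d) <- "integer"
  dimnames(d) <- list(NULL, vt$samples)
  d
}

#' Keep only biallelic SNP sites
#'
#' Restricts to sites with exactly one ALT allele where both REF and ALT are
#' single nucleotides.
#'
#' @param vt a `variant_table`
#' @return a `variant_table` of biallelic SNPs only
#' @export
vt_biallelic_snps <- function(vt) {
  one_alt <- !grepl(",", vt$sites$alt, fixed = TRUE) &
    nzchar(vt$sites$alt) & vt$sites$alt != "."
  snp <- nchar(vt$sites$ref) == 1L & nchar(vt$sites$alt) == 1L
  vt_subset(vt, sites = one_alt & snp)
}

#' Per-site called allele counts and alternate-allele frequency
#'
#' @param vt a `variant_table` (biallelic sites assumed for `p_alt`)
#' @return data.frame with `n_called` (called allele count, i.e. twice the
#'   called genotypes) and `p_alt` (frequency of ALT allele 1 among called
#'   alleles; `NA` when nothing is called)
#' @export
vt_allele_freq <- function(vt) {
  called <- !is.na(vt$geno_a) & !is.na(vt$geno_b)
  n_called <- 2L * rowSums(called)
  n_alt <- rowSums((vt$geno_a == 1L) * called, na.rm = TRUE) +
    rowSums((vt$geno_b == 1L) * called, na.rm = TRUE)
  data.frame(n_called = n_called,
             p_alt = ifelse(n_called > 0, n_alt / n_called, NA_real_))
}

#' Read a sample sheet
#'
#' Tab-separated file with header columns `sample_id`, `population_label`,
#' `cultivar_group` and `geography`. Cultivar groups follow the maturation
#' nomenclature (EEMC, EMC, LMC, wild).
#'
#' @param path path to a TSV file
#' @return data.frame, one row per sample
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, quote = "")
  need <- c("sample_id", "population_label", "cultivar_group", "geography")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stop("sample sheet lacks columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id)) stop("duplicate sample ids in sheet")
  if (any(!nzchar(sheet$population_label)))
    stop("empty population labels in sheet")
  sheet
}

#' Check that every variant-table sample resolves in a sample sheet
#' @param vt a `variant_table`
#' @param sheet data.frame from [read_sample_sheet()]
#' @return invisibly TRUE; errors listing unresolved samples otherwise
#' @export
validate_samples <- function(vt, sheet) {
  miss <- setdiff(vt$samples, sheet$sample_id)
  if (length(miss)) stop("samples absent from sheet: ",
                         paste(miss, collapse = ", "))
  invisible(TRUE)
}
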