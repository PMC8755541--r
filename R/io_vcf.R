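#' Read a VCF file into a variant table
#'
#' Parsing is delegated to \pkg{vcfR}; genotypes are decoded into the two
#' allele-index matrices of a [variant_table()] and the standard hard-filter
#' site annotations (QD, FS, MQ, SOR, DP, MQRankSum, ReadPosRankSum) are
#' pulled from INFO where the header declares them. Coordinates stay 1-based
#' as on disk; interval arithmetic elsewhere in the package is 0-based
#' half-open, converted only at the I/O boundary.
#'
#' @param path path to a VCF 4.x file (plain text or gzipped)
#' @param biallelic_only drop sites with more than one ALT allele (the usual
#'   first step before population analysis); the number removed is logged
#' @return a `variant_table`
#' @export
read_vcf <- function(path, biallelic_only = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "##fileformat=VCF"))
    stop("malformed VCF header at line 1: expected '##fileformat=VCF...', got '",
         substr(first, 1, 40), "'")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(vcf@fix)
  samples <- colnames(vcf@gt)[-1]
  if (is.null(samples)) samples <- character(0)

  sites <- data.frame(chrom = as.character(vcf@fix[, "CHROM"]),
                      pos = as.integer(vcf@fix[, "POS"]),
                      ref = as.character(vcf@fix[, "REF"]),
                      alt = as.character(vcf@fix[, "ALT"]),
                      stringsAsFactors = FALSE)
  sites$alt[is.na(sites$alt)] <- "."

  std_ann <- c("QD", "FS", "MQ", "SOR", "DP", "MQRankSum", "ReadPosRankSum")
  declared <- vapply(std_ann, function(a)
    any(grepl(sprintf("##INFO=<ID=%s,", a), vcf@meta, fixed = TRUE)), logical(1))
  for (a in std_ann[declared])
    sites[[a]] <- suppressWarnings(
      as.numeric(vcfR::extract.info(vcf, element = a)))

  if (length(samples)) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    if (is.null(dim(gt))) gt <- matrix(gt, nrow = n,
                                       dimnames = list(NULL, samples))
    split_gt <- function(which_allele) {
      al <- sub("^([0-9.]+)[/|]([0-9.]+)$",
                if (which_allele == 1) "\\1" else "\\2", gt)
      al[al == "." | is.na(gt) | !grepl("[/|]", gt)] <- NA
      matrix(suppressWarnings(as.integer(al)), nrow = n,
             ncol = length(samples), dimnames = list(NULL, samples))
    }
    geno_a <- split_gt(1); geno_b <- split_gt(2)
  } else {
    geno_a <- geno_b <- matrix(integer(0), nrow = n, ncol = 0)
  }

  vt <- variant_table(sites, geno_a, geno_b, samples)
  ord <- order(vt$sites$chrom, vt$sites$pos)
  vt <- vt_subset(vt, sites = ord)

  if (biallelic_only) {
    multi <- grepl(",", vt$sites$alt, fixed = TRUE)
    if (any(multi))
      hp_log("INFO", sprintf("dropped %d multiallelic site(s)", sum(multi)))
    vt <- vt_subset(vt, sites = !multi)
  }
  vt
}

#' Write a variant table as VCF 4.2
#'
#' Emits the supported subset: CHROM/POS/ID/REF/ALT/QUAL/FILTER, the numeric
#' site annotations carried in the table as INFO fields, and GT genotypes.
#' Reading the file back reproduces chrom/pos/alleles/genotypes exactly.
#'
#' @param vt a `variant_table`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_vcf <- function(vt, path) {
  ann_cols <- setdiff(names(vt$sites), c("chrom", "pos", "id", "ref", "alt"))
  ann_cols <- ann_cols[vapply(vt$sites[ann_cols], is.numeric, logical(1))]
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
                   ann_cols, ann_cols),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", vt$samples), collapse = "\t"))
  n <- n_sites(vt)
  body <- character(0)
  if (n > 0) {
    info <- if (length(ann_cols)) {
      parts <- lapply(ann_cols, function(a) {
        v <- vt$sites[[a]]
        ifelse(is.na(v), NA_character_, paste0(a, "=", format(v, trim = TRUE,
                                                              digits = 10)))
      })
      apply(do.call(cbind, parts), 1, function(r) {
        r <- r[!is.na(r)]
        if (length(r)) paste(r, collapse = ";") else "."
      })
    } else rep(".", n)
    gt <- matrix(".", nrow = n, ncol = length(vt$samples))
    ok <- !is.na(vt$geno_a) & !is.na(vt$geno_b)
    gt[ok] <- paste0(vt$geno_a[ok], "/", vt$geno_b[ok])
    gt[!ok] <- "./."
    gt_field <- if (length(vt$samples))
      apply(gt, 1, paste, collapse = "\t") else NULL
    body <- paste(vt$sites$chrom, vt$sites$pos, ".", vt$sites$ref,
                  vt$sites$alt, ".", ".", info, "GT", sep = "\t")
    if (!is.null(gt_field)) body <- paste(body, gt_field, sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Hard-filter rule
#'
#' An ordered set of predicates over site annotations; a site fails the rule
#' if ANY predicate is true (the GATK VariantFiltration `||` semantics).
#'
#' @param annotation character vector of annotation names
#' @param comparator character vector over `<` and `>`
#' @param threshold numeric thresholds
#' @return data.frame of class `filter_rule`
#' @export
filter_rule <- function(annotation, comparator, threshold) {
  stopifnot(all(comparator %in% c("<", ">")),
            length(annotation) == length(comparator),
            length(annotation) == length(threshold))
  structure(data.frame(annotation = annotation, comparator = comparator,
                       threshold = threshold, stringsAsFactors = FALSE),
            class = c("filter_rule", "data.frame"))
}

#' Built-in hard-filter presets
#'
#' `"population"` is the joint-calling filter used on a resequencing panel
#' (`DP < 300 || DP > 3000 || QD < 2.0 || FS > 60.0 || MQ < 40.0 ||
#' MQRankSum < -12.5 || ReadPosRankSum < -8.0`); `"phasing"` is the
#' single-accession filter applied before haplotype phasing
#' (`QD < 2.0 || MQ < 26.0 || FS > 100.0 || SOR > 5.0 || MQRankSum < -7.5 ||
#' ReadPosRankSum < -8.0`).
#'
#' @param name `"population"` or `"phasing"`
#' @return a [filter_rule()]
#' @export
filter_preset <- function(name = c("population", "phasing")) {
  name <- match.arg(name)
  if (name == "population")
    filter_rule(c("DP", "DP", "QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum"),
                c("<", ">", "<", ">", "<", "<", "<"),
                c(300, 3000, 2.0, 60.0, 40.0, -12.5, -8.0))
  else
    filter_rule(c("QD", "MQ", "FS", "SOR", "MQRankSum", "ReadPosRankSum"),
                c("<", "<", ">", ">", "<", "<"),
                c(2.0, 26.0, 100.0, 5.0, -7.5, -8.0))
}

#' Apply a hard-filter rule to a variant table
#'
#' A site is removed if any predicate fires. Sites lacking an annotation named
#' in the rule are retained with a warning in lenient mode (the default,
#' mirroring common hard-filter behavior) and removed in strict mode; a rule
#' naming an annotation entirely absent from the table is a configuration
#' error in strict mode.
#'
#' @param vt a `variant_table`
#' @param rule a [filter_rule()]
#' @param strict reject sites with missing annotations instead of keeping them
#' @return list with `vt` (surviving sites), `fail_counts` (per-predicate fail
#'   counts; a site can fail several, so their sum can exceed `n_removed`) and
#'   `n_removed`
#' @export
apply_hard_filter <- function(vt, rule, strict = FALSE) {
  stopifnot(inherits(rule, "filter_rule"))
  n <- n_sites(vt)
  fails <- matrix(FALSE, nrow = n, ncol = nrow(rule))
  labels <- paste0(rule$annotation, rule$comparator, rule$threshold)
  warned <- character(0)
  for (k in seq_len(nrow(rule))) {
    a <- rule$annotation[k]
    if (!a %in% names(vt$sites)) {
      if (strict) stop("filter rule references unknown annotation: ", a)
      if (!a %in% warned) {
        hp_log("WARN", sprintf("annotation %s absent; predicate skipped", a))
        warned <- c(warned, a)
      }
      next
    }
    v <- vt$sites[[a]]
    f <- if (rule$comparator[k] == "<") v < rule$threshold[k]
         else v > rule$threshold[k]
    f[is.na(f)] <- strict   # per-site missing annotation
    fails[, k] <- f
  }
  any_fail <- rowSums(fails) > 0
  list(vt = vt_subset(vt, sites = !any_fail),
       fail_counts = stats::setNames(colSums(fails), labels),
       n_removed = sum(any_fail))
}

#' Remove sites with too much missing data
#'
#' Keeps sites where the fraction of samples with a called genotype strictly
#' exceeds `min_called_fraction` (the "over 80% of the individuals"
#' convention: 8 of 10 called does NOT survive a 0.8 threshold).
#'
#' @param vt a `variant_table`
#' @param min_called_fraction real in \[0, 1\]
#' @return a `variant_table`
#' @export
missingness_filter <- function(vt, min_called_fraction = 0.8) {
  stopifnot(min_called_fraction >= 0, min_called_fraction <= 1)
  if (n_samples(vt) == 0) return(vt)
  called <- rowMeans(!is.na(vt$geno_a) & !is.na(vt$geno_b))
  vt_subset(vt, sites = called > min_called_fraction)
}

#' Timestamped logging to standard error
#' @param level tag such as "INFO" or "WARN"
#' @param msg message text
#' @keywords internal
hp_log <- function(level, msg) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  level, msg))
}
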