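#' Read a genome FASTA
#'
#' @param path FASTA file
#' @return a `Biostrings::DNAStringSet`, names truncated to the first token
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write a genome FASTA
#' @param genome a `DNAStringSet`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 80L)
  invisible(path)
}

#' Gene models from a GFF3 file
#'
#' Builds the single-transcript gene models the impact classifier works on:
#' per gene an ordered set of exon and CDS intervals (1-based, closed, the
#' Bioconductor convention) plus strand and TSS. Parsing is delegated to
#' \pkg{rtracklayer}.
#'
#' @param path GFF3 file with gene/mRNA/exon/CDS features
#' @return a `gene_model_set`: named list of models, each a list with
#'   `gene_id`, `chrom`, `strand`, `exons` and `cds` (2-column start/end
#'   matrices sorted by start) and `tss`
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  # resolve each feature to its gene: via Parent chain (CDS -> mRNA -> gene)
  id2gene <- stats::setNames(as.character(df$ID[df$type == "gene"]),
                             as.character(df$ID[df$type == "gene"]))
  mrna <- df$type == "mRNA"
  if (any(mrna)) {
    par <- vapply(df$Parent[mrna], function(p) as.character(p)[1], character(1))
    id2gene[as.character(df$ID[mrna])] <- id2gene[par]
  }
  feat_gene <- function(rows) {
    par <- vapply(df$Parent[rows], function(p) as.character(p)[1], character(1))
    unname(id2gene[par])
  }
  models <- list()
  genes <- which(df$type == "gene")
  for (i in genes) {
    gid <- as.character(df$ID[i])
    models[[gid]] <- list(gene_id = gid, chrom = as.character(df$seqnames[i]),
                          strand = as.character(df$strand[i]),
                          exons = NULL, cds = NULL,
                          tss = if (df$strand[i] == "-") df$end[i] else df$start[i])
  }
  for (type in c("exon", "CDS")) {
    rows <- which(df$type == type)
    if (!length(rows)) next
    gids <- feat_gene(rows)
    for (k in seq_along(rows)) {
      r <- rows[k]; gid <- gids[k]
      if (is.na(gid) || is.null(models[[gid]])) next
      slot <- if (type == "exon") "exons" else "cds"
      models[[gid]][[slot]] <- rbind(models[[gid]][[slot]],
                                     c(df$start[r], df$end[r]))
    }
  }
  for (gid in names(models)) {
    for (slot in c("exons", "cds")) {
      m <- models[[gid]][[slot]]
      if (is.null(m)) m <- matrix(numeric(0), ncol = 2)
      m <- m[order(m[, 1]), , drop = FALSE]
      colnames(m) <- c("start", "end")
      models[[gid]][[slot]] <- m
    }
    if (nrow(models[[gid]]$exons) == 0)
      models[[gid]]$exons <- models[[gid]]$cds
  }
  structure(models, class = "gene_model_set")
}

#' Write gene models as GFF3
#' @param models a `gene_model_set`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_gene_models <- function(models, path) {
  lines <- "##gff-version 3"
  for (m in models) {
    span <- range(c(m$exons, m$cds))
    lines <- c(lines,
      sprintf("%s\thaplopop\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              m$chrom, span[1], span[2], m$strand, m$gene_id),
      sprintf("%s\thaplopop\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              m$chrom, span[1], span[2], m$strand, m$gene_id, m$gene_id))
    for (k in seq_len(nrow(m$exons)))
      lines <- c(lines, sprintf("%s\thaplopop\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s.t1",
                                m$chrom, m$exons[k, 1], m$exons[k, 2], m$strand,
                                m$gene_id, k, m$gene_id))
    phase <- 0L
    for (k in seq_len(nrow(m$cds))) {
      idx <- if (m$strand == "-") nrow(m$cds) - k + 1L else k
      lines <- c(lines, sprintf("%s\thaplopop\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.c%d;Parent=%s.t1",
                                m$chrom, m$cds[idx, 1], m$cds[idx, 2], m$strand,
                                phase, m$gene_id, k, m$gene_id))
      phase <- (3L - (sum(m$cds[, 2] - m$cds[, 1] + 1)[1] %% 3L)) %% 3L
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Spliced CDS sequence of a gene model
#'
#' Concatenates the CDS intervals in genomic order and reverse-complements
#' for minus-strand genes, so the result always starts at the start codon.
#'
#' @param model one element of a `gene_model_set`
#' @param genome a `DNAStringSet` containing the model's chromosome
#' @return a character scalar (the CDS, 5' to 3')
#' @export
cds_sequence <- function(model, genome) {
  if (!model$chrom %in% names(genome))
    stop("chromosome absent from genome: ", model$chrom)
  chrseq <- genome[[model$chrom]]
  pieces <- apply(model$cds, 1, function(iv)
    as.character(Biostrings::subseq(chrseq, iv[1], iv[2])))
  s <- paste(pieces, collapse = "")
  if (model$strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

#' High-quality gene-model filter
#'
#' Keeps models whose CDS (the coding exon sum) begins with ATG — a
#' methionine as the first amino acid, checked strand-aware against the
#' model's own haplotype sequence — and whose total CDS length is divisible
#' by three. These are the models admitted to the pi_n pipeline.
#'
#' @param models a `gene_model_set`
#' @param genome a `DNAStringSet`
#' @return list with `kept` (a `gene_model_set`) and `rejected`
#'   (data.frame gene_id/reason; a model failing both checks lists both)
#' @export
filter_high_quality_models <- function(models, genome) {
  missing_chrom <- unique(vapply(models, function(m) m$chrom, character(1)))
  missing_chrom <- setdiff(missing_chrom, names(genome))
  if (length(missing_chrom))
    stop("model chromosomes absent from genome: ",
         paste(missing_chrom, collapse = ", "))
  kept <- list(); rej_id <- character(0); rej_reason <- character(0)
  for (m in models) {
    cds <- cds_sequence(m, genome)
    reasons <- character(0)
    if (substr(cds, 1, 3) != "ATG") reasons <- c(reasons, "non-ATG start")
    if (nchar(cds) %% 3 != 0)
      reasons <- c(reasons, "length not divisible by three")
    if (length(reasons)) {
      rej_id <- c(rej_id, m$gene_id)
      rej_reason <- c(rej_reason, paste(reasons, collapse = "; "))
    } else kept[[m$gene_id]] <- m
  }
  list(kept = structure(kept, class = "gene_model_set"),
       rejected = data.frame(gene_id = rej_id, reason = rej_reason,
                             stringsAsFactors = FALSE))
}

severity_order <- c(MODIFIER = 0, LOW = 1, MODERATE = 2, HIGH = 3)

#' Classify variant effects against gene models
#'
#' A minimal effect classifier restricted to the classes downstream analyses
#' consume. Coding SNPs are classified by translating the affected codon
#' under the standard genetic code, strand-aware: stop gained/lost is HIGH,
#' a missense change MODERATE, a synonymous change LOW. CDS indels are
#' MODERATE when in frame (length divisible by three) and HIGH otherwise;
#' an indel truncating an exon boundary is HIGH. Everything outside CDS
#' (introns, UTRs, intergenic) is MODIFIER. A variant overlapping several
#' genes is classified against each; the most severe call is reported and
#' all calls are kept in the `details` attribute.
#'
#' @param variants a `variant_table` (first ALT allele used) or a data.frame
#'   with columns chrom/pos/ref/alt
#' @param models a `gene_model_set`
#' @param genome a `DNAStringSet`
#' @return data.frame with one row per variant: chrom, pos, ref, alt,
#'   gene_id (NA outside genes), impact, consequence, ref_codon, alt_codon;
#'   attribute `details` holds every per-gene call
#' @export
classify_variant_effects <- function(variants, models, genome) {
  if (inherits(variants, "variant_table")) {
    v <- variants$sites[, c("chrom", "pos", "ref", "alt")]
    v$alt <- sub(",.*$", "", v$alt)
  } else v <- variants[, c("chrom", "pos", "ref", "alt")]
  nv <- nrow(v)
  if (nv == 0) {
    out <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      gene_id = character(0), impact = character(0),
                      consequence = character(0), ref_codon = character(0),
                      alt_codon = character(0), stringsAsFactors = FALSE)
    attr(out, "details") <- out
    return(out)
  }

  spans <- t(vapply(models, function(m) range(c(m$exons, m$cds)), numeric(2)))
  gchrom <- vapply(models, function(m) m$chrom, character(1))
  gr_genes <- GenomicRanges::GRanges(gchrom,
                IRanges::IRanges(spans[, 1], spans[, 2]))
  var_end <- v$pos + nchar(v$ref) - 1L
  gr_var <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$pos, var_end))
  hits <- GenomicRanges::findOverlaps(gr_var, gr_genes)

  cds_cache <- new.env(parent = emptyenv())
  get_cds <- function(gid) {
    if (is.null(cds_cache[[gid]]))
      cds_cache[[gid]] <- cds_sequence(models[[gid]], genome)
    cds_cache[[gid]]
  }
  code <- Biostrings::GENETIC_CODE
  comp <- c(A = "T", C = "G", G = "C", T = "A")

  det <- vector("list", nv)
  classify_one <- function(i, gid) {
    m <- models[[gid]]
    ref <- v$ref[i]; alt <- v$alt[i]; pos <- v$pos[i]
    is_snp <- nchar(ref) == 1L && nchar(alt) == 1L
    in_cds_iv <- which(pos >= m$cds[, 1] & pos <= m$cds[, 2])
    if (is_snp) {
      if (!length(in_cds_iv))
        return(list(impact = "MODIFIER", consequence = "noncoding",
                    ref_codon = NA_character_, alt_codon = NA_character_))
      iv <- in_cds_iv[1]
      offset <- if (iv > 1) sum(m$cds[seq_len(iv - 1), 2] -
                                m$cds[seq_len(iv - 1), 1] + 1) else 0
      local_plus <- offset + (pos - m$cds[iv, 1] + 1)
      total <- sum(m$cds[, 2] - m$cds[, 1] + 1)
      local <- if (m$strand == "-") total - local_plus + 1 else local_plus
      codon_idx <- (local - 1) %/% 3
      pos_in_codon <- (local - 1) %% 3 + 1
      cds <- get_cds(gid)
      ref_codon <- substr(cds, codon_idx * 3 + 1, codon_idx * 3 + 3)
      alt_base <- if (m$strand == "-") comp[[alt]] else alt
      alt_codon <- ref_codon
      substr(alt_codon, pos_in_codon, pos_in_codon) <- alt_base
      ref_aa <- code[[ref_codon]]; alt_aa <- code[[alt_codon]]
      if (ref_aa != "*" && alt_aa == "*")
        res <- list("HIGH", "stop_gained")
      else if (ref_aa == "*" && alt_aa != "*")
        res <- list("HIGH", "stop_lost")
      else if (ref_aa != alt_aa)
        res <- list("MODERATE", "missense")
      else res <- list("LOW", "synonymous")
      return(list(impact = res[[1]], consequence = res[[2]],
                  ref_codon = ref_codon, alt_codon = alt_codon))
    }
    # indel
    iv_end <- pos + nchar(ref) - 1L
    overlaps_cds <- any(pos <= m$cds[, 2] & iv_end >= m$cds[, 1])
    if (!overlaps_cds)
      return(list(impact = "MODIFIER", consequence = "noncoding",
                  ref_codon = NA_character_, alt_codon = NA_character_))
    fully_inside <- any(pos >= m$cds[, 1] & iv_end <= m$cds[, 2])
    if (!fully_inside)   # truncates an exon boundary
      return(list(impact = "HIGH", consequence = "splice_truncation",
                  ref_codon = NA_character_, alt_codon = NA_character_))
    shift <- abs(nchar(ref) - nchar(alt)) %% 3
    if (shift == 0)
      list(impact = "MODERATE", consequence = "inframe_indel",
           ref_codon = NA_character_, alt_codon = NA_character_)
    else
      list(impact = "HIGH", consequence = "frameshift",
           ref_codon = NA_character_, alt_codon = NA_character_)
  }

  out <- data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
                    gene_id = NA_character_, impact = "MODIFIER",
                    consequence = "intergenic", ref_codon = NA_character_,
                    alt_codon = NA_character_, stringsAsFactors = FALSE)
  details <- list()
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    gids <- names(models)
    for (k in seq_along(qh)) {
      i <- qh[k]; gid <- gids[sh[k]]
      call <- classify_one(i, gid)
      details[[length(details) + 1L]] <-
        data.frame(chrom = v$chrom[i], pos = v$pos[i], ref = v$ref[i],
                   alt = v$alt[i], gene_id = gid, impact = call$impact,
                   consequence = call$consequence, ref_codon = call$ref_codon,
                   alt_codon = call$alt_codon, stringsAsFactors = FALSE)
      if (severity_order[call$impact] >= severity_order[out$impact[i]] &&
          (severity_order[call$impact] > severity_order[out$impact[i]] ||
           is.na(out$gene_id[i]))) {
        out$gene_id[i] <- gid; out$impact[i] <- call$impact
        out$consequence[i] <- call$consequence
        out$ref_codon[i] <- call$ref_codon; out$alt_codon[i] <- call$alt_codon
      }
    }
  }
  attr(out, "details") <- if (length(details)) do.call(rbind, details)
                          else out[0, ]
  out
}

#' Percentage at one-decimal rounding
#'
#' The reporting convention of the divergence summaries: `round(100 n/d, 1)`,
#' `NA` (undefined, not 0) on a zero denominator.
#'
#' @param num numerator count
#' @param den denominator count
#' @return numeric percentage, or NA if `den == 0`
#' @export
ratio_percent <- function(num, den) {
  ifelse(den == 0, NA_real_, round(100 * num / den, 1))
}

#' Haplotype divergence summary
#'
#' Gene-level roll-up of an impact table computed against one haplotype's
#' annotation: how many genes carry any variant, how many carry an
#' amino-acid change (HIGH or MODERATE), how many nonsynonymous SNPs there
#' are in total, and how many genes are hit by nonsense variants. By default
#' "nonsense" counts stop-gains and frameshifts; set
#' `nonsense_includes_frameshift = FALSE` to restrict to stop-gains.
#'
#' @param impact_calls data.frame from [classify_variant_effects()]
#' @param models a `gene_model_set` (the denominator of all gene fractions)
#' @param nonsense_includes_frameshift logical
#' @return list of counts plus one-decimal percentages (NA when undefined)
#' @export
summarize_haplotype_divergence <- function(impact_calls, models,
                                           nonsense_includes_frameshift = TRUE) {
  det <- attr(impact_calls, "details")
  if (is.null(det)) det <- impact_calls
  is_snp <- nchar(det$ref) == 1L & nchar(det$alt) == 1L
  nonsense_cons <- if (nonsense_includes_frameshift)
    c("stop_gained", "frameshift") else "stop_gained"
  n_total <- length(models)
  genes_var <- unique(det$gene_id[!is.na(det$gene_id)])
  genes_aa <- unique(det$gene_id[det$impact %in% c("HIGH", "MODERATE")])
  n_nonsyn_snp <- sum(is_snp & det$consequence %in%
                        c("missense", "stop_gained", "stop_lost"))
  nonsense <- det$consequence %in% nonsense_cons
  genes_nonsense <- unique(det$gene_id[nonsense])
  res <- list(n_genes_total = n_total,
              n_genes_with_variant = length(genes_var),
              n_genes_with_aa_change = length(genes_aa),
              n_nonsyn_snps_total = n_nonsyn_snp,
              n_nonsense_snps = sum(nonsense & is_snp),
              n_genes_with_nonsense = length(genes_nonsense))
  res$pct_genes_with_variant <- ratio_percent(res$n_genes_with_variant, n_total)
  res$pct_genes_with_aa_change <- ratio_percent(res$n_genes_with_aa_change,
                                                res$n_genes_with_variant)
  res$n_nonsense_variants <- sum(nonsense)
  res$pct_nonsense_of_nonsyn <- ratio_percent(res$n_nonsense_variants,
                                              res$n_nonsyn_snps_total)
  res$pct_genes_with_nonsense <- ratio_percent(res$n_genes_with_nonsense,
                                               n_total)
  res
}

#' Per-individual counts of variant carriers by impact class
#'
#' A genotype contributes to a sample's count for class `c` iff the sample
#' carries at least one alternate allele at a site of class `c`. When a
#' grouping is supplied the group means are compared with one-way ANOVA and
#' Tukey HSD post hoc contrasts per class.
#'
#' @param vt a `variant_table`
#' @param impact_calls data.frame from [classify_variant_effects()] with one
#'   row per site of `vt`, in the same order
#' @param groups optional factor/character of length `n_samples(vt)`
#' @return list with `counts` (samples x impact classes),
#'   and when groups are given `anova` (per-class p-values) and `tukey`
#'   (per-class TukeyHSD tables)
#' @export
count_impact_per_individual <- function(vt, impact_calls, groups = NULL) {
  stopifnot(nrow(impact_calls) == n_sites(vt))
  carrier <- (vt$geno_a >= 1L) | (vt$geno_b >= 1L)
  carrier[is.na(carrier)] <- FALSE
  classes <- names(severity_order)
  counts <- sapply(classes, function(cl)
    colSums(carrier[impact_calls$impact == cl, , drop = FALSE]))
  if (is.null(dim(counts)))
    counts <- matrix(counts, nrow = n_samples(vt),
                     dimnames = list(vt$samples, classes))
  rownames(counts) <- vt$samples
  out <- list(counts = counts)
  if (!is.null(groups)) {
    groups <- factor(groups)
    pv <- numeric(0); tk <- list()
    for (cl in classes) {
      y <- counts[, cl]
      if (stats::var(y) == 0 || nlevels(groups) < 2) {
        pv[cl] <- NA_real_; next
      }
      fit <- stats::aov(y ~ groups)
      pv[cl] <- summary(fit)[[1]][["Pr(>F)"]][1]
      tk[[cl]] <- stats::TukeyHSD(fit)$groups
    }
    out$anova <- pv
    out$tukey <- tk
  }
  out
}
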