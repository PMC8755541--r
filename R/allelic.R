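#' Classify accessions by haplotype-of-origin mapping fraction
#'
#' Accessions whose reads align predominantly to one haplotype assembly are
#' called for that haplotype; intermediate fractions mark admixed (hybrid)
#' accessions. Default thresholds (0.64 / 0.36) sit between the observed
#' group ranges: pure-group accessions map 64-83% to their own haplotype
#' while admixed ones sit near one half.
#'
#' @param n_reads_hy,n_reads_hh read counts aligned to each haplotype
#' @param hi f_HY at or above this is HY-dominant
#' @param lo f_HY at or below this is HH-dominant
#' @return data.frame: f_hy and class in
#'   \{HY-dominant, HH-dominant, admixed\}
#' @export
classify_mapping_fraction <- function(n_reads_hy, n_reads_hh,
                                      hi = 0.64, lo = 0.36) {
  f <- n_reads_hy / (n_reads_hy + n_reads_hh)
  cls <- ifelse(f >= hi, "HY-dominant",
         ifelse(f <= lo, "HH-dominant", "admixed"))
  data.frame(f_hy = f, class = cls, stringsAsFactors = FALSE)
}

#' Call differentially expressed alleles (DEA) in one library
#'
#' Per gene with total allelic coverage of at least `min_depth`, an exact
#' two-sided binomial test of the null that both alleles are expressed
#' equally (theta = 0.5); Benjamini-Hochberg correction within the library;
#' DEA iff q < alpha.
#'
#' @param counts list with matrices `a` and `b` (genes x libraries) or two
#'   numeric vectors via `a`/`b` columns of one library
#' @param library library name or index; NULL with vector input
#' @param alpha FDR level
#' @param min_depth minimum a + b to test a gene
#' @return data.frame: gene, count_a, count_b, tested, p, q, dea, direction
#' @export
call_dea <- function(counts, library = NULL, alpha = 0.05, min_depth = 10L) {
  if (is.list(counts) && !is.null(counts$a) && is.matrix(counts$a)) {
    stopifnot(!is.null(library))
    a <- counts$a[, library]; b <- counts$b[, library]
    genes <- rownames(counts$a)
  } else {
    a <- counts[[1]]; b <- counts[[2]]
    genes <- names(a)
  }
  if (is.null(genes)) genes <- as.character(seq_along(a))
  n <- a + b
  tested <- n >= min_depth
  p <- rep(NA_real_, length(a))
  p[tested] <- vapply(which(tested), function(i)
    stats::binom.test(a[i], n[i], p = 0.5)$p.value, numeric(1))
  q <- rep(NA_real_, length(a))
  q[tested] <- stats::p.adjust(p[tested], method = "BH")
  data.frame(gene = genes, count_a = a, count_b = b, tested = tested,
             p = p, q = q,
             dea = tested & !is.na(q) & q < alpha,
             direction = ifelse(a > b, "A", ifelse(b > a, "B", "=")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' DEA calls for every library of a count matrix
#'
#' @inheritParams call_dea
#' @return named list of per-library data.frames from [call_dea()]
#' @export
call_dea_all <- function(counts, alpha = 0.05, min_depth = 10L) {
  libs <- colnames(counts$a)
  if (is.null(libs)) libs <- seq_len(ncol(counts$a))
  stats::setNames(lapply(libs, function(l)
    call_dea(counts, library = l, alpha = alpha, min_depth = min_depth)),
    libs)
}

#' Union of DEA gene sets
#' @param call_sets list of [call_dea()] data.frames (or character vectors)
#' @return character vector of genes DEA in at least one library
#' @export
dea_union <- function(call_sets) {
  sets <- lapply(call_sets, function(cs)
    if (is.data.frame(cs)) cs$gene[cs$dea] else cs)
  sort(unique(unlist(sets)))
}

#' DEA saturation curve
#'
#' For each k, random k-subsets of libraries are drawn and the mean size of
#' the union of their DEA sets is reported — the saturation behavior of DEA
#' discovery with sample count. When all C(n, k) subsets number at most
#' `reps` the enumeration is exhaustive (zero Monte-Carlo error).
#'
#' @param call_sets list of per-library DEA gene sets (character vectors or
#'   [call_dea()] data.frames)
#' @param k_values subset sizes to evaluate
#' @param reps replicates per k
#' @param seed integer seed
#' @return data.frame: k, mean_union, sd_union, n_reps, exhaustive
#' @export
saturation_curve <- function(call_sets, k_values, reps = 500L, seed) {
  sets <- lapply(call_sets, function(cs)
    if (is.data.frame(cs)) cs$gene[cs$dea] else cs)
  nlib <- length(sets)
  stopifnot(all(k_values >= 0), all(k_values <= nlib))
  with_seed(seed, {
    rows <- lapply(k_values, function(k) {
      if (k == 0)
        return(data.frame(k = 0L, mean_union = 0, sd_union = 0,
                          n_reps = 1L, exhaustive = TRUE))
      n_comb <- choose(nlib, k)
      if (n_comb <= reps) {
        sizes <- utils::combn(nlib, k, function(idx)
          length(unique(unlist(sets[idx]))))
        data.frame(k = k, mean_union = mean(sizes),
                   sd_union = if (length(sizes) > 1) stats::sd(sizes) else 0,
                   n_reps = as.integer(n_comb), exhaustive = TRUE)
      } else {
        sizes <- vapply(seq_len(reps), function(r)
          length(unique(unlist(sets[sample.int(nlib, k)]))), numeric(1))
        data.frame(k = k, mean_union = mean(sizes),
                   sd_union = stats::sd(sizes), n_reps = as.integer(reps),
                   exhaustive = FALSE)
      }
    })
    do.call(rbind, rows)
  })
}

# ---- Nei-Gojobori (1986) Ka/Ks -------------------------------------------

.ng86_env <- new.env(parent = emptyenv())

.codon_split <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1, n, 3), seq(3, n, 3))
}

.is_stop <- function(codon) Biostrings::GENETIC_CODE[[codon]] == "*"

# potential synonymous sites of one codon: per position, the fraction of the
# three possible changes that are synonymous; changes to stop codons count
# as nonsynonymous
.ng86_sites <- function(codon) {
  key <- paste0("S_", codon)
  if (!is.null(.ng86_env[[key]])) return(.ng86_env[[key]])
  code <- Biostrings::GENETIC_CODE
  aa <- code[[codon]]
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(bases, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (code[[mut]] == aa && code[[mut]] != "*") s <- s + 1 / 3
    }
  }
  .ng86_env[[key]] <- s
  s
}

# observed synonymous/nonsynonymous differences between two codons,
# averaged over mutation paths; paths through intermediate stop codons are
# excluded (all paths are used if every path hits a stop)
.ng86_diffs <- function(c1, c2) {
  key <- paste0("D_", c1, "_", c2)
  if (!is.null(.ng86_env[[key]])) return(.ng86_env[[key]])
  code <- Biostrings::GENETIC_CODE
  pos_diff <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(pos_diff)
  if (nd == 0) {
    res <- c(syn = 0, nonsyn = 0)
  } else {
    perms <- if (nd == 1) list(pos_diff)
      else if (nd == 2) lapply(list(c(1, 2), c(2, 1)), function(o) pos_diff[o])
      else lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1),
                       c(3,1,2), c(3,2,1)), function(o) pos_diff[o])
    eval_path <- function(order) {
      cur <- c1; s <- 0; n <- 0
      for (pos in order) {
        nxt <- cur
        substr(nxt, pos, pos) <- substr(c2, pos, pos)
        if (.is_stop(nxt) && nxt != c2) return(NULL)   # intermediate stop
        if (code[[cur]] == code[[nxt]]) s <- s + 1 else n <- n + 1
        cur <- nxt
      }
      c(s, n)
    }
    paths <- Filter(Negate(is.null), lapply(perms, eval_path))
    if (!length(paths))   # all paths blocked: fall back to all paths
      paths <- lapply(perms, function(order) {
        cur <- c1; s <- 0; n <- 0
        for (pos in order) {
          nxt <- cur
          substr(nxt, pos, pos) <- substr(c2, pos, pos)
          if (code[[cur]] == code[[nxt]]) s <- s + 1 else n <- n + 1
          cur <- nxt
        }
        c(s, n)
      })
    m <- Reduce(`+`, paths) / length(paths)
    res <- c(syn = m[1], nonsyn = m[2])
  }
  .ng86_env[[key]] <- res
  res
}

#' Ka and Ks between two allelic coding sequences (Nei-Gojobori 1986)
#'
#' Approximate-method site counting: potential synonymous and nonsynonymous
#' sites are computed per codon and averaged over the two sequences;
#' observed differences are averaged over mutation paths (paths through
#' intermediate stop codons excluded); proportions are corrected with the
#' Jukes-Cantor formula d = -3/4 log(1 - 4/3 p). A shared terminal stop
#' codon is trimmed; an internal stop codon is an error, as is a length
#' mismatch or a length not divisible by three. The result is symmetric
#' in the order of the two sequences.
#'
#' @param cds_a,cds_b equal-length, in-frame, gap-free coding sequences
#'   (character scalars over ACGT)
#' @return list: `ka`, `ks`, `ratio` (NA when Ks = 0 or a correction is
#'   undefined), `n_sites`, `s_sites`, `n_diffs`, `s_diffs`
#' @export
allelic_kaks <- function(cds_a, cds_b) {
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  if (nchar(cds_a) != nchar(cds_b)) stop("CDS length mismatch")
  if (nchar(cds_a) %% 3 != 0) stop("CDS length not divisible by three")
  ca <- .codon_split(cds_a); cb <- .codon_split(cds_b)
  nc <- length(ca)
  if (nc > 1 && .is_stop(ca[nc]) && .is_stop(cb[nc])) {
    ca <- ca[-nc]; cb <- cb[-nc]; nc <- nc - 1
  }
  if (any(vapply(ca, .is_stop, logical(1))) ||
      any(vapply(cb, .is_stop, logical(1))))
    stop("internal stop codon")
  s_a <- sum(vapply(ca, .ng86_sites, numeric(1)))
  s_b <- sum(vapply(cb, .ng86_sites, numeric(1)))
  S <- (s_a + s_b) / 2
  N <- 3 * nc - S
  diffs <- mapply(function(x, y) .ng86_diffs(x, y), ca, cb)
  Sd <- sum(diffs["syn", ]); Nd <- sum(diffs["nonsyn", ])
  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  ks <- if (S > 0) jc(Sd / S) else NA_real_
  ka <- if (N > 0) jc(Nd / N) else NA_real_
  ratio <- if (!is.na(ks) && ks > 0 && !is.na(ka)) ka / ks else NA_real_
  list(ka = ka, ks = ks, ratio = ratio,
       n_sites = N, s_sites = S, n_diffs = Nd, s_diffs = Sd)
}

#' SNP density per gene feature
#'
#' Densities (SNPs per 100 bp) across the canonical gene features: promoter
#' (2 kb upstream of the TSS), 5' UTR, exon, intron, 3' UTR and the 2-kb
#' stretch downstream of the 3' UTR. All intervals are strand-aware.
#'
#' @param variants a `variant_table` or data.frame with chrom/pos (SNPs)
#' @param models a `gene_model_set`
#' @param promoter_len promoter length upstream of the TSS, bp
#' @param downstream_len downstream feature length, bp
#' @return list with `per_gene` (gene_id, feature, length, n_snps, density)
#'   and `aggregate` (feature, length, n_snps, density per 100 bp)
#' @export
snp_feature_density <- function(variants, models, promoter_len = 2000L,
                                downstream_len = 2000L) {
  v <- if (inherits(variants, "variant_table")) variants$sites else variants
  snp_gr <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$pos, v$pos))
  rows <- list()
  for (m in models) {
    span <- range(c(m$exons, m$cds))
    ex <- IRanges::IRanges(m$exons[, 1], m$exons[, 2])
    cds <- IRanges::IRanges(m$cds[, 1], m$cds[, 2])
    introns <- IRanges::setdiff(IRanges::IRanges(span[1], span[2]), ex)
    utr <- IRanges::setdiff(ex, cds)
    cds_lo <- min(m$cds[, 1]); cds_hi <- max(m$cds[, 2])
    left_utr <- utr[IRanges::end(utr) < cds_lo]
    right_utr <- utr[IRanges::start(utr) > cds_hi]
    if (m$strand == "+") {
      utr5 <- left_utr; utr3 <- right_utr
      prom <- IRanges::IRanges(max(1L, span[1] - promoter_len), span[1] - 1L)
      down <- IRanges::IRanges(span[2] + 1L, span[2] + downstream_len)
    } else {
      utr5 <- right_utr; utr3 <- left_utr
      prom <- IRanges::IRanges(span[2] + 1L, span[2] + promoter_len)
      down <- IRanges::IRanges(max(1L, span[1] - downstream_len), span[1] - 1L)
    }
    feats <- list(promoter = prom, utr5 = utr5, exon = ex, intron = introns,
                  utr3 = utr3, downstream2kb = down)
    for (fn in names(feats)) {
      iv <- feats[[fn]]
      len <- sum(IRanges::width(iv))
      n_snp <- if (len == 0) 0L else
        sum(IRanges::overlapsAny(snp_gr,
          GenomicRanges::GRanges(m$chrom, iv)))
      rows[[length(rows) + 1L]] <-
        data.frame(gene_id = m$gene_id, feature = fn, length = len,
                   n_snps = n_snp,
                   density = if (len > 0) 100 * n_snp / len else NA_real_,
                   stringsAsFactors = FALSE)
    }
  }
  per_gene <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(length, n_snps) ~ feature, per_gene, sum)
  agg$density <- ifelse(agg$length > 0, 100 * agg$n_snps / agg$length,
                        NA_real_)
  list(per_gene = per_gene, aggregate = agg)
}
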