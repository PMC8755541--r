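#' Evaluate an expression under a fixed RNG seed, restoring RNG state after
#'
#' All generator randomness flows through this helper; sub-streams are
#' derived from the master seed by fixed offsets so each generator's output
#' is independently reproducible.
#' @param seed integer seed
#' @param expr expression
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# fixed sub-stream offsets per generator
.seed_offsets <- c(two_pop = 101L, pedigree = 211L, genome = 307L,
                   allelic = 401L, coverage = 503L)

#' Parameters for the two-population genotype simulator
#'
#' The Balding-Nichols model: per site an ancestral frequency p is drawn from
#' `ancestral_freq_law`, and each source population's frequency from a Beta
#' distribution with mean p and variance p(1-p)F, where F is the per-population
#' drift (divergence) parameter. Within-population inbreeding is modeled as a
#' probability `inbreeding_F_within` of copying the first allele, giving an
#' expected heterozygosity deficit equal to F_within. Admixed (F1) samples
#' receive one haplotype drawn from each source population.
#'
#' @param n_sites number of unlinked biallelic sites
#' @param n_per_population integer vector of length 2: diploids per source
#'   population
#' @param n_admixed number of F1 (one haplotype per source) samples
#' @param divergence_F Balding-Nichols drift parameter in (0,1); scalar or
#'   length 2
#' @param ancestral_freq_law function(n) returning n ancestral frequencies in
#'   (0,1); default uniform on (0.05, 0.95)
#' @param inbreeding_F_within per-population inbreeding in \[0,1); scalar or
#'   length 2 (admixed samples are outbred by construction)
#' @param seed mandatory integer seed
#' @return a `sim_params` list
#' @export
simulation_params <- function(n_sites, n_per_population = c(20L, 20L),
                              n_admixed = 0L, divergence_F = 0.15,
                              ancestral_freq_law = function(n) stats::runif(n, 0.05, 0.95),
                              inbreeding_F_within = c(0, 0), seed) {
  if (missing(seed)) stop("seed is mandatory")
  divergence_F <- rep_len(divergence_F, 2L)
  inbreeding_F_within <- rep_len(inbreeding_F_within, 2L)
  stopifnot(n_sites >= 1, length(n_per_population) == 2,
            all(divergence_F >= 0), all(divergence_F < 1),
            all(inbreeding_F_within >= 0), all(inbreeding_F_within < 1))
  structure(list(n_sites = as.integer(n_sites),
                 n_per_population = as.integer(n_per_population),
                 n_admixed = as.integer(n_admixed),
                 divergence_F = divergence_F,
                 ancestral_freq_law = ancestral_freq_law,
                 inbreeding_F_within = inbreeding_F_within,
                 seed = as.integer(seed)),
            class = "sim_params")
}

# one population's diploid genotypes given per-site frequency and inbreeding
.draw_genotypes <- function(p_site, n_ind, f_within) {
  n <- length(p_site)
  a1 <- matrix(stats::rbinom(n * n_ind, 1L, rep(p_site, n_ind)), nrow = n)
  fresh <- matrix(stats::rbinom(n * n_ind, 1L, rep(p_site, n_ind)), nrow = n)
  copy <- matrix(stats::runif(n * n_ind) < f_within, nrow = n)
  a2 <- ifelse(copy, a1, fresh)
  list(a = a1, b = a2)
}

#' Simulate genotypes under a two-population Balding-Nichols model
#'
#' @param params a [simulation_params()] object
#' @return list with `vt` (a `variant_table` with passing filter annotations)
#'   and `truth` (ancestral and per-population frequencies, each sample's
#'   population of origin per haplotype, seed)
#' @export
simulate_two_population_genotypes <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed + .seed_offsets[["two_pop"]], {
    n <- params$n_sites
    p_anc <- params$ancestral_freq_law(n)
    n_resampled <- 0L
    bad <- which(p_anc <= 0 | p_anc >= 1)
    while (length(bad)) {
      n_resampled <- n_resampled + length(bad)
      p_anc[bad] <- params$ancestral_freq_law(length(bad))
      bad <- which(p_anc <= 0 | p_anc >= 1)
    }
    if (n_resampled > 0.5 * n)
      hp_log("WARN", sprintf("%d degenerate ancestral frequencies resampled",
                             n_resampled))
    p_pop <- sapply(1:2, function(k) {
      f <- params$divergence_F[k]
      if (f < 1e-12) p_anc
      else stats::rbeta(n, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
    })
    n1 <- params$n_per_population[1]; n2 <- params$n_per_population[2]
    g1 <- .draw_genotypes(p_pop[, 1], n1, params$inbreeding_F_within[1])
    g2 <- .draw_genotypes(p_pop[, 2], n2, params$inbreeding_F_within[2])
    ga <- cbind(g1$a, g2$a); gb <- cbind(g1$b, g2$b)
    samples <- c(sprintf("pop1_%02d", seq_len(n1)),
                 sprintf("pop2_%02d", seq_len(n2)))
    hap_origin <- rbind(cbind(rep("pop1", n1), rep("pop1", n1)),
                        cbind(rep("pop2", n2), rep("pop2", n2)))
    if (params$n_admixed > 0) {
      na <- params$n_admixed
      fa <- matrix(stats::rbinom(n * na, 1L, rep(p_pop[, 1], na)), nrow = n)
      fb <- matrix(stats::rbinom(n * na, 1L, rep(p_pop[, 2], na)), nrow = n)
      ga <- cbind(ga, fa); gb <- cbind(gb, fb)
      samples <- c(samples, sprintf("F1_%02d", seq_len(na)))
      hap_origin <- rbind(hap_origin, cbind(rep("pop1", na), rep("pop2", na)))
    }
    rownames(hap_origin) <- samples
    ref_alt <- replicate(n, sample(c("A", "C", "G", "T"), 2L))
    sites <- data.frame(chrom = "chr1", pos = seq_len(n) * 100L,
                        ref = ref_alt[1, ], alt = ref_alt[2, ],
                        QD = 25, FS = 1, MQ = 60, SOR = 1, DP = 1500,
                        MQRankSum = 0, ReadPosRankSum = 0,
                        stringsAsFactors = FALSE)
    vt <- variant_table(sites, ga, gb, samples)
    pop_of <- sub("_.*$", "", samples)
    truth <- list(p_ancestral = p_anc, p_population = p_pop,
                  sample_population = stats::setNames(pop_of, samples),
                  haplotype_origin = hap_origin, params = params,
                  seed = params$seed)
    list(vt = vt, truth = truth)
  })
}

#' Expected pedigree kinship coefficients and relationship degrees
#'
#' Standard recursive pedigree kinship: founders are taken as unrelated and
#' non-inbred, phi(i,i) = (1 + F_i)/2, and a child's kinship with anyone
#' earlier in the pedigree is the mean of its parents' kinships. A clone
#' (pedigree row with `parent_b` NA) shares its parent's kinship vector.
#' Degrees are assigned with the standard powers-of-two bins, see
#' [classify_relationship()].
#'
#' @param ids sample ids in pedigree order (parents precede children)
#' @param pedigree data.frame with columns `child`, `parent_a`, `parent_b`
#'   (`parent_b` NA marks a clone of `parent_a`); founders are ids absent
#'   from `child`
#' @return list with `phi` (ids x ids expected kinship matrix) and `degree`
#'   (character matrix)
#' @export
pedigree_kinship <- function(ids, pedigree) {
  k <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  ped <- pedigree[match(ids, pedigree$child), ]
  for (i in seq_along(ids)) {
    pa <- ped$parent_a[i]; pb <- ped$parent_b[i]
    if (is.na(pa)) {                      # founder
      k[i, i] <- 0.5
    } else if (is.na(pb)) {               # clone
      j <- match(pa, ids)
      if (is.na(j) || j >= i) stop("clone parent must precede child: ", pa)
      k[i, seq_len(i - 1)] <- k[j, seq_len(i - 1)]
      k[seq_len(i - 1), i] <- k[seq_len(i - 1), j]
      k[i, i] <- k[j, j]
      k[i, j] <- k[j, i] <- k[j, j]
    } else {
      ja <- match(pa, ids); jb <- match(pb, ids)
      if (anyNA(c(ja, jb)) || max(ja, jb) >= i)
        stop("parents must precede child in pedigree order: ", ids[i])
      for (j in seq_len(i - 1)) {
        k[i, j] <- k[j, i] <- 0.5 * (k[ja, j] + k[jb, j])
      }
      k[i, i] <- 0.5 * (1 + k[ja, jb])
    }
  }
  deg <- matrix(classify_relationship(k), nrow = nrow(k),
                dimnames = dimnames(k))
  list(phi = k, degree = deg)
}

#' Drop Mendelian genotypes down a pedigree
#'
#' Children receive one uniformly sampled allele from each parent per site
#' (sites are treated as unlinked); a clone row copies its parent's
#' genotypes verbatim. The truth records the exact expected relationship
#' degree for every pair of output samples.
#'
#' @param founders a `variant_table` of founder genotypes
#' @param pedigree data.frame with columns `child`, `parent_a`, `parent_b`
#'   (`parent_b` NA = clone); parents must precede children
#' @param seed integer seed
#' @return list with `vt` (founders plus children) and `truth`
#'   (`phi`, `degree` matrices over all samples)
#' @export
simulate_pedigree_genotypes <- function(founders, pedigree, seed) {
  with_seed(seed + .seed_offsets[["pedigree"]], {
    ga <- founders$geno_a; gb <- founders$geno_b
    samples <- founders$samples
    n <- n_sites(founders)
    for (i in seq_len(nrow(pedigree))) {
      ch <- pedigree$child[i]; pa <- pedigree$parent_a[i]
      pb <- pedigree$parent_b[i]
      ja <- match(pa, samples)
      if (is.na(ja)) stop("unknown parent id: ", pa)
      if (is.na(pb)) {                     # clone
        new_a <- ga[, ja]; new_b <- gb[, ja]
      } else {
        jb <- match(pb, samples)
        if (is.na(jb)) stop("unknown parent id: ", pb)
        pick_a <- stats::runif(n) < 0.5
        pick_b <- stats::runif(n) < 0.5
        new_a <- ifelse(pick_a, ga[, ja], gb[, ja])
        new_b <- ifelse(pick_b, ga[, jb], gb[, jb])
      }
      ga <- cbind(ga, new_a); gb <- cbind(gb, new_b)
      samples <- c(samples, ch)
    }
    colnames(ga) <- colnames(gb) <- samples
    vt <- variant_table(founders$sites, ga, gb, samples)
    full_ped <- data.frame(child = pedigree$child,
                           parent_a = pedigree$parent_a,
                           parent_b = pedigree$parent_b,
                           stringsAsFactors = FALSE)
    truth <- pedigree_kinship(samples, full_ped)
    truth$seed <- seed
    list(vt = vt, truth = truth)
  })
}

.codons_no_stop <- function() {
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
}

#' Generate a two-haplotype annotated genome with a planted deletion
#'
#' Builds haplotype 1 as alternating intergenic spacers and genes (each gene:
#' optional minus strand, 60-bp UTRs, 1-3 coding exons with GT..AG introns,
#' ATG start, in-frame TAA stop, no internal stops), then derives haplotype 2
#' by sprinkling SNPs and short indels at a configurable density
#' (default ~2.3 events per 100 bp, the heterozygosity scale of a highly
#' heterozygous cultivar) and removing one multi-kb intergenic segment
#' downstream of a designated gene — the planted deletion, default 3,781 bp.
#' A configurable fraction of gene models is deliberately malformed (non-ATG
#' start or CDS length not divisible by three) to exercise the high-quality
#' model filter.
#'
#' @param n_genes number of gene models
#' @param gene_length_law function(n) returning internal codon counts
#' @param deletion_length planted deletion length in bp
#' @param snp_rate per-base SNP probability between haplotypes
#' @param indel_rate per-base short-indel probability
#' @param malformed_fraction fraction of genes given a defect
#' @param intergenic_length spacer length between genes
#' @param seed integer seed
#' @return list with `genomes` (list of one-chromosome DNAStringSets named
#'   hap1 and hap2; the sequence is named by chromosome), `models`
#'   (`gene_model_set` on hap1 coordinates), `variants` (data.frame of
#'   hap1-vs-hap2 differences in hap1 coordinates), and `truth` (deletion
#'   interval and carrier, malformed gene ids, designated gene, seed)
#' @export
generate_genome_with_annotation <- function(n_genes = 20,
                                            gene_length_law = function(n) sample(60:150, n, replace = TRUE),
                                            deletion_length = 3781L,
                                            snp_rate = 0.02,
                                            indel_rate = 0.003,
                                            malformed_fraction = 0,
                                            intergenic_length = 1500L,
                                            seed) {
  with_seed(seed + .seed_offsets[["genome"]], {
    bases <- c("A", "C", "G", "T")
    body_codons <- .codons_no_stop()
    rand_seq <- function(len) paste(sample(bases, len, replace = TRUE),
                                    collapse = "")
    n_codons <- gene_length_law(n_genes)
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)
    malformed <- rep(FALSE, n_genes)
    if (malformed_fraction > 0)
      malformed <- stats::runif(n_genes) < malformed_fraction
    designated <- ceiling(n_genes / 2)   # deletion goes downstream of this one

    seq_parts <- character(0)
    cursor <- 0L
    models <- list()
    malformed_ids <- character(0)
    del_start <- NA_integer_
    utr <- 60L
    for (g in seq_len(n_genes)) {
      spacer_len <- intergenic_length
      if (g == designated + 1L) {
        # host spacer: margin, deletion, margin
        pre <- 1000L
        seq_parts <- c(seq_parts, rand_seq(pre))
        cursor <- cursor + pre
        del_start <- cursor + 1L
        seq_parts <- c(seq_parts, rand_seq(deletion_length))
        cursor <- cursor + deletion_length
        spacer_len <- 1000L
      }
      seq_parts <- c(seq_parts, rand_seq(spacer_len))
      cursor <- cursor + spacer_len

      # coding sequence 5'->3': ATG + body + TAA
      cds5 <- paste0("ATG", paste(sample(body_codons, n_codons[g],
                                         replace = TRUE), collapse = ""), "TAA")
      defect <- NA_character_
      if (malformed[g]) {
        defect <- sample(c("start", "frame"), 1L)
        if (defect == "start") substr(cds5, 1, 3) <- "GTG"
        else cds5 <- paste0(cds5, sample(bases, 1L))  # CDS length % 3 != 0
      }
      n_exons <- sample(1:3, 1L)
      cuts <- if (n_exons > 1)
        sort(sample(seq_len(nchar(cds5) - 1L), n_exons - 1L)) else integer(0)
      bounds <- cbind(c(1L, cuts + 1L), c(cuts, nchar(cds5)))
      pieces5 <- apply(bounds, 1, function(b) substr(cds5, b[1], b[2]))
      # genomic order of exons: reverse-complement each piece for minus strand
      if (strands[g] == "-") {
        pieces_gen <- rev(vapply(pieces5, function(p)
          as.character(Biostrings::reverseComplement(Biostrings::DNAString(p))),
          character(1), USE.NAMES = FALSE))
      } else pieces_gen <- unname(pieces5)
      intron_lens <- if (n_exons > 1)
        sample(80:200, n_exons - 1L, replace = TRUE) else integer(0)
      gene_start <- cursor + 1L
      cds_iv <- NULL
      # 5' UTR in genomic coordinates sits before the first genomic exon on
      # the plus strand, after the last on the minus strand
      utr_left <- rand_seq(utr); utr_right <- rand_seq(utr)
      seq_parts <- c(seq_parts, utr_left)
      cursor <- cursor + utr
      first_exon_start <- cursor + 1L
      for (e in seq_len(n_exons)) {
        piece <- pieces_gen[e]
        seq_parts <- c(seq_parts, piece)
        cds_iv <- rbind(cds_iv, c(cursor + 1L, cursor + nchar(piece)))
        cursor <- cursor + nchar(piece)
        if (e < n_exons) {
          ilen <- intron_lens[e]
          intr <- paste0("GT", rand_seq(ilen - 4L), "AG")
          seq_parts <- c(seq_parts, intr)
          cursor <- cursor + ilen
        }
      }
      seq_parts <- c(seq_parts, utr_right)
      cursor <- cursor + utr
      gene_end <- cursor
      # exons = CDS pieces, with the terminal ones extended by the UTRs
      exons <- cds_iv
      exons[1, 1] <- exons[1, 1] - utr
      exons[nrow(exons), 2] <- exons[nrow(exons), 2] + utr
      gid <- sprintf("gene%03d", g)
      models[[gid]] <- list(gene_id = gid, chrom = "chr1",
                            strand = strands[g],
                            exons = `colnames<-`(exons, c("start", "end")),
                            cds = `colnames<-`(cds_iv, c("start", "end")),
                            tss = if (strands[g] == "-") gene_end else gene_start)
      if (malformed[g]) malformed_ids <- c(malformed_ids, gid)
    }
    seq_parts <- c(seq_parts, rand_seq(intergenic_length))
    hap1 <- paste(seq_parts, collapse = "")
    L <- nchar(hap1)
    if (is.na(del_start))
      stop("infeasible packing: no intergenic spacer could host the deletion; ",
           "increase n_genes above the designated index")
    del_end <- del_start + deletion_length - 1L

    # haplotype 2: SNPs and short indels relative to hap1, plus the deletion
    h1 <- strsplit(hap1, "")[[1]]
    n_snp <- stats::rbinom(1L, L, snp_rate)
    n_ind <- stats::rbinom(1L, L, indel_rate)
    cand <- sort(sample.int(L - 10L, n_snp + n_ind))
    keep <- c(TRUE, diff(cand) > 5L)
    cand <- cand[keep]
    is_ind <- rep(FALSE, length(cand))
    if (n_ind > 0 && length(cand) > 0)
      is_ind[sample.int(length(cand), min(n_ind, length(cand)))] <- TRUE
    # exclude events inside the deletion (they would vanish from hap2) and
    # keep its 1-kb flanks indel-free so marker product lengths differ by
    # exactly the deletion length (SNPs in the flanks are fine)
    inside_del <- cand >= del_start - 5L & cand <= del_end
    cand <- cand[!inside_del]; is_ind <- is_ind[!inside_del]
    flank <- (cand >= del_start - 1000L & cand < del_start) |
      (cand > del_end & cand <= del_end + 1000L)
    is_ind[flank] <- FALSE

    variants <- data.frame(chrom = character(0), pos = integer(0),
                           ref = character(0), alt = character(0))
    edits <- list()
    for (k in seq_along(cand)) {
      p <- cand[k]
      if (!is_ind[k]) {
        ref <- h1[p]
        alt <- sample(setdiff(bases, ref), 1L)
        variants <- rbind(variants, data.frame(chrom = "chr1", pos = p,
                                               ref = ref, alt = alt))
        edits[[length(edits) + 1L]] <- list(pos = p, ref_len = 1L, alt = alt)
      } else if (stats::runif(1) < 0.5) {   # deletion in hap2
        dlen <- sample(1:3, 1L)
        ref <- paste(h1[p:(p + dlen)], collapse = "")
        alt <- h1[p]
        variants <- rbind(variants, data.frame(chrom = "chr1", pos = p,
                                               ref = ref, alt = alt))
        edits[[length(edits) + 1L]] <- list(pos = p, ref_len = dlen + 1L,
                                            alt = alt)
      } else {                              # insertion in hap2
        ilen <- sample(1:3, 1L)
        ins <- paste(sample(bases, ilen, replace = TRUE), collapse = "")
        ref <- h1[p]
        alt <- paste0(ref, ins)
        variants <- rbind(variants, data.frame(chrom = "chr1", pos = p,
                                               ref = ref, alt = alt))
        edits[[length(edits) + 1L]] <- list(pos = p, ref_len = 1L, alt = alt)
      }
    }
    edits[[length(edits) + 1L]] <- list(pos = del_start, ref_len = deletion_length,
                                        alt = "")
    ords <- order(vapply(edits, `[[`, numeric(1), "pos"))
    edits <- edits[ords]
    out <- character(0); last <- 1L
    for (e in edits) {
      if (e$pos > last) out <- c(out, substr(hap1, last, e$pos - 1L))
      out <- c(out, e$alt)
      last <- e$pos + e$ref_len
    }
    if (last <= L) out <- c(out, substr(hap1, last, L))
    hap2 <- paste(out, collapse = "")

    genomes <- list(hap1 = Biostrings::DNAStringSet(c(chr1 = hap1)),
                    hap2 = Biostrings::DNAStringSet(c(chr1 = hap2)))
    truth <- list(deletion = list(chrom = "chr1", start = del_start,
                                  end = del_end, length = deletion_length,
                                  carrier = "hap2"),
                  malformed_gene_ids = malformed_ids,
                  designated_gene = sprintf("gene%03d", designated),
                  genome_length = L, seed = seed)
    list(genomes = genomes,
         models = structure(models, class = "gene_model_set"),
         variants = variants, truth = truth)
  })
}

#' Simulate allele-specific expression count matrices
#'
#' Per gene and RNA-seq library, total depth is Poisson(`depth_mean`) and the
#' count of the first-haplotype allele is Binomial(depth, theta): theta = 0.5
#' for balanced genes, theta = `theta_dea` (direction randomized per gene)
#' for the planted differentially-expressed-allele (DEA) genes.
#'
#' @param gene_ids character vector of gene ids
#' @param n_libraries number of libraries
#' @param depth_mean mean total allelic depth per gene and library
#' @param dea_fraction fraction of genes planted as DEA
#' @param theta_dea allelic ratio of DEA genes, in (0,1)
#' @param seed integer seed
#' @return list with `counts` (list of matrices `a`, `b`, genes x libraries)
#'   and `truth` (`dea_genes`, per-gene `theta`, seed)
#' @export
simulate_allelic_counts <- function(gene_ids, n_libraries, depth_mean = 100,
                                    dea_fraction = 0.1, theta_dea = 0.8,
                                    seed) {
  stopifnot(theta_dea > 0, theta_dea < 1)
  with_seed(seed + .seed_offsets[["allelic"]], {
    ng <- length(gene_ids)
    theta <- rep(0.5, ng)
    n_dea <- round(dea_fraction * ng)
    dea_idx <- if (n_dea > 0) sample.int(ng, n_dea) else integer(0)
    if (length(dea_idx)) {
      flip <- stats::runif(length(dea_idx)) < 0.5
      theta[dea_idx] <- ifelse(flip, 1 - theta_dea, theta_dea)
    }
    depth <- matrix(stats::rpois(ng * n_libraries, depth_mean), nrow = ng)
    a <- matrix(stats::rbinom(ng * n_libraries, as.vector(depth),
                              rep(theta, n_libraries)), nrow = ng)
    b <- depth - a
    dimnames(a) <- dimnames(b) <-
      list(gene_ids, sprintf("lib%02d", seq_len(n_libraries)))
    list(counts = list(a = a, b = b),
         truth = list(dea_genes = gene_ids[sort(dea_idx)],
                      theta = stats::setNames(theta, gene_ids), seed = seed))
  })
}

#' Simulate per-base genomic coverage over a region with a deletion
#'
#' Per-base depth is Poisson(lambda) with lambda = `mean_depth` outside the
#' deletion and `mean_depth * (2 - g)/2` inside it for a sample carrying
#' g deleted copies (g = 0, 1, 2).
#'
#' @param region_length region length in bp
#' @param deletion list/vector with `start` and `end` (1-based, inclusive)
#' @param genotypes named integer vector: copies deleted per sample
#' @param mean_depth mean depth outside the deletion
#' @param seed integer seed
#' @return list with `depth` (region_length x samples integer matrix),
#'   `deletion`, `genotypes`, `seed`
#' @export
simulate_coverage <- function(region_length, deletion, genotypes,
                              mean_depth = 30, seed) {
  with_seed(seed + .seed_offsets[["coverage"]], {
    stopifnot(deletion$start >= 1, deletion$end <= region_length)
    lam <- matrix(mean_depth, nrow = region_length, ncol = length(genotypes))
    inside <- seq(deletion$start, deletion$end)
    for (j in seq_along(genotypes))
      lam[inside, j] <- mean_depth * (2 - genotypes[j]) / 2
    depth <- matrix(stats::rpois(length(lam), as.vector(lam)),
                    nrow = region_length,
                    dimnames = list(NULL, names(genotypes)))
    list(depth = depth, deletion = deletion, genotypes = genotypes,
         seed = seed)
  })
}
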