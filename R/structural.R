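#' Fixed-width coverage windows with normalized ratios
#'
#' Mean per-base depth in fixed windows (default 800 bp, grid aligned to
#' multiples of the width; a trailing partial window is averaged over its
#' actual length), normalized by the sample's genome-wide mean depth.
#'
#' @param depth numeric vector of per-base depth along the region
#' @param window window width in bp
#' @param genome_mean the sample's genome-wide mean depth used for
#'   normalization; defaults to the mean of `depth`
#' @return data.frame (coverage track): start, end (1-based inclusive),
#'   mean_depth, ratio
#' @export
window_coverage <- function(depth, window = 800L, genome_mean = mean(depth)) {
  L <- length(depth)
  starts <- seq(1L, L, by = window)
  ends <- pmin(starts + window - 1L, L)
  means <- vapply(seq_along(starts), function(k)
    mean(depth[starts[k]:ends[k]]), numeric(1))
  data.frame(start = starts, end = ends, mean_depth = means,
             ratio = if (genome_mean > 0) means / genome_mean else NA_real_)
}

#' Compare normalized coverage between groups over a region
#'
#' Per sample, the mean window ratio over the windows overlapping `region`;
#' then a two-sided t-test between the two groups (pooled-variance Student's
#' test by default; Welch via `var_equal = FALSE`).
#'
#' @param tracks named list of coverage tracks from [window_coverage()]
#' @param region numeric length-2: start, end (1-based inclusive)
#' @param groups named list of two character vectors of sample names
#' @param var_equal pooled-variance (Student's) t-test if TRUE
#' @return list: `sample_ratio` (named), `group_means`, `t`, `p`, `df`
#' @export
compare_groups_over_region <- function(tracks, region, groups,
                                       var_equal = TRUE) {
  stopifnot(length(groups) == 2, all(lengths(groups) >= 2))
  sample_ratio <- vapply(tracks, function(tr) {
    in_reg <- tr$start <= region[2] & tr$end >= region[1]
    mean(tr$ratio[in_reg])
  }, numeric(1))
  g1 <- sample_ratio[groups[[1]]]; g2 <- sample_ratio[groups[[2]]]
  if (stats::sd(c(g1, g2)) == 0) {
    tt <- list(statistic = c(t = 0), p.value = 1,
               parameter = c(df = length(g1) + length(g2) - 2))
  } else {
    tt <- stats::t.test(g1, g2, var.equal = var_equal)
  }
  list(sample_ratio = sample_ratio,
       group_means = c(mean(g1), mean(g2)),
       t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Genotype a deletion from a normalized coverage ratio
#'
#' Copy-ratio thresholds are midpoints between the expected ratios
#' \{1, 0.5, 0\} for 0, 1 and 2 deleted copies: above `upper` no-deletion,
#' between the cutoffs heterozygous, below `lower` homozygous-deletion.
#'
#' @param region_ratio normalized mean coverage ratio over the deletion
#'   region (vectorized)
#' @param lower,upper genotype cutoffs
#' @return character vector over
#'   no-deletion / heterozygous / homozygous-deletion
#' @export
genotype_deletion <- function(region_ratio, lower = 0.25, upper = 0.75) {
  ifelse(region_ratio > upper, "no-deletion",
  ifelse(region_ratio < lower, "homozygous-deletion", "heterozygous"))
}

#' Recover a deletion interval from a coverage track
#'
#' The longest contiguous run of windows with ratio below `max_ratio`;
#' the candidate deletion interval of a heterozygous or homozygous carrier.
#'
#' @param track a coverage track from [window_coverage()]
#' @param max_ratio windows below this ratio are candidate deletion windows
#' @return list `start`, `end` (1-based), or NULL when no window qualifies
#' @export
detect_deletion_interval <- function(track, max_ratio = 0.75) {
  low <- track$ratio < max_ratio
  if (!any(low)) return(NULL)
  r <- rle(low)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  list(start = track$start[starts_i[best]], end = track$end[ends_i[best]])
}

#' In-silico PCR against template sequences
#'
#' Exact primer matching (no mismatches, no degenerate bases), both strands
#' searched: a product runs from the start of a forward-strand primer match
#' to the end of a reverse-complement match of another (or the same) primer,
#' subject to the maximum amplicon length. Primers matching multiple loci
#' have all products reported and the ambiguity flagged.
#'
#' @param templates named character vector or `DNAStringSet` of templates
#' @param primers data.frame with columns `id` and `seq` (15-30 nt, ACGT)
#' @param max_len maximum amplicon length in bp
#' @return data.frame: template, forward, reverse, start, end, length,
#'   with attribute `ambiguous` naming primers matching more than one locus
#'   on a template
#' @export
insilico_pcr <- function(templates, primers, max_len = 10000L) {
  if (!inherits(templates, "DNAStringSet"))
    templates <- Biostrings::DNAStringSet(templates)
  stopifnot(all(grepl("^[ACGT]+$", primers$seq)),
            !anyDuplicated(primers$id))
  if (any(nchar(primers$seq) < 15 | nchar(primers$seq) > 30))
    warning("primer length outside the usual 15-30 nt range")
  out <- NULL; ambiguous <- character(0)
  for (ti in seq_along(templates)) {
    tmpl <- templates[[ti]]
    tname <- names(templates)[ti]
    fwd <- list(); rev <- list()
    for (k in seq_len(nrow(primers))) {
      p <- Biostrings::DNAString(primers$seq[k])
      mf <- Biostrings::matchPattern(p, tmpl)
      mr <- Biostrings::matchPattern(Biostrings::reverseComplement(p), tmpl)
      if (length(mf) + length(mr) > 1)
        ambiguous <- union(ambiguous, primers$id[k])
      fwd[[primers$id[k]]] <- Biostrings::start(mf)
      rev[[primers$id[k]]] <- Biostrings::end(mr)
    }
    for (fid in names(fwd)) for (rid in names(rev)) {
      for (s in fwd[[fid]]) for (e in rev[[rid]]) {
        if (e > s && e - s + 1L <= max_len)
          out <- rbind(out, data.frame(template = tname, forward = fid,
                                       reverse = rid, start = s, end = e,
                                       length = e - s + 1L,
                                       stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out))
    out <- data.frame(template = character(0), forward = character(0),
                      reverse = character(0), start = integer(0),
                      end = integer(0), length = integer(0))
  attr(out, "ambiguous") <- ambiguous
  out
}

#' Classify a diploid band pattern at the deletion marker
#'
#' The diploid band pattern is the union of both haplotypes' amplicons. The
#' non-deleted haplotype yields the product of the `normal_pair` (forward
#' primer upstream, reverse primer inside the deletion); the deleted
#' haplotype loses that product and instead yields the `spanning_pair`
#' product (reverse primer downstream of the deletion), which only fits
#' under the amplicon-length cap once the deletion shortens the template.
#' Deletion-spanning product only: EEMC-like (deletion on both haplotypes);
#' non-deleted product only: LMC-like; both bands: EMC-like (heterozygote).
#'
#' @param amplicons data.frame from [insilico_pcr()] over both haplotypes
#' @param normal_pair character length-2: forward/reverse primer ids of the
#'   non-deleted-specific product
#' @param spanning_pair character length-2: primer ids of the
#'   deletion-spanning product
#' @return one of "EEMC-like", "EMC-like", "LMC-like", or "no-band"
#' @export
classify_marker <- function(amplicons, normal_pair, spanning_pair) {
  has <- function(pair) any(amplicons$forward == pair[1] &
                            amplicons$reverse == pair[2])
  has_normal <- has(normal_pair)
  has_span <- has(spanning_pair)
  if (has_normal && has_span) "EMC-like"
  else if (has_span) "EEMC-like"
  else if (has_normal) "LMC-like"
  else "no-band"
}

#' Read a per-base depth track from a BED-like file
#'
#' Columns chrom, start (0-based), end (half-open), depth; expanded into a
#' per-base vector for one chromosome.
#'
#' @param path BED file path
#' @param chrom chromosome to extract
#' @param region_length length of the output vector (defaults to the
#'   largest end coordinate)
#' @return numeric per-base depth vector
#' @export
read_depth_bed <- function(path, chrom = NULL, region_length = NULL) {
  bed <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("chrom", "start", "end", "depth"))
  if (!is.null(chrom)) bed <- bed[bed$chrom == chrom, ]
  if (is.null(region_length)) region_length <- max(bed$end)
  depth <- numeric(region_length)
  for (i in seq_len(nrow(bed)))
    depth[(bed$start[i] + 1L):bed$end[i]] <- bed$depth[i]
  depth
}

#' Write a per-base depth vector as a BED-like file (run-length encoded)
#' @param depth numeric per-base depth vector
#' @param chrom chromosome name
#' @param path output path
#' @return invisibly, `path`
#' @export
write_depth_bed <- function(depth, chrom, path) {
  r <- rle(depth)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths   # 0-based
  utils::write.table(data.frame(chrom, starts, ends, r$values), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Design a three-primer deletion marker on a synthetic genome
#'
#' Picks the classic three-primer configuration around the planted deletion
#' of [generate_genome_with_annotation()]: a shared forward primer `a1`
#' upstream of the deletion, a reverse primer `b1` inside it (so its band is
#' specific to the non-deleted haplotype) and a reverse primer `c1`
#' downstream (whose band with `a1` only fits under the amplicon-length cap
#' once the deletion shortens the template). Primer sites are chosen in
#' variant-free windows of haplotype 1 so both haplotypes are matched
#' exactly where the primer is present.
#'
#' @param genome_result the list returned by
#'   [generate_genome_with_annotation()]
#' @param primer_len primer length in nt
#' @return list: `primers` (data.frame id/seq), `normal_pair`,
#'   `spanning_pair`, `max_len` (recommended amplicon cap: the deletion
#'   length), and the chosen primer start coordinates on haplotype 1
#' @export
design_deletion_primers <- function(genome_result, primer_len = 20L) {
  del <- genome_result$truth$deletion
  h1 <- as.character(genome_result$genomes$hap1[[1]])
  v <- genome_result$variants
  blocked <- unlist(mapply(function(p, r) seq(p, p + nchar(r) - 1L),
                           v$pos, v$ref, SIMPLIFY = FALSE))
  clean <- function(from, to) {   # first variant-free window scanning 5'->3'
    for (s in seq(from, to - primer_len + 1L)) {
      win <- seq(s, s + primer_len - 1L)
      if (!any(win %in% blocked)) return(s)
    }
    stop("no variant-free primer window in [", from, ", ", to, "]")
  }
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  a1_start <- clean(del$start - 900L, del$start - 50L)
  b1_start <- del$start + 200L                      # inside: variant-free
  c1_start <- clean(del$end + 50L, del$end + 900L)
  a1 <- substr(h1, a1_start, a1_start + primer_len - 1L)
  b1 <- rc(substr(h1, b1_start, b1_start + primer_len - 1L))
  c1 <- rc(substr(h1, c1_start, c1_start + primer_len - 1L))
  list(primers = data.frame(id = c("a1", "b1", "c1"),
                            seq = c(a1, b1, c1), stringsAsFactors = FALSE),
       normal_pair = c("a1", "b1"), spanning_pair = c("a1", "c1"),
       max_len = del$length,
       starts = c(a1 = a1_start, b1 = b1_start, c1 = c1_start))
}
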