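#' Sitewise nucleotide diversity
#'
#' Unbiased pairwise-difference estimator per site over called alleles:
#' pi = sum_{a<b} n_a n_b / C(n, 2). Missing genotypes are excluded
#' site-wise; a value is emitted only where at least two alleles are called
#' (monomorphic called sites get 0). Indel sites are skipped by default —
#' the diversity statistics are SNP statistics.
#'
#' @param vt a `variant_table`
#' @param samples optional sample subset (character ids)
#' @param snps_only skip sites whose REF or ALT is not a single base
#' @return data.frame (the site diversity track): chrom, pos, pi, n_called
#' @export
sitewise_pi <- function(vt, samples = NULL, snps_only = TRUE) {
  if (!is.null(samples)) vt <- vt_subset(vt, samples = samples)
  keep <- rep(TRUE, n_sites(vt))
  if (snps_only)
    keep <- nchar(vt$sites$ref) == 1L &
      nchar(sub(",.*$", "", vt$sites$alt)) == 1L &
      !grepl(",", vt$sites$alt, fixed = TRUE)
  vt <- vt_subset(vt, sites = keep)
  ga <- vt$geno_a; gb <- vt$geno_b
  called <- !is.na(ga) & !is.na(gb)
  n <- 2L * rowSums(called)
  max_allele <- max(1L, suppressWarnings(max(ga, gb, na.rm = TRUE)))
  sum_sq <- rep(0, n_sites(vt))
  for (al in 0:max_allele) {
    cnt <- rowSums((ga == al) & called, na.rm = TRUE) +
      rowSums((gb == al) & called, na.rm = TRUE)
    sum_sq <- sum_sq + cnt^2
  }
  pi <- ifelse(n >= 2, (n^2 - sum_sq) / (n * (n - 1)), NA_real_)
  out <- data.frame(chrom = vt$sites$chrom, pos = vt$sites$pos,
                    pi = pi, n_called = n, stringsAsFactors = FALSE)
  out[n >= 2, , drop = FALSE]
}

#' Windowed nucleotide diversity
#'
#' Sliding windows (default 100 kb with a 10-kb step). The window value is
#' the sum of sitewise pi divided by the full window length in bp —
#' monomorphic and uncalled positions contribute 0 to the numerator but
#' their full length to the denominator, the convention of the common
#' windowed-diversity tools. `denominator = "called"` divides by the number
#' of track positions in the window instead.
#'
#' @param track data.frame from [sitewise_pi()]
#' @param window window size in bp
#' @param step step size in bp
#' @param denominator `"window"` (full length) or `"called"`
#' @return data.frame: chrom, start, end (1-based, inclusive), pi, n_sites
#' @export
windowed_pi <- function(track, window = 100000L, step = 10000L,
                        denominator = c("window", "called")) {
  denominator <- match.arg(denominator)
  out <- NULL
  for (ch in unique(track$chrom)) {
    t_ch <- track[track$chrom == ch, ]
    max_pos <- max(t_ch$pos)
    starts <- seq(0L, max(0L, max_pos - 1L), by = step)
    for (s in starts) {
      in_w <- t_ch$pos > s & t_ch$pos <= s + window
      den <- if (denominator == "window") window else max(1L, sum(in_w))
      out <- rbind(out, data.frame(chrom = ch, start = s + 1L,
                                   end = s + window,
                                   pi = sum(t_ch$pi[in_w]) / den,
                                   n_sites = sum(in_w)))
    }
  }
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), pi = numeric(0), n_sites = integer(0))
  out
}

#' Tajima's D
#'
#' Standardized difference between the pairwise-diversity and
#' segregating-sites estimators of theta, with the standard a1, a2, b1, b2,
#' c1, c2, e1, e2 constants. With missing data the sequence count n is taken
#' as the rounded mean called-allele count over segregating sites.
#'
#' @param vt a `variant_table`
#' @param samples optional sample subset
#' @return D as a numeric scalar; `NA` (undefined) when there are no
#'   segregating sites, with attributes `theta_pi`, `theta_w`, `S`, `n`
#' @export
tajimas_d <- function(vt, samples = NULL) {
  track <- sitewise_pi(vt, samples = samples)
  seg <- track$pi > 0
  S <- sum(seg)
  if (S == 0) {
    out <- NA_real_
    attr(out, "S") <- 0L
    return(out)
  }
  n <- round(mean(track$n_called[seg]))
  if (n < 4) stop("Tajima's D needs at least 4 sequences")
  theta_pi <- sum(track$pi)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  theta_w <- S / a1
  D <- (theta_pi - theta_w) / sqrt(e1 * S + e2 * S * (S - 1))
  attr(D, "theta_pi") <- theta_pi
  attr(D, "theta_w") <- theta_w
  attr(D, "S") <- S
  attr(D, "n") <- n
  D
}

#' Called-site counts: the pi_n / pi_s denominators
#'
#' Counts of confidently called positions (from an all-sites genotyping run
#' that includes monomorphic positions) inside high-quality gene models and
#' in intergenic space.
#'
#' @param n_called_hq called positions inside high-quality gene-model CDS
#' @param n_called_intergenic called positions outside all gene models
#' @return a `called_site_counts` list
#' @export
called_site_counts <- function(n_called_hq, n_called_intergenic) {
  stopifnot(n_called_hq >= 0, n_called_intergenic >= 0)
  structure(list(n_called_hq = n_called_hq,
                 n_called_intergenic = n_called_intergenic),
            class = "called_site_counts")
}

#' Count called positions from an all-sites variant table
#'
#' @param vt_allsites a `variant_table` from all-sites genotyping (monomorphic
#'   positions included), already hard-filtered with the same thresholds as
#'   the variant-only table
#' @param hq_models high-quality `gene_model_set` (CDS intervals are counted)
#' @param all_models full `gene_model_set` (gene spans define "genic" for the
#'   intergenic complement)
#' @param samples optional population subset; a position counts as called
#'   when at least `min_called` genotypes are called in the subset
#' @param min_called minimum called genotypes
#' @return a [called_site_counts()] object
#' @export
count_called_sites <- function(vt_allsites, hq_models, all_models,
                               samples = NULL, min_called = 1L) {
  if (!is.null(samples)) vt_allsites <- vt_subset(vt_allsites, samples = samples)
  called <- rowSums(!is.na(vt_allsites$geno_a) &
                    !is.na(vt_allsites$geno_b)) >= min_called
  pos <- GenomicRanges::GRanges(vt_allsites$sites$chrom,
           IRanges::IRanges(vt_allsites$sites$pos, vt_allsites$sites$pos))
  cds_gr <- .models_granges(hq_models, "cds")
  gene_gr <- .models_granges(all_models, "span")
  in_cds <- IRanges::overlapsAny(pos, cds_gr)
  in_gene <- IRanges::overlapsAny(pos, gene_gr)
  called_site_counts(sum(called & in_cds), sum(called & !in_gene))
}

.models_granges <- function(models, what = c("span", "cds", "exons")) {
  what <- match.arg(what)
  if (!length(models))
    return(GenomicRanges::GRanges())
  if (what == "span") {
    spans <- t(vapply(models, function(m) range(c(m$exons, m$cds)), numeric(2)))
    GenomicRanges::GRanges(vapply(models, function(m) m$chrom, character(1)),
                           IRanges::IRanges(spans[, 1], spans[, 2]))
  } else {
    chroms <- unlist(lapply(models, function(m)
      rep(m$chrom, nrow(m[[what]]))))
    ivs <- do.call(rbind, lapply(models, function(m) m[[what]]))
    GenomicRanges::GRanges(chroms, IRanges::IRanges(ivs[, 1], ivs[, 2]))
  }
}

#' pi_n / pi_s with called-site normalization
#'
#' The mutational-load estimator: pi_n sums sitewise diversity at sites with
#' HIGH or MODERATE effect annotation inside high-quality gene models and
#' divides by two-thirds of the called positions in those models (the
#' operational assumption that every third coding position is synonymous);
#' pi_s sums diversity at intergenic sites — all gene-model regions filtered
#' out — and divides by the intergenic called positions.
#'
#' @param vt a `variant_table` of variant sites
#' @param impact_calls data.frame from [classify_variant_effects()] computed
#'   against the high-quality models, one row per site of `vt` in order
#' @param hq_models high-quality `gene_model_set`
#' @param all_models full `gene_model_set` (intergenic complement); defaults
#'   to `hq_models`
#' @param called a [called_site_counts()] object
#' @param samples optional population subset applied before diversity
#'   computation
#' @return list: `pi_n`, `pi_s`, `ratio` (NA when pi_s is 0 or undefined),
#'   `sum_diversity_nonsyn`, `sum_diversity_intergenic`, and the denominators
#'   used
#' @export
pin_pis <- function(vt, impact_calls, hq_models, called, all_models = hq_models,
                    samples = NULL) {
  stopifnot(inherits(called, "called_site_counts"),
            nrow(impact_calls) == n_sites(vt))
  sub <- if (!is.null(samples)) vt_subset(vt, samples = samples) else vt
  track <- sitewise_pi(sub)
  key <- paste(sub$sites$chrom, sub$sites$pos)
  pi_site <- stats::setNames(rep(0, n_sites(sub)), key)
  pi_site[paste(track$chrom, track$pos)] <- track$pi
  # impact_calls rows align with vt sites; map through chrom:pos keys
  call_key <- paste(impact_calls$chrom, impact_calls$pos)
  nonsyn <- impact_calls$impact %in% c("HIGH", "MODERATE") &
    !is.na(impact_calls$gene_id)
  pos_gr <- GenomicRanges::GRanges(impact_calls$chrom,
              IRanges::IRanges(impact_calls$pos, impact_calls$pos))
  in_gene <- IRanges::overlapsAny(pos_gr, .models_granges(all_models, "span"))
  sum_n <- sum(pi_site[call_key[nonsyn]], na.rm = TRUE)
  sum_s <- sum(pi_site[call_key[!in_gene]], na.rm = TRUE)
  den_n <- called$n_called_hq * 2 / 3
  den_s <- called$n_called_intergenic
  pi_n <- if (den_n > 0) sum_n / den_n else NA_real_
  pi_s <- if (den_s > 0) sum_s / den_s else NA_real_
  ratio <- if (!is.na(pi_s) && pi_s > 0 && !is.na(pi_n)) pi_n / pi_s
           else NA_real_
  list(pi_n = pi_n, pi_s = pi_s, ratio = ratio,
       sum_diversity_nonsyn = sum_n, sum_diversity_intergenic = sum_s,
       denominator_nonsyn = den_n, denominator_intergenic = den_s)
}

# Weir & Cockerham (1984) per-site variance components a, b, c for one
# biallelic site across r populations. freq/het/n are per-population:
# alt-allele frequency, observed heterozygote fraction, called diploids.
.wc_components <- function(p_i, h_i, n_i) {
  r <- length(n_i)
  n_bar <- mean(n_i)
  if (n_bar <= 1) return(c(a = NA, b = NA, c = NA))
  nc <- (r * n_bar - sum(n_i^2) / (r * n_bar)) / (r - 1)
  p_bar <- sum(n_i * p_i) / (r * n_bar)
  s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- sum(n_i * h_i) / (r * n_bar)
  a <- (n_bar / nc) *
    (s2 - (p_bar * (1 - p_bar) - s2 * (r - 1) / r - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - s2 * (r - 1) / r -
       h_bar * (2 * n_bar - 1) / (4 * n_bar))
  cc <- h_bar / 2
  c(a = a, b = b, c = cc)
}

#' Weir-Cockerham F_ST in windows and genome-wide
#'
#' Per-site variance components a (among populations), b (among individuals
#' within populations) and c (within individuals) following Weir & Cockerham
#' (1984); the window and genome-wide estimates are the weighted
#' (ratio-of-sums) form theta = sum(a) / sum(a + b + c). Sites monomorphic
#' across all populations, or with fewer than one called diploid in any
#' population, are skipped.
#'
#' @param vt a `variant_table` (biallelic SNPs)
#' @param populations named list: population -> character vector of samples
#' @param window window size in bp (boundaries at multiples of the size)
#' @return list with `windows` (chrom, start, end, theta, n_sites),
#'   `global` (genome-wide weighted theta) and `per_site` components
#' @export
weir_cockerham_fst <- function(vt, populations, window = 100000L) {
  stopifnot(length(populations) >= 2)
  dos <- vt_dosage(vt)
  ns <- n_sites(vt)
  r <- length(populations)
  p_i <- h_i <- n_i <- matrix(NA_real_, ns, r)
  for (k in seq_len(r)) {
    d <- dos[, populations[[k]], drop = FALSE]
    n_i[, k] <- rowSums(!is.na(d))
    p_i[, k] <- rowMeans(d, na.rm = TRUE) / 2
    h_i[, k] <- rowMeans(d == 1L, na.rm = TRUE)
  }
  usable <- rowSums(n_i >= 1) == r
  p_all <- rowSums(p_i * n_i, na.rm = TRUE) / rowSums(n_i, na.rm = TRUE)
  usable <- usable & p_all > 0 & p_all < 1
  comp <- matrix(NA_real_, ns, 3, dimnames = list(NULL, c("a", "b", "c")))
  for (i in which(usable))
    comp[i, ] <- .wc_components(p_i[i, ], h_i[i, ], n_i[i, ])
  ok <- usable & !is.na(comp[, 1])
  per_site <- data.frame(chrom = vt$sites$chrom, pos = vt$sites$pos,
                         a = comp[, "a"], b = comp[, "b"], c = comp[, "c"])
  glob <- sum(comp[ok, "a"]) / sum(comp[ok, ])
  wins <- NULL
  for (ch in unique(vt$sites$chrom)) {
    sel <- ok & vt$sites$chrom == ch
    if (!any(sel)) next
    w_idx <- (vt$sites$pos[sel] - 1L) %/% window
    for (w in sort(unique(w_idx))) {
      rows <- which(sel)[w_idx == w]
      wins <- rbind(wins, data.frame(chrom = ch, start = w * window + 1L,
                                     end = (w + 1L) * window,
                                     theta = sum(comp[rows, "a"]) /
                                       sum(comp[rows, ]),
                                     n_sites = length(rows)))
    }
  }
  list(windows = wins, global = glob, per_site = per_site)
}

#' Pairwise LD and its decay with distance
#'
#' r-squared is the squared correlation of genotype dosages for every site
#' pair within `max_dist` on the same chromosome, after requiring minor
#' allele count greater than `mac_min`. Pairs with r^2 above `r2_min` are
#' reported and a linear model r^2 ~ log10(distance) is fitted to them; the
#' "initial value" r0 is the fitted value at the smallest observed distance
#' and the half-decay distance is where the fit drops to half of r0.
#'
#' @param vt a `variant_table`
#' @param samples optional sample subset
#' @param max_dist maximum pair distance in bp
#' @param r2_min report pairs with r^2 strictly above this
#' @param mac_min minor allele count must exceed this (strict)
#' @return list of class `ld_decay`: `pairs` (distance, r2), `beta0`,
#'   `beta1`, `d_min`, `r0`, `half_decay` (NA when the fitted slope is not
#'   negative or no pairs survive)
#' @export
ld_decay <- function(vt, samples = NULL, max_dist = 500000L, r2_min = 0.01,
                     mac_min = 4L) {
  if (!is.null(samples)) vt <- vt_subset(vt, samples = samples)
  dos <- vt_dosage(vt)
  alt_count <- rowSums(dos, na.rm = TRUE)
  n_called2 <- 2L * rowSums(!is.na(dos))
  mac <- pmin(alt_count, n_called2 - alt_count)
  keep <- mac > mac_min
  vt <- vt_subset(vt, sites = keep); dos <- dos[keep, , drop = FALSE]
  dists <- r2s <- numeric(0)
  for (ch in unique(vt$sites$chrom)) {
    idx <- which(vt$sites$chrom == ch)
    pos <- vt$sites$pos[idx]
    for (ii in seq_along(idx)) {
      jj <- which(pos > pos[ii] & pos - pos[ii] <= max_dist)
      for (j in jj) {
        r <- suppressWarnings(stats::cor(dos[idx[ii], ], dos[idx[j], ],
                                         use = "pairwise.complete.obs"))
        if (is.na(r)) next
        dists <- c(dists, pos[j] - pos[ii]); r2s <- c(r2s, r^2)
      }
    }
  }
  rep_sel <- r2s > r2_min
  pairs <- data.frame(distance = dists[rep_sel], r2 = r2s[rep_sel])
  out <- list(pairs = pairs, beta0 = NA_real_, beta1 = NA_real_,
              d_min = NA_real_, r0 = NA_real_, half_decay = NA_real_)
  if (nrow(pairs) >= 2 && length(unique(pairs$distance)) >= 2) {
    fit <- stats::lm(r2 ~ log10(distance), data = pairs)
    out$beta0 <- unname(stats::coef(fit)[1])
    out$beta1 <- unname(stats::coef(fit)[2])
    out$d_min <- min(pairs$distance)
    out$r0 <- out$beta0 + out$beta1 * log10(out$d_min)
    out$half_decay <- half_decay(out)
  }
  class(out) <- "ld_decay"
  out
}

#' Half-decay distance of an LD curve
#'
#' Inverts the fitted line r^2 = beta0 + beta1 log10(d) at half the initial
#' value: d_half = 10^((r0/2 - beta0)/beta1). Undefined (NA) when the slope
#' is not negative.
#'
#' @param curve an `ld_decay` object (or list with beta0, beta1, r0)
#' @return distance in bp, or NA
#' @export
half_decay <- function(curve) {
  if (is.na(curve$beta1) || curve$beta1 >= 0) return(NA_real_)
  10^((0.5 * curve$r0 - curve$beta0) / curve$beta1)
}

#' LD pruning in SNP-count windows
#'
#' Within each sliding window of `window` SNPs (advancing by `step` SNPs),
#' any pair with r^2 above `r2_max` loses one member: the lower-MAF SNP is
#' removed first, ties broken by removing the larger coordinate.
#'
#' @param vt a `variant_table`
#' @param window window size in SNPs
#' @param step step in SNPs
#' @param r2_max maximum tolerated r^2
#' @return a pruned `variant_table`
#' @export
ld_prune <- function(vt, window = 50L, step = 10L, r2_max = 0.1) {
  dos <- vt_dosage(vt)
  alt_count <- rowSums(dos, na.rm = TRUE)
  n2 <- 2L * rowSums(!is.na(dos))
  maf <- pmin(alt_count, n2 - alt_count) / pmax(n2, 1L)
  removed <- rep(FALSE, n_sites(vt))
  for (ch in unique(vt$sites$chrom)) {
    idx <- which(vt$sites$chrom == ch)
    starts <- seq(1L, max(1L, length(idx)), by = step)
    for (s in starts) {
      w <- idx[s:min(s + window - 1L, length(idx))]
      w <- w[!removed[w]]
      if (length(w) < 2) next
      for (ii in seq_len(length(w) - 1)) for (j in seq(ii + 1, length(w))) {
        i1 <- w[ii]; i2 <- w[j]
        if (removed[i1] || removed[i2]) next
        r <- suppressWarnings(stats::cor(dos[i1, ], dos[i2, ],
                                         use = "pairwise.complete.obs"))
        if (is.na(r) || r^2 <= r2_max) next
        drop <- if (maf[i1] < maf[i2]) i1
                else if (maf[i2] < maf[i1]) i2
                else max(i1, i2)   # tie: larger coordinate goes
        removed[drop] <- TRUE
      }
    }
  }
  vt_subset(vt, sites = !removed)
}

#' f3 admixture statistic with block-jackknife errors
#'
#' f3(C; A, B) averages (c - a)(c - b) over sites, where a, b, c are sample
#' allele frequencies; a significantly negative value indicates that the
#' target C is admixed between sources related to A and B. The finite-sample
#' bias from sampling noise in c is removed (toggleable) by subtracting
#' c(1 - c)/(n_C - 1) per site, the unbiased-heterozygosity correction, with
#' n_C the called allele count in the target. Standard errors come from a
#' delete-one block jackknife over contiguous site blocks.
#'
#' @param vt a `variant_table`
#' @param target,source_a,source_b character vectors of sample ids
#' @param block_size sites per jackknife block
#' @param correction apply the finite-sample correction for C
#' @return list: `f3`, `se` (NA with fewer than 2 blocks), `z`, `n_sites`,
#'   `n_blocks`
#' @export
f3_statistic <- function(vt, target, source_a, source_b, block_size = 5000L,
                         correction = TRUE) {
  freq <- function(ids) {
    sub <- vt_subset(vt, samples = ids)
    f <- vt_allele_freq(sub)
    list(p = f$p_alt, n = f$n_called)
  }
  fa <- freq(source_a); fb <- freq(source_b); fc <- freq(target)
  ok <- !is.na(fa$p) & !is.na(fb$p) & !is.na(fc$p)
  if (correction) ok <- ok & fc$n >= 2
  site_f3 <- (fc$p - fa$p) * (fc$p - fb$p)
  if (correction)
    site_f3 <- site_f3 - fc$p * (1 - fc$p) / (fc$n - 1)
  site_f3 <- site_f3[ok]
  m <- length(site_f3)
  f3 <- mean(site_f3)
  blocks <- split(site_f3, ceiling(seq_len(m) / block_size))
  B <- length(blocks)
  if (B < 2) return(list(f3 = f3, se = NA_real_, z = NA_real_,
                         n_sites = m, n_blocks = B))
  total <- sum(site_f3)
  loo <- vapply(blocks, function(bl) (total - sum(bl)) / (m - length(bl)),
                numeric(1))
  se <- sqrt((B - 1) / B * sum((loo - mean(loo))^2))
  list(f3 = f3, se = se, z = f3 / se, n_sites = m, n_blocks = B)
}

#' Method-of-moments inbreeding coefficient per sample
#'
#' F = (O_hom - E_hom) / (L - E_hom), where O_hom is the observed count of
#' homozygous genotypes over the L sites called in the sample and E_hom sums
#' the per-site Hardy-Weinberg expectation 1 - 2 p q n/(n - 1) computed from
#' the sample allele frequency p and called allele count n at each site.
#' F1 hybrids of diverged populations show the diagnostic negative values
#' (excess heterozygosity).
#'
#' @param vt a `variant_table` (biallelic sites)
#' @param samples samples to report (default all)
#' @return named numeric vector of F
#' @export
inbreeding_coefficient <- function(vt, samples = NULL) {
  if (is.null(samples)) samples <- vt$samples
  f <- vt_allele_freq(vt)
  usable <- f$n_called >= 2
  p <- f$p_alt; n <- f$n_called
  e_hom_site <- 1 - 2 * p * (1 - p) * n / (n - 1)
  dos <- vt_dosage(vt)
  vapply(samples, function(s) {
    d <- dos[, s]
    use <- usable & !is.na(d)
    L <- sum(use)
    e_hom <- sum(e_hom_site[use])
    o_hom <- sum(d[use] != 1L)
    if (L - e_hom == 0) return(NA_real_)
    (o_hom - e_hom) / (L - e_hom)
  }, numeric(1))
}
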