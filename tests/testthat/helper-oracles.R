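# Independent brute-force oracles. These deliberately avoid the package's
# code paths: pair enumeration for pi, direct constant evaluation for
# Tajima's D, the 1984 component formulas written out long-hand for F_ST,
# explicit sums for r^2, and recursive per-codon path enumeration for NG86.

# pi at one site: enumerate every unordered pair of called alleles
oracle_site_pi <- function(alleles) {
  alleles <- alleles[!is.na(alleles)]
  n <- length(alleles)
  if (n < 2) return(NA_real_)
  diff <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
    if (alleles[i] != alleles[j]) diff <- diff + 1
  diff / choose(n, 2)
}

oracle_pi_track <- function(vt) {
  sapply(seq_len(nrow(vt$sites)), function(i)
    oracle_site_pi(c(vt$geno_a[i, ], vt$geno_b[i, ])))
}

# Tajima's D from n haplotypes and per-site pi values (complete data)
oracle_tajima <- function(n, site_pi) {
  S <- sum(site_pi > 0)
  if (S == 0) return(NA_real_)
  th_pi <- sum(site_pi)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (th_pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Weir & Cockerham 1984, per-site a/b/c, written independently
oracle_wc_site <- function(geno_by_pop) {
  # geno_by_pop: list of dosage vectors (0/1/2, NA = missing)
  r <- length(geno_by_pop)
  n_i <- p_i <- h_i <- numeric(r)
  for (k in seq_len(r)) {
    d <- geno_by_pop[[k]][!is.na(geno_by_pop[[k]])]
    n_i[k] <- length(d)
    p_i[k] <- sum(d) / (2 * length(d))
    h_i[k] <- mean(d == 1)
  }
  if (any(n_i < 1)) return(NULL)
  nbar <- sum(n_i) / r
  if (nbar <= 1) return(NULL)
  pbar <- sum(n_i * p_i) / (r * nbar)
  if (pbar <= 0 || pbar >= 1) return(NULL)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a, b, cc)
}

oracle_wc_global <- function(vt, pops) {
  dos <- vt_dosage(vt)
  num <- den <- 0
  for (i in seq_len(nrow(dos))) {
    comp <- oracle_wc_site(lapply(pops, function(s) dos[i, s]))
    if (is.null(comp)) next
    num <- num + comp[1]; den <- den + sum(comp)
  }
  num / den
}

# r^2 between two dosage vectors via explicit sums over complete pairs
oracle_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(y^2) - sum(y)^2 / n
  (sxy / sqrt(sxx * syy))^2
}

# ---- NG86 oracle: recursive path enumeration, independent coding --------
oracle_codon_table <- function() Biostrings::GENETIC_CODE

oracle_syn_sites <- function(codon) {
  code <- oracle_codon_table()
  total <- 0
  for (pos in 1:3) for (b in c("A", "C", "G", "T")) {
    if (b == substr(codon, pos, pos)) next
    mut <- paste0(substr(codon, 1, pos - 1), b, substr(codon, pos + 1, 3))
    if (code[[mut]] != "*" && code[[mut]] == code[[codon]])
      total <- total + 1 / 3
  }
  total
}

# all mutation paths from c1 to c2 via recursion; returns matrix of
# (syn, nonsyn) per complete path, skipping intermediate-stop paths
oracle_paths <- function(c1, c2, allow_stop = FALSE) {
  code <- oracle_codon_table()
  res <- list()
  recurse <- function(cur, s, n) {
    if (cur == c2) {
      res[[length(res) + 1]] <<- c(s, n)
      return(invisible())
    }
    for (pos in 1:3) {
      if (substr(cur, pos, pos) == substr(c2, pos, pos)) next
      nxt <- paste0(substr(cur, 1, pos - 1), substr(c2, pos, pos),
                    substr(cur, pos + 1, 3))
      if (!allow_stop && code[[nxt]] == "*" && nxt != c2) next
      if (code[[cur]] == code[[nxt]]) recurse(nxt, s + 1, n)
      else recurse(nxt, s, n + 1)
    }
  }
  recurse(c1, 0, 0)
  if (!length(res)) return(NULL)
  do.call(rbind, res)
}

oracle_ng86 <- function(seq1, seq2) {
  split_codons <- function(s)
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  c1 <- split_codons(seq1); c2 <- split_codons(seq2)
  code <- oracle_codon_table()
  nc <- length(c1)
  if (code[[c1[nc]]] == "*" && code[[c2[nc]]] == "*") {
    c1 <- c1[-nc]; c2 <- c2[-nc]
  }
  S <- (sum(sapply(c1, oracle_syn_sites)) +
        sum(sapply(c2, oracle_syn_sites))) / 2
  N <- 3 * length(c1) - S
  Sd <- Nd <- 0
  for (k in seq_along(c1)) {
    if (c1[k] == c2[k]) next
    paths <- oracle_paths(c1[k], c2[k])
    if (is.null(paths)) paths <- oracle_paths(c1[k], c2[k], allow_stop = TRUE)
    Sd <- Sd + mean(paths[, 1]); Nd <- Nd + mean(paths[, 2])
  }
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(ka = jc(Nd / N), ks = jc(Sd / S), S = S, N = N, Sd = Sd, Nd = Nd)
}

# random in-frame CDS pair without internal stops
random_cds_pair <- function(n_codons, n_mut = 6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)[code != "*"]
  s1 <- sample(codons, n_codons, replace = TRUE)
  s2 <- s1
  idx <- sample(n_codons, min(n_mut, n_codons))
  for (i in idx) {
    repeat {
      cand <- s2[i]
      pos <- sample(3, 1)
      b <- sample(setdiff(c("A", "C", "G", "T"), substr(cand, pos, pos)), 1)
      substr(cand, pos, pos) <- b
      if (code[[cand]] != "*") { s2[i] <- cand; break }
    }
  }
  list(a = paste(s1, collapse = ""), b = paste(s2, collapse = ""))
}
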