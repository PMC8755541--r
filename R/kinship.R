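#' KING-robust kinship for all sample pairs
#'
#' The within-pair estimator that is independent of sample composition and
#' population structure, built from shared-heterozygosity counts over
#' jointly called biallelic sites:
#' phi = (N_AaAa - 2 N_AA,aa) / (2 min(N_Aa_i, N_Aa_j))
#'       + 1/2 - (N_Aa_i + N_Aa_j) / (4 min(N_Aa_i, N_Aa_j)),
#' where N_AaAa counts sites where both samples are heterozygous, N_AA,aa
#' sites with opposite homozygotes, and N_Aa_i / N_Aa_j each sample's
#' heterozygous sites among the jointly called ones. phi is invariant under
#' swapping REF and ALT at any site.
#'
#' @param vt a `variant_table` of biallelic SNPs
#' @param pairs optional 2-column matrix/data.frame of sample ids; default
#'   all unordered pairs
#' @return data.frame of class `kinship_matrix`: sample_i, sample_j, phi
#'   (NA, flagged, when a sample has no heterozygous site in the joint set),
#'   the supporting counts, n_joint, degree, and IBS0/IBS1/IBS2 fractions
#' @export
king_kinship <- function(vt, pairs = NULL) {
  dos <- vt_dosage(vt)
  samples <- vt$samples
  if (is.null(pairs)) {
    if (length(samples) < 2) stop("need at least two samples")
    pairs <- t(utils::combn(samples, 2))
  }
  pairs <- as.matrix(pairs)
  out <- data.frame(sample_i = pairs[, 1], sample_j = pairs[, 2],
                    phi = NA_real_, n_AaAa = NA_integer_,
                    n_AA_aa = NA_integer_, n_Aa_i = NA_integer_,
                    n_Aa_j = NA_integer_, n_joint = NA_integer_,
                    ibs0 = NA_real_, ibs1 = NA_real_, ibs2 = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(pairs))) {
    di <- dos[, pairs[k, 1]]; dj <- dos[, pairs[k, 2]]
    joint <- !is.na(di) & !is.na(dj)
    di <- di[joint]; dj <- dj[joint]
    n_joint <- length(di)
    if (n_joint == 0) stop("no jointly called site for pair ",
                           pairs[k, 1], "/", pairs[k, 2])
    n_aaAA <- sum(abs(di - dj) == 2L)
    n_hethet <- sum(di == 1L & dj == 1L)
    n_het_i <- sum(di == 1L); n_het_j <- sum(dj == 1L)
    mn <- min(n_het_i, n_het_j)
    phi <- if (mn == 0) NA_real_ else
      (n_hethet - 2 * n_aaAA) / (2 * mn) + 0.5 -
        (n_het_i + n_het_j) / (4 * mn)
    out$phi[k] <- phi
    out$n_AaAa[k] <- n_hethet; out$n_AA_aa[k] <- n_aaAA
    out$n_Aa_i[k] <- n_het_i; out$n_Aa_j[k] <- n_het_j
    out$n_joint[k] <- n_joint
    ibs <- abs(di - dj)
    out$ibs0[k] <- n_aaAA / n_joint
    out$ibs1[k] <- sum(ibs == 1L) / n_joint
    out$ibs2[k] <- sum(ibs == 0L) / n_joint
  }
  out$degree <- classify_relationship(out$phi)
  class(out) <- c("kinship_matrix", "data.frame")
  out
}

#' Relationship degree from a kinship coefficient
#'
#' The standard powers-of-two bins with cutoffs at 2^-(d + 3/2):
#' duplicate/monozygotic above 0.3536, 1st degree in (0.1768, 0.3536\],
#' 2nd in (0.0884, 0.1768\], 3rd in (0.0442, 0.0884\], unrelated below.
#'
#' @param phi numeric vector of kinship coefficients (NA passes through)
#' @return character vector over duplicate/1/2/3/unrelated
#' @export
classify_relationship <- function(phi) {
  cut_dup <- 2^(-3 / 2); cut1 <- 2^(-5 / 2); cut2 <- 2^(-7 / 2)
  cut3 <- 2^(-9 / 2)
  out <- ifelse(phi > cut_dup, "duplicate",
         ifelse(phi > cut1, "1",
         ifelse(phi > cut2, "2",
         ifelse(phi > cut3, "3", "unrelated"))))
  out[is.na(phi)] <- NA_character_
  out
}

#' Closest-relative graph
#'
#' For each sample, a directed edge to its highest-phi partner, provided
#' that phi is positive (ties broken by lexical order of the partner id);
#' samples whose best phi is non-positive stay isolated. Node annotations
#' (cultivar group, geography) are carried from the sample sheet when given.
#'
#' @param km a `kinship_matrix` from [king_kinship()]
#' @param sheet optional sample sheet data.frame
#' @return list of class `relative_graph`: `edges` (from, to, phi, degree)
#'   and `nodes` (sample plus annotations)
#' @export
closest_relative_graph <- function(km, sheet = NULL) {
  samples <- sort(unique(c(km$sample_i, km$sample_j)))
  edges <- NULL
  for (s in samples) {
    rows <- which(km$sample_i == s | km$sample_j == s)
    partner <- ifelse(km$sample_i[rows] == s, km$sample_j[rows],
                      km$sample_i[rows])
    phi <- km$phi[rows]
    keep <- !is.na(phi) & phi > 0
    if (!any(keep)) next
    partner <- partner[keep]; phi <- phi[keep]; deg <- km$degree[rows][keep]
    ord <- order(-phi, partner)      # max phi, ties by lexical partner id
    edges <- rbind(edges, data.frame(from = s, to = partner[ord[1]],
                                     phi = phi[ord[1]],
                                     degree = deg[ord[1]],
                                     stringsAsFactors = FALSE))
  }
  nodes <- data.frame(sample = samples, stringsAsFactors = FALSE)
  if (!is.null(sheet)) {
    m <- match(samples, sheet$sample_id)
    nodes$cultivar_group <- sheet$cultivar_group[m]
    nodes$geography <- sheet$geography[m]
  }
  structure(list(edges = if (is.null(edges))
                   data.frame(from = character(0), to = character(0),
                              phi = numeric(0), degree = character(0))
                 else edges,
                 nodes = nodes),
            class = "relative_graph")
}

#' Export a relative graph in DOT format
#' @param graph a `relative_graph`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_graph_dot <- function(graph, path) {
  lab <- graph$nodes$sample
  if (!is.null(graph$nodes$cultivar_group))
    lab <- paste0(lab, "\\n", graph$nodes$cultivar_group)
  lines <- c("digraph relatives {",
             sprintf("  \"%s\" [label=\"%s\"];", graph$nodes$sample, lab),
             sprintf("  \"%s\" -> \"%s\" [label=\"phi=%.3f deg=%s\"];",
                     graph$edges$from, graph$edges$to, graph$edges$phi,
                     graph$edges$degree),
             "}")
  writeLines(lines, path)
  invisible(path)
}
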