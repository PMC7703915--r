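## Adjacency-constrained hierarchical clustering of SNPs along a chromosome
## and the exclusion window around the target SNP.

#' Adjacency-constrained hierarchical clustering of SNPs
#'
#' Agglomerative clustering restricted to physically adjacent clusters.
#' The dissimilarity between two adjacent clusters is 1 minus the maximum
#' absolute Pearson correlation between their member SNPs' dosage vectors;
#' merging proceeds greedily (smallest dissimilarity first, leftmost pair on
#' ties) and stops when no adjacent pair reaches \code{corrThreshold} in
#' maximum absolute correlation. Correlations are computed on all samples
#' (cases and controls), since the LD structure concerns the general
#' population. Zero-variance SNP columns are treated as uncorrelated with
#' everything (with a warning).
#'
#' @param ds an imputed \linkS4class{GenotypeData}.
#' @param chromosome chromosome identifier to cluster.
#' @param corrThreshold maximum-correlation merge threshold (default 0.5).
#' @return A \linkS4class{ClusterMap}.
#' @export
adjacencyCluster <- function(ds, chromosome, corrThreshold = 0.5) {
  rd <- snpInfo(ds)
  snpIdx <- which(rd$chromosome == chromosome)
  m <- length(snpIdx)
  if (m < 2L) stop("need at least 2 SNPs on chromosome ", chromosome)
  g <- t(dosages(ds)[snpIdx, , drop = FALSE])   # samples x SNPs, physical order
  sds <- apply(g, 2, stats::sd)
  if (any(sds == 0))
    warning(sum(sds == 0), " constant SNP column(s) treated as correlation 0")
  cc <- suppressWarnings(abs(stats::cor(g)))
  cc[!is.finite(cc)] <- 0

  ## clusters as index ranges; track max |r| between adjacent clusters
  starts <- seq_len(m); ends <- seq_len(m)
  adj <- if (m > 1) vapply(seq_len(m - 1),
                           function(i) cc[i, i + 1], numeric(1)) else numeric(0)
  while (length(adj) > 0 && max(adj) >= corrThreshold) {
    i <- which.max(adj)              # leftmost maximal pair on ties
    starts <- starts[-(i + 1)]
    ends <- ends[-i]
    adj <- adj[-i]
    nc <- length(starts)
    if (i > 1)
      adj[i - 1] <- max(cc[starts[i - 1]:ends[i - 1], starts[i]:ends[i]])
    if (i <= length(adj))
      adj[i] <- max(cc[starts[i]:ends[i], starts[i + 1]:ends[i + 1]])
  }
  labels <- integer(m)
  for (k in seq_along(starts)) labels[starts[k]:ends[k]] <- k
  methods::new("ClusterMap", chromosome = as.character(chromosome),
               snpIndex = as.integer(snpIdx), labels = labels,
               boundaries = IRanges::IRanges(start = starts, end = ends))
}

#' SNP indices inside the exclusion window around the target
#'
#' Returns the (dataset) row indices of all SNPs in the target's own
#' cluster plus \code{width} clusters on each side, truncated at the
#' chromosome ends. These SNPs are in strong LD with the target: they are
#' removed both from the propensity conditioning set and from every
#' downstream interaction design.
#'
#' @param cm a \linkS4class{ClusterMap}.
#' @param targetIndex dataset row index of the target SNP (must lie on
#'   \code{cm}'s chromosome).
#' @param width number of clusters excluded on each side (default 3).
#' @return Sorted integer vector of excluded SNP row indices (always
#'   containing the target).
#' @export
exclusionWindow <- function(cm, targetIndex, width = 3L) {
  pos <- match(targetIndex, cm@snpIndex)
  if (is.na(pos)) stop("target is not on chromosome ", cm@chromosome)
  tc <- cm@labels[pos]
  keep <- cm@labels >= tc - width & cm@labels <= tc + width
  sort(cm@snpIndex[keep])
}
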