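#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' GenotypeData: a cohort of SNP dosages with sample phenotypes
#'
#' Thin wrapper around \linkS4class{SummarizedExperiment} holding one assay
#' \code{"dosage"} (SNPs in rows, samples in columns, minor-allele counts in
#' \{0, 1, 2\}, \code{NA} for missing). \code{rowData} carries the SNP records
#' (\code{snp}, \code{chromosome}, \code{position}, \code{allele1},
#' \code{allele2}); \code{colData} carries \code{sample} ids and the
#' \code{phenotype} (0/1 for case-control, or a non-negative continuous
#' trait, \code{NA} for missing).
#'
#' @slot .
#' See \code{\link{GenotypeData}} for the constructor.
#'
#' @export
setClass("GenotypeData", contains = "SummarizedExperiment")

.validGenotypeData <- function(object) {
  msg <- character(0)
  if (!("dosage" %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assay 'dosage' is required")
  g <- SummarizedExperiment::assay(object, "dosage")
  if (nrow(g) < 1L || ncol(g) < 1L)
    msg <- c(msg, "at least one SNP and one sample are required")
  bad <- !is.na(g) & !(g %in% c(0, 1, 2))
  if (any(bad))
    msg <- c(msg, "dosages must be in {0, 1, 2} or NA")
  rd <- SummarizedExperiment::rowData(object)
  need <- c("snp", "chromosome", "position")
  if (!all(need %in% colnames(rd))) {
    msg <- c(msg, "rowData must contain 'snp', 'chromosome', 'position'")
  } else {
    if (anyDuplicated(rd$snp))
      msg <- c(msg, "SNP ids must be unique")
    for (chr in unique(rd$chromosome)) {
      pos <- rd$position[rd$chromosome == chr]
      if (is.unsorted(pos))
        msg <- c(msg, sprintf("positions must be non-decreasing on chromosome %s", chr))
    }
  }
  if (!("phenotype" %in% colnames(SummarizedExperiment::colData(object))))
    msg <- c(msg, "colData must contain 'phenotype'")
  if (length(msg)) msg else TRUE
}
setValidity("GenotypeData", .validGenotypeData)

#' Construct a GenotypeData object
#'
#' @param dosage numeric matrix of minor-allele counts, SNPs x samples,
#'   entries in \{0, 1, 2\} or \code{NA}.
#' @param snps data.frame-like with columns \code{snp}, \code{chromosome},
#'   \code{position} and optionally \code{allele1}, \code{allele2}; one row
#'   per SNP, in the row order of \code{dosage}.
#' @param samples data.frame-like with columns \code{sample} and
#'   \code{phenotype}, one row per sample.
#' @return A \linkS4class{GenotypeData} object.
#' @examples
#' g <- matrix(c(0, 1, 2, 1, 0, 2), nrow = 3)
#' gd <- GenotypeData(g,
#'   snps = data.frame(snp = c("rs1", "rs2", "rs3"), chromosome = "1",
#'                     position = c(100, 200, 300)),
#'   samples = data.frame(sample = c("s1", "s2"), phenotype = c(0, 1)))
#' dosages(gd)
#' @export
GenotypeData <- function(dosage, snps, samples) {
  dosage <- as.matrix(dosage)
  snps <- S4Vectors::DataFrame(snps)
  samples <- S4Vectors::DataFrame(samples)
  if (!("allele1" %in% colnames(snps))) snps$allele1 <- "A"
  if (!("allele2" %in% colnames(snps))) snps$allele2 <- "B"
  rownames(dosage) <- snps$snp
  colnames(dosage) <- samples$sample
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosage), rowData = snps, colData = samples)
  methods::new("GenotypeData", se)
}

#' TargetEncoding: a target SNP binarized to {-1, +1}
#'
#' @slot targetId character(1), the id of the target SNP.
#' @slot targetIndex integer(1), its row index in the parent dataset.
#' @slot rule character(1), \code{"dominant"} (dosage 1 or 2 maps to +1) or
#'   \code{"recessive"} (only dosage 2 maps to +1).
#' @slot A numeric vector in \{-1, +1\}, one entry per sample.
#' @slot aTilde numeric vector in \{0, 1\}, equal to (A + 1) / 2.
#' @export
setClass("TargetEncoding",
  representation(targetId = "character", targetIndex = "integer",
                 rule = "character", A = "numeric", aTilde = "numeric"))

setValidity("TargetEncoding", function(object) {
  msg <- character(0)
  if (!object@rule %in% c("dominant", "recessive"))
    msg <- c(msg, "rule must be 'dominant' or 'recessive'")
  if (!all(object@A %in% c(-1, 1)))
    msg <- c(msg, "A must take values in {-1, +1}")
  if (!isTRUE(all.equal(object@aTilde, (object@A + 1) / 2)))
    msg <- c(msg, "aTilde must equal (A + 1)/2")
  if (length(msg)) msg else TRUE
})

#' ClusterMap: adjacency-constrained SNP clusters on one chromosome
#'
#' @slot chromosome character(1).
#' @slot snpIndex integer, the row indices (in the parent dataset) of the
#'   chromosome's SNPs in physical order.
#' @slot labels integer, per-SNP cluster label, non-decreasing along the
#'   chromosome, starting at 1.
#' @slot boundaries an \linkS4class{IRanges}: one range of positions (into
#'   \code{snpIndex}) per cluster.
#' @export
setClass("ClusterMap",
  representation(chromosome = "character", snpIndex = "integer",
                 labels = "integer", boundaries = "IRanges"))

setValidity("ClusterMap", function(object) {
  msg <- character(0)
  if (length(object@labels) != length(object@snpIndex))
    msg <- c(msg, "one label per SNP required")
  if (is.unsorted(object@labels))
    msg <- c(msg, "labels must be non-decreasing along the chromosome")
  covered <- sum(IRanges::width(object@boundaries))
  if (covered != length(object@snpIndex))
    msg <- c(msg, "cluster boundaries must partition the chromosome")
  if (length(msg)) msg else TRUE
})

#' GenotypeHMM: haplotype-cluster hidden Markov model for LD
#'
#' The generative model behind fastPHASE/HAPGEN: each individual carries two
#' independent haplotype paths over K latent clusters; between adjacent
#' sites a path jumps with probability \code{rho[s]} to a cluster drawn from
#' \code{alpha[s, ]}, otherwise it stays; each site emits a minor allele
#' with cluster-specific probability \code{theta[s, k]}, and the observed
#' genotype is the sum of the two emitted alleles.
#'
#' @slot K integer(1), number of haplotype clusters.
#' @slot sites integer, ordered SNP row indices (one chromosome).
#' @slot alpha S x K matrix of cluster weights, rows sum to 1.
#' @slot theta S x K matrix of minor-allele emission frequencies in (0, 1).
#' @slot rho numeric(S), jump probabilities; rho[1] is fixed at 1 so the
#'   first site draws from alpha[1, ].
#' @slot logLik numeric(1), observed-data log-likelihood at the fit.
#' @slot logLikTrace numeric, per-iteration observed-data log-likelihood of
#'   the winning EM run (non-decreasing up to arithmetic noise).
#' @slot nIter integer(1), EM iterations run.
#' @export
setClass("GenotypeHMM",
  representation(K = "integer", sites = "integer", alpha = "matrix",
                 theta = "matrix", rho = "numeric", logLik = "numeric",
                 logLikTrace = "numeric", nIter = "integer"))

setValidity("GenotypeHMM", function(object) {
  msg <- character(0)
  S <- length(object@sites)
  if (nrow(object@alpha) != S || nrow(object@theta) != S ||
      length(object@rho) != S)
    msg <- c(msg, "alpha, theta, rho must have one row/entry per site")
  if (ncol(object@alpha) != object@K || ncol(object@theta) != object@K)
    msg <- c(msg, "alpha and theta must have K columns")
  if (any(abs(rowSums(object@alpha) - 1) > 1e-8))
    msg <- c(msg, "alpha rows must sum to 1")
  if (any(object@theta <= 0 | object@theta >= 1))
    msg <- c(msg, "theta must lie strictly inside (0, 1)")
  if (any(object@rho < 0 | object@rho > 1))
    msg <- c(msg, "rho must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' PropensityScores: per-sample P(A = +1 | same-chromosome genotype)
#'
#' @slot e numeric(n), propensity scores strictly inside (0, 1).
#' @slot conditioningSites integer, SNP row indices actually conditioned on
#'   (target chromosome minus the exclusion window and the target itself).
#' @slot targetIndex integer(1).
#' @slot rule character(1), binarization rule of the target.
#' @export
setClass("PropensityScores",
  representation(e = "numeric", conditioningSites = "integer",
                 targetIndex = "integer", rule = "character"))

setValidity("PropensityScores", function(object) {
  if (any(object@e <= 0 | object@e >= 1))
    "propensity scores must lie strictly inside (0, 1)" else TRUE
})

#' ModifiedOutcome: an inverse-propensity-weighted transformed response
#'
#' @slot yTilde numeric(n), the transformed response.
#' @slot variant one of \code{"plain"}, \code{"shifted"}, \code{"normalized"},
#'   \code{"robust"}.
#' @slot xi numeric(1), denominator shift (shifted variant; NA otherwise).
#' @slot w numeric(2), per-arm normalizers (w0, w1) for the normalized and
#'   robust variants (NA otherwise).
#' @slot Ct numeric(2), robust-variant corrections (C0, C1) (NA otherwise).
#' @export
setClass("ModifiedOutcome",
  representation(yTilde = "numeric", variant = "character", xi = "numeric",
                 w = "numeric", Ct = "numeric"))

setValidity("ModifiedOutcome", function(object) {
  msg <- character(0)
  if (!object@variant %in% c("plain", "shifted", "normalized", "robust"))
    msg <- c(msg, "unknown variant")
  if (any(!is.finite(object@yTilde)))
    msg <- c(msg, "yTilde must be finite")
  if (length(msg)) msg else TRUE
})

#' OwlSample: weights and response for outcome-weighted learning
#'
#' @slot weights numeric(n), W = Y / P(A | X), zero exactly for controls.
#' @slot response numeric(n) in \{-1, +1\}, the binarized target.
#' @export
setClass("OwlSample",
  representation(weights = "numeric", response = "numeric"))

setValidity("OwlSample", function(object) {
  msg <- character(0)
  if (any(object@weights < 0)) msg <- c(msg, "weights must be non-negative")
  if (!all(object@response %in% c(-1, 1)))
    msg <- c(msg, "response must take values in {-1, +1}")
  if (length(msg)) msg else TRUE
})

#' StabilityPath: selection frequencies along the regularization grid
#'
#' @slot omega p x L matrix of selection frequencies in [0, 1]; rows are
#'   design columns (SNPs), columns are grid positions.
#' @slot lambda numeric(L), the decreasing regularization grid.
#' @slot nSubsamples integer(1).
#' @slot subsampleSize integer(1), floor(n/2).
#' @slot scores numeric(p), area under each stability path (mean of omega
#'   over grid positions), in [0, 1].
#' @slot ids character(p), design column (SNP) identifiers.
#' @export
setClass("StabilityPath",
  representation(omega = "matrix", lambda = "numeric",
                 nSubsamples = "integer", subsampleSize = "integer",
                 scores = "numeric", ids = "character"))

setValidity("StabilityPath", function(object) {
  msg <- character(0)
  if (any(object@omega < 0 | object@omega > 1))
    msg <- c(msg, "selection frequencies must lie in [0, 1]")
  if (any(object@scores < 0 | object@scores > 1))
    msg <- c(msg, "scores must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' DiseaseModel: causal architecture of the simulated logit phenotype
#'
#' Index sets V (synergistic with the target), W (marginal), Z1/Z2 (paired
#' quadratic) and their N(0, 1) effect sizes. The scenario fixes the overlap
#' cardinalities between V and (W, Z1).
#'
#' @slot V,W,Z1,Z2 integer(8) SNP row indices.
#' @slot beta0V,beta1V numeric(8), effects of X_V under aTilde = 0 / 1.
#' @slot betaW numeric(8), marginal effects.
#' @slot betaZ numeric(8), diagonal coupling of the Z1-Z2 products.
#' @slot scenario integer(1) in 1..4.
#' @export
setClass("DiseaseModel",
  representation(V = "integer", W = "integer", Z1 = "integer", Z2 = "integer",
                 beta0V = "numeric", beta1V = "numeric", betaW = "numeric",
                 betaZ = "numeric", scenario = "integer"))

setValidity("DiseaseModel", function(object) {
  msg <- character(0)
  if (!all(lengths(list(object@V, object@W, object@Z1, object@Z2)) == 8L))
    msg <- c(msg, "V, W, Z1, Z2 must each contain 8 SNP indices")
  ov <- c(length(intersect(object@V, object@W)),
          length(intersect(object@V, object@Z1)))
  want <- switch(object@scenario, c(0L, 0L), c(4L, 0L), c(0L, 4L), c(2L, 2L))
  if (is.null(want) || !all(ov == want))
    msg <- c(msg, "overlap cardinalities do not match the scenario")
  if (length(msg)) msg else TRUE
})

#' TrueEffects: closed-form synergy and common-effect functions
#'
#' @slot delta function(X) returning 0.5 * (E[Y | A = +1, X] - E[Y | A = -1, X]).
#' @slot mu function(X) returning 0.5 * (E[Y | A = +1, X] + E[Y | A = -1, X]).
#' @slot delta0 numeric(1), Monte-Carlo estimate of E[delta(X)] under the
#'   generator (the main effect of the target); delta1(X) = delta(X) - delta0.
#' @export
setClass("TrueEffects",
  representation(delta = "function", mu = "function", delta0 = "numeric"))
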