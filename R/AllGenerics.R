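#' Accessors for epiTarget classes
#'
#' \code{dosages} returns the SNPs x samples dosage matrix; \code{phenotype}
#' the per-sample phenotype vector; \code{snpInfo} the per-SNP metadata;
#' \code{nSamples}/\code{nSnps} the cohort dimensions; \code{pathScores} the
#' per-SNP area-under-stability-path scores; \code{propensity} the
#' per-sample propensity scores.
#'
#' @param x an epiTarget object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname accessors
#' @export
setGeneric("phenotype", function(x) standardGeneric("phenotype"))

#' @rdname accessors
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname accessors
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' @rdname accessors
#' @export
setGeneric("pathScores", function(x) standardGeneric("pathScores"))

#' @rdname accessors
#' @export
setGeneric("propensity", function(x) standardGeneric("propensity"))

#' @rdname accessors
#' @export
setGeneric("modifiedY", function(x) standardGeneric("modifiedY"))

#' @rdname accessors
#' @export
setMethod("dosages", "GenotypeData", function(x)
  SummarizedExperiment::assay(x, "dosage"))

#' @rdname accessors
#' @export
setMethod("phenotype", "GenotypeData", function(x)
  SummarizedExperiment::colData(x)$phenotype)

#' @rdname accessors
#' @export
setMethod("snpInfo", "GenotypeData", function(x)
  SummarizedExperiment::rowData(x))

#' @rdname accessors
#' @export
setMethod("nSamples", "GenotypeData", function(x) ncol(x))

#' @rdname accessors
#' @export
setMethod("nSnps", "GenotypeData", function(x) nrow(x))

#' @rdname accessors
#' @export
setMethod("pathScores", "StabilityPath", function(x)
  stats::setNames(x@scores, x@ids))

#' @rdname accessors
#' @export
setMethod("propensity", "PropensityScores", function(x) x@e)

#' @rdname accessors
#' @export
setMethod("modifiedY", "ModifiedOutcome", function(x) x@yTilde)

setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", nrow(object), "SNPs x", ncol(object), "samples\n")
  y <- phenotype(object)
  if (all(y %in% c(0, 1, NA)))
    cat("  case-control phenotype:", sum(y == 1, na.rm = TRUE), "cases /",
        sum(y == 0, na.rm = TRUE), "controls\n")
  cat("  chromosomes:",
      paste(unique(SummarizedExperiment::rowData(object)$chromosome),
            collapse = ", "), "\n")
  nmiss <- sum(is.na(SummarizedExperiment::assay(object, "dosage")))
  if (nmiss > 0) cat("  missing dosages:", nmiss, "\n")
})

setMethod("show", "TargetEncoding", function(object) {
  cat("TargetEncoding: target", object@targetId,
      sprintf("(index %d, %s rule)\n", object@targetIndex, object@rule))
  cat("  A = +1 for", sum(object@A == 1), "samples, A = -1 for",
      sum(object@A == -1), "\n")
})

setMethod("show", "ClusterMap", function(object) {
  cat("ClusterMap: chromosome", object@chromosome, "-",
      length(object@snpIndex), "SNPs in",
      length(object@boundaries), "adjacency-constrained clusters\n")
})

setMethod("show", "GenotypeHMM", function(object) {
  cat(sprintf("GenotypeHMM: K = %d clusters, %d sites, logLik = %.3f (%d EM iterations)\n",
              object@K, length(object@sites), object@logLik, object@nIter))
})

setMethod("show", "PropensityScores", function(object) {
  cat(sprintf("PropensityScores: n = %d, e in [%.4f, %.4f], %d conditioning sites (%s rule)\n",
              length(object@e), min(object@e), max(object@e),
              length(object@conditioningSites), object@rule))
})

setMethod("show", "ModifiedOutcome", function(object) {
  cat(sprintf("ModifiedOutcome (%s): n = %d, range [%.3f, %.3f]\n",
              object@variant, length(object@yTilde),
              min(object@yTilde), max(object@yTilde)))
})

setMethod("show", "StabilityPath", function(object) {
  cat(sprintf("StabilityPath: %d variables x %d grid points, N = %d subsamples of %d\n",
              nrow(object@omega), ncol(object@omega), object@nSubsamples,
              object@subsampleSize))
  top <- utils::head(order(object@scores, decreasing = TRUE), 5)
  cat("  top scores:",
      paste(sprintf("%s=%.3f", object@ids[top], object@scores[top]),
            collapse = ", "), "\n")
})

setMethod("show", "DiseaseModel", function(object) {
  cat(sprintf("DiseaseModel (scenario %d): |V ^ W| = %d, |V ^ Z1| = %d\n",
              object@scenario, length(intersect(object@V, object@W)),
              length(intersect(object@V, object@Z1))))
})
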