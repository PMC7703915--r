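## Plain-text serialization of intermediate objects: cluster maps as TSV,
## HMM parameters and simulation truth as versioned JSON documents.

#' Tabulate a ClusterMap
#'
#' @param cm a \linkS4class{ClusterMap}.
#' @param ds the parent \linkS4class{GenotypeData} (for SNP ids).
#' @return data.frame with columns snp, chromosome, cluster.
#' @export
clusterTable <- function(cm, ds) {
  data.frame(snp = as.character(snpInfo(ds)$snp[cm@snpIndex]),
             chromosome = cm@chromosome, cluster = cm@labels)
}

#' Write / read GenotypeHMM parameters as a versioned JSON document
#'
#' @param hmm a \linkS4class{GenotypeHMM}.
#' @param path output (input) file path.
#' @return \code{writeGenotypeHMM}: \code{path}, invisibly;
#'   \code{readGenotypeHMM}: the reconstructed \linkS4class{GenotypeHMM}.
#' @export
writeGenotypeHMM <- function(hmm, path) {
  doc <- list(format = "epiTarget-hmm", version = 1L, K = hmm@K,
              sites = hmm@sites, alpha = hmm@alpha, theta = hmm@theta,
              rho = hmm@rho, logLik = hmm@logLik, nIter = hmm@nIter)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeGenotypeHMM
#' @export
readGenotypeHMM <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "epiTarget-hmm"))
    stop("not an epiTarget HMM document: ", path)
  methods::new("GenotypeHMM", K = as.integer(doc$K),
               sites = as.integer(doc$sites),
               alpha = matrix(doc$alpha, ncol = doc$K),
               theta = matrix(doc$theta, ncol = doc$K),
               rho = as.numeric(doc$rho),
               logLik = as.numeric(doc$logLik),
               logLikTrace = NA_real_, nIter = as.integer(doc$nIter))
}

#' Write the simulation truth as JSON
#'
#' Records the target, the causal index sets and ids, the effect sizes
#' and the scenario of a simulated study, for downstream evaluation.
#'
#' @param model a \linkS4class{DiseaseModel}.
#' @param target a \linkS4class{TargetEncoding}.
#' @param ds the simulated \linkS4class{GenotypeData}.
#' @param path output file path.
#' @param seeds optional named list of the seeds used.
#' @return \code{path}, invisibly.
#' @export
writeTruth <- function(model, target, ds, path, seeds = NULL) {
  ids <- as.character(snpInfo(ds)$snp)
  doc <- list(format = "epiTarget-truth", version = 1L,
              target = target@targetId, rule = target@rule,
              scenario = model@scenario,
              V = ids[model@V], W = ids[model@W],
              Z1 = ids[model@Z1], Z2 = ids[model@Z2],
              beta0V = model@beta0V, beta1V = model@beta1V,
              betaW = model@betaW, betaZ = model@betaZ,
              seeds = seeds)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
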