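## High-level SNP ranking: builds the interaction design (all SNPs outside
## the target's exclusion window), constructs the estimator-specific
## response/weights, and scores SNPs by the area under the stability path.

#' Rank SNPs for synergy with the target
#'
#' Runs one of the five propensity-based estimators end to end: the design
#' matrix contains the standardized dosages of every SNP outside the
#' target's exclusion window; the response is the chosen modified outcome
#' (squared loss) or the binarized target with outcome weights (OWL,
#' weighted logistic loss); support frequencies come from stability
#' selection over \code{N} subsamples of size floor(n/2) along the first
#' half of a 200-point log-spaced lambda grid. Sample-dependent arm
#' normalizers (normalized/robust variants) are recomputed inside each
#' subsample.
#'
#' @param ds an imputed \linkS4class{GenotypeData}.
#' @param target a \linkS4class{TargetEncoding}.
#' @param e a \linkS4class{PropensityScores} or numeric vector in (0, 1).
#' @param excluded integer vector of excluded SNP row indices (the
#'   exclusion window; see \code{\link{exclusionWindow}}).
#' @param method estimator: \code{"plain"}, \code{"shifted"},
#'   \code{"normalized"}, \code{"robust"} (modified outcomes) or
#'   \code{"owl"}.
#' @param xi denominator shift for the shifted variant (default 0.1).
#' @param N number of stability-selection subsamples (default 50).
#' @param seed integer seed for the subsampling.
#' @param gridSize,ratio,gridKeep lambda-grid construction (defaults
#'   200, 100, 100; see \code{\link{makeLambdaGrid}}).
#' @param s elastic-net mixing (default 1e-6).
#' @return A \linkS4class{StabilityPath} whose ids are the SNP ids in the
#'   design; \code{\link{pathScores}} extracts the ranking scores.
#' @export
rankSnps <- function(ds, target, e, excluded = integer(0),
                     method = c("plain", "shifted", "normalized", "robust",
                                "owl"),
                     xi = 0.1, N = 50L, seed = 1L, gridSize = 200L,
                     ratio = 100, gridKeep = 100L, s = 1e-6) {
  method <- match.arg(method)
  e <- .asE(e)
  Y <- phenotype(ds)
  if (anyNA(Y)) stop("phenotype contains missing values")
  keep <- setdiff(seq_len(nSnps(ds)), union(excluded, target@targetIndex))
  if (length(keep) == 0L) stop("no SNPs left outside the exclusion window")
  X <- standardizeDesign(t(dosages(ds)[keep, , drop = FALSE]))
  ids <- snpInfo(ds)$snp[keep]
  at <- target@aTilde

  if (method == "owl") {
    W <- owlWeights(Y, target@A, e)
    response <- at                      # 0/1 class labels for A
    grid <- makeLambdaGrid(X, response, sampleWeights = W@weights,
                           loss = "logistic", s = s, gridSize = gridSize,
                           ratio = ratio, gridKeep = gridKeep)
    path <- stabilitySelection(X, response, sampleWeights = W@weights,
                               grid = grid, N = N, seed = seed,
                               loss = "logistic", s = s, ids = ids)
  } else {
    fullY <- modifiedY(modifiedOutcome(Y, at, e, variant = method, xi = xi))
    grid <- makeLambdaGrid(X, fullY, loss = "squared", s = s,
                           gridSize = gridSize, ratio = ratio,
                           gridKeep = gridKeep)
    refit <- if (method %in% c("normalized", "robust")) {
      function(idx) list(
        response = modifiedY(modifiedOutcome(Y[idx], at[idx], e[idx],
                                             variant = method, xi = xi)),
        weights = NULL)
    } else NULL
    path <- stabilitySelection(X, fullY, grid = grid, N = N, seed = seed,
                               loss = "squared", s = s, refit = refit,
                               ids = ids)
  }
  path
}

#' Score table over all SNPs, with exclusion flags
#'
#' Expands per-design scores to the full SNP panel: SNPs inside the
#' exclusion window (or the target itself) carry an NA sentinel score and
#' an \code{excluded} flag rather than silently disappearing.
#'
#' @param scores named numeric vector of scores for the ranked SNPs.
#' @param ds the \linkS4class{GenotypeData} the design came from.
#' @param excluded integer vector of excluded SNP row indices.
#' @param targetIndex row index of the target SNP.
#' @return data.frame with columns snp, score, rank, excluded.
#' @export
scoreTable <- function(scores, ds, excluded = integer(0),
                       targetIndex = NA_integer_) {
  ids <- snpInfo(ds)$snp
  out <- data.frame(snp = ids, score = NA_real_, rank = NA_integer_,
                    excluded = seq_along(ids) %in% c(excluded, targetIndex))
  m <- match(names(scores), ids)
  out$score[m] <- scores
  ranked <- !is.na(out$score)
  out$rank[ranked] <- rank(-out$score[ranked], ties.method = "average")
  out
}
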