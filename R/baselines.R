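## Comparison methods: per-pair likelihood-ratio tests in the style of
## BOOST/GBOOST (saturated genotypic coding, no sure-screening stage), and
## the product LASSO of treatment-covariate interaction learning.

## Ridge-stabilized logistic fit (penalty on non-intercept coefficients),
## used as a fallback under quasi-separation. Returns the deviance.
.ridgeLogisticDeviance <- function(Xm, y, penalty = 1e-6, maxIter = 100L) {
  p <- ncol(Xm)
  pen <- rep(penalty, p); pen[1] <- 0      # unpenalized intercept
  beta <- rep(0, p)
  for (it in seq_len(maxIter)) {
    eta <- drop(Xm %*% beta)
    mu <- 1 / (1 + exp(-eta))
    wts <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / wts
    H <- crossprod(Xm, Xm * wts) + diag(pen, p)
    betaNew <- tryCatch(solve(H, crossprod(Xm, wts * z)),
                        error = function(e) beta)
    if (max(abs(betaNew - beta)) < 1e-10) { beta <- betaNew; break }
    beta <- betaNew
  }
  eta <- drop(Xm %*% beta)
  mu <- pmin(pmax(1 / (1 + exp(-eta)), 1e-12), 1 - 1e-12)
  -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
}

.logisticDeviance <- function(Xm, y) {
  fit <- suppressWarnings(stats::glm.fit(Xm, y,
                                         family = stats::binomial()))
  sep <- !fit$converged ||
    any(fit$fitted.values < 1e-10 | fit$fitted.values > 1 - 1e-10)
  ok <- !is.na(fit$coefficients)
  list(deviance = fit$deviance, nCoef = sum(ok), separated = sep)
}

#' GBOOST-style likelihood-ratio test for one SNP pair
#'
#' Compares the full logistic model (genotypic main effects of both SNPs
#' plus their saturated interaction) against the main-effects-only model.
#' Both SNPs enter as factors (two indicator columns each, four interaction
#' columns when all genotype cells are populated); unestimable columns are
#' dropped and the degrees of freedom reduced accordingly. Under
#' quasi-separation both models are refit with a tiny ridge penalty
#' (1e-6) and a warning.
#'
#' @param Y 0/1 phenotype vector.
#' @param targetGeno,xkGeno dosage vectors in \{0, 1, 2\}.
#' @return data.frame with \code{lrt} (deviance difference), \code{df}
#'   (estimable interaction columns) and \code{p} (chi-square upper tail).
#' @export
gboostLrt <- function(Y, targetGeno, xkGeno) {
  if (!all(Y %in% c(0, 1))) stop("Y must be binary 0/1")
  if (!all(targetGeno %in% 0:2) || !all(xkGeno %in% 0:2))
    stop("genotypes must lie in {0, 1, 2}")
  fa <- factor(targetGeno, levels = 0:2)
  fb <- factor(xkGeno, levels = 0:2)
  mmMain <- stats::model.matrix(~ fa + fb)
  mmFull <- stats::model.matrix(~ fa * fb)
  ## drop columns with no variation (empty genotype cells)
  mmMain <- mmMain[, c(TRUE, apply(mmMain[, -1, drop = FALSE], 2,
                                   function(v) stats::var(v) > 0)),
                   drop = FALSE]
  mmFull <- mmFull[, c(TRUE, apply(mmFull[, -1, drop = FALSE], 2,
                                   function(v) stats::var(v) > 0)),
                   drop = FALSE]
  fullFit <- .logisticDeviance(mmFull, Y)
  mainFit <- .logisticDeviance(mmMain, Y)
  if (fullFit$separated || mainFit$separated) {
    warning("quasi-separation detected; ridge-stabilized refit (penalty 1e-6)")
    devFull <- .ridgeLogisticDeviance(mmFull, Y)
    devMain <- .ridgeLogisticDeviance(mmMain, Y)
    df <- fullFit$nCoef - mainFit$nCoef
  } else {
    devFull <- fullFit$deviance
    devMain <- mainFit$deviance
    df <- fullFit$nCoef - mainFit$nCoef
  }
  stat <- max(devMain - devFull, 0)
  p <- if (df > 0) stats::pchisq(stat, df = df, lower.tail = FALSE) else 1
  data.frame(lrt = stat, df = df, p = p)
}

#' Per-pair LRT scan of the target against all candidate SNPs
#'
#' Runs \code{\link{gboostLrt}} for every pair (target, SNP_k) with SNP_k
#' outside the exclusion window. SNPs are scored by the LRT statistic.
#'
#' @param ds an imputed \linkS4class{GenotypeData} with 0/1 phenotypes.
#' @param target a \linkS4class{TargetEncoding}.
#' @param excluded integer vector of excluded SNP row indices.
#' @return data.frame with columns snp, lrt, df, p.
#' @export
gboostScan <- function(ds, target, excluded = integer(0)) {
  Y <- phenotype(ds)
  g <- dosages(ds)
  tg <- g[target@targetIndex, ]
  keep <- setdiff(seq_len(nSnps(ds)), union(excluded, target@targetIndex))
  res <- lapply(keep, function(k) gboostLrt(Y, tg, g[k, ]))
  out <- do.call(rbind, res)
  out <- cbind(snp = snpInfo(ds)$snp[keep], out)
  rownames(out) <- NULL
  out
}

#' Product LASSO scores
#'
#' Fits an L1-penalized logistic regression of the phenotype on the
#' products A * x_k (target-covariate interactions, standardized), with an
#' unpenalized intercept, and scores SNPs by the same area under the
#' stability path as the propensity-based methods.
#'
#' @param ds an imputed \linkS4class{GenotypeData} with 0/1 phenotypes.
#' @param target a \linkS4class{TargetEncoding} (A in \{-1, +1\}).
#' @param excluded integer vector of excluded SNP row indices.
#' @param N,seed,gridSize,ratio,gridKeep,s as in \code{\link{rankSnps}}.
#' @return A \linkS4class{StabilityPath}.
#' @export
productLassoScores <- function(ds, target, excluded = integer(0), N = 50L,
                               seed = 1L, gridSize = 200L, ratio = 100,
                               gridKeep = 100L, s = 1e-6) {
  Y <- phenotype(ds)
  if (!all(Y %in% c(0, 1))) stop("product LASSO requires a 0/1 phenotype")
  keep <- setdiff(seq_len(nSnps(ds)), union(excluded, target@targetIndex))
  X <- t(dosages(ds)[keep, , drop = FALSE])
  D <- standardizeDesign(target@A * X)
  ids <- snpInfo(ds)$snp[keep]
  grid <- makeLambdaGrid(D, Y, loss = "logistic", s = s,
                         gridSize = gridSize, ratio = ratio,
                         gridKeep = gridKeep)
  stabilitySelection(D, Y, grid = grid, N = N, seed = seed,
                     loss = "logistic", s = s, ids = ids)
}
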