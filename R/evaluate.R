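## Ranking-quality metrics and the replicate benchmark harness.

#' ROC and precision-recall curves with areas
#'
#' The ROC curve comes from a standard threshold sweep (tied scores are
#' grouped into one operating point) and its area from the trapezoidal
#' rule. The precision-recall area uses nonlinear interpolation between
#' operating points: along a segment the false-positive count grows
#' linearly in the true-positive count, which yields a closed-form
#' integral of precision over recall (linear interpolation in PR space
#' would overestimate the area).
#'
#' @param scores numeric score vector, larger = more likely positive.
#' @param labels 0/1 labels, both classes present.
#' @return List with \code{roc} (data.frame fpr, tpr), \code{pr}
#'   (data.frame recall, precision), \code{aucRoc} and \code{aucPr}.
#' @export
rocPr <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("length mismatch")
  ok <- !is.na(scores)
  scores <- scores[ok]; labels <- labels[ok]
  if (!all(labels %in% c(0, 1)) || length(unique(labels)) < 2L)
    stop("labels must be 0/1 with both classes present")
  P <- sum(labels == 1); Nn <- sum(labels == 0)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp <- cumsum(!duplicated(s))              # tie groups share a threshold
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(grp, fromLast = TRUE)  # last index of each group
  TP <- c(0, tp[last]); FP <- c(0, fp[last])

  tpr <- TP / P; fpr <- FP / Nn
  aucRoc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)

  ## Davis-Goadrich: integrate precision d(recall) segment by segment
  aucPr <- 0
  for (i in seq_len(length(TP) - 1)) {
    a <- TP[i]; b <- TP[i + 1]
    if (b == a) next
    sl <- (FP[i + 1] - FP[i]) / (b - a)
    cc <- FP[i] - sl * a                     # FP(t) = sl * t + cc
    f <- function(t) t / (1 + sl) -
      if (abs(cc) < 1e-300) 0 else cc / (1 + sl)^2 * log((1 + sl) * t + cc)
    aucPr <- aucPr + (f(b) - f(a)) / P
  }
  prPoints <- data.frame(recall = tpr[-1], precision = TP[-1] / (TP[-1] + FP[-1]))
  list(roc = data.frame(fpr = fpr, tpr = tpr), pr = prPoints,
       aucRoc = aucRoc, aucPr = aucPr)
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall correlation between two score or rank vectors.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return tau-b in [-1, 1].
#' @export
kendallTau <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("x and y must have equal length >= 2")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Kendall's tau is undefined for constant vectors")
  stats::cor(x, y, method = "kendall")
}

## one-directional weighted tau: ranks (average for ties) taken from the
## ordering of the first argument, descending; pair weight is the product
## of hyperbolic rank weights 1/(1 + rank), ranks counted from 0.
.weightedTauAsym <- function(x, y) {
  r <- rank(-x, ties.method = "average") - 1
  w <- 1 / (1 + r)
  n <- length(x)
  ij <- utils::combn(n, 2)
  i <- ij[1, ]; j <- ij[2, ]
  wij <- w[i] * w[j]
  conc <- sign(x[i] - x[j]) * sign(y[i] - y[j])
  sum(wij * conc) / sum(wij)
}

#' Weighted Kendall tau with multiplicative hyperbolic weights
#'
#' Each element receives a hyperbolic weight 1/(1 + rank) (rank 0 for the
#' top-scoring element, average ranks for ties); a pair's weight is the
#' product of its members' weights, so agreement among highly-ranked
#' elements dominates. The statistic is symmetrized by averaging the
#' values computed with ranks taken from each argument in turn.
#'
#' @param x,y numeric score vectors of equal length >= 2.
#' @return Weighted tau in [-1, 1].
#' @export
weightedKendallTau <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("x and y must have equal length >= 2")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("weighted tau is undefined for constant vectors")
  (.weightedTauAsym(x, y) + .weightedTauAsym(y, x)) / 2
}

#' Cochran-Armitage trend test for a 2 x 3 genotype table
#'
#' Tests for a linear trend in case proportion across the ordered genotype
#' classes with additive dosage weights (0, 1, 2). The signed statistic is
#' positive when cases skew toward higher dosages; the two-sided p-value
#' comes from the 1-df chi-square reference (the square of the statistic).
#'
#' @param caseCounts,controlCounts integer vectors of genotype counts
#'   (dosage 0, 1, 2).
#' @return List with \code{statistic} (signed z) and \code{p}.
#' @export
cochranArmitage <- function(caseCounts, controlCounts) {
  if (length(caseCounts) != 3L || length(controlCounts) != 3L)
    stop("expected genotype count vectors of length 3")
  N <- sum(caseCounts) + sum(controlCounts)
  if (N <= 0) stop("empty table")
  w <- c(0, 1, 2)
  R <- sum(caseCounts)
  nj <- caseCounts + controlCounts
  num <- sum(w * caseCounts) - R * sum(w * nj) / N
  den <- R / N * (1 - R / N) * (sum(nj * w^2) - sum(nj * w)^2 / N)
  if (den <= 0) return(list(statistic = 0, p = 1))
  z <- num / sqrt(den)
  list(statistic = z, p = stats::pchisq(z^2, df = 1, lower.tail = FALSE))
}

#' Replicate benchmark of all methods on simulated cohorts
#'
#' For each grid cell (scenario x sample size x replicate seed): simulate
#' an LD-structured cohort, sample a disease model, simulate phenotypes,
#' estimate propensity scores with the genotype HMM, rank SNPs with every
#' requested method and score the rankings against the truth labels
#' (1 for SNPs in V) by ROC/PR areas. Failed cells are logged and reported
#' as NA rows, never silently dropped.
#'
#' @param scenarios integer vector of disease scenarios (default 4).
#' @param nValues integer vector of cohort sizes (default 500).
#' @param p number of SNPs (default 500).
#' @param replicates integer vector of replicate seeds (default 1:10).
#' @param methods character vector among plain, shifted, normalized,
#'   robust, owl, productLasso, gboost (default all seven).
#' @param genK,ldJump,mafRange generator settings (defaults 4, 0.05,
#'   c(0.2, 0.5)).
#' @param fitK,emIter,emRestarts propensity-HMM settings (defaults 5, 12, 1).
#' @param N stability-selection subsamples (default 50).
#' @param corrThreshold,exclusionWidth LD filter settings (defaults 0.5, 3).
#' @param rule target binarization rule (default dominant).
#' @param seedBase offset folded into every per-cell seed (default 0), so a
#'   single master seed controls the whole study.
#' @param verbose print per-cell progress (default FALSE).
#' @return data.frame with columns scenario, n, method, replicate, aucRoc,
#'   aucPr.
#' @export
runBenchmark <- function(scenarios = 4L, nValues = 500L, p = 500L,
                         replicates = 1:10,
                         methods = c("plain", "shifted", "normalized",
                                     "robust", "owl", "productLasso",
                                     "gboost"),
                         genK = 4L, ldJump = 0.05, mafRange = c(0.2, 0.5),
                         fitK = 5L, emIter = 12L, emRestarts = 1L,
                         N = 50L, corrThreshold = 0.5, exclusionWidth = 3L,
                         rule = "dominant", seedBase = 0L, verbose = FALSE) {
  rows <- list()
  for (scenario in scenarios) for (n in nValues) for (rep in replicates) {
    cell <- sprintf("scenario %d, n = %d, replicate %d", scenario, n, rep)
    res <- tryCatch(
      .benchmarkCell(scenario, n, p, rep, methods, genK, ldJump, mafRange,
                     fitK, emIter, emRestarts, N, corrThreshold,
                     exclusionWidth, rule, seedBase, verbose),
      error = function(err) {
        warning("benchmark cell failed (", cell, "): ",
                conditionMessage(err))
        data.frame(scenario = scenario, n = n, method = methods,
                   replicate = rep, aucRoc = NA_real_, aucPr = NA_real_)
      })
    rows[[length(rows) + 1L]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.benchmarkCell <- function(scenario, n, p, rep, methods, genK, ldJump,
                           mafRange, fitK, emIter, emRestarts, N,
                           corrThreshold, exclusionWidth, rule, seedBase,
                           verbose) {
  baseSeed <- seedBase + 10000L * scenario + 101L * rep
  ds <- simulateGenotypes(n, p, K = genK, ldJump = ldJump,
                          mafRange = mafRange, seed = baseSeed)
  ds <- qcFilter(ds)$dataset             # same QC as a real cohort
  p <- nSnps(ds)
  ## target: eligible common SNP nearest the chromosome midpoint
  maf <- pmin(rowMeans(dosages(ds)) / 2, 1 - rowMeans(dosages(ds)) / 2)
  eligible <- which(maf >= 0.2)
  if (length(eligible) == 0L) stop("no eligible target SNP")
  tIdx <- eligible[which.min(abs(eligible - p / 2))]
  target <- binarizeTarget(ds, snpInfo(ds)$snp[tIdx], rule = rule)

  cm <- adjacencyCluster(ds, chromosome = snpInfo(ds)$chromosome[tIdx],
                         corrThreshold = corrThreshold)
  excl <- exclusionWindow(cm, tIdx, width = exclusionWidth)

  model <- sampleDiseaseModel(ds, target, excl, scenario,
                              seed = baseSeed + 1L)
  ds <- simulatePhenotypes(ds, target, model, seed = baseSeed + 2L)

  hmm <- fitGenotypeHMM(t(dosages(ds)), K = fitK, nIter = emIter,
                        nRestarts = emRestarts, seed = baseSeed + 3L,
                        sites = seq_len(p))
  e <- propensityScores(hmm, ds, target, excluded = excl)

  keep <- setdiff(seq_len(p), union(excl, tIdx))
  labels <- as.numeric(keep %in% model@V)
  out <- lapply(methods, function(method) {
    if (verbose) message("  method ", method)
    scores <- tryCatch(switch(method,
      gboost = {
        scan <- gboostScan(ds, target, excluded = excl)
        scan$lrt
      },
      productLasso = {
        path <- productLassoScores(ds, target, excluded = excl, N = N,
                                   seed = baseSeed + 4L)
        unname(pathScores(path))
      },
      {
        path <- rankSnps(ds, target, e, excluded = excl, method = method,
                         N = N, seed = baseSeed + 4L)
        unname(pathScores(path))
      }),
      error = function(err) {
        warning("method ", method, " failed on this cell: ",
                conditionMessage(err))
        NULL
      })
    if (is.null(scores))
      return(data.frame(scenario = scenario, n = n, method = method,
                        replicate = rep, aucRoc = NA_real_,
                        aucPr = NA_real_))
    curves <- rocPr(scores, labels)
    data.frame(scenario = scenario, n = n, method = method,
               replicate = rep, aucRoc = curves$aucRoc,
               aucPr = curves$aucPr)
  })
  do.call(rbind, out)
}
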