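## Shared fixtures and independent oracles for the test suite. All
## fixtures are generated in code; the oracles deliberately use naive
## enumeration rather than the package's recursions.

## A random, valid haplotype-cluster HMM.
makeToyHMM <- function(K, S, seed = 1) {
  set.seed(seed)
  alpha <- matrix(stats::rgamma(S * K, 2), S, K)
  alpha <- alpha / rowSums(alpha)
  theta <- matrix(stats::runif(S * K, 0.15, 0.85), S, K)
  rho <- c(1, stats::runif(S - 1))
  methods::new("GenotypeHMM", K = as.integer(K), sites = seq_len(S),
               alpha = alpha, theta = theta, rho = rho, logLik = NA_real_,
               logLikTrace = NA_real_, nIter = 0L)
}

## Brute-force P(genotype row) by enumerating all ordered cluster-pair
## paths (exponential in the number of sites; tiny models only).
bruteForwardProb <- function(hmm, row) {
  K <- hmm@K; S <- length(hmm@sites)
  alpha <- hmm@alpha; theta <- hmm@theta; rho <- hmm@rho
  emis <- function(s, g, k, l) {
    tk <- theta[s, k]; tl <- theta[s, l]
    if (is.na(g)) return(1)
    if (g == 0) (1 - tk) * (1 - tl)
    else if (g == 1) tk * (1 - tl) + (1 - tk) * tl
    else tk * tl
  }
  t1 <- function(s, kp, k) (1 - rho[s]) * (kp == k) + rho[s] * alpha[s, kp]
  tot <- 0
  recur <- function(s, pk, pl, prob) {
    for (k in seq_len(K)) for (l in seq_len(K)) {
      pr <- prob *
        (if (s == 1) alpha[1, k] * alpha[1, l]
         else t1(s, k, pk) * t1(s, l, pl)) * emis(s, row[s], k, l)
      if (s == S) tot <<- tot + pr else recur(s + 1, k, l, pr)
    }
  }
  recur(1, 0, 0, 1)
  tot
}

## Wrap a dosage matrix (samples x SNPs) as a single-chromosome cohort.
makeCohort <- function(G, phenotype = rep(0, nrow(G)), chromosome = "1") {
  p <- ncol(G)
  GenotypeData(t(G),
    snps = data.frame(snp = sprintf("rs%04d", seq_len(p)),
                      chromosome = chromosome, position = seq_len(p) * 1000),
    samples = data.frame(sample = sprintf("s%04d", seq_len(nrow(G))),
                         phenotype = phenotype))
}

## An orthogonal +/-1 design (Hadamard-style): mean-zero, unit-variance,
## mutually orthogonal columns, so lasso solutions are soft thresholds.
hadamardDesign <- function() {
  signs <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  cbind(signs, signs[, 1] * signs[, 2], signs[, 1] * signs[, 3],
        signs[, 2] * signs[, 3], signs[, 1] * signs[, 2] * signs[, 3])
}

## Independent transcription of the robust (Lunceford-Davidian) modified
## outcome as explicit loops over samples.
robustOracle <- function(Y, at, e) {
  n <- length(Y)
  Cv <- numeric(2)
  for (t in 0:1) {
    num <- 0; den <- 0
    for (j in seq_len(n)) {
      d <- t * e[j] + (1 - t) * (1 - e[j])
      num <- num + (at[j] - e[j]) / d
      den <- den + ((at[j] - e[j]) / d)^2
    }
    Cv[t + 1] <- num / den
  }
  s1 <- 0; s0 <- 0
  for (j in seq_len(n)) {
    s1 <- s1 + (1 - Cv[2] / e[j]) * at[j] / e[j]
    s0 <- s0 + (1 - Cv[1] / (1 - e[j])) * (1 - at[j]) / (1 - e[j])
  }
  out <- numeric(n)
  for (i in seq_len(n))
    out[i] <- Y[i] * ((1 - Cv[2] / e[i]) * at[i] / e[i] / s1 -
                        (1 - Cv[1] / (1 - e[i])) * (1 - at[i]) / (1 - e[i]) / s0)
  out
}

## Numeric (fine trapezoid) PR area under the same nonlinear
## interpolation model, as an oracle for the closed-form integral.
numericPrAuc <- function(scores, labels, steps = 20000) {
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]; s <- scores[o]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(grp, fromLast = TRUE)
  TP <- c(0, tp[last]); FP <- c(0, fp[last]); P <- sum(labels)
  a <- 0
  for (i in seq_len(length(TP) - 1)) {
    if (TP[i + 1] == TP[i]) next
    ts <- seq(TP[i], TP[i + 1], length.out = steps + 1)
    sl <- (FP[i + 1] - FP[i]) / (TP[i + 1] - TP[i])
    fps <- FP[i] + sl * (ts - TP[i])
    prec <- ifelse(ts + fps == 0, 1, ts / (ts + fps))
    a <- a + sum((prec[-1] + prec[-length(prec)]) / 2 * diff(ts)) / P
  }
  a
}

## Exhaustive-pair weighted Kendall tau (one direction).
bruteWeightedTau <- function(x, y) {
  r <- rank(-x, ties.method = "average") - 1
  w <- 1 / (1 + r)
  num <- 0; den <- 0
  n <- length(x)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    num <- num + w[i] * w[j] * sign(x[i] - x[j]) * sign(y[i] - y[j])
    den <- den + w[i] * w[j]
  }
  num / den
}

## A small simulated case-control cohort ready for the pipeline.
smallStudy <- function(n = 150, p = 60, scenario = 1, seed = 42) {
  ds <- simulateGenotypes(n, p, K = 3, ldJump = 0.1, seed = seed)
  maf <- pmin(rowMeans(dosages(ds)) / 2, 1 - rowMeans(dosages(ds)) / 2)
  tIdx <- which(maf >= 0.2)[which.min(abs(which(maf >= 0.2) - p / 2))]
  target <- binarizeTarget(ds, snpInfo(ds)$snp[tIdx], "dominant")
  cm <- adjacencyCluster(ds, "1")
  excl <- exclusionWindow(cm, tIdx)
  ## effect draws are heavy-tailed; retry until the cohort is usable
  for (try in 0:9) {
    model <- sampleDiseaseModel(ds, target, excl, scenario,
                                seed = seed + 1 + 37 * try)
    ds <- simulatePhenotypes(ds, target, model, seed = seed + 2 + 37 * try)
    frac <- mean(phenotype(ds))
    if (frac >= 0.2 && frac <= 0.8) break
  }
  list(ds = ds, target = target, cm = cm, excluded = excl, model = model,
       targetIndex = tIdx)
}
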