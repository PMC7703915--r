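## Synthetic cohorts: LD-structured genotypes sampled from a
## haplotype-cluster HMM (a desk-scale analogue of reference-panel
## resampling), and case-control phenotypes from a logit disease model
## with four configurable overlap scenarios between synergistic, marginal
## and quadratic effect sets.

#' Sample genotypes from a GenotypeHMM
#'
#' Draws two independent haplotype paths per individual and sums the
#' emitted alleles, so Hardy-Weinberg equilibrium holds at every site by
#' construction.
#'
#' @param hmm a \linkS4class{GenotypeHMM}.
#' @param n number of individuals.
#' @param seed integer seed.
#' @return n x S dosage matrix.
#' @export
sampleFromHMM <- function(hmm, n, seed = 1L) {
  S <- length(hmm@sites); K <- hmm@K
  .withSeed(seed, {
    G <- matrix(0L, n, S)
    z <- matrix(0L, 2L * n, 1L)
    zcur <- rep(1L, 2L * n)
    for (s in seq_len(S)) {
      jump <- stats::runif(2L * n) < hmm@rho[s]
      if (any(jump))
        zcur[jump] <- sample.int(K, sum(jump), replace = TRUE,
                                 prob = hmm@alpha[s, ])
      alleles <- stats::runif(2L * n) < hmm@theta[s, zcur]
      G[, s] <- as.integer(alleles[seq_len(n)] +
                             alleles[n + seq_len(n)])
    }
    G
  })
}

#' Simulate an LD-structured genotype cohort
#'
#' Builds a haplotype-cluster HMM with uniform cluster weights, constant
#' jump probability \code{ldJump} between adjacent sites, and per-site
#' emission frequencies drawn around a target minor-allele frequency
#' sampled uniformly from \code{mafRange} (cluster-specific frequencies
#' are Beta-distributed around it, which is what differentiates clusters
#' and creates LD). Low \code{ldJump} means long cluster persistence and
#' strong local LD; \code{ldJump = 1} gives independent sites.
#'
#' @param n,p samples and SNPs.
#' @param K haplotype clusters of the generating HMM (default 4).
#' @param ldJump jump probability between adjacent sites, in (0, 1]
#'   (default 0.05).
#' @param mafRange range of expected minor allele frequencies, within
#'   (0, 0.5] (default c(0.2, 0.5)).
#' @param seed integer seed.
#' @param chromosome chromosome label (default "1").
#' @param concentration Beta concentration of cluster frequencies around
#'   the site MAF (default 1.5; smaller = more cluster differentiation,
#'   hence stronger LD).
#' @return A \linkS4class{GenotypeData} with all-missing phenotypes (fill
#'   with \code{\link{simulatePhenotypes}}); the generating
#'   \linkS4class{GenotypeHMM} is stored in \code{metadata(ds)$hmm}.
#' @export
simulateGenotypes <- function(n, p, K = 4L, ldJump = 0.05,
                              mafRange = c(0.2, 0.5), seed = 1L,
                              chromosome = "1", concentration = 1.5) {
  if (n < 1 || p < 1) stop("n and p must be >= 1")
  if (K < 1) stop("K must be >= 1")
  if (ldJump <= 0 || ldJump > 1) stop("ldJump must lie in (0, 1]")
  if (min(mafRange) <= 0 || max(mafRange) > 0.5)
    stop("mafRange must lie within (0, 0.5]")
  hmm <- .withSeed(seed, {
    m <- stats::runif(p, mafRange[1], mafRange[2])
    theta <- matrix(stats::rbeta(p * K, rep(m, K) * concentration,
                                 rep(1 - m, K) * concentration), p, K)
    theta <- pmin(pmax(theta, 1e-3), 1 - 1e-3)
    methods::new("GenotypeHMM", K = as.integer(K), sites = seq_len(p),
                 alpha = matrix(1 / K, p, K), theta = theta,
                 rho = c(1, rep(ldJump, p - 1L)), logLik = NA_real_,
                 logLikTrace = NA_real_, nIter = 0L)
  })
  G <- sampleFromHMM(hmm, n, seed = seed + 1L)
  ds <- GenotypeData(t(G),
    snps = data.frame(snp = sprintf("snp%05d", seq_len(p)),
                      chromosome = chromosome,
                      position = seq_len(p) * 5000),
    samples = data.frame(sample = sprintf("ind%05d", seq_len(n)),
                         phenotype = NA_real_))
  S4Vectors::metadata(ds)$hmm <- hmm
  ds
}

#' Sample a disease model with scenario-specific overlaps
#'
#' Draws the causal index sets V (synergistic with the target), W
#' (marginal), Z1/Z2 (paired quadratic), each of size 8, among SNPs with
#' minor allele frequency at least \code{mafMin} lying outside the
#' target's exclusion window; effect sizes are i.i.d. standard normal.
#' Scenario overlaps: 1: |V^W| = 0, |V^Z1| = 0; 2: |V^W| = 4; 3:
#' |V^Z1| = 4; 4: |V^W| = 2, |V^Z1| = 2.
#'
#' @param ds a \linkS4class{GenotypeData}.
#' @param target a \linkS4class{TargetEncoding}.
#' @param excluded integer vector of excluded SNP row indices.
#' @param scenario integer in 1..4.
#' @param seed integer seed.
#' @param mafMin causal-SNP MAF lower bound (default 0.2).
#' @return A \linkS4class{DiseaseModel}.
#' @export
sampleDiseaseModel <- function(ds, target, excluded = integer(0), scenario,
                               seed = 1L, mafMin = 0.2) {
  scenario <- as.integer(scenario)
  if (!scenario %in% 1:4) stop("scenario must be 1, 2, 3 or 4")
  ov <- switch(scenario, c(0L, 0L), c(4L, 0L), c(0L, 4L), c(2L, 2L))
  g <- dosages(ds)
  maf <- rowMeans(g) / 2
  maf <- pmin(maf, 1 - maf)
  eligible <- setdiff(which(maf >= mafMin),
                      union(excluded, target@targetIndex))
  need <- 32L - sum(ov)
  if (length(eligible) < need)
    stop("insufficient eligible SNPs for the disease model: ",
         length(eligible), " available, ", need, " required")
  .withSeed(seed, {
    V <- sample(eligible, 8L)
    pool <- setdiff(eligible, V)
    W <- c(if (ov[1] > 0) sample(V, ov[1]) else integer(0),
           sample(pool, 8L - ov[1]))
    pool <- setdiff(pool, W)
    vFree <- setdiff(V, W)               # keep V-overlaps of W and Z1 disjoint
    Z1 <- c(if (ov[2] > 0) sample(vFree, ov[2]) else integer(0),
            sample(pool, 8L - ov[2]))
    pool <- setdiff(pool, Z1)
    Z2 <- sample(pool, 8L)
    methods::new("DiseaseModel",
                 V = sort(as.integer(V)), W = sort(as.integer(W)),
                 Z1 = sort(as.integer(Z1)), Z2 = sort(as.integer(Z2)),
                 beta0V = stats::rnorm(8), beta1V = stats::rnorm(8),
                 betaW = stats::rnorm(8), betaZ = stats::rnorm(8),
                 scenario = scenario)
  })
}

## linear predictors of the two logit arms for a dosage matrix X (n x p)
.diseaseEta <- function(X, model) {
  XV <- X[, model@V, drop = FALSE]
  common <- drop(X[, model@W, drop = FALSE] %*% model@betaW) +
    rowSums(X[, model@Z1, drop = FALSE] * X[, model@Z2, drop = FALSE] *
              matrix(model@betaZ, nrow(X), 8L, byrow = TRUE))
  list(eta0 = unname(drop(XV %*% model@beta0V) + common),
       eta1 = unname(drop(XV %*% model@beta1V) + common))
}

#' Simulate case-control phenotypes from the logit disease model
#'
#' P(Y = 1 | aTilde = i, X) = logistic(beta_iV' X_V + betaW' X_W +
#' X_Z1' diag(betaZ) X_Z2); Y is drawn Bernoulli per sample. Effect sizes
#' being symmetric around zero, cohorts are approximately balanced between
#' cases and controls on average over effect draws.
#'
#' @param ds a \linkS4class{GenotypeData}.
#' @param target a \linkS4class{TargetEncoding}.
#' @param model a \linkS4class{DiseaseModel} sampled on \code{ds}.
#' @param seed integer seed.
#' @return \code{ds} with the simulated 0/1 phenotype filled in.
#' @export
simulatePhenotypes <- function(ds, target, model, seed = 1L) {
  X <- t(dosages(ds))
  eta <- .diseaseEta(X, model)
  prob <- stats::plogis(ifelse(target@aTilde == 1, eta$eta1, eta$eta0))
  y <- .withSeed(seed, as.numeric(stats::runif(nrow(X)) < prob))
  SummarizedExperiment::colData(ds)$phenotype <- y
  ds
}

#' Closed-form synergy and common-effect functions of the disease model
#'
#' delta(X) = (sigma(eta1) - sigma(eta0)) / 2 and mu(X) =
#' (sigma(eta1) + sigma(eta0)) / 2 follow in closed form from the two
#' logit arms. The target's main effect delta0 = E[delta(X)] is estimated
#' by Monte Carlo under the generating HMM (model-based centering), so
#' delta1(X) = delta(X) - delta0 has mean zero under the generator.
#'
#' @param ds a \linkS4class{GenotypeData} produced by
#'   \code{\link{simulateGenotypes}} (its metadata holds the generator).
#' @param target a \linkS4class{TargetEncoding}.
#' @param model a \linkS4class{DiseaseModel}.
#' @param nMC Monte-Carlo draws for delta0 (default 2000).
#' @param seed integer seed for the Monte-Carlo centering.
#' @return A \linkS4class{TrueEffects}.
#' @export
trueEffects <- function(ds, target, model, nMC = 2000L, seed = 1L) {
  deltaFun <- function(X) {
    eta <- .diseaseEta(X, model)
    (stats::plogis(eta$eta1) - stats::plogis(eta$eta0)) / 2
  }
  muFun <- function(X) {
    eta <- .diseaseEta(X, model)
    (stats::plogis(eta$eta1) + stats::plogis(eta$eta0)) / 2
  }
  hmm <- S4Vectors::metadata(ds)$hmm
  Xmc <- if (!is.null(hmm)) sampleFromHMM(hmm, nMC, seed = seed)
         else t(dosages(ds))
  methods::new("TrueEffects", delta = deltaFun, mu = muFun,
               delta0 = mean(deltaFun(Xmc)))
}
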