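test_that("forward log-likelihood matches brute-force path enumeration", {
  hmm <- makeToyHMM(K = 2, S = 4, seed = 21)
  rows <- rbind(c(0, 1, 2, 1), c(2, 2, 0, 1), c(1, NA, 2, 0), c(0, 0, 0, 0))
  for (i in seq_len(nrow(rows)))
    expect_equal(forwardLoglik(hmm, rows[i, ]),
                 log(bruteForwardProb(hmm, rows[i, ])), tolerance = 1e-10)
})

test_that("forward probabilities sum to one over all genotype rows", {
  hmm <- makeToyHMM(K = 2, S = 4, seed = 22)
  allRows <- as.matrix(expand.grid(0:2, 0:2, 0:2, 0:2))
  expect_equal(sum(exp(forwardLoglik(hmm, allRows))), 1, tolerance = 1e-8)
})

test_that("single-cluster model factorizes into independent HWE sites", {
  h1 <- methods::new("GenotypeHMM", K = 1L, sites = 1:3,
                     alpha = matrix(1, 3, 1), theta = matrix(0.5, 3, 1),
                     rho = c(1, 0.3, 0.9), logLik = NA_real_,
                     logLikTrace = NA_real_, nIter = 0L)
  expect_equal(forwardLoglik(h1, c(1, 1, 1)), log(0.5^3), tolerance = 1e-12)
  expect_error(forwardLoglik(h1, c(1, 3, 1)), "0, 1, 2")
})

test_that("EM is monotone, deterministic, and beats the generating parameters", {
  gen <- methods::new("GenotypeHMM", K = 2L, sites = 1:15,
                      alpha = matrix(0.5, 15, 2),
                      theta = cbind(rep(0.15, 15), rep(0.7, 15)),
                      rho = c(1, rep(0.1, 14)), logLik = NA_real_,
                      logLikTrace = NA_real_, nIter = 0L)
  G <- sampleFromHMM(gen, 250, seed = 23)
  fit <- fitGenotypeHMM(G, K = 2, nIter = 15, nRestarts = 2, seed = 24)
  expect_true(all(diff(fit@logLikTrace) >= -1e-8))
  expect_gte(fit@logLik, sum(forwardLoglik(gen, G)))
  fit2 <- fitGenotypeHMM(G, K = 2, nIter = 15, nRestarts = 2, seed = 24)
  expect_identical(fit@theta, fit2@theta)
  expect_identical(fit@alpha, fit2@alpha)
})

test_that("K = 1 EM converges to the sample allele frequencies", {
  set.seed(25)
  G <- sapply(c(0.2, 0.35, 0.5), function(q) rbinom(400, 2, q))
  fit <- fitGenotypeHMM(G, K = 1, nIter = 5, nRestarts = 1, seed = 1)
  expect_equal(fit@theta[, 1], colMeans(G) / 2, tolerance = 1e-8)
})

test_that("the HMM size budget triggers an informative error", {
  G <- matrix(0, 10, 10)
  expect_error(fitGenotypeHMM(G, K = 5, budget = 100), "budget")
})

test_that("propensity scores match brute-force joint-probability enumeration", {
  hmm <- makeToyHMM(K = 2, S = 4, seed = 26)
  set.seed(27)
  G <- matrix(sample(0:2, 20, replace = TRUE), 5, 4)
  G[, 3] <- c(0, 1, 2, 1, 0)           # target column with both A classes
  ds <- makeCohort(G, phenotype = rep(c(0, 1), length.out = 5))
  target <- binarizeTarget(ds, "rs0003", "dominant")
  ps <- propensityScores(hmm, ds, target, excluded = 3L)
  for (i in 1:5) {
    r <- G[i, ]
    L <- sapply(0:2, function(d) { r2 <- r; r2[3] <- d
                                   bruteForwardProb(hmm, r2) })
    expect_equal(ps@e[i], (L[2] + L[3]) / sum(L), tolerance = 1e-10)
  }
  ## recessive rule groups dosages {0, 1} into A = -1
  G2 <- G; G2[, 3] <- c(0, 1, 2, 2, 0)
  ds2 <- makeCohort(G2, phenotype = rep(0, 5))
  t2 <- binarizeTarget(ds2, "rs0003", "recessive")
  ps2 <- propensityScores(hmm, ds2, t2, excluded = 3L)
  for (i in 1:2) {
    r <- G2[i, ]
    L <- sapply(0:2, function(d) { r2 <- r; r2[3] <- d
                                   bruteForwardProb(hmm, r2) })
    expect_equal(ps2@e[i], L[3] / sum(L), tolerance = 1e-10)
  }
})

test_that("under independence the propensity equals the HWE marginal", {
  q <- 0.3
  h1 <- methods::new("GenotypeHMM", K = 1L, sites = 1:3,
                     alpha = matrix(1, 3, 1),
                     theta = matrix(c(0.5, q, 0.5), 3, 1),
                     rho = c(1, 0.3, 0.7), logLik = NA_real_,
                     logLikTrace = NA_real_, nIter = 0L)
  G <- rbind(c(0, 1, 2), c(2, 0, 0), c(1, 2, 1))
  ds <- makeCohort(G)
  target <- binarizeTarget(ds, "rs0002", "dominant")
  ps <- propensityScores(h1, ds, target, excluded = 2L)
  expect_equal(ps@e, rep(1 - (1 - q)^2, 3), tolerance = 1e-10)
  ## an empty conditioning set gives the marginal too
  psAll <- propensityScores(h1, ds, target, excluded = 1:3)
  expect_equal(psAll@e, rep(1 - (1 - q)^2, 3), tolerance = 1e-10)
  expect_length(psAll@conditioningSites, 0)
})

test_that("joint probabilities are sum-consistent with the marginal forward pass", {
  hmm <- makeToyHMM(K = 3, S = 5, seed = 28)
  set.seed(29)
  G <- matrix(sample(0:2, 40, replace = TRUE), 8, 5)
  G[, 2] <- rep(c(0, 1, 2, 1), 2)
  ds <- makeCohort(G)
  target <- binarizeTarget(ds, "rs0002", "dominant")
  ps <- propensityScores(hmm, ds, target, excluded = 2L)
  ## P(A=+1, X) + P(A=-1, X) must equal P(X) with the target marginalized
  Gm <- G; Gm[, 2] <- NA
  pX <- exp(forwardLoglik(hmm, Gm))
  pJoint <- sapply(seq_len(8), function(i) {
    r <- G[i, ]
    sum(sapply(0:2, function(d) { r2 <- r; r2[2] <- d
                                  exp(forwardLoglik(hmm, r2)) }))
  })
  expect_equal(pJoint, pX, tolerance = 1e-12)
})

test_that("predicted propensities are calibrated on data from a known HMM", {
  set.seed(30)
  p <- 30
  m <- runif(p, 0.2, 0.5)
  theta <- matrix(rbeta(p * 3, rep(m, 3) * 1.5, rep(1 - m, 3) * 1.5), p, 3)
  theta <- pmin(pmax(theta, 0.02), 0.98)
  gen <- methods::new("GenotypeHMM", K = 3L, sites = seq_len(p),
                      alpha = matrix(1 / 3, p, 3), theta = theta,
                      rho = c(1, rep(0.05, p - 1)), logLik = NA_real_,
                      logLikTrace = NA_real_, nIter = 0L)
  G <- sampleFromHMM(gen, 2000, seed = 31)
  tcol <- 15L
  ds <- makeCohort(G)
  target <- binarizeTarget(ds, snpInfo(ds)$snp[tcol], "dominant")
  ps <- propensityScores(gen, ds, target, excluded = tcol)
  aPlus <- target@aTilde
  bins <- cut(ps@e, breaks = quantile(ps@e, seq(0, 1, 0.2)),
              include.lowest = TRUE)
  pred <- tapply(ps@e, bins, mean)
  obs <- tapply(aPlus, bins, mean)
  slope <- coef(lm(obs ~ pred))[2]
  expect_gt(slope, 0.8)
  expect_lt(slope, 1.2)
})
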