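test_that("plain modified outcome applies inverse-propensity weighting", {
  expect_equal(modifiedY(plainModifiedOutcome(1, 1, 0.5)), 2)
  expect_equal(modifiedY(plainModifiedOutcome(c(0, 0), c(1, 0), c(0.3, 0.8))),
               c(0, 0))                               # controls vanish
  ## with e = 1/2 throughout, yTilde = 2 Y A
  set.seed(41)
  Y <- rbinom(30, 1, 0.5); A <- sample(c(-1, 1), 30, replace = TRUE)
  at <- (A + 1) / 2
  expect_equal(modifiedY(plainModifiedOutcome(Y, at, rep(0.5, 30))),
               2 * Y * A, tolerance = 1e-12)
  expect_error(plainModifiedOutcome(1, 1, 1), "strictly inside")
})

test_that("shifted modified outcome caps weights at 1/xi and has the right limit", {
  expect_equal(modifiedY(shiftedModifiedOutcome(1, 1, 0.9, xi = 0.1)), 1)
  set.seed(42)
  e <- runif(50, 0.01, 0.99); at <- rbinom(50, 1, 0.5); Y <- rbinom(50, 1, 0.6)
  sh <- modifiedY(shiftedModifiedOutcome(Y, at, e, xi = 0.1))
  expect_true(all(abs(sh) <= 1 / 0.1 * Y + 1e-12))
  ## xi -> 0 recovers the plain outcome
  expect_equal(modifiedY(shiftedModifiedOutcome(Y, at, e, xi = 1e-9)),
               modifiedY(plainModifiedOutcome(Y, at, e)), tolerance = 1e-6)
  expect_error(shiftedModifiedOutcome(1, 1, 0.5, xi = 0), "positive")
})

test_that("normalized modified outcome makes per-arm weights sum to one", {
  ## two treated samples with e = (0.5, 0.25): w1 = 1/(2 + 4) = 1/6
  e <- c(0.5, 0.25, 0.4, 0.6); at <- c(1, 1, 0, 0); Y <- rep(1, 4)
  mo <- normalizedModifiedOutcome(Y, at, e)
  expect_equal(mo@w[2], 1 / 6)
  expect_equal(sum(at / e) * mo@w[2], 1)              # exact by construction
  expect_equal(sum((1 - at) / (1 - e)) * mo@w[1], 1)
  ## constant e = c with n1 treated: w1 = c / n1
  e2 <- rep(0.35, 6); at2 <- c(1, 1, 1, 0, 0, 0)
  mo2 <- normalizedModifiedOutcome(rep(1, 6), at2, e2)
  expect_equal(mo2@w[2], 0.35 / 3, tolerance = 1e-12)
  expect_error(normalizedModifiedOutcome(c(1, 1), c(1, 1), c(0.5, 0.5)),
               "non-empty")
})

test_that("robust modified outcome matches an independent transcription", {
  e <- c(0.2, 0.4, 0.6, 0.8); at <- c(0, 1, 0, 1); Y <- rep(1, 4)
  expect_equal(modifiedY(robustModifiedOutcome(Y, at, e)),
               robustOracle(Y, at, e), tolerance = 1e-12)
  set.seed(43)
  e3 <- runif(40, 0.1, 0.9); at3 <- rbinom(40, 1, 0.5)
  Y3 <- rbinom(40, 1, 0.5)
  expect_equal(modifiedY(robustModifiedOutcome(Y3, at3, e3)),
               robustOracle(Y3, at3, e3), tolerance = 1e-12)
  expect_equal(modifiedY(robustModifiedOutcome(rep(0, 40), at3, e3)),
               rep(0, 40))
})

test_that("robust reduces to normalized when e is constant at mean(aTilde)", {
  at <- c(rep(1, 3), rep(0, 5)); Y <- c(1, 0, 1, 1, 0, 1, 0, 1)
  e <- rep(mean(at), 8)
  rob <- robustModifiedOutcome(Y, at, e)
  expect_equal(rob@Ct, c(0, 0), tolerance = 1e-12)
  expect_equal(modifiedY(rob),
               modifiedY(normalizedModifiedOutcome(Y, at, e)),
               tolerance = 1e-14)
})

test_that("all variants coincide up to a positive constant for constant e, balanced arms", {
  at <- rep(c(1, 0), 10); Y <- rbinom(20, 1, 0.5)
  e <- rep(0.5, 20)
  base <- modifiedY(plainModifiedOutcome(Y, at, e))
  for (v in c("shifted", "normalized", "robust")) {
    yt <- modifiedY(modifiedOutcome(Y, at, e, variant = v))
    nz <- base != 0
    ratio <- yt[nz] / base[nz]
    if (any(nz)) {
      expect_gt(min(ratio), 0)
      expect_lt(diff(range(ratio)), 1e-10)
    }
    expect_equal(yt[!nz], rep(0, sum(!nz)))
  }
})

test_that("OWL weights implement the case-only inverse-propensity weighting", {
  expect_equal(owlWeights(1, 1, 0.25)@weights, 4)     # 1 / 0.25
  expect_equal(owlWeights(0, -1, 0.7)@weights, 0)     # controls: weight 0
  set.seed(44)
  Y <- rbinom(30, 1, 0.5); A <- sample(c(-1, 1), 30, replace = TRUE)
  ow <- owlWeights(Y, A, rep(0.5, 30))
  expect_equal(ow@weights, 2 * Y)                     # e = 1/2 -> W = 2Y
  expect_identical(ow@weights == 0, Y == 0)
  expect_error(owlWeights(c(-1, 1), c(1, -1), c(0.5, 0.5)), "non-negative")
})

test_that("stratified means of the plain outcome recover twice the synergy", {
  ## two causal SNPs independent of a HWE target; true e is the marginal
  set.seed(45)
  n <- 20000
  q <- 0.4
  tdose <- rbinom(n, 2, q)
  X <- cbind(rbinom(n, 2, 0.35), rbinom(n, 2, 0.45))
  at <- as.numeric(tdose >= 1)
  eTrue <- rep(1 - (1 - q)^2, n)
  b0 <- c(0.4, -0.3); b1 <- c(-0.8, 0.9)
  eta0 <- drop(X %*% b0); eta1 <- drop(X %*% b1)
  prob <- plogis(ifelse(at == 1, eta1, eta0))
  Y <- as.numeric(runif(n) < prob)
  yt <- modifiedY(plainModifiedOutcome(Y, at, eTrue))
  delta <- (plogis(eta1) - plogis(eta0)) / 2
  strata <- interaction(X[, 1], X[, 2])
  for (s in levels(strata)) {
    i <- strata == s
    if (sum(i) < 50) next
    se <- sd(yt[i]) / sqrt(sum(i))
    expect_lt(abs(mean(yt[i]) - 2 * delta[i][1]), 3 * se + 1e-12)
  }
})

test_that("the minimized OWL risk recovers the log-ratio of arm means", {
  ## tabulated toy model: one stratum, expectations realized as weighted
  ## atoms (A, Y) with exact joint probabilities
  for (setting in list(c(e = 0.3, m1 = 0.7, m0 = 0.2),
                       c(e = 0.6, m1 = 0.25, m0 = 0.55))) {
    e <- unname(setting["e"]); m1 <- unname(setting["m1"])
    m0 <- unname(setting["m0"])
    A <- c(1, 1, -1, -1); Y <- c(1, 0, 1, 0)
    prob <- c(e * m1, e * (1 - m1), (1 - e) * m0, (1 - e) * (1 - m0))
    W <- owlWeights(Y, A, rep(e, 4))@weights
    risk <- function(u) sum(prob * W * log(1 + exp(-A * u)))
    uStar <- optimize(risk, c(-20, 20), tol = 1e-10)$minimum
    expect_equal(uStar, log(m1 / m0), tolerance = 1e-6)
    ## the sign of the minimizer agrees with the sign of delta
    expect_equal(sign(uStar), sign((m1 - m0) / 2))
  }
})
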