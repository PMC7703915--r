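## Haplotype-cluster hidden Markov model on unphased genotypes.
##
## Each individual carries two independent haplotype paths over K latent
## clusters. Between adjacent sites a path jumps with probability rho[s] to
## a cluster drawn from alpha[s, ] and otherwise stays put; site s emits a
## minor allele with probability theta[s, k] and the observed genotype is
## the sum over the two paths. The hidden chain over ordered cluster pairs
## (K^2 states) has a rank-one-plus-identity transition kernel, which keeps
## every forward/backward sweep at O(n K^2) per site. Missing genotypes
## (NA) are marginalized, which is how excluded sites are skipped in the
## propensity forward pass.

## Run expr with a private RNG state so fits are seeded without
## perturbing the caller's random stream.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Index helpers for the ordered-pair state space: column (l-1)*K + k.
.pairIndex <- function(K) {
  K2 <- K * K
  kIdx <- rep(seq_len(K), times = K)
  lIdx <- rep(seq_len(K), each = K)
  Kmat <- matrix(0, K2, K); Kmat[cbind(seq_len(K2), kIdx)] <- 1  # sum over l
  Lmat <- matrix(0, K2, K); Lmat[cbind(seq_len(K2), lIdx)] <- 1  # sum over k
  list(K = K, K2 = K2, kIdx = kIdx, lIdx = lIdx, Kmat = Kmat, Lmat = Lmat)
}

## 3 x K^2 emission table for one site: P(g | pair), rows g = 0, 1, 2.
.emissionTable <- function(th, px) {
  tk <- th[px$kIdx]; tl <- th[px$lIdx]
  rbind((1 - tk) * (1 - tl),
        tk * (1 - tl) + (1 - tk) * tl,
        tk * tl)
}

## n x K^2 emission matrix for a genotype column g (NA -> flat emission 1).
.emissionMatrix <- function(g, E3, K2) {
  n <- length(g)
  Em <- matrix(1, n, K2)
  ok <- !is.na(g)
  Em[ok, ] <- E3[g[ok] + 1L, , drop = FALSE]
  Em
}

## Forward transition: newF(k', l') = sum_{k,l} F(k,l) T1(k'|k) T1(l'|l)
## with T1 = (1 - rho) I + rho 1 alpha^T, applied one chain axis at a time.
.applyTfwd <- function(F, rho, alpha, px) {
  n <- nrow(F)
  aK <- matrix(alpha[px$kIdx], n, px$K2, byrow = TRUE)
  aL <- matrix(alpha[px$lIdx], n, px$K2, byrow = TRUE)
  Sl <- F %*% px$Lmat                     # sum over k, per l
  F1 <- (1 - rho) * F + rho * Sl[, px$lIdx, drop = FALSE] * aK
  Sk <- F1 %*% px$Kmat                    # sum over l, per k
  (1 - rho) * F1 + rho * Sk[, px$kIdx, drop = FALSE] * aL
}

## Backward transition: newB(k, l) = sum_{k',l'} T1(k'|k) T1(l'|l) B(k',l').
.applyTbwd <- function(B, rho, alpha, px) {
  n <- nrow(B)
  SlA <- B %*% (px$Lmat * alpha[px$kIdx])  # alpha-weighted sum over k'
  B1 <- (1 - rho) * B + rho * SlA[, px$lIdx, drop = FALSE]
  SkA <- B1 %*% (px$Kmat * alpha[px$lIdx]) # alpha-weighted sum over l'
  (1 - rho) * B1 + rho * SkA[, px$kIdx, drop = FALSE]
}

## Scaled forward pass over an n x S genotype matrix (values 0/1/2/NA).
## Returns per-sample log-likelihoods and, if keep, the scaled forward
## matrices and scale factors for the E-step.
.hmmForward <- function(theta, alpha, rho, G, px, keep = FALSE) {
  n <- nrow(G); S <- ncol(G)
  loglik <- numeric(n)
  fs <- if (keep) vector("list", S) else NULL
  cs <- if (keep) matrix(0, n, S) else NULL
  Fm <- matrix(1 / px$K2, n, px$K2)  # virtual start; rho[1] = 1 lands on alpha[1, ]
  for (s in seq_len(S)) {
    Fm <- .applyTfwd(Fm, rho[s], alpha[s, ], px)
    Em <- .emissionMatrix(G[, s], .emissionTable(theta[s, ], px), px$K2)
    Fm <- Fm * Em
    cvec <- rowSums(Fm)
    if (any(cvec <= 0) || any(!is.finite(cvec)))
      stop("non-finite likelihood in the forward pass")
    Fm <- Fm / cvec
    loglik <- loglik + log(cvec)
    if (keep) { fs[[s]] <- Fm; cs[, s] <- cvec }
  }
  list(loglik = loglik, f = fs, c = cs)
}

## One EM iteration: E-step statistics via forward-backward, M-step update.
.hmmEMStep <- function(theta, alpha, rho, G, px) {
  n <- nrow(G); S <- ncol(G); K <- px$K; K2 <- px$K2
  fw <- .hmmForward(theta, alpha, rho, G, px, keep = TRUE)

  thNum <- matrix(0, S, K); thDen <- matrix(0, S, K)
  jl <- matrix(0, S, K)      # expected jump landings (both chains), sites >= 2
  nj <- numeric(S)           # expected jump counts (both chains)

  B <- matrix(1, n, K2)
  for (s in seq(S, 1L)) {
    th <- theta[s, ]
    E3 <- .emissionTable(th, px)
    gamma <- fw$f[[s]] * B   # rows sum to 1

    ## expected emitted minor alleles per chain given pair and genotype
    tk <- th[px$kIdx]; tl <- th[px$lIdx]
    het <- tk * (1 - tl) + (1 - tk) * tl
    A1 <- rbind(0, tk * (1 - tl) / het, 1)  # chain-1 allele | g = 0,1,2
    A2 <- rbind(0, (1 - tk) * tl / het, 1)
    g <- G[, s]; ok <- !is.na(g)
    A1m <- matrix(tk, n, K2, byrow = TRUE)  # NA: prior allele prob
    A2m <- matrix(tl, n, K2, byrow = TRUE)
    A1m[ok, ] <- A1[g[ok] + 1L, , drop = FALSE]
    A2m[ok, ] <- A2[g[ok] + 1L, , drop = FALSE]
    thNum[s, ] <- colSums(gamma * A1m) %*% px$Kmat +
                  colSums(gamma * A2m) %*% px$Lmat
    thDen[s, ] <- colSums(gamma) %*% px$Kmat + colSums(gamma) %*% px$Lmat

    if (s > 1L) {
      ## jump statistics; Gt folds the emission and forward scale of site s
      Em <- .emissionMatrix(g, E3, K2)
      Gt <- Em * B / fw$c[, s]
      fprev <- fw$f[[s - 1L]]
      a <- alpha[s, ]; r <- rho[s]
      ## chain 1: U(k', l) = sum_{l'} T1(l'|l) Gt(k', l')
      SkA <- Gt %*% (px$Kmat * a[px$lIdx])
      U <- (1 - r) * Gt + r * SkA[, px$kIdx, drop = FALSE]
      fl <- fprev %*% px$Lmat
      e1 <- colSums((U * fl[, px$lIdx, drop = FALSE]) %*% px$Kmat)
      ## chain 2: V(k, l') = sum_{k'} T1(k'|k) Gt(k', l')
      SlA <- Gt %*% (px$Lmat * a[px$kIdx])
      V <- (1 - r) * Gt + r * SlA[, px$lIdx, drop = FALSE]
      fk <- fprev %*% px$Kmat
      e2 <- colSums((V * fk[, px$kIdx, drop = FALSE]) %*% px$Lmat)
      jl[s, ] <- r * a * (e1 + e2)
      nj[s] <- sum(jl[s, ])
      B <- .applyTbwd(Gt, r, a, px)
    } else {
      ## site 1 always "jumps" from the virtual start
      jl[1L, ] <- colSums(gamma %*% px$Kmat + gamma %*% px$Lmat)
      nj[1L] <- 2 * n
    }
  }

  thetaNew <- thNum / pmax(thDen, 1e-300)
  thetaNew <- pmin(pmax(thetaNew, 1e-3), 1 - 1e-3)
  alphaNew <- alpha
  rhoNew <- rho
  for (s in seq_len(S)) {
    if (nj[s] > 1e-8) alphaNew[s, ] <- jl[s, ] / sum(jl[s, ])
    if (s > 1L) rhoNew[s] <- min(max(nj[s] / (2 * n), 0), 1)
  }
  list(theta = thetaNew, alpha = alphaNew, rho = rhoNew,
       loglik = sum(fw$loglik))
}

#' Fit the haplotype-cluster HMM by EM on unphased genotypes
#'
#' Estimates site-specific cluster weights, emission frequencies and jump
#' probabilities by expectation-maximization over the ordered-cluster-pair
#' hidden chain. Multiple seeded random restarts are run and the fit with
#' the best observed-data log-likelihood is returned. Emission frequencies
#' are floored to [1e-3, 1 - 1e-3] to avoid degenerate emissions.
#'
#' @param genotypes n x S matrix of dosages in \{0, 1, 2\} (NA allowed,
#'   marginalized during fitting), restricted to one chromosome in physical
#'   order.
#' @param K number of haplotype clusters (default 12, the fastPHASE
#'   convention).
#' @param nIter EM iterations per restart (default 25).
#' @param nRestarts random restarts (default 3); the best likelihood wins.
#' @param seed integer seed; fits are deterministic given the seed.
#' @param sites optional integer vector of dataset row indices the columns
#'   of \code{genotypes} correspond to (defaults to 1..S).
#' @param budget maximum allowed K^2 * S * n work size (default 2e9);
#'   larger problems error with advice to thin the sites.
#' @return A \linkS4class{GenotypeHMM}.
#' @export
fitGenotypeHMM <- function(genotypes, K = 12L, nIter = 25L, nRestarts = 3L,
                           seed = 1L, sites = NULL, budget = 2e9) {
  genotypes <- as.matrix(genotypes)
  n <- nrow(genotypes); S <- ncol(genotypes)
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  if (as.numeric(K)^2 * S * n > budget)
    stop("HMM problem size K^2 * sites * n = ", K^2 * S * n,
         " exceeds the budget (", budget, "); thin the sites or reduce K")
  vals <- genotypes[!is.na(genotypes)]
  if (!all(vals %in% c(0, 1, 2)))
    stop("genotypes must take values in {0, 1, 2}")
  if (is.null(sites)) sites <- seq_len(S)
  px <- .pairIndex(K)
  freq <- pmin(pmax(colMeans(genotypes, na.rm = TRUE) / 2, 0.02), 0.98)

  best <- NULL
  .withSeed(seed, {
    for (r in seq_len(nRestarts)) {
      theta <- matrix(pmin(pmax(freq + stats::rnorm(S * K, sd = 0.1), 1e-3),
                           1 - 1e-3), S, K)
      alpha <- matrix(stats::rgamma(S * K, shape = 5), S, K)
      alpha <- alpha / rowSums(alpha)
      rho <- c(1, rep(0.05, S - 1L))
      trace <- numeric(nIter)
      for (it in seq_len(nIter)) {
        step <- .hmmEMStep(theta, alpha, rho, genotypes, px)
        trace[it] <- step$loglik    # likelihood of the *entering* parameters
        theta <- step$theta; alpha <- step$alpha; rho <- step$rho
      }
      final <- sum(.hmmForward(theta, alpha, rho, genotypes, px)$loglik)
      trace <- c(trace, final)
      if (is.null(best) || final > best$final)
        best <- list(theta = theta, alpha = alpha, rho = rho,
                     trace = trace, final = final)
    }
  })
  methods::new("GenotypeHMM", K = K, sites = as.integer(sites),
               alpha = best$alpha, theta = best$theta, rho = best$rho,
               logLik = best$final, logLikTrace = best$trace,
               nIter = as.integer(nIter))
}

#' Log-likelihood of genotype rows under the pair HMM (forward algorithm)
#'
#' Runs the scaled forward recursion over ordered cluster pairs. Missing
#' values (NA) are marginalized: the site contributes no emission, only its
#' transition, which is how conditioning subsets are evaluated.
#'
#' @param hmm a \linkS4class{GenotypeHMM}.
#' @param genotypes a vector of length S or an n x S matrix with values in
#'   \{0, 1, 2\} or NA.
#' @return Numeric vector of per-row log-probabilities.
#' @export
forwardLoglik <- function(hmm, genotypes) {
  if (is.null(dim(genotypes))) genotypes <- matrix(genotypes, nrow = 1)
  if (ncol(genotypes) != length(hmm@sites))
    stop("genotype row length must equal the number of HMM sites")
  vals <- genotypes[!is.na(genotypes)]
  if (!all(vals %in% c(0, 1, 2)))
    stop("genotype values must lie in {0, 1, 2}")
  px <- .pairIndex(hmm@K)
  .hmmForward(hmm@theta, hmm@alpha, hmm@rho, genotypes, px)$loglik
}

#' Propensity scores for the binarized target from the genotype HMM
#'
#' For each sample, the forward algorithm evaluates the joint probabilities
#' of the conditioning genotype with the target dosage fixed at 0, 1 and 2
#' (excluded-window sites are marginalized); Bayes' theorem then gives
#' e_i = P(A = +1, X_A) / (P(A = +1, X_A) + P(A = -1, X_A)), where dosages
#' \{1, 2\} (dominant) or \{2\} (recessive) are consistent with A = +1.
#'
#' @param hmm a \linkS4class{GenotypeHMM} fitted on the target's chromosome
#'   (its sites must include the target).
#' @param ds the imputed \linkS4class{GenotypeData}.
#' @param target a \linkS4class{TargetEncoding}.
#' @param excluded integer vector of excluded SNP row indices (the
#'   exclusion window; may include the target itself).
#' @param clip numerical guard: scores are clamped to
#'   [clip, 1 - clip] with a warning if they escape (default 1e-6).
#' @return A \linkS4class{PropensityScores}.
#' @export
propensityScores <- function(hmm, ds, target, excluded = integer(0),
                             clip = 1e-6) {
  sites <- hmm@sites
  tpos <- match(target@targetIndex, sites)
  if (is.na(tpos)) stop("the HMM sites must include the target SNP")
  G <- t(dosages(ds)[sites, , drop = FALSE])   # n x S
  if (anyNA(G)) stop("impute missing dosages before propensity estimation")
  drop <- setdiff(intersect(excluded, sites), target@targetIndex)
  G[, match(drop, sites)] <- NA_real_

  ll <- vapply(0:2, function(d) {
    Gd <- G; Gd[, tpos] <- d
    forwardLoglik(hmm, Gd)
  }, numeric(nrow(G)))                          # n x 3
  lse <- function(M) {                          # row-wise log-sum-exp
    m <- apply(M, 1, max)
    m + log(rowSums(exp(M - m)))
  }
  if (target@rule == "dominant") {
    lplus <- lse(ll[, 2:3, drop = FALSE]); lminus <- ll[, 1]
  } else {
    lplus <- ll[, 3]; lminus <- lse(ll[, 1:2, drop = FALSE])
  }
  e <- 1 / (1 + exp(lminus - lplus))
  if (any(e < clip | e > 1 - clip)) {
    warning("propensity scores clamped to [", clip, ", ", 1 - clip, "]")
    e <- pmin(pmax(e, clip), 1 - clip)
  }
  cond <- setdiff(sites, union(excluded, target@targetIndex))
  methods::new("PropensityScores", e = as.numeric(e),
               conditioningSites = as.integer(cond),
               targetIndex = target@targetIndex, rule = target@rule)
}
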