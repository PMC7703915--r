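## The four inverse-propensity-weighted modified outcomes and the
## outcome-weighted-learning sample weights. Throughout, aTilde is the
## {0, 1} encoding of the binarized target, e the propensity score
## P(A = +1 | X), and Y a binary or non-negative continuous phenotype.

.checkOutcomeArgs <- function(Y, aTilde, e, requireOpen = TRUE) {
  if (length(Y) != length(aTilde) || length(Y) != length(e))
    stop("Y, aTilde and e must have equal length")
  if (!all(aTilde %in% c(0, 1))) stop("aTilde must take values in {0, 1}")
  if (requireOpen && any(e <= 0 | e >= 1))
    stop("propensity scores must lie strictly inside (0, 1)")
}

.asE <- function(e) if (methods::is(e, "PropensityScores")) e@e else e

#' Plain modified outcome
#'
#' yTilde_i = Y_i (aTilde_i / e_i - (1 - aTilde_i) / (1 - e_i)). The
#' conditional mean identity E[yTilde | X] = 2 delta(X) makes the support
#' of the synergy function recoverable by sparse regression of yTilde on X.
#' When e = 1/2 everywhere this reduces to 2 Y A.
#'
#' @param Y phenotype vector (0/1 or non-negative continuous).
#' @param aTilde \{0, 1\} target encoding (see
#'   \code{\link{binarizeTarget}}).
#' @param e propensity scores in (0, 1), or a
#'   \linkS4class{PropensityScores}.
#' @return A \linkS4class{ModifiedOutcome}.
#' @export
plainModifiedOutcome <- function(Y, aTilde, e) {
  e <- .asE(e)
  .checkOutcomeArgs(Y, aTilde, e)
  yt <- Y * (aTilde / e - (1 - aTilde) / (1 - e))
  methods::new("ModifiedOutcome", yTilde = yt, variant = "plain",
               xi = NA_real_, w = c(NA_real_, NA_real_),
               Ct = c(NA_real_, NA_real_))
}

#' Shifted modified outcome
#'
#' Adds a small constant \code{xi} to both denominators, which caps every
#' individual inverse-propensity weight at 1/xi:
#' yTilde_i = Y_i (aTilde_i / (e_i + xi) - (1 - aTilde_i) / (1 - e_i + xi)).
#'
#' @inheritParams plainModifiedOutcome
#' @param xi positive shift added to the denominators (default 0.1).
#' @return A \linkS4class{ModifiedOutcome}.
#' @export
shiftedModifiedOutcome <- function(Y, aTilde, e, xi = 0.1) {
  e <- .asE(e)
  if (xi <= 0) stop("xi must be positive")
  .checkOutcomeArgs(Y, aTilde, e)
  yt <- Y * (aTilde / (e + xi) - (1 - aTilde) / (1 - e + xi))
  methods::new("ModifiedOutcome", yTilde = yt, variant = "shifted",
               xi = xi, w = c(NA_real_, NA_real_), Ct = c(NA_real_, NA_real_))
}

#' Normalized modified outcome
#'
#' Rescales the inverse-propensity weights so the total weight of each
#' target arm equals one: w_t = 1 / sum_j [t aTilde_j / e_j +
#' (1 - t)(1 - aTilde_j) / (1 - e_j)], and
#' yTilde_i = Y_i (w1 aTilde_i / e_i - w0 (1 - aTilde_i) / (1 - e_i)).
#'
#' @inheritParams plainModifiedOutcome
#' @return A \linkS4class{ModifiedOutcome}.
#' @export
normalizedModifiedOutcome <- function(Y, aTilde, e) {
  e <- .asE(e)
  .checkOutcomeArgs(Y, aTilde, e)
  if (sum(aTilde == 1) == 0 || sum(aTilde == 0) == 0)
    stop("both target arms must be non-empty")
  w1 <- 1 / sum(aTilde / e)
  w0 <- 1 / sum((1 - aTilde) / (1 - e))
  yt <- Y * (w1 * aTilde / e - w0 * (1 - aTilde) / (1 - e))
  methods::new("ModifiedOutcome", yTilde = yt, variant = "normalized",
               xi = NA_real_, w = c(w0, w1), Ct = c(NA_real_, NA_real_))
}

#' Robust modified outcome
#'
#' The low-variance inverse-propensity estimator of Lunceford and Davidian,
#' with arm corrections
#' C_t = sum_j [(aTilde_j - e_j) / d_tj] / sum_j [(aTilde_j - e_j) / d_tj]^2,
#' d_tj = t e_j + (1 - t)(1 - e_j), arm normalizers
#' w_t = 1 / sum_j [t (1 - C_1/e_j) aTilde_j / e_j +
#'                  (1 - t)(1 - C_0/(1 - e_j))(1 - aTilde_j) / (1 - e_j)],
#' and yTilde_i = Y_i (w1 (1 - C_1/e_i) aTilde_i / e_i -
#'                     w0 (1 - C_0/(1 - e_i))(1 - aTilde_i) / (1 - e_i)).
#' When the estimated propensity is constant and equal to mean(aTilde) the
#' corrections vanish and the estimator coincides with the normalized one.
#'
#' @inheritParams plainModifiedOutcome
#' @return A \linkS4class{ModifiedOutcome}.
#' @export
robustModifiedOutcome <- function(Y, aTilde, e) {
  e <- .asE(e)
  .checkOutcomeArgs(Y, aTilde, e)
  if (sum(aTilde == 1) == 0 || sum(aTilde == 0) == 0)
    stop("both target arms must be non-empty")
  Cval <- numeric(2)
  for (t in 0:1) {
    d <- t * e + (1 - t) * (1 - e)
    z <- (aTilde - e) / d
    den <- sum(z^2)
    if (den < 1e-300) {
      warning("degenerate denominator in C_", t, "; falling back to C = 0")
      Cval[t + 1] <- 0
    } else {
      Cval[t + 1] <- sum(z) / den
    }
  }
  C0 <- Cval[1]; C1 <- Cval[2]
  u1 <- (1 - C1 / e) * aTilde / e
  u0 <- (1 - C0 / (1 - e)) * (1 - aTilde) / (1 - e)
  w1 <- 1 / sum(u1)
  w0 <- 1 / sum(u0)
  yt <- Y * (w1 * u1 - w0 * u0)
  methods::new("ModifiedOutcome", yTilde = yt, variant = "robust",
               xi = NA_real_, w = c(w0, w1), Ct = c(C0, C1))
}

#' Construct a modified outcome by variant name
#'
#' @inheritParams plainModifiedOutcome
#' @param variant one of \code{"plain"}, \code{"shifted"},
#'   \code{"normalized"}, \code{"robust"}.
#' @param xi shift for the shifted variant.
#' @return A \linkS4class{ModifiedOutcome}.
#' @export
modifiedOutcome <- function(Y, aTilde, e,
                            variant = c("plain", "shifted", "normalized",
                                        "robust"),
                            xi = 0.1) {
  variant <- match.arg(variant)
  switch(variant,
         plain = plainModifiedOutcome(Y, aTilde, e),
         shifted = shiftedModifiedOutcome(Y, aTilde, e, xi = xi),
         normalized = normalizedModifiedOutcome(Y, aTilde, e),
         robust = robustModifiedOutcome(Y, aTilde, e))
}

#' Outcome-weighted-learning sample weights
#'
#' W_i = Y_i / P(A_i | X_i) with P(A_i | X_i) = e_i when A_i = +1 and
#' 1 - e_i otherwise. With a 0/1 phenotype, controls receive weight exactly
#' zero, making the downstream weighted classification of A on X a
#' case-only analysis.
#'
#' @param Y non-negative phenotype vector.
#' @param A \{-1, +1\} target encoding.
#' @param e propensity scores in (0, 1), or a
#'   \linkS4class{PropensityScores}.
#' @return An \linkS4class{OwlSample}.
#' @export
owlWeights <- function(Y, A, e) {
  e <- .asE(e)
  if (any(Y < 0)) stop("OWL requires a non-negative phenotype")
  if (!all(A %in% c(-1, 1))) stop("A must take values in {-1, +1}")
  if (any(e <= 0 | e >= 1))
    stop("propensity scores must lie strictly inside (0, 1)")
  pA <- ifelse(A == 1, e, 1 - e)
  methods::new("OwlSample", weights = Y / pA, response = as.numeric(A))
}
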