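## Elastic-net support estimation over a regularization grid, stability
## selection by repeated subsampling, and the area-under-stability-path
## score. The elastic-net mixing is s = 1e-6 (essentially lasso, with a
## whisper of ridge for numerical stability); solvers are provided by
## glmnet, with the penalty conventions aligned so that our lambda is
## glmnet's lambda exactly (alpha = 1 - s).

#' Standardize design columns to zero mean and unit variance
#'
#' Variance uses the 1/n denominator (glmnet's internal convention) so the
#' lambda-grid arithmetic is exact. Zero-variance columns error.
#'
#' @param design numeric matrix, samples x variables.
#' @return The standardized matrix.
#' @export
standardizeDesign <- function(design) {
  design <- as.matrix(design)
  mu <- colMeans(design)
  sd2 <- colMeans(design^2) - mu^2
  if (any(sd2 <= 0)) stop("zero-variance design column(s): ",
                          paste(which(sd2 <= 0), collapse = ", "))
  scale(design, center = mu, scale = sqrt(sd2))
}

#' Build the regularization grid
#'
#' lambda_max is the smallest penalty yielding an all-zero model: the
#' maximum absolute coordinate of the null-model score function, scaled by
#' 1/(1 - s). A log-spaced grid of \code{gridSize} values from lambda_max
#' down to lambda_max/\code{ratio} is generated and truncated to its first
#' \code{gridKeep} values, discarding the low-penalty half of the path
#' where irrelevant covariates flood the support.
#'
#' @param design standardized design matrix (samples x variables).
#' @param response response vector (the modified outcome for squared loss;
#'   0/1 class for weighted logistic loss).
#' @param sampleWeights non-negative sample weights (default 1).
#' @param loss \code{"squared"} or \code{"logistic"}.
#' @param s elastic-net mixing (default 1e-6).
#' @param gridSize,ratio,gridKeep grid construction: \code{gridSize}
#'   log-spaced points spanning a factor of \code{ratio}, first
#'   \code{gridKeep} retained.
#' @return Decreasing numeric vector of lambda values.
#' @export
makeLambdaGrid <- function(design, response, sampleWeights = NULL,
                           loss = c("squared", "logistic"), s = 1e-6,
                           gridSize = 200L, ratio = 100, gridKeep = 100L) {
  loss <- match.arg(loss)
  n <- nrow(design)
  w <- if (is.null(sampleWeights)) rep(1, n) else sampleWeights
  w <- w / sum(w) * n                    # glmnet normalizes weights to sum n
  ybar <- sum(w * response) / n
  grad <- abs(crossprod(design, w * (response - ybar))) / n
  lambdaMax <- max(grad) / (1 - s)
  if (lambdaMax <= 0) stop("degenerate response: lambda_max is zero")
  full <- exp(seq(log(lambdaMax), log(lambdaMax / ratio),
                  length.out = gridSize))
  full[seq_len(min(gridKeep, gridSize))]
}

#' Elastic-net support along a lambda path
#'
#' Minimizes R(gamma) + lambda[(1 - s)|gamma|_1 + (s/2)|gamma|_2^2] with an
#' unpenalized intercept, where R is the mean squared error (glmnet's
#' 1/(2n) scaling) or the weighted logistic deviance. The support is the
#' set of coefficients exceeding 1e-12 in absolute value on the
#' standardized scale.
#'
#' @param design standardized design matrix.
#' @param response response vector (for logistic loss, values coercible to
#'   0/1).
#' @param sampleWeights non-negative sample weights.
#' @param lambda a single penalty or a decreasing vector of penalties.
#' @param s elastic-net mixing (default 1e-6).
#' @param loss \code{"squared"} or \code{"logistic"}.
#' @return If \code{lambda} is scalar, an integer vector of selected column
#'   indices; otherwise a logical variables x lambda matrix.
#' @export
enetSupport <- function(design, response, sampleWeights = NULL, lambda,
                        s = 1e-6, loss = c("squared", "logistic")) {
  loss <- match.arg(loss)
  supp <- .enetSupportMatrix(design, response, sampleWeights, lambda, s, loss)
  if (length(lambda) == 1L) which(supp[, 1]) else supp
}

.enetSupportMatrix <- function(design, response, sampleWeights, lambda,
                               s, loss) {
  n <- nrow(design)
  w <- if (is.null(sampleWeights)) rep(1, n) else sampleWeights
  if (any(w < 0)) stop("sample weights must be non-negative")
  family <- if (loss == "squared") "gaussian" else "binomial"
  if (loss == "logistic") {
    cls <- unique(response[w > 0])
    if (length(cls) < 2L)
      stop("logistic loss requires both response classes among positive-weight samples")
  }
  fit <- suppressWarnings(glmnet::glmnet(
    x = design, y = response, weights = w, family = family,
    alpha = 1 - s, lambda = lambda, standardize = FALSE, intercept = TRUE,
    thresh = 1e-10, maxit = 1e6))
  beta <- as.matrix(fit$beta)
  ## glmnet may drop trailing lambdas on non-convergence; that is an error
  if (ncol(beta) != length(lambda))
    stop("elastic net failed to converge over the full lambda path (",
         ncol(beta), "/", length(lambda), " fitted)")
  abs(beta) > 1e-12
}

#' Stability selection over subsamples
#'
#' Draws \code{N} subsamples of size floor(n/2) uniformly without
#' replacement, fits the elastic net over the full lambda grid on each, and
#' records the per-variable selection frequencies omega (variables x grid).
#' Per-method normalizers that depend on the sample (the w_t and C_t of the
#' normalized/robust modified outcomes) are recomputed inside each
#' subsample through the \code{refit} hook.
#'
#' @param design standardized design matrix (samples x variables).
#' @param response full-cohort response vector.
#' @param sampleWeights full-cohort sample weights (or NULL).
#' @param grid decreasing lambda grid (see \code{\link{makeLambdaGrid}}).
#' @param N number of subsamples (default 50).
#' @param seed integer seed; results are deterministic given the seed.
#' @param loss \code{"squared"} or \code{"logistic"}.
#' @param s elastic-net mixing (default 1e-6).
#' @param refit optional \code{function(idx)} returning
#'   \code{list(response =, weights =)} for the subsample \code{idx},
#'   used to rebuild sample-dependent responses inside each subsample.
#' @param ids variable identifiers (default column names or indices).
#' @return A \linkS4class{StabilityPath}.
#' @export
stabilitySelection <- function(design, response = NULL, sampleWeights = NULL,
                               grid, N = 50L, seed = 1L,
                               loss = c("squared", "logistic"), s = 1e-6,
                               refit = NULL, ids = NULL) {
  loss <- match.arg(loss)
  n <- nrow(design); p <- ncol(design)
  if (n < 4L) stop("stability selection needs at least 4 samples")
  m <- n %/% 2L
  counts <- matrix(0, p, length(grid))
  .withSeed(seed, {
    for (j in seq_len(N)) {
      idx <- sample.int(n, m)
      sub <- if (is.null(refit)) {
        list(response = response[idx],
             weights = if (is.null(sampleWeights)) NULL
                       else sampleWeights[idx])
      } else refit(idx)
      supp <- tryCatch(
        .enetSupportMatrix(design[idx, , drop = FALSE], sub$response,
                           sub$weights, grid, s, loss),
        error = function(err) {
          ## one retry with a fresh subsample (e.g. single-class draw)
          idx2 <- sample.int(n, m)
          sub2 <- if (is.null(refit)) {
            list(response = response[idx2],
                 weights = if (is.null(sampleWeights)) NULL
                           else sampleWeights[idx2])
          } else refit(idx2)
          .enetSupportMatrix(design[idx2, , drop = FALSE], sub2$response,
                             sub2$weights, grid, s, loss)
        })
      counts <- counts + supp
    }
  })
  omega <- counts / N
  if (is.null(ids)) {
    ids <- colnames(design)
    if (is.null(ids)) ids <- as.character(seq_len(p))
  }
  methods::new("StabilityPath", omega = omega, lambda = as.numeric(grid),
               nSubsamples = as.integer(N), subsampleSize = as.integer(m),
               scores = rowMeans(omega), ids = as.character(ids))
}

#' Area under the stability path
#'
#' The per-variable score is the mean selection frequency over grid
#' positions (rectangle rule with unit spacing on the grid index, 1/|Grid|
#' normalization): score_k = mean_l omega_k(lambda_l), in [0, 1]. Using
#' grid positions rather than lambda values makes scores comparable across
#' methods whose regularization paths live on different lambda scales.
#'
#' @param path a \linkS4class{StabilityPath}.
#' @return Named numeric vector of per-variable scores.
#' @export
areaScore <- function(path) {
  stats::setNames(rowMeans(path@omega), path@ids)
}
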