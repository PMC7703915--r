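test_that("the lambda grid has the prescribed shape and lambda_max", {
  set.seed(51)
  X <- standardizeDesign(matrix(rnorm(600), 100, 6))
  y <- rnorm(100) + 0.7 * X[, 2]
  grid <- makeLambdaGrid(X, y, loss = "squared")
  expect_length(grid, 100)
  expect_true(all(diff(grid) < 0))
  ## log-spacing arithmetic: lambda_100 / lambda_1 = (1/100)^(99/199)
  expect_equal(grid[100] / grid[1], (1 / 100)^(99 / 199), tolerance = 1e-12)
  ## lambda_max formula for a standardized design
  s <- 1e-6
  expect_equal(grid[1], max(abs(crossprod(X, y - mean(y)))) / 100 / (1 - s),
               tolerance = 1e-12)
  ## the single-column case pins the formula exactly
  x1 <- X[, 1, drop = FALSE]
  g1 <- makeLambdaGrid(x1, y, loss = "squared")
  expect_equal(g1[1], abs(sum(x1 * (y - mean(y)))) / 100 / (1 - s),
               tolerance = 1e-12)
  expect_error(standardizeDesign(cbind(X[, 1], rep(2, 100))),
               "zero-variance")
})

test_that("lambda_max is the boundary of the empty support (both losses)", {
  set.seed(52)
  X <- standardizeDesign(matrix(rnorm(1200), 150, 8))
  y <- rnorm(150) + X[, 3]
  grid <- makeLambdaGrid(X, y, loss = "squared")
  expect_length(enetSupport(X, y, lambda = grid[1], loss = "squared"), 0)
  expect_gt(length(enetSupport(X, y, lambda = grid[1] * 0.98,
                               loss = "squared")), 0)
  yb <- rbinom(150, 1, plogis(X[, 2]))
  w <- runif(150, 0.2, 2)
  gl <- makeLambdaGrid(X, yb, sampleWeights = w, loss = "logistic")
  expect_length(enetSupport(X, yb, w, lambda = gl[1], loss = "logistic"), 0)
  expect_gt(length(enetSupport(X, yb, w, lambda = gl[1] * 0.95,
                               loss = "logistic")), 0)
})

test_that("supports on orthonormal designs match soft-thresholding", {
  H <- hadamardDesign()                  # 8 x 7, orthogonal, unit variance
  set.seed(53)
  y <- rnorm(8, sd = 2)
  X <- standardizeDesign(H)
  rho <- abs(crossprod(X, y - mean(y))) / 8
  for (lam in c(0.9, 0.5, 0.25, 0.1) * max(rho)) {
    ## stay away from the decision boundary by a safety margin
    if (min(abs(rho - lam)) < 1e-4) next
    supp <- enetSupport(X, y, lambda = lam, loss = "squared")
    expect_identical(unname(supp), which(rho > lam * (1 - 1e-6))[TRUE])
  }
})

test_that("stability selection frequencies behave like frequencies", {
  set.seed(54)
  n <- 200; p <- 12
  X <- standardizeDesign(matrix(rnorm(n * p), n, p))
  y <- drop(X[, 1:2] %*% c(2, -2)) + rnorm(n, sd = 0.5)
  grid <- makeLambdaGrid(X, y, loss = "squared")
  path <- stabilitySelection(X, y, grid = grid, N = 20, seed = 7,
                             loss = "squared")
  expect_true(all(path@omega >= 0 & path@omega <= 1))
  expect_true(all(path@scores >= 0 & path@scores <= 1))
  expect_equal(path@subsampleSize, 100L)
  ## strong causal columns dominate the score ranking
  expect_gt(min(path@scores[1:2]), max(path@scores[3:p]))
  ## determinism under the same seed
  path2 <- stabilitySelection(X, y, grid = grid, N = 20, seed = 7,
                              loss = "squared")
  expect_identical(path@omega, path2@omega)
  ## the refit hook is honoured inside each subsample: an identity hook
  ## reproduces the plain run, a sign-flipping hook still selects the
  ## causal columns (supports are sign-invariant)
  hook <- function(idx) list(response = y[idx], weights = NULL)
  pathHook <- stabilitySelection(X, y, grid = grid, N = 20, seed = 7,
                                 loss = "squared", refit = hook)
  expect_identical(pathHook@omega, path@omega)
  flipHook <- function(idx) list(response = -y[idx], weights = NULL)
  pathFlip <- stabilitySelection(X, y, grid = grid, N = 20, seed = 7,
                                 loss = "squared", refit = flipHook)
  expect_equal(pathFlip@omega, path@omega, tolerance = 1e-12)
})

test_that("the area score is the mean selection frequency over grid positions", {
  omega <- rbind(rep(1, 3), c(1, 0.5, 0), rep(0, 3))
  path <- methods::new("StabilityPath", omega = omega,
                       lambda = c(3, 2, 1), nSubsamples = 2L,
                       subsampleSize = 5L, scores = rowMeans(omega),
                       ids = c("a", "b", "c"))
  sc <- areaScore(path)
  expect_equal(unname(sc), c(1, 0.5, 0))
  ## scores depend on grid positions only, not on the lambda values
  path@lambda <- c(300, 2, 0.1)
  expect_equal(areaScore(path), sc)
})

test_that("causal columns outscore null columns across seeded runs", {
  set.seed(55)
  n <- 300; p <- 60
  wins <- 0
  for (run in 1:10) {
    X <- standardizeDesign(matrix(rnorm(n * p), n, p))
    causal <- 1:5
    y <- drop(X[, causal] %*% rep(1.5, 5)) + rnorm(n)
    grid <- makeLambdaGrid(X, y, loss = "squared")
    path <- stabilitySelection(X, y, grid = grid, N = 15, seed = run,
                               loss = "squared")
    if (mean(path@scores[causal]) > mean(path@scores[-causal]))
      wins <- wins + 1
  }
  expect_gte(wins, 10 * 0.95)
})
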