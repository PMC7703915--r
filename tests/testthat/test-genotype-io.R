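test_that("PLINK triplet round-trips dosages, metadata and phenotypes", {
  set.seed(1)
  n <- 17; p <- 7                       # n not divisible by 4: byte padding
  G <- matrix(rbinom(n * p, 2, 0.3), n, p)
  G[2, 3] <- NA; G[5, 1] <- NA
  y <- c(rep(0, 8), rep(1, 8), NA)
  ds <- makeCohort(G, phenotype = y)
  prefix <- file.path(tempdir(), "rt")
  writePlink(ds, prefix)
  back <- readPlink(paste0(prefix, ".bed"))
  expect_equal(unname(dosages(back)), unname(dosages(ds)))
  expect_equal(snpInfo(back)$snp, snpInfo(ds)$snp)
  expect_equal(snpInfo(back)$position, as.numeric(snpInfo(ds)$position))
  expect_identical(phenotype(back), phenotype(ds))
  ## a second round trip is the identity on the re-read object
  writePlink(back, paste0(prefix, "2"))
  back2 <- readPlink(paste0(prefix, "2.bed"))
  expect_equal(dosages(back2), dosages(back))
})

test_that("fam phenotype codes follow PLINK conventions", {
  G <- matrix(c(0, 1, 2, 1, 0, 2, 1, 1), 4, 2)
  ds <- makeCohort(G, phenotype = c(0, 1, 1, NA))
  prefix <- file.path(tempdir(), "ph")
  writePlink(ds, prefix)
  fam <- read.table(paste0(prefix, ".fam"))
  expect_equal(fam$V6, c(1, 2, 2, -9))        # 0->1, 1->2, NA->-9
  back <- readPlink(paste0(prefix, ".bed"))
  expect_identical(phenotype(back), c(0, 1, 1, NA))
})

test_that("malformed bed magic bytes are rejected", {
  G <- matrix(c(0, 1, 2, 0), 2, 2)
  ds <- makeCohort(G, phenotype = c(0, 1))
  prefix <- file.path(tempdir(), "bad")
  writePlink(ds, prefix)
  raw <- readBin(paste0(prefix, ".bed"), "raw", 100)
  raw[1] <- as.raw(0xff)
  writeBin(raw, paste0(prefix, ".bed"))
  expect_error(readPlink(paste0(prefix, ".bed")), "magic")
})

test_that("modal imputation fills missing dosages with tie-break to smaller", {
  G <- rbind(c(0, 1, 0), c(0, 1, 1), c(NA, 2, NA), c(2, NA, 0), c(1, 1, 1))
  ds <- imputeMissing(makeCohort(G))
  gi <- t(dosages(ds))
  expect_equal(gi[3, 1], 0)             # column (0,0,NA,2,1): mode 0
  expect_equal(gi[4, 2], 1)             # column (1,1,2,NA,1): mode 1
  expect_equal(gi[3, 3], 0)             # counts {0:2, 1:2}: tie -> 0
  ## an entirely missing SNP errors with its name
  G2 <- cbind(c(NA, NA, NA), c(0, 1, 2))
  expect_error(imputeMissing(makeCohort(G2)), "rs0001")
})

test_that("HWE p-value matches the closed-form chi-square oracle", {
  expect_equal(hwePvalue(25, 50, 25), 1)          # exact HWE at q = 0.5
  expect_equal(hwePvalue(100, 0, 0), 1)           # monomorphic convention
  ## independent formula oracle for (n0, n1, n2)
  hweOracle <- function(n0, n1, n2) {
    n <- n0 + n1 + n2
    q <- (n1 + 2 * n2) / (2 * n)
    ex <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
    pchisq(sum((c(n0, n1, n2) - ex)^2 / ex), 1, lower.tail = FALSE)
  }
  expect_lt(hwePvalue(50, 0, 50), 1e-6)
  expect_equal(hwePvalue(50, 0, 50), hweOracle(50, 0, 50), tolerance = 1e-12)
  expect_equal(hwePvalue(30, 45, 25), hweOracle(30, 45, 25), tolerance = 1e-12)
})

test_that("QC filter drops by MAF and HWE with reasons, and is idempotent", {
  set.seed(2)
  n <- 200
  good <- rbinom(n, 2, 0.45)                     # common, in HWE
  rare <- c(rep(1, 2), rep(0, n - 2))            # MAF = 0.005
  offHwe <- c(rep(0, n / 2), rep(2, n / 2))      # no hets at q = 0.5
  G <- cbind(good, rare, offHwe, rbinom(n, 2, 0.3))
  ds <- makeCohort(G)
  out <- qcFilter(ds)
  expect_setequal(out$report$snp, c("rs0002", "rs0003"))
  expect_equal(out$report$reason[out$report$snp == "rs0002"], "maf")
  expect_equal(out$report$reason[out$report$snp == "rs0003"], "hwe")
  expect_true("rs0001" %in% snpInfo(out$dataset)$snp)
  ## idempotence: filtering a filtered dataset drops nothing
  again <- qcFilter(out$dataset)
  expect_equal(nrow(again$report), 0L)
  expect_equal(nSnps(again$dataset), nSnps(out$dataset))
})

test_that("target binarization follows the dominant/recessive mapping", {
  G <- cbind(c(0, 1, 2), c(2, 0, 1))
  ds <- makeCohort(G, phenotype = c(0, 1, 1))
  dom <- binarizeTarget(ds, "rs0001", "dominant")
  expect_equal(dom@A, c(-1, 1, 1))
  expect_equal(dom@aTilde, c(0, 1, 1))
  rec <- binarizeTarget(ds, "rs0001", "recessive")
  expect_equal(rec@A, c(-1, -1, 1))
  expect_error(binarizeTarget(ds, "nope", "dominant"), "not found")
  ## constant encodings are rejected
  G2 <- cbind(c(1, 2, 1), c(0, 1, 2))
  expect_error(binarizeTarget(makeCohort(G2), "rs0001", "dominant"),
               "constant")
  ## the two rules agree wherever dosage is 0 or 2
  set.seed(3)
  G3 <- cbind(rbinom(40, 2, 0.5), rbinom(40, 2, 0.5))
  ds3 <- makeCohort(G3)
  d3 <- binarizeTarget(ds3, "rs0001", "dominant")
  r3 <- binarizeTarget(ds3, "rs0001", "recessive")
  hom <- G3[, 1] %in% c(0, 2)
  expect_equal(d3@A[hom], r3@A[hom])
})
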