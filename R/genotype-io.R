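## PLINK 1.9 binary triplet IO, QC and target binarization.
##
## The .bed decoder follows the SNP-major v1.00 layout: magic bytes
## 0x6c 0x1b 0x01, then ceiling(n/4) bytes per SNP, two bits per sample
## (LSB first): 00 = homozygous A1, 01 = missing, 10 = heterozygous,
## 11 = homozygous A2. Dosages count minor alleles; the minor/major
## assignment is determined from the file's allele frequencies at load
## time and frozen thereafter.

#' Read a PLINK binary genotype triplet
#'
#' @param bedPath,bimPath,famPath paths to the .bed / .bim / .fam files. If
#'   \code{bimPath}/\code{famPath} are missing they are derived from
#'   \code{bedPath} by extension replacement.
#' @return A \linkS4class{GenotypeData}. Phenotypes follow PLINK fam coding:
#'   1 = control (0), 2 = case (1), 0 or -9 = missing (\code{NA}); any other
#'   value is taken as a continuous phenotype.
#' @details Dosages are re-oriented so that they always count the minor
#'   allele (allele frequencies computed from the file at load time);
#'   \code{allele1} in \code{snpInfo} is the counted allele.
#' @seealso \code{\link{writePlink}}, \code{\link{imputeMissing}},
#'   \code{\link{qcFilter}}
#' @export
readPlink <- function(bedPath, bimPath = sub("\\.bed$", ".bim", bedPath),
                      famPath = sub("\\.bed$", ".fam", bedPath)) {
  for (f in c(bedPath, bimPath, famPath))
    if (!file.exists(f)) stop("file not found: ", f)
  bim <- utils::read.table(bimPath, header = FALSE, sep = "\t",
                           colClasses = c("character", "character", "numeric",
                                          "numeric", "character", "character"))
  colnames(bim) <- c("chromosome", "snp", "cm", "position", "a1", "a2")
  fam <- utils::read.table(famPath, header = FALSE,
                           colClasses = c("character", "character", "character",
                                          "character", "character", "numeric"))
  colnames(fam) <- c("fid", "iid", "pat", "mat", "sex", "pheno")
  p <- nrow(bim); n <- nrow(fam)

  raw <- readBin(bedPath, "raw", n = file.info(bedPath)$size)
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("malformed .bed file: wrong magic bytes")
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed files are supported")
  bytesPerSnp <- ceiling(n / 4)
  if (length(raw) - 3L != p * bytesPerSnp)
    stop(sprintf(".bed size inconsistent with bim/fam dimensions (expected %d data bytes, found %d)",
                 p * bytesPerSnp, length(raw) - 3L))

  ## decode all 2-bit fields at once
  body <- as.integer(raw[-(1:3)])
  codes <- rbind(body %% 4L, (body %/% 4L) %% 4L,
                 (body %/% 16L) %% 4L, body %/% 64L)  # 4 samples per byte
  dim(codes) <- c(4L * bytesPerSnp, p)
  codes <- codes[seq_len(n), , drop = FALSE]          # samples x SNPs
  lookup <- c(2, NA, 1, 0)                            # codes 0,1,2,3 -> A1 count
  dosage <- matrix(lookup[codes + 1L], nrow = n, ncol = p)

  ## orient to minor-allele counts, freezing the assignment
  a1 <- bim$a1; a2 <- bim$a2
  freq <- colMeans(dosage, na.rm = TRUE) / 2
  flip <- !is.na(freq) & freq > 0.5
  if (any(flip)) {
    dosage[, flip] <- 2 - dosage[, flip]
    tmp <- a1[flip]; a1[flip] <- a2[flip]; a2[flip] <- tmp
  }

  pheno <- fam$pheno
  y <- ifelse(pheno %in% c(0, -9), NA,
              ifelse(pheno == 1, 0, ifelse(pheno == 2, 1, pheno)))
  if (any(!is.na(y) & y < 0))
    stop("unknown phenotype codes in .fam column 6")

  GenotypeData(t(dosage),
    snps = data.frame(snp = bim$snp, chromosome = bim$chromosome,
                      position = bim$position, allele1 = a1, allele2 = a2),
    samples = data.frame(sample = fam$iid, phenotype = y))
}

#' Write a GenotypeData cohort as a PLINK binary triplet
#'
#' @param ds a \linkS4class{GenotypeData}.
#' @param prefix output path prefix; \code{prefix.bed/.bim/.fam} are written.
#' @return \code{prefix}, invisibly.
#' @export
writePlink <- function(ds, prefix) {
  g <- dosages(ds)                      # SNPs x samples
  p <- nrow(g); n <- ncol(g)
  rd <- snpInfo(ds)
  bim <- data.frame(rd$chromosome, rd$snp, 0, rd$position, rd$allele1, rd$allele2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  y <- phenotype(ds)
  pheno <- ifelse(is.na(y), -9, ifelse(y == 0, 1, ifelse(y == 1, 2, y)))
  ids <- SummarizedExperiment::colData(ds)$sample
  fam <- data.frame(ids, ids, 0, 0, 0, pheno)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  ## dosage -> 2-bit code: 2 -> 00(0), NA -> 01(1), 1 -> 10(2), 0 -> 11(3)
  codeOf <- function(d) ifelse(is.na(d), 1L, ifelse(d == 2, 0L, ifelse(d == 1, 2L, 3L)))
  bytesPerSnp <- ceiling(n / 4)
  padded <- matrix(3L, nrow = 4L * bytesPerSnp, ncol = p)  # pad with hom-A2
  padded[seq_len(n), ] <- codeOf(t(g))
  ## pack 4 codes per byte, LSB first
  idx <- seq(1, nrow(padded), by = 4)
  bytes <- padded[idx, , drop = FALSE] + 4L * padded[idx + 1L, , drop = FALSE] +
    16L * padded[idx + 2L, , drop = FALSE] + 64L * padded[idx + 3L, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  invisible(prefix)
}

#' Impute missing dosages by the per-SNP mode
#'
#' Each missing dosage is replaced by the most frequent observed dosage for
#' that SNP; ties are broken toward the smaller dosage.
#'
#' @param ds a \linkS4class{GenotypeData}, possibly with missing dosages.
#' @return A \linkS4class{GenotypeData} with no missing dosages.
#' @export
imputeMissing <- function(ds) {
  g <- dosages(ds)
  miss <- is.na(g)
  if (!any(miss)) return(ds)
  bad <- rowSums(!miss) == 0
  if (any(bad))
    stop("SNP(s) entirely missing: ",
         paste(snpInfo(ds)$snp[bad], collapse = ", "))
  rows <- which(rowSums(miss) > 0)
  for (i in rows) {
    counts <- tabulate(g[i, !miss[i, ]] + 1L, nbins = 3L)
    mode <- which.max(counts) - 1L   # which.max takes the first max: ties -> smaller
    g[i, miss[i, ]] <- mode
  }
  out <- ds
  SummarizedExperiment::assay(out, "dosage") <- g
  out
}

#' Hardy-Weinberg equilibrium goodness-of-fit p-value
#'
#' One-degree-of-freedom chi-square test of the genotype counts against the
#' HWE expectations p^2, 2pq, q^2 at the sample allele frequency.
#' Monomorphic SNPs return p = 1 by convention.
#'
#' @param n0,n1,n2 counts of dosage 0, 1 and 2 genotypes.
#' @return The p-value.
#' @export
hwePvalue <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  if (n < 1) stop("at least one genotype is required")
  q <- (n1 + 2 * n2) / (2 * n)   # minor allele frequency of the counted allele
  if (q <= 0 || q >= 1) return(1)
  expd <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  stat <- sum((c(n0, n1, n2) - expd)^2 / expd)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Quality-control filter on MAF and Hardy-Weinberg equilibrium
#'
#' Drops SNPs with minor allele frequency at or below \code{mafMin} and SNPs
#' out of Hardy-Weinberg equilibrium at level \code{hweAlpha} (retaining
#' MAF > mafMin and HWE p >= hweAlpha). The sample set is unchanged.
#'
#' @param ds an imputed \linkS4class{GenotypeData}.
#' @param mafMin minor allele frequency threshold (default 0.01).
#' @param hweAlpha HWE p-value threshold (default 1e-6).
#' @return A list with the filtered \code{dataset} and a \code{report}
#'   data.frame (snp, reason, value) of the dropped SNPs.
#' @export
qcFilter <- function(ds, mafMin = 0.01, hweAlpha = 1e-6) {
  g <- dosages(ds)
  if (anyNA(g)) stop("impute missing dosages before QC filtering")
  maf <- rowMeans(g) / 2
  maf <- pmin(maf, 1 - maf)
  n0 <- rowSums(g == 0); n1 <- rowSums(g == 1); n2 <- rowSums(g == 2)
  hwe <- vapply(seq_len(nrow(g)),
                function(i) hwePvalue(n0[i], n1[i], n2[i]), numeric(1))
  dropMaf <- maf <= mafMin
  dropHwe <- !dropMaf & hwe < hweAlpha
  keep <- !(dropMaf | dropHwe)
  if (!any(keep)) stop("all SNPs removed by QC")
  report <- rbind(
    data.frame(snp = as.character(snpInfo(ds)$snp[dropMaf]),
               reason = rep("maf", sum(dropMaf)), value = maf[dropMaf]),
    data.frame(snp = as.character(snpInfo(ds)$snp[dropHwe]),
               reason = rep("hwe", sum(dropHwe)), value = hwe[dropHwe]))
  list(dataset = ds[keep, ], report = report)
}

#' Binarize the target SNP to {-1, +1}
#'
#' Under the dominant rule, dosages 1 and 2 map to +1 and dosage 0 to -1;
#' under the recessive rule only dosage 2 maps to +1. The companion
#' encoding aTilde = (A + 1)/2 takes values in \{0, 1\}.
#'
#' @param ds a \linkS4class{GenotypeData} with no missing dosage at the target.
#' @param targetId SNP id of the target.
#' @param rule \code{"dominant"} or \code{"recessive"}.
#' @return A \linkS4class{TargetEncoding}.
#' @export
binarizeTarget <- function(ds, targetId, rule = c("dominant", "recessive")) {
  rule <- match.arg(rule)
  idx <- match(targetId, snpInfo(ds)$snp)
  if (is.na(idx)) stop("target SNP not found: ", targetId)
  d <- dosages(ds)[idx, ]
  if (anyNA(d)) stop("target SNP has missing dosages; impute first")
  A <- unname(if (rule == "dominant") ifelse(d >= 1, 1, -1)
              else ifelse(d == 2, 1, -1))
  if (length(unique(A)) < 2L)
    stop("target encoding is constant across samples under the ", rule, " rule")
  methods::new("TargetEncoding", targetId = targetId, targetIndex = idx,
               rule = rule, A = as.numeric(A), aTilde = (A + 1) / 2)
}
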