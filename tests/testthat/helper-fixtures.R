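## Shared fixture builders. Everything is generated in code under a fixed seed.

## A small family dataset: pedigree, kinship, imputed dosage matrix, phenotypes.
smallFamilyData <- function(nFamilies = 50, nVariants = 10, h2 = 0.5,
                            rho = 0.5, K = 2, seed = 101) {
  set.seed(seed)
  ped <- generatePedigrees(nFamilies)
  kin <- pedigreeKinship(ped)
  g <- geneDropGenotypes(ped, nVariants)
  ph <- simulateNullPhenotypes(kin, K = K, h2 = h2, rho = rho)
  list(ped = ped, kin = kin, g = g, D = dosages(meanImpute(g)), ph = ph)
}

## Random positive definite correlation matrix.
randomCorr <- function(K, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(K * K), K)
  stats::cov2cor(crossprod(A) + diag(K) * 0.5)
}

## Hand-encoded 3-sample x 2-SNP PLINK fileset (independent of writePlink):
## SNP1 minor-allele dosages (0, 1, 2), SNP2 (NA, 0, 1).
writeBedFixtureByHand <- function(prefix) {
  writeLines(c("1\tsnpA\t0\t100\tA\tG", "1\tsnpB\t0\t200\tC\tT"),
             paste0(prefix, ".bim"))
  writeLines(c("FAM1\tID1\t0\t0\t1\t-9", "FAM1\tID2\t0\t0\t2\t-9",
               "FAM2\tID3\t0\t0\t1\t-9"), paste0(prefix, ".fam"))
  con <- file(paste0(prefix, ".bed"), "wb")
  ## magic bytes + 1 byte per SNP: codes 00=2 copies A1, 01=missing, 10=het,
  ## 11=0 copies; samples fill the low bits first.
  ## SNP1 (0,1,2) -> codes (3,2,0) -> 3 + 2*4 + 0*16 = 11
  ## SNP2 (NA,0,1) -> codes (1,3,2) -> 1 + 3*4 + 2*16 = 45
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 11, 45)), con)
  close(con)
  prefix
}

## Random StatVector instances for property-style checks.
randomStatVector <- function(K = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sigma <- randomCorr(K)
  t <- drop(matSqrtTest(sigma) %*% rnorm(K))
  StatVector(t, sigma)
}

matSqrtTest <- function(V) {
  e <- eigen(V, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

## Monte-Carlo distribution of the min-p statistic under t ~ N(0, sigma),
## evaluated on the default weight grid (independent oracle for the
## integrated p-value).
mcMinP <- function(sigma, n, grid = usatWeights()) {
  K <- nrow(sigma)
  e <- eigen(sigma, symmetric = TRUE)
  Z <- matrix(rnorm(n * K), n, K)
  tmat <- Z %*% (sqrt(e$values) * t(e$vectors))
  tS <- rowSums(tmat^2)
  zt <- tmat %*% e$vectors
  tM <- drop((zt^2) %*% (1 / e$values))
  pmat <- vapply(grid, function(w)
    liuPvalue(w * tM + (1 - w) * tS, w + (1 - w) * e$values), numeric(n))
  apply(pmat, 1, min)
}
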