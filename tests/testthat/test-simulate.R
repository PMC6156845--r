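test_that("pedigree generation is sized and seeded deterministically", {
  ped <- generatePedigrees(200, offspring = 2, seed = 70)
  expect_equal(nrow(ped), 800L)
  expect_equal(sum(ped$father == "0"), 400L)
  ped2 <- generatePedigrees(200, offspring = 2, seed = 70)
  expect_identical(ped, ped2)
  ## full dataset reproducibility: identical config => identical outputs
  ds1 <- simulateDataset(simConfig(nFamilies = 5L, nVariants = 4L, seed = 71L))
  ds2 <- simulateDataset(simConfig(nFamilies = 5L, nVariants = 4L, seed = 71L))
  expect_identical(dosages(ds1$genotypes), dosages(ds2$genotypes))
  expect_identical(traits(ds1$phenotypes), traits(ds2$phenotypes))
  expect_identical(ds1$pedigree, ds2$pedigree)
})

test_that("config validation rejects out-of-range study parameters", {
  expect_error(simConfig(mafRange = c(0, 0.5)), class = "pusatConfigError")
  expect_error(simConfig(mafRange = c(0.1, 0.6)), class = "pusatConfigError")
  expect_error(simConfig(h2 = 1.2), class = "pusatConfigError")
  expect_error(simConfig(rho = 1), class = "pusatConfigError")
})

test_that("gene-dropped founder allele frequencies match their targets", {
  set.seed(72)
  ped <- generatePedigrees(2500, offspring = 1)   # 5000 founders
  g <- geneDropGenotypes(ped, 4, mafRange = c(0.2, 0.2001), mafFloor = 0.05)
  founders <- ped$father == "0"
  frq <- colMeans(dosages(g)[founders, ]) / 2
  se <- sqrt(0.2 * 0.8 / (2 * sum(founders)))
  expect_true(all(abs(frq - 0.2) < 3.5 * se))
  ## realized MAF respects the analysis floor
  fr <- colMeans(dosages(g)) / 2
  expect_true(all(pmin(fr, 1 - fr) >= 0.05))
})

test_that("Mendelian transmission gives parent-offspring dosage covariance 2pq/2", {
  set.seed(73)
  ped <- generatePedigrees(5000, offspring = 1)
  g <- geneDropGenotypes(ped, 2, mafRange = c(0.3, 0.3001), mafFloor = 0.01)
  D <- dosages(g)
  fa <- match(ped$father, ped$iid)
  kid <- which(!is.na(fa))
  for (j in 1:2) {
    cpo <- cov(D[fa[kid], j], D[kid, j])
    vFounder <- var(D[ped$father == "0", j])
    ## additive transmission: cov(parent, child) = vFounder / 2
    expect_lt(abs(cpo - vFounder / 2), 0.05 * vFounder + 0.02)
  }
})

test_that("a duplicated individual shows GRM off-diagonal equal to diagonal", {
  set.seed(74)
  ped <- generatePedigrees(30)
  g <- geneDropGenotypes(ped, 400)
  D <- dosages(g)
  D <- rbind(D, D[1, ])     # copy of sample 1
  k <- empiricalGRM(GenotypeMatrix(D, orient = FALSE, imputed = TRUE))
  phi <- relMatrix(k)
  n <- nrow(phi)
  expect_equal(phi[1, n], phi[1, 1], tolerance = 1e-12)
  expect_gt(phi[1, n], median(diag(phi)) * 0.5)
})

test_that("null phenotypes have unit founder variance and correlation rho", {
  set.seed(75)
  ped <- generatePedigrees(50)
  kin <- pedigreeKinship(ped)
  founders <- ped$father == "0"
  Y1 <- c(); Y2 <- c()
  for (b in 1:100) {
    ph <- simulateNullPhenotypes(kin, K = 2, h2 = 0.5, rho = 0.25)
    Y1 <- c(Y1, traits(ph)[founders, 1])
    Y2 <- c(Y2, traits(ph)[founders, 2])
  }
  n <- length(Y1)          # 10,000 founder draws
  expect_equal(n, 10000L)
  expect_lt(abs(var(Y1) - 1), 3 * sqrt(2 / n) + 0.01)
  expect_lt(abs(cor(Y1, Y2) - 0.25), 3 / sqrt(n) + 0.01)
})

test_that("h2 = 0 removes the between-sibling trait covariance", {
  set.seed(76)
  ped <- generatePedigrees(400)
  kin <- pedigreeKinship(ped)
  sib1 <- which(ped$iid %in% sprintf("F%04d_I03", 1:400))
  sib2 <- which(ped$iid %in% sprintf("F%04d_I04", 1:400))
  covs <- replicate(20, {
    ph <- simulateNullPhenotypes(kin, K = 2, h2 = 0, rho = 0.25)
    cov(traits(ph)[sib1, 1], traits(ph)[sib2, 1])
  })
  expect_lt(abs(mean(covs)), 3 * sd(covs) / sqrt(20))
  ## and with h2 = 0.5 the sibling covariance is h2 * A_sib / ... = 0.25
  covs2 <- replicate(20, {
    ph <- simulateNullPhenotypes(kin, K = 2, h2 = 0.5, rho = 0.25)
    cov(traits(ph)[sib1, 1], traits(ph)[sib2, 1])
  })
  expect_lt(abs(mean(covs2) - 0.25), 3 * sd(covs2) / sqrt(20) + 0.01)
})

test_that("the matrix-variate sampler matches the dense Kronecker covariance", {
  set.seed(77)
  ped <- data.frame(fid = "F1", iid = c("a", "b", "c", "d"),
                    father = c("0", "0", "a", "a"),
                    mother = c("0", "0", "b", "b"), sex = c(1, 2, 1, 2))
  kin <- pedigreeKinship(ped)
  h2 <- 0.4; rho <- 0.3; K <- 2; N <- 4
  Vg <- h2 * matrix(c(1, rho, rho, 1), 2)
  Ve <- (1 - h2) * matrix(c(1, rho, rho, 1), 2)
  target <- kronecker(Vg, relMatrix(kin)) + kronecker(Ve, diag(N))
  draws <- vapply(1:20000, function(b)
    as.vector(traits(simulateNullPhenotypes(kin, K, h2, rho))), numeric(N * K))
  emp <- tcrossprod(draws) / ncol(draws)
  expect_lt(max(abs(emp - target)), 0.06)
})

test_that("the Type I error harness is seeded, bounded and sane", {
  cfg <- simConfig(nFamilies = 20L, nVariants = 5L, nReplicates = 4L,
                   nominalAlpha = 1, seed = 78L)
  res <- type1Harness(cfg, rhos = 0.5)
  expect_equal(res$est_type1, 1)          # everything is <= alpha = 1
  expect_equal(res$n_tests, 20L)
  cfg2 <- simConfig(nFamilies = 20L, nVariants = 5L, nReplicates = 6L,
                    nominalAlpha = 0.05, seed = 79L)
  r1 <- type1Harness(cfg2, rhos = c(0, 0.5))
  r2 <- type1Harness(cfg2, rhos = c(0, 0.5))
  expect_identical(r1, r2)                # determinism
  expect_true(all(r1$est_type1 >= 0 & r1$est_type1 <= 1))
  expect_true(all(r1$se >= 0))
})
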