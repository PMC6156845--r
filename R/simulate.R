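## Family-data simulator: pedigrees, gene-dropped genotypes, matrix-variate
## null phenotypes, and the seeded Type I error harness.

#' Simulation configuration
#'
#' Defaults emulate the study conditions of a pedigree-based lipid cohort:
#' ~821 individuals in nuclear pedigrees, two quantitative traits with
#' heritability 0.5 and compound-symmetry cross-trait correlation, common
#' variants with minor allele frequency in \[0.052, 0.500\], 1000 null
#' replicates at nominal level 0.05.
#'
#' @param nFamilies number of families (default 205; with 2 offspring each,
#'   N = 820).
#' @param offspring offspring per family (default 2).
#' @param generations 2 (nuclear) or 3 (adds a founder spouse and two
#'   grandchildren per family).
#' @param nVariants variants per dataset (default 20).
#' @param mafRange founder minor-allele-frequency range, within (0, 0.5].
#' @param h2 heritability in \[0, 1\] (default 0.5).
#' @param rho compound-symmetry trait correlation in \[0, 1).
#' @param K number of traits (default 2).
#' @param nReplicates null replicates for the harness (default 1000).
#' @param nominalAlpha nominal level (default 0.05).
#' @param seed integer seed.
#' @return list of class `SimConfig`.
#' @export
simConfig <- function(nFamilies = 205L, offspring = 2L, generations = 2L,
                      nVariants = 20L, mafRange = c(0.052, 0.5), h2 = 0.5,
                      rho = 0, K = 2L, nReplicates = 1000L,
                      nominalAlpha = 0.05, seed = 1L) {
  if (mafRange[1] <= 0 || mafRange[2] > 0.5 || mafRange[1] > mafRange[2])
    configError("mafRange must lie within (0, 0.5]")
  if (h2 < 0 || h2 > 1) configError("h2 must lie in [0, 1]")
  if (rho < 0 || rho >= 1) configError("rho must lie in [0, 1)")
  structure(list(nFamilies = nFamilies, offspring = offspring,
                 generations = generations, nVariants = nVariants,
                 mafRange = mafRange, h2 = h2, rho = rho, K = K,
                 nReplicates = nReplicates, nominalAlpha = nominalAlpha,
                 seed = seed), class = "SimConfig")
}

#' Generate synthetic pedigrees
#'
#' Nuclear families of two founders plus `offspring` children; with
#' `generations = 3` the first child marries a new founder and has two
#' children, so grandparent-grandchild pairs exist. Parents precede offspring
#' in the output. Deterministic given the seed.
#'
#' @param nFamilies number of families.
#' @param offspring offspring per family.
#' @param generations 2 or 3.
#' @param seed optional integer seed (`set.seed` applied when non-NULL).
#' @return data.frame: `fid, iid, father, mother, sex`.
#' @export
generatePedigrees <- function(nFamilies, offspring = 2L, generations = 2L,
                              seed = NULL) {
  if (nFamilies < 1) configError("nFamilies must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", nFamilies)
  for (f in seq_len(nFamilies)) {
    fid <- sprintf("F%04d", f)
    iid <- function(i) sprintf("%s_I%02d", fid, i)
    ped <- data.frame(
      fid = fid,
      iid = c(iid(1), iid(2)),
      father = "0", mother = "0",
      sex = c(1L, 2L), stringsAsFactors = FALSE)
    kids <- seq_len(offspring) + 2L
    ped <- rbind(ped, data.frame(
      fid = fid, iid = vapply(kids, iid, character(1)),
      father = iid(1), mother = iid(2),
      sex = sample(c(1L, 2L), offspring, replace = TRUE),
      stringsAsFactors = FALSE))
    if (generations >= 3L) {
      spouse <- iid(max(kids) + 1L)
      child1 <- iid(3)
      ped$sex[ped$iid == child1] <- 1L
      ped <- rbind(ped,
        data.frame(fid = fid, iid = spouse, father = "0", mother = "0",
                   sex = 2L, stringsAsFactors = FALSE),
        data.frame(fid = fid,
                   iid = vapply(max(kids) + 2:3, iid, character(1)),
                   father = child1, mother = spouse,
                   sex = sample(c(1L, 2L), 2L, replace = TRUE),
                   stringsAsFactors = FALSE))
    }
    rows[[f]] <- ped
  }
  do.call(rbind, rows)
}

#' Gene-drop genotypes down a pedigree
#'
#' Founder alleles are drawn from Hardy-Weinberg proportions at a per-variant
#' MAF sampled uniformly from `mafRange`; offspring receive one random allele
#' from each parent (Mendelian transmission). Columns whose realized sample
#' MAF falls below `mafFloor` are redrawn so simulated panels respect the
#' analysis MAF filter. Output columns are oriented to minor-allele counts.
#'
#' @param ped pedigree data.frame (parents before offspring).
#' @param nVariants number of independent variants.
#' @param mafRange founder MAF range within (0, 0.5].
#' @param mafFloor minimum realized sample MAF (default 0.05).
#' @param chr chromosome label for the variant records (default "21").
#' @param seed optional integer seed.
#' @return A [GenotypeMatrix-class].
#' @export
geneDropGenotypes <- function(ped, nVariants, mafRange = c(0.052, 0.5),
                              mafFloor = 0.05, chr = "21", seed = NULL) {
  if (mafRange[1] <= 0 || mafRange[2] > 0.5 || mafRange[1] > mafRange[2])
    configError("mafRange must lie within (0, 0.5]")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ped)
  id <- as.character(ped$iid)
  fa <- match(as.character(ped$father), id)
  mo <- match(as.character(ped$mother), id)
  founder <- is.na(fa) & is.na(mo)
  if (any(xor(is.na(fa), is.na(mo))))
    pedigreeError("individuals must have both parents or neither")
  M <- nVariants
  a1 <- matrix(0L, n, M); a2 <- matrix(0L, n, M)

  dropCols <- function(cols) {
    m <- length(cols)
    maf <- stats::runif(m, mafRange[1], mafRange[2])
    nf <- sum(founder)
    a1[founder, cols] <<- matrix(stats::rbinom(nf * m, 1L, rep(maf, each = nf)), nf, m)
    a2[founder, cols] <<- matrix(stats::rbinom(nf * m, 1L, rep(maf, each = nf)), nf, m)
    for (i in which(!founder)) {
      pickF <- stats::rbinom(m, 1L, 0.5) == 1L
      a1[i, cols] <<- ifelse(pickF, a1[fa[i], cols], a2[fa[i], cols])
      pickM <- stats::rbinom(m, 1L, 0.5) == 1L
      a2[i, cols] <<- ifelse(pickM, a1[mo[i], cols], a2[mo[i], cols])
    }
  }
  dropCols(seq_len(M))
  for (round in seq_len(100)) {
    fr <- colMeans(a1 + a2) / 2
    low <- which(pmin(fr, 1 - fr) < mafFloor)
    if (!length(low)) break
    dropCols(low)
  }
  d <- a1 + a2
  vdf <- data.frame(chr = rep(chr, M), id = sprintf("sim%04d", seq_len(M)),
                    pos = seq_len(M) * 1000L,
                    allele1 = rep("A", M), allele2 = rep("B", M),
                    stringsAsFactors = FALSE)
  sdf <- data.frame(fid = as.character(ped$fid), iid = id,
                    stringsAsFactors = FALSE)
  g <- GenotypeMatrix(d, vdf, sdf)
  attr(g, "fam") <- data.frame(fid = sdf$fid, iid = sdf$iid,
                               father = as.character(ped$father),
                               mother = as.character(ped$mother),
                               sex = as.character(ped$sex), pheno = "-9",
                               stringsAsFactors = FALSE)
  g
}

#' Simulate null phenotypes from the matrix-variate model
#'
#' Y = L_Phi Z1 L_g' + Z2 L_e' with L_Phi L_Phi' = Phi, L_g L_g' = Vg =
#' h2 * B(rho), L_e L_e' = Ve = (1 - h2) * E, B and E compound-symmetry
#' correlation matrices, and Z1, Z2 independent standard normal matrices. No
#' variant has any effect (global null). Founder trait variances are
#' h2 * Phi_ii + (1 - h2) = 1 and the founder cross-trait correlation is rho.
#'
#' @param kin a [KinshipMatrix-class].
#' @param K number of traits.
#' @param h2 heritability in \[0, 1\].
#' @param rho compound-symmetry correlation in \[0, 1).
#' @param seed optional integer seed.
#' @param samples optional sample data.frame (`fid`, `iid`); defaults to the
#'   kinship row names when present.
#' @return A [PhenotypeSet-class] (no covariates).
#' @export
simulateNullPhenotypes <- function(kin, K = 2L, h2 = 0.5, rho = 0,
                                   seed = NULL, samples = NULL) {
  if (h2 < 0 || h2 > 1) domainError("h2 must lie in [0, 1]")
  if (rho < 0 || rho >= 1) domainError("rho must lie in [0, 1) for positive definite Ve")
  if (!is.null(seed)) set.seed(seed)
  N <- nSamples(kin)
  Lg <- matSqrt(h2 * csMatrix(K, rho))
  Le <- matSqrt((1 - h2) * csMatrix(K, rho))
  U <- eigenVectors(kin); sql <- sqrt(eigenValues(kin))
  Z1 <- matrix(stats::rnorm(N * K), N, K)
  Z2 <- matrix(stats::rnorm(N * K), N, K)
  Y <- U %*% (sql * Z1) %*% t(Lg) + Z2 %*% t(Le)
  colnames(Y) <- paste0("trait", seq_len(K))
  if (is.null(samples) && !is.null(rownames(relMatrix(kin))))
    samples <- data.frame(fid = rownames(relMatrix(kin)),
                          iid = rownames(relMatrix(kin)),
                          stringsAsFactors = FALSE)
  PhenotypeSet(Y, samples = samples)
}

#' Simulate a complete family dataset
#'
#' Pedigree, pedigree relationship matrix, gene-dropped genotypes and null
#' phenotypes, bundled with the configuration for provenance.
#'
#' @param cfg a [simConfig()] list.
#' @return list of class `SimulatedDataset`: `pedigree`, `kinship`,
#'   `genotypes`, `phenotypes`, `config`.
#' @export
simulateDataset <- function(cfg = simConfig()) {
  set.seed(cfg$seed)
  ped <- generatePedigrees(cfg$nFamilies, cfg$offspring, cfg$generations)
  kin <- pedigreeKinship(ped)
  g <- geneDropGenotypes(ped, cfg$nVariants, cfg$mafRange)
  ph <- simulateNullPhenotypes(kin, cfg$K, cfg$h2, cfg$rho,
                               samples = data.frame(fid = as.character(ped$fid),
                                                    iid = as.character(ped$iid),
                                                    stringsAsFactors = FALSE))
  structure(list(pedigree = ped, kinship = kin, genotypes = g,
                 phenotypes = ph, config = cfg),
            class = "SimulatedDataset")
}

#' Type I error harness for pUSAT
#'
#' For each requested trait correlation rho, simulates `cfg$nReplicates` null
#' phenotype datasets over a fixed synthetic pedigree (relationship matrix
#' eigendecomposition computed once) and a fixed gene-dropped variant panel,
#' runs [runPusat()] on each, pools the integrated p-values, and reports the
#' fraction at or below the nominal level with its binomial standard error.
#' Fully seeded and deterministic.
#'
#' @param cfg a [simConfig()] list (`rho` ignored in favor of `rhos`).
#' @param rhos correlations to assess (default 0, 0.25, 0.5, 0.75).
#' @param conditional passed to [runPusat()].
#' @param verbose print a progress line per rho.
#' @return data.frame: `rho, n_reps, n_tests, est_type1, se`, with the pooled
#'   p-values in attribute `"pvalues"` (a list by rho).
#' @export
type1Harness <- function(cfg = simConfig(nFamilies = 200L),
                         rhos = c(0, 0.25, 0.5, 0.75),
                         conditional = TRUE, verbose = FALSE) {
  set.seed(cfg$seed)
  ped <- generatePedigrees(cfg$nFamilies, cfg$offspring, cfg$generations)
  kin <- pedigreeKinship(ped)
  g <- geneDropGenotypes(ped, cfg$nVariants, cfg$mafRange)
  D <- dosages(meanImpute(g))
  alpha <- cfg$nominalAlpha
  pvals <- vector("list", length(rhos))
  rows <- vector("list", length(rhos))
  for (r in seq_along(rhos)) {
    rho <- rhos[r]
    ps <- vector("list", cfg$nReplicates)
    for (b in seq_len(cfg$nReplicates)) {
      ph <- simulateNullPhenotypes(kin, cfg$K, cfg$h2, rho)
      res <- runPusat(ph, G = D, kin = kin, conditional = conditional)
      ps[[b]] <- res$p_final
    }
    p <- unlist(ps)
    p <- p[!is.na(p)]
    est <- mean(p <= alpha)
    se <- sqrt(est * (1 - est) / length(p))
    if (verbose)
      message(sprintf("rho = %.2f: type I = %.4f (SE %.4f) over %d tests",
                      rho, est, se, length(p)))
    pvals[[r]] <- p
    rows[[r]] <- data.frame(rho = rho, n_reps = cfg$nReplicates,
                            n_tests = length(p), est_type1 = est, se = se)
  }
  out <- do.call(rbind, rows)
  names(pvals) <- as.character(rhos)
  attr(out, "pvalues") <- pvals
  out
}
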