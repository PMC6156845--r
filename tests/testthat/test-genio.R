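test_that("hand-encoded .bed bytes decode to the documented dosages", {
  prefix <- writeBedFixtureByHand(file.path(tempdir(), "hand"))
  g <- readPlink(prefix)
  expect_equal(dim(dosages(g)), c(3L, 2L))
  expect_equal(dosages(g)[, 1], c(0, 1, 2))
  expect_equal(dosages(g)[, 2], c(NA, 0, 1))
  expect_equal(variants(g)$id, c("snpA", "snpB"))
  expect_equal(samples(g)$iid, c("ID1", "ID2", "ID3"))
  expect_equal(sum(is.na(dosages(g))), 1L)
})

test_that("PLINK write/read round trip is identity in dosage and metadata", {
  set.seed(5)
  d <- matrix(rbinom(60, 2, 0.3), 10, 6)
  d[2, 3] <- NA
  g <- GenotypeMatrix(d)
  prefix <- file.path(tempdir(), "rt")
  writePlink(g, prefix)
  g2 <- readPlink(prefix)
  expect_identical(dosages(g2), dosages(g))
  expect_equal(variants(g2)$id, variants(g)$id)
  expect_equal(variants(g2)$allele1, variants(g)$allele1)
  expect_equal(samples(g2), samples(g), ignore_attr = TRUE)
  ## writing again reproduces byte-identical files
  prefix3 <- file.path(tempdir(), "rt2")
  writePlink(g2, prefix3)
  expect_identical(readBin(paste0(prefix, ".bed"), "raw", 100),
                   readBin(paste0(prefix3, ".bed"), "raw", 100))
})

test_that("columns stored as major-allele counts are flipped to minor", {
  ## stored dosage (1,2,2): frequency 5/6 > 0.5, so reader returns 2 - g
  prefix <- file.path(tempdir(), "flip")
  writeLines("1\tsnpF\t0\t1\tA\tG", paste0(prefix, ".bim"))
  writeLines(c("F1\tI1\t0\t0\t1\t-9", "F2\tI2\t0\t0\t1\t-9",
               "F3\tI3\t0\t0\t1\t-9"), paste0(prefix, ".fam"))
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 2L)), con)  # codes (2,0,0) = (1,2,2)
  close(con)
  g <- readPlink(prefix)
  expect_equal(dosages(g)[, 1], c(1, 0, 0))
  expect_equal(variants(g)$allele1, "G")  # alleles swapped with the flip
  expect_equal(variants(g)$allele2, "A")
})

test_that("malformed PLINK input raises format errors", {
  prefix <- writeBedFixtureByHand(file.path(tempdir(), "bad"))
  ## corrupt magic
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(0x00, 0x1b, 0x01, 11, 45)), con); close(con)
  expect_error(readPlink(prefix), class = "pusatFormatError")
  ## payload shorter than bim/fam imply
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 11)), con); close(con)
  expect_error(readPlink(prefix), class = "pusatFormatError")
  expect_error(readPlink(file.path(tempdir(), "nosuchfix")),
               class = "pusatFormatError")
})

test_that("VCF genotypes load as oriented dosages and skip multi-allelics", {
  skip_if_not_installed("vcfR")
  path <- file.path(tempdir(), "tiny.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t./.\t0/0\t0|1",
    "1\t300\trs3\tG\tA,C\t.\tPASS\t.\tGT\t0/0\t0/1\t0/2"), path)
  expect_message(g <- readVcfGenotypes(path), "multi-allelic")
  expect_equal(nVariants(g), 2L)
  expect_equal(dosages(g)[, 1], c(0, 1, 2), ignore_attr = TRUE)
  expect_equal(dosages(g)[, 2], c(NA, 0, 1), ignore_attr = TRUE)
})

test_that("phenotype reader expands factors, aligns and log-transforms", {
  pp <- file.path(tempdir(), "ph.tsv")
  cp <- file.path(tempdir(), "cv.tsv")
  write.table(data.frame(FID = paste0("F", 1:5), IID = paste0("I", 1:5),
                         tg = c(10, 20, 30, 40, 50), hdl = 1:5),
              pp, row.names = FALSE, quote = FALSE, sep = "\t")
  write.table(data.frame(FID = paste0("F", 1:5), IID = paste0("I", 1:5),
                         age = c(40, 50, 60, 55, 45),
                         smoke = c("never", "past", "current", "never", "past")),
              cp, row.names = FALSE, quote = FALSE, sep = "\t")
  ## 3-level factor expands to 2 indicator columns (reference level dropped)
  ps <- readPhenotypes(pp, c("tg", "hdl"), covarPath = cp)
  expect_equal(ncol(covariates(ps)), 3L)  # age + 2 smoke indicators
  expect_equal(sum(grepl("smoke", colnames(covariates(ps)))), 2L)
  ## log transform
  ps2 <- readPhenotypes(pp, "tg", logTraits = "tg")
  expect_equal(traits(ps2)[, "tg"], log(c(10, 20, 30, 40, 50)),
               ignore_attr = TRUE)
  ## alignment: 4 genotype samples -> 4 aligned rows, genotype order
  gsamp <- data.frame(fid = paste0("F", c(2, 4, 1, 3)),
                      iid = paste0("I", c(2, 4, 1, 3)))
  ps3 <- readPhenotypes(pp, "tg", samples = gsamp)
  expect_equal(nSamples(ps3), 4L)
  expect_equal(samples(ps3)$iid, gsamp$iid)
  ## absent trait is a configuration error
  expect_error(readPhenotypes(pp, "nope"), class = "pusatConfigError")
})

test_that("incomplete phenotype rows are dropped and counted", {
  pp <- file.path(tempdir(), "phna.tsv")
  write.table(data.frame(FID = paste0("F", 1:4), IID = paste0("I", 1:4),
                         tg = c(1, NA, 3, 4)),
              pp, row.names = FALSE, quote = FALSE, sep = "\t")
  expect_message(ps <- readPhenotypes(pp, "tg"), "dropped 1")
  expect_equal(nSamples(ps), 3L)
  expect_equal(attr(ps, "dropped"), 1L)
})

test_that("kinship text round trip, symmetrization and clamping", {
  path <- file.path(tempdir(), "kin.txt")
  writeKinship(identityKinship(4), path)
  k <- readKinship(path)
  expect_equal(relMatrix(k), diag(4))
  ## tiny asymmetry accepted and symmetrized
  m <- diag(3); m[1, 2] <- 1e-9
  write.table(m, path, row.names = FALSE, col.names = FALSE)
  k2 <- readKinship(path)
  expect_equal(relMatrix(k2), t(relMatrix(k2)))
  ## a slightly indefinite matrix is accepted with a clamping warning
  m3 <- matrix(c(1, 0.9995, 0.0005, 0.9995, 1, 0.9995, 0.0005, 0.9995, 1), 3)
  stopifnot(min(eigen(m3)$values) < -1e-4)
  write.table(m3, path, row.names = FALSE, col.names = FALSE)
  expect_warning(k3 <- readKinship(path), "clamping")
  expect_true(all(eigenValues(k3) >= 0))
  ## non-square input is a format error
  write.table(matrix(1, 2, 3), path, row.names = FALSE, col.names = FALSE)
  expect_error(readKinship(path), class = "pusatFormatError")
})

test_that("sample alignment is an inner join keyed by FID/IID", {
  g <- GenotypeMatrix(matrix(rbinom(12, 2, 0.4), 4, 3),
                      samples = data.frame(fid = paste0("F", 1:4),
                                           iid = paste0("I", 1:4)))
  ps <- PhenotypeSet(matrix(rnorm(6), 3, 2),
                     samples = data.frame(fid = paste0("F", c(3, 1, 9)),
                                          iid = paste0("I", c(3, 1, 9))))
  al <- alignSamples(g, ps)
  expect_equal(samples(al$genotypes)$iid, c("I1", "I3"))
  expect_equal(samples(al$phenotypes)$iid, c("I1", "I3"))
  ps0 <- PhenotypeSet(matrix(rnorm(2), 1, 2),
                      samples = data.frame(fid = "X", iid = "X"))
  expect_error(alignSamples(g, ps0), class = "pusatDataError")
})
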