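## PLINK 1.9 binary genotype IO. The .bed payload is SNP-major, two bits per
## genotype packed four samples per byte, low bits first:
##   00 = homozygous allele1 (2 copies), 01 = missing, 10 = het, 11 = hom allele2.

.bedMagic <- as.raw(c(0x6c, 0x1b, 0x01))

## dosage of allele1 indexed by 2-bit code + 1
.bedCodeToDosage <- c(2, NA, 1, 0)
## inverse: dosage 0,1,2,NA -> code
.bedDosageToCode <- function(g) {
  code <- integer(length(g))
  code[is.na(g)] <- 1L
  code[!is.na(g) & g == 2] <- 0L
  code[!is.na(g) & g == 1] <- 2L
  code[!is.na(g) & g == 0] <- 3L
  code
}

#' Read PLINK .bed/.bim/.fam genotypes
#'
#' Reads a PLINK 1.9 binary fileset into a [GenotypeMatrix-class]. Dosages are
#' oriented to minor-allele counts per column (columns whose counted-allele
#' frequency exceeds 0.5 are flipped, swapping the recorded alleles); missing
#' genotypes are preserved as `NA`; variants keep .bim order.
#'
#' @param prefix path prefix, or explicit `bed`, `bim`, `fam` paths.
#' @param bed,bim,fam explicit file paths (override `prefix`).
#' @return A [GenotypeMatrix-class].
#' @export
readPlink <- function(prefix = NULL, bed = NULL, bim = NULL, fam = NULL) {
  if (!is.null(prefix)) {
    bed <- bed %||% paste0(prefix, ".bed")
    bim <- bim %||% paste0(prefix, ".bim")
    fam <- fam %||% paste0(prefix, ".fam")
  }
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) formatError("file not found: %s", f)
  bimDf <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                             colClasses = c("character", "character", "numeric",
                                            "integer", "character", "character"))
  names(bimDf) <- c("chr", "id", "cm", "pos", "allele1", "allele2")
  famDf <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(famDf) < 6) formatError(".fam must have 6 columns")
  names(famDf)[1:6] <- c("fid", "iid", "father", "mother", "sex", "pheno")
  famDf[] <- lapply(famDf, as.character)

  N <- nrow(famDf); M <- nrow(bimDf)
  bytesPerSnp <- ceiling(N / 4)
  raw <- readBin(bed, what = "raw", n = 3 + M * bytesPerSnp + 1)
  if (length(raw) < 3 || !identical(raw[1:3], .bedMagic))
    formatError("%s: not a SNP-major PLINK .bed file (bad magic bytes)", bed)
  payload <- raw[-(1:3)]
  if (length(payload) != M * bytesPerSnp)
    formatError("%s: payload has %d bytes, expected %d for %d samples x %d variants",
                bed, length(payload), M * bytesPerSnp, N, M)

  bytes <- as.integer(payload)
  ## decode all four 2-bit slots for every byte, then keep the first N per SNP
  codes <- rbind(bytes %% 4L, (bytes %/% 4L) %% 4L,
                 (bytes %/% 16L) %% 4L, (bytes %/% 64L) %% 4L)
  dim(codes) <- c(4L * bytesPerSnp, M)
  d <- matrix(.bedCodeToDosage[codes[seq_len(N), , drop = FALSE] + 1L], N, M)

  vdf <- bimDf[, c("chr", "id", "pos", "allele1", "allele2")]
  sdf <- famDf[, c("fid", "iid")]
  g <- GenotypeMatrix(d, vdf, sdf)
  attr(g, "fam") <- famDf
  g
}

#' Write a GenotypeMatrix as PLINK .bed/.bim/.fam
#'
#' Dosages are written as counts of `allele1` in the stored orientation, so a
#' read/write round trip is identity. Imputed (real-valued) matrices cannot be
#' written.
#'
#' @param g a [GenotypeMatrix-class].
#' @param prefix output path prefix.
#' @param fam optional full 6-column fam data.frame (fid, iid, father, mother,
#'   sex, pheno); defaults to the sample table with zeros filled in.
#' @return `prefix`, invisibly.
#' @export
writePlink <- function(g, prefix, fam = NULL) {
  if (g@imputed) dataError("cannot write mean-imputed dosages to .bed")
  d <- dosages(g)
  N <- nrow(d); M <- ncol(d)
  v <- variants(g)
  bim <- data.frame(chr = v$chr, id = v$id, cm = 0, pos = v$pos,
                    a1 = v$allele1, a2 = v$allele2)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  if (is.null(fam)) {
    s <- samples(g)
    fam <- attr(g, "fam") %||%
      data.frame(fid = s$fid, iid = s$iid, father = "0", mother = "0",
                 sex = "0", pheno = "-9", stringsAsFactors = FALSE)
  }
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)

  bytesPerSnp <- ceiling(N / 4)
  pad <- 4L * bytesPerSnp - N
  codes <- matrix(0L, 4L * bytesPerSnp, M)
  codes[seq_len(N), ] <- matrix(.bedDosageToCode(d), N, M)
  dim(codes) <- c(4L, bytesPerSnp * M)
  bytes <- as.raw(codes[1L, ] + 4L * codes[2L, ] + 16L * codes[3L, ] +
                  64L * codes[4L, ])
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(.bedMagic, con)
  writeBin(bytes, con)
  invisible(prefix)
}

#' Read genotypes from a VCF (GT field only)
#'
#' Thin wrapper over `vcfR`: extracts the GT field, counts ALT alleles, skips
#' multi-allelic sites with a message, and orients columns to minor-allele
#' counts.
#'
#' @param path VCF file (plain or bgzipped).
#' @return A [GenotypeMatrix-class].
#' @export
readVcfGenotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    configError("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi))
    message(sprintf("skipping %d multi-allelic site(s)", sum(multi)))
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  cnt <- function(s) {
    out <- rep(NA_real_, length(s))
    ok <- !is.na(s) & !grepl("\\.", s)
    al <- strsplit(gsub("\\|", "/", s[ok]), "/", fixed = TRUE)
    out[ok] <- vapply(al, function(a) sum(a == "1"), numeric(1))
    out
  }
  d <- t(apply(gt, 1, cnt))                      # variants x samples
  d <- t(d)                                      # samples x variants
  vdf <- data.frame(chr = fix$CHROM,
                    id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                paste0(fix$CHROM, ":", fix$POS), fix$ID),
                    pos = as.integer(fix$POS),
                    allele1 = fix$ALT, allele2 = fix$REF,
                    stringsAsFactors = FALSE)
  sdf <- data.frame(fid = colnames(gt), iid = colnames(gt),
                    stringsAsFactors = FALSE)
  GenotypeMatrix(d, vdf, sdf)
}

#' Read phenotype and covariate tables
#'
#' Reads whitespace/tab-delimited tables with a header whose first two columns
#' are FID and IID. Requested traits may be log-transformed; categorical
#' covariates (character/factor columns, or those named in `factorCovariates`)
#' are expanded to reference-level-dropped indicator columns. Rows with any
#' missing trait or covariate are dropped with a message. When `samples` is
#' given (e.g. `samples(genotypes)`), the result is inner-joined to and ordered
#' by it.
#'
#' @param phenoPath phenotype table path.
#' @param traits character vector of trait column names to analyze.
#' @param covarPath optional covariate table path.
#' @param covariateNames covariate columns to use (default: all non-key
#'   columns of the covariate table).
#' @param factorCovariates covariate names to force categorical.
#' @param logTraits trait names to replace by their natural log.
#' @param samples optional data.frame (`fid`, `iid`) defining sample order.
#' @return A [PhenotypeSet-class]; attribute `"dropped"` counts removed rows.
#' @export
readPhenotypes <- function(phenoPath, traits, covarPath = NULL,
                           covariateNames = NULL, factorCovariates = NULL,
                           logTraits = NULL, samples = NULL) {
  ph <- utils::read.table(phenoPath, header = TRUE, stringsAsFactors = FALSE)
  names(ph)[1:2] <- c("fid", "iid")
  miss <- setdiff(traits, names(ph))
  if (length(miss))
    configError("trait(s) not found in %s: %s", phenoPath,
                paste(miss, collapse = ", "))
  tab <- ph[, c("fid", "iid", traits), drop = FALSE]
  tab$fid <- as.character(tab$fid); tab$iid <- as.character(tab$iid)

  covCols <- character(0)
  if (!is.null(covarPath)) {
    cv <- utils::read.table(covarPath, header = TRUE, stringsAsFactors = FALSE)
    names(cv)[1:2] <- c("fid", "iid")
    cv$fid <- as.character(cv$fid); cv$iid <- as.character(cv$iid)
    covariateNames <- covariateNames %||% setdiff(names(cv), c("fid", "iid"))
    miss <- setdiff(covariateNames, names(cv))
    if (length(miss))
      configError("covariate(s) not found in %s: %s", covarPath,
                  paste(miss, collapse = ", "))
    cv <- cv[, c("fid", "iid", covariateNames), drop = FALSE]
    tab <- merge(tab, cv, by = c("fid", "iid"), sort = FALSE)
    covCols <- covariateNames
  }

  n0 <- nrow(tab)
  tab <- tab[stats::complete.cases(tab), , drop = FALSE]
  dropped <- n0 - nrow(tab)
  if (dropped) message(sprintf("dropped %d incomplete row(s)", dropped))

  if (!is.null(samples)) {
    key <- paste(as.character(samples$fid), as.character(samples$iid), sep = "\r")
    tkey <- paste(tab$fid, tab$iid, sep = "\r")
    idx <- match(key, tkey)
    tab <- tab[idx[!is.na(idx)], , drop = FALSE]
    if (!nrow(tab)) dataError("no samples overlap between phenotypes and genotypes")
  }

  for (tr in intersect(logTraits, traits)) tab[[tr]] <- log(tab[[tr]])
  Y <- as.matrix(tab[, traits, drop = FALSE])
  storage.mode(Y) <- "double"

  C <- matrix(numeric(0), nrow(tab), 0L)
  if (length(covCols)) {
    cd <- tab[, covCols, drop = FALSE]
    for (nm in covCols)
      if (nm %in% factorCovariates || is.character(cd[[nm]]))
        cd[[nm]] <- factor(cd[[nm]])
    C <- stats::model.matrix(~ ., data = cd)[, -1, drop = FALSE]
    rownames(C) <- NULL
  }
  out <- PhenotypeSet(Y, C, samples = tab[, c("fid", "iid")])
  attr(out, "dropped") <- dropped
  out
}

#' Align genotypes and phenotypes to their common samples
#'
#' Inner join on (fid, iid) keeping the genotype order of the shared samples.
#'
#' @param g a [GenotypeMatrix-class].
#' @param ps a [PhenotypeSet-class].
#' @return list with aligned `genotypes` and `phenotypes`.
#' @export
alignSamples <- function(g, ps) {
  gs <- samples(g); pss <- samples(ps)
  gkey <- paste(gs$fid, gs$iid, sep = "\r")
  pkey <- paste(pss$fid, pss$iid, sep = "\r")
  keep <- which(gkey %in% pkey)
  if (!length(keep)) dataError("no overlapping samples between genotypes and phenotypes")
  pidx <- match(gkey[keep], pkey)
  g2 <- new("GenotypeMatrix", dosages = dosages(g)[keep, , drop = FALSE],
            variants = variants(g), samples = gs[keep, , drop = FALSE],
            imputed = g@imputed)
  ps2 <- new("PhenotypeSet", Y = ps@Y[pidx, , drop = FALSE],
             covar = ps@covar[pidx, , drop = FALSE],
             samples = pss[pidx, , drop = FALSE])
  list(genotypes = g2, phenotypes = ps2)
}

#' Read a kinship matrix from delimited text
#'
#' Accepts a plain N x N numeric matrix (GEMMA "cXX.txt" style) or one with an
#' ID header row and ID first column. The matrix is symmetrized as
#' (phi + t(phi))/2 (asymmetry beyond 1e-6 is a format error) and negative
#' eigenvalues are clamped to zero with a warning.
#'
#' @param path file path.
#' @return A [KinshipMatrix-class] with source `"external"`.
#' @export
readKinship <- function(path) {
  first <- scan(path, what = "character", nlines = 1, quiet = TRUE)
  hasHeader <- anyNA(suppressWarnings(as.numeric(first)))
  tab <- utils::read.table(path, header = hasHeader, stringsAsFactors = FALSE)
  if (hasHeader && anyNA(suppressWarnings(as.numeric(tab[, 1]))))
    tab <- tab[, -1, drop = FALSE]
  m <- as.matrix(tab)
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m))
    formatError("%s: kinship matrix is %d x %d, must be square",
                path, nrow(m), ncol(m))
  makeKinship(m, source = "external")
}

#' Write a kinship matrix as tab-delimited text
#' @param kin a [KinshipMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeKinship <- function(kin, path) {
  utils::write.table(relMatrix(kin), path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
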