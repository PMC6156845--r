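#' @import methods
NULL

## ---------------------------------------------------------------------------
## GenotypeMatrix
## ---------------------------------------------------------------------------

#' GenotypeMatrix: minor-allele dosages with variant and sample metadata
#'
#' An N x M matrix of minor-allele counts (0, 1, 2, or `NA` for missing)
#' together with per-variant records (chromosome, identifier, position, the
#' counted allele and the other allele) and ordered (family ID, individual ID)
#' sample records. After construction every column is oriented so that the
#' counted allele is the minor allele (non-missing column mean / 2 <= 0.5);
#' ties at frequency exactly 0.5 keep the file's allele order. After mean
#' imputation (`meanImpute()`) dosages are real-valued in \[0, 2\] and the
#' `imputed` flag is set.
#'
#' @slot dosages numeric matrix, N samples x M variants.
#' @slot variants data.frame with columns `chr`, `id`, `pos`, `allele1`
#'   (counted allele), `allele2`.
#' @slot samples data.frame with columns `fid`, `iid`.
#' @slot imputed logical; `TRUE` once missing entries have been mean-imputed.
#'
#' @aliases GenotypeMatrix
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(
    dosages = "matrix",
    variants = "data.frame",
    samples = "data.frame",
    imputed = "logical"
  ),
  prototype(imputed = FALSE)
)

setValidity("GenotypeMatrix", function(object) {
  d <- object@dosages
  msg <- character()
  if (ncol(d) != nrow(object@variants))
    msg <- c(msg, "column count must equal variant record count")
  if (nrow(d) != nrow(object@samples))
    msg <- c(msg, "row count must equal sample record count")
  if (!all(c("chr", "id", "pos", "allele1", "allele2") %in%
           names(object@variants)))
    msg <- c(msg, "variants needs columns chr, id, pos, allele1, allele2")
  if (!all(c("fid", "iid") %in% names(object@samples)))
    msg <- c(msg, "samples needs columns fid, iid")
  v <- d[!is.na(d)]
  if (length(v)) {
    if (isTRUE(object@imputed)) {
      if (any(v < 0 | v > 2)) msg <- c(msg, "imputed dosages must lie in [0, 2]")
      if (anyNA(d)) msg <- c(msg, "imputed matrix must be complete")
    } else if (!all(v %in% c(0, 1, 2))) {
      msg <- c(msg, "non-missing dosages must be 0, 1 or 2")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param dosages numeric N x M matrix of allele counts (0/1/2/NA).
#' @param variants optional variant metadata data.frame (`chr`, `id`, `pos`,
#'   `allele1`, `allele2`); defaults are synthesized when omitted.
#' @param samples optional sample data.frame (`fid`, `iid`).
#' @param imputed logical, see class docs.
#' @param orient if `TRUE` (default) flip columns stored as major-allele
#'   counts to minor-allele counts (`2 - g` when non-missing mean/2 > 0.5),
#'   swapping the recorded alleles.
#' @return A [GenotypeMatrix-class] object.
#' @export
GenotypeMatrix <- function(dosages, variants = NULL, samples = NULL,
                           imputed = FALSE, orient = TRUE) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  M <- ncol(dosages); N <- nrow(dosages)
  if (is.null(variants)) {
    variants <- data.frame(
      chr = rep("1", M), id = paste0("snp", seq_len(M)), pos = seq_len(M),
      allele1 = rep("A", M), allele2 = rep("B", M),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(samples)) {
    samples <- data.frame(fid = paste0("F", seq_len(N)),
                          iid = paste0("I", seq_len(N)),
                          stringsAsFactors = FALSE)
  }
  if (orient && M > 0L && N > 0L) {
    fr <- colMeans(dosages, na.rm = TRUE) / 2
    flip <- which(!is.na(fr) & fr > 0.5)
    if (length(flip)) {
      dosages[, flip] <- 2 - dosages[, flip]
      a1 <- variants$allele1[flip]
      variants$allele1[flip] <- variants$allele2[flip]
      variants$allele2[flip] <- a1
    }
  }
  new("GenotypeMatrix", dosages = dosages, variants = variants,
      samples = samples, imputed = imputed)
}

## ---------------------------------------------------------------------------
## PhenotypeSet
## ---------------------------------------------------------------------------

#' PhenotypeSet: trait matrix, covariate matrix and sample keys
#'
#' Holds the N x K trait matrix Y and the N x q covariate matrix C (without
#' intercept; possibly zero columns) for N samples, complete-case and in a
#' fixed sample order. Analyses require the sample order to match the
#' GenotypeMatrix they are run against (see [alignSamples()]).
#'
#' @slot Y numeric trait matrix (columns named by trait).
#' @slot C numeric covariate matrix (columns named; may have zero columns).
#' @slot samples data.frame with columns `fid`, `iid`.
#' @aliases PhenotypeSet
#' @exportClass PhenotypeSet
setClass("PhenotypeSet",
  representation(Y = "matrix", covar = "matrix", samples = "data.frame")
)

setValidity("PhenotypeSet", function(object) {
  msg <- character()
  if (nrow(object@Y) != nrow(object@samples))
    msg <- c(msg, "Y row count must equal sample record count")
  if (nrow(object@covar) != nrow(object@Y))
    msg <- c(msg, "C row count must equal Y row count")
  if (anyNA(object@Y) || anyNA(object@covar))
    msg <- c(msg, "traits and covariates must be complete (no missing values)")
  if (length(msg)) msg else TRUE
})

#' Construct a PhenotypeSet
#'
#' @param Y numeric N x K trait matrix (or vector for K = 1).
#' @param C optional numeric N x q covariate matrix (no intercept column).
#' @param samples optional sample data.frame (`fid`, `iid`).
#' @return A [PhenotypeSet-class] object.
#' @export
PhenotypeSet <- function(Y, C = NULL, samples = NULL) {
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  if (is.null(colnames(Y))) colnames(Y) <- paste0("trait", seq_len(ncol(Y)))
  if (is.null(C)) C <- matrix(numeric(0), nrow(Y), 0L)
  C <- as.matrix(C)
  storage.mode(C) <- "double"
  if (ncol(C) && is.null(colnames(C))) colnames(C) <- paste0("cov", seq_len(ncol(C)))
  if (is.null(samples)) {
    samples <- data.frame(fid = paste0("F", seq_len(nrow(Y))),
                          iid = paste0("I", seq_len(nrow(Y))),
                          stringsAsFactors = FALSE)
  }
  new("PhenotypeSet", Y = Y, covar = C, samples = samples)
}

## ---------------------------------------------------------------------------
## KinshipMatrix
## ---------------------------------------------------------------------------

#' KinshipMatrix: relatedness matrix with cached eigendecomposition
#'
#' A symmetric positive semidefinite N x N relatedness matrix (additive
#' relationship scale, diagonal near 1 for non-inbred individuals) with its
#' eigendecomposition cached for the mixed-model modules. Negative numerical
#' eigenvalues are clamped to zero at construction and the stored matrix is
#' the clamped reconstruction, so `phi == U diag(lambda) U'` holds to
#' numerical precision.
#'
#' @slot phi symmetric PSD matrix.
#' @slot values nonnegative eigenvalues, descending.
#' @slot vectors orthonormal eigenvector columns.
#' @slot source one of `"empirical"`, `"pedigree"`, `"external"`, `"identity"`.
#' @aliases KinshipMatrix
#' @exportClass KinshipMatrix
setClass("KinshipMatrix",
  representation(phi = "matrix", values = "numeric", vectors = "matrix",
                 source = "character")
)

setValidity("KinshipMatrix", function(object) {
  msg <- character()
  N <- nrow(object@phi)
  if (ncol(object@phi) != N) msg <- c(msg, "phi must be square")
  if (length(object@values) != N || nrow(object@vectors) != N)
    msg <- c(msg, "eigendecomposition dimensions must match phi")
  if (any(object@values < 0)) msg <- c(msg, "eigenvalues must be nonnegative")
  if (is.unsorted(rev(object@values))) msg <- c(msg, "eigenvalues must descend")
  if (max(abs(object@phi - t(object@phi))) > 0)
    msg <- c(msg, "phi must be exactly symmetric")
  if (N) {
    ortho <- crossprod(object@vectors) - diag(N)
    if (max(abs(ortho)) > 1e-8) msg <- c(msg, "eigenvectors must be orthonormal")
    rec <- object@vectors %*% (object@values * t(object@vectors)) - object@phi
    if (max(abs(rec)) > 1e-8 * max(1, max(abs(object@phi))))
      msg <- c(msg, "phi must equal its eigendecomposition reconstruction")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a KinshipMatrix from a symmetric matrix
#'
#' Symmetrizes as (phi + t(phi))/2, eigendecomposes, clamps negative
#' eigenvalues to zero (warning when the most negative eigenvalue is below
#' -1e-8 times the largest) and stores the PSD reconstruction.
#'
#' @param phi square numeric matrix.
#' @param source provenance label.
#' @return A [KinshipMatrix-class] object.
#' @export
makeKinship <- function(phi, source = "external") {
  phi <- as.matrix(phi)
  if (nrow(phi) != ncol(phi)) formatError("kinship matrix must be square")
  asym <- max(abs(phi - t(phi)))
  if (asym > 1e-6)
    formatError("kinship matrix asymmetry %.3g exceeds 1e-6", asym)
  phi <- (phi + t(phi)) / 2
  e <- eigen(phi, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(1, max(abs(e$values))))
    warning(sprintf("clamping negative kinship eigenvalue %.3g to 0",
                    min(e$values)))
  vals <- pmax(e$values, 0)
  rec <- e$vectors %*% (vals * t(e$vectors))
  rec <- (rec + t(rec)) / 2
  dimnames(rec) <- dimnames(phi)
  new("KinshipMatrix", phi = rec, values = vals, vectors = e$vectors,
      source = source)
}

#' Identity kinship (unrelated samples)
#' @param n number of samples.
#' @return A [KinshipMatrix-class] equal to the identity.
#' @export
identityKinship <- function(n) {
  new("KinshipMatrix", phi = diag(n), values = rep(1, n), vectors = diag(n),
      source = "identity")
}

## ---------------------------------------------------------------------------
## Fit and statistic containers
## ---------------------------------------------------------------------------

#' NullModelFit: per-trait null linear mixed model (REML)
#'
#' Result of [fitNullReml()]: variance components of the null model
#' y = X b + Q + e with Q ~ N(0, sigma_g^2 Phi), e ~ N(0, sigma_e^2 I),
#' fitted in the eigenbasis of Phi, plus the rotated data reused by
#' [marginalTest()] and [estimateSigma()].
#'
#' @slot trait trait name.
#' @slot sigmaG2,sigmaE2 genetic and environmental variance components.
#' @slot delta variance ratio sigma_g^2 / sigma_e^2.
#' @slot beta fixed-effect estimates (intercept first).
#' @slot loglik restricted log-likelihood at the optimum.
#' @slot boundary `TRUE` when delta was returned at a search boundary.
#' @slot rotY,rotX data rotated by t(U); `weights` holds delta*lambda + 1.
#' @slot kinship the [KinshipMatrix-class] used.
#' @aliases NullModelFit
#' @exportClass NullModelFit
setClass("NullModelFit",
  representation(trait = "character", sigmaG2 = "numeric", sigmaE2 = "numeric",
                 delta = "numeric", beta = "numeric", loglik = "numeric",
                 boundary = "logical", rotY = "numeric", rotX = "matrix",
                 weights = "numeric", kinship = "KinshipMatrix")
)

setValidity("NullModelFit", function(object) {
  msg <- character()
  if (object@sigmaG2 < 0) msg <- c(msg, "sigma_g^2 must be >= 0")
  if (object@sigmaE2 <= 0) msg <- c(msg, "sigma_e^2 must be > 0")
  if (length(msg)) msg else TRUE
})

#' MvNullFit: K-trait matrix-variate null mixed model
#'
#' Result of [fitMvNull()]: genetic (Vg) and environmental (Ve) K x K trait
#' covariance matrices of Y = X Gamma + Q + E with rows of the rotated model
#' having covariance lambda_i Vg + Ve, estimated by EM.
#'
#' @slot Vg,Ve K x K covariance components.
#' @slot Gamma p x K fixed-effect matrix.
#' @slot loglik marginal log-likelihood at the final iterate.
#' @slot loglikTrace per-iteration log-likelihood (monotone nondecreasing).
#' @slot iterations,converged EM diagnostics.
#' @slot rotY,rotX rotated data; `lambda` the kinship eigenvalues.
#' @slot kinship the [KinshipMatrix-class] used.
#' @aliases MvNullFit
#' @exportClass MvNullFit
setClass("MvNullFit",
  representation(Vg = "matrix", Ve = "matrix", Gamma = "matrix",
                 loglik = "numeric", loglikTrace = "numeric",
                 iterations = "integer", converged = "logical",
                 rotY = "matrix", rotX = "matrix", lambda = "numeric",
                 kinship = "KinshipMatrix")
)

setValidity("MvNullFit", function(object) {
  msg <- character()
  eg <- eigen(object@Vg, symmetric = TRUE, only.values = TRUE)$values
  ee <- eigen(object@Ve, symmetric = TRUE, only.values = TRUE)$values
  if (min(eg) < -1e-8 * max(1, max(abs(eg)))) msg <- c(msg, "Vg must be PSD")
  if (min(ee) <= 0) msg <- c(msg, "Ve must be positive definite")
  if (length(msg)) msg else TRUE
})

#' StatVector: per-SNP marginal statistics and their null covariance
#'
#' The K-vector t = (t_1, ..., t_K) of standardized marginal association
#' statistics for one variant, together with the K x K null covariance Sigma
#' of t (a correlation matrix: unit diagonal, positive definite after the
#' upstream ridge).
#'
#' @slot id variant identifier.
#' @slot t numeric length-K statistic vector.
#' @slot sigma K x K correlation matrix.
#' @aliases StatVector
#' @exportClass StatVector
setClass("StatVector",
  representation(id = "character", t = "numeric", sigma = "matrix")
)

setValidity("StatVector", function(object) {
  msg <- character()
  K <- length(object@t)
  if (!all(dim(object@sigma) == c(K, K)))
    msg <- c(msg, "sigma must be K x K")
  else {
    if (max(abs(object@sigma - t(object@sigma))) > 1e-8)
      msg <- c(msg, "sigma must be symmetric")
    if (max(abs(diag(object@sigma) - 1)) > 1e-8)
      msg <- c(msg, "sigma must have unit diagonal")
    ev <- eigen(object@sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) msg <- c(msg, "sigma must be positive definite")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a StatVector
#' @param t length-K numeric vector of marginal statistics.
#' @param sigma K x K null correlation matrix of t.
#' @param id variant identifier.
#' @return A [StatVector-class] object.
#' @export
StatVector <- function(t, sigma, id = "snp") {
  new("StatVector", id = as.character(id), t = as.numeric(t),
      sigma = as.matrix(sigma))
}
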