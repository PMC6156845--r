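#' Empirical genomic relationship matrix (GRM)
#'
#' Centered GRM Phi = W W' / M with W the column-centered dosage matrix
#' (GEMMA's default flavor). With `standardized = TRUE` columns are also
#' scaled by their standard deviation before the cross-product (GEMMA's
#' alternative). Monomorphic columns contribute nothing and are skipped with a
#' warning.
#'
#' @param g a complete (post-imputation) [GenotypeMatrix-class] with at least
#'   two variants.
#' @param standardized use the standardized rather than centered GRM.
#' @return A [KinshipMatrix-class] with source `"empirical"`.
#' @export
empiricalGRM <- function(g, standardized = FALSE) {
  d <- dosages(g)
  if (anyNA(d)) dataError("empiricalGRM requires complete dosages; run meanImpute")
  if (ncol(d) < 2) dataError("empiricalGRM requires at least 2 variants")
  mono <- apply(d, 2, function(x) max(x) == min(x))
  if (any(mono)) {
    warning(sprintf("skipping %d monomorphic variant(s) in GRM", sum(mono)))
    d <- d[, !mono, drop = FALSE]
    if (ncol(d) < 2) dataError("fewer than 2 polymorphic variants for GRM")
  }
  W <- scale(d, center = TRUE, scale = standardized)
  phi <- tcrossprod(W) / ncol(W)
  makeKinship(phi, source = "empirical")
}

#' Additive relationship matrix from a pedigree
#'
#' Computes the additive (numerator) relationship matrix A by the standard
#' recursion: founders have A_ii = 1; A_ii = 1 + A_fm / 2 for an individual
#' with parents f and m; A_ij = (A_jf + A_jm) / 2 for j preceding i (missing
#' parents contribute 0). Diagonal 1 for non-inbred individuals, so the
#' genetic variance scale matches the usual heritability definition.
#'
#' @param ped data.frame with columns `fid`, `iid`, `father`, `mother`
#'   ("0" or NA = founder). Parents must precede offspring; individuals listed
#'   as their own ancestor raise a pedigree error.
#' @return A [KinshipMatrix-class] with source `"pedigree"`.
#' @export
pedigreeKinship <- function(ped) {
  n <- nrow(ped)
  id <- as.character(ped$iid)
  if (anyDuplicated(id)) pedigreeError("duplicated individual IDs in pedigree")
  fa <- match(as.character(ped$father), id)
  mo <- match(as.character(ped$mother), id)
  if (any(which(!is.na(fa)) <= fa[!is.na(fa)]) ||
      any(which(!is.na(mo)) <= mo[!is.na(mo)]))
    pedigreeError("pedigree not sorted: a parent appears at or after its offspring (or an individual is its own ancestor)")
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    f <- fa[i]; m <- mo[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      rel <- numeric(i - 1L)
      if (!is.na(f)) rel <- rel + A[j, f]
      if (!is.na(m)) rel <- rel + A[j, m]
      A[j, i] <- A[i, j] <- rel / 2
    }
    A[i, i] <- 1 + if (!is.na(f) && !is.na(m)) A[f, m] / 2 else 0
  }
  dimnames(A) <- list(id, id)
  makeKinship(A, source = "pedigree")
}
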