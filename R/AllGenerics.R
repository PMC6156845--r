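#' Accessors for pusat data classes
#'
#' `dosages()`, `variants()`, `samples()` access the GenotypeMatrix slots;
#' `traits()` and `covariates()` the PhenotypeSet matrices; `relMatrix()`,
#' `eigenValues()` and `eigenVectors()` the KinshipMatrix and its cached
#' spectral decomposition; `nSamples()`, `nVariants()`, `nTraits()` give
#' dimensions.
#'
#' @param x a pusat data object.
#' @return The corresponding slot or dimension.
#' @name accessors
#' @aliases dosages variants samples traits covariates relMatrix eigenValues
#'   eigenVectors nSamples nVariants nTraits
NULL

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname accessors
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))
#' @rdname accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("traits", function(x) standardGeneric("traits"))
#' @rdname accessors
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))
#' @rdname accessors
#' @export
setGeneric("relMatrix", function(x) standardGeneric("relMatrix"))
#' @rdname accessors
#' @export
setGeneric("eigenValues", function(x) standardGeneric("eigenValues"))
#' @rdname accessors
#' @export
setGeneric("eigenVectors", function(x) standardGeneric("eigenVectors"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))
#' @rdname accessors
#' @export
setGeneric("nTraits", function(x) standardGeneric("nTraits"))

#' @rdname accessors
setMethod("dosages", "GenotypeMatrix", function(x) x@dosages)
#' @rdname accessors
setMethod("variants", "GenotypeMatrix", function(x) x@variants)
#' @rdname accessors
setMethod("samples", "GenotypeMatrix", function(x) x@samples)
#' @rdname accessors
setMethod("samples", "PhenotypeSet", function(x) x@samples)
#' @rdname accessors
setMethod("traits", "PhenotypeSet", function(x) x@Y)
#' @rdname accessors
setMethod("covariates", "PhenotypeSet", function(x) x@covar)
#' @rdname accessors
setMethod("relMatrix", "KinshipMatrix", function(x) x@phi)
#' @rdname accessors
setMethod("eigenValues", "KinshipMatrix", function(x) x@values)
#' @rdname accessors
setMethod("eigenVectors", "KinshipMatrix", function(x) x@vectors)
#' @rdname accessors
setMethod("nSamples", "GenotypeMatrix", function(x) nrow(x@dosages))
#' @rdname accessors
setMethod("nSamples", "PhenotypeSet", function(x) nrow(x@Y))
#' @rdname accessors
setMethod("nSamples", "KinshipMatrix", function(x) nrow(x@phi))
#' @rdname accessors
setMethod("nVariants", "GenotypeMatrix", function(x) ncol(x@dosages))
#' @rdname accessors
setMethod("nTraits", "PhenotypeSet", function(x) ncol(x@Y))

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d samples x %d variants%s\n",
              nrow(object@dosages), ncol(object@dosages),
              if (object@imputed) " (mean-imputed)" else ""))
  nm <- sum(is.na(object@dosages))
  cat(sprintf("  missing entries: %d (%.2f%%)\n", nm,
              100 * nm / max(1, length(object@dosages))))
})

setMethod("show", "PhenotypeSet", function(object) {
  cat(sprintf("PhenotypeSet: %d samples, %d trait(s) [%s], %d covariate(s)\n",
              nrow(object@Y), ncol(object@Y),
              paste(colnames(object@Y), collapse = ", "), ncol(object@covar)))
})

setMethod("show", "KinshipMatrix", function(object) {
  cat(sprintf("KinshipMatrix (%s): %d x %d, eigenvalues in [%.4g, %.4g]\n",
              object@source, nrow(object@phi), ncol(object@phi),
              min(object@values), max(object@values)))
})

setMethod("show", "NullModelFit", function(object) {
  cat(sprintf(
    "NullModelFit '%s': sigma_g2 = %.4g, sigma_e2 = %.4g (h2 = %.3f)%s\n",
    object@trait, object@sigmaG2, object@sigmaE2,
    object@sigmaG2 / (object@sigmaG2 + object@sigmaE2),
    if (object@boundary) " [boundary]" else ""))
})

setMethod("show", "MvNullFit", function(object) {
  cat(sprintf("MvNullFit: K = %d, %d EM iterations, %s\n",
              ncol(object@Vg), object@iterations,
              if (object@converged) "converged" else "NOT converged"))
  cat("Vg:\n"); print(round(object@Vg, 4))
  cat("Ve:\n"); print(round(object@Ve, 4))
})

setMethod("show", "StatVector", function(object) {
  cat(sprintf("StatVector '%s': t = (%s)\n", object@id,
              paste(sprintf("%.3f", object@t), collapse = ", ")))
})
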