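#' Quality-control thresholds
#'
#' Container for the variant- and sample-level filters: variants are kept when
#' call rate >= `minCallRate`, MAF >= `minMaf` and the Hardy-Weinberg
#' equilibrium p-value >= `hwePFloor`; samples are removed when their missing
#' fraction exceeds `maxSampleMissing` (strict inequality).
#'
#' @param minCallRate minimum variant call rate (default 0.95).
#' @param minMaf minimum minor allele frequency (default 0.05).
#' @param hwePFloor minimum HWE p-value (default 1e-6).
#' @param maxSampleMissing maximum per-sample missing fraction (default 0.05).
#' @return list of class `QcThresholds`.
#' @export
qcThresholds <- function(minCallRate = 0.95, minMaf = 0.05, hwePFloor = 1e-6,
                         maxSampleMissing = 0.05) {
  thr <- list(minCallRate = minCallRate, minMaf = minMaf,
              hwePFloor = hwePFloor, maxSampleMissing = maxSampleMissing)
  if (any(unlist(thr) < 0 | unlist(thr) > 1))
    configError("all QC thresholds must lie in [0, 1]")
  structure(thr, class = "QcThresholds")
}

#' Hardy-Weinberg equilibrium chi-square p-value
#'
#' Plain 1-df Pearson goodness-of-fit of the genotype counts against
#' Hardy-Weinberg proportions at the observed allele frequency, no continuity
#' correction, all individuals used. Monomorphic variants return p = 1.
#'
#' @param n0,n1,n2 counts of dosage 0, 1, 2 genotypes.
#' @return p-value.
#' @export
hwePvalue <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  if (n == 0) return(NA_real_)
  p <- (2 * n2 + n1) / (2 * n)       # frequency of the counted allele
  q <- 1 - p
  if (p <= 0 || q <= 0) return(1)
  ex <- n * c(q^2, 2 * p * q, p^2)
  chi2 <- sum((c(n0, n1, n2) - ex)^2 / ex)
  stats::pchisq(chi2, df = 1, lower.tail = FALSE)
}

#' Variant quality control
#'
#' Applies the call-rate, MAF and HWE filters of [qcThresholds()] and returns
#' the retained variants plus a per-removal report (`variant_id`, `reason` in
#' `{call_rate, maf, hwe}`, `value`; the first failed filter is reported).
#'
#' @param g a [GenotypeMatrix-class].
#' @param thr a [qcThresholds()] list.
#' @return list with elements `genotypes` (filtered [GenotypeMatrix-class]) and
#'   `report` (data.frame of dropped variants).
#' @export
variantQC <- function(g, thr = qcThresholds()) {
  d <- dosages(g)
  M <- ncol(d)
  callRate <- colMeans(!is.na(d))
  fr <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(fr, 1 - fr)
  maf[is.nan(maf)] <- 0
  hwe <- vapply(seq_len(M), function(j) {
    x <- d[, j]; x <- x[!is.na(x)]
    hwePvalue(sum(x == 0), sum(x == 1), sum(x == 2))
  }, numeric(1))

  failCall <- callRate < thr$minCallRate
  failMaf <- !failCall & maf < thr$minMaf
  failHwe <- !failCall & !failMaf & !is.na(hwe) & hwe < thr$hwePFloor
  drop <- failCall | failMaf | failHwe

  report <- data.frame(
    variant_id = variants(g)$id[drop],
    reason = ifelse(failCall[drop], "call_rate",
                    ifelse(failMaf[drop], "maf", "hwe")),
    value = ifelse(failCall[drop], callRate[drop],
                   ifelse(failMaf[drop], maf[drop], hwe[drop])),
    stringsAsFactors = FALSE
  )
  keep <- which(!drop)
  if (!length(keep)) message("variant QC removed every variant")
  g2 <- new("GenotypeMatrix", dosages = d[, keep, drop = FALSE],
            variants = variants(g)[keep, , drop = FALSE],
            samples = samples(g), imputed = g@imputed)
  list(genotypes = g2, report = report)
}

#' Sample quality control
#'
#' Removes samples whose fraction of missing genotypes strictly exceeds
#' `thr$maxSampleMissing` (a sample missing exactly the threshold fraction is
#' retained).
#'
#' @inheritParams variantQC
#' @return filtered [GenotypeMatrix-class].
#' @export
sampleQC <- function(g, thr = qcThresholds()) {
  d <- dosages(g)
  missFrac <- rowMeans(is.na(d))
  keep <- which(missFrac <= thr$maxSampleMissing)
  if (!length(keep)) dataError("sample QC removed every sample")
  new("GenotypeMatrix", dosages = d[keep, , drop = FALSE],
      variants = variants(g), samples = samples(g)[keep, , drop = FALSE],
      imputed = g@imputed)
}

#' Mean imputation of missing dosages
#'
#' Replaces each missing entry with the column's non-missing mean, preserving
#' observed entries and per-column means (so MAF is unchanged). Intended after
#' variant QC; an all-missing column is an error.
#'
#' @param g a [GenotypeMatrix-class].
#' @return a real-valued [GenotypeMatrix-class] with `imputed = TRUE`.
#' @export
meanImpute <- function(g) {
  d <- dosages(g)
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    if (anyNA(mu) || any(is.nan(mu)))
      dataError("all-missing column encountered; run variantQC first")
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  new("GenotypeMatrix", dosages = d, variants = variants(g),
      samples = samples(g), imputed = TRUE)
}
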