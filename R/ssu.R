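## Sum-of-squared-score test and the Liu et al. moment-matched chi-square
## approximation for quadratic-form null distributions sum_k c_k chi^2_1.

#' Liu et al. moment-matching coefficients
#'
#' For a central quadratic form with eigenvalues `c` (all positive), the null
#' distribution sum c_k chi^2_1 is approximated by a * chi^2_d + b with
#' a = sum(c^3)/sum(c^2), b = sum(c) - sum(c^2)^2/sum(c^3),
#' d = sum(c^2)^3/sum(c^3)^2. Exact when all eigenvalues are equal.
#'
#' @param c positive eigenvalues of the covariance of the statistic vector.
#' @return named list `a`, `b`, `d`.
#' @export
liuCoefficients <- function(c) {
  if (any(c <= 0)) domainError("Liu coefficients require all eigenvalues > 0")
  s1 <- sum(c); s2 <- sum(c^2); s3 <- sum(c^3)
  list(a = s3 / s2, b = s1 - s2^2 / s3, d = s2^3 / s3^2)
}

#' Liu-approximate survival, CDF and quantile of a chi-square mixture
#'
#' `liuPvalue(q, c)` is P(sum c_k chi^2_1 >= q) under the a*chi^2_d + b
#' approximation (returns 1 when (q - b)/a < 0); `liuCdf` its complement;
#' `liuQuantile(p, c)` the exact inverse a * qchisq(p, d) + b.
#'
#' @param q quantile(s).
#' @param p probability(ies).
#' @param c positive eigenvalues.
#' @return numeric vector.
#' @export
liuPvalue <- function(q, c) {
  k <- liuCoefficients(c)
  x <- (q - k$b) / k$a
  out <- stats::pchisq(pmax(x, 0), df = k$d, lower.tail = FALSE)
  out[x < 0] <- 1
  pmin(pmax(out, .Machine$double.xmin), 1)
}

#' @rdname liuPvalue
#' @export
liuCdf <- function(q, c) {
  k <- liuCoefficients(c)
  stats::pchisq(pmax((q - k$b) / k$a, 0), df = k$d)
}

#' @rdname liuPvalue
#' @export
liuQuantile <- function(p, c) {
  k <- liuCoefficients(c)
  k$a * stats::qchisq(p, df = k$d) + k$b
}

#' Estimate the cross-trait covariance of the marginal statistics
#'
#' Under the null, the per-SNP statistic vector t is asymptotically
#' N(0, Sigma) with Sigma the cross-trait correlation of the (kinship-
#' whitened) trait noise. For each trait the null-model residuals are rotated
#' to the kinship eigenbasis and whitened by (delta lambda_i + 1)^{-1/2};
#' Sigma-hat is the sample correlation of the whitened residual vectors, with
#' a 1e-6 diagonal ridge renormalized back to unit diagonal to guard
#' near-singular cases. Estimated once per trait set and reused genome-wide.
#'
#' @param Y N x K trait matrix (or [PhenotypeSet-class]).
#' @param C covariate matrix (ignored when `Y` is a PhenotypeSet).
#' @param kin a [KinshipMatrix-class].
#' @param fits optional list of per-trait [NullModelFit-class] objects to
#'   reuse.
#' @return K x K correlation matrix.
#' @export
estimateSigma <- function(Y, C = NULL, kin, fits = NULL) {
  if (is(Y, "PhenotypeSet")) {
    C <- if (ncol(covariates(Y))) covariates(Y) else NULL
    Y <- traits(Y)
  }
  Y <- as.matrix(Y)
  K <- ncol(Y)
  if (K < 2) configError("estimateSigma requires at least 2 traits")
  if (is.null(fits))
    fits <- lapply(seq_len(K), function(k)
      fitNullReml(Y[, k], C, kin, trait = colnames(Y)[k] %||% paste0("trait", k)))
  R <- vapply(fits, function(f) {
    r <- f@rotY - drop(f@rotX %*% f@beta)
    r / sqrt(f@weights)
  }, numeric(nrow(Y)))
  S <- stats::cor(R)
  S <- S + diag(1e-6, K)
  stats::cov2cor(S)
}

#' SSU test from a statistic vector
#'
#' The sum-of-squared-score statistic S = t' t = sum t_k^2, with p-value from
#' the Liu approximation using the eigenvalues of Sigma:
#' p = P(a chi^2_d + b >= S).
#'
#' @param sv a [StatVector-class], or a numeric vector `t` with `sigma` given.
#' @param sigma K x K covariance of t (when `sv` is a plain vector).
#' @return list: `s_sq`, Liu coefficients `a`, `b`, `d`, and `p`.
#' @export
ssuTest <- function(sv, sigma = NULL) {
  if (is(sv, "StatVector")) {
    t <- sv@t; sigma <- sv@sigma
  } else t <- as.numeric(sv)
  sSq <- sum(t^2)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  k <- liuCoefficients(ev)
  p <- liuPvalue(sSq, ev)
  list(s_sq = sSq, a = k$a, b = k$b, d = k$d, p = p)
}
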