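## Per-trait null linear mixed model and per-SNP marginal statistics.
##
## Model: y = X b + Q + e, Q ~ N(0, sigma_g^2 Phi), e ~ N(0, sigma_e^2 I).
## With Phi = U diag(lambda) U', premultiplying by U' gives independent
## residual variances sigma_e^2 (delta lambda_i + 1), delta = sigma_g^2 /
## sigma_e^2, so REML reduces to a 1-D profile over delta.

.remlProfile <- function(delta, ry, rX, lambda) {
  v <- delta * lambda + 1
  w <- 1 / v
  XtWX <- crossprod(rX, rX * w)
  XtWy <- crossprod(rX, ry * w)
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(list(ll = -Inf))
  beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
  r <- ry - drop(rX %*% beta)
  rss <- sum(r * r * w)
  n <- length(ry); p <- ncol(rX)
  sigmaE2 <- rss / (n - p)
  ll <- -0.5 * ((n - p) * log(2 * pi * sigmaE2) + (n - p) +
                sum(log(v)) + 2 * sum(log(diag(ch))))
  list(ll = ll, beta = drop(beta), sigmaE2 = sigmaE2, v = v)
}

#' Fit the per-trait null mixed model by REML
#'
#' Maximizes the restricted likelihood over the variance ratio
#' delta = sigma_g^2 / sigma_e^2 in the kinship eigenbasis: a 64-point
#' log-spaced grid on \[1e-5, 1e5\] brackets the optimum, followed by bounded
#' scalar refinement; delta = 0 (no genetic variance) and the grid maximum are
#' always candidate boundary solutions. Deterministic.
#'
#' @param y numeric response vector (complete).
#' @param C optional covariate matrix (no intercept; an intercept is added).
#' @param kin a [KinshipMatrix-class].
#' @param trait trait label carried into the fit.
#' @return A [NullModelFit-class].
#' @export
fitNullReml <- function(y, C = NULL, kin, trait = "trait") {
  y <- as.numeric(y)
  n <- length(y)
  if (n != nSamples(kin)) dataError("y length does not match kinship dimension")
  if (stats::var(y) == 0) modelError("response '%s' has zero variance", trait)
  X <- cbind(`(Intercept)` = rep(1, n), C)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- sort(qrX$pivot[seq_len(qrX$rank)])
    if (!1L %in% keep) modelError("covariate matrix is rank deficient")
    warning("dropping aliased covariate column(s)")
    X <- X[, keep, drop = FALSE]
  }
  U <- eigenVectors(kin)
  lambda <- eigenValues(kin)
  ry <- drop(crossprod(U, y))
  rX <- crossprod(U, X)

  grid <- 10^seq(-5, 5, length.out = 64)
  lls <- vapply(grid, function(d) .remlProfile(d, ry, rX, lambda)$ll, numeric(1))
  if (all(!is.finite(lls))) numericError("non-finite restricted likelihood")
  iBest <- which.max(lls)
  lo <- grid[max(1L, iBest - 1L)]
  hi <- grid[min(length(grid), iBest + 1L)]
  opt <- stats::optimize(function(ld) .remlProfile(10^ld, ry, rX, lambda)$ll,
                         lower = log10(lo), upper = log10(hi),
                         maximum = TRUE, tol = 1e-8)
  cand <- c(0, 10^opt$maximum, grid[length(grid)])
  candLL <- vapply(cand, function(d) .remlProfile(d, ry, rX, lambda)$ll,
                   numeric(1))
  ## ties (e.g. a flat profile when Phi = I) break toward the smallest delta
  tol <- 1e-7 * (1 + abs(max(candLL)))
  k <- which(candLL >= max(candLL) - tol)[1]
  delta <- cand[k]
  fit <- .remlProfile(delta, ry, rX, lambda)
  boundary <- k != 2L || iBest %in% c(1L, length(grid))
  new("NullModelFit", trait = trait, sigmaG2 = delta * fit$sigmaE2,
      sigmaE2 = fit$sigmaE2, delta = delta, beta = fit$beta,
      loglik = candLL[k], boundary = boundary, rotY = ry, rotX = rX,
      weights = fit$v, kinship = kin)
}

#' Narrow-sense heritability from a null fit
#' @param fit a [NullModelFit-class].
#' @return sigma_g^2 / (sigma_g^2 + sigma_e^2).
#' @export
heritability <- function(fit) fit@sigmaG2 / (fit@sigmaG2 + fit@sigmaE2)

## Shared internals for single- and many-SNP marginal tests. rG: rotated
## genotype columns (U' g). Variance components fixed at the null fit
## (score-test / EMMAX style): cov(theta) = sigmaE2 (Z' V^-1 Z)^-1 with
## V = diag(delta lambda + 1).
.marginalStats <- function(rG, fit) {
  w <- 1 / fit@weights
  rX <- fit@rotX
  ry <- fit@rotY
  XtWX <- crossprod(rX, rX * w)
  XtWXinv <- solve(XtWX)
  XtWy <- crossprod(rX, ry * w)
  b1 <- crossprod(rX, rG * w)                      # p x M
  gWg <- colSums(rG * rG * w)
  gWy <- colSums(rG * ry * w)
  s <- gWg - colSums(b1 * (XtWXinv %*% b1))        # Schur complement per SNP
  ok <- s > max(gWg, 1) * 1e-12
  beta <- rep(NA_real_, length(s)); se <- rep(NA_real_, length(s))
  beta[ok] <- (gWy[ok] - drop(crossprod(b1[, ok, drop = FALSE],
                                        drop(XtWXinv %*% XtWy)))) / s[ok]
  se[ok] <- sqrt(fit@sigmaE2 / s[ok])
  t <- beta / se
  p <- 2 * stats::pnorm(-abs(t))
  data.frame(beta = beta, se = se, t = t, p = p)
}

#' Marginal association test for one SNP
#'
#' Generalized-least-squares estimate of the SNP effect with variance
#' components fixed at the null fit; t = beta / se is referenced to the
#' standard normal. A SNP that is constant after covariate projection is
#' returned flagged with `NA` statistics.
#'
#' @param g numeric dosage vector (complete, aligned to the fit's samples).
#' @param fit a [NullModelFit-class].
#' @param id variant identifier.
#' @return one-row data.frame: `id, beta, se, t, p`.
#' @export
marginalTest <- function(g, fit, id = "snp") {
  rG <- crossprod(eigenVectors(fit@kinship), matrix(as.numeric(g), ncol = 1))
  cbind(data.frame(id = id, stringsAsFactors = FALSE), .marginalStats(rG, fit))
}

#' Marginal association scan over all variants
#'
#' Vectorized [marginalTest()] over the columns of a genotype matrix.
#'
#' @param G a [GenotypeMatrix-class] (complete) or numeric matrix.
#' @param fit a [NullModelFit-class].
#' @return data.frame with one row per variant: `id, beta, se, t, p`.
#' @export
marginalScan <- function(G, fit) {
  if (is(G, "GenotypeMatrix")) {
    ids <- variants(G)$id
    G <- dosages(G)
  } else {
    G <- as.matrix(G)
    ids <- colnames(G) %||% paste0("snp", seq_len(ncol(G)))
  }
  if (anyNA(G)) dataError("marginalScan requires complete dosages; run meanImpute")
  rG <- crossprod(eigenVectors(fit@kinship), G)
  cbind(data.frame(id = ids, stringsAsFactors = FALSE), .marginalStats(rG, fit))
}
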