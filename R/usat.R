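## Unified score-based association test and its pedigree extension.
##
## Both the MANOVA-type statistic T_M = t' Sigma^{-1} t and the SSU statistic
## T_S = t' t are quadratic forms in the same asymptotically normal vector
## t ~ N(0, Sigma). Writing t = Sigma^{1/2} z with z ~ N(0, I): T_M = z'z and
## T_S = z' Sigma z, so the weighted statistic T_w = w T_M + (1 - w) T_S is a
## quadratic form with null eigenvalues kappa_i = w + (1 - w) lambda_i(Sigma),
## and every per-weight p-value comes from the same Liu machinery as the SSU
## test.

#' Default weight grid for the unified test
#' @return the 11-point grid 0, 0.1, ..., 1.
#' @export
usatWeights <- function() seq(0, 1, by = 0.1)

.checkGrid <- function(grid) {
  if (is.unsorted(grid, strictly = TRUE) || grid[1] != 0 ||
      grid[length(grid)] != 1)
    configError("weight grid must be strictly increasing and contain 0 and 1")
  grid
}

.sigmaEigen <- function(sigma) {
  e <- eigen(sigma, symmetric = TRUE)
  if (min(e$values) <= 0)
    domainError("Sigma must be positive definite (apply the upstream ridge)")
  e
}

#' Per-weight p-value of the weighted statistic
#'
#' p_w of T_w = w T_M + (1 - w) T_S, computed by applying the Liu
#' approximation to the mixture eigenvalues kappa_i = w + (1 - w)
#' lambda_i(Sigma). At w = 1 the mixture is exactly chi-square with K df; at
#' w = 0 this reduces to [ssuTest()].
#'
#' @param sv a [StatVector-class].
#' @param w weight in \[0, 1\].
#' @return p-value.
#' @export
weightedP <- function(sv, w) {
  e <- .sigmaEigen(sv@sigma)
  tS <- sum(sv@t^2)
  tM <- sum(drop(crossprod(e$vectors, sv@t))^2 / e$values)
  liuPvalue(w * tM + (1 - w) * tS, w + (1 - w) * e$values)
}

#' The min-p unified statistic over the weight grid
#'
#' Computes p_w at every grid weight and returns the minimum (the USAT/pUSAT
#' statistic), the smallest weight attaining it, and the per-weight p-values.
#'
#' @param sv a [StatVector-class].
#' @param grid weight grid (strictly increasing, containing 0 and 1).
#' @return list: `t_usat` (min p_w), `w_opt`, `p_w`, plus the underlying
#'   quadratic statistics `t_M`, `t_S`.
#' @export
usatStatistic <- function(sv, grid = usatWeights()) {
  grid <- .checkGrid(grid)
  e <- .sigmaEigen(sv@sigma)
  tS <- sum(sv@t^2)
  tM <- sum(drop(crossprod(e$vectors, sv@t))^2 / e$values)
  pw <- vapply(grid, function(w)
    liuPvalue(w * tM + (1 - w) * tS, w + (1 - w) * e$values), numeric(1))
  i <- which.min(pw)                      # ties break toward the smallest w
  list(t_usat = pw[i], w_opt = grid[i], p_w = pw, t_M = tM, t_S = tS)
}

## Conditional CDF of T_S given T_M = x under t ~ N(0, Sigma):
## with z uniform on the sphere z'z = x, T_S = x * sum(lambda_i d_i) with
## d ~ Dirichlet(1/2, ..., 1/2). At K = 2 this is exactly
## x * (l_min + (l_max - l_min) Beta(1/2, 1/2)); for K > 2 a Beta on
## [l_min x, l_max x] is moment-matched to the Dirichlet mean and variance
## (which reproduces the exact K = 2 law).
.condCdfTS <- function(s, x, lam) {
  K <- length(lam)
  lmin <- min(lam); lmax <- max(lam)
  if (lmax - lmin < 1e-12 * max(lmax, 1))
    return(as.numeric(lmin * x <= s))
  mu <- mean(lam)
  v2 <- 2 * (K * sum(lam^2) - sum(lam)^2) / (K^2 * (K + 2))  # Var/x^2
  muF <- (mu - lmin) / (lmax - lmin)
  vF <- v2 / (lmax - lmin)^2
  common <- muF * (1 - muF) / vF - 1
  alpha <- muF * common
  beta <- (1 - muF) * common
  z <- (s / x - lmin) / (lmax - lmin)
  out <- stats::pbeta(pmin(pmax(z, 0), 1), alpha, beta)
  out[x <= 0] <- as.numeric(s[x <= 0] >= 0)
  out
}

#' Integrated p-value of the min-p unified statistic
#'
#' Converts the observed min-p statistic t into its own p-value
#' P(min_w p_w <= t) under t ~ N(0, Sigma):
#' p = 1 - P(T_{w_1} < q_min(w_1), ..., T_{w_B} < q_min(w_B)), where
#' q_min(w) is the (1 - t) quantile of the T_w null mixture (Liu quantile, in
#' closed form). The joint event is T_M < q_min(1) and T_S < delta(T_M) with
#' delta(x) = min over grid weights w < 1 of (q_min(w) - w x)/(1 - w), so
#' p = 1 - integral over (0, q_min(1)) of F(delta(x) | T_M = x) f_chi2_K(x) dx
#' by adaptive quadrature. By default F is the conditional CDF of T_S given
#' T_M = x (exact at K = 2); `conditional = FALSE` uses the unconditional
#' Liu CDF of T_S instead (an independence approximation, markedly
#' conservative as Sigma approaches the identity). The result is clamped into
#' the exact min-p/Bonferroni sandwich \[t, min(1, B t)\].
#'
#' @param tUsat observed min-p statistic in (0, 1\].
#' @param sigma K x K positive definite correlation matrix of t.
#' @param grid weight grid.
#' @param conditional use the conditional CDF of T_S given T_M (default).
#' @return integrated p-value.
#' @export
pusatPvalue <- function(tUsat, sigma, grid = usatWeights(),
                        conditional = TRUE) {
  grid <- .checkGrid(grid)
  if (is.na(tUsat) || tUsat < 0 || tUsat > 1)
    domainError("t_usat must lie in (0, 1]")
  if (tUsat == 0) {
    warning("t_usat underflowed to 0; returning smallest positive value")
    return(.Machine$double.xmin)
  }
  lam <- .sigmaEigen(sigma)$values
  K <- length(lam)
  qmin <- vapply(grid, function(w)
    liuQuantile(1 - tUsat, w + (1 - w) * lam), numeric(1))
  wg <- grid[grid < 1]
  qg <- qmin[grid < 1]
  upper <- qmin[grid == 1]                # exact chi2_K quantile at w = 1
  delta <- function(x) {
    d <- rep(Inf, length(x))
    for (j in seq_along(wg)) d <- pmin(d, (qg[j] - wg[j] * x) / (1 - wg[j]))
    d
  }
  Fts <- if (conditional) {
    function(s, x) .condCdfTS(s, x, lam)
  } else {
    function(s, x) ifelse(s <= 0, 0, liuCdf(pmax(s, 0), lam))
  }
  integrand <- function(x) Fts(delta(x), x) * stats::dchisq(x, df = K)

  if (conditional) {
    ## Given T_M = x, T_S is supported on [lmin x, lmax x], so the integrand
    ## is exactly chi2_K density below x1 (delta(x) >= lmax x) and exactly 0
    ## above x2 (delta(x) <= lmin x). Integrating only (x1, x2) removes the
    ## saturation kinks and the Beta(1/2,1/2) edge singularities at the
    ## domain ends. delta() is decreasing, so both crossings are unique.
    lmin <- min(lam); lmax <- max(lam)
    x1 <- if (delta(upper) - lmax * upper >= 0) upper else
      stats::uniroot(function(x) delta(x) - lmax * x, c(0, upper),
                     tol = 1e-12)$root
    x2 <- if (delta(upper) - lmin * upper >= 0) upper else
      stats::uniroot(function(x) delta(x) - lmin * x, c(0, upper),
                     tol = 1e-12)$root
    head_ <- stats::pchisq(x1, df = K)
    mid <- 0
    if (x2 > x1 + 1e-14) {
      mid <- tryCatch(
        stats::integrate(integrand, x1, x2, abs.tol = 1e-8, rel.tol = 1e-6,
                         subdivisions = 1000L)$value,
        error = function(e) {
          xs <- seq(x1, x2, length.out = 20001L)
          fv <- integrand(xs)
          sum((fv[-1] + fv[-length(fv)]) / 2) * (xs[2] - xs[1])
        })
    }
    p <- 1 - (head_ + mid)
  } else {
    val <- tryCatch(
      stats::integrate(integrand, 0, upper, abs.tol = 1e-8, rel.tol = 1e-6,
                       subdivisions = 1000L)$value,
      error = function(e) {
        xs <- seq(0, upper, length.out = 20001L)
        fv <- integrand(xs)
        sum((fv[-1] + fv[-length(fv)]) / 2) * (xs[2] - xs[1])
      })
    if (!is.finite(val))
      numericError("pusat quadrature failed (t = %.3g, K = %d)", tUsat, K)
    p <- 1 - val
  }
  min(max(p, tUsat, .Machine$double.xmin), length(grid) * tUsat, 1)
}

## Shared per-SNP driver given marginal t statistics (M x K), Sigma and ids.
.usatScan <- function(tMat, sigma, ids, grid, conditional) {
  e <- .sigmaEigen(sigma)
  lam <- e$values
  nW <- length(grid)
  M <- nrow(tMat)
  out <- data.frame(id = ids, stringsAsFactors = FALSE)
  tS <- rowSums(tMat^2)
  zt <- tMat %*% e$vectors
  tM <- drop((zt^2) %*% (1 / lam))
  pw <- matrix(NA_real_, M, nW)
  for (j in seq_len(nW)) {
    w <- grid[j]
    pw[, j] <- liuPvalue(w * tM + (1 - w) * tS, w + (1 - w) * lam)
  }
  bad <- !stats::complete.cases(tMat)
  pw[bad, ] <- 1
  iMin <- max.col(-pw, ties.method = "first")
  tUsat <- pw[cbind(seq_len(M), iMin)]
  out$stat_ssu <- tS
  out$p_ssu <- pw[, 1]
  out$stat_mvq <- tM
  out$p_mvlmm <- stats::pchisq(tM, df = ncol(tMat), lower.tail = FALSE)
  out$t_usat <- tUsat
  out$w_opt <- grid[iMin]
  out$p_final <- vapply(seq_len(M), function(i) {
    if (bad[i] || is.na(tUsat[i])) return(NA_real_)
    pusatPvalue(tUsat[i], sigma, grid, conditional)
  }, numeric(1))
  out[bad, setdiff(names(out), "id")] <- NA_real_
  out
}

#' Unified score association test for unrelated samples (USAT)
#'
#' Marginal statistics and their cross-trait correlation come from ordinary
#' least squares (no kinship adjustment): per trait, the SNP effect is tested
#' with the residual variance fixed at the null (covariates-only) model, and
#' Sigma is the ridged correlation of the null residuals. Downstream the
#' weighted combination, min-p statistic and integrated p-value are as in
#' [runPusat()].
#'
#' @param Y N x K trait matrix or [PhenotypeSet-class].
#' @param C covariate matrix (ignored for a PhenotypeSet).
#' @param G [GenotypeMatrix-class] or numeric dosage matrix (complete).
#' @param grid weight grid.
#' @param conditional see [pusatPvalue()].
#' @return data.frame, one row per variant: per-trait `t_`/`p_` columns,
#'   `stat_ssu`, `p_ssu`, `stat_mvq`, `p_mvlmm`, `t_usat`, `w_opt`, `p_final`,
#'   with attribute `"sigma"`.
#' @export
runUsat <- function(Y, C = NULL, G, grid = usatWeights(), conditional = TRUE) {
  if (is(Y, "PhenotypeSet")) {
    C <- if (ncol(covariates(Y))) covariates(Y) else NULL
    Y <- traits(Y)
  }
  Y <- as.matrix(Y)
  if (is(G, "GenotypeMatrix")) {
    ids <- variants(G)$id; D <- dosages(G)
  } else {
    D <- as.matrix(G)
    ids <- colnames(D) %||% paste0("snp", seq_len(ncol(D)))
  }
  if (anyNA(D)) dataError("runUsat requires complete dosages; run meanImpute")
  N <- nrow(Y); K <- ncol(Y)
  if (K < 2) configError("joint tests require at least 2 traits")
  X <- cbind(`(Intercept)` = rep(1, N), C)
  qrX <- qr(X)
  R <- qr.resid(qrX, Y)                     # null residuals per trait
  sig2 <- colSums(R^2) / (N - ncol(X))
  Gp <- qr.resid(qrX, D)                    # SNPs residualized on covariates
  ss <- colSums(Gp^2)
  ok <- ss > 1e-12 * max(ss, 1)
  tMat <- matrix(NA_real_, ncol(D), K)
  num <- crossprod(Gp, R)                   # M x K
  tMat[ok, ] <- num[ok, , drop = FALSE] /
    (sqrt(ss[ok]) %o% sqrt(sig2))
  sigma <- stats::cov2cor(stats::cor(R) + diag(1e-6, K))
  out <- .usatScan(tMat, sigma, ids, grid, conditional)
  tn <- colnames(Y)
  for (k in seq_len(K)) {
    out[[paste0("t_", tn[k])]] <- tMat[, k]
    out[[paste0("p_", tn[k])]] <- 2 * stats::pnorm(-abs(tMat[, k]))
  }
  attr(out, "sigma") <- sigma
  out
}

#' Pedigree-based unified score association test (pUSAT)
#'
#' The family-data version: per-trait marginal statistics come from the
#' kinship-adjusted mixed model ([fitNullReml()] + [marginalScan()]) and Sigma
#' from the whitened null residuals ([estimateSigma()]). Inside the weighted
#' combination the MANOVA-type statistic is represented as the quadratic form
#' t' Sigma^{-1} t of the mixed-model statistics (asymptotically the mvLMM
#' K-df test), so that both components share the eigenstructure the
#' per-weight null distribution requires; the EM-based [mvTest()] is reported
#' separately by the assoc front end.
#'
#' @param Y N x K trait matrix or [PhenotypeSet-class].
#' @param C covariate matrix (ignored for a PhenotypeSet).
#' @param G [GenotypeMatrix-class] or numeric dosage matrix (complete).
#' @param kin a [KinshipMatrix-class].
#' @param grid weight grid.
#' @param conditional see [pusatPvalue()].
#' @param fits optional precomputed per-trait [NullModelFit-class] list.
#' @return data.frame as in [runUsat()].
#' @export
runPusat <- function(Y, C = NULL, G, kin, grid = usatWeights(),
                     conditional = TRUE, fits = NULL) {
  if (is(Y, "PhenotypeSet")) {
    C <- if (ncol(covariates(Y))) covariates(Y) else NULL
    Y <- traits(Y)
  }
  Y <- as.matrix(Y)
  K <- ncol(Y)
  if (K < 2) configError("joint tests require at least 2 traits")
  if (is.null(colnames(Y))) colnames(Y) <- paste0("trait", seq_len(K))
  if (is.null(fits))
    fits <- lapply(seq_len(K), function(k)
      fitNullReml(Y[, k], C, kin, trait = colnames(Y)[k]))
  sigma <- estimateSigma(Y, C, kin, fits = fits)
  scans <- lapply(fits, function(f) marginalScan(G, f))
  ids <- scans[[1]]$id
  tMat <- vapply(scans, function(s) s$t, numeric(length(ids)))
  tMat <- matrix(tMat, ncol = K)
  out <- .usatScan(tMat, sigma, ids, grid, conditional)
  tn <- colnames(Y)
  for (k in seq_len(K)) {
    out[[paste0("t_", tn[k])]] <- tMat[, k]
    out[[paste0("p_", tn[k])]] <- scans[[k]]$p
  }
  attr(out, "sigma") <- sigma
  attr(out, "fits") <- fits
  out
}
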