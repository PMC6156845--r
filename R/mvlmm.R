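## Matrix-variate multivariate linear mixed model:
##   Y = X Gamma + Q + E,  Q ~ MVN_{N x K}(0, Phi, Vg),  E ~ MVN(0, I, Ve).
## Rotating rows by U' (Phi = U diag(lambda) U') makes rows independent with
## covariance lambda_i Vg + Ve. EM exploits the simultaneous diagonalization
## T = P' Ve^{-1/2} (with Ve^{-1/2} Vg Ve^{-1/2} = P D P'): in transformed
## coordinates the genetic covariance is diag(D) and the error covariance is
## the identity, so E- and M-steps vectorize over rows and components.

.veFloor <- function(Ve) {
  e <- eigen(Ve, symmetric = TRUE)
  floorVal <- 1e-8 * max(sum(diag(Ve)) / ncol(Ve), 1e-12)
  nFloored <- sum(e$values < floorVal)
  vals <- pmax(e$values, floorVal)
  list(Ve = e$vectors %*% (vals * t(e$vectors)), nFloored = nFloored)
}

#' Fit the K-trait null mixed model by EM
#'
#' Estimates (Vg, Ve) by maximum likelihood with an EM algorithm in the
#' kinship eigenbasis; fixed effects are profiled by generalized least squares
#' each iteration. Iterates until the relative log-likelihood change is below
#' `tol` or `maxIter` iterations (non-convergence returns the best iterate
#' with a warning and `converged = FALSE`). The EM objective (the marginal
#' log-likelihood) is monotone nondecreasing and its trace is stored. A K = 1
#' input delegates to [fitNullReml()].
#'
#' @param Y N x K trait matrix or [PhenotypeSet-class].
#' @param C covariate matrix (ignored for a PhenotypeSet).
#' @param kin a [KinshipMatrix-class].
#' @param maxIter maximum EM iterations (default 500).
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @return A [MvNullFit-class].
#' @export
fitMvNull <- function(Y, C = NULL, kin, maxIter = 500L, tol = 1e-6) {
  if (is(Y, "PhenotypeSet")) {
    C <- if (ncol(covariates(Y))) covariates(Y) else NULL
    Y <- traits(Y)
  }
  Y <- as.matrix(Y)
  N <- nrow(Y); K <- ncol(Y)
  if (K == 1L) {
    uf <- fitNullReml(Y[, 1], C, kin)
    rX <- uf@rotX
    return(new("MvNullFit", Vg = matrix(uf@sigmaG2, 1, 1),
               Ve = matrix(uf@sigmaE2, 1, 1),
               Gamma = matrix(uf@beta, ncol = 1), loglik = uf@loglik,
               loglikTrace = uf@loglik, iterations = 1L, converged = TRUE,
               rotY = matrix(uf@rotY, ncol = 1), rotX = rX,
               lambda = eigenValues(kin), kinship = kin))
  }
  X <- cbind(`(Intercept)` = rep(1, N), C)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- sort(qrX$pivot[seq_len(qrX$rank)])
    if (!1L %in% keep) modelError("covariate matrix is rank deficient")
    warning("dropping aliased covariate column(s)")
    X <- X[, keep, drop = FALSE]
  }
  U <- eigenVectors(kin); lambda <- eigenValues(kin)
  rY <- crossprod(U, Y); rX <- crossprod(U, X)
  p <- ncol(X)

  ## initialize from the OLS residual covariance, split evenly
  G0 <- solve(crossprod(rX), crossprod(rX, rY))
  S0 <- crossprod(rY - rX %*% G0) / N
  Vg <- S0 / 2; Ve <- S0 / 2
  Gamma <- G0
  pos <- lambda > 1e-12
  nPos <- sum(pos)
  llTrace <- numeric(0)
  llPrev <- -Inf
  converged <- FALSE
  vewarn <- 0L
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    fl <- .veFloor(Ve); Ve <- fl$Ve; vewarn <- vewarn + fl$nFloored
    eVe <- eigen(Ve, symmetric = TRUE)
    VeIH <- eVe$vectors %*% ((1 / sqrt(eVe$values)) * t(eVe$vectors))
    VeH <- eVe$vectors %*% (sqrt(eVe$values) * t(eVe$vectors))
    M <- VeIH %*% Vg %*% VeIH
    eM <- eigen((M + t(M)) / 2, symmetric = TRUE)
    D <- pmax(eM$values, 0)
    Tm <- t(eM$vectors) %*% VeIH           # transform: tilde = Tm %*% (K-vector)
    Tinv <- VeH %*% eM$vectors
    Yt <- rY %*% t(Tm)                     # N x K in tilde coordinates

    ## CM step for Gamma (tilde): per-component weighted least squares
    Gt <- matrix(0, p, K)
    vmat <- outer(lambda, D) + 1           # N x K variances
    for (j in seq_len(K)) {
      wj <- 1 / vmat[, j]
      Gt[, j] <- solve(crossprod(rX, rX * wj), crossprod(rX, Yt[, j] * wj))
    }
    Rt <- Yt - rX %*% Gt

    ## marginal log-likelihood at (Vg, Ve, Gamma)
    ll <- -0.5 * (N * K * log(2 * pi) + sum(log(vmat)) + sum(Rt^2 / vmat)) -
      0.5 * N * sum(log(eVe$values))
    llTrace <- c(llTrace, ll)
    if (is.finite(llPrev) && abs(ll - llPrev) / (abs(llPrev) + 1) < tol) {
      converged <- TRUE
      Gamma <- Gt %*% t(Tinv)
      break
    }
    llPrev <- ll

    ## E-step: posterior moments of the rotated random effects (tilde coords)
    Gain <- outer(lambda, D) / vmat                        # lam D / (lam D + 1)
    Mt <- Gain * Rt                                        # posterior means
    Ct <- Gain                                             # posterior variances = lam D/(lam D+1)

    ## M-step: Vg from sum_i E[a_i a_i']/lambda_i over lambda_i > 0;
    ## the posterior-variance term is C_tilde/lambda = D/(lambda D + 1)
    sl <- sqrt(lambda[pos])
    VgT <- crossprod(Mt[pos, , drop = FALSE] / sl) / nPos
    diag(VgT) <- diag(VgT) +
      colSums(matrix(D, nPos, K, byrow = TRUE) / vmat[pos, , drop = FALSE]) / nPos
    VeT <- (crossprod(Rt - Mt) + diag(colSums(Ct), K)) / N
    Vg <- Tinv %*% VgT %*% t(Tinv)
    Ve <- Tinv %*% VeT %*% t(Tinv)
    Vg <- (Vg + t(Vg)) / 2; Ve <- (Ve + t(Ve)) / 2
    Gamma <- Gt %*% t(Tinv)
  }
  if (!converged)
    warning(sprintf("EM did not converge in %d iterations (last rel change %.2g)",
                    maxIter, abs(llTrace[it] - llTrace[it - 1]) /
                      (abs(llTrace[it - 1]) + 1)))
  if (vewarn > 3L)
    warning("Ve eigenvalue floor activated repeatedly; fit may be degenerate")
  dimnames(Vg) <- dimnames(Ve) <- list(colnames(Y), colnames(Y))
  new("MvNullFit", Vg = Vg, Ve = Ve, Gamma = Gamma,
      loglik = llTrace[length(llTrace)], loglikTrace = llTrace,
      iterations = it, converged = converged, rotY = rY, rotX = rX,
      lambda = lambda, kinship = kin)
}

#' K-degree-of-freedom joint test of a SNP across all traits
#'
#' With variance components fixed at the null fit, estimates the K-vector of
#' SNP effects by generalized least squares (jointly with the covariate
#' effects) and forms the Wald statistic beta' cov(beta)^{-1} beta referenced
#' to chi-square with K degrees of freedom.
#'
#' @param g numeric dosage vector (complete, aligned).
#' @param fit a [MvNullFit-class].
#' @param id variant identifier.
#' @return one-row data.frame: `id`, `beta_1..beta_K`, `stat`, `p`.
#' @export
mvTest <- function(g, fit, id = "snp") {
  K <- ncol(fit@Vg)
  rg <- drop(crossprod(eigenVectors(fit@kinship), as.numeric(g)))
  Z <- cbind(fit@rotX, rg)
  q <- ncol(Z)
  fl <- .veFloor(fit@Ve); Ve <- fl$Ve
  eVe <- eigen(Ve, symmetric = TRUE)
  VeIH <- eVe$vectors %*% ((1 / sqrt(eVe$values)) * t(eVe$vectors))
  M <- VeIH %*% fit@Vg %*% VeIH
  eM <- eigen((M + t(M)) / 2, symmetric = TRUE)
  D <- pmax(eM$values, 0)
  Tm <- t(eM$vectors) %*% VeIH
  Tinv <- solve(Tm)
  Yt <- fit@rotY %*% t(Tm)
  vmat <- outer(fit@lambda, D) + 1

  betaT <- numeric(K); varT <- numeric(K)
  for (j in seq_len(K)) {
    wj <- 1 / vmat[, j]
    A <- crossprod(Z, Z * wj)
    Ainv <- tryCatch(solve(A), error = function(e) NULL)
    if (is.null(Ainv) || Ainv[q, q] <= 0) {
      out <- data.frame(id = id, stringsAsFactors = FALSE)
      out[paste0("beta_", seq_len(K))] <- NA_real_
      out$stat <- NA_real_; out$p <- NA_real_
      return(out)
    }
    coefs <- Ainv %*% crossprod(Z, Yt[, j] * wj)
    betaT[j] <- coefs[q]
    varT[j] <- Ainv[q, q]
  }
  ## beta_tilde components are independent (diagonal covariance in tilde
  ## coordinates); map back for reporting
  stat <- sum(betaT^2 / varT)
  beta <- drop(Tinv %*% betaT)
  out <- data.frame(id = id, stringsAsFactors = FALSE)
  out[paste0("beta_", seq_len(K))] <- as.list(beta)
  out$stat <- stat
  out$p <- stats::pchisq(stat, df = K, lower.tail = FALSE)
  out
}

#' Joint mvLMM scan over all variants
#' @param G a [GenotypeMatrix-class] or numeric matrix.
#' @param fit a [MvNullFit-class].
#' @return data.frame, one row per variant (columns as [mvTest()]).
#' @export
mvScan <- function(G, fit) {
  if (is(G, "GenotypeMatrix")) {
    ids <- variants(G)$id; G <- dosages(G)
  } else {
    G <- as.matrix(G)
    ids <- colnames(G) %||% paste0("snp", seq_len(ncol(G)))
  }
  do.call(rbind, lapply(seq_len(ncol(G)), function(j)
    mvTest(G[, j], fit, id = ids[j])))
}
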