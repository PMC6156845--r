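## Internal condition helpers: every user-facing failure carries a class so the
## command-line front end can map it to an exit code (2 usage, 3 data/format,
## 4 numeric).

pusatStop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "pusatError", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

usageError    <- function(fmt, ...) pusatStop("pusatUsageError", fmt, ...)
formatError   <- function(fmt, ...) pusatStop("pusatFormatError", fmt, ...)
dataError     <- function(fmt, ...) pusatStop("pusatDataError", fmt, ...)
configError   <- function(fmt, ...) pusatStop("pusatConfigError", fmt, ...)
modelError    <- function(fmt, ...) pusatStop("pusatModelError", fmt, ...)
numericError  <- function(fmt, ...) pusatStop("pusatNumericError", fmt, ...)
domainError   <- function(fmt, ...) pusatStop("pusatDomainError", fmt, ...)
pedigreeError <- function(fmt, ...) pusatStop("pusatPedigreeError", fmt, ...)

## Symmetric matrix square root with clamping of tiny negative eigenvalues.
matSqrt <- function(V) {
  if (length(V) == 1L) return(matrix(sqrt(max(V, 0)), 1L, 1L))
  e <- eigen(V, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

## Compound-symmetry correlation matrix: unit diagonal, off-diagonal rho.
csMatrix <- function(K, rho) {
  m <- matrix(rho, K, K)
  diag(m) <- 1
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
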