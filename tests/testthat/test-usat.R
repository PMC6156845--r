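test_that("per-weight p-values reduce to their closed-form ends", {
  sv <- randomStatVector(3, seed = 60)
  e <- eigen(sv@sigma, symmetric = TRUE)
  tM <- sum(drop(crossprod(e$vectors, sv@t))^2 / e$values)
  ## w = 1: exact chi-square with K df on the MANOVA quadratic form
  expect_equal(weightedP(sv, 1), pchisq(tM, df = 3, lower.tail = FALSE),
               tolerance = 1e-12)
  ## w = 0: identical to the SSU test
  expect_equal(weightedP(sv, 0), ssuTest(sv)$p, tolerance = 1e-12)
  ## Sigma = I: every weight gives the same p (T_M = T_S)
  svI <- StatVector(c(1.3, -0.4), diag(2))
  pw <- vapply(usatWeights(), function(w) weightedP(svI, w), numeric(1))
  expect_lt(diff(range(pw)), 1e-12)
})

test_that("the min-p statistic, tie-break and opposite-effect argmin behave", {
  sv <- randomStatVector(2, seed = 61)
  u <- usatStatistic(sv)
  expect_equal(u$t_usat, min(u$p_w))
  expect_true(all(u$t_usat <= u$p_w))
  ## Sigma = I: all p_w tie, smallest weight wins
  uI <- usatStatistic(StatVector(c(2.1, 0.3), diag(2)))
  expect_equal(uI$w_opt, 0)
  expect_equal(uI$t_usat, uI$p_w[1])
  ## effects opposing the trait correlation favor the MANOVA end (w = 1)
  sigma <- matrix(c(1, 0.5, 0.5, 1), 2)
  uOpp <- usatStatistic(StatVector(c(2.5, -2.5), sigma))
  expect_equal(uOpp$w_opt, 1)
  expect_equal(uOpp$p_w[12 - 1], min(uOpp$p_w))
})

test_that("integrated p-value is exact when all weighted tests coincide", {
  for (tu in c(0.2, 0.05, 0.01, 0.001))
    expect_equal(pusatPvalue(tu, diag(2)), tu, tolerance = 1e-4)
  ## near-identity correlation: the min-p correction vanishes
  sg <- matrix(c(1, 0.01, 0.01, 1), 2)
  expect_lt(abs(pusatPvalue(0.01, sg) - 0.01), 1e-3)
})

test_that("integrated p-value respects the min-p/Bonferroni sandwich", {
  set.seed(62)
  for (i in 1:60) {
    K <- sample(2:4, 1)
    sigma <- randomCorr(K)
    tu <- runif(1, 1e-4, 0.99)
    pf <- pusatPvalue(tu, sigma)
    expect_gte(pf, tu)
    expect_lte(pf, min(1, 11 * tu))
  }
})

test_that("integrated p-value is monotone in the observed min-p", {
  sigma <- matrix(c(1, 0.6, 0.6, 1), 2)
  tus <- c(1e-4, 1e-3, 0.01, 0.05, 0.1, 0.3, 0.6)
  pf <- vapply(tus, function(t) pusatPvalue(t, sigma), numeric(1))
  expect_true(all(diff(pf) > 0))
})

test_that("integrated p-value agrees with the Monte-Carlo min-p oracle", {
  set.seed(63)
  sigma <- matrix(c(1, 0.5, 0.5, 1), 2)
  mp <- mcMinP(sigma, n = 2e5)
  for (tu in c(0.05, 0.01)) {
    emp <- mean(mp <= tu)
    se <- sqrt(emp * (1 - emp) / length(mp))
    expect_lt(abs(pusatPvalue(tu, sigma) - emp), 3 * se)
  }
})

test_that("null min-p p-values are not anticonservative", {
  ## P(p_final <= x) <= x (+ Monte-Carlo slack): invert the integrated
  ## p-value and compare with the Monte-Carlo law of the min-p statistic
  set.seed(64)
  sigma <- matrix(c(1, 0.5, 0.5, 1), 2)
  mp <- mcMinP(sigma, n = 2e5)
  for (x in c(0.01, 0.05, 0.1)) {
    qx <- uniroot(function(t) pusatPvalue(t, sigma) - x,
                  c(1e-8, x), tol = 1e-12)$root
    reject <- mean(mp <= qx)
    se <- sqrt(x * (1 - x) / length(mp))
    expect_lte(reject, x + 3 * se)
  }
})

test_that("USAT on unrelated samples is exchangeable over sample order", {
  set.seed(65)
  N <- 150
  Y <- matrix(rnorm(2 * N), N, 2)
  C <- cbind(rnorm(N))
  G <- matrix(rbinom(3 * N, 2, 0.3), N, 3)
  r1 <- runUsat(Y, C, G)
  perm <- sample(N)
  r2 <- runUsat(Y[perm, ], C[perm, , drop = FALSE], G[perm, ])
  expect_equal(r1$p_final, r2$p_final, tolerance = 1e-10)
  expect_equal(r1$p_ssu, r2$p_ssu, tolerance = 1e-10)
})

test_that("pUSAT with identity kinship reproduces USAT exactly", {
  set.seed(66)
  N <- 200
  Y <- matrix(rnorm(2 * N), N, 2)
  Y[, 2] <- 0.4 * Y[, 1] + Y[, 2]
  C <- cbind(rnorm(N))
  G <- matrix(rbinom(6 * N, 2, 0.35), N, 6)
  ru <- runUsat(Y, C, G)
  rp <- runPusat(Y, C, G, identityKinship(N))
  for (col in c("p_ssu", "p_mvlmm", "t_usat", "p_final"))
    expect_equal(rp[[col]], ru[[col]], tolerance = 1e-6)
})

test_that("USAT holds its level on unrelated null data", {
  set.seed(67)
  N <- 300
  ps <- unlist(lapply(1:20, function(b) {
    Y <- matrix(rnorm(2 * N), N, 2)
    Y[, 2] <- 0.5 * Y[, 1] + sqrt(0.75) * Y[, 2]
    G <- matrix(rbinom(100 * N, 2, 0.3), N, 100)
    runUsat(Y, G = G)$p_final
  }))
  rate <- mean(ps <= 0.05)
  band <- qnorm(0.995) * sqrt(0.05 * 0.95 / length(ps))
  expect_equal(length(ps), 2000L)
  expect_lt(abs(rate - 0.05), band + 0.006)
})

test_that("flagged variants propagate NA without derailing the scan", {
  set.seed(68)
  N <- 100
  Y <- matrix(rnorm(2 * N), N, 2)
  G <- cbind(rbinom(N, 2, 0.3), rep(1, N), rbinom(N, 2, 0.4))
  r <- runUsat(Y, G = G)
  expect_true(is.na(r$p_final[2]))
  expect_false(anyNA(r$p_final[c(1, 3)]))
})

test_that("degenerate min-p inputs are rejected or repaired", {
  expect_error(pusatPvalue(1.5, diag(2)), class = "pusatDomainError")
  expect_warning(p0 <- pusatPvalue(0, diag(2)), "underflow")
  expect_gt(p0, 0)
  expect_error(pusatPvalue(0.05, matrix(c(1, 1, 1, 1), 2)),
               class = "pusatDomainError")
  expect_error(usatStatistic(randomStatVector(2, seed = 69),
                             grid = c(0.1, 0.5, 1)),
               class = "pusatConfigError")
})
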