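test_that("the kernel reduces as documented at the rho extremes", {
  ks <- kernelStudy()
  gm <- panelGenotypes(ks$st$panel)
  w <- genotypeWindow(gm, IRanges::IRanges(1, 10))
  Gw <- w@G %*% diag(mafWeights(w))
  kp1 <- buildKernel(Gw, ks$e, 1)
  expect_equal(kernelMatrix(kp1), tcrossprod(Gw), tolerance = 1e-12)
  kp0 <- buildKernel(Gw, rep(0, nrow(Gw)), 0)
  expect_equal(max(abs(kernelMatrix(kp0))), 0)
  expect_error(buildKernel(Gw, ks$e, 1.2), "rho")
})

test_that("a 3 x 1 kernel at rho = 0.5 matches hand arithmetic", {
  Gw <- matrix(c(0, 1, 2), 3, 1)
  e <- c(1, 0, 1)
  K <- kernelMatrix(buildKernel(Gw, e, 0.5))
  # K = 0.5 g g' + 0.5 (e*g)(e*g)' with g = (0,1,2), e*g = (0,0,2)
  g <- c(0, 1, 2); eg <- c(0, 0, 2)
  expect_equal(K, 0.5 * g %o% g + 0.5 * eg %o% eg, tolerance = 1e-14)
})

test_that("the residual-form Q equals the doubly projected form and the
           low-rank eigenvalues match the dense n x n path", {
  set.seed(61)
  for (i in 1:6) {
    n <- 20; p <- 5; m <- 4
    ped <- simPedigrees(3, seed = 60 + i)
    R <- relationshipMatrix(kinshipMatrix(ped))[1:n, 1:n]
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
    y <- rnorm(n)
    fit <- fitNull(y, X, R)
    Gw <- matrix(rbinom(n * m, 2, 0.2), n) %*% diag(runif(m, 0.5, 2))
    e <- rbinom(n, 1, 0.4)
    rho <- runif(1)
    kp <- buildKernel(Gw, e, rho)
    st <- scoreStatistic(fit, kp)
    oracle <- denseScore(y, X, R, fit@sigmaB2, fit@sigmaE2,
                         kernelMatrix(kp))
    expect_equal(st$Q, oracle$Qres, tolerance = 1e-8)
    expect_equal(oracle$Qres, oracle$Qproj, tolerance = 1e-8)
    expect_equal(sort(st$lambdas), sort(oracle$lambdas), tolerance = 1e-7)
    expect_equal(sum(st$lambdas), oracle$trace, tolerance = 1e-8)
  }
})

test_that("a zero kernel yields Q = 0 and p = 1", {
  ks <- kernelStudy()
  n <- length(ks$fit@y)
  kp <- buildKernel(matrix(0, n, 2), ks$e, 0.5)
  st <- scoreStatistic(ks$fit, kp)
  expect_equal(st$Q, 0)
  expect_length(st$lambdas, 0)
  expect_equal(pvalueMixture(st$Q, st$lambdas)$p, 1)
})

test_that("the rho grid test returns 11 p-values whose rho = 1 entry is the
           plain family-SKAT p-value, independent of the environment", {
  ks <- kernelStudy()
  gm <- panelGenotypes(ks$st$panel)
  w <- genotypeWindow(gm, IRanges::IRanges(1, 20))
  wt <- mafWeights(w)
  res <- testWindow(ks$fit, w, wt, ks$e)
  expect_length(pPerRho(res), 11L)
  expect_equal(res@rhoGrid, seq(0, 1, 0.1))
  # rho = 1 path must not depend on E: scramble the environment
  set.seed(77)
  res2 <- testWindow(ks$fit, w, wt, sample(ks$e))
  expect_equal(pFFBSKAT(res2), pFFBSKAT(res), tolerance = 1e-10)
  # and equals an independently built plain kernel p-value
  Gw <- recodeGenotypes(w@G, "additive") %*% diag(wt)
  st <- scoreStatistic(ks$fit, buildKernel(Gw, ks$e, 1))
  expect_equal(unname(pFFBSKAT(res)),
               pvalueMixture(st$Q, st$lambdas, method = "kuonen")$p,
               tolerance = 1e-10)
  expect_equal(res@pAdjusted, min(1, 2 * res@pMin))
  expect_gte(res@pAdjusted, res@pMin)
})

test_that("p-values are invariant to positive rescaling of the weights", {
  ks <- kernelStudy()
  gm <- panelGenotypes(ks$st$panel)
  w <- genotypeWindow(gm, IRanges::IRanges(6, 15))
  wt <- mafWeights(w)
  r1 <- testWindow(ks$fit, w, wt, ks$e)
  r2 <- testWindow(ks$fit, w, 2 * wt, ks$e)
  expect_equal(pPerRho(r2), pPerRho(r1), tolerance = 1e-9)
  expect_equal(r2@Q, 4 * r1@Q, tolerance = 1e-9)   # Q and lambda co-scale
})

test_that("a constant environment degrades gracefully", {
  ks <- kernelStudy()
  gm <- panelGenotypes(ks$st$panel)
  w <- genotypeWindow(gm, IRanges::IRanges(1, 10))
  wt <- mafWeights(w)
  e0 <- rep(0, length(ks$e))
  res <- testWindow(ks$fit, w, wt, e0)
  # K2 = 0: every rho < 1 tests a scaled genetic kernel, so p is constant
  # on (0, 1]; rho = 0 is the degenerate zero kernel
  ps <- pPerRho(res)
  expect_equal(unname(ps[1]), 1)
  expect_equal(res@flags[1], "degenerate")
  expect_lt(max(abs(ps[-1] - ps[2])), 1e-9)
})

test_that("an all-monomorphic window is flagged with p = 1, not an error", {
  ks <- kernelStudy()
  n <- length(ks$fit@y)
  wMono <- new("GenotypeWindow", G = matrix(0, n, 3),
               variantIds = paste0("m", 1:3), pos = 1:3 * 10L,
               chrom = rep("1", 3), maf = rep(0, 3))
  res <- testWindow(ks$fit, wMono, mafWeights(wMono), ks$e)
  expect_true(all(res@flags == "degenerate"))
  expect_equal(res@pAdjusted, 1)
})

test_that("null p-values are uniform for every rho (KS check)", {
  ks <- kernelStudy()
  fit <- ks$fit
  gm <- panelGenotypes(ks$st$panel)
  w <- genotypeWindow(gm, IRanges::IRanges(1, 15))
  Gw <- recodeGenotypes(w@G, "additive") %*% diag(mafWeights(w))
  n <- length(fit@y)
  v <- fit@sigmaB2 * fit@d + fit@sigmaE2
  nrep <- 2000
  set.seed(91)
  Z <- matrix(rnorm(n * nrep), n)
  Y <- drop(fit@X %*% fit@alpha) + fit@U %*% (sqrt(v) * Z)
  Xt <- crossprod(fit@U, fit@X)
  M <- crossprod(Xt, Xt / v)
  for (rho in c(0, 0.5, 1)) {
    kp <- buildKernel(Gw, ks$e, rho)
    st <- scoreStatistic(fit, kp)   # lambdas fixed under the null fit
    B <- kp@B
    Bt <- crossprod(fit@U, B)
    # A'y* with A = P'V^-1 B, computed in the rotated basis
    C <- crossprod(Bt / v, Xt)
    Yt <- crossprod(fit@U, Y)
    Tm <- crossprod(Bt / v, Yt) - C %*% solve(M, crossprod(Xt / v, Yt))
    Qs <- 0.5 * colSums(Tm^2)
    ps <- vapply(Qs, function(q)
      pvalueMixture(q, st$lambdas, method = "kuonen")$p, 0)
    expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  }
})
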