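randomInstance <- function(n, p, seed) {
  set.seed(seed)
  ped <- simPedigrees(ceiling(n / 8), seed = seed)
  while (length(ped@id) < n)
    ped <- simPedigrees(ceiling(n / 4), seed = (seed <- seed + 1))
  R <- relationshipMatrix(kinshipMatrix(ped))[1:n, 1:n]
  diag(R) <- diag(R) + 0.01   # keep V well conditioned at small sigmaE2
  X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
  y <- rnorm(n, sd = 2)
  list(y = y, X = X, R = R)
}

test_that("spectral restricted log-likelihood equals the dense evaluation", {
  for (s in 1:8) {
    inst <- randomInstance(8, 3, 100 + s)
    th <- c(runif(1, 0.2, 3), runif(1, 0.5, 3))
    expect_equal(restrictedLoglik(th, inst$y, inst$X, inst$R),
                 denseREML(th[1], th[2], inst$y, inst$X, inst$R),
                 tolerance = 1e-10)
    expect_equal(restrictedLoglik(th, inst$y, inst$X, inst$R, reml = FALSE),
                 denseREML(th[1], th[2], inst$y, inst$X, inst$R,
                           reml = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("larger random instances agree with the dense formula", {
  for (n in c(20, 50)) {
    inst <- randomInstance(n, 3, n)
    th <- c(1.3, 0.7)
    expect_equal(restrictedLoglik(th, inst$y, inst$X, inst$R),
                 denseREML(th[1], th[2], inst$y, inst$X, inst$R),
                 tolerance = 1e-8)
  }
})

test_that("zero residuals kill the quadratic term", {
  n <- 10
  set.seed(3)
  R <- diag(n)
  X <- cbind(1, rnorm(n))
  y <- drop(X %*% c(2, -1))     # exactly in the column span
  th <- c(0.5, 1.5)
  # l should equal the no-residual value: -0.5 ln|V| - 0.5 ln|X'V^-1 X|
  V <- th[1] * R + th[2] * diag(n)
  Vi <- solve(V)
  expected <- -0.5 * determinant(V)$modulus -
    0.5 * determinant(t(X) %*% Vi %*% X)$modulus
  expect_equal(restrictedLoglik(th, y, X, R), as.numeric(expected),
               tolerance = 1e-10)
})

test_that("GLS coefficients match the dense formula and OLS at V = I", {
  set.seed(5)
  n <- 10
  X <- cbind(1, rnorm(n), rnorm(n))
  y <- rnorm(n)
  ols <- drop(solve(crossprod(X), crossprod(X, y)))
  expect_equal(unname(glsAlpha(c(0.4, 0.6), y, X, diag(n))), ols,
               tolerance = 1e-10)   # V propto I
  inst <- randomInstance(10, 3, 55)
  expect_equal(unname(glsAlpha(c(1.1, 0.9), inst$y, inst$X, inst$R)),
               denseGLS(1.1, 0.9, inst$y, inst$X, inst$R),
               tolerance = 1e-10)
  # duplicate covariate column is a singularity error
  Xd <- cbind(X, X[, 2])
  expect_error(glsAlpha(c(1, 1), y, Xd, diag(n)), "singular")
  expect_error(fitNull(y, Xd, diag(n)), "singular")
})

test_that("REML recovers variance components on a sibship design", {
  # 40 sibships of size 4, true (sigmaB2, sigmaE2) = (4, 6); a quick
  # low-replicate version of the full parameter-recovery study
  nf <- 40; fs <- 4; n <- nf * fs
  Rblock <- matrix(0.5, fs, fs); diag(Rblock) <- 1
  R <- kronecker(diag(nf), Rblock)
  cb <- chol(Rblock)
  X <- cbind(rep(1, n))
  est <- matrix(0, 150, 2)
  set.seed(17)
  for (r in seq_len(nrow(est))) {
    b <- as.vector(t(cb) %*% matrix(rnorm(n), fs)) * 2
    y <- 3 + b + rnorm(n, sd = sqrt(6))
    fit <- fitNull(y, X, R)
    est[r, ] <- varComponents(fit)
  }
  expect_equal(mean(est[, 1]), 4, tolerance = 0.15)
  expect_equal(mean(est[, 2]), 6, tolerance = 0.15)
})

test_that("permuting phenotypes drives the family component to zero", {
  st <- makeStudy(nFamilies = 5, m = 5, seed = 31)
  n <- nrow(st$R)
  cR <- chol(st$R + 1e-8 * diag(n))
  X <- cbind(rep(1, n))
  set.seed(8)
  ratio <- replicate(20, {
    y <- 2 + drop(t(cR) %*% rnorm(n)) * 2 + rnorm(n, sd = 1)
    yp <- sample(y)
    vc <- varComponents(fitNull(yp, X, st$R))
    vc[1] / vc[2]
  })
  expect_lt(median(ratio), 0.1)
})

test_that("the fit is invariant to sample reordering", {
  inst <- randomInstance(12, 2, 77)
  fit <- fitNull(inst$y, inst$X, inst$R)
  set.seed(9)
  pm <- sample(12)
  fit2 <- fitNull(inst$y[pm], inst$X[pm, ], inst$R[pm, pm])
  expect_equal(varComponents(fit2), varComponents(fit), tolerance = 1e-8)
  expect_equal(fixedEffects(fit2), fixedEffects(fit), tolerance = 1e-8)
  expect_equal(fit2@loglik, fit@loglik, tolerance = 1e-8)
})

test_that("profiled sigmaE2 maximises the likelihood at fixed gamma", {
  inst <- randomInstance(15, 2, 88)
  rot <- fgeskat:::.rotate(inst$y, inst$X, inst$R)
  n <- length(inst$y); p <- ncol(inst$X)
  for (gamma in c(0.3, 1, 4)) {
    prof <- fgeskat:::.profileGamma(gamma, rot$yt, rot$Xt, rot$d, n, p)
    base <- restrictedLoglik(c(gamma, 1) * prof$se2, inst$y, inst$X, inst$R)
    for (eps in c(-0.05, 0.05)) {
      other <- restrictedLoglik(c(gamma, 1) * prof$se2 * (1 + eps),
                                inst$y, inst$X, inst$R)
      expect_lt(other, base + 1e-10)
    }
  }
})

test_that("unstructured R yields a warned boundary fit, and the gradient
           vanishes at an interior optimum", {
  set.seed(12)
  y <- rnorm(30); X <- cbind(rep(1, 30))
  expect_warning(fit <- fitNull(y, X, diag(30)), "identified only in sum")
  expect_equal(fit@sigmaB2, 0)
  expect_equal(unname(fixedEffects(fit)), mean(y), tolerance = 1e-10)

  st <- makeStudy(nFamilies = 4, m = 5, seed = 41)
  n <- nrow(st$R)
  cR <- chol(st$R + 1e-8 * diag(n))
  set.seed(13)
  y2 <- drop(t(cR) %*% rnorm(n)) * 2 + rnorm(n, sd = 2)
  X2 <- cbind(rep(1, n))
  fit2 <- fitNull(y2, X2, st$R)
  if (fit2@sigmaB2 > 1e-6) {
    vc <- varComponents(fit2)
    h <- 1e-5
    for (k in 1:2) {
      up <- vc; up[k] <- up[k] * (1 + h)
      dn <- vc; dn[k] <- dn[k] * (1 - h)
      grad <- (restrictedLoglik(up, y2, X2, st$R) -
               restrictedLoglik(dn, y2, X2, st$R)) / (2 * vc[k] * h)
      expect_lt(abs(grad), 1e-3)
    }
  }
})

test_that("fits serialise to JSON with components and sample order", {
  inst <- randomInstance(10, 2, 91)
  fit <- fitNull(inst$y, inst$X, inst$R, ids = paste0("S", 1:10))
  f <- withr::local_tempfile(fileext = ".json")
  writeNullModel(fit, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$sigmaE2, fit@sigmaE2, tolerance = 1e-12)
  expect_equal(unlist(back$ids), fit@ids)
})
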