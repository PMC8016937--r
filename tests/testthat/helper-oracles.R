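# Independent brute-force oracles used across tests.

# Dense evaluation of the restricted log-likelihood straight from its
# printed form: l = -0.5 ln|V| - 0.5 ln|X'V^-1 X| - 0.5 r' V^-1 r with
# alpha the GLS solution, everything via explicit inverses.
denseREML <- function(sigmaB2, sigmaE2, y, X, R, reml = TRUE) {
  V <- sigmaB2 * R + sigmaE2 * diag(nrow(R))
  Vi <- solve(V)
  M <- t(X) %*% Vi %*% X
  alpha <- solve(M, t(X) %*% Vi %*% y)
  r <- y - X %*% alpha
  ll <- -0.5 * determinant(V)$modulus - 0.5 * t(r) %*% Vi %*% r
  if (reml) ll <- ll - 0.5 * determinant(M)$modulus
  as.numeric(ll)
}

denseGLS <- function(sigmaB2, sigmaE2, y, X, R) {
  V <- sigmaB2 * R + sigmaE2 * diag(nrow(R))
  Vi <- solve(V)
  drop(solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y))
}

# Dense score statistic in both printed forms, plus the full n x n
# eigenvalue problem.
denseScore <- function(y, X, R, sigmaB2, sigmaE2, K) {
  n <- nrow(R)
  V <- sigmaB2 * R + sigmaE2 * diag(n)
  Vi <- solve(V)
  alpha <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- drop(y - X %*% alpha)
  P <- diag(n) - X %*% solve(t(X) %*% Vi %*% X, t(X) %*% Vi)
  Qres <- 0.5 * drop(t(r) %*% Vi %*% K %*% Vi %*% r)
  Qproj <- 0.5 * drop(t(y) %*% t(P) %*% Vi %*% P %*% K %*% t(P) %*% Vi %*%
                        P %*% y)
  es <- eigen(V, symmetric = TRUE)
  Vmh <- es$vectors %*% diag(1 / sqrt(es$values)) %*% t(es$vectors)
  lam <- eigen(0.5 * Vmh %*% P %*% K %*% t(P) %*% Vmh,
               symmetric = TRUE, only.values = TRUE)$values
  list(Qres = Qres, Qproj = Qproj,
       lambdas = lam[lam > 1e-10 * max(lam)],
       trace = 0.5 * sum(diag(Vi %*% P %*% K %*% t(P))))
}

# Monte-Carlo kinship by dropping founder-labelled alleles through the
# pedigree: phi_ij is the probability that a random allele of i is identical
# by descent to a random allele of j.
mcKinship <- function(ped, nDrops = 50000L, seed = 99L) {
  set.seed(seed)
  n <- length(ped@id)
  key <- paste(ped@fid, ped@id, sep = "\r")
  idx <- stats::setNames(seq_len(n), key)
  fa <- unname(idx[ifelse(is.na(ped@father), NA,
                          paste(ped@fid, ped@father, sep = "\r"))])
  mo <- unname(idx[ifelse(is.na(ped@mother), NA,
                          paste(ped@fid, ped@mother, sep = "\r"))])
  ord <- fgeskat:::.pedOrder(ped)
  # vectorised across drops: one row per individual, one column per drop,
  # founder alleles labelled uniquely within each drop
  A1 <- matrix(0L, n, nDrops); A2 <- matrix(0L, n, nDrops)
  lab <- 0L
  for (i in ord) {
    if (is.na(fa[i])) { lab <- lab + 1L; A1[i, ] <- lab }
    else {
      pick <- runif(nDrops) < 0.5
      A1[i, ] <- ifelse(pick, A1[fa[i], ], A2[fa[i], ])
    }
    if (is.na(mo[i])) { lab <- lab + 1L; A2[i, ] <- lab }
    else {
      pick <- runif(nDrops) < 0.5
      A2[i, ] <- ifelse(pick, A1[mo[i], ], A2[mo[i], ])
    }
  }
  acc <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    acc[i, j] <- mean((A1[i, ] == A1[j, ]) + (A1[i, ] == A2[j, ]) +
                      (A2[i, ] == A1[j, ]) + (A2[i, ] == A2[j, ])) / 4
  }
  acc
}

# A small random pedigree (<= 12 members): founder couple, children,
# possibly one grandchild sibship via a married-in founder.
smallRandomPedigree <- function(seed) {
  set.seed(seed)
  fid <- "F"; id <- c("p1", "p2"); fa <- c(NA, NA); mo <- c(NA, NA)
  sex <- c(1L, 2L)
  nk <- sample(2:4, 1)
  for (k in seq_len(nk)) {
    id <- c(id, paste0("c", k)); fa <- c(fa, "p1"); mo <- c(mo, "p2")
    sex <- c(sex, sample(1:2, 1))
  }
  if (runif(1) < 0.7) {
    id <- c(id, "sp"); fa <- c(fa, NA); mo <- c(mo, NA); sex <- c(sex, 2L)
    ng <- sample(1:3, 1)
    for (g in seq_len(ng)) {
      id <- c(id, paste0("g", g)); fa <- c(fa, "c1"); mo <- c(mo, "sp")
      sex <- c(sex, sample(1:2, 1))
    }
  }
  Pedigree(rep(fid, length(id)), id, fa, mo, sex)
}

# Shared small simulated study used by several test files.
makeStudy <- function(nFamilies = 6L, m = 50L, seed = 11L,
                      ldBlocks = if (m >= 40L) list(11:40) else list()) {
  ped <- simPedigrees(nFamilies, seed = seed)
  set.seed(seed + 1L)
  panel <- geneDrop(ped, mafs = runif(m, 0.05, 0.4), ldBlocks = ldBlocks,
                    seed = seed + 2L)
  R <- relationshipMatrix(kinshipMatrix(ped))
  list(ped = ped, panel = panel, R = R)
}

# Shared small fitted study for kernel tests.
kernelStudy <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      st <- makeStudy(nFamilies = 4, m = 25, seed = 51)
      n <- nrow(st$R)
      set.seed(52)
      e <- rbinom(n, 1, 0.3)
      y <- 120 + 2 * e + drop(chol(st$R + 1e-8 * diag(n)) %*% rnorm(n)) * 3 +
        rnorm(n, sd = 4)
      X <- cbind(1, env = e)
      fit <- fitNull(y, X, st$R)
      cache <<- list(st = st, fit = fit, e = e, X = X, y = y)
    }
    cache
  }
})

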