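# Combined gene + gene-environment kernels, score statistics, rho-grid test.

#' Build the combined kernel at one rho
#'
#' K = rho G W W G' + (1 - rho) E G W W G' E, held as its low-rank factor
#' B = [sqrt(rho) GW, sqrt(1-rho) diag(e) GW] with K = B B'.  At rho = 1 the
#' kernel is the plain weighted linear (family-SKAT) kernel and is
#' independent of the environment; at rho = 0 only the interaction term
#' remains.
#'
#' @param Gw n x m weighted (and recoded, imputed) genotype block, columns
#'   G W.
#' @param e environment values (diagonal of E), aligned to rows of `Gw`;
#'   entered as given (not centred) — the environment main effect must be in
#'   the null-model covariates.
#' @param rho mixing weight in [0, 1].
#' @return a [KernelPair-class].
#' @export
buildKernel <- function(Gw, e, rho) {
  Gw <- as.matrix(Gw)
  if (length(e) != nrow(Gw)) stop("environment length must match samples")
  if (anyNA(e)) stop("environment values must be complete")
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]")
  B <- if (rho == 1) Gw
       else if (rho == 0) e * Gw
       else cbind(sqrt(rho) * Gw, sqrt(1 - rho) * (e * Gw))
  new("KernelPair", rho = rho, B = B, e = as.numeric(e))
}

setValidity("KernelPair", function(object) {
  if (object@rho < 0 || object@rho > 1) return("rho must lie in [0, 1]")
  if (length(object@e) != nrow(object@B)) return("e misaligned with B")
  TRUE
})

setMethod("show", "KernelPair", function(object) {
  cat(sprintf("KernelPair: rho = %.2f, n = %d, rank <= %d\n",
              object@rho, nrow(object@B), ncol(object@B)))
})

#' Materialise the n x n kernel matrix
#'
#' @param kp a [KernelPair-class].
#' @return dense K = B B'.
#' @export
kernelMatrix <- function(kp) tcrossprod(kp@B)

#' Kernel score statistic and its null eigenvalues
#'
#' Q = 1/2 (y - X alpha)' V^{-1} K V^{-1} (y - X alpha) evaluated at the
#' null-model estimates, which (for GLS alpha-hat) equals the doubly
#' projected form 1/2 y' P' V^{-1} P K P' V^{-1} P y with
#' P = I - X (X'V^{-1}X)^{-1} X'V^{-1}.  The null distribution of Q is
#' sum_i lambda_i chi^2_1 with lambda the nonzero eigenvalues of
#' 1/2 V^{-1/2} P K P' V^{-1/2}, computed here from the r x r Gram matrix of
#' V^{-1/2} P B (r <= 2m), never the n x n form.
#'
#' @param fit a [NullModelFit-class].
#' @param kp a [KernelPair-class] on the same sample order.
#' @return list with `Q` and `lambdas` (eigenvalues below
#'   `1e-10 * max(lambda)` dropped).
#' @export
scoreStatistic <- function(fit, kp) {
  B <- kp@B
  if (nrow(B) != length(fit@y)) stop("dimension mismatch between fit and kernel")
  v <- fit@sigmaB2 * fit@d + fit@sigmaE2
  Bt <- crossprod(fit@U, B)                      # rotated factor
  rt <- crossprod(fit@U, fit@residuals)
  Q <- 0.5 * sum((crossprod(Bt, rt / v))^2)
  Xt <- crossprod(fit@U, fit@X)
  WB <- Bt / v
  S <- crossprod(Bt, WB)
  C <- crossprod(WB, Xt)                         # B' V^{-1} X
  M <- crossprod(Xt, Xt / v)
  S <- S - C %*% solve(M, t(C))
  lam <- eigen(0.25 * (S + t(S)), symmetric = TRUE,
               only.values = TRUE)$values
  lam <- lam[lam > 1e-10 * max(lam, 0)]
  list(Q = Q, lambdas = lam)
}

#' rho-grid score test of one genotype window
#'
#' Recodes the window under the requested disease model, applies the
#' variant weights, and for each rho on the grid computes the score
#' statistic of the combined kernel and its chi-square-mixture p-value.
#' The final p-value is `min(1, adjust * min_rho p(rho))`; the default
#' adjust = 2 accounts for the two joint tests (gene, gene-environment) and
#' is deliberately not scaled by the number of grid points.  The rho = 1
#' entry is the plain family-SKAT (FFBSKAT) p-value for the window.
#'
#' @param fit a [NullModelFit-class].
#' @param window a [GenotypeWindow-class] aligned to the fit's samples.
#' @param weights per-variant weights (e.g. [mafWeights()]); recycled
#'   checks apply.
#' @param e environment values (diagonal of E).
#' @param rhoGrid rho values; default `seq(0, 1, by = 0.1)` (11 values).
#' @param model disease model for recoding.
#' @param method p-value route, see [pvalueMixture()]; scans default to the
#'   saddlepoint.
#' @param adjust multiplier applied to the grid minimum.
#' @return a [ScoreTestResult-class].
#' @export
testWindow <- function(fit, window, weights, e,
                       rhoGrid = seq(0, 1, by = 0.1),
                       model = c("additive", "dominant", "recessive"),
                       method = "kuonen", adjust = 2) {
  model <- match.arg(model)
  G <- recodeGenotypes(window@G, model)
  m <- ncol(G)
  if (length(weights) != m) stop("weights length must match variant count")
  Gw <- G %*% diag(weights, nrow = m)
  n <- nrow(Gw)
  if (n != length(fit@y)) stop("window misaligned with null fit")
  polymorphic <- apply(Gw, 2L, function(col) diff(range(col)) > 0)
  degenerate <- !any(polymorphic)
  nrho <- length(rhoGrid)
  Qs <- numeric(nrho); ps <- numeric(nrho)
  lams <- vector("list", nrho); flags <- character(nrho)
  for (i in seq_len(nrho)) {
    kp <- buildKernel(Gw, e, rhoGrid[i])
    st <- scoreStatistic(fit, kp)
    Qs[i] <- st$Q; lams[[i]] <- st$lambdas
    pv <- pvalueMixture(st$Q, st$lambdas, method = method)
    ps[i] <- pv$p
    flags[i] <- if (degenerate || !length(st$lambdas)) "degenerate" else pv$flag
  }
  imin <- which.min(ps)
  new("ScoreTestResult", rhoGrid = rhoGrid, Q = Qs, lambdas = lams,
      pPerRho = ps, rhoMin = rhoGrid[imin], pMin = ps[imin],
      pAdjusted = min(1, adjust * ps[imin]), flags = flags)
}

setValidity("ScoreTestResult", function(object) {
  k <- length(object@rhoGrid)
  if (length(object@Q) != k || length(object@pPerRho) != k ||
      length(object@lambdas) != k || length(object@flags) != k)
    return("per-rho slots must match the grid length")
  if (any(object@Q < -1e-12)) return("Q must be nonnegative")
  if (any(object@pPerRho <= 0 | object@pPerRho > 1))
    return("p-values must lie in (0, 1]")
  if (object@pAdjusted < object@pMin - 1e-15)
    return("pAdjusted must be >= pMin")
  TRUE
})

setMethod("show", "ScoreTestResult", function(object) {
  cat(sprintf(
    "ScoreTestResult: %d rho values; min p = %.3g at rho = %.2f; adjusted p = %.3g\n",
    length(object@rhoGrid), object@pMin, object@rhoMin, object@pAdjusted))
})

#' Per-rho p-values and the adjusted p-value
#'
#' @param x a [ScoreTestResult-class].
#' @return `pPerRho()` named numeric (names = rho); `pAdjusted()` scalar;
#'   `pFFBSKAT()` the rho = 1 entry (plain family-SKAT p-value).
#' @export
pPerRho <- function(x) setNames(x@pPerRho, format(x@rhoGrid))

#' @rdname pPerRho
#' @export
pAdjusted <- function(x) x@pAdjusted

#' @rdname pPerRho
#' @export
pFFBSKAT <- function(x) {
  i <- which(abs(x@rhoGrid - 1) < 1e-12)
  if (!length(i)) stop("rho = 1 is not on the grid")
  x@pPerRho[i]
}
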