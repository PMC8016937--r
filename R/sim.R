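# Gene-drop simulation, G x E phenotype scenarios, permutation type-I-error
# and power studies.

#' Simulate a multi-generation pedigree cohort
#'
#' Three-generation families: one founding couple, their children, married-in
#' spouses (founders) and grandchildren.  With the defaults, 20 families give
#' roughly 650-850 individuals — a GAW-like cohort of large pedigrees.
#'
#' @param nFamilies number of families (default 20).
#' @param childRange inclusive range of children per founding couple.
#' @param grandchildRange inclusive range of children per second-generation
#'   couple.
#' @param marryProb probability that a second-generation child has a family.
#' @param seed RNG seed.
#' @return a [Pedigree-class].
#' @export
simPedigrees <- function(nFamilies = 20L, childRange = c(4L, 8L),
                         grandchildRange = c(3L, 6L), marryProb = 0.9,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fid <- id <- fa <- mo <- character(0)
  sex <- integer(0)
  for (f in seq_len(nFamilies)) {
    fam <- paste0("F", f)
    cnt <- 0L
    nid <- function() { cnt <<- cnt + 1L; paste0(fam, "_", cnt) }
    add <- function(i, s, fat = NA, mot = NA) {
      fid <<- c(fid, fam); id <<- c(id, i); sex <<- c(sex, s)
      fa <<- c(fa, fat); mo <<- c(mo, mot)
    }
    gf <- nid(); add(gf, 1L)
    gm <- nid(); add(gm, 2L)
    for (k in seq_len(sample(childRange[1L]:childRange[2L], 1L))) {
      child <- nid()
      csex <- sample(1:2, 1L)
      add(child, csex, gf, gm)
      if (runif(1) < marryProb) {
        sp <- nid(); add(sp, 3L - csex)
        for (g in seq_len(sample(grandchildRange[1L]:grandchildRange[2L], 1L))) {
          gc <- nid()
          add(gc, sample(1:2, 1L),
              if (csex == 1L) child else sp,
              if (csex == 1L) sp else child)
        }
      }
    }
  }
  Pedigree(fid, id, fa, mo, sex)
}

#' Gene-drop genotypes through a pedigree
#'
#' Founder haplotypes are drawn per variant from the given allele
#' frequencies — or, inside an LD block, from a finite pool of correlated
#' founder haplotypes (default pool size 32), which induces linkage
#' disequilibrium whose realised r-squared is a property of the draw, not a
#' target.  Children inherit one untransformed haplotype per parent: one
#' random pick per independent variant, one pick per LD block (no
#' recombination within a block).  A missing parent contributes a population
#' gamete.  Genotypes are Mendelian-consistent by construction (see
#' [mendelianCheck()]).
#'
#' @param ped a [Pedigree-class].
#' @param mafs per-variant founder allele frequencies in (0, 0.5].
#' @param ldBlocks optional list of integer index vectors; variants inside a
#'   block are drawn from a shared haplotype pool and co-transmitted.
#' @param poolSize founder-haplotype pool size per LD block (default 32).
#' @param seed RNG seed.
#' @return a [SimPanel-class].
#' @export
geneDrop <- function(ped, mafs, ldBlocks = NULL, poolSize = 32L, seed = NULL) {
  stopifnot(is(ped, "Pedigree"))
  n <- length(ped@id)
  if (n == 0L) stop("empty pedigree")
  if (any(mafs <= 0 | mafs > 0.5)) stop("mafs must lie in (0, 0.5]")
  if (!is.null(seed)) set.seed(seed)
  m <- length(mafs)
  if (is.null(ldBlocks)) ldBlocks <- list()
  if (length(ldBlocks) && !all(unlist(ldBlocks) %in% seq_len(m)))
    stop("ldBlocks indices must lie in 1..", m)
  inBlock <- rep(0L, m)
  for (b in seq_along(ldBlocks)) inBlock[ldBlocks[[b]]] <- b
  indep <- which(inBlock == 0L)
  # pool haplotypes carry the exact (rounded) allele count per variant so a
  # designated MAF is realised faithfully even in a small pool
  pools <- lapply(ldBlocks, function(ix) {
    pool <- matrix(0L, poolSize, length(ix))
    for (jj in seq_along(ix)) {
      k <- max(1L, min(poolSize - 1L, round(mafs[ix[jj]] * poolSize)))
      pool[sample.int(poolSize, k), jj] <- 1L
    }
    pool
  })
  key <- .pedKeys(ped)
  idx <- setNames(seq_len(n), key)
  fa <- unname(idx[ifelse(is.na(ped@father), NA,
                          paste(ped@fid, ped@father, sep = "\r"))])
  mo <- unname(idx[ifelse(is.na(ped@mother), NA,
                          paste(ped@fid, ped@mother, sep = "\r"))])
  # founder gametes draw pool rows in balanced (stratified) fashion so the
  # founding generation realises the pool frequencies without sampling drift
  nGam <- sum(is.na(fa)) + sum(is.na(mo))
  rowQueue <- lapply(seq_along(ldBlocks), function(b)
    sample(rep_len(seq_len(poolSize), nGam)))
  gamCount <- 0L
  drawHap <- function() {
    gamCount <<- gamCount + 1L
    h <- integer(m)
    if (length(indep)) h[indep] <- rbinom(length(indep), 1L, mafs[indep])
    for (b in seq_along(ldBlocks))
      h[ldBlocks[[b]]] <- pools[[b]][rowQueue[[b]][gamCount], ]
    h
  }
  H1 <- matrix(0L, n, m); H2 <- matrix(0L, n, m)
  gamete <- function(p) {
    if (is.na(p)) return(drawHap())
    pick <- integer(m)
    if (length(indep)) pick[indep] <- rbinom(length(indep), 1L, 0.5)
    for (b in seq_along(ldBlocks))
      pick[ldBlocks[[b]]] <- rbinom(1L, 1L, 0.5)
    ifelse(pick == 0L, H1[p, ], H2[p, ])
  }
  for (i in .pedOrder(ped)) {
    if (is.na(fa[i]) && is.na(mo[i])) {
      H1[i, ] <- drawHap(); H2[i, ] <- drawHap()
    } else {
      H1[i, ] <- gamete(fa[i])
      H2[i, ] <- gamete(mo[i])
    }
  }
  G <- H1 + H2
  rownames(G) <- pedIds(ped)
  colnames(G) <- paste0("v", seq_len(m))
  new("SimPanel", ped = ped, G = G, H1 = H1, H2 = H2, mafs = mafs,
      ldBlocks = ldBlocks)
}

setMethod("show", "SimPanel", function(object) {
  cat(sprintf("SimPanel: %d individuals x %d variants, %d LD block(s)\n",
              nrow(object@G), ncol(object@G), length(object@ldBlocks)))
})

#' Mendelian-consistency check of a gene-dropped panel
#'
#' Verifies for every child with known parents that each dosage is
#' achievable from the parents' dosages (0 transmits 0, 2 transmits 1,
#' 1 transmits either).
#'
#' @param panel a [SimPanel-class].
#' @return `TRUE` invisibly; stops with the offending trio otherwise.
#' @export
mendelianCheck <- function(panel) {
  ped <- panel@ped; G <- panel@G
  key <- .pedKeys(ped)
  idx <- setNames(seq_along(key), key)
  fa <- unname(idx[ifelse(is.na(ped@father), NA,
                          paste(ped@fid, ped@father, sep = "\r"))])
  mo <- unname(idx[ifelse(is.na(ped@mother), NA,
                          paste(ped@fid, ped@mother, sep = "\r"))])
  both <- which(!is.na(fa) & !is.na(mo))
  for (i in both) {
    lo <- (G[fa[i], ] == 2) + (G[mo[i], ] == 2)
    hi <- (G[fa[i], ] >= 1) + (G[mo[i], ] >= 1)
    bad <- G[i, ] < lo | G[i, ] > hi
    if (any(bad))
      stop(sprintf("Mendelian inconsistency: child %s, variant %s",
                   ped@id[i], colnames(G)[which(bad)[1L]]))
  }
  invisible(TRUE)
}

#' Wrap a simulated panel as a genotype store
#'
#' @param panel a [SimPanel-class].
#' @param chrom chromosome label for all variants.
#' @param spacing base pairs between consecutive variants.
#' @return a [GenotypeMatrix-class].
#' @export
panelGenotypes <- function(panel, chrom = "1", spacing = 1000L) {
  G <- panel@G
  storage.mode(G) <- "double"
  new("GenotypeMatrix", dosage = G,
      chrom = rep(chrom, ncol(G)),
      pos = as.integer(seq_len(ncol(G)) * spacing))
}

#' Build the default simulation study panel
#'
#' The cohort and panel used by the validation studies: 20 three-generation
#' pedigrees (n of roughly 650-850), 50 variants in four sliding windows,
#' MAFs uniform on `mafRange` with the causal variant pinned at `causalMaf`,
#' and one LD block spanning variants 11-40 so the windows that do not
#' contain the causal variant are still in linkage disequilibrium with it.
#'
#' @param nFamilies,m cohort and panel size.
#' @param causalIndex,causalMaf designated causal variant and its MAF.
#' @param mafRange MAF range of the remaining variants.
#' @param ldBlocks LD block index list (default variants 11-40).
#' @param seed RNG seed.
#' @return a [SimPanel-class].
#' @export
simStudyPanel <- function(nFamilies = 20L, m = 50L, causalIndex = 16L,
                          causalMaf = 0.25, mafRange = c(0.25, 0.5),
                          ldBlocks = list(11:40), seed = 1L) {
  ped <- simPedigrees(nFamilies, seed = seed)
  set.seed(seed + 1L)
  mafs <- runif(m, mafRange[1L], mafRange[2L])
  mafs[causalIndex] <- causalMaf
  geneDrop(ped, mafs, ldBlocks = ldBlocks, seed = seed + 2L)
}

#' Define a four-group gene-environment scenario
#'
#' @param means length-4 numeric: trait means for (non-exposed without SNV,
#'   non-exposed with SNV, exposed without SNV, exposed with SNV).
#' @param sd common within-group SD (default 10, blood-pressure-like units).
#' @param generatingModel disease model defining carrier status for
#'   generation (default `"recessive"`: carrier iff dosage 2).
#' @param causalIndex causal variant column (default 16, inside the first
#'   two 20-variant windows of a 50-variant panel).
#' @param envPrevalence exposure probability (default 0.228, a typical adult
#'   smoking prevalence).
#' @param analysisModel disease model handed to the test.
#' @return a [SimulationScenario-class].
#' @export
simScenario <- function(means, sd = 10, generatingModel = "recessive",
                        causalIndex = 16L, envPrevalence = 0.228,
                        analysisModel = generatingModel) {
  new("SimulationScenario", means = as.numeric(means), sd = sd,
      generatingModel = generatingModel, causalIndex = as.integer(causalIndex),
      envPrevalence = envPrevalence, analysisModel = analysisModel)
}

setValidity("SimulationScenario", function(object) {
  if (length(object@means) != 4L) return("means must have length 4")
  if (!all(is.finite(object@means))) return("means must be finite")
  if (object@sd <= 0) return("sd must be > 0")
  if (!object@generatingModel %in% c("additive", "dominant", "recessive"))
    return("unknown generating model")
  TRUE
})

setMethod("show", "SimulationScenario", function(object) {
  cat(sprintf(
    "SimulationScenario: means (%s), sd %.3g, %s generation at variant %d, exposure %.3f\n",
    paste(object@means, collapse = ","), object@sd, object@generatingModel,
    object@causalIndex, object@envPrevalence))
})

#' Simulate a quantitative trait under a four-group G x E scenario
#'
#' Exposure is Bernoulli per individual; carrier status follows the
#' generating disease model at the causal variant (recessive: dosage 2;
#' dominant: dosage >= 1; additive: group means interpolated linearly in
#' dosage/2).  The trait is normal around the group mean with the common SD,
#' independently given group.
#'
#' @param panel a [SimPanel-class].
#' @param scenario a [SimulationScenario-class].
#' @param seed RNG seed.
#' @return list with `y`, `env` (0/1) and `carrier`.
#' @export
simulatePhenotype <- function(panel, scenario, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  G <- panel@G
  n <- nrow(G)
  if (scenario@causalIndex > ncol(G)) stop("causal index outside the panel")
  dos <- G[, scenario@causalIndex]
  env <- rbinom(n, 1L, scenario@envPrevalence)
  mns <- scenario@means
  if (scenario@generatingModel == "additive") {
    w <- dos / 2
    mu <- ifelse(env == 0, (1 - w) * mns[1L] + w * mns[2L],
                           (1 - w) * mns[3L] + w * mns[4L])
    carrier <- w
  } else {
    carrier <- if (scenario@generatingModel == "recessive") as.numeric(dos == 2)
               else as.numeric(dos >= 1)
    mu <- ifelse(env == 0,
                 ifelse(carrier == 1, mns[2L], mns[1L]),
                 ifelse(carrier == 1, mns[4L], mns[3L]))
  }
  if (scenario@generatingModel == "recessive" && !any(dos == 2))
    warning("no recessive carriers in the sample; ",
            "power results are not interpretable")
  list(y = mu + rnorm(n, 0, scenario@sd), env = env, carrier = carrier)
}

# ---------------------------------------------------------------------------
# Fast replicated-testing engine.  All replicate loops share one
# eigendecomposition of R; per replicate only the 1-D REML profile and
# low-rank window algebra are redone.

# Per-window preparation: recode under the analysis model, weight by the
# Beta(1,25) density of the pre-recoding MAF (minor-allele oriented).
.prepWindows <- function(G, windows, model, weightsBeta = c(1, 25)) {
  lapply(seq_along(windows$start), function(k) {
    idx <- seq(windows$start[k], windows$end[k])
    ori <- orientMinorAllele(G[, idx, drop = FALSE])
    w <- mafWeights(ori$maf, weightsBeta[1L], weightsBeta[2L])
    Gr <- recodeGenotypes(ori$G, model)
    Gw <- Gr %*% diag(w, nrow = length(w))
    list(idx = idx, Gw = Gw)
  })
}

.windowRanges <- function(mTotal, size, step) {
  r <- slidingWindows(mTotal, size = size, step = step)
  list(start = IRanges::start(r), end = IRanges::end(r))
}

# One-dimensional REML profile fit in the rotated basis; returns the fitted
# null covariance eigenvalues v (true scale) and the GLS residual rotation.
.fitGammaRot <- function(yt, Xt, d) {
  n <- length(yt); p <- ncol(Xt)
  obj <- function(lg) .profileGamma(exp(lg), yt, Xt, d, n, p)$loglik
  opt <- optimize(obj, interval = log(c(1e-6, 1e6)), maximum = TRUE,
                  tol = 1e-8)
  at0 <- .profileGamma(0, yt, Xt, d, n, p)
  if (at0$loglik >= opt$objective - 1e-10) {
    gamma <- 0; best <- at0
  } else {
    gamma <- exp(opt$maximum)
    best <- .profileGamma(gamma, yt, Xt, d, n, p)
  }
  v <- (gamma * d + 1) * best$se2
  list(v = v, rt = yt - drop(Xt %*% best$alpha))
}

# p-values over the rho grid from the 2m score vector t12 and the 2m x 2m
# projected Gram matrix S (both on the doubled [G, EG] factor).
.gridPvalues <- function(t12, S, m, rhoGrid, adjust = 2,
                         method = "kuonen") {
  q1 <- sum(t12[seq_len(m)]^2)
  q2 <- sum(t12[m + seq_len(m)]^2)
  ps <- numeric(length(rhoGrid))
  for (i in seq_along(rhoGrid)) {
    rho <- rhoGrid[i]
    Dv <- c(rep(sqrt(rho), m), rep(sqrt(1 - rho), m))
    Gram <- 0.5 * (Dv %o% Dv) * (S + t(S)) / 2
    lam <- eigen(Gram, symmetric = TRUE, only.values = TRUE)$values
    lam <- lam[lam > 1e-10 * max(lam, 0)]
    Q <- 0.5 * (rho * q1 + (1 - rho) * q2)
    ps[i] <- pvalueMixture(Q, lam, method = method)$p
  }
  iff <- which(abs(rhoGrid - 1) < 1e-12)
  list(pPerRho = ps,
       pFFB = if (length(iff)) ps[iff] else NA_real_,
       pFGE = min(1, adjust * min(ps)))
}

# Window test given rotated design/window factors and fitted v.
.windowP <- function(GwT, eGwT, Xt, v, rt, rhoGrid, adjust = 2,
                     method = "kuonen") {
  m <- ncol(GwT)
  Ft <- cbind(GwT, eGwT)
  rtv <- rt / v
  t12 <- drop(crossprod(Ft, rtv))
  WF <- Ft / v
  S <- crossprod(Ft, WF)
  C <- crossprod(WF, Xt)
  M <- crossprod(Xt, Xt / v)
  S <- S - C %*% solve(M, t(C))
  .gridPvalues(t12, S, m, rhoGrid, adjust = adjust, method = method)
}

#' Permutation study of the empirical type-I error
#'
#' Generates the null distribution by randomly permuting the phenotype
#' vector across individuals while leaving genotypes, covariates and the
#' family structure in place; each replicate refits the null model and tests
#' every sliding window with both the plain family-SKAT (rho = 1) p-value
#' and the adjusted rho-grid minimum.
#'
#' @param panel a [SimPanel-class].
#' @param y observed phenotype vector (any trait; it is permuted).
#' @param e environment values (kept with individuals).
#' @param X optional covariate matrix (default intercept + e); kept with
#'   individuals.  Set `permuteCovariates = TRUE` to permute rows of X and e
#'   jointly with y instead.
#' @param nReps permutation replicates (default 1000; fewer than 100 warns).
#' @param levels nominal significance levels.
#' @param windowSize,step,rhoGrid,model,adjust analysis settings.
#' @param method p-value route (default saddlepoint), see [pvalueMixture()].
#' @param permuteCovariates permute (y, X, e) rows jointly.
#' @param seed global seed; per-replicate substreams are derived from it.
#' @return data.frame with one row per window x method x level: the
#'   empirical rejection rate and its binomial 95% CI.
#' @export
permutationType1 <- function(panel, y, e, X = NULL, nReps = 1000L,
                             levels = c(0.05, 0.01), windowSize = 20L,
                             step = 10L, rhoGrid = seq(0, 1, by = 0.1),
                             model = "additive", adjust = 2,
                             method = "kuonen",
                             permuteCovariates = FALSE, seed = 1L) {
  if (nReps < 100L) warning("fewer than 100 replicates: CIs will be wide")
  R <- relationshipMatrix(kinshipMatrix(panel@ped))
  n <- nrow(R)
  stopifnot(length(y) == n, length(e) == n)
  if (is.null(X)) X <- cbind(`(Intercept)` = 1, env = e)
  eig <- eigen(R, symmetric = TRUE)
  U <- eig$vectors; d <- pmax(eig$values, 0)
  win <- .windowRanges(ncol(panel@G), windowSize, step)
  prep <- .prepWindows(panel@G, win, model)
  nw <- length(prep)
  Xt <- crossprod(U, X)
  GwT <- lapply(prep, function(p) crossprod(U, p$Gw))
  eGwT <- lapply(prep, function(p) crossprod(U, e * p$Gw))
  rej <- array(0L, dim = c(nw, 2L, length(levels)))
  for (rep_ in seq_len(nReps)) {
    set.seed((seed %% 1000000L) * 1000L + rep_)
    perm <- sample.int(n)
    yp <- y[perm]
    if (permuteCovariates) {
      Xp <- X[perm, , drop = FALSE]; ep <- e[perm]
      Xtp <- crossprod(U, Xp)
      fit <- .fitGammaRot(crossprod(U, yp)[, 1L], Xtp, d)
      for (k in seq_len(nw)) {
        res <- .windowP(GwT[[k]], crossprod(U, ep * prep[[k]]$Gw), Xtp,
                        fit$v, fit$rt, rhoGrid, adjust, method)
        rej[k, 1L, ] <- rej[k, 1L, ] + (res$pFFB <= levels)
        rej[k, 2L, ] <- rej[k, 2L, ] + (res$pFGE <= levels)
      }
    } else {
      fit <- .fitGammaRot(crossprod(U, yp)[, 1L], Xt, d)
      for (k in seq_len(nw)) {
        res <- .windowP(GwT[[k]], eGwT[[k]], Xt, fit$v, fit$rt, rhoGrid,
                        adjust, method)
        rej[k, 1L, ] <- rej[k, 1L, ] + (res$pFFB <= levels)
        rej[k, 2L, ] <- rej[k, 2L, ] + (res$pFGE <= levels)
      }
    }
  }
  out <- expand.grid(window = seq_len(nw), method = c("ffbskat", "fgeskat"),
                     level = levels, stringsAsFactors = FALSE)
  out$rate <- mapply(function(w, meth, lv)
    rej[w, match(meth, c("ffbskat", "fgeskat")), match(lv, levels)] / nReps,
    out$window, out$method, out$level)
  se <- sqrt(out$rate * (1 - out$rate) / nReps)
  out$ci_lo <- pmax(0, out$rate - 1.96 * se)
  out$ci_hi <- pmin(1, out$rate + 1.96 * se)
  out
}

#' Power study over gene-environment scenarios
#'
#' For each scenario and replicate, a fresh phenotype (and exposure) is
#' generated on the fixed gene-dropped panel (set
#' `regenerateGenotypes = TRUE` to re-drop genotypes each replicate), both
#' tests are run on every sliding window, and rejections at `level` are
#' counted using the adjusted rho-grid minimum (FGE-SKAT) and the rho = 1
#' p-value (FFBSKAT).
#'
#' @param panel a [SimPanel-class].
#' @param scenarios a [SimulationScenario-class] or list of them.
#' @param nReps replicates per scenario.
#' @param level significance level.
#' @param windowSize,step,rhoGrid,adjust analysis settings; the disease
#'   model handed to the test is each scenario's `analysisModel`.
#' @param method p-value route (default saddlepoint), see [pvalueMixture()].
#' @param regenerateGenotypes re-run the gene drop each replicate.
#' @param seed global seed; per-replicate substreams are derived from it.
#' @return data.frame with one row per scenario x window and the empirical
#'   power of both methods.
#' @export
powerStudy <- function(panel, scenarios, nReps = 1000L, level = 0.05,
                       windowSize = 20L, step = 10L,
                       rhoGrid = seq(0, 1, by = 0.1), adjust = 2,
                       method = "kuonen",
                       regenerateGenotypes = FALSE, seed = 1L) {
  if (is(scenarios, "SimulationScenario")) scenarios <- list(scenarios)
  R <- relationshipMatrix(kinshipMatrix(panel@ped))
  eig <- eigen(R, symmetric = TRUE)
  U <- eig$vectors; d <- pmax(eig$values, 0)
  n <- nrow(R)
  win <- .windowRanges(ncol(panel@G), windowSize, step)
  nw <- length(win$start)
  rows <- list()
  for (s in seq_along(scenarios)) {
    sc <- scenarios[[s]]
    prep <- .prepWindows(panel@G, win, sc@analysisModel)
    GwT <- lapply(prep, function(p) crossprod(U, p$Gw))
    rej <- matrix(0L, nw, 2L)
    pan <- panel
    for (rep_ in seq_len(nReps)) {
      rs <- (seed %% 1000000L) * 1000L + s * 101L + rep_
      if (regenerateGenotypes) {
        pan <- geneDrop(panel@ped, panel@mafs, panel@ldBlocks,
                        seed = rs + 500000000L)
        prep <- .prepWindows(pan@G, win, sc@analysisModel)
        GwT <- lapply(prep, function(p) crossprod(U, p$Gw))
      }
      ph <- simulatePhenotype(pan, sc, seed = rs)
      X <- cbind(`(Intercept)` = 1, env = ph$env)
      Xt <- crossprod(U, X)
      fit <- .fitGammaRot(drop(crossprod(U, ph$y)), Xt, d)
      for (k in seq_len(nw)) {
        res <- .windowP(GwT[[k]], crossprod(U, ph$env * prep[[k]]$Gw), Xt,
                        fit$v, fit$rt, rhoGrid, adjust, method)
        rej[k, ] <- rej[k, ] + c(res$pFFB <= level, res$pFGE <= level)
      }
    }
    rows[[s]] <- data.frame(
      scenario = paste(sc@means, collapse = ","),
      generating_model = sc@generatingModel,
      analysis_model = sc@analysisModel,
      window = seq_len(nw),
      power_ffbskat = rej[, 1L] / nReps,
      power_fgeskat = rej[, 2L] / nReps)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a simulated panel as plain-text analysis inputs
#'
#' Writes `<prefix>.vcf` (uncompressed VCF v4.2 with GT only),
#' `<prefix>.ped` (LINKAGE pedigree) and `<prefix>.pheno.tsv`, so a
#' simulated study round-trips through the scan interface.
#'
#' @param panel a [SimPanel-class].
#' @param y,env phenotype and exposure vectors (e.g. from
#'   [simulatePhenotype()]).
#' @param prefix output path prefix.
#' @param chrom,spacing variant coordinates, as in [panelGenotypes()].
#' @return the prefix, invisibly.
#' @export
exportPanel <- function(panel, y, env, prefix, chrom = "1",
                        spacing = 1000L) {
  ped <- panel@ped
  write.table(
    data.frame(ped@fid, ped@id,
               ifelse(is.na(ped@father), "0", ped@father),
               ifelse(is.na(ped@mother), "0", ped@mother),
               ifelse(is.na(ped@sex), 0L, ped@sex)),
    paste0(prefix, ".ped"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  ids <- pedIds(ped)
  write.table(data.frame(id = ids, trait = y, env = env),
              paste0(prefix, ".pheno.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  m <- ncol(panel@G)
  gtmat <- matrix(paste0(t(panel@H1), "/", t(panel@H2)), nrow = m)
  lines <- c("##fileformat=VCFv4.2",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", ids), collapse = "\t"),
             vapply(seq_len(m), function(j)
               paste(c(chrom, j * spacing, colnames(panel@G)[j], "A", "T",
                       ".", "PASS", ".", "GT", gtmat[j, ]), collapse = "\t"),
               ""))
  writeLines(lines, paste0(prefix, ".vcf"))
  invisible(prefix)
}
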