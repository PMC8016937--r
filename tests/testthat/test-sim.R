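test_that("simulated cohorts look like multi-generation family samples", {
  ped <- simPedigrees(20, seed = 5)
  expect_length(unique(ped@fid), 20L)
  n <- length(ped@id)
  expect_gt(n, 350); expect_lt(n, 900)
  expect_true(any(!isFounder(ped)))
  # three generations present: some non-founder has a non-founder parent
  nf <- !isFounder(ped)
  parents <- unique(stats::na.omit(c(ped@father[nf], ped@mother[nf])))
  expect_true(any(parents %in% ped@id[nf]))
})

test_that("gene-dropped founders sit at Hardy-Weinberg proportions", {
  ped <- Pedigree(fid = paste0("F", 1:10000), id = paste0("I", 1:10000),
                  father = NA, mother = NA, sex = 1)
  panel <- geneDrop(ped, mafs = 0.5, seed = 6)
  tab <- tabulate(panel@G[, 1] + 1L, 3L) / 10000
  se <- sqrt(c(0.25, 0.5, 0.25) * c(0.75, 0.5, 0.75) / 10000)
  expect_true(all(abs(tab - c(0.25, 0.5, 0.25)) < 3 * se))
  # rare-limit: very small maf gives (almost) no carriers at these sizes
  panel0 <- geneDrop(ped, mafs = 1e-6, seed = 7)
  expect_equal(sum(panel0@G), 0)
})

test_that("transmission is Mendelian: Aa x Aa children are half het", {
  nTrio <- 4000L
  fa <- rep(NA_character_, 3 * nTrio)
  mo <- rep(NA_character_, 3 * nTrio)
  fa[seq(3, 3 * nTrio, 3)] <- paste0("f", seq_len(nTrio))
  mo[seq(3, 3 * nTrio, 3)] <- paste0("m", seq_len(nTrio))
  ped <- Pedigree(fid = rep(paste0("T", seq_len(nTrio)), each = 3),
                  id = paste0(rep(c("f", "m", "c"), nTrio),
                              rep(seq_len(nTrio), each = 3)),
                  father = fa, mother = mo, sex = c(1, 2, 1))
  panel <- geneDrop(ped, mafs = 0.5, seed = 8)
  mendelianCheck(panel)
  G <- panel@G[, 1]
  fa <- G[seq(1, 3 * nTrio, 3)]; mo <- G[seq(2, 3 * nTrio, 3)]
  ch <- G[seq(3, 3 * nTrio, 3)]
  hetBoth <- fa == 1 & mo == 1
  phet <- mean(ch[hetBoth] == 1)
  expect_lt(abs(phet - 0.5), 3 * sqrt(0.25 / sum(hetBoth)))
})

test_that("every simulated panel passes the exhaustive Mendelian check and
           LD blocks induce correlation", {
  st <- makeStudy(nFamilies = 5, m = 50, seed = 15, ldBlocks = list(11:40))
  expect_true(mendelianCheck(st$panel))
  G <- st$panel@G
  r2in <- stats::cor(G[, 16], G[, 25])^2      # same LD block
  r2out <- stats::cor(G[, 16], G[, 5])^2      # independent variant
  expect_gt(r2in, r2out)
  # independent variants should be near-uncorrelated (within-family IBD
  # correlation aside)
  expect_lt(r2out, 0.05)
})

test_that("phenotype scenarios realise their four group means", {
  ped <- Pedigree(fid = paste0("F", 1:5000), id = paste0("I", 1:5000),
                  father = NA, mother = NA, sex = 1)
  panel <- geneDrop(ped, mafs = rep(0.5, 2), seed = 9)
  # null scenario: y independent of genotype and exposure
  ph0 <- simulatePhenotype(panel, simScenario(c(120, 120, 120, 120),
                                              causalIndex = 1L), seed = 10)
  fitc <- stats::coef(summary(stats::lm(
    ph0$y ~ panel@G[, 1] + ph0$env)))
  expect_gt(fitc[2, 4], 0.01)
  expect_equal(mean(ph0$y), 120, tolerance = 0.5)
  # pure recessive genetic effect of 60
  ph1 <- simulatePhenotype(panel, simScenario(c(120, 180, 120, 180),
                                              causalIndex = 1L), seed = 11)
  d <- panel@G[, 1]
  expect_equal(mean(ph1$y[d == 2]) - mean(ph1$y[d < 2]), 60, tolerance = 2)
  # pure environment effect of 60, no genotype effect within strata
  ph2 <- simulatePhenotype(panel, simScenario(c(120, 120, 180, 180),
                                              causalIndex = 1L), seed = 12)
  expect_equal(mean(ph2$y[ph2$env == 1]) - mean(ph2$y[ph2$env == 0]), 60,
               tolerance = 2)
  sub <- ph2$env == 1
  expect_lt(abs(mean(ph2$y[sub & d == 2]) - mean(ph2$y[sub & d < 2])), 3)
  # exposure prevalence honoured
  expect_equal(mean(ph2$env), 0.228, tolerance = 0.03)
  # recessive scenario with no carriers warns
  tiny <- geneDrop(Pedigree("F", "A", NA, NA, 1), mafs = 0.01, seed = 13)
  if (!any(tiny@G == 2))
    expect_warning(simulatePhenotype(tiny, simScenario(c(120, 180, 120, 180),
                                                       causalIndex = 1L),
                                     seed = 14), "carrier")
})

test_that("the fast replicate engine reproduces the reference window test", {
  st <- makeStudy(nFamilies = 4, m = 30, seed = 25, ldBlocks = list())
  n <- nrow(st$R)
  set.seed(26)
  e <- rbinom(n, 1, 0.3)
  y <- 120 + 3 * e + rnorm(n, sd = 8)
  X <- cbind(`(Intercept)` = 1, env = e)
  fit <- fitNull(y, X, st$R)
  # reference route
  gm <- panelGenotypes(st$panel)
  w <- genotypeWindow(gm, IRanges::IRanges(1, 20))
  ref <- testWindow(fit, w, mafWeights(w), e, model = "dominant")
  # fast engine route with the same fitted variance components
  win <- fgeskat:::.windowRanges(30, 20, 10)
  prep <- fgeskat:::.prepWindows(st$panel@G, win, "dominant")
  U <- fit@U; v <- fit@sigmaB2 * fit@d + fit@sigmaE2
  res <- fgeskat:::.windowP(crossprod(U, prep[[1]]$Gw),
                            crossprod(U, e * prep[[1]]$Gw),
                            crossprod(U, X), v,
                            crossprod(U, fit@residuals)[, 1],
                            seq(0, 1, 0.1))
  expect_equal(res$pPerRho, unname(pPerRho(ref)), tolerance = 1e-8)
  expect_equal(res$pFGE, pAdjusted(ref), tolerance = 1e-8)
  expect_equal(res$pFFB, unname(pFFBSKAT(ref)), tolerance = 1e-8)
})

test_that("permutation and power tables are deterministic given the seed", {
  # one 20-variant window; the LD block keeps the designated causal MAF
  # from drifting in a small cohort
  panel <- simStudyPanel(nFamilies = 6, m = 20, causalIndex = 5L,
                         ldBlocks = list(1:20), seed = 35)
  sc <- simScenario(c(120, 180, 120, 180), causalIndex = 5L)
  ph <- simulatePhenotype(panel, sc, seed = 36)
  t1 <- suppressWarnings(
    permutationType1(panel, ph$y, ph$env, nReps = 30, seed = 37))
  t2 <- suppressWarnings(
    permutationType1(panel, ph$y, ph$env, nReps = 30, seed = 37))
  expect_identical(t1, t2)
  expect_true(all(t1$rate >= 0 & t1$rate <= 1))
  expect_true(all(t1$ci_lo <= t1$rate & t1$rate <= t1$ci_hi))
  expect_warning(permutationType1(panel, ph$y, ph$env, nReps = 50,
                                  seed = 38), "wide")
  p1 <- powerStudy(panel, sc, nReps = 20, seed = 39)
  p2 <- powerStudy(panel, sc, nReps = 20, seed = 39)
  expect_identical(p1, p2)
  # saturated recessive effect in the (single full) causal window
  expect_gte(p1$power_fgeskat[1], 0.9)
})

test_that("panels export to plain-text inputs that round-trip the scan", {
  st <- makeStudy(nFamilies = 3, m = 25, seed = 45, ldBlocks = list())
  sc <- simScenario(c(120, 150, 120, 150), causalIndex = 10L)
  ph <- simulatePhenotype(st$panel, sc, seed = 46)
  out <- withr::local_tempdir()
  prefix <- file.path(out, "sim")
  exportPanel(st$panel, ph$y, ph$env, prefix)
  ped <- readPedigree(paste0(prefix, ".ped"))
  gm <- readGenotypeMatrix(paste0(prefix, ".vcf"))
  pheno <- read.table(paste0(prefix, ".pheno.tsv"), header = TRUE,
                      sep = "\t")
  expect_equal(unname(dosages(gm)[pedIds(ped), ]), unname(st$panel@G))
  res <- runScan(ped, gm, pheno, trait = "trait", env = "env")
  expect_equal(nrow(res), length(slidingWindows(25)))
  expect_true(all(is.finite(res$p_adjusted)))
})
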