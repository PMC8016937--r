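#' @import methods
#' @importFrom stats dbeta dnorm pnorm qnorm pchisq rnorm rbinom runif
#'   optimize uniroot integrate rchisq setNames complete.cases
#' @importFrom utils read.table write.table head tail
NULL

#' Pedigree structure
#'
#' An ordered collection of individuals with family, parent and sex
#' annotations, as read from a LINKAGE / PLINK `.fam` style file.  Parent
#' identifiers are `NA` for founders (coded `"0"` on disk).  Validity requires
#' unique individual ids within each family, parents that resolve within the
#' family, and an acyclic parent graph.
#'
#' @slot fid family identifiers.
#' @slot id individual identifiers (unique within family).
#' @slot father,mother parent identifiers, `NA` when unknown.  An individual
#'   with exactly one known parent is treated downstream as having an implicit
#'   unrelated founder for the missing side.
#' @slot sex integer code (1 = male, 2 = female, `NA` = unknown).  Read but
#'   not used by the autosomal kinship computation.
#' @export
setClass("Pedigree",
  representation(fid = "character", id = "character",
                 father = "character", mother = "character", sex = "integer"))

#' Pairwise kinship coefficients of a pedigree
#'
#' Symmetric matrix of kinship coefficients \eqn{\Phi_{ij}}, the probability
#' that a randomly sampled allele from i is identical by descent to one from
#' j.  Diagonal entries are self-kinships, 0.5 for non-inbred individuals.
#' Cross-family entries are exactly zero.
#'
#' @slot ids individual keys, in pedigree order.
#' @slot phi symmetric n x n kinship matrix with `ids` as dimnames.
#' @export
setClass("KinshipMatrix",
  representation(ids = "character", phi = "matrix"))

#' Genotype dosage store
#'
#' Samples-by-variants dosage matrix on the 0/1/2 minor-allele-count scale
#' (missing allowed), with per-variant chromosome and position metadata.
#'
#' @slot dosage numeric n x M matrix, rownames samples, colnames variant ids.
#' @slot chrom,pos per-variant chromosome label and 1-based position.
#' @export
setClass("GenotypeMatrix",
  representation(dosage = "matrix", chrom = "character", pos = "integer"))

#' A windowed genotype block ready for kernel testing
#'
#' @slot G n x m dosage block (0/1/2 scale, pre-recoding; missing allowed).
#' @slot variantIds,pos,chrom variant metadata.
#' @slot maf per-variant minor allele frequency in [0, 0.5], computed after
#'   missing-data handling and minor-allele orientation.
#' @export
setClass("GenotypeWindow",
  representation(G = "matrix", variantIds = "character", pos = "integer",
                 chrom = "character", maf = "numeric"))

#' REML fit of the polygenic null model
#'
#' The null linear mixed model y = X alpha + b + e with
#' b ~ N(0, sigma_b^2 R) and e ~ N(0, sigma_e^2 I), fitted with the two
#' kernel variance components fixed at zero.  The spectral factorisation
#' R = U diag(d) U' is retained so that V = sigma_b^2 R + sigma_e^2 I and all
#' derived quantities reuse one eigendecomposition.
#'
#' @slot sigmaB2,sigmaE2 variance components (sigmaB2 >= 0, sigmaE2 > 0).
#' @slot alpha GLS fixed-effect estimates.
#' @slot U,d eigenvectors / eigenvalues of the relationship matrix R.
#' @slot loglik restricted (or ordinary) log-likelihood at the optimum.
#' @slot residuals y - X alpha-hat.
#' @slot y,X the data the model was fitted to.
#' @slot ids sample keys, in model order.
#' @slot method "reml" or "ml".
#' @export
setClass("NullModelFit",
  representation(sigmaB2 = "numeric", sigmaE2 = "numeric", alpha = "numeric",
                 U = "matrix", d = "numeric", loglik = "numeric",
                 residuals = "numeric", y = "numeric", X = "matrix",
                 ids = "character", method = "character"))

#' Combined gene + gene-environment kernel at one rho
#'
#' Holds the low-rank factor B with K = B B' where
#' K = rho G W W G' + (1 - rho) E G W W G' E; the n x n kernel itself is only
#' materialised on request via [kernelMatrix()].
#'
#' @slot rho mixing weight in [0, 1]; 1 = genetic kernel only.
#' @slot B n x r low-rank factor, r <= 2m.
#' @slot e environment values (diagonal of E).
#' @export
setClass("KernelPair",
  representation(rho = "numeric", B = "matrix", e = "numeric"))

#' Result of the rho-grid score test on one window
#'
#' @slot rhoGrid rho values tested.
#' @slot Q per-rho score statistics.
#' @slot lambdas per-rho eigenvalue vectors of the null mixture.
#' @slot pPerRho per-rho p-values.
#' @slot rhoMin rho attaining the minimum p-value.
#' @slot pMin minimum p-value over the grid.
#' @slot pAdjusted final p-value, min(1, adjust * pMin); the default
#'   adjust = 2 accounts for the two joint tests and is deliberately not
#'   scaled by the grid size.
#' @slot flags per-rho method annotations ("saddlepoint", "fallback",
#'   "degenerate").
#' @export
setClass("ScoreTestResult",
  representation(rhoGrid = "numeric", Q = "numeric", lambdas = "list",
                 pPerRho = "numeric", rhoMin = "numeric", pMin = "numeric",
                 pAdjusted = "numeric", flags = "character"))

#' Four-group gene-environment simulation scenario
#'
#' Group means of a normal trait for the four cells
#' (non-exposed/exposed x without/with the risk genotype), a common SD,
#' the generating disease model defining "with the risk genotype", the causal
#' variant index, and the exposure prevalence.
#'
#' @slot means length-4 numeric: (nonexp-noSNV, nonexp-SNV, exp-noSNV,
#'   exp-SNV) trait means.
#' @slot sd common within-group standard deviation (> 0).
#' @slot generatingModel disease model defining carrier status.
#' @slot causalIndex variant column used to generate the trait.
#' @slot envPrevalence probability of exposure (e.g. smoking).
#' @slot analysisModel disease model handed to the test.
#' @export
setClass("SimulationScenario",
  representation(means = "numeric", sd = "numeric",
                 generatingModel = "character", causalIndex = "integer",
                 envPrevalence = "numeric", analysisModel = "character"))

#' Gene-dropped genotype panel on a pedigree
#'
#' @slot ped the generating [Pedigree-class].
#' @slot G n x m dosages, Mendelian-consistent with the pedigree.
#' @slot H1,H2 the underlying transmitted haplotypes (0/1 matrices).
#' @slot mafs founder allele frequencies used for the drop.
#' @slot ldBlocks list of integer index vectors simulated as non-recombining
#'   blocks from a small founder-haplotype pool (empty = all independent).
#' @export
setClass("SimPanel",
  representation(ped = "Pedigree", G = "matrix", H1 = "matrix", H2 = "matrix",
                 mafs = "numeric", ldBlocks = "list"))
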