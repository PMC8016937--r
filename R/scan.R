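# Genome scan: trait normalisation, per-chromosome windows, result tables.

#' Blom rank-based inverse-normal transform
#'
#' z_i = qnorm((r_i - 3/8) / (n + 1/4)) with r_i the rank of y_i (average
#' ranks for ties).  Strictly increasing in y among untied values; the
#' output is an odd function of rank about the midrank.
#'
#' @param y numeric vector, no missing values (exclude beforehand), n >= 2.
#' @return transformed vector.
#' @export
blomTransform <- function(y) {
  if (anyNA(y)) stop("exclude missing values before the Blom transform")
  n <- length(y)
  if (n < 2L) stop("need at least two observations")
  if (diff(range(y)) == 0) stop("all values identical: no rank information")
  r <- rank(y, ties.method = "average")
  qnorm((r - 3 / 8) / (n + 1 / 4))
}

#' Bonferroni significance threshold
#'
#' @param nTests number of tests (windows), >= 1.
#' @param alpha family-wise level.
#' @return alpha / nTests.
#' @examples
#' bonferroniThreshold(834030)   # 5.995e-08
#' @export
bonferroniThreshold <- function(nTests, alpha = 0.05) {
  stopifnot(nTests >= 1)
  alpha / nTests
}

#' Genome scan with the rho-grid kernel test
#'
#' End-to-end driver: aligns samples across pedigree, genotypes and
#' phenotype table by id intersection (kinship is computed on the full
#' pedigree, then sub-matrixed — dropping relatives before the recursion
#' would corrupt it), optionally Blom-normalises the trait, fits one null
#' model, and tests every sliding window on every chromosome.  Per-window
#' failures are flagged rows, never an abort.
#'
#' @param ped a [Pedigree-class].
#' @param genotypes a [GenotypeMatrix-class].
#' @param pheno data.frame, one row per sample; must contain `idCol`, the
#'   trait, all covariates and the environment column.
#' @param trait trait column name.
#' @param covars covariate column names (the environment column is added to
#'   the fixed effects automatically if not listed).
#' @param env environment column name (no missing values allowed).
#' @param model disease model for recoding.
#' @param windowSize,step sliding-window geometry in variants.
#' @param rhoGrid rho values (default 11 values, 0 to 1 by 0.1).
#' @param blom Blom-normalise the trait before fitting (default TRUE).
#' @param method p-value route per window (default saddlepoint).
#' @param adjust final p-value multiplier (default 2).
#' @param weightsBeta Beta shape parameters for [mafWeights()].
#' @param idCol sample id column of `pheno`.
#' @param out optional output prefix; writes `<out>.results.tsv`,
#'   `<out>.manhattan.tsv` and `<out>.log`.
#' @return data.frame (ScanResult): chrom, start_bp, end_bp, n_snv,
#'   p_ffbskat, p_min, rho_min, p_adjusted, flags — one row per window,
#'   ordered by (chrom, window start).
#' @export
runScan <- function(ped, genotypes, pheno, trait, covars = character(0),
                    env, model = "additive", windowSize = 20L, step = 10L,
                    rhoGrid = seq(0, 1, by = 0.1), blom = TRUE,
                    method = "kuonen", adjust = 2,
                    weightsBeta = c(1, 25), idCol = "id", out = NULL) {
  stopifnot(is(ped, "Pedigree"), is(genotypes, "GenotypeMatrix"))
  for (col in c(idCol, trait, covars, env))
    if (!col %in% names(pheno)) stop("pheno is missing column '", col, "'")
  if (!env %in% covars) covars <- c(covars, env)
  phenoIds <- as.character(pheno[[idCol]])
  keep <- complete.cases(pheno[, c(trait, covars), drop = FALSE])
  nDropped <- sum(!keep)
  pheno <- pheno[keep, , drop = FALSE]
  phenoIds <- phenoIds[keep]
  pedKeys <- pedIds(ped)
  ids <- intersect(intersect(pedKeys, rownames(genotypes@dosage)), phenoIds)
  if (!length(ids)) stop("zero overlapping samples across pedigree, ",
                         "genotypes and phenotypes")
  extra <- setdiff(intersect(phenoIds, rownames(genotypes@dosage)), pedKeys)
  if (length(extra))
    stop("sample(s) with data but absent from the pedigree: ",
         paste(head(extra, 5L), collapse = ", "))
  R <- relationshipMatrix(kinshipMatrix(ped))[ids, ids]
  gm <- genotypes
  gm@dosage <- gm@dosage[ids, , drop = FALSE]
  pheno <- pheno[match(ids, phenoIds), , drop = FALSE]
  if (diff(range(as.numeric(pheno[[env]]))) == 0) {
    warning("environment column '", env, "' is constant; dropping it from ",
            "the fixed effects (collinear with the intercept)")
    covars <- setdiff(covars, env)
  }
  y <- as.numeric(pheno[[trait]])
  if (blom) y <- blomTransform(y)
  X <- cbind(`(Intercept)` = rep(1, length(ids)))
  if (length(covars))
    X <- cbind(X, as.matrix(as.data.frame(lapply(pheno[covars], as.numeric))))
  e <- as.numeric(pheno[[env]])
  if (anyNA(e)) stop("environment column '", env, "' has missing values")
  fit <- fitNull(y, X, R, ids = ids)
  rows <- list()
  for (chr in unique(gm@chrom)) {
    vsel <- which(gm@chrom == chr)
    win <- slidingWindows(length(vsel), size = windowSize, step = step)
    for (k in seq_along(win)) {
      idx <- vsel[seq(IRanges::start(win)[k], IRanges::end(win)[k])]
      row <- tryCatch({
        w <- genotypeWindow(gm, idx)
        res <- testWindow(fit, w, mafWeights(w, weightsBeta[1L],
                                             weightsBeta[2L]),
                          e, rhoGrid = rhoGrid, model = model,
                          method = method, adjust = adjust)
        data.frame(chrom = chr, start_bp = min(w@pos), end_bp = max(w@pos),
                   n_snv = ncol(w@G), p_ffbskat = unname(pFFBSKAT(res)),
                   p_min = res@pMin, rho_min = res@rhoMin,
                   p_adjusted = res@pAdjusted,
                   flags = paste(unique(res@flags), collapse = ";"))
      }, error = function(err)
        data.frame(chrom = chr, start_bp = min(gm@pos[idx]),
                   end_bp = max(gm@pos[idx]), n_snv = length(idx),
                   p_ffbskat = NA_real_, p_min = NA_real_,
                   rho_min = NA_real_, p_adjusted = NA_real_,
                   flags = paste0("error:", conditionMessage(err))))
      rows[[length(rows) + 1L]] <- row
    }
  }
  result <- do.call(rbind, rows)
  rownames(result) <- NULL
  threshold <- bonferroniThreshold(nrow(result))
  if (!is.null(out)) {
    write.table(result, paste0(out, ".results.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    manhattanExport(result, threshold, paste0(out, ".manhattan.tsv"))
    writeLines(c(
      sprintf("samples analysed: %d (dropped %d incomplete phenotype rows)",
              length(ids), nDropped),
      sprintf("windows tested: %d", nrow(result)),
      sprintf("bonferroni threshold (alpha 0.05): %.6g", threshold),
      sprintf("null model: sigma_b^2 = %.6g, sigma_e^2 = %.6g",
              fit@sigmaB2, fit@sigmaE2)),
      paste0(out, ".log"))
  }
  attr(result, "threshold") <- threshold
  attr(result, "fit") <- fit
  result
}

#' Manhattan plot data export
#'
#' One point per window at the chromosome-offset midpoint on x and
#' -log10(p_adjusted) on y, plus the threshold line level.
#'
#' @param result a scan result data.frame from [runScan()].
#' @param threshold significance threshold on the p scale.
#' @param path optional TSV output.
#' @return data.frame with chrom, x (genome-cumulative midpoint bp),
#'   y (-log10 p_adjusted); attribute `"hline"` = -log10(threshold).
#' @export
manhattanExport <- function(result, threshold, path = NULL) {
  stopifnot(nrow(result) >= 1L)
  chrOrder <- unique(result$chrom)
  offsets <- setNames(numeric(length(chrOrder)), chrOrder)
  run <- 0
  for (chr in chrOrder) {
    offsets[chr] <- run
    run <- run + max(result$end_bp[result$chrom == chr])
  }
  mid <- (result$start_bp + result$end_bp) / 2
  df <- data.frame(chrom = result$chrom,
                   x = mid + offsets[as.character(result$chrom)],
                   y = -log10(result$p_adjusted))
  attr(df, "hline") <- -log10(threshold)
  if (!is.null(path)) {
    write.table(cbind(df, hline = -log10(threshold)), path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  df
}

#' Manhattan plot (requires ggplot2)
#'
#' @param result scan result from [runScan()].
#' @param threshold p-scale threshold (default: the result's attribute).
#' @return a ggplot object.
#' @export
plotManhattan <- function(result, threshold = attr(result, "threshold")) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- manhattanExport(result, threshold)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = factor(.data$chrom))) +
    ggplot2::geom_point(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = attr(df, "hline"), colour = "red") +
    ggplot2::labs(x = "genomic position", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}
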