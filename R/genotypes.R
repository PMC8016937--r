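# Genotype input, sliding windows, disease-model recoding, MAF weights.

setValidity("GenotypeMatrix", function(object) {
  M <- ncol(object@dosage)
  if (length(object@chrom) != M || length(object@pos) != M)
    return("chrom/pos must have one entry per variant")
  d <- object@dosage
  if (any(d < -1e-9 | d > 2 + 1e-9, na.rm = TRUE))
    return("dosages must lie in [0, 2]")
  TRUE
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d samples x %d variants (%s)\n",
              nrow(object@dosage), ncol(object@dosage),
              paste(unique(object@chrom), collapse = ", ")))
})

#' Dosages, variant metadata and sample accessors
#'
#' @param x a [GenotypeMatrix-class] or [GenotypeWindow-class].
#' @return `dosages()` the numeric matrix; `variantInfo()` a data.frame of
#'   chrom/pos/id; `sampleIds()` rownames.
#' @export
dosages <- function(x) {
  if (is(x, "GenotypeWindow")) x@G else x@dosage
}

#' @rdname dosages
#' @export
variantInfo <- function(x) {
  if (is(x, "GenotypeWindow"))
    data.frame(chrom = x@chrom, pos = x@pos, id = x@variantIds)
  else
    data.frame(chrom = x@chrom, pos = x@pos, id = colnames(x@dosage))
}

#' @rdname dosages
#' @export
sampleIds <- function(x) rownames(dosages(x))

.parseGT <- function(gt) {
  # "0/1", "0|1", "./.", possibly with trailing FORMAT fields removed upstream
  gt[gt %in% c("./.", ".|.", ".")] <- NA
  out <- rep(NA_real_, length(gt))
  ok <- !is.na(gt)
  if (!any(ok)) return(out)
  parts <- strsplit(gt[ok], "[/|]")
  len <- lengths(parts)
  if (any(len != 2L))
    stop("non-diploid GT encountered (e.g. '", gt[ok][which(len != 2L)[1L]],
         "')")
  al <- suppressWarnings(matrix(as.integer(unlist(parts)), nrow = 2L))
  miss <- is.na(al[1L, ]) | is.na(al[2L, ])
  out[ok] <- ifelse(miss, NA_real_, (al[1L, ] > 0) + (al[2L, ] > 0))
  out
}

#' Read a genotype dosage store
#'
#' Reads either a VCF (via \pkg{vcfR}; GT field, phase ignored) or a plain
#' dosage TSV (rows = samples, first column sample id, remaining columns one
#' variant each; an optional sidecar TSV supplies chrom/pos per variant).
#' The result is aligned to `sampleIds` when given; samples requested but
#' absent from the file are an error.
#'
#' @param path VCF (`.vcf`/`.vcf.gz`) or dosage TSV path.
#' @param sampleIds optional ordered sample keys to align to.
#' @param format `"auto"` (by extension), `"vcf"` or `"dosage"`.
#' @param sidecar for dosage input, optional TSV with columns id/chrom/pos.
#' @param multiallelic `"error"` rejects multi-ALT records, `"split"`
#'   expands each ALT allele into its own dosage column.
#' @return a [GenotypeMatrix-class].
#' @export
readGenotypeMatrix <- function(path, sampleIds = NULL,
                               format = c("auto", "vcf", "dosage"),
                               sidecar = NULL,
                               multiallelic = c("error", "split")) {
  format <- match.arg(format)
  multiallelic <- match.arg(multiallelic)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage"
  gm <- if (format == "vcf") .readVcfDosage(path, multiallelic)
        else .readDosageTsv(path, sidecar)
  if (!is.null(sampleIds)) {
    missing <- setdiff(sampleIds, rownames(gm@dosage))
    if (length(missing))
      stop("sample(s) requested but not in genotype file: ",
           paste(missing, collapse = ", "))
    gm@dosage <- gm@dosage[sampleIds, , drop = FALSE]
  }
  validObject(gm)
  gm
}

.readVcfDosage <- function(path, multiallelic) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  gt <- vcfR::extract.gt(v, element = "GT")   # variants x samples
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1L, dimnames = list(NULL, names(gt)))
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  if (any(multi)) {
    if (multiallelic == "error")
      stop("multiallelic record(s) at ",
           paste(head(paste0(chrom[multi], ":", pos[multi]), 5L),
                 collapse = ", "),
           "; decompose first or use multiallelic = 'split'")
    # split: one dosage column per ALT allele
    cols <- list(); cn <- character(0); cc <- character(0); pp <- integer(0)
    for (i in seq_along(alt)) {
      nalt <- length(strsplit(alt[i], ",")[[1L]])
      g <- gt[i, ]
      g[g %in% c("./.", ".|.", ".")] <- NA
      parts <- strsplit(ifelse(is.na(g), "NA/NA", g), "[/|]")
      if (any(lengths(parts) != 2L)) stop("non-diploid GT encountered")
      a1 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
      a2 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
      for (k in seq_len(nalt)) {
        dk <- (a1 == k) + (a2 == k)
        cols[[length(cols) + 1L]] <- dk
        cn <- c(cn, if (nalt > 1L) paste0(ids[i], "_alt", k) else ids[i])
        cc <- c(cc, chrom[i]); pp <- c(pp, pos[i])
      }
    }
    dos <- do.call(cbind, cols)
    dimnames(dos) <- list(colnames(gt), cn)
    return(new("GenotypeMatrix", dosage = dos, chrom = cc, pos = pp))
  }
  dos <- apply(gt, 1L, .parseGT)               # samples x variants
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = ncol(gt))
  dimnames(dos) <- list(colnames(gt), ids)
  new("GenotypeMatrix", dosage = dos, chrom = unname(chrom),
      pos = unname(pos))
}

.readDosageTsv <- function(path, sidecar) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  ids <- as.character(tab[[1L]])
  dos <- as.matrix(tab[-1L])
  storage.mode(dos) <- "double"
  rownames(dos) <- ids
  M <- ncol(dos)
  chrom <- rep("0", M); pos <- seq_len(M)
  if (!is.null(sidecar)) {
    sc <- read.table(sidecar, header = TRUE, sep = "\t",
                     check.names = FALSE, colClasses = "character")
    m <- match(colnames(dos), sc$id)
    if (anyNA(m)) stop("sidecar is missing variant(s): ",
                       paste(colnames(dos)[is.na(m)], collapse = ", "))
    chrom <- sc$chrom[m]; pos <- as.integer(sc$pos[m])
  }
  new("GenotypeMatrix", dosage = dos, chrom = chrom, pos = pos)
}

#' Write a dosage TSV (round-trips through [readGenotypeMatrix()])
#'
#' @param gm a [GenotypeMatrix-class].
#' @param path output TSV; `sidecar`, if given, receives chrom/pos metadata.
#' @param sidecar optional sidecar path.
#' @export
writeDosage <- function(gm, path, sidecar = NULL) {
  df <- data.frame(sample = rownames(gm@dosage), gm@dosage,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sidecar))
    write.table(data.frame(id = colnames(gm@dosage), chrom = gm@chrom,
                           pos = gm@pos),
                sidecar, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sliding variant windows
#'
#' Windows of `size` variants advanced by `step`, defined over variant index
#' within one chromosome.  Every variant is covered; a trailing window
#' shorter than `size` is emitted once (never duplicating the final full
#' window).  Returned 1-based inclusive as an [IRanges::IRanges].
#'
#' @param mTotal number of variants on the chromosome.
#' @param size window size in variants (default 20).
#' @param step shift between consecutive windows (default 10); `step > size`
#'   would leave gaps and is an error.
#' @return an `IRanges` of windows.
#' @examples
#' slidingWindows(50)          # 4 windows: 1-20, 11-30, 21-40, 31-50
#' @export
slidingWindows <- function(mTotal, size = 20L, step = 10L) {
  stopifnot(mTotal >= 1L, size >= 1L, step >= 1L)
  if (step > size)
    stop("step > size would skip variants (step = ", step,
         ", size = ", size, ")")
  starts <- 0L
  while (tail(starts, 1L) + size < mTotal)
    starts <- c(starts, tail(starts, 1L) + step)
  ends <- pmin(starts + size, mTotal)
  IRanges::IRanges(start = starts + 1L, end = ends)
}

#' Recode dosages under a disease model
#'
#' `additive` leaves 0/1/2 unchanged; `dominant` codes carrier status
#' (dosage >= 1); `recessive` codes homozygous-alternate status
#' (dosage == 2).  Missing values stay missing.
#'
#' @param G dosage matrix (entries 0/1/2 or `NA`).
#' @param model one of `"additive"`, `"dominant"`, `"recessive"`.
#' @return recoded matrix of the same shape.
#' @export
recodeGenotypes <- function(G, model = c("additive", "dominant", "recessive")) {
  model <- match.arg(model)
  switch(model,
    additive  = G,
    dominant  = ifelse(is.na(G), NA_real_, as.numeric(G >= 1)),
    recessive = ifelse(is.na(G), NA_real_, as.numeric(G == 2)))
}

#' Beta-density variant weights
#'
#' SKAT-style weights \eqn{w_j = f(\mathrm{maf}_j; a_1, a_2)} with f the
#' Beta density; the default (1, 25) gives \eqn{w_j = 25 (1 - p_j)^{24}},
#' upweighting rare variants (w = 25 at maf 0, ~1.5e-6 at maf 0.5).
#'
#' @param maf minor allele frequencies in [0, 0.5], or a
#'   [GenotypeWindow-class] whose `maf` slot is used.
#' @param a1,a2 Beta shape parameters.
#' @return nonnegative weight vector, one per variant.
#' @export
mafWeights <- function(maf, a1 = 1, a2 = 25) {
  if (is(maf, "GenotypeWindow")) maf <- maf@maf
  if (any(maf < 0 | maf > 1)) stop("maf must lie in [0, 1]")
  dbeta(maf, a1, a2)
}

#' Mean-impute missing dosages
#'
#' Missing entries are replaced per variant by the mean dosage among
#' observed samples.  Variants that are entirely missing are dropped with a
#' warning.  Variants whose missingness exceeds `maxMissing` are an error.
#'
#' @param G dosage matrix.
#' @param maxMissing per-variant missingness ceiling (default 0.10).
#' @return complete matrix (possibly with fewer columns).
#' @export
imputeMissing <- function(G, maxMissing = 0.10) {
  nmiss <- colSums(is.na(G))
  allmiss <- nmiss == nrow(G)
  if (any(allmiss)) {
    warning("dropping ", sum(allmiss), " entirely missing variant(s): ",
            paste(colnames(G)[allmiss], collapse = ", "))
    G <- G[, !allmiss, drop = FALSE]
    nmiss <- nmiss[!allmiss]
  }
  over <- nmiss / nrow(G) > maxMissing
  if (any(over))
    stop("variant(s) exceed missingness ceiling (", maxMissing, "): ",
         paste(colnames(G)[over], collapse = ", "))
  for (j in which(nmiss > 0L)) {
    m <- mean(G[, j], na.rm = TRUE)
    G[is.na(G[, j]), j] <- m
  }
  G
}

#' Orient dosages to the minor allele
#'
#' Columns whose alternate-allele frequency exceeds 0.5 are flipped
#' (d -> 2 - d) so that dosage counts the minor allele, as the Beta(1,25)
#' weighting presumes.
#'
#' @param G dosage matrix (missing allowed; frequencies use observed values).
#' @return list with `G` (oriented matrix), `flipped` (logical per variant)
#'   and `maf` (minor allele frequency per variant, in [0, 0.5]).
#' @export
orientMinorAllele <- function(G) {
  af <- colMeans(G, na.rm = TRUE) / 2
  flip <- !is.na(af) & af > 0.5
  if (any(flip)) G[, flip] <- 2 - G[, flip]
  maf <- pmin(ifelse(is.na(af), 0, ifelse(flip, 1 - af, af)), 0.5)
  list(G = G, flipped = flip, maf = unname(maf))
}

#' Extract one window from a genotype store
#'
#' Subsets the store to a variant index range, mean-imputes missingness,
#' orients to the minor allele and records MAF.  Monomorphic variants are
#' retained (weight from maf = 0, zero signal) to keep window coordinates
#' stable.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param range an `IRanges` row (or integer vector of variant indices).
#' @param maxMissing passed to [imputeMissing()].
#' @return a [GenotypeWindow-class].
#' @export
genotypeWindow <- function(gm, range, maxMissing = 0.10) {
  idx <- if (is(range, "IRanges"))
    seq(IRanges::start(range)[1L], IRanges::end(range)[1L]) else as.integer(range)
  G <- gm@dosage[, idx, drop = FALSE]
  G <- imputeMissing(G, maxMissing = maxMissing)
  sel <- match(colnames(G), colnames(gm@dosage))
  ori <- orientMinorAllele(G)
  new("GenotypeWindow", G = ori$G, variantIds = colnames(G),
      pos = gm@pos[sel], chrom = gm@chrom[sel], maf = ori$maf)
}

setValidity("GenotypeWindow", function(object) {
  m <- ncol(object@G)
  if (length(object@maf) != m || length(object@pos) != m ||
      length(object@variantIds) != m || length(object@chrom) != m)
    return("metadata length must match variant count")
  if (any(object@maf < 0 | object@maf > 0.5 + 1e-12))
    return("maf must lie in [0, 0.5]")
  TRUE
})

setMethod("show", "GenotypeWindow", function(object) {
  cat(sprintf("GenotypeWindow: %d samples x %d variants, %s:%d-%d\n",
              nrow(object@G), ncol(object@G), object@chrom[1L],
              min(object@pos), max(object@pos)))
})
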