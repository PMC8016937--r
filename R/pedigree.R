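# Pedigree reading, kinship recursion, relationship matrix.

setValidity("Pedigree", function(object) {
  n <- length(object@id)
  if (length(object@fid) != n || length(object@father) != n ||
      length(object@mother) != n || length(object@sex) != n)
    return("all slots must have equal length")
  msgs <- character(0)
  for (f in unique(object@fid)) {
    sel <- object@fid == f
    ids <- object@id[sel]
    dup <- unique(ids[duplicated(ids)])
    if (length(dup))
      msgs <- c(msgs, sprintf("duplicate individual id(s) in family %s: %s",
                              f, paste(dup, collapse = ", ")))
    for (p in c(object@father[sel], object@mother[sel])) {
      if (!is.na(p) && !(p %in% ids))
        msgs <- c(msgs, sprintf("unknown parent id '%s' in family %s", p, f))
    }
  }
  if (length(msgs)) return(msgs)
  ord <- tryCatch(.pedOrder(object), error = function(e) e)
  if (inherits(ord, "error")) return(conditionMessage(ord))
  TRUE
})

# Topological order (founders first) via Kahn's algorithm; errors on cycles,
# naming an individual on one.
.pedOrder <- function(ped) {
  n <- length(ped@id)
  key <- .pedKeys(ped)
  idx <- setNames(seq_len(n), key)
  fa <- ifelse(is.na(ped@father), NA, paste(ped@fid, ped@father, sep = "\r"))
  mo <- ifelse(is.na(ped@mother), NA, paste(ped@fid, ped@mother, sep = "\r"))
  fi <- unname(idx[fa]); mi <- unname(idx[mo])
  indeg <- (!is.na(fi)) + (!is.na(mi))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(fi[i], mi[i])) if (!is.na(p))
      children[[p]] <- c(children[[p]], i)
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    out <- c(out, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < n) {
    stuck <- setdiff(seq_len(n), out)
    stop(sprintf("pedigree cycle detected involving individual '%s' (family %s)",
                 ped@id[stuck[1L]], ped@fid[stuck[1L]]), call. = FALSE)
  }
  out
}

# Unique per-sample keys: bare IID when globally unique, else FID:IID.
.pedKeys <- function(ped) paste(ped@fid, ped@id, sep = "\r")

#' Individual keys of a pedigree
#'
#' Returns the identifier used to label kinship/relationship matrices: the
#' individual id itself when ids are unique across families, otherwise
#' `"FID:IID"`.
#'
#' @param ped a [Pedigree-class].
#' @return character vector, one key per individual, in pedigree order.
#' @export
pedIds <- function(ped) {
  if (anyDuplicated(ped@id)) paste(ped@fid, ped@id, sep = ":") else ped@id
}

#' Founder indicator
#'
#' @param ped a [Pedigree-class].
#' @return logical vector: `TRUE` where both parents are unknown.
#' @export
isFounder <- function(ped) is.na(ped@father) & is.na(ped@mother)

setMethod("show", "Pedigree", function(object) {
  cat(sprintf("Pedigree: %d individuals in %d families (%d founders)\n",
              length(object@id), length(unique(object@fid)),
              sum(isFounder(object))))
})

#' Construct a pedigree from vectors
#'
#' @param fid,id,father,mother character vectors; parent entries `NA`, `""`
#'   or `"0"` mean unknown.
#' @param sex integer-like; values other than 1/2 become `NA`.
#' @return a validated [Pedigree-class].
#' @export
Pedigree <- function(fid, id, father, mother, sex = NA_integer_) {
  clean <- function(x) {
    x <- as.character(x)
    x[x %in% c("0", "", "NA") | is.na(x)] <- NA_character_
    x
  }
  n <- length(id)
  sex <- suppressWarnings(as.integer(sex))
  sex[!sex %in% c(1L, 2L)] <- NA_integer_
  new("Pedigree", fid = rep_len(as.character(fid), n), id = as.character(id),
      father = rep_len(clean(father), n), mother = rep_len(clean(mother), n),
      sex = rep_len(sex, n))
}

#' Read a LINKAGE / PLINK-fam pedigree file
#'
#' Whitespace- or tab-delimited, columns FID IID PAT MAT SEX (extra trailing
#' columns, e.g. the `.fam` phenotype, are ignored).  `"0"` codes a missing
#' parent.  The file is validated on read: duplicate ids within a family,
#' parent ids that do not resolve, and parent-graph cycles are errors.
#'
#' @param path file path.
#' @param dialect `"linkage"` or `"plink_fam"`; both share the five leading
#'   columns, so the dialect only documents intent.
#' @return a [Pedigree-class].
#' @export
readPedigree <- function(path, dialect = c("linkage", "plink_fam")) {
  match.arg(dialect)
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  tab <- read.table(path, header = FALSE, colClasses = "character",
                    comment.char = "#")
  if (ncol(tab) < 5L)
    stop("pedigree file must have at least 5 columns (FID IID PAT MAT SEX)")
  Pedigree(tab[[1L]], tab[[2L]], tab[[3L]], tab[[4L]], tab[[5L]])
}

setValidity("KinshipMatrix", function(object) {
  p <- object@phi
  if (nrow(p) != ncol(p) || nrow(p) != length(object@ids))
    return("phi must be square with one row per id")
  if (max(abs(p - t(p))) > 1e-12) return("phi must be symmetric")
  if (any(diag(p) < 0.5 - 1e-12)) return("self-kinship must be >= 0.5")
  TRUE
})

setMethod("show", "KinshipMatrix", function(object) {
  cat(sprintf("KinshipMatrix: %d individuals, mean off-diagonal phi %.4f\n",
              length(object@ids),
              mean(object@phi[upper.tri(object@phi)])))
})

#' Kinship matrix of a pedigree
#'
#' Computes pairwise kinship coefficients by the standard recursion over a
#' founders-first ordering: self-kinship
#' \eqn{\Phi_{ii} = (1 + \Phi_{fm})/2} (0.5 for founders, more under
#' inbreeding) and \eqn{\Phi_{ij} = (\Phi_{fj} + \Phi_{mj})/2} for j not a
#' descendant of i.  A missing parent contributes zero kinship, i.e. behaves
#' as an implicit unique founder, so half-founders are handled without
#' augmenting the pedigree.  The result is block-diagonal across families.
#'
#' @param ped a [Pedigree-class].
#' @return a [KinshipMatrix-class] in pedigree order.
#' @seealso [relationshipMatrix()] for R = 2 Phi.
#' @export
kinshipMatrix <- function(ped) {
  stopifnot(is(ped, "Pedigree"))
  validObject(ped)
  n <- length(ped@id)
  keys <- .pedKeys(ped)
  idx <- setNames(seq_len(n), keys)
  fa <- unname(idx[ifelse(is.na(ped@father), NA,
                          paste(ped@fid, ped@father, sep = "\r"))])
  mo <- unname(idx[ifelse(is.na(ped@mother), NA,
                          paste(ped@fid, ped@mother, sep = "\r"))])
  ord <- .pedOrder(ped)
  phi <- matrix(0, n, n)
  for (k in seq_along(ord)) {
    i <- ord[k]
    f <- fa[i]; m <- mo[i]
    phi[i, i] <- 0.5 * (1 + if (!is.na(f) && !is.na(m)) phi[f, m] else 0)
    if (k > 1L) {
      js <- ord[seq_len(k - 1L)]
      same <- ped@fid[js] == ped@fid[i]
      js <- js[same]
      if (length(js)) {
        v <- 0.5 * ((if (!is.na(f)) phi[f, js] else 0) +
                    (if (!is.na(m)) phi[m, js] else 0))
        phi[i, js] <- v
        phi[js, i] <- v
      }
    }
  }
  ids <- pedIds(ped)
  dimnames(phi) <- list(ids, ids)
  new("KinshipMatrix", ids = ids, phi = phi)
}

#' Relationship matrix R = 2 Phi
#'
#' Twice the kinship matrix: the expected genetic covariance structure used
#' as the family random-effect covariance.  Diagonal is 1 for non-inbred
#' individuals, symmetric positive semidefinite, block-diagonal by family.
#'
#' @param kin a [KinshipMatrix-class] (or a [Pedigree-class], which is
#'   converted first).
#' @return base numeric matrix with individual keys as dimnames.
#' @export
relationshipMatrix <- function(kin) {
  if (is(kin, "Pedigree")) kin <- kinshipMatrix(kin)
  stopifnot(is(kin, "KinshipMatrix"))
  2 * kin@phi
}

#' Export / import a kinship matrix as TSV
#'
#' Square matrix with a header row and a leading id column, tab-delimited.
#'
#' @param kin a [KinshipMatrix-class].
#' @param path output file.
#' @export
writeKinship <- function(kin, path) {
  stopifnot(is(kin, "KinshipMatrix"))
  df <- data.frame(id = kin@ids, kin@phi, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeKinship
#' @return `readKinship` returns a [KinshipMatrix-class].
#' @export
readKinship <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = c("character"))
  ids <- tab[[1L]]
  phi <- as.matrix(tab[-1L])
  storage.mode(phi) <- "double"
  dimnames(phi) <- list(ids, ids)
  new("KinshipMatrix", ids = ids, phi = phi)
}
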