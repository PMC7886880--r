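#' Primer design constraints
#'
#' Bundles the marker-design windows.  Defaults are the standard
#' agarose-marker settings: primers of 18-28 bp with Tm 57-63 degrees C and a
#' PCR product of 80-300 bp on the reference allele; GC content outside
#' 40-60\% and homopolymer runs of 5+ bases are penalized (not rejected)
#' during pair scoring.
#'
#' @param primerLenMin,primerLenMax primer length window in bases.
#' @param tmMin,tmMax melting temperature window in degrees Celsius.
#' @param productMin,productMax product size window in bp, evaluated on the
#'   reference allele.
#' @param gcMin,gcMax unpenalized GC-content window (fractions).
#' @return named list of constraints.
#' @export
markerConstraints <- function(primerLenMin = 18L, primerLenMax = 28L,
                              tmMin = 57, tmMax = 63,
                              productMin = 80L, productMax = 300L,
                              gcMin = 0.40, gcMax = 0.60) {
  stopifnot(primerLenMin >= 8L, primerLenMax >= primerLenMin,
            tmMax >= tmMin, productMax >= productMin)
  list(primerLenMin = as.integer(primerLenMin),
       primerLenMax = as.integer(primerLenMax),
       tmMin = tmMin, tmMax = tmMax,
       productMin = as.integer(productMin),
       productMax = as.integer(productMax),
       gcMin = gcMin, gcMax = gcMax)
}

#' Extract the design template around an InDel
#'
#' Returns the reference-strand sequence of \code{flankLen} bases upstream of
#' the anchor, the reference allele itself, and \code{flankLen} bases
#' downstream.  Flanks truncated by a chromosome end shorten the template
#' with a warning.
#'
#' @param genome named \code{DNAStringSet}.
#' @param indel a length-1 [IndelCallSet-class] or
#'   [CrossParentIndelSet-class] (the longer of the two parental reference
#'   alleles is used for the latter).
#' @param flankLen flank length in bases (default 150).
#' @return list with \code{template} (string), \code{upLen}, \code{refLen},
#'   \code{downLen}, \code{chrom}, \code{pos}.
#' @export
extractFlanks <- function(genome, indel, flankLen = 150L) {
  stopifnot(length(indel) == 1L)
  chrom <- as.character(seqnames(indel))
  if (!chrom %in% names(genome))
    stop("chromosome absent from genome: ", chrom)
  pos <- start(indel)
  mc <- mcols(indel)
  ref <- if (!is.null(mc$ref)) mc$ref else
    ifelse(nchar(mc$refA) >= nchar(mc$refB), mc$refA, mc$refB)
  seq <- as.character(genome[[chrom]])
  n <- nchar(seq)
  if (substr(seq, pos, pos + nchar(ref) - 1L) != ref)
    stop("reference allele mismatch at ", chrom, ":", pos)
  upStart <- pos - flankLen
  if (upStart < 1L) {
    warning("upstream flank truncated at start of ", chrom)
    upStart <- 1L
  }
  downEnd <- pos + nchar(ref) - 1L + flankLen
  if (downEnd > n) {
    warning("downstream flank truncated at end of ", chrom)
    downEnd <- n
  }
  up <- substr(seq, upStart, pos - 1L)
  down <- substr(seq, pos + nchar(ref), downEnd)
  list(template = paste0(up, ref, down),
       upLen = nchar(up), refLen = nchar(ref), downLen = nchar(down),
       chrom = chrom, pos = pos)
}

#' Design a primer pair on an InDel template
#'
#' Exhaustively scans candidate forward primers in the upstream flank and
#' reverse primers in the downstream flank (both strictly outside the InDel
#' allele), rejects pairs violating the length, Tm or reference-product
#' windows, and among survivors picks the pair minimizing
#' \code{|Tm_f - 60| + |Tm_r - 60| + |Tm_f - Tm_r|} plus one point per
#' primer with GC outside the configured window and one per homopolymer run
#' of 5+ bases.  Ties break deterministically by (smaller product, leftmost
#' forward start, lexicographic primer sequences), so the design is a pure
#' function of the template and constraints.
#'
#' @param flanks template description from [extractFlanks()].
#' @param constraints from [markerConstraints()].
#' @return list with \code{fwd}, \code{rev} (5'->3' sequences), \code{tmF},
#'   \code{tmR}, \code{productRef}, \code{fwdStart}, \code{revEnd} (template
#'   coordinates), or \code{NULL} when no pair satisfies the constraints.
#' @export
designPrimers <- function(flanks, constraints = markerConstraints()) {
  cn <- constraints
  up <- substr(flanks$template, 1L, flanks$upLen)
  down <- substr(flanks$template, flanks$upLen + flanks$refLen + 1L,
                 nchar(flanks$template))
  fwd <- .tmProfile(up, cn$primerLenMin, cn$primerLenMax)
  rev <- .tmProfile(down, cn$primerLenMin, cn$primerLenMax)
  fwd <- fwd[fwd$tm >= cn$tmMin & fwd$tm <= cn$tmMax, , drop = FALSE]
  rev <- rev[rev$tm >= cn$tmMin & rev$tm <= cn$tmMax, , drop = FALSE]
  if (nrow(fwd) == 0L || nrow(rev) == 0L) {
    message("designPrimers: no primer pair satisfies the constraints")
    return(NULL)
  }
  idx <- expand.grid(f = seq_len(nrow(fwd)), r = seq_len(nrow(rev)))
  revEndDown <- rev$start[idx$r] + rev$len[idx$r] - 1L
  product <- flanks$upLen + flanks$refLen + revEndDown - fwd$start[idx$f] + 1L
  keep <- product >= cn$productMin & product <= cn$productMax
  if (!any(keep)) {
    message("designPrimers: no primer pair satisfies the constraints")
    return(NULL)
  }
  idx <- idx[keep, , drop = FALSE]
  product <- product[keep]
  tmF <- fwd$tm[idx$f]; tmR <- rev$tm[idx$r]
  gcPen <- as.integer(fwd$gc[idx$f] < cn$gcMin | fwd$gc[idx$f] > cn$gcMax) +
    as.integer(rev$gc[idx$r] < cn$gcMin | rev$gc[idx$r] > cn$gcMax)
  score <- abs(tmF - 60) + abs(tmR - 60) + abs(tmF - tmR) +
    gcPen + fwd$runPenalty[idx$f] + rev$runPenalty[idx$r]
  fwdSeq <- substr(rep(up, nrow(idx)), fwd$start[idx$f],
                   fwd$start[idx$f] + fwd$len[idx$f] - 1L)
  revSite <- substr(rep(down, nrow(idx)), rev$start[idx$r],
                    rev$start[idx$r] + rev$len[idx$r] - 1L)
  o <- order(score, product, fwd$start[idx$f], fwdSeq, revSite,
             method = "radix")[1L]
  list(fwd = fwdSeq[o],
       rev = .revComp(revSite[o]),
       tmF = tmF[o], tmR = tmR[o],
       productRef = as.integer(product[o]),
       fwdStart = fwd$start[idx$f[o]],
       revEnd = flanks$upLen + flanks$refLen + rev$start[idx$r[o]] +
         rev$len[idx$r[o]] - 1L)
}

#' Predict an in-silico PCR product size
#'
#' Exact-string matching: the forward primer and the reverse complement of
#' the reverse primer must each bind exactly once in the subject, in
#' amplifiable orientation.  The product is the end-to-end distance inclusive
#' of both primers.
#'
#' @param fwd,rev primer sequences 5'->3'.
#' @param subject template sequence (one parental allele context).
#' @return product size in bp, or \code{NA} when either primer has zero or
#'   two or more binding sites, or the orientation cannot amplify.
#' @export
predictProductSize <- function(fwd, rev, subject) {
  fSites <- gregexpr(fwd, subject, fixed = TRUE)[[1L]]
  rSites <- gregexpr(.revComp(rev), subject, fixed = TRUE)[[1L]]
  if (fSites[1L] == -1L || length(fSites) != 1L) return(NA_integer_)
  if (rSites[1L] == -1L || length(rSites) != 1L) return(NA_integer_)
  rEnd <- rSites + nchar(rev) - 1L
  if (rSites <= fSites) return(NA_integer_)
  as.integer(rEnd - fSites + 1L)
}

#' Gel class of a marker
#'
#' Band-size differences greater than 30 bp resolve on standard agarose
#' gels; smaller differences need polyacrylamide.
#'
#' @param alleleSizeDiff absolute bp difference between the parental
#'   amplicons.
#' @return character vector over \code{"agarose"}, \code{"polyacrylamide"}.
#' @examples
#' assignGelClass(c(31, 30, 1))
#' @export
assignGelClass <- function(alleleSizeDiff) {
  ifelse(alleleSizeDiff > 30, "agarose", "polyacrylamide")
}

# parent-specific local sequence: substitute the parent's alt allele into the
# template whose central reference allele is refLong
.parentTemplate <- function(flanks, refParent, altParent) {
  up <- substr(flanks$template, 1L, flanks$upLen)
  down <- substr(flanks$template, flanks$upLen + flanks$refLen + 1L,
                 nchar(flanks$template))
  refLong <- substr(flanks$template, flanks$upLen + 1L,
                    flanks$upLen + flanks$refLen)
  # refParent is a prefix of refLong (shared anchor); keep the remainder
  local <- paste0(altParent, substr(refLong, nchar(refParent) + 1L,
                                    nchar(refLong)))
  paste0(up, local, down)
}

#' Design markers for a cross-parent InDel set
#'
#' Runs flank extraction, constrained primer design, per-parent in-silico
#' amplicon prediction and gel classification for every cross-parent InDel.
#' Loci where no primer pair satisfies the constraints are kept with empty
#' primer fields.
#'
#' @param crossParent a [CrossParentIndelSet-class].
#' @param genome named \code{DNAStringSet} reference.
#' @param flankLen flank length in bases (default 150).
#' @param constraints from [markerConstraints()].
#' @param idPrefix prefix for generated marker ids.
#' @return a [MarkerSet-class].
#' @export
designMarkers <- function(crossParent, genome, flankLen = 150L,
                          constraints = markerConstraints(),
                          idPrefix = "InDel") {
  n <- length(crossParent)
  o <- order(as.character(seqnames(crossParent)), start(crossParent),
             method = "radix")
  crossParent <- crossParent[o]
  mc <- mcols(crossParent)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    x <- crossParent[i]
    flanks <- extractFlanks(genome, x, flankLen)
    pr <- suppressMessages(designPrimers(flanks, constraints))
    seqA <- .parentTemplate(flanks, mc$refA[i], mc$altA[i])
    seqB <- .parentTemplate(flanks, mc$refB[i], mc$altB[i])
    pA <- pB <- NA_integer_
    if (!is.null(pr)) {
      pA <- predictProductSize(pr$fwd, pr$rev, seqA)
      pB <- predictProductSize(pr$fwd, pr$rev, seqB)
    }
    signedLen <- if (mc$carrier[i] == "B") mc$lengthB[i] else mc$lengthA[i]
    rows[[i]] <- data.frame(
      marker_id = sprintf("%s%03d", idPrefix, i),
      chrom = as.character(seqnames(x)),
      pos = start(x),
      indel_length = signedLen,
      allele_size_diff = mc$alleleSizeDiff[i],
      size_class = as.character(mc$sizeClass[i]),
      gel_class = assignGelClass(mc$alleleSizeDiff[i]),
      fwd_primer = if (is.null(pr)) "" else pr$fwd,
      rev_primer = if (is.null(pr)) "" else pr$rev,
      tm_fwd = if (is.null(pr)) NA_real_ else round(pr$tmF, 2L),
      tm_rev = if (is.null(pr)) NA_real_ else round(pr$tmR, 2L),
      product_ref = if (is.null(pr)) NA_integer_ else pr$productRef,
      product_A = pA,
      product_B = pB,
      template = flanks$template)
  }
  tab <- do.call(rbind, rows)
  nFail <- sum(!nzchar(tab$fwd_primer))
  if (nFail > 0L)
    message("designMarkers: no compliant primer pair for ", nFail,
            " of ", n, " loci")
  MarkerSet(tab)
}

#' Seeded random marker subsample
#'
#' Models cost-driven arbitrary selection of a fixed number of candidate
#' markers for experimental validation.
#'
#' @param markers a [MarkerSet-class].
#' @param n subsample size.
#' @param seed integer seed making the draw reproducible.
#' @return a [MarkerSet-class] with \code{n} markers in (chrom, pos) order.
#' @export
subsampleMarkers <- function(markers, n, seed) {
  tab <- markerTable(markers)
  if (n > nrow(tab)) stop("subsample larger than marker set")
  set.seed(seed)
  tab <- tab[sort(sample.int(nrow(tab), n)), , drop = FALSE]
  MarkerSet(tab)
}
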