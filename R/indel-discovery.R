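#' @importFrom S4Vectors metadata metadata<-
NULL

# Left-align + parsimony for a single call against the chromosome sequence
# (plain character).  Returns list(pos, ref, alt).
.normalizeOne <- function(seq, pos, ref, alt) {
  # trim shared suffix while both alleles keep >= 1 base
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  # shift left through repeat context
  repeat {
    if (nchar(ref) > 0L && nchar(alt) > 0L &&
        substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt)) &&
        (nchar(ref) > 1L || nchar(alt) > 1L)) {
      ref <- substr(ref, 1L, nchar(ref) - 1L)
      alt <- substr(alt, 1L, nchar(alt) - 1L)
    } else if (nchar(ref) == 0L || nchar(alt) == 0L) {
      if (pos <= 1L)
        stop("cannot left-align past the start of the chromosome")
      pos <- pos - 1L
      b <- substr(seq, pos, pos)
      ref <- paste0(b, ref)
      alt <- paste0(b, alt)
    } else {
      break
    }
  }
  # trim shared prefix down to the anchor base
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Normalize InDel calls to canonical left-aligned form
#'
#' Shifts each call left through its repeat context until no further shift is
#' possible and trims shared suffix/prefix bases down to the anchor base, so
#' that all equivalent representations of one event map to a single canonical
#' key (chrom, pos, ref, alt).  Idempotent.
#'
#' @param calls an [IndelCallSet-class].
#' @param genome named \code{DNAStringSet}; each call's reference allele must
#'   match the genome at its position.
#' @return the normalized [IndelCallSet-class], sorted.
#' @export
normalizeIndels <- function(calls, genome) {
  if (length(calls) == 0L) return(calls)
  chrom <- as.character(seqnames(calls))
  missingChrom <- setdiff(unique(chrom), names(genome))
  if (length(missingChrom))
    stop("chromosome(s) absent from genome: ",
         paste(missingChrom, collapse = ", "))
  seqs <- vapply(unique(chrom), function(cc) as.character(genome[[cc]]),
                 character(1))
  pos <- start(calls)
  ref <- mcols(calls)$ref
  alt <- mcols(calls)$alt
  for (i in seq_along(pos)) {
    s <- seqs[[chrom[i]]]
    if (substr(s, pos[i], pos[i] + nchar(ref[i]) - 1L) != ref[i])
      stop("reference allele mismatch at ", chrom[i], ":", pos[i])
    nm <- .normalizeOne(s, pos[i], ref[i], alt[i])
    pos[i] <- nm$pos; ref[i] <- nm$ref; alt[i] <- nm$alt
  }
  IndelCallSet(chrom, pos, ref, alt)
}

.callKeys <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Derive cross-parent polymorphic InDels
#'
#' Compares two parent-versus-reference call sets after normalization.  An
#' InDel whose canonical key (chrom, pos, ref, alt) occurs in exactly one
#' parent is polymorphic, with that parent as carrier: at its locus the other
#' parent is identical to the reference.  Identical InDels present in both
#' parents are shared, hence not polymorphic, and excluded.  Two different
#' InDel alleles at the same canonical anchor are kept as
#' \code{both_distinct} when their lengths differ (distinguishable band
#' sizes); same-length distinct alleles are size-monomorphic and dropped with
#' a message.
#'
#' @param callsA,callsB [IndelCallSet-class] objects called against
#'   \code{genome}.
#' @param genome named \code{DNAStringSet} reference.
#' @return a [CrossParentIndelSet-class] sorted by (chrom, pos, carrier,
#'   alt).
#' @export
deriveCrossParent <- function(callsA, callsB, genome) {
  nA <- normalizeIndels(callsA, genome)
  nB <- normalizeIndels(callsB, genome)
  dfOf <- function(x) {
    df <- data.frame(chrom = as.character(seqnames(x)), pos = start(x),
                     ref = mcols(x)$ref, alt = mcols(x)$alt)
    df$key <- .callKeys(df$chrom, df$pos, df$ref, df$alt)
    df[!duplicated(df$key), , drop = FALSE]
  }
  dA <- dfOf(nA); dB <- dfOf(nB)
  shared <- intersect(dA$key, dB$key)
  uA <- dA[!dA$key %in% shared, , drop = FALSE]
  uB <- dB[!dB$key %in% shared, , drop = FALSE]
  uA$anchor <- paste(uA$chrom, uA$pos, sep = ":")
  uB$anchor <- paste(uB$chrom, uB$pos, sep = ":")

  bothAnchors <- intersect(uA$anchor, uB$anchor)
  recs <- list()
  addRec <- function(chrom, pos, refA, altA, refB, altB, carrier) {
    lenA <- nchar(altA) - nchar(refA)
    lenB <- nchar(altB) - nchar(refB)
    diff <- abs(lenA - lenB)
    data.frame(chrom = chrom, pos = pos, refA = refA, altA = altA,
               refB = refB, altB = altB, carrier = carrier,
               lengthA = lenA, lengthB = lenB, alleleSizeDiff = diff)
  }
  onlyA <- uA[!uA$anchor %in% bothAnchors, , drop = FALSE]
  if (nrow(onlyA))
    recs[[length(recs) + 1L]] <- addRec(onlyA$chrom, onlyA$pos,
                                        onlyA$ref, onlyA$alt,
                                        onlyA$ref, onlyA$ref, "A")
  onlyB <- uB[!uB$anchor %in% bothAnchors, , drop = FALSE]
  if (nrow(onlyB))
    recs[[length(recs) + 1L]] <- addRec(onlyB$chrom, onlyB$pos,
                                        onlyB$ref, onlyB$ref,
                                        onlyB$ref, onlyB$alt, "B")
  dropped <- 0L
  for (anc in bothAnchors) {
    ra <- uA[uA$anchor == anc, , drop = FALSE]
    ra <- ra[order(ra$alt), , drop = FALSE][1L, , drop = FALSE]
    rb <- uB[uB$anchor == anc, , drop = FALSE]
    rb <- rb[order(rb$alt), , drop = FALSE][1L, , drop = FALSE]
    lenA <- nchar(ra$alt) - nchar(ra$ref)
    lenB <- nchar(rb$alt) - nchar(rb$ref)
    if (lenA == lenB) {
      dropped <- dropped + 1L
      next
    }
    recs[[length(recs) + 1L]] <- addRec(ra$chrom, ra$pos, ra$ref, ra$alt,
                                        rb$ref, rb$alt, "both_distinct")
  }
  if (dropped > 0L)
    message("deriveCrossParent: dropped ", dropped,
            " same-length distinct-allele anchor(s) (size-monomorphic)")
  tab <- if (length(recs)) do.call(rbind, recs) else
    data.frame(chrom = character(), pos = integer(), refA = character(),
               altA = character(), refB = character(), altB = character(),
               carrier = character(), lengthA = integer(),
               lengthB = integer(), alleleSizeDiff = integer())
  tab <- tab[order(tab$chrom, tab$pos, tab$carrier,
                   pmax(tab$altA, tab$altB), method = "radix"), , drop = FALSE]
  refLong <- ifelse(nchar(tab$refA) >= nchar(tab$refB), tab$refA, tab$refB)
  gr <- GRanges(tab$chrom, IRanges(tab$pos, width = nchar(refLong)))
  mcols(gr) <- DataFrame(refA = tab$refA, altA = tab$altA,
                         refB = tab$refB, altB = tab$altB,
                         carrier = tab$carrier,
                         lengthA = as.integer(tab$lengthA),
                         lengthB = as.integer(tab$lengthB),
                         alleleSizeDiff = as.integer(tab$alleleSizeDiff),
                         sizeClass = classifySize(pmax(tab$alleleSizeDiff, 1L)))
  new("CrossParentIndelSet", gr)
}

#' Classify InDels by size
#'
#' Bins the absolute event length into the standard size classes: small
#' (1-10 bp), medium (11-20 bp and 21-30 bp) and large (> 30 bp).
#'
#' @param length signed or absolute InDel lengths in bp; zero is an error.
#' @return factor with levels \code{small}, \code{medium_11_20},
#'   \code{medium_21_30}, \code{large}.
#' @examples
#' classifySize(c(-10, 30, 31))   # small, medium_21_30, large
#' @export
classifySize <- function(length) {
  a <- abs(as.numeric(length))
  if (any(a < 1)) stop("InDel length must be non-zero")
  cut(a, breaks = c(0, 10, 20, 30, Inf),
      labels = c("small", "medium_11_20", "medium_21_30", "large"))
}

#' InDel density per chromosome
#'
#' @param counts InDel counts (named by chromosome, or plain numeric).
#' @param lengthsMb chromosome lengths in megabase pairs.
#' @return density in InDels/Mb, rounded to 1 decimal.
#' @examples
#' indelDensity(10470, 210.99)   # 49.6
#' @export
indelDensity <- function(counts, lengthsMb) {
  if (any(lengthsMb <= 0)) stop("chromosome lengths must be positive")
  round(counts / lengthsMb, 1L)
}

#' Size-class accounting for a set of signed lengths
#'
#' @param lengths signed InDel lengths (bp difference; positive = insertion).
#' @return data.frame with rows small / medium_11_20 / medium_21_30 / large
#'   and columns deletion, insertion, total, percentage (of grand total, to 1
#'   decimal).  A \code{collapsed} attribute aggregates the two medium bins.
#' @export
sizeClassSummary <- function(lengths) {
  cls <- classifySize(lengths)
  isIns <- lengths > 0
  tab <- data.frame(
    size_class = levels(cls),
    deletion = as.integer(table(cls[!isIns])[levels(cls)]),
    insertion = as.integer(table(cls[isIns])[levels(cls)]))
  tab$deletion[is.na(tab$deletion)] <- 0L
  tab$insertion[is.na(tab$insertion)] <- 0L
  tab$total <- tab$deletion + tab$insertion
  tab$percentage <- round(100 * tab$total / sum(tab$total), 1L)
  med <- sum(tab$total[tab$size_class %in% c("medium_11_20", "medium_21_30")])
  collapsed <- data.frame(
    size_class = c("small", "medium", "large"),
    total = c(tab$total[tab$size_class == "small"], med,
              tab$total[tab$size_class == "large"]))
  collapsed$percentage <- round(100 * collapsed$total / sum(tab$total), 1L)
  attr(tab, "collapsed") <- collapsed
  tab
}

#' Summarize a cross-parent InDel set
#'
#' Produces the discovery accounting: per-chromosome counts and densities
#' (InDels/Mb) plus size-class counts split by insertion/deletion with
#' percentages of the total.
#'
#' @param crossParent a [CrossParentIndelSet-class].
#' @param lengths chromosome lengths in bp (named; e.g.
#'   [chromLengths()] or [readChromLengths()]).
#' @return list with elements \code{per_chrom} (chrom, count, length_mb,
#'   density), \code{size_class} (as [sizeClassSummary()]), \code{total}
#'   and \code{total_density}.
#' @export
discoverySummary <- function(crossParent, lengths) {
  if (length(crossParent) == 0L) stop("empty cross-parent set")
  chrom <- as.character(seqnames(crossParent))
  missingChrom <- setdiff(unique(chrom), names(lengths))
  if (length(missingChrom))
    stop("no length for chromosome(s): ", paste(missingChrom, collapse = ", "))
  lenMb <- lengths / 1e6
  counts <- table(factor(chrom, levels = names(lengths)))
  perChrom <- data.frame(chrom = names(lengths),
                         count = as.integer(counts),
                         length_mb = round(as.numeric(lenMb), 2L),
                         density = indelDensity(as.integer(counts),
                                                as.numeric(lenMb)))
  # sign of the band-size change: carrier allele length, or the longer of
  # the two distinct alleles
  mc <- mcols(crossParent)
  signedLen <- ifelse(mc$carrier == "B", mc$lengthB,
               ifelse(mc$carrier == "A", mc$lengthA,
                      ifelse(abs(mc$lengthA) >= abs(mc$lengthB),
                             mc$lengthA, mc$lengthB)))
  signedDiff <- sign(signedLen) * mc$alleleSizeDiff
  list(per_chrom = perChrom,
       size_class = sizeClassSummary(signedDiff),
       total = length(crossParent),
       total_density = indelDensity(length(crossParent), sum(as.numeric(lenMb))))
}
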