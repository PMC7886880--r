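#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges seqnames start width
#' @importFrom IRanges IRanges
NULL

.DNA_RE <- "^[ACGT]+$"

#' InDel call set
#'
#' A set of insertion/deletion calls against one reference genome, stored as a
#' \linkS4class{GRanges} whose range covers the reference allele.  Coordinates
#' are 1-based and follow the VCF anchor convention: \code{start()} is the
#' position of the base immediately preceding the event, and that base is the
#' first character of both alleles.  Metadata columns \code{ref} and
#' \code{alt} hold the allele strings; exactly one must be a strict prefix of
#' the other (pure InDels only, no complex substitutions).
#'
#' @slot . inherits all slots from \code{GRanges}.
#' @seealso [IndelCallSet()] for construction, [indelLength()] for signed
#'   event lengths, [readIndelCalls()] for import from VCF/TSV.
#' @export
setClass("IndelCallSet", contains = "GRanges")

.validIndelCallSet <- function(object) {
  mc <- mcols(object)
  if (!all(c("ref", "alt") %in% colnames(mc)))
    return("metadata columns 'ref' and 'alt' are required")
  ref <- as.character(mc$ref)
  alt <- as.character(mc$alt)
  if (length(ref) == 0L)
    return(TRUE)
  if (!all(grepl(.DNA_RE, ref)) || !all(grepl(.DNA_RE, alt)))
    return("alleles must be non-empty strings over A,C,G,T")
  nr <- nchar(ref); na <- nchar(alt)
  if (any(nr == na))
    return("ref and alt must differ in length (pure InDels only)")
  short <- ifelse(nr < na, ref, alt)
  long  <- ifelse(nr < na, alt, ref)
  if (!all(substr(long, 1L, nchar(short)) == short))
    return("one allele must be a strict prefix of the other")
  if (!all(width(object) == nr))
    return("range width must equal the reference allele length")
  if (any(start(object) < 1L))
    return("positions must be >= 1")
  TRUE
}
setValidity("IndelCallSet", .validIndelCallSet)

#' Construct an IndelCallSet
#'
#' @param chrom character vector of chromosome names.
#' @param pos 1-based anchor positions (base preceding the event).
#' @param ref,alt allele strings; one must be a strict prefix of the other.
#' @return An [IndelCallSet-class] object sorted by (chrom, pos, alt).
#' @examples
#' IndelCallSet("Chr1", 100, "A", "ATTG")   # a +3 insertion
#' @export
IndelCallSet <- function(chrom = character(), pos = integer(),
                         ref = character(), alt = character()) {
  gr <- GRanges(as.character(chrom),
                IRanges(as.integer(pos), width = nchar(as.character(ref))))
  mcols(gr) <- DataFrame(ref = as.character(ref), alt = as.character(alt))
  obj <- new("IndelCallSet", gr)
  sortIndelCalls(obj)
}

#' Cross-parent polymorphic InDel set
#'
#' InDels that distinguish two re-sequenced parents (A and B) called against
#' the same reference.  Each record carries the canonical (left-aligned)
#' anchor, the per-parent allele pair (a parent identical to the reference at
#' the anchor has \code{alt == ref} and length 0), the carrier label
#' (\code{"A"}, \code{"B"}, or \code{"both_distinct"} when the parents hold
#' two different InDel alleles at one anchor), the allele size difference in
#' bp between the parents' local alleles, and the size class of that
#' difference.
#'
#' @seealso [deriveCrossParent()], [carrier()], [alleleSizeDiff()],
#'   [sizeClass()].
#' @export
setClass("CrossParentIndelSet", contains = "GRanges")

.validCrossParent <- function(object) {
  mc <- mcols(object)
  need <- c("refA", "altA", "refB", "altB", "carrier",
            "lengthA", "lengthB", "alleleSizeDiff", "sizeClass")
  if (!all(need %in% colnames(mc)))
    return(paste("missing metadata columns:",
                 paste(setdiff(need, colnames(mc)), collapse = ", ")))
  if (length(object) == 0L)
    return(TRUE)
  if (!all(mc$carrier %in% c("A", "B", "both_distinct")))
    return("carrier must be one of A, B, both_distinct")
  if (any(mc$alleleSizeDiff < 1L))
    return("alleleSizeDiff must be >= 1")
  TRUE
}
setValidity("CrossParentIndelSet", .validCrossParent)

#' Co-dominant genotype matrix
#'
#' Lines-by-markers table of observed PCR band sizes.  Calls are serialized
#' as slash-joined sizes in bp: \code{"191"} for a homozygote (one band),
#' \code{"191/218"} for a heterozygote (two bands), \code{NA} for missing.
#'
#' @slot calls character matrix, rows = lines, columns = markers.
#' @seealso [GenotypeMatrix()], [alleleFrequencies()], [binarizeGenotypes()].
#' @export
setClass("GenotypeMatrix", representation(calls = "matrix"))

.parseCall <- function(x) {
  if (is.na(x) || !nzchar(x)) return(numeric(0))
  as.numeric(strsplit(x, "/", fixed = TRUE)[[1L]])
}

.validGenotypeMatrix <- function(object) {
  m <- object@calls
  if (!is.character(m))
    return("calls must be a character matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("calls must have line ids as rownames and marker ids as colnames")
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    return("line ids and marker ids must be unique")
  vals <- m[!is.na(m)]
  if (length(vals)) {
    parsed <- strsplit(vals, "/", fixed = TRUE)
    n <- lengths(parsed)
    if (any(n < 1L | n > 2L))
      return("each call must hold 1 or 2 allele sizes")
    if (any(vapply(parsed, function(p) anyNA(suppressWarnings(as.numeric(p))), logical(1))))
      return("allele sizes must be numeric")
    if (any(vapply(parsed, function(p) length(p) == 2L && p[1L] == p[2L], logical(1))))
      return("heterozygous calls must hold two distinct allele sizes")
  }
  TRUE
}
setValidity("GenotypeMatrix", .validGenotypeMatrix)

#' Construct a GenotypeMatrix
#'
#' @param calls character matrix of slash-joined band sizes
#'   (\code{"191/218"}), with line ids as rownames and marker ids as
#'   colnames.  \code{NA} marks a missing call.
#' @return A [GenotypeMatrix-class] object.
#' @examples
#' m <- matrix(c("191", "191/218", "218", NA), nrow = 2,
#'             dimnames = list(c("L1", "L2"), c("mk1", "mk2")))
#' GenotypeMatrix(m)
#' @export
GenotypeMatrix <- function(calls) {
  new("GenotypeMatrix", calls = calls)
}

#' Designed marker set
#'
#' Tabular container for marker candidates: one row per cross-parent InDel
#' with its design template, primer pair (when design succeeded), melting
#' temperatures, predicted per-parent amplicon sizes and gel class.
#'
#' @seealso [designMarkers()], [markerTable()], [writeMarkerTable()].
#' @export
setClass("MarkerSet", representation(table = "data.frame"))

.MARKER_COLS <- c("marker_id", "chrom", "pos", "indel_length",
                  "allele_size_diff", "size_class", "gel_class",
                  "fwd_primer", "rev_primer", "tm_fwd", "tm_rev",
                  "product_ref", "product_A", "product_B", "template")

.validMarkerSet <- function(object) {
  tab <- object@table
  if (!all(.MARKER_COLS %in% colnames(tab)))
    return(paste("missing marker columns:",
                 paste(setdiff(.MARKER_COLS, colnames(tab)), collapse = ", ")))
  if (anyDuplicated(tab$marker_id))
    return("marker ids must be unique")
  TRUE
}
setValidity("MarkerSet", .validMarkerSet)

MarkerSet <- function(table) new("MarkerSet", table = table)
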