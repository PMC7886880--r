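#' @include AllClasses.R
NULL

#' Signed InDel lengths
#'
#' Positive for insertions, negative for deletions; the magnitude is the
#' difference between alternative and reference allele lengths.
#'
#' @param x an [IndelCallSet-class].
#' @return integer vector.
#' @export
setGeneric("indelLength", function(x) standardGeneric("indelLength"))

#' @rdname indelLength
#' @export
setMethod("indelLength", "IndelCallSet", function(x) {
  as.integer(nchar(mcols(x)$alt) - nchar(mcols(x)$ref))
})

#' Carrier parent of cross-parent InDels
#'
#' @param x a [CrossParentIndelSet-class].
#' @return character vector over \code{"A"}, \code{"B"},
#'   \code{"both_distinct"}.
#' @export
setGeneric("carrier", function(x) standardGeneric("carrier"))

#' @rdname carrier
#' @export
setMethod("carrier", "CrossParentIndelSet", function(x) mcols(x)$carrier)

#' Allele size difference between parents
#'
#' The absolute bp difference between the two parents' local allele lengths
#' at a cross-parent InDel; this is the band-size difference a co-dominant
#' PCR marker at the locus will show.
#'
#' @param x a [CrossParentIndelSet-class].
#' @return integer vector, all values >= 1.
#' @export
setGeneric("alleleSizeDiff", function(x) standardGeneric("alleleSizeDiff"))

#' @rdname alleleSizeDiff
#' @export
setMethod("alleleSizeDiff", "CrossParentIndelSet",
          function(x) mcols(x)$alleleSizeDiff)

#' Size class of cross-parent InDels
#'
#' @param x a [CrossParentIndelSet-class].
#' @return factor with levels \code{small}, \code{medium_11_20},
#'   \code{medium_21_30}, \code{large}.
#' @seealso [classifySize()] for the binning rule.
#' @export
setGeneric("sizeClass", function(x) standardGeneric("sizeClass"))

#' @rdname sizeClass
#' @export
setMethod("sizeClass", "CrossParentIndelSet", function(x) mcols(x)$sizeClass)

#' Line and marker identifiers of a genotype matrix
#'
#' @param x a [GenotypeMatrix-class].
#' @return character vector of ids, in storage order.
#' @export
setGeneric("lineIds", function(x) standardGeneric("lineIds"))

#' @rdname lineIds
#' @export
setMethod("lineIds", "GenotypeMatrix", function(x) rownames(x@calls))

#' @rdname lineIds
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))

#' @rdname lineIds
#' @export
setMethod("markerIds", "GenotypeMatrix", function(x) colnames(x@calls))

#' Raw call matrix
#'
#' @param x a [GenotypeMatrix-class].
#' @return character matrix of slash-joined band sizes.
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))

#' @rdname genotypeCalls
#' @export
setMethod("genotypeCalls", "GenotypeMatrix", function(x) x@calls)

#' Marker table of a MarkerSet
#'
#' @param x a [MarkerSet-class].
#' @return data.frame with one row per marker candidate.
#' @export
setGeneric("markerTable", function(x) standardGeneric("markerTable"))

#' @rdname markerTable
#' @export
setMethod("markerTable", "MarkerSet", function(x) x@table)

setMethod("show", "IndelCallSet", function(object) {
  len <- indelLength(object)
  cat("IndelCallSet with", length(object), "calls (",
      sum(len > 0), "insertions,", sum(len < 0), "deletions )\n")
  if (length(object))
    callNextMethod()
})

setMethod("show", "CrossParentIndelSet", function(object) {
  cat("CrossParentIndelSet with", length(object), "cross-parent InDels\n")
  if (length(object)) {
    print(table(carrier = carrier(object)))
    callNextMethod()
  }
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@calls), "lines x",
      ncol(object@calls), "markers;",
      sum(is.na(object@calls)), "missing calls\n")
})

setMethod("show", "MarkerSet", function(object) {
  tab <- object@table
  cat("MarkerSet with", nrow(tab), "marker candidates;",
      sum(nzchar(tab$fwd_primer)), "with designed primers;",
      sum(tab$gel_class == "agarose"), "agarose-class\n")
})
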