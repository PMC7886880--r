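#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAStringSet
#'   letterFrequency
#' @importFrom utils read.delim write.table
NULL

#' Read a reference genome from FASTA
#'
#' Sequence names are taken from the first whitespace-delimited token of each
#' header; sequences are stored uppercase.  Only A, C, G, T and N are
#' accepted.
#'
#' @param path FASTA file.
#' @return A named \code{DNAStringSet}; chromosome lengths are available via
#'   [chromLengths()].
#' @export
readReferenceFasta <- function(path) {
  seqs <- readDNAStringSet(path)
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(names(seqs)))
    stop("duplicate chromosome name in FASTA: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  if (any(width(seqs) == 0L))
    stop("empty FASTA record: ",
         paste(names(seqs)[width(seqs) == 0L], collapse = ", "))
  bad <- rowSums(letterFrequency(seqs, c("A", "C", "G", "T", "N"))) != width(seqs)
  if (any(bad))
    stop("non-ACGTN characters in sequence(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  seqs
}

#' Chromosome lengths of a genome
#'
#' @param genome a named \code{DNAStringSet} as returned by
#'   [readReferenceFasta()].
#' @param mb return lengths in megabase pairs instead of bp.
#' @return named numeric vector.
#' @export
chromLengths <- function(genome, mb = FALSE) {
  len <- stats::setNames(as.numeric(width(genome)), names(genome))
  if (mb) len / 1e6 else len
}

#' Read a chromosome length table
#'
#' Two-column tab-separated file (chromosome name, length in bp) so that
#' density accounting can run without a genome in memory.
#'
#' @param path TSV file without header.
#' @return named numeric vector of lengths in bp.
#' @export
readChromLengths <- function(path) {
  tab <- read.delim(path, header = FALSE, col.names = c("chrom", "length"),
                    colClasses = c("character", "numeric"))
  if (any(tab$length <= 0)) stop("chromosome lengths must be positive")
  stats::setNames(tab$length, tab$chrom)
}

.isPureIndel <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  if (nr == na) return(FALSE)
  if (!grepl(.DNA_RE, ref) || !grepl(.DNA_RE, alt)) return(FALSE)
  short <- if (nr < na) ref else alt
  long <- if (nr < na) alt else ref
  substr(long, 1L, nchar(short)) == short
}

#' Read InDel calls from VCF or a tab-separated call table
#'
#' Only pure InDel alleles are retained: records where one allele is a strict
#' prefix of the other.  SNVs and complex substitutions are skipped and
#' counted; pure-InDel alleles of multi-allelic VCF records are expanded into
#' separate calls.  Genotype and INFO columns are ignored.
#'
#' @param path input file.
#' @param dialect \code{"vcf"} (columns CHROM, POS, REF, ALT of a VCF 4.x
#'   body) or \code{"tsv"} (headered columns chrom, pos, ref, alt).
#' @return An [IndelCallSet-class], sorted by (chrom, pos, alt), with the
#'   number of skipped non-InDel alleles in \code{metadata()$skipped}.
#' @export
readIndelCalls <- function(path, dialect = c("vcf", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "vcf") {
    lines <- readLines(path)
    keep <- !startsWith(lines, "#") & nzchar(lines)
    lineno <- which(keep)
    if (!length(lineno))
      return(IndelCallSet())
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    if (any(lengths(fields) < 5L))
      stop("malformed VCF record at line ",
           lineno[which(lengths(fields) < 5L)[1L]])
    chrom <- vapply(fields, `[`, character(1), 1L)
    posStr <- vapply(fields, `[`, character(1), 2L)
    ref <- toupper(vapply(fields, `[`, character(1), 4L))
    altStr <- toupper(vapply(fields, `[`, character(1), 5L))
    alts <- strsplit(altStr, ",", fixed = TRUE)
  } else {
    tab <- read.delim(path, header = TRUE, colClasses = "character")
    names(tab) <- tolower(names(tab))
    need <- c("chrom", "pos", "ref", "alt")
    if (!all(need %in% names(tab)))
      stop("call table must have columns chrom, pos, ref, alt")
    chrom <- tab$chrom
    posStr <- tab$pos
    ref <- toupper(tab$ref)
    alts <- strsplit(toupper(tab$alt), ",", fixed = TRUE)
    lineno <- seq_along(chrom) + 1L
  }
  pos <- suppressWarnings(as.integer(posStr))
  bad <- is.na(pos) | pos < 1L
  if (any(bad))
    stop("malformed coordinate '", posStr[which(bad)[1L]],
         "' at line ", lineno[which(bad)[1L]])
  outChrom <- character(0); outPos <- integer(0)
  outRef <- character(0); outAlt <- character(0)
  skipped <- 0L
  for (i in seq_along(chrom)) {
    for (a in alts[[i]]) {
      if (.isPureIndel(ref[i], a)) {
        outChrom <- c(outChrom, chrom[i])
        outPos <- c(outPos, pos[i])
        outRef <- c(outRef, ref[i])
        outAlt <- c(outAlt, a)
      } else {
        skipped <- skipped + 1L
      }
    }
  }
  res <- IndelCallSet(outChrom, outPos, outRef, outAlt)
  S4Vectors::metadata(res)$skipped <- skipped
  if (skipped > 0L)
    message("readIndelCalls: skipped ", skipped, " non-InDel allele(s)")
  res
}

#' Write InDel calls as a tab-separated call table
#'
#' @param calls an [IndelCallSet-class].
#' @param path output file; columns chrom, pos, ref, alt.
#' @export
writeIndelCalls <- function(calls, path) {
  tab <- data.frame(chrom = as.character(seqnames(calls)),
                    pos = start(calls),
                    ref = mcols(calls)$ref,
                    alt = mcols(calls)$alt)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sort InDel calls deterministically
#'
#' Orders by (chrom, pos, alt allele); keeps output files and derived sets
#' independent of input row order.
#'
#' @param calls an [IndelCallSet-class].
#' @return the sorted set.
#' @export
sortIndelCalls <- function(calls) {
  o <- order(as.character(seqnames(calls)), start(calls), mcols(calls)$alt,
             method = "radix")
  calls[o]
}

#' Write a marker table
#'
#' One row per marker candidate, sorted by (chrom, pos).  Markers without
#' designed primers are written with empty primer/product fields and a
#' warning.
#'
#' @param markers a [MarkerSet-class].
#' @param path output TSV.
#' @export
writeMarkerTable <- function(markers, path) {
  tab <- markerTable(markers)
  if (nrow(tab) == 0L) stop("no markers to write")
  tab <- tab[order(tab$chrom, tab$pos, method = "radix"), .MARKER_COLS]
  tab$template <- NULL
  n_undesigned <- sum(!nzchar(tab$fwd_primer))
  if (n_undesigned > 0L)
    warning(n_undesigned, " marker(s) without designed primers written with empty primer fields")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a marker table written by [writeMarkerTable()]
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
readMarkerTable <- function(path) {
  read.delim(path, header = TRUE,
             colClasses = c(marker_id = "character", chrom = "character",
                            fwd_primer = "character", rev_primer = "character"))
}

#' Read a co-dominant genotype matrix
#'
#' First column holds line ids; remaining columns are markers.  Calls are
#' slash-joined band sizes (\code{"191/218"}); the missing token is
#' \code{"NA"}.
#'
#' @param path CSV or TSV file (separator chosen by extension, \code{.csv}
#'   vs anything else).
#' @return a [GenotypeMatrix-class].
#' @export
readGenotypeMatrix <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- read.delim(path, header = TRUE, sep = sep, colClasses = "character",
                    check.names = FALSE, na.strings = "NA")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  GenotypeMatrix(m)
}

#' Write a co-dominant genotype matrix
#'
#' @param gm a [GenotypeMatrix-class].
#' @param path output file; CSV when the extension is \code{.csv}, else TSV.
#' @export
writeGenotypeMatrix <- function(gm, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- data.frame(line_id = lineIds(gm), genotypeCalls(gm),
                    check.names = FALSE)
  write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a tree in Newick format
#'
#' Leaf labels are line ids verbatim; branch lengths are kept.
#'
#' @param tree an \code{ape} \code{phylo} object (e.g. from [upgmaTree()]).
#' @param path output file.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path Newick file.
#' @return an \code{ape} \code{phylo} object.
#' @export
readNewick <- function(path) {
  ape::read.tree(path)
}
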