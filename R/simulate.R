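#' @importFrom Biostrings replaceAt
NULL

# Empirical defaults for the planted size mixture and insertion share,
# matching the size-class accounting of a genome-wide cucumber parent pair
# (small 1-10, medium 11-20 / 21-30, large > 30).
.SIZE_PROPS <- c(small = 5683, medium_11_20 = 2758,
                 medium_21_30 = 940, large = 1171) / 10552
.INS_FRAC <- 5208 / 10552

#' Simulate a reference genome
#'
#' Chromosomes of i.i.d. bases at a configured GC fraction; fully
#' reproducible from the seed.
#'
#' @param nChrom number of chromosomes (named Chr1, Chr2, ...).
#' @param chromLength length(s) in bp, recycled over chromosomes.
#' @param gc GC fraction.
#' @param seed integer seed; \code{NULL} uses the current RNG state.
#' @return named \code{DNAStringSet}.
#' @export
simulateReference <- function(nChrom = 7L, chromLength = 1e5, gc = 0.4,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lens <- as.integer(rep_len(chromLength, nChrom))
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seqs <- vapply(lens, function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
          collapse = ""), character(1))
  names(seqs) <- paste0("Chr", seq_len(nChrom))
  DNAStringSet(seqs)
}

# shifted (non-canonical but equivalent) representation of a canonical
# event, anchored j bases into its downstream repeat run
.shiftRepresentation <- function(seq, pos, ref, alt, j) {
  if (j == 0L)
    return(list(pos = pos, ref = ref, alt = alt))
  ins <- nchar(alt) > nchar(ref)
  s <- abs(nchar(alt) - nchar(ref))
  p2 <- pos + j
  anchor <- substr(seq, p2, p2)
  unit <- if (ins) substr(alt, 2L, nchar(alt)) else substr(ref, 2L, nchar(ref))
  if (ins) list(pos = p2, ref = anchor, alt = paste0(anchor, unit))
  else list(pos = p2, ref = paste0(anchor, unit), alt = anchor)
}

#' Plant InDels into two parental copies of a reference genome
#'
#' Generates parent-unique and shared InDel events with known ground truth:
#' A-only events mutate only parent A, B-only only parent B, shared events
#' mutate both identically.  Event sizes are drawn from a size-class mixture
#' (uniform within class, the large class uniform on 31-60 bp); a
#' configurable fraction of events is placed as homopolymer
#' insertions/deletions inside repeat tracts, and those events are exported
#' in the call sets at randomized (equivalent, right-shifted) anchors to
#' exercise normalization.  Events are spaced so that flank extraction and
#' primer design never straddle two events.
#'
#' @param genome named \code{DNAStringSet} reference.
#' @param nA,nB,nShared event counts per carrier category.
#' @param sizeProps mixture proportions over the four size classes (must sum
#'   to 1); defaults follow the empirical genome-wide accounting.
#' @param insFrac insertion share of events.
#' @param minSpacing minimum distance between planted anchors in bp
#'   (default 200).
#' @param repeatFrac fraction of events planted in repeat context.
#' @param seed integer seed; \code{NULL} uses the current RNG state.
#' @return list with \code{parentA}, \code{parentB} (\code{DNAStringSet}),
#'   \code{truth} (data.frame: chrom, pos, ref, alt, length, category,
#'   repeat_context — canonical representations), and \code{callsA},
#'   \code{callsB} ([IndelCallSet-class] parent-vs-reference call sets, with
#'   randomized anchors for repeat-context events).
#' @export
plantIndels <- function(genome, nA = 100L, nB = 50L, nShared = 25L,
                        sizeProps = .SIZE_PROPS, insFrac = .INS_FRAC,
                        minSpacing = 200L, repeatFrac = 0.1,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(abs(sum(sizeProps) - 1) < 1e-8, minSpacing >= 1L)
  nTotal <- nA + nB + nShared
  pad <- 300L
  chromSeqs <- vapply(names(genome), function(cc) as.character(genome[[cc]]),
                      character(1))
  slotList <- lapply(chromSeqs, function(s) {
    n <- nchar(s)
    if (n < 2L * pad + minSpacing) integer(0) else
      seq.int(pad, n - pad, by = minSpacing)
  })
  nSlots <- lengths(slotList)
  if (sum(nSlots) < nTotal)
    stop("infeasible packing: ", nTotal, " events requested but only ",
         sum(nSlots), " slots at spacing ", minSpacing)
  chromPick <- sample(rep(names(genome), nSlots), nTotal)
  events <- vector("list", nTotal)
  used <- lapply(slotList, function(x) integer(0))
  category <- sample(rep(c("A_only", "B_only", "shared"),
                         c(nA, nB, nShared)))
  ranges <- list(small = 1:10, medium_11_20 = 11:20,
                 medium_21_30 = 21:30, large = 31:60)
  for (i in seq_len(nTotal)) {
    cc <- chromPick[i]
    free <- setdiff(slotList[[cc]], used[[cc]])
    pos0 <- if (length(free) == 1L) free else sample(free, 1L)
    used[[cc]] <- c(used[[cc]], pos0)
    seq <- chromSeqs[[cc]]
    cls <- sample(names(sizeProps), 1L, prob = sizeProps)
    sz <- sample(ranges[[cls]], 1L)
    ins <- stats::runif(1) < insFrac
    inRepeat <- stats::runif(1) < repeatFrac
    anchorBase <- substr(seq, pos0, pos0)
    if (inRepeat) {
      b <- substr(seq, pos0 + 1L, pos0 + 1L)
      r <- 1L
      while (substr(seq, pos0 + r + 1L, pos0 + r + 1L) == b) r <- r + 1L
      # a deletion must fit inside the run; fall back to plain placement
      # so the insertion:deletion ratio stays at its configuration
      if (!ins && r < sz) inRepeat <- FALSE
    }
    if (inRepeat) {
      if (ins) {
        ref <- anchorBase
        alt <- paste0(anchorBase, strrep(b, sz))
      } else {
        ref <- paste0(anchorBase, strrep(b, sz))
        alt <- anchorBase
      }
    } else if (ins) {
      insSeq <- paste(sample(c("A", "C", "G", "T"), sz, replace = TRUE),
                      collapse = "")
      ref <- anchorBase
      alt <- paste0(anchorBase, insSeq)
    } else {
      ref <- substr(seq, pos0, pos0 + sz)
      alt <- anchorBase
    }
    nm <- .normalizeOne(seq, pos0, ref, alt)
    events[[i]] <- data.frame(chrom = cc, pos = nm$pos, ref = nm$ref,
                              alt = nm$alt,
                              length = nchar(nm$alt) - nchar(nm$ref),
                              category = category[i],
                              repeat_context = inRepeat)
  }
  truth <- do.call(rbind, events)
  truth <- truth[order(truth$chrom, truth$pos, method = "radix"), ,
                 drop = FALSE]
  rownames(truth) <- NULL

  exportCalls <- function(rows) {
    out <- vector("list", nrow(rows))
    for (i in seq_len(nrow(rows))) {
      e <- rows[i, ]
      j <- 0L
      if (e$repeat_context) {
        seq <- chromSeqs[[e$chrom]]
        s <- abs(e$length)
        unitBase <- if (e$length > 0)
          substr(e$alt, 2L, 2L) else substr(e$ref, 2L, 2L)
        r2 <- 0L
        while (substr(seq, e$pos + r2 + 1L, e$pos + r2 + 1L) == unitBase)
          r2 <- r2 + 1L
        jmax <- if (e$length > 0) r2 else max(r2 - s, 0L)
        if (jmax > 0L) j <- sample.int(min(jmax, 10L) + 1L, 1L) - 1L
      }
      sh <- .shiftRepresentation(chromSeqs[[e$chrom]], e$pos, e$ref, e$alt, j)
      out[[i]] <- data.frame(chrom = e$chrom, pos = sh$pos,
                             ref = sh$ref, alt = sh$alt)
    }
    tab <- do.call(rbind, out)
    IndelCallSet(tab$chrom, tab$pos, tab$ref, tab$alt)
  }
  rowsA <- truth[truth$category %in% c("A_only", "shared"), , drop = FALSE]
  rowsB <- truth[truth$category %in% c("B_only", "shared"), , drop = FALSE]

  applyEvents <- function(rows) {
    seqs <- genome
    for (cc in names(genome)) {
      sub <- rows[rows$chrom == cc, , drop = FALSE]
      if (!nrow(sub)) next
      seqs[[cc]] <- replaceAt(genome[[cc]],
                              IRanges(sub$pos, width = nchar(sub$ref)),
                              DNAStringSet(sub$alt))
    }
    seqs
  }
  list(parentA = applyEvents(rowsA),
       parentB = applyEvents(rowsB),
       truth = truth,
       callsA = exportCalls(rowsA),
       callsB = exportCalls(rowsB))
}

#' Simulate a co-dominant genotype panel
#'
#' Draws breeding lines as inbreds (homozygous) by default, with an optional
#' heterozygosity rate and optional two-group structure where a subset of
#' markers is fixed for alternate alleles between the groups (mimicking
#' group-specific markers).
#'
#' @param nLines number of lines (ids L01, L02, ...).
#' @param markerFreqs named list; one named numeric vector of allele
#'   frequencies per marker (names = allele sizes in bp).
#' @param hetRate probability that a line is heterozygous at a marker
#'   (two distinct alleles drawn without replacement).
#' @param groups optional list with \code{assignment} (vector of 1/2 per
#'   line) and \code{fixedMarkers} (marker names fixed for the first allele
#'   in group 1 and the second allele in group 2).
#' @param seed integer seed; \code{NULL} uses the current RNG state.
#' @return a [GenotypeMatrix-class].
#' @export
simulateGenotypeMatrix <- function(nLines, markerFreqs, hetRate = 0,
                                   groups = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("L%02d", seq_len(nLines))
  mk <- names(markerFreqs)
  calls <- matrix(NA_character_, nLines, length(mk),
                  dimnames = list(ids, mk))
  for (m in mk) {
    p <- markerFreqs[[m]]
    stopifnot(abs(sum(p) - 1) < 1e-8)
    fixed <- !is.null(groups) && m %in% groups$fixedMarkers
    for (i in seq_len(nLines)) {
      if (fixed) {
        g <- groups$assignment[i]
        calls[i, m] <- names(p)[min(g, length(p))]
      } else if (length(p) >= 2L && stats::runif(1) < hetRate) {
        a <- sample(names(p), 2L, prob = p)
        calls[i, m] <- paste(sort(as.numeric(a)), collapse = "/")
      } else {
        calls[i, m] <- sample(names(p), 1L, prob = p)
      }
    }
  }
  GenotypeMatrix(calls)
}

#' Simulate an F1 seed lot for purity testing
#'
#' Produces per-seedling co-dominant calls at one marker with known class
#' labels: true hybrids show both parental bands, selfed seedlings a single
#' parental band, off-types a foreign band, and a configurable fraction is
#' missing.  Class counts are exact (rounded from the fractions) and the
#' seedling order is shuffled.
#'
#' @param femaleAllele,maleAllele parental band sizes in bp.
#' @param n batch size.
#' @param hybridFraction fraction of true hybrids.
#' @param contamFractions named fractions for \code{selfed_male} and
#'   \code{off_type}; together with \code{hybridFraction} and
#'   \code{missingRate} they must not exceed 1, and the remainder is
#'   selfed females (the dominant contaminant in practice).
#' @param missingRate fraction of failed (missing) calls.
#' @param offAllele band size of off-type seedlings (default: 25 bp above
#'   the larger parental band).
#' @param seed integer seed; \code{NULL} uses the current RNG state.
#' @return list with \code{calls} (character vector of slash-joined sizes)
#'   and \code{truth} (class labels).
#' @export
simulateF1Batch <- function(femaleAllele, maleAllele, n,
                            hybridFraction = 0.9,
                            contamFractions = c(selfed_male = 0, off_type = 0),
                            missingRate = 0, offAllele = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fSelfM <- if ("selfed_male" %in% names(contamFractions))
    contamFractions[["selfed_male"]] else 0
  fOff <- if ("off_type" %in% names(contamFractions))
    contamFractions[["off_type"]] else 0
  if (hybridFraction + fSelfM + fOff + missingRate > 1 + 1e-9)
    stop("class fractions exceed 1")
  nH <- round(n * hybridFraction)
  nSM <- round(n * fSelfM)
  nOff <- round(n * fOff)
  nMiss <- round(n * missingRate)
  nSF <- n - nH - nSM - nOff - nMiss
  if (nSF < 0L) stop("class fractions exceed 1 after rounding")
  if (is.null(offAllele)) offAllele <- max(femaleAllele, maleAllele) + 25
  truth <- sample(rep(c("true_hybrid", "selfed_female", "selfed_male",
                        "off_type", "missing"),
                      c(nH, nSF, nSM, nOff, nMiss)))
  hybridCall <- paste(sort(c(femaleAllele, maleAllele)), collapse = "/")
  calls <- c(true_hybrid = hybridCall,
             selfed_female = as.character(femaleAllele),
             selfed_male = as.character(maleAllele),
             off_type = as.character(offAllele),
             missing = NA_character_)[truth]
  list(calls = unname(calls), truth = truth)
}
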