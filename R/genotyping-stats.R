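#' Allele frequencies at one marker
#'
#' Each observed band contributes per allele copy: a homozygote (one band)
#' counts two copies of its allele, a heterozygote one copy of each.
#' Missing calls are excluded from the denominator.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param marker marker id.
#' @return named numeric vector of frequencies (names = allele sizes),
#'   sorted by decreasing frequency then allele size; sums to 1.
#' @export
alleleFrequencies <- function(gm, marker) {
  calls <- genotypeCalls(gm)[, marker]
  parsed <- lapply(calls, .parseCall)
  parsed <- parsed[lengths(parsed) > 0L]
  if (!length(parsed))
    stop("marker ", marker, " has no non-missing calls")
  copies <- unlist(lapply(parsed, function(a)
    if (length(a) == 1L) c(a, a) else a))
  tab <- table(copies)
  p <- as.numeric(tab) / sum(tab)
  names(p) <- names(tab)
  p[order(-p, as.numeric(names(p)))]
}

#' Gene diversity (expected heterozygosity)
#'
#' \code{1 - sum(p_i^2)}, without small-sample correction.
#'
#' @param freqs allele frequency vector summing to 1.
#' @return value in [0, 1).
#' @examples
#' geneDiversity(c(0.5, 0.5))   # 0.5
#' @export
geneDiversity <- function(freqs) {
  stopifnot(abs(sum(freqs) - 1) < 1e-8)
  1 - sum(freqs^2)
}

#' Polymorphism information content (Botstein)
#'
#' \code{PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2}.
#'
#' @param freqs allele frequency vector summing to 1.
#' @return value in [0, 1).
#' @examples
#' picValue(c(0.5, 0.5))   # 0.375
#' @export
picValue <- function(freqs) {
  stopifnot(abs(sum(freqs) - 1) < 1e-8)
  s2 <- sum(freqs^2)
  s4 <- sum(freqs^4)
  1 - s2 - (s2^2 - s4)
}

#' Observed heterozygosity at one marker
#'
#' Fraction of non-missing lines whose call shows two distinct bands.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param marker marker id.
#' @return value in [0, 1].
#' @export
observedHeterozygosity <- function(gm, marker) {
  calls <- genotypeCalls(gm)[, marker]
  parsed <- lapply(calls, .parseCall)
  n <- lengths(parsed)
  if (!any(n > 0L))
    stop("marker ", marker, " has no non-missing calls")
  sum(n == 2L) / sum(n > 0L)
}

#' Per-marker summary statistics and panel averages
#'
#' @param gm a [GenotypeMatrix-class] with at least one marker.
#' @return list with \code{markers} (data.frame: marker_id, allele_count,
#'   major_allele_freq, gene_diversity, observed_heterozygosity, pic) and
#'   \code{means} (arithmetic means of those statistics over markers).
#' @export
panelSummary <- function(gm) {
  ids <- markerIds(gm)
  if (!length(ids)) stop("genotype matrix has no markers")
  rows <- lapply(ids, function(mk) {
    p <- alleleFrequencies(gm, mk)
    data.frame(marker_id = mk,
               allele_count = length(p),
               major_allele_freq = max(p),
               gene_diversity = geneDiversity(p),
               observed_heterozygosity = observedHeterozygosity(gm, mk),
               pic = picValue(p))
  })
  tab <- do.call(rbind, rows)
  list(markers = tab,
       means = colMeans(tab[, -1L, drop = FALSE]))
}

# within-line allele frequency vector at one locus: 1 for a homozygote,
# 0.5/0.5 for a heterozygote; NULL when missing
.lineFreqs <- function(call) {
  a <- .parseCall(call)
  if (!length(a)) return(NULL)
  if (length(a) == 1L) stats::setNames(1, a) else
    stats::setNames(c(0.5, 0.5), a)
}

#' Nei's minimum genetic distance between two lines
#'
#' Per shared non-missing locus, with x and y the within-line allele
#' frequency vectors, the locus term is
#' \code{(sum(x^2) + sum(y^2)) / 2 - sum(x * y)} (identity sums over the
#' union of alleles); the distance is the mean locus term over shared loci.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param lineX,lineY line ids.
#' @return distance >= 0; 0 iff the two lines have identical allele profiles
#'   at every shared locus.
#' @export
neiMinimumDistance <- function(gm, lineX, lineY) {
  cx <- genotypeCalls(gm)[lineX, ]
  cy <- genotypeCalls(gm)[lineY, ]
  terms <- numeric(0)
  for (k in seq_along(cx)) {
    x <- .lineFreqs(cx[k]); y <- .lineFreqs(cy[k])
    if (is.null(x) || is.null(y)) next
    alleles <- union(names(x), names(y))
    xv <- ifelse(alleles %in% names(x), x[alleles], 0)
    yv <- ifelse(alleles %in% names(y), y[alleles], 0)
    terms <- c(terms, (sum(xv^2) + sum(yv^2)) / 2 - sum(xv * yv))
  }
  if (!length(terms))
    stop("lines ", lineX, " and ", lineY, " share no non-missing loci")
  mean(terms)
}

#' Pairwise Nei minimum distance matrix
#'
#' @param gm a [GenotypeMatrix-class].
#' @return symmetric matrix with zero diagonal, dimnames = line ids.
#' @export
neiDistanceMatrix <- function(gm) {
  ids <- lineIds(gm)
  d <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids))
    for (j in seq_len(i - 1L)) {
      d[i, j] <- d[j, i] <- neiMinimumDistance(gm, ids[i], ids[j])
    }
  d
}

#' UPGMA clustering of a distance matrix
#'
#' Iteratively merges the closest pair of clusters; the merged node sits at
#' height d/2 and distances to the new cluster are size-weighted arithmetic
#' averages.  Ties are broken by the lexicographically smallest combined
#' member-label set, so the tree is reproducible and invariant to input
#' order.  The result is ultrametric: all leaves are equidistant from the
#' root.
#'
#' @param d symmetric distance matrix with dimnames (or a \code{dist}).
#' @return an \code{ape} \code{phylo} object with node heights encoded in
#'   the branch lengths.
#' @export
upgmaTree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (anyNA(d)) stop("distance matrix contains NA/NaN")
  ids <- rownames(d)
  n <- length(ids)
  stopifnot(n >= 2L, identical(rownames(d), colnames(d)))
  active <- seq_len(n)
  members <- as.list(ids)
  newick <- ids
  heights <- rep(0, n)
  sizes <- rep(1L, n)
  dm <- d
  repeat {
    k <- length(active)
    if (k == 1L) break
    best <- NULL; bestD <- Inf; bestKey <- NULL
    for (ii in seq_len(k - 1L)) for (jj in (ii + 1L):k) {
      a <- active[ii]; b <- active[jj]
      dv <- dm[a, b]
      key <- paste(sort(c(members[[a]], members[[b]])), collapse = "\r")
      if (dv < bestD - 1e-12 ||
          (abs(dv - bestD) <= 1e-12 && key < bestKey)) {
        bestD <- dv; best <- c(a, b); bestKey <- key
      }
    }
    a <- best[1L]; b <- best[2L]
    h <- bestD / 2
    newIdx <- length(members) + 1L
    members[[newIdx]] <- c(members[[a]], members[[b]])
    sizes[newIdx] <- sizes[a] + sizes[b]
    heights[newIdx] <- h
    newick[newIdx] <- sprintf("(%s:%.10g,%s:%.10g)",
                              newick[a], h - heights[a],
                              newick[b], h - heights[b])
    rest <- setdiff(active, c(a, b))
    dm <- rbind(cbind(dm, 0), 0)
    for (x in rest)
      dm[newIdx, x] <- dm[x, newIdx] <-
        (sizes[a] * dm[a, x] + sizes[b] * dm[b, x]) / (sizes[a] + sizes[b])
    active <- c(rest, newIdx)
  }
  ape::read.tree(text = paste0(newick[active], ";"))
}

#' Binarize a co-dominant genotype matrix
#'
#' One 0/1 column per (marker, allele size) pair; 1 iff the line shows that
#' band, NA for missing calls.
#'
#' @param gm a [GenotypeMatrix-class].
#' @return integer matrix, column names \code{"marker.size"}.
#' @seealso [debinarizeGenotypes()] for the inverse transform.
#' @export
binarizeGenotypes <- function(gm) {
  calls <- genotypeCalls(gm)
  cols <- list()
  for (mk in colnames(calls)) {
    sizes <- sort(unique(unlist(lapply(calls[, mk], .parseCall))))
    for (s in sizes) {
      v <- vapply(calls[, mk], function(x) {
        a <- .parseCall(x)
        if (!length(a)) NA_integer_ else as.integer(s %in% a)
      }, integer(1))
      cols[[paste(mk, s, sep = ".")]] <- v
    }
  }
  out <- do.call(cbind, cols)
  rownames(out) <- rownames(calls)
  out
}

#' Reconstruct a co-dominant matrix from allele-presence codes
#'
#' Inverse of [binarizeGenotypes()]: columns named \code{"marker.size"} are
#' regrouped per marker and the 1-coded sizes become the line's band set.
#'
#' @param bin 0/1 matrix from [binarizeGenotypes()].
#' @return a [GenotypeMatrix-class].
#' @export
debinarizeGenotypes <- function(bin) {
  parts <- strsplit(colnames(bin), ".", fixed = TRUE)
  mk <- vapply(parts, function(p) paste(p[-length(p)], collapse = "."),
               character(1))
  size <- vapply(parts, function(p) p[length(p)], character(1))
  markers <- unique(mk)
  calls <- matrix(NA_character_, nrow(bin), length(markers),
                  dimnames = list(rownames(bin), markers))
  for (m in markers) {
    cols <- which(mk == m)
    for (i in seq_len(nrow(bin))) {
      v <- bin[i, cols]
      if (anyNA(v)) next
      present <- size[cols][v == 1L]
      if (length(present))
        calls[i, m] <- paste(sort(as.numeric(present)), collapse = "/")
    }
  }
  GenotypeMatrix(calls)
}
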