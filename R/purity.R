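.PURITY_CLASSES <- c("true_hybrid", "selfed_female", "selfed_male",
                     "off_type", "missing")

#' Classify one seedling from a co-dominant marker call
#'
#' A true F1 hybrid shows both parental bands simultaneously; a single
#' female or male band indicates a selfed seed; any band matching neither
#' parent marks an off-type; no call is missing.  A band matches a parent
#' when it lies within \code{tolerance} bp of that parent's allele.
#'
#' @param call band sizes in bp (numeric vector) or a slash-joined string
#'   (\code{"191/218"}); \code{NA} or empty = missing.
#' @param femaleAllele,maleAllele parental band sizes in bp; must differ by
#'   more than \code{2 * tolerance} or the marker cannot separate them.
#' @param tolerance band-size tolerance in bp (0 for in-silico sizes;
#'   configurable for gel-estimated sizes).
#' @return one of \code{"true_hybrid"}, \code{"selfed_female"},
#'   \code{"selfed_male"}, \code{"off_type"}, \code{"missing"}.
#' @export
classifySeedling <- function(call, femaleAllele, maleAllele, tolerance = 0) {
  if (abs(femaleAllele - maleAllele) <= 2 * tolerance)
    stop("parental alleles indistinguishable under tolerance; marker unusable")
  bands <- if (is.character(call)) .parseCall(call) else
    call[!is.na(call)]
  if (!length(bands)) return("missing")
  isF <- abs(bands - femaleAllele) <= tolerance
  isM <- abs(bands - maleAllele) <= tolerance
  if (any(!isF & !isM)) return("off_type")
  if (any(isF) && any(isM)) return("true_hybrid")
  if (any(isF)) return("selfed_female")
  "selfed_male"
}

#' Batch hybrid-seed purity from one marker
#'
#' @param calls list or character vector of per-seedling calls (see
#'   [classifySeedling()]).
#' @param femaleAllele,maleAllele parental band sizes in bp.
#' @param tolerance band-size tolerance in bp.
#' @return list with \code{classes} (per-seedling), \code{counts} (per
#'   class), and \code{purity}: percent true hybrids among classified
#'   (non-missing) seedlings.
#' @export
batchPurity <- function(calls, femaleAllele, maleAllele, tolerance = 0) {
  if (!length(calls)) stop("empty batch")
  classes <- vapply(calls, classifySeedling, character(1),
                    femaleAllele = femaleAllele, maleAllele = maleAllele,
                    tolerance = tolerance, USE.NAMES = FALSE)
  classified <- sum(classes != "missing")
  if (classified == 0L) stop("all seedlings missing; nothing to classify")
  counts <- table(factor(classes, levels = .PURITY_CLASSES))
  list(classes = classes,
       counts = counts,
       purity = 100 * as.integer(counts["true_hybrid"]) / classified)
}

#' Multi-marker hybrid-seed purity
#'
#' Scores a seedling batch genotyped at several co-dominant markers against
#' a two-row parental allele table.  A seedling is a true hybrid only if it
#' is hybrid at every informative marker with a non-missing call
#' (conservative AND rule); any off-type call dominates; conflicting selfed
#' calls across markers are reported as off-type.
#'
#' @param gm a [GenotypeMatrix-class] of seedlings.
#' @param parents data.frame with columns \code{marker}, \code{female},
#'   \code{male} (allele sizes in bp).
#' @param tolerance band-size tolerance in bp.
#' @return list with \code{per_marker} (named list of [batchPurity()]
#'   results), \code{combined} classes per seedling, and overall
#'   \code{purity} percentage under the AND rule.
#' @export
batchPurityMatrix <- function(gm, parents, tolerance = 0) {
  stopifnot(all(c("marker", "female", "male") %in% names(parents)))
  markers <- intersect(parents$marker, markerIds(gm))
  if (!length(markers)) stop("no parental marker present in the matrix")
  perMarker <- list()
  classMat <- matrix(NA_character_, nrow(genotypeCalls(gm)), length(markers),
                     dimnames = list(lineIds(gm), markers))
  for (mk in markers) {
    p <- parents[parents$marker == mk, ][1L, ]
    res <- batchPurity(genotypeCalls(gm)[, mk], p$female, p$male, tolerance)
    perMarker[[mk]] <- res
    classMat[, mk] <- res$classes
  }
  combined <- apply(classMat, 1L, function(cl) {
    cl <- cl[cl != "missing"]
    if (!length(cl)) return("missing")
    if (all(cl == "true_hybrid")) return("true_hybrid")
    cl <- cl[cl != "true_hybrid"]
    if (any(cl == "off_type")) return("off_type")
    u <- unique(cl)
    if (length(u) == 1L) u else "off_type"
  })
  classified <- sum(combined != "missing")
  if (classified == 0L) stop("all seedlings missing at every marker")
  list(per_marker = perMarker,
       combined = combined,
       purity = 100 * sum(combined == "true_hybrid") / classified)
}
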