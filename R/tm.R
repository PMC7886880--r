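# Unified nearest-neighbor duplex parameters (SantaLucia 1998):
# stack enthalpies in kcal/mol and entropies in cal/(mol K), 1 M NaCl.
.NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
# duplex initiation with a terminal G.C vs terminal A.T pair
.INIT_DH <- c(A = 2.3, T = 2.3, G = 0.1, C = 0.1)
.INIT_DS <- c(A = 4.1, T = 4.1, G = -2.8, C = -2.8)
.GAS_R <- 1.9872      # cal/(mol K)

#' Primer melting temperature (nearest-neighbor model)
#'
#' Duplex Tm from the unified nearest-neighbor thermodynamic parameter set
#' (SantaLucia 1998), with an entropic monovalent-salt correction of
#' 0.368 (n-1) ln[Na+] and the non-self-complementary concentration term
#' R ln(CT/4).  Defaults model a standard PCR mix without divalent
#' correction: 50 mM monovalent salt and 500 nM total primer.
#'
#' @param primer DNA string(s), 5'->3', alphabet ACGT, length >= 8.
#' @param na monovalent cation concentration in mol/L.
#' @param primerConc total primer concentration in mol/L.
#' @return melting temperature(s) in degrees Celsius.
#' @examples
#' meltingTemperature("AGCGTAGCTAGCTAGCTAGC")
#' @export
meltingTemperature <- function(primer, na = 0.05, primerConc = 5e-7) {
  vapply(as.character(primer), function(s) {
    s <- toupper(s)
    n <- nchar(s)
    if (n < 8L) stop("primer shorter than 8 bases")
    b <- strsplit(s, "", fixed = TRUE)[[1L]]
    if (!all(b %in% c("A", "C", "G", "T")))
      stop("ambiguous base in primer: ", s)
    pairs <- paste0(b[-n], b[-1L])
    dH <- sum(.NN_DH[pairs]) + .INIT_DH[b[1L]] + .INIT_DH[b[n]]
    dS <- sum(.NN_DS[pairs]) + .INIT_DS[b[1L]] + .INIT_DS[b[n]] +
      0.368 * (n - 1L) * log(na)
    1000 * dH / (dS + .GAS_R * log(primerConc / 4)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

# All-window Tm/GC profile of one flank sequence, vectorized via cumulative
# stack sums.  Returns a data.frame of candidate windows (start, len, tm, gc,
# runPenalty) for the requested length range; used by the primer scan.
.tmProfile <- function(seq, lenMin, lenMax, na = 0.05, primerConc = 5e-7) {
  n <- nchar(seq)
  if (n < lenMin)
    return(data.frame(start = integer(), len = integer(), tm = numeric(),
                      gc = numeric(), runPenalty = integer()))
  b <- strsplit(seq, "", fixed = TRUE)[[1L]]
  pairs <- paste0(b[-n], b[-1L])
  csH <- c(0, cumsum(.NN_DH[pairs]))
  csS <- c(0, cumsum(.NN_DS[pairs]))
  csGC <- c(0, cumsum(b %in% c("G", "C")))
  runs <- rle(b)
  runEnds <- cumsum(runs$lengths)
  bigRuns <- which(runs$lengths >= 5L)
  runA <- runEnds[bigRuns] - runs$lengths[bigRuns] + 1L
  runB <- runEnds[bigRuns]
  out <- vector("list", lenMax - lenMin + 1L)
  concTerm <- .GAS_R * log(primerConc / 4)
  for (len in lenMin:min(lenMax, n)) {
    i <- seq_len(n - len + 1L)
    j <- i + len - 1L
    dH <- (csH[j] - csH[i]) + .INIT_DH[b[i]] + .INIT_DH[b[j]]
    dS <- (csS[j] - csS[i]) + .INIT_DS[b[i]] + .INIT_DS[b[j]] +
      0.368 * (len - 1L) * log(na)
    tm <- 1000 * dH / (dS + concTerm) - 273.15
    gc <- (csGC[j + 1L] - csGC[i]) / len
    pen <- integer(length(i))
    for (k in seq_along(runA)) {
      ov <- pmin(runB[k], j) - pmax(runA[k], i) + 1L
      pen <- pen + as.integer(ov >= 5L)
    }
    out[[len - lenMin + 1L]] <-
      data.frame(start = i, len = len, tm = as.numeric(tm),
                 gc = as.numeric(gc), runPenalty = pen)
  }
  do.call(rbind, out)
}

.revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
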