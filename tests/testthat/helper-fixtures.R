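# Shared fixtures, built in code at test time.

# deterministic random genome
testGenome <- function(nChrom = 2, chromLength = 2e3, gc = 0.5, seed = 11) {
  simulateReference(nChrom, chromLength, gc, seed = seed)
}

writeTempFasta <- function(records) {
  path <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(records), function(n)
    c(paste0(">", n), records[[n]]))), path)
  path
}

writeTempVcf <- function(rows) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               rows), path)
  path
}

callKeys <- function(calls) {
  paste(as.character(GenomicRanges::seqnames(calls)),
        GenomicRanges::start(calls),
        S4Vectors::mcols(calls)$ref,
        S4Vectors::mcols(calls)$alt, sep = ":")
}

# canonical keys of a cross-parent set, using the carrier's allele pair
crossKeys <- function(cp) {
  mc <- S4Vectors::mcols(cp)
  ref <- ifelse(mc$carrier == "B", mc$refB, mc$refA)
  alt <- ifelse(mc$carrier == "B", mc$altB, mc$altA)
  paste(as.character(GenomicRanges::seqnames(cp)),
        GenomicRanges::start(cp), ref, alt, sep = ":")
}

# small genotype matrix used across stats tests
toyGenotypes <- function() {
  calls <- matrix(
    c("191",     "191",     "200",
      "100/110", "100",     "110",
      "50",      "60",      NA,
      "70",      "70/80",   "80"),
    nrow = 3, ncol = 4,
    dimnames = list(c("L1", "L2", "L3"), paste0("mk", 1:4)))
  GenotypeMatrix(calls)
}
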