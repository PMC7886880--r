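test_that("normalization left-aligns through repeat context and is idempotent", {
  g <- Biostrings::DNAStringSet(c(chr = "GCAAATGGGTACGT"))
  # deletion of one A in the AAA run, anchored at the rightmost A
  calls <- IndelCallSet("chr", 4, "AA", "A")
  norm <- normalizeIndels(calls, g)
  expect_identical(GenomicRanges::start(norm), 2L)
  expect_identical(S4Vectors::mcols(norm)$ref, "CA")
  expect_identical(S4Vectors::mcols(norm)$alt, "C")
  again <- normalizeIndels(norm, g)
  expect_identical(callKeys(again), callKeys(norm))
})

test_that("all equivalent placements of one event collapse to a single canonical key", {
  g <- Biostrings::DNAStringSet(c(chr = "GATTTTTTCGATTACGGATCCA"))
  seq <- as.character(g[["chr"]])
  # every anchored representation of "delete two Ts from the T6 run":
  # the independent oracle is sequence-level equality of the edited string
  reps <- lapply(2:6, function(p)
    list(pos = p, ref = substr(seq, p, p + 2), alt = substr(seq, p, p)))
  edited <- vapply(reps, function(r)
    paste0(substr(seq, 1, r$pos), substr(seq, r$pos + 3, nchar(seq))),
    character(1))
  expect_length(unique(edited), 1L)
  keys <- vapply(reps, function(r) {
    n <- normalizeIndels(IndelCallSet("chr", r$pos, r$ref, r$alt), g)
    callKeys(n)
  }, character(1))
  expect_length(unique(keys), 1L)
  expect_identical(keys[1], "chr:2:ATT:A")

  # same collapse for a homopolymer insertion at every valid anchor
  insReps <- lapply(2:8, function(p)
    list(pos = p, ref = substr(seq, p, p),
         alt = paste0(substr(seq, p, p), "TT")))
  insEdited <- vapply(insReps, function(r)
    paste0(substr(seq, 1, r$pos), "TT", substr(seq, r$pos + 1, nchar(seq))),
    character(1))
  expect_length(unique(insEdited), 1L)
  insKeys <- vapply(insReps, function(r)
    callKeys(normalizeIndels(IndelCallSet("chr", r$pos, r$ref, r$alt), g)),
    character(1))
  expect_length(unique(insKeys), 1L)
})

test_that("normalization validates the reference allele", {
  g <- Biostrings::DNAStringSet(c(chr = "GCAAATG"))
  expect_error(normalizeIndels(IndelCallSet("chr", 2, "GA", "G"), g),
               "mismatch at chr:2")
})

test_that("identical call sets yield no cross-parent InDels", {
  g <- testGenome()
  sim <- plantIndels(g, nA = 8, nB = 0, nShared = 0, minSpacing = 150, seed = 2)
  cp <- deriveCrossParent(sim$callsA, sim$callsA, g)
  expect_length(cp, 0L)
})

test_that("a single parent-unique insertion is reported with carrier and size diff", {
  g <- Biostrings::DNAStringSet(c(chr = paste(rep("ACGT", 25), collapse = "")))
  ins <- paste(rep("GATC", 9), collapse = "")  # 36 bp, non-repetitive context
  callsA <- IndelCallSet("chr", 48, "T", paste0("T", ins, "A"))
  callsB <- IndelCallSet(character(), integer(), character(), character())
  cp <- deriveCrossParent(callsA, callsB, g)
  expect_length(cp, 1L)
  expect_identical(carrier(cp), "A")
  expect_identical(alleleSizeDiff(cp), 37L)
  expect_identical(as.character(sizeClass(cp)), "large")
})

test_that("derivation matches the planted truth table on simulated parents", {
  g <- simulateReference(4, 5e4, 0.45, seed = 21)
  sim <- plantIndels(g, nA = 30, nB = 15, nShared = 10, seed = 22)
  cp <- deriveCrossParent(sim$callsA, sim$callsB, g)
  expect_length(cp, 45L)
  tru <- sim$truth[sim$truth$category != "shared", ]
  expect_setequal(crossKeys(cp),
                  paste(tru$chrom, tru$pos, tru$ref, tru$alt, sep = ":"))
  expect_identical(sum(carrier(cp) == "A"), 30L)
  expect_identical(sum(carrier(cp) == "B"), 15L)
})

test_that("cross-parent derivation is symmetric with carriers swapped", {
  g <- testGenome(seed = 31)
  sim <- plantIndels(g, nA = 6, nB = 6, nShared = 3, minSpacing = 150, seed = 32)
  ab <- deriveCrossParent(sim$callsA, sim$callsB, g)
  ba <- deriveCrossParent(sim$callsB, sim$callsA, g)
  expect_identical(length(ab), length(ba))
  expect_setequal(crossKeys(ab), crossKeys(ba))
  swap <- c(A = "B", B = "A", both_distinct = "both_distinct")
  expect_identical(table(swap[carrier(ab)])[c("A", "B")],
                   table(carrier(ba))[c("A", "B")])
})

test_that("calls on chromosomes absent from the genome are an error", {
  g <- Biostrings::DNAStringSet(c(chr1 = "GCAAATGG"))
  calls <- IndelCallSet("chrX", 2, "CA", "C")
  expect_error(deriveCrossParent(calls, calls, g), "absent")
})

test_that("size classes partition all lengths at the documented bounds", {
  expect_identical(as.character(classifySize(c(-10, 30, 31, -1, 11, 21))),
                   c("small", "medium_21_30", "large", "small",
                     "medium_11_20", "medium_21_30"))
  expect_error(classifySize(0), "non-zero")
  # partition property: every length maps to exactly one class
  expect_false(anyNA(classifySize(c(-200:-1, 1:200))))
})

test_that("densities reproduce count/Mb arithmetic at 1-decimal rounding", {
  expect_identical(indelDensity(10470, 210.99), 49.6)
  expect_identical(indelDensity(694, 22.47), 30.9)
  expect_identical(indelDensity(0, 31.9), 0)
  expect_error(indelDensity(5, 0), "positive")
})

test_that("size-class summaries report counts, splits and percentages", {
  single <- sizeClassSummary(-7)
  expect_identical(single$total, c(1L, 0L, 0L, 0L))
  expect_identical(single$percentage[1], 100)
  mixed <- sizeClassSummary(c(5, -5, 15, -40))
  expect_identical(mixed$insertion, c(1L, 1L, 0L, 0L))
  expect_identical(mixed$deletion, c(1L, 0L, 0L, 1L))
  expect_identical(attr(mixed, "collapsed")$percentage, c(50, 25, 25))
})

test_that("discovery summary recovers the generator's empirical mixture exactly", {
  g <- simulateReference(4, 6e4, 0.45, seed = 41)
  sim <- plantIndels(g, nA = 40, nB = 20, nShared = 0, seed = 42)
  cp <- deriveCrossParent(sim$callsA, sim$callsB, g)
  summ <- discoverySummary(cp, chromLengths(g))
  expect_identical(summ$total, 60L)
  expect_identical(sum(summ$per_chrom$count), 60L)
  truthCls <- table(as.character(classifySize(sim$truth$length)))
  got <- with(summ$size_class, stats::setNames(total, size_class))
  expect_identical(got[names(truthCls)], stats::setNames(as.integer(truthCls), names(truthCls)))
  expect_equal(sum(summ$size_class$percentage), 100, tolerance = 0.3)
  expect_identical(summ$total_density, indelDensity(60, 0.24))
})
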