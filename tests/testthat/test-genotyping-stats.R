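test_that("allele frequencies count copies with heterozygotes contributing one each", {
  hom <- GenotypeMatrix(matrix(rep("150", 10), ncol = 1,
                               dimnames = list(paste0("L", 1:10), "mk")))
  expect_identical(alleleFrequencies(hom, "mk"), c("150" = 1))
  half <- GenotypeMatrix(matrix(rep(c("100", "120"), each = 5), ncol = 1,
                                dimnames = list(paste0("L", 1:10), "mk")))
  expect_equal(unname(alleleFrequencies(half, "mk")), c(0.5, 0.5))
  het <- GenotypeMatrix(matrix(c("100/120", "100", NA), ncol = 1,
                               dimnames = list(paste0("L", 1:3), "mk")))
  p <- alleleFrequencies(het, "mk")
  expect_equal(unname(p[c("100", "120")]), c(0.75, 0.25))
  allNA <- GenotypeMatrix(matrix(NA_character_, 2, 1,
                                 dimnames = list(c("a", "b"), "mk")))
  expect_error(alleleFrequencies(allNA, "mk"), "no non-missing")
})

test_that("gene diversity and PIC follow their closed forms", {
  expect_identical(geneDiversity(1), 0)
  expect_identical(geneDiversity(c(0.5, 0.5)), 0.5)
  expect_equal(geneDiversity(c(0.88, 0.12)), 0.2112)
  expect_identical(picValue(1), 0)
  expect_identical(picValue(c(0.5, 0.5)), 0.375)
  # biallelic locus whose diversity is 0.22: PIC rounds to 0.20
  p <- (1 + sqrt(1 - 2 * 0.22)) / 2
  expect_equal(geneDiversity(c(p, 1 - p)), 0.22)
  expect_equal(round(picValue(c(p, 1 - p)), 2), 0.20)
})

test_that("PIC never exceeds gene diversity (random frequency simplex)", {
  set.seed(99)
  for (i in 1:200) {
    k <- sample(2:5, 1)
    p <- stats::rgamma(k, 1)
    p <- p / sum(p)
    expect_lte(picValue(p), geneDiversity(p) + 1e-12)
    # equal frequencies attain the diversity bound 1 - 1/k
    expect_equal(geneDiversity(rep(1 / k, k)), 1 - 1 / k)
  }
})

test_that("observed heterozygosity is the two-band fraction of scored lines", {
  calls <- matrix(c(rep("100/120", 10), rep("100", 38)), ncol = 1,
                  dimnames = list(paste0("L", 1:48), "mk"))
  gm <- GenotypeMatrix(calls)
  expect_equal(observedHeterozygosity(gm, "mk"), 10 / 48)
  expect_equal(round(observedHeterozygosity(gm, "mk"), 2), 0.21)
  hom <- GenotypeMatrix(matrix(c("1", "2"), ncol = 1,
                               dimnames = list(c("a", "b"), "mk")))
  expect_identical(observedHeterozygosity(hom, "mk"), 0)
  allHet <- GenotypeMatrix(matrix(c("1/2", "1/2"), ncol = 1,
                                  dimnames = list(c("a", "b"), "mk")))
  expect_identical(observedHeterozygosity(allHet, "mk"), 1)
})

test_that("panel summary averages allele counts as in a 38+1 marker panel", {
  lines <- paste0("L", 1:3)
  biallelic <- matrix(rep(c("100", "120", "100"), 38), nrow = 3)
  triallelic <- matrix(c("100", "120", "140"), nrow = 3)
  calls <- cbind(biallelic, triallelic)
  dimnames(calls) <- list(lines, paste0("InDel", 1:39))
  ps <- panelSummary(GenotypeMatrix(calls))
  expect_identical(ps$markers$allele_count,
                   c(rep(2L, 38), 3L))
  expect_equal(round(unname(ps$means["allele_count"]), 2), 2.03)
  mono <- GenotypeMatrix(matrix("5", 2, 1, dimnames = list(c("a", "b"), "m")))
  pm <- panelSummary(mono)
  expect_identical(pm$markers$allele_count, 1L)
  expect_identical(pm$markers$gene_diversity, 0)
  expect_identical(pm$markers$pic, 0)
})

test_that("Nei minimum distance matches hand-computed values on a toy panel", {
  gm <- toyGenotypes()
  expect_identical(neiMinimumDistance(gm, "L1", "L1"), 0)
  expect_equal(neiMinimumDistance(gm, "L1", "L2"), 0.375)
  expect_equal(neiMinimumDistance(gm, "L1", "L3"), 0.75)
  expect_equal(neiMinimumDistance(gm, "L2", "L3"), 0.75)
  d <- neiDistanceMatrix(gm)
  expect_identical(d, t(d))
  expect_identical(unname(diag(d)), rep(0, 3))
})

test_that("Nei distance is 1 for homozygous lines sharing no alleles, and equals mismatch share for inbreds", {
  calls <- matrix(c("1", "2", "3", "4", "5", "6"), nrow = 2,
                  dimnames = list(c("X", "Y"), paste0("m", 1:3)))
  expect_identical(neiMinimumDistance(GenotypeMatrix(calls), "X", "Y"), 1)
  set.seed(7)
  L <- 40
  a <- as.character(sample(1:2, L, replace = TRUE))
  b <- as.character(sample(1:2, L, replace = TRUE))
  gm <- GenotypeMatrix(matrix(c(a, b), nrow = 2, byrow = TRUE,
                              dimnames = list(c("X", "Y"), paste0("m", 1:L))))
  expect_equal(neiMinimumDistance(gm, "X", "Y"), mean(a != b))
})

test_that("UPGMA merges two taxa at half their distance", {
  d <- matrix(c(0, 0.8, 0.8, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  tr <- upgmaTree(d)
  expect_identical(sort(tr$tip.label), c("A", "B"))
  expect_equal(unname(tr$edge.length), c(0.4, 0.4))
})

test_that("UPGMA recovers a known ultrametric tree exactly and is permutation-invariant", {
  ids <- c("A", "B", "C", "D")
  # tree ((A,B) at height 1, (C,D) at height 2) joined at height 3
  d <- matrix(6, 4, 4, dimnames = list(ids, ids))
  d["A", "B"] <- d["B", "A"] <- 2
  d["C", "D"] <- d["D", "C"] <- 4
  diag(d) <- 0
  tr <- upgmaTree(d)
  coph <- ape::cophenetic.phylo(tr)[ids, ids]
  expect_equal(coph, d, tolerance = 1e-12)
  depths <- ape::node.depth.edgelength(tr)[seq_along(ids)]
  expect_lt(diff(range(depths)), 1e-9)   # ultrametric
  perm <- c("C", "A", "D", "B")
  tr2 <- upgmaTree(d[perm, perm])
  expect_true(ape::all.equal.phylo(tr, tr2, use.edge.length = TRUE,
                                   tolerance = 1e-12))
  expect_error(upgmaTree(matrix(c(0, NA, NA, 0), 2, 2,
                                dimnames = list(c("a", "b"), c("a", "b")))),
               "NA")
})

test_that("UPGMA agrees with average-linkage hierarchical clustering", {
  set.seed(17)
  n <- 8
  m <- matrix(stats::runif(n * n), n, n)
  d <- (m + t(m)) / 2
  diag(d) <- 0
  ids <- paste0("T", 1:n)
  dimnames(d) <- list(ids, ids)
  tr <- upgmaTree(d)
  mine <- ape::cophenetic.phylo(tr)[ids, ids]
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  ref <- as.matrix(stats::cophenetic(hc))[ids, ids]
  expect_equal(mine, ref, tolerance = 1e-10)
})

test_that("binarization yields per-allele presence columns and round-trips", {
  calls <- matrix(c("100", "120", "100/120",
                    "80", "80", "90"), nrow = 3,
                  dimnames = list(c("L1", "L2", "L3"), c("mkA", "mkB")))
  gm <- GenotypeMatrix(calls)
  bin <- binarizeGenotypes(gm)
  expect_identical(colnames(bin), c("mkA.100", "mkA.120", "mkB.80", "mkB.90"))
  expect_identical(unname(bin["L1", ]), c(1L, 0L, 1L, 0L))
  expect_identical(unname(bin["L3", ]), c(1L, 1L, 0L, 1L))
  # complementary columns for a biallelic all-homozygous marker
  expect_identical(unname(bin[c("L1", "L2"), "mkA.100"] +
                          bin[c("L1", "L2"), "mkA.120"]), c(1L, 1L))
  back <- debinarizeGenotypes(bin)
  expect_identical(genotypeCalls(back), genotypeCalls(gm))
})
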