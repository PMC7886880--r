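# InDelMarkers

Breeders of inbred-parent hybrid crops need cheap, co-dominant PCR markers
that tell a true F1 seed from a selfed or off-type contaminant on a standard
agarose gel. Insertion/deletion (InDel) polymorphisms between the two
re-sequenced breeding parents of a hybrid are ideal sources for such markers:
when the two parental alleles differ by more than ~30 bp, the two amplicons
separate on 2% agarose, and a heterozygous F1 shows both parental bands at
once.

`InDelMarkers` implements that marker-development workflow as a reusable R
package, starting from per-parent variant calls against a shared reference
genome (running the upstream read mapping and variant calling is out of
scope):

1. **Cross-parent InDel discovery** — parental call sets (VCF or TSV) are
   left-aligned to canonical form; an InDel whose canonical key
   `(chrom, pos, ref, alt)` occurs in exactly one parent is polymorphic
   between them (the other parent matches the reference), while identical
   calls in both parents are shared and discarded. Events are binned into
   the standard size classes (small 1–10, medium 11–20 / 21–30, large
   > 30 bp) and summarized as per-chromosome densities (InDels/Mb).
2. **Marker design** — 150-nt flanks around each InDel form the design
   template; an exhaustive primer scan applies the classical constraints
   (primer length 18–28 bp, Tm 57–63 °C from the unified nearest-neighbor
   thermodynamic model, product 80–300 bp on the reference allele) and picks
   the pair minimizing `|Tm_f − 60| + |Tm_r − 60| + |Tm_f − Tm_r|` plus GC
   and homopolymer penalties. Per-parent amplicon sizes are predicted by
   exact in-silico PCR; band differences > 30 bp are classed
   `agarose`, the rest `polyacrylamide`.
3. **Hybrid-seed purity testing** — co-dominant band calls of a seedling
   batch are scored against the two parental alleles
   (both bands → true hybrid; one parental band → selfed; foreign band →
   off-type) and summarized as percent true hybrids among classified
   seedlings.
4. **Marker statistics and phylogenetics** — per-marker allele frequencies,
   gene diversity `1 − Σp_i²`, Botstein's polymorphism information content
   `PIC = 1 − Σp_i² − Σ_{i<j} 2p_i²p_j²`, observed heterozygosity, Nei's
   minimum genetic distance `mean_loci[(Σx_i² + Σy_i²)/2 − Σx_i y_i]` and a
   deterministic UPGMA dendrogram written as Newick.
5. **Synthetic data** — a first-class simulator generates reference genomes,
   parental genomes with planted InDels (including repeat-context events
   exported at randomized, equivalent anchors), genotype panels with group
   structure, and F1 seed lots — all with known ground truth, so every
   pipeline stage can be validated against a truth table.

## Worked example

```r
library(InDelMarkers)

genome <- simulateReference(nChrom = 7, chromLength = 1e5, gc = 0.4, seed = 2024)
sim    <- plantIndels(genome, nA = 100, nB = 50, nShared = 25, seed = 2024)
cross  <- deriveCrossParent(sim$callsA, sim$callsB, genome)
cross
#> CrossParentIndelSet with 150 cross-parent InDels
#> carrier
#>   A   B
#> 100  50
```

The 25 planted shared events are excluded; all 150 parent-unique events are
recovered. Size-class and density accounting:

```r
summ <- discoverySummary(cross, chromLengths(genome))
attr(summ$size_class, "collapsed")
#>   size_class total percentage
#> 1      small    76       50.7
#> 2     medium    52       34.7
#> 3      large    22       14.7
summ$total_density
#> [1] 214.3      # InDels/Mb over the 0.7 Mb simulated genome
```

Design agarose-resolvable markers for the large (> 30 bp) InDels:

```r
large   <- cross[alleleSizeDiff(cross) > 30]
markers <- designMarkers(large, genome)
head(markerTable(markers)[, c("marker_id", "allele_size_diff", "gel_class",
                              "fwd_primer", "tm_fwd", "product_A", "product_B")], 3)
#>   marker_id allele_size_diff gel_class                  fwd_primer tm_fwd product_A product_B
#> 1  InDel001               35   agarose  ACGCCTACATTCTTGTAAATTCGGCT  59.72       261       226
#> 2  InDel002               47   agarose GTAACTCTTCATCTCTGGGCCTGGTAT  60.00       130       177
#> 3  InDel003               33   agarose       CAAGGGCTCTGAAGTGCCCAA  60.02       253       220
```

Every designed pair satisfies the constraint windows, and the two parental
products always differ by exactly the planted allele-size difference
(e.g. 261 − 226 = 35). Purity testing of a simulated seed lot with a marker
whose parental bands are 218 bp (female) and 191 bp (male):

```r
batch <- simulateF1Batch(femaleAllele = 218, maleAllele = 191, n = 100,
                         hybridFraction = 0.9, seed = 2024)
res <- batchPurity(batch$calls, femaleAllele = 218, maleAllele = 191)
res$counts
#>   true_hybrid selfed_female   selfed_male      off_type       missing
#>            90            10             0             0             0
res$purity
#> [1] 90        # percent true hybrids among classified seedlings
```

A command-line wrapper over the same functions ships in
`inst/scripts/indelmarkers.R` with subcommands `simulate`, `discover`,
`design`, `stats`, `distance`, `tree`, `purity` and `report`.

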