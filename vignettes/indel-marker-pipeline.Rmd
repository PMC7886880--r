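---
title: "Developing agarose-resolvable InDel markers from two re-sequenced parents"
author: "InDelMarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing agarose-resolvable InDel markers from two re-sequenced parents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(InDelMarkers)
```

## The problem

Commercial hybrid seed lots of inbred-parent crops (the motivating system is
cucumber, *Cucumis sativus*) are contaminated at some rate by selfed or
off-type seed. A co-dominant PCR marker whose two parental alleles differ
enough in amplicon size separates true F1 seedlings — which show both
parental bands — from contaminants on a plain 2% agarose gel, with no
polyacrylamide equipment. InDel polymorphisms between the two re-sequenced
breeding parents are a natural source of such markers: the allele-size
difference of the PCR products equals the InDel length, so events larger
than 30 bp are directly agarose-resolvable.

`InDelMarkers` starts from per-parent InDel call sets against a shared
reference genome. Read mapping, duplicate marking and variant calling are
deliberately upstream of the package boundary: the package trusts the calls
it is given and applies no depth or quality re-filtering.

## Cross-parent derivation

Two parents X1 and X2 are each called against the same reference. A locus is
marker-worthy when the parents produce *different* PCR products, which in
call-set terms means: an InDel present in exactly one parent (the other
parent matching the reference at that position), or two different-length
InDel alleles at the same position.

The subtlety is representation: the same physical event inside a repeat
tract can be reported at any anchor within the tract. `normalizeIndels()`
reduces every call to the canonical, parsimonious, left-aligned form (trim
the shared suffix, shift left through the repeat context, trim the shared
prefix down to the anchor base), and "the same InDel" is *defined* as
equality of the canonical `(chrom, pos, ref, alt)` key. This is the one
place where the package fixes an interpretation the source workflow left
open; it is the standard, testable reading, and the test suite verifies by
sequence-level brute force that all equivalent placements of an event
collapse to one key.

`deriveCrossParent()` then classifies canonical keys:

* key in exactly one parent → a cross-parent InDel with that parent as
  `carrier`; the band-size difference is the event length;
* identical key in both parents → shared, not polymorphic, excluded;
* two different alleles at one anchor → kept as `carrier = "both_distinct"`
  with band difference `|length_A − length_B|`, *unless* the two alleles
  have equal length — such loci are sequence-polymorphic but
  size-monomorphic, produce indistinguishable bands, and are dropped with a
  message.

Ties in output order are broken by `(chrom, pos, carrier, alt)` so all
downstream artifacts are byte-reproducible.

Size classes follow the conventional bins — small 1–10 bp, medium 11–20 and
21–30 bp, large > 30 bp — and `discoverySummary()` reports per-chromosome
counts, densities in InDels/Mb (rounded to one decimal, the resolution used
in published tables), and the size-class split with percentages of the
total.

## Marker design

### Template

`extractFlanks()` takes 150 reference bases on each side of the InDel's
reference allele (flank length is tunable). Templates at chromosome ends
are shortened with a warning rather than rejected. For `both_distinct` loci
the longer of the two parental reference alleles defines the template
center, so both parental alleles can be substituted into it.

### Melting temperature

No Tm formula is canonical for gel-marker design, so the package fixes a
deterministic, documented model: unified nearest-neighbor thermodynamics
(SantaLucia 1998), with duplex initiation terms, an entropic salt
correction `0.368 (n − 1) ln[Na+]`, and the non-self-complementary
concentration term `R ln(C_T/4)`. Defaults are 50 mM monovalent salt and
500 nM total primer, with no divalent correction — a plain PCR mix. The test
suite pins `meltingTemperature()` against independently computed reference
values to 0.1 °C and checks the model's qualitative properties (reverse
complement symmetry, AT→GC monotonicity).

### Primer scan and scoring

`designPrimers()` enumerates *every* candidate window of 18–28 bases in the
upstream flank (forward) and downstream flank (reverse), both strictly
outside the InDel allele. Windows outside 57–63 °C are rejected, as are
pairs whose product on the reference allele leaves 80–300 bp. Among the
survivors the chosen pair minimizes

```
|Tm_f − 60| + |Tm_r − 60| + |Tm_f − Tm_r| + GC penalty + homopolymer penalty
```

with one penalty point per primer whose GC lies outside 40–60% and one per
homopolymer run of ≥ 5 bases inside a primer. Ties break by smaller
product, leftmost forward start, then lexicographic sequence, making the
design a pure function of `(template, constraints)`. When no pair survives,
the locus is kept in the marker table with empty primer fields. The scoring
function itself is a package design decision (the source workflow used an
interactive desktop tool and published only the constraint windows); any
monotone preference for Tm ≈ 60 °C and matched primers would serve, and the
acceptance-level audit only relies on the hard windows.

The Tm evaluation over all windows is computed from cumulative
enthalpy/entropy sums along the flank, so the exhaustive scan costs
O(flank × lengths) rather than O(flank × lengths × primer length).

### In-silico PCR and gel class

`predictProductSize()` requires the forward primer and the reverse
complement of the reverse primer to each match the subject exactly once, in
amplifiable orientation; the product is the end-to-end distance including
both primers. Binding is checked within the locus template only — genome-wide
specificity screening is out of scope, mirroring practice where specificity
is established empirically by PCR. Per-parent products are predicted on the
template with each parent's allele substituted in; by construction
`|product_A − product_B|` equals the allele-size difference, and the test
suite asserts this end to end on simulated parents. The product window is
enforced on the *reference* allele product; an alternate-allele product may
exceed 300 bp for large insertions, which is allowed.

Markers with band difference > 30 bp are classed `agarose`; others
`polyacrylamide`. `subsampleMarkers()` provides the seeded random
subsampling used in practice to cap experimental validation cost; it is
never applied by default.

## Panel statistics

For a panel of breeding lines genotyped with co-dominant markers (calls are
band-size sets: `"191"` homozygote, `"191/218"` heterozygote):

* allele frequencies count copies — a homozygote contributes two copies, a
  heterozygote one of each; missing calls leave the denominator;
* gene diversity is `1 − Σp_i²`, with no small-sample correction (the
  uncorrected form is fixed here because the reference implementation's
  option state is unknowable; the choice is documented rather than silent);
* PIC is Botstein's `1 − Σp_i² − Σ_{i<j} 2 p_i² p_j²`, which never exceeds
  gene diversity (property-tested over random frequency simplexes);
* observed heterozygosity is the two-band fraction of scored lines.

Nei's minimum genetic distance is computed on within-line allele frequency
vectors (1 for a homozygote, 0.5/0.5 for a heterozygote): per locus
`(Σx_i² + Σy_i²)/2 − Σx_i y_i`, averaged over loci non-missing in both
lines. For fully inbred panels this reduces to the simple mismatch
proportion, a closed-form limit the tests exploit. Naming a specific
formula is the largest interpretive decision in the package — "Nei's
distance" is a family — and the minimum-distance form on within-line
frequencies is frozen so that results are testable.

`upgmaTree()` is a from-scratch UPGMA with size-weighted average linkage,
node height d/2, and ties broken by the lexicographically smallest combined
member set; the output is ultrametric to numerical precision and invariant
to input permutation. It is cross-checked in the tests against
average-linkage `hclust()` cophenetic distances (the independent oracle),
and exactly recovers distance matrices constructed from a known ultrametric
tree. Trees are returned as `ape` `phylo` objects and serialized as Newick.

`binarizeGenotypes()` provides the lossless 0/1 allele-presence coding used
by qualitative-analysis tools, with `debinarizeGenotypes()` as its tested
inverse.

## Purity testing

`classifySeedling()` compares a seedling's band set to the two parental
alleles within a tolerance (default 0 bp — exact, the right choice for
in-silico sizes; set a few bp for gel-estimated sizes). Both parental bands
→ `true_hybrid`; only one → `selfed_female`/`selfed_male`; any band matching
neither parent → `off_type` (this takes precedence even when parental bands
are also present, since an aberrant band means the assay cannot vouch for
the seedling); no bands → `missing`. Parental alleles closer than
`2 × tolerance` make the marker unusable and raise an error. Batch purity is
the percentage of true hybrids among *classified* (non-missing) seedlings.
Multi-marker batches combine by a conservative AND rule: a seedling is
hybrid only if hybrid at every informative marker with a call.

## The synthetic-data module

The simulator exists so that every stage has a ground truth. Its defaults
are the study conditions, not tuning knobs:

* size mixture 53.9% / 26.1% / 8.9% / 11.1% over the four size classes and
  insertion share 5208/10552 ≈ 0.494, taken from the genome-wide accounting
  of the cucumber parent pair; the large class draws uniformly on 31–60 bp;
* events are planted on a ≥ 200 bp spacing grid so flanks and primers never
  straddle two events;
* 10% of events are planted as homopolymer insertions/deletions inside
  repeat tracts and *exported at randomized equivalent anchors*, so that
  discovery is exercised against non-canonical representations (a
  repeat-context deletion that does not fit its run falls back to a plain
  placement, keeping the insertion:deletion ratio at its configuration);
* the default GC fraction is 0.4, a realistic plant-genome neighborhood;
  chromosome count defaults to 7 (the cucumber karyotype).

Truth tables store canonical representations; the test suite independently
verifies canonicality by re-normalizing and by sequence-level equality of
edited strings. Genotype panels draw inbred (homozygous) lines by default,
with optional heterozygosity and an optional two-group structure in which
chosen markers are fixed for alternate alleles — the construction that a
group-separating UPGMA topology is tested against. F1 batches use exact
rounded class counts (so a 90% hybrid fraction at n = 100 yields exactly 90
hybrids) with shuffled order and retained labels.

What the simulator does **not** emulate: sequencing error and miscalled
variants, complex substitutions, overlapping or nested events, SNVs
adjacent to InDels, reference assembly errors, and PCR artifacts (stutter,
null alleles). Passing tests therefore demonstrate correctness of the
algorithms under clean calls, not robustness to upstream calling noise.

## Problem sizes and numerical choices

The shipped tests run the discovery oracle on a 7 × 100 kb genome with
100/50/25 planted events, the design audit on 120 large-InDel templates,
panel statistics on up to 1000 simulated lines, and purity on 100-seedling
batches — sizes chosen to exercise every code path in seconds while keeping
sampling noise well inside the asserted bounds. Densities and percentages
are rounded to one decimal to match published table resolution; UPGMA
ultrametricity is asserted to 1e-9; Tm oracle agreement to 0.1 °C.

## Known limitations

* Primer specificity is local to the template; genome-wide e-PCR with
  mismatches is not implemented.
* No thermodynamic secondary-structure or primer-dimer screening.
* `both_distinct` loci with equal-length alleles are dropped as
  size-monomorphic even though they are sequence-polymorphic.
* The package does not attempt to reproduce panel results that depend on
  unreleased raw reads or supplementary genotype tables (e.g. specific
  published call counts, cluster memberships, or a particular pairwise Nei
  distance); simulation-backed property checks stand in for them.
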