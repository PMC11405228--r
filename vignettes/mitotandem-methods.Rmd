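---
title: "Tandem gene pairs and repeats in plant mitochondrial genomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tandem gene pairs and repeats in plant mitochondrial genomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitotandem)
```

## The problem

Plant mitochondrial genomes are large (hundreds of kb), usually map as
circles, and rearrange so freely that gene *order* carries almost no
long-range phylogenetic signal.  What does persist is local: a handful of
gene pairs stay physically adjacent ("tandem") across very distant
angiosperms — rps3 with rpl16, the small rRNA with the 5S rRNA, rpl5 with
cob, nad3 with rps12, nad1 with matR — and the NADH-dehydrogenase (nad)
subunits of respiratory complex I cluster with each other, with nad5 in
particular essentially always carrying a nad neighbor.  mitotandem turns
that observation into a reusable analysis: it reads annotated mt genomes,
detects tandem pairs on the circular gene ring, compares gene-order blocks
between genomes, classifies a panel of species by the arrangement states of
a reference pair set, tests the nad5 tandem rule, and re-implements the
microsatellite and dispersed-repeat layer so the whole pipeline can be
validated end to end on synthetic data with planted truth.

## The gene ring and the definition of "tandem"

All adjacency reasoning happens on the **adjacency ring**: the features of
one genome, restricted to a class set (default CDS, rRNA and ORF — tRNAs are
invisible to adjacency, as comparative mt-genome figures conventionally drop
them), in circular start order.  Two families form a tandem pair when their
features are *consecutive on the ring*, including the edge that crosses the
origin.  Adjacency, not distance, is the criterion: published descriptions
of conserved mt gene pairs never state a bp cutoff, and intergenic spacers
of several kb are normal in these genomes.  A `max_gap` argument exists
purely for sensitivity analysis and defaults to unlimited.  ORFs stay on the
ring by default because the figures this convention follows exclude only
tRNAs; a caller can drop them through `keep_classes`.

Coordinates are 1-based inclusive throughout (the GenBank/GFF3 convention).
A feature spanning the origin of a circular molecule is stored once, with
its annotated start and end and a `wraps` flag; its length is
`(genome_length - start + 1) + end`.  Ring construction sorts by start with
deterministic tie-breaks (end, then family), so identical inputs always give
identical output.

Orientation of a pair refers to the shared strand of both members:
`tandem_sense` when both genes sit on the plus strand, `tandem_antisense`
when both sit on the minus strand — whole-pair strand flips between species
are exactly the signal the profile analysis uses.  Genes adjacent on
*opposite* strands are scored `present_not_tandem` by default, because the
biological observation being modeled is whole-block inversion, not head-on
adjacency; `allow_opposite = TRUE` relaxes this.

## Name normalization

Published annotations mix vocabularies (rrn18/rrnS, rrn26/rrnL, rpl6/rpl16,
casing of nad4L and ccmFN).  Every name is lowercased, copy decorations
(`atp9-2`, `nad1_1`) are stripped when the stem is still recognisable gene
vocabulary, and a built-in alias table collapses synonyms.  Two choices are
deliberate:

* **rpl16 is the canonical name** for the rps3 partner.  The literature uses
  both rpl6 and rpl16 for this gene; rpl16 is the standard plant
  mitochondrial symbol, so the alias table maps rpl6 to rpl16.
* **tRNAs keep their anticodon suffix** (`trnm-cau`), because isoacceptor
  copy counting is meaningful; rRNA aliases collapse (rrn18 → rrns,
  rrn26 → rrnl).

Unknown names pass through lowercased with a warning instead of being
dropped.  Mixed-vocabulary panels are the rule, and silently discarding an
unmatched name would bias presence/absence calls, which feed directly into
the profile states.

## Conservation, profiles and grouping

`conserved_families()` is strict intersection at its default
(`min_presence = 1`): a family counts once per genome regardless of copy
number.  `conserved_pairs()` scores a candidate pair only over the genomes
that contain **both** members, so a pair survives the loss of one gene in
individual species — the behavior needed to keep, e.g., the rRNA pair
conserved when a few annotations lack the 5S gene.  The reference pair
rpl5–cob is satisfied either by direct adjacency or by the
rpl5–rps14–cob arrangement; rps14 is the *only* intermediate that
qualifies, since that specific three-gene form is the documented alternative
and admitting arbitrary intermediates would dilute the pair definition to
meaninglessness.

Species grouping is **exact state-vector equality** over the reference
pairs, with states ordered by precedence `both_missing` > `one_missing` >
`present_not_tandem` > `tandem_{sense,antisense}`.  Exact matching, rather
than clustering under a distance, reflects what an arrangement group is: a
set of species whose pair states are literally identical.  Group ids are
assigned in order of first appearance, so the partition is deterministic and
input-order invariant up to relabelling.

Tree concordance needed a quantitative reading of "groups are consistent
with the tree", which the source material leaves informal.  The criterion
used here: after pruning the tree to the grouped species, a group of two or
more members is *concordant* when it is monophyletic; singletons are
trivially concordant; overall concordance is the fraction of concordant
groups, and non-concordant groups report their smallest containing clade.
This is one defensible reading and is reported as the package's own
definition, not asserted as anyone else's.

`nj_tree()` is a deterministic wrapper over classical neighbor joining
(rows are sorted lexicographically before agglomeration so ties always
resolve the same way), and `p_distance_matrix()` supplies raw pairwise
mismatch proportions for *aligned* input.  Maximum-likelihood inference and
sequence alignment are intentionally out of scope — callers with real data
should align externally and may supply their own phylogeny to
`tree_concordance()` directly.

## The nad layer

The nad subfamily whitelist is fixed: nad1–nad7, nad9, nad4L.  `nad5_rule()`
asks, per genome, whether nad5 is present *and* participates in at least one
nad–nad tandem pair.  When a genome carries several nad5 copies, any one
partnered copy satisfies the rule — the rule is about the family, and the
per-copy detail remains available from `nad_pairs()`.  Group summaries take
the union of partnered subfamilies over member genomes.  For the nad gene
tree, `collect_nad_sequences()` extracts strand-corrected gene sequences and
drops fragments under 200 bp (default), which otherwise contribute mostly
noise to distance estimation.

## The repeat layer

**Microsatellites.**  A perfect SSR is a maximal tandem run of a primitive
1–6 nt motif meeting per-unit minimum repeat counts of 8, 4, 4, 3, 3, 3
(monomer through hexamer) — the standard survey settings for plant mt
genomes.  Maximality is at base resolution: the run cannot be extended by
one base in either direction while keeping its period.  "Primitive" excludes
motifs that are themselves periodic, so a poly-A run is reported once as a
monomer, never again as an AA dimer or AAAA tetramer: sub-periodic runs
resolve to the smallest period.  Perfect runs separated by at most 100 bp
merge into additional *compound* records.  Motifs are reported **as
observed** on the given strand — AT and TA, CT and TC are distinct
categories, matching how mt microsatellite tables are conventionally
printed; `canonicalize_motif()` exists for interoperability with tools that
group rotations and complements.  N matches nothing, including another N.

**Dispersed repeats.**  The detector reports forward and palindromic repeat
pairs of at least 50 bp within a mismatch budget of 8 (defaults).  The
published parameter settings this mirrors do not pin down the matching
model, so the model is defined here explicitly: a **fixed-pair Hamming
model**, no indels.  A forward pair is a maximal window along one offset
where the sequence matches itself shifted; a palindromic pair is a maximal
window along one antidiagonal where the sequence matches its own reverse
complement; maximal means not extendable at either end without exceeding
the budget or leaving the sequence.  Palindromic copies may not overlap (the
antidiagonal is clipped at its midpoint); forward copies may, which is how
closely spaced tandem duplications naturally surface.  Containment
suppression at equal offsets is automatic under maximality.  The scan kernel
is O(n²) C++; that is comfortable to a few hundred kb, and the brute-force
oracles used in the tests re-derive the same definition independently on
small sequences.  Circular input is handled by scanning the sequence plus a
prefix copy and de-duplicating wrapped hits.

**Editing-site summaries.**  RNA-editing *prediction* is out of scope; the
summary module consumes a site table (gene, CDS position, codon position,
amino-acid conversion, score) so that published spectra can be reproduced
from their own counts and the generator can plant sites with known
structure.  All edits are C→U by construction; a synonymous row is rejected
as a validation error.  The `1&2` codon-position category is kept as its own
class rather than split, matching how such tables tally conversions that
involve both first and second positions.

## The synthetic panel generator

`simulate_panel()` builds the study conditions the analysis is validated
under: by default 8 circular genomes of 30 kb in three arrangement groups,
background i.i.d. ACGT at GC 0.45 (the typical plant mt value), the five
reference clusters planted intact in every genome (rpl5–cob in its
three-gene rps14 form), a nad5 partner cluster (nad4, or nad9 in the third
group), per-group strand flips (group two carries nad3–rps12 and nad1–matR
on the antisense strand) and a gene loss (group three lacks rrn5), which
make the three group profiles pairwise distinct.  The species tree emitted
alongside has the groups as clades, so planted grouping and tree concordance
can be checked jointly.

Two design points deserve explanation:

* **Gene order outside planted clusters is drawn independently per genome.**
  A single ancestral order with per-gene relocation noise cannot support the
  generator's own contract: with low noise, *every* ancestral adjacency
  would be conserved across the panel and the planted clusters would be
  indistinguishable from background.  Independent orders make the expected
  conserved set exactly the planted set, deterministically, at every seed.
  The `shuffle_rate` parameter applies additional relocations on top and is
  kept as a sensitivity dial.
* **Gene sequences are random ORF-like stretches**, evolved ancestor →
  group → genome at fixed substitution rates, with all nad subfamilies
  sharing one length so they can feed `p_distance_matrix()` unaligned.
  There is no codon realism because the analysis consumes annotations, not
  codons; what must be realistic is adjacency, strandedness, copy number,
  coordinates and repeat structure, and those are planted and verified
  against the emitted sequence before the generator returns.

Planted SSRs get flanking bases chosen to break the period at both ends, so
each planted run is recovered at exactly its planted coordinates.  Planted
dispersed repeats are recovered as *containment at the same offset or
antidiagonal*: the maximal detected window legitimately extends beyond the
planted copy until the mismatch budget is spent, exactly as a seed-extend
tool would extend them.  Desk-scale gene lengths (a full gene complement in
under 20 kb) were chosen so a complete panel builds and analyses in seconds;
genome length is configurable across the 10–1000 kb range the model
supports.

What passing on synthetic panels does **not** show: robustness to
annotation errors and vocabulary drift in real records beyond the alias
table, trans-spliced or fragmented nad genes, repeat families with indels,
or genomes whose structural heterogeneity (substoichiometric isoforms,
multichromosomal forms) breaks the single-circle model.

## Numerical and degenerate-input choices

* Intergenic gaps are clamped at 0 when annotations overlap; the wrap edge
  uses circular arithmetic.
* A ring of one gene has no adjacency edges unless self-adjacency is
  explicitly enabled; edges between two copies of the same family are
  dropped by default.
* An empty ring after class filtering is an empty result, not an error.
* Shared blocks require at least two families and one representative per
  family per run; extension stops rather than revisiting a family, which
  also caps block length when two rings are circularly identical.
* `find_dispersed_repeats()` rejects `min_len` below 8, where the windowed
  model degenerates into noise.
* Percentages in every summary table are relative to the table's own total
  and sum to 100 within floating-point rounding.
* The generator restores the caller's RNG state, and a given seed fully
  determines every emitted byte.

## Reproducing the headline numbers

`scripts/acceptance.R --seed <int> --out <path>` recomputes, at run time:
the SSR category percentages and monomer A/T share from the shipped
microsatellite motif table; the serine→leucine, proline→leucine and
codon-position percentages from the shipped conversion table; and the
planted-truth recovery rates (conserved pairs, group partition, nad5
verdict, tree concordance, SSR and repeat recovery, realised GC) on a fresh
8-genome, 30 kb simulated panel.  The test suite additionally contains a
full-published-panel check that requires the 20 published genome records
themselves; those are third-party data of several megabytes and are not
redistributed, so that check reports the missing inputs on a plain checkout.

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
panel <- simulate_panel(cfg)
cp <- conserved_pairs(panel$genomes, min_tandem_fraction = 1,
                      extra_pairs = conserved_pair_defaults())
cp[cp$conserved, c("family_a", "family_b", "n_both_present", "n_tandem")]
group_species(build_profiles(panel$genomes))
nad5_rule(panel$genomes)$verdict
```
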