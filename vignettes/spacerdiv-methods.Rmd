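---
title: "Methods: CRISPR spacer-array diversity versus MLSA in a single population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CRISPR spacer-array diversity versus MLSA in a single population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spacerdiv)
```

## The problem

CRISPR loci record a host's encounters with viruses and plasmids as an
ordered array of short spacers separated by near-identical direct repeats.
New spacers enter at the leader end, so the leader is the youngest, most
variable region and the trailer the oldest and most conserved. Within a
single population (here modelled on *Sulfolobus islandicus* from one hot
spring, with up to three loci per strain: C, A1 and A2), the arrays evolve
much faster than housekeeping genes, so contrasting spacer-array diversity
with multi-locus sequence analysis (MLSA) of core genes reveals structure —
independently acquired resistance, spacer loss, clonal expansion — that
MLSA alone cannot.

`spacerdiv` implements that contrast end to end: spacer extraction from
repeat-delimited fragments, a spacer identity/similarity catalogue,
spacer-level array comparison (ancestry, loss, independent acquisition),
MLSA genotyping, and diversity estimation — plus a forward simulator that
generates all inputs with a complete ground-truth event log, so every stage
is testable without any sequence download.

## Spacer extraction

`find_repeats()` scans both strands for the locus family's repeat (A:
`GATAATCTACTATAGAATTGAAAG`, 24 nt; C: `GATTAATCCTAAAAGGAATTGAAAG`, 25 nt)
at a configurable Hamming distance (default `max_mismatches = 2`; exact
matching is available with 0, but real loci diverge enough that some
fragments otherwise fail to parse). Overlapping fuzzy candidates are
resolved greedily left to right, fewest mismatches first — repeats never
legitimately overlap, so this only disambiguates spurious hits.
`extract_spacers()` emits the substrings strictly between consecutive
repeats, leader to trailer; minus-strand fragments are reverse-complemented
first, so orientation of the input never changes the result (a tested
invariant). Fragments with fewer than two repeat hits are reported as
unsequenceable (`NA` status) and strains flagged as lacking a locus carry
an `X` status, the same bookkeeping the per-strain locus tables use.
Zero-length inter-repeat gaps are sequencing artifacts and are skipped with
a warning. Coordinates are 0-based half-open internally; spacer positions
are 1-based from the leader-most spacer of each fragment.

## Spacer identity and the 88%/17-nt rule

Two spacers match when their best ungapped overlap has identity ≥ 0.88
over ≥ 17 nt (`pair_match()`). For a full-length 39-nt pair this admits at
most 4 SNPs. The comparison is ungapped by design: observed non-identical
matches are offsets, length differences and isolated SNPs, never indels,
which is also how assembly-style matching at these thresholds behaves on
~39-nt sequences. Offsets whose overlap reaches 17 nt always outrank
shorter overlaps, then identity, then overlap length; ties go to the
smaller absolute offset. Reverse-complement matching is off by default for
spacer–spacer comparison (arrays are orientation-normalised at extraction)
and on for protospacer search.

`build_catalog()` partitions spacers into exact (full-length identical)
classes and single-linkage clusters over the fuzzy matches; the cluster
count is the "unique spacer" count (complete linkage is available as a
sensitivity option). Exact classes always refine clusters. The pairwise
overlap scan is implemented in C++ for the all-pairs catalogue; the tests
hold it to a plain-R reimplementation and the clustering to independent
graph components.

`search_protospacers()` scans each spacer against a supplied
virus/plasmid/genome FASTA on both strands, reporting all full-length
placements above an identity floor (default 0.9), scored match +1 /
mismatch −1, with perfect full-length hits flagged; `pam_context()`
extracts the flanking nucleotides (default 2, the PAM width in this
system) strand-aware, without motif calling. E-values are out of scope:
target databases here are megabases, not public repositories.

## Array comparison

`align_arrays()` aligns two arrays at the spacer level with symbols equal
to exact identity classes, scoring match +2 and gap −1 with mismatch
columns disallowed: the model of array change is acquisition plus loss,
never in-place substitution, so two different spacers can only face paired
gaps. Exact full-length identity is deliberately the only match symbol —
fuzzy (88/17) similarity is reserved for acquisition detection, where near
matches in different contexts are the signal, not evidence of shared
descent. Traceback is deterministic (match, then gap in the first array,
then gap in the second), so results are reproducible to the byte.

`detect_losses()` reads maximal gap runs flanked on both sides by match
columns as loss events in the gapped strain; terminal runs carry no
flanking evidence and are never reported. `population_losses()` runs all
compatible pairs and collapses repeated sightings of the same physical
loss (same strain, fragment, position and run length against different
partners).

`group_ancestral()` links two strains when some fragment alignment has at
least `min_run = 2` match columns ("multiple identical spacers in a row",
loss gaps permitted) and groups by single linkage. Cross-end alignments
are included: with short arrays a leader and a trailer fragment overlap,
and shared context there is genuine evidence (disjoint fragments simply
align with zero match columns). Links supported only by trailer-end
fragments are flagged `trailer_only` — the dual-colour case where the
conserved trailer is the only remaining trace of common ancestry.

## Independent-acquisition classification

`classify_acquisitions()` assigns every cross-strain fuzzy match exactly
one verdict:

1. **ancestral** — the strains are ancestrally linked at the locus and the
   pair occupies a match column of its fragments' alignment. Linkage is
   required: without it, a single identical pair between otherwise
   unrelated arrays would self-align into a match column and the central
   signal — identical or near-identical spacers in *different* contexts —
   could never be detected.
2. **excluded** — an exact full-length pair inside a run of ≥ 2
   consecutive exact pairs that is embedded in conflicting context on both
   sides and constitutes the *entire* shared context of the two fragments.
   Such runs are too consistent to be independent and too short to call
   ancestry; they are conservatively removed from the acquisition count.
   A single isolated exact pair remains a candidate.
3. **acquisition** — the rest: independent acquisitions from (nearly) the
   same protospacer, annotated with the offset/SNP signature and an end
   class (leader–leader, trailer–trailer, mixed). For fully sequenced
   loci, spacers at positions ≤ `leader_depth` (default 10, matching the
   sequenced end depth) count as leader-end.

`leader_internal_check()` tests the alternative explanation for leader
variability — loss rather than acquisition — by searching each strain's
leader-end spacers against internal positions (> `leader_depth`) of other
strains' fully sequenced loci. In-context matches between ancestrally
linked strains (a shared spacer pushed past the depth cutoff by a
difference in acquisition counts) are filtered by default; only
out-of-context internal relocations are reported, and an empty result
supports leader-end acquisition.

## MLSA

Locus sequences arrive pre-aligned and equal-length (the amplicons are
fixed coding fragments; alignment itself is routine and out of scope).
`assign_alleles()` gives identical sequences one allele id, numbering by
decreasing frequency with lexicographic tie-breaks; `N` matches any base
by default so single-read ambiguities do not split alleles. N-wildcard
compatibility is not transitive, so groups merge greedily into the
largest (then earliest) compatible allele — deterministic, and exact when
ambiguities are rare. `concatenate_profiles()` builds the allele vector,
the concatenated sequence (12 × 557 = 6684 bp under the default
simulation), and SNP counts against a reference strain with pairwise
deletion of `N`/gap sites. `epidemic_summary()` reports genotype counts
and the dominant genotype's share — the epidemic-structure statistic.

## Diversity

Distances are p-distances: `mlsa_distance()` on concatenations (pairwise
deletion), `coded_array_distance()` on the coded array matrix, where a gap
against a spacer is a real difference and missing data is deleted
pairwise. The coded matrix (`coded_matrix()`) stacks arrays per locus and
end into aligned columns by progressive profile alignment (longest array
first, same DP as pairwise alignment) and codes each cell by exact
identity class; full arrays are split into leader/trailer views so they
share columns with end fragments; per-locus matrices are concatenated by
default. Strain pairs with disjoint coverage (complementary locus losses)
error by default or can be dropped greedily.

`bin_otus()` is furthest-neighbour clustering at a cutoff (the
era-standard for OTU binning; single/average available), via
`stats::hclust`. `rarefaction_curve()` is the analytic (hypergeometric)
individual-based expectation
$E[S_n] = S - \sum_i \binom{N-N_i}{n} / \binom{N}{n}$, computed with
log-binomials; resampling survives as a test oracle only. `chao1()`
reports the bias-corrected form $S_{obs} + F_1(F_1-1)/(2(F_2+1))$ —
chosen over the classical $F_1^2/(2F_2)$ to avoid division by zero — with
the classical value alongside when defined. `rank_abundance()` sorts any
grouping by size with deterministic ties.

## The simulator

`simulate_population()` is a discrete-step binary lineage process, not a
calibrated coalescent: the study's claims need qualitative structure
(variable leaders, conserved trailers, shared virus pool), not genealogies.
Founders (default 4) carry independent root arrays of 20 spacers per
locus; the population splits one lineage per step until 39 strains exist,
then runs 5 further steps. Per step and lineage:

* **acquisition** (p = 0.25 per locus): a new leader spacer copied from a
  window adjacent to a PAM dinucleotide (`GG`) on a random strand of a
  random virus (three 15-kb, SSV-sized genomes by default). Windows
  overlapping one the genome already carries are redrawn — immunity
  against that region exists, so re-acquisition is suppressed; collisions
  *between* lineages are exactly the independent acquisitions the analysis
  must find.
* **loss** (p = 0.01 per locus): a contiguous run, truncated-geometric
  with mean 2 and maximum 5. The rate is set where observed gaps almost
  never merge adjacent events, keeping emitted gap runs within the
  configured law.
* **locus loss** (p = 0.002), producing strains with absent loci.
* **MLSA**: per-site substitution (2.5 × 10⁻⁶ per step, giving a dominant
  genotype near half the sample at the default depth) and gene conversion
  (p = 0.02, 500-nt tracts copied from a coexisting lineage). The
  recombination-to-mutation balance is a descriptive input, not an
  estimated quantity.

Emission clips each array to 10-spacer leader and trailer fragments, with
a 20% fully-sequenced subset, writes repeat-interleaved locus sequences
with `strain|locus|end` headers, and records ground truth: the lineage
tree, founder partition, every event, final states, and the provenance of
every emitted spacer. `replay()` reapplies each strain's log to its root
state and must reproduce the final states exactly. `summary_stats()`
scores analysis output against truth: detected loss-run statistics,
adjusted Rand index of ancestral groups versus the founder partition, and
acquisition precision/recall — a detected pair counts as correct when its
two spacers trace to different acquisition events (pairs whose windows
overlap slightly less than the nominal truth cutoff can still satisfy the
sequence rule legitimately, and are still independent).

## What the simulation does and does not show

The generator reproduces the analytic structure of the real data: repeat
arithmetic, end-fragment clipping, loss gaps, PAM-constrained shared-pool
acquisition, epidemic MLSA structure, locus absence. It does not emulate
sequencing error, chimeric amplicons, repeat divergence within a locus,
virus evolution, or selection; passing recovery tests therefore
demonstrates algorithmic correctness under the stated model, not
robustness to raw chromatogram artifacts. Absolute counts (spacers
sequenced, unique spacers, acquisition pairs) land in the right regime but
depend on free rate parameters for which no empirical estimates exist;
recovery metrics (precision/recall, run-length laws, partition indices)
are the meaningful outputs. With three 15-kb viruses the shared pool is
deliberately small, so independent overlapping acquisitions are common;
real viral communities may be far more complex, which would lower the
match counts without changing the method.

## Numerical choices and degenerate inputs

* Identity thresholds are compared with a 10⁻⁹ tolerance so exact
  boundaries (e.g. 22/25 = 0.88) are never lost to floating point.
* DP tie-breaks are fixed (match, gap-in-first, gap-in-second; leftmost),
  making alignments, groupings and classifications order-independent and
  reproducible.
* `bin_otus` at cutoff 0 groups identical individuals only; single-strain
  input returns one OTU without calling `hclust`.
* Empty FASTA input warns and returns an empty list; malformed headers and
  unparseable loci name the offending record.
* Problem sizes in the test suite are scaled down (8–12 strains, 20 seeds
  for recovery statistics; oracle comparisons at n ≤ 60 sequences, arrays
  ≤ 8 spacers) — chosen so each brute-force oracle stays exhaustive while
  the statistics retain enough events to be meaningful.

## Known limitations

* Multi-strain array stacking is greedy-progressive (longest first), not a
  joint optimisation; column placement can differ from a global optimum,
  though distances are insensitive to any injective recoding.
* Mixed-end spacer pairs between strains whose fragments do not overlap
  cannot be context-adjudicated; they remain acquisition candidates, as
  they must with end-fragment data.
* The 88/17 rule is applied without reverse-complement awareness by
  default; a flag enables it.
* Whether "unique spacers" counts fuzzy clusters or exact classes is
  ambiguous in the field's usage; both are reported
  (`n_clusters`, `n_exact`).
* Distance-bin labels in the literature are sometimes internally
  inconsistent (a "0.01%" label for one SNP per 1000 bp, which is 0.1%);
  all cutoffs here are raw proportions supplied by the caller.
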