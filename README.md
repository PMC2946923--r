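# spacerdiv

CRISPR spacer arrays record a microbe's history of viral encounters: an
ordered series of short (~39 nt) spacers between near-identical direct
repeats, with new spacers added at the leader end. Within a single
population these arrays evolve far faster than core genes, so comparing
spacer-array diversity against housekeeping-gene diversity (MLSA) exposes
what core genotyping hides — independently acquired resistance from a
shared virus pool, spacer loss, and a diversity of coexisting resistance
genotypes where MLSA sees one dominant clone.

`spacerdiv` is an R package for that analysis, written for microbial
population geneticists working with repeat-delimited amplicon data
(modelled on *Sulfolobus islandicus* hot-spring isolates with loci C, A1
and A2). It provides:

* **Spacer extraction** — `find_repeats()`, `extract_spacers()`,
  `load_locus_fasta()`: fuzzy repeat location on both strands, spacers as
  the sequence between consecutive repeats, leader-to-trailer orientation,
  `NA`/`X` bookkeeping for unsequenceable or absent loci.
* **Spacer catalogue** — `pair_match()` implements the ungapped
  88%-identity / 17-nt-overlap match rule (at most 4 SNPs over a
  full-length 39-nt pair); `build_catalog()` gives exact identity classes
  and single-linkage "unique spacer" clusters; `search_protospacers()` and
  `pam_context()` scan a virus/plasmid database (match +1 / mismatch −1,
  perfect hits flagged) and extract PAM-flanking context.
* **Array comparison** — `align_arrays()` (spacer-level DP, match +2 /
  gap −1, mismatch columns disallowed: arrays change by acquisition and
  loss, not substitution), `detect_losses()` / `population_losses()`
  (internal gap runs flanked by matching spacers), `group_ancestral()`
  (shared-context single-linkage groups, trailer-only links flagged),
  `leader_internal_check()` (are leader spacers ever found internally
  elsewhere?), and `classify_acquisitions()` — every cross-strain fuzzy
  match becomes exactly one of *ancestral*, *excluded*
  (consecutive-exact) or *independent acquisition*, with offset/SNP and
  leader/trailer annotations.
* **MLSA** — `assign_alleles()`, `concatenate_profiles()`,
  `epidemic_summary()`: frequency-ranked allele ids (N-insensitive),
  concatenated genotypes, SNPs versus a reference strain, dominant-clone
  fraction.
* **Diversity** — `coded_matrix()`, `mlsa_distance()`,
  `coded_array_distance()`, `bin_otus()` (complete linkage),
  `rarefaction_curve()` (analytic, E[S_n] = S − Σᵢ C(N−Nᵢ, n)/C(N, n)),
  `chao1()` (bias-corrected, S_obs + F₁(F₁−1)/(2(F₂+1))),
  `rank_abundance()`.
* **Forward simulator** — `simulate_population()`: founder lineages with
  binary splitting, PAM-constrained leader acquisition from a shared pool
  of SSV-sized viruses, truncated-geometric spacer loss (mean 2, max 5),
  locus loss, MLSA mutation and gene conversion; emits the same FASTA
  shapes the pipeline consumes plus a complete ground-truth event log
  (`replay()` reproduces every strain exactly; `summary_stats()` scores
  recovery).

## Worked example

Simulate a small population, run the pipeline, and summarise:

```r
library(spacerdiv)

cfg <- sim_config(n_strains = 12, n_founders = 3, extra_steps = 3)
sim <- simulate_population(cfg, seed = 42, out_dir = "simdir")

arrays  <- load_locus_fasta(file.path("simdir", "crispr.fasta"))
catalog <- build_catalog(spacer_table(arrays))
catalog
#> <spacer_catalog> 718 spacers: 244 exact classes, 235 unique (single linkage, 88%/17 nt)

pairs <- classify_acquisitions(catalog, arrays)
acquisition_end_summary(pairs)
#>         end_class  n   fraction
#> 1   leader-leader  4 0.04166667
#> 2 trailer-trailer 32 0.33333333
#> 3           mixed 60 0.62500000

group_ancestral(Filter(function(a) a$locus == "C", arrays))
#> <ancestral_groups> locus C: 12 strains in 3 groups (min_run 2)

profiles <- concatenate_profiles(sim$mlsa, reference = "S01")
profiles
#> <genotype_table> 12 strains x 12 loci (6684 bp concatenated), 2 genotypes, reference S01
epidemic_summary(profiles)$dominant_fraction
#> [1] 0.9166667

chao1(bin_otus(mlsa_distance(profiles), 0))
#> <diversity_estimate> S_obs 2 (F1 1, F2 0), Chao1 2.00 from 12 individuals
```

Reading the output: 718 sequenced spacers collapse to 235 unique spacers
under the 88/17 rule; 96 cross-strain matches survive ancestry screening
as independent acquisitions of overlapping protospacers, most involving
conserved trailer or mixed ends here because this small simulation is
dominated by old shared windows. The three planted founder lineages are
recovered exactly as the three ancestral groups at locus C, while MLSA
sees only two genotypes with one clone at 92% — the core-gene view that
the CRISPR view splits apart.

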