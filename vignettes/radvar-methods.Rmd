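---
title: "Methods: models, thresholds and design choices in radvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, thresholds and design choices in radvar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`radvar` analyses intragenomic and intraspecies 18S rDNA variation in
long-read amplicon data from individually isolated, morphologically
identified specimens. This vignette documents the models and procedures it
implements, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the choices made where the design was
genuinely open. It states no empirical result that the test suite does not
itself compute.

## The vetting model

A vetted dataset is defined by four rules applied in a fixed order:

1. **Confidence** (`min_confidence`, default 0.3): ASVs whose single
   reported taxonomic-assignment confidence falls below the threshold are
   removed everywhere. Only one confidence per ASV is available in the
   supported input layouts, so no per-rank treatment is attempted.
2. **Taxonomic consistency**: within each specimen, counts of ASVs whose
   assigned family (the parsed family rank of the lineage string, trimmed
   and case-folded; no fuzzy matching) differs from the specimen's
   morphological family are zeroed. Specimens flagged `relaxed_filter` —
   naked or putative-juvenile individuals without a confident
   morphological family — instead retain any ASV assigned within a
   polycystine order (`scope_for_relaxed`).
3. **Abundance** (`min_reads_presence` = 3, `min_asv_reads_somewhere` = 3):
   cells below the presence threshold are zeroed; ASVs that then fail to
   reach the global threshold in any specimen are removed entirely.
4. **Specimen total** (`min_specimen_reads` = 5): specimens whose surviving
   read total falls below the threshold are removed. ASVs whose only
   surviving reads sat in removed specimens are dropped with them (they
   carry zero remaining reads); attributing them to the specimen stage
   keeps `vet_dataset()` idempotent.

The source narrative does not say whether the global ASV rule is
re-evaluated after specimen removal, nor whether the 5-read specimen total
is counted before or after presence-zeroing. Defaults: the global rule is
evaluated once, before specimen removal, and the specimen total is counted
after zeroing ("taxonomically-consistent ASV reads" read as reads of
retained ASVs). `strict_reevaluate = TRUE` re-applies the global rule
afterwards, and the default report always lists the ASVs the strict mode
would additionally drop, so the difference is visible rather than silent.
Every read of the input is attributed to exactly one fate
(`report$mass_balance`), which the tests verify as a partition invariant.

## V4 extraction and merging

Primer matching is IUPAC-aware on both sides: two positions are compatible
when their IUPAC sets intersect (the usual in-silico PCR convention).
Matches are ungapped, case-insensitive, fully inside the sequence, and
reverse primers are additionally scanned as their reverse complement. The
best hit has the fewest mismatches, ties broken leftmost for the forward
and rightmost for the reverse primer — the geometry that maximises the
enclosed region of a single rDNA locus. Defaults: `max_mismatch = 0`
(matching the exact-pattern search the source workflow performed in an
alignment viewer), with a tolerant mode (≤ 2) available for divergent
taxa.

The extracted V4 region *excludes* the primer-matched segments, so merged
read counts depend only on the hypervariable interior; an
`include_primers` flag exists for layouts that keep them. Merging sums
counts over ASVs with byte-identical extracted V4 strings, conserves
per-specimen read totals over the merged subset (a tested invariant), and
reports ASVs without an extractable V4 separately. Merging is performed
across the whole chart rather than per order: order templates diverge far
beyond the V4 region, so cross-order identical V4s do not arise in
practice, and a collision would be visible in the provenance map.

## Richness, rank profiles, classification

Relative abundance is always computed against the specimen's post-vetting
total (pre-vetting totals are not part of a vetted chart). Threshold
comparison is inclusive (`>=`), following the wording "at least"; an ASV
sitting exactly on a threshold counts. Medians of even-sized groups are
the mean of the two central values, so half-integer medians are
representable. Rank-abundance ties are broken lexicographically by ASV id,
making profiles deterministic.

The three-way intraspecies classification is defined for morphospecies
with at least two specimens morphologically identified to species rank
(genus-level and open-nomenclature groups are excluded):
`SHARED_DOMINANT` requires a single ASV belonging to every specimen's
dominant *set* (exact count ties are preserved as sets, not broken);
otherwise `SHARED_ASV_DIFFERENT_DOMINANTS` requires some ASV present with
≥ 3 reads in every specimen; otherwise `NO_UNIVERSAL_ASV`. The three
categories are mutually exclusive and exhaustive; the test suite checks
agreement with an independent set-logic oracle over systematic small
charts.

## p-distances

For an aligned pair, `p = differing retained sites / retained sites`.
Pairwise deletion (default) retains sites where neither member has a gap;
complete deletion removes set-wide gap columns first. Within-group means
average all unordered pairs; a singleton group yields `NA` (the N/A
convention of per-specimen distance tables), never an error. Between-group
means average all cross pairs and are symmetric.

Group computations require equal-length sequences — either an externally
supplied MSA or indel-free data (the synthetic generator's default). They
are deliberately not auto-aligned: silently choosing alignment parameters
would make distances irreproducible. For pairs, `align_pair()` provides a
deterministic Needleman–Wunsch global alignment (match +1, mismatch −1,
gap −2; traceback prefers substitution over a gap in the first sequence
over a gap in the second), verified against an exhaustive recursive oracle
on short sequences. The all-pairs distance matrix is computed via
base-indicator cross-products, which makes hierarchies over hundreds of
ASVs effectively instantaneous; any character mismatch (including IUPAC
ambiguity codes) counts as a difference, matching the literal definition.

Hierarchy levels: intragenomic = ASVs present in one specimen;
intraspecies = unique ASVs pooled over all species-rank specimens of a
morphospecies; interspecies = between pooled morphospecies groups of the
same order, orders summarised separately. Only species-rank specimens
enter the two upper levels, avoiding mixed taxonomic levels in one
analysis.

## Chimera candidates

The screening heuristic quantifies "long-branching" as a stem branch
longer than `long_branch_factor` (default 3) times the median tip branch
length — the original workflow used visual inspection, so the factor is an
explicit knob and the output is advisory. A candidate is a maximal
ASV-only clade (or single ASV tip) with no reference tips and fewer than
`read_threshold` (default 50) summed reads. Flags never remove anything;
removal is an explicit vetting input. The module exports the first and
last ~300 bases of each flagged ASV for external split-query database
checks. Flag sets are invariant under tip reordering and re-rooting at a
reference tip, and monotone in both knobs (tested).

## The synthetic generator

The generator encodes the study's qualitative structure and printed
summary scales; it is a test harness, not a claim about radiolarian
biology.

* **Scale**: the default species table carries the study's 14
  multi-specimen morphospecies with their real specimen counts and
  observed variation categories (1 / 4 / 9 across the three categories);
  read depth is log-normal with arithmetic mean 22,617 reads (the study's
  mean) and `sdlog = 0.6`, a typical amplicon depth spread.
* **Dominance**: haplotype frequencies follow a one-parameter geometric
  decay per order, set to the observed median rank-1 read shares
  (Collodaria 0.77, Nassellaria 0.92, Spumellaria 0.60). This reproduces
  the rank-1 contrast between orders but under-represents the long flat
  tail of rare variants seen in real Collodaria (a geometric tail decays
  faster than the observed rank-abundance curves), so observed synthetic
  richness per specimen is lower than the study's medians. Tests that
  depend on deep richness therefore do not exist; tests use the rank-1
  share and category structure, which the law does reproduce.
* **Divergence**: per order, an ancestral ~1,450-nt template carries
  concrete planted V4 primer sites (protected from mutation — primer
  sites are conserved in real 18S too, which is why they are primers).
  Morphospecies ancestors, subgroup ancestors and per-genome haplotypes
  are produced by independent per-site substitution with rates inverted
  from the target pairwise distances, including the two-branch
  back-mutation correction `P(diff) = 2r(1−r) + (2/3)r²`. Mutants are
  drawn conditioned on carrying at least one substitution — a silent
  mutant would be the same ASV and collapse at deduplication, which would
  otherwise inflate observed pair distances — and the per-branch rate is
  calibrated under that conditioning so the expected within-genome mean
  equals the order target. Genomes whose one-substitution floor exceeds a
  very small target (e.g. 0.001 with ≥ 4 distinct ~1.4-kb haplotypes)
  saturate at the floor; the order-level average stays within a few
  percent of target, inside the 20 % recovery tolerance.
* **Truth forcing**: categories hold by construction — the subgroup
  ancestor is shared by every specimen of its subgroup and dominant unless
  the specimen is a designated "flip" (which promotes a private haplotype
  to rank 1); multi-subgroup morphospecies have disjoint haplotype sets,
  enforced by redrawing colliding subgroup ancestors.
* **Injections**: noise variants are fresh 1–2-read single/double mutants
  with the correct family lineage (removable only by the presence rule);
  contaminants are random sequences with non-polycystine lineages and
  3–30 reads (removable only by the taxonomy rule). Injection bookkeeping
  makes recall/precision exactly scorable.
* **Not emulated**: indels (kept out by default so truth distances are
  exact and alignment trivial; `align_pair()` exists for data that need
  it), PCR chimeras, sequencing-error models beyond low-count singletons,
  copy-number dynamics (depth presets stand in for solitary/colonial
  copy-number differences), and the real data's heavy rank-abundance
  tail. A green recovery test therefore establishes that the pipeline
  recovers planted structure under multinomial read sampling — not that
  it would be robust to artefact classes the generator does not produce.

## Numerical conventions

Counts are absolute integers; relative abundances are derived, never
stored. Confidence values outside [0, 1] are clipped with a warning (some
classifier exports overshoot slightly). All randomness flows from one
integer seed; `generate_dataset()` is bit-reproducible. Degenerate inputs
are values, not errors, wherever the field convention says so: absent V4
regions, singleton distance groups, empty charts and empty order groups
all propagate as explicit absences.
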