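---
title: "Benchmarking taxonomic profilers in undercharacterized communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking taxonomic profilers in undercharacterized communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdmbench)
```

## Why this framework exists

Environmental metagenomes — soils, oceans, animal guts — are dominated by
species absent from reference databases. A profiler evaluated only on
communities of well-characterized genomes is being tested on the easy part
of the problem. `mdmbench` builds synthetic communities in which the
uncharacterized ("dark matter") fraction is a controlled design parameter,
and evaluates profiler outputs under a protocol that neither rewards nor
punishes a method for the part of the community it could not possibly
name.

The package deliberately stops at the boundaries of the profilers
themselves: it emits read-simulator configurations (CAMISIM INI dialect)
and consumes profiler/assembly outputs as tables. Nothing here shells out
to external tools.

## Community construction

### Genome classes

A `genome_catalog` holds three characterization classes:

* `ncbi_available` — species present in the reference taxonomy before the
  profiler-database cutoff; the "known" side of a community.
* `new_ncbi` — species added to the taxonomy after the cutoff. These are
  characterized *now* but invisible to every profiler database, so they
  count as uncharacterized in a benchmark.
* `new_sgb` — species-level genome bins with no species-level placement at
  all; their lineage stops at genus, family or order.

Each record carries an `available_rank`: the lowest rank at which the
genome counts as NCBI-available. This single field drives the evaluation
restriction (below). Curation rules follow the source protocols exactly:
genome quality is scored as completeness − 5 × contamination; at most 10
new SGBs per genus enter a profile (genus-unknown SGBs form their own
capped group); and a new SGB that is >90% complete, <5% contaminated and
names a species already in the reference list *replaces* the reference
genome, on the reasoning that an environmental bin better represents the
strain actually present.

### Abundance model

Abundances are log-normal: weights are `exp(N(mu, sigma^2))` on the
natural-log scale, with defaults `mu = -3`, `sigma = 1` and grid values
`sigma` ∈ {0.5, 1, 2, 4}. The characterized block respects real-data rank
structure: the species list ranked by observed mean abundance is truncated
to `n_species * (1 - unknown_prop)`, randomly split into two equal groups
that preserve internal order (the first group takes the extra member when
the count is odd), interleaved, and assigned a descending-sorted vector of
draws. Top-ranked species therefore *tend* to dominate without being
pinned to fixed abundances. The uncharacterized block receives unsorted
draws in selection order: the rank information that justifies sorting
exists only for characterized species, so imposing it on the unknown block
would fabricate structure. Both blocks are rescaled so the unknown mass
equals `unknown_prop` exactly — the nominal dark-matter fraction holds by
both species count and abundance.

### Genome-size matching

To control genome-size skew the target sizes follow the geometric sequence
`s_j = median_size * r^(j - (n-1)/2)` with `r = (k-1)/k` and
`k` ∈ {40, 100, 250} (smaller `k`, wider spread). The stated rule —
a sequence "normalized to the median" — does not pin down the centring; we
centre the exponent at `(n-1)/2` so the sequence's geometric centre equals
the median genome size, which makes the middle entry exactly the median
for odd `n` and leaves the total size budget approximately invariant under
`k`. Known genomes are slotted into the sequence first (descending length,
each taking the free slot with minimal absolute size difference); the
remaining slots are then filled greedily from the uncharacterized pool in
sequence order. Ties break deterministically (earliest slot, then
lexicographic genome id).

### Mutation and read-simulator output

An optional per-base substitution rate (grid {0, 0.01, 0.02, 0.05};
default 0) mutates every A/C/G/T position independently and uniformly to
one of the other three bases, leaving ambiguity codes untouched. This
emulates divergence between a database genome and an environmental strain;
it does **not** model conserved regions, so mutated fixtures are adequate
for testing mutation-rate recovery and sketch behaviour but are not
biologically realistic read inputs. `emit_camisim_config()` writes the
INI config (depth in Gbp in the `size` field, art_illumina error profile,
150-bp paired-end reads), the genome-to-id and metadata tables, and an
abundance column that sums to 1; emission is byte-deterministic so a
rerun from the same manifest reproduces the files exactly.

### Seeding

Every design carries one root seed; each stochastic sub-step (known-block
split, known draws, unknown draws, per-genome mutation, Mantel
permutations) derives its own stream via a labelled integer hash
(`derive_seed`), all below 2^31. Identical designs therefore give
identical profiles, FASTA and configs, and grids expanded twice from the
same core agree seed for seed.

## Evaluation protocol

### Harmonization

Different profilers spell the same taxon differently. Names are resolved
through a synonym-aware index built from `names.dmp`/`nodes.dmp`
(pipe-delimited dump dialect), after normalization: trim, collapse
whitespace, underscores to spaces, case-fold. A name matching several ids
resolves to the smallest id with a warning — the reference data does not
say how such homonyms should resolve, so we pick the deterministic
option. Unresolvable names are data, not errors: their mass is tracked as
"unmappable".

### Thresholding and unknown mass

Assigned profiles are thresholded at 0.05% relative abundance (the
false-positive filter; `theta` is always compared against the profile
total at call time), then unknown-labeled mass — blank names, or names
containing "noname" or "incertae" — and unmappable mass are removed and
the survivors renormalized. The threshold is applied once, not re-applied
after unmappable removal; the prose of the source protocol is ambiguous on
this point and a second application would only compound renormalization
drift. For assembly pipelines the unknown fraction is the sum of reads
aligned to no MAG, low-quality-MAG mass, and unplaced-MAG mass.

### Restriction to the available truth

At each evaluation rank (phylum, family, genus, species) the true profile
is restricted to genomes NCBI-available at that rank and renormalized. A
genome known only to family level is excluded at species and genus — a
method calling it unknown there is *right* — but contributes at family and
above, where failing to name it is an error. This is the core fairness
device of the whole benchmark: methods are never penalized for refusing to
name what the reference cannot name, and never rewarded for inventing
names there.

### Metrics

Per rank: precision, recall and F1 over taxon-id sets, Bray–Curtis
dissimilarity (vegan `vegdist`) and intersection-over-union. Per dataset:
a Mantel test (vegan `mantel`, Pearson on the upper triangle, 999
permutations by default — the delegated implementation's convention, since
the protocol names the tool but not the permutation count) between true
and assigned Bray–Curtis matrices computed from *full* profiles (naming is
irrelevant to structure, so unmappable taxa stay in); Spearman correlation
of inverse Simpson indices; and the OLS slope of estimated on true unknown
fraction (slope 1 = perfectly calibrated dark-matter estimation).

### Genome recovery

An uncharacterized genome counts as recovered when some MAG (i) is at
least 50% complete and less than 10% contaminated, (ii) is *strictly*
nearer to that genome than to any other input genome by Mash distance —
ties conservatively fail, and (iii) has its NCBI-mappable taxonomy
contained within the genome's (stopping higher is fine, contradicting is
not). Recovered abundance sums the *true* abundances of recovered
genomes. The completeness gate uses ≥ 50% (the recovery criterion's
wording) even though the generic MAG-retention step elsewhere says
"> 50%"; the divergence is deliberate and documented here. Distances come
from bottom-`s` MinHash sketches of canonical 21-mers (k = 21, s = 1000,
the published Mash convention; the protocol names the tool but not its
parameters) hashed with a fixed 64-bit FNV-1a truncated to 53 bits so
hashes are exact in doubles and sketching is fully deterministic. A
precomputed distance matrix can bypass sketching entirely.
`optimal_coverage_threshold()` finds the coverage cut separating recovered
from non-recovered genomes: among misclassification minimizers it returns
the midpoint of the widest separating gap.

## Synthetic fixtures: what they do and do not show

`fixture_spec()` worlds are rank-complete taxonomies with one genome per
species, log-normal genome sizes, i.i.d. uniform-base sequences, and
profiler-error emulation (`perturb_profile`: drops, multiplicative
log-normal abundance noise, false positives drawn from the fixture
taxonomy, rank truncation, declared unknown mass). Because sequences are
i.i.d., unrelated genomes share essentially no 21-mers and Mash distances
are near 0 or near 1; this is ideal for testing the recovery logic but
says nothing about borderline intra-species distances (~0.05) in real
data. Likewise the error emulation reproduces the *modes* of profiler
failure, not any particular profiler's biases; a passing test suite
demonstrates the correctness of the protocol arithmetic, not the field
performance of any method.

## Numerical choices and degenerate inputs

* Mass conservation is enforced to 1e-9 on profile sums and 1e-12 in
  harmonization (mapped + unmappable = input total).
* Degenerate profiles (everything sub-threshold, nothing mappable,
  nothing available at a rank) raise a dedicated condition class;
  orchestrated evaluation reports them as flagged rows instead of
  aborting a whole dataset.
* All ties anywhere (quality scores, size matching, abundance ranking,
  ambiguous names) break lexicographically, making every pipeline output
  a pure function of its inputs and seed.
* The identity check — truth fed back as the assignment — holds exactly
  at `theta = 0`. With a positive threshold the protocol is intentionally
  asymmetric (the assignment is thresholded before aggregation, the truth
  after restriction), so exact identity is not expected there;
  `evaluate_sample(threshold_truth = TRUE)` symmetrizes it when needed.

## Problem sizes

The shipped checks use worlds of 16–1,200 species with genomes of 4–20 kb,
one-parameter-at-a-time grids at 3 seeds, 20-fixture oracle comparisons,
10^4-draw distribution recovery and a 1 Mb mutation fixture. These sizes
were chosen so the whole suite exercises every code path, including the
largest grid designs (600 species, 450 of them uncharacterized), while
remaining comfortably reproducible on a laptop; the statistical assertions
(binomial and multinomial 99% bounds, 5% σ recovery) are sized to their
sample counts, not to wall-clock convenience.

## Known limitations

* Uniform-random fixture sequences (see above) — no conserved regions, no
  realistic k-mer spectra.
* The framework evaluates profiles, not reads: read-level ground truth
  (which read came from which genome) is the read simulator's concern.
* GTDB↔NCBI translation, live taxonomy lookups, and merging multiple
  taxonomy versions are out of scope; one dump pair defines the universe.
* PERMANOVA and per-taxon differential abundance are deliberately left to
  external statistics tooling.
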