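---
title: "Stepwise threshold clustering: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stepwise threshold clustering: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stclust)
```

## The genotyping problem

Multigene families such as the vertebrate MHC class II loci are usually
amplified with primers conserved across paralogous loci, so a single PCR
co-amplifies every allele an individual carries - anywhere from 2 to about
12 sequences for a 6-locus system. Deep amplicon sequencing of such
reactions yields, per barcoded sample, a *sample library* of reads that
mixes true allelic sequences with PCR and sequencing artifacts. Two
well-known failure modes make per-sequence classification unreliable: the
*gray zone*, where low-frequency alleles and high-frequency artifacts
overlap in read counts, and the *similar-allele problem*, where two real
alleles differ by only a couple of bases and the rarer one looks like an
error of the commoner one.

Stepwise threshold clustering (STC) sidesteps per-sequence classification.
It groups a sample's reads into clusters of similar sequences and decides
allele status *per cluster*: each true allele should nucleate one cluster
containing the allele itself as the dominant sequence plus its cloud of
derived artifacts. Genotyping one sample proceeds in four phases:

1. **Read preparation** (`demultiplex()`): reads are assigned to samples by
   their dual barcodes, stripped of barcodes and primers, and kept only if
   the intra-primer sequence reaches a minimum length (default 200 bp for
   a 213-bp amplicon, ~94%). Reads whose barcode pair matches no sample,
   or matches two samples equally well, are discarded rather than
   guessed.
2. **Sequence combination** (`combine_library()`): pairs of sequences
   where one member is a clear length-variant artifact of the other
   (pyrosequencing's dominant error mode is a homopolymer
   over-/under-call) are *combined* - the artifact's reads are converted
   to reads of the correct-length source. Pair types are defined on a
   fixed global alignment: (I) one indel; (II) one insertion plus one
   deletion; (III) one indel plus one substitution; (IV) one indel plus
   two substitutions; (V) everything else, never combined. A pair is
   combined only if the first member has the expected amplicon length, is
   strictly more common, and the derived member is not ambiguously
   derivable from several sources.
3. **Stepwise clustering** (`run_stc()`): reads are clustered at a
   similarity threshold γ that starts at the library's minimum pairwise
   similarity and rises by 1 percentage point per round. After each round
   every cluster is classified: **good** if it holds at least a fraction
   θ of the library *and* its dominant/subdominant read ratio exceeds δ;
   **small** if it passes dominance but not size; **ambiguous** if it
   fails dominance. Good and small clusters are exempted from further
   rounds; ambiguous clusters (which likely mix two alleles) are pooled
   and re-clustered at the next, stricter γ. Residual ambiguous clusters
   after the final round are split in proportion to their two most
   frequent correct-length sequences.
4. **Post-processing** (`promote_dropped()`, `classify_chimeras()`):
   small clusters are cross-checked across samples - if a small cluster's
   sequence labels good clusters in at least ε *other* samples and the
   cluster holds at least 3 reads, it is promoted to a *dropped* true
   allele. Finally each allele is screened as a potential PCR chimera: an
   allele that looks like a single-crossover recombinant of two other
   alleles and co-occurs with possible parents in **every** sample where
   it appears is removed; recombinants that appear without parents
   somewhere are taken to be naturally segregating.

The clustering step is a quasi-Dirichlet ("Chinese restaurant")
sequential process: reads enter in random order; each read joins the most
similar existing cluster whose current label (its dominant sequence)
is at least γ-similar, or founds a new cluster; labels are updated after
every insertion, and identical reads always co-cluster. Because the only
stochasticity is the entry order, each round is repeated (default 100
times) and every sequence is assigned to its modal cluster label.

## Parameters

| Parameter | Meaning | Default | Rationale |
|---|---|---|---|
| θ (`theta`) | minimum cluster share of the library | 1/22 | `recommend_theta()`: 1/(2 × loci × safety); 1/22 is the calibrated value used for a 6-locus system |
| δ (`delta`) | dominant/subdominant ratio that must be exceeded | 0.82/0.18 ≈ 4.56 | `recommend_delta()`: with ~82% of reads error-free, a one-allele cluster's ratio should not fall below error-free/erroneous |
| γ start | first similarity threshold (%) | auto | floor of the library's minimum pairwise similarity, so round 1 forms a single all-inclusive cluster |
| γ end | last threshold (%) | 97 | stopping just below 100 keeps minor-error artifacts attached to their source clusters |
| γ step | increment per round (%) | 1 | the published schedule |
| replicates | clustering replicates per round | 100 | enough for a stable per-sequence mode |
| ε (`epsilon`) | other samples needed for an allele to be "common" | 3 | promotion evidence across samples; the focal sample never counts toward its own promotion |
| `min_dropped_reads` | smallest promotable small cluster | 3 | conservative floor against barcode bleed-through and contamination |
| `expected_len` | amplicon length (bp) | 213 | the MHC class IIβ exon-2 amplicon the defaults target |
| `min_library_size` | smallest genotypable sample | 80 reads | below this, alleles are likely missing outright |
| `subsample_cap` | largest library used | 1000 reads | phase-2/3 cost grows with the square of unique sequences |

The size criterion uses `>=` and the dominance criterion a strict `>`;
single-sequence clusters have an infinite dominance ratio. θ's
denominator is the post-filter, post-subsampling library size, fixed
across rounds.

## Numerical and design choices

*Alignment.* All difference profiles and percent similarities come from
one fixed scheme: end-to-end global alignment with match +1, mismatch -1
and linear gap cost 2 per column (each gap column counts as one indel, so
a 2-base gap is two indels). Similarity is 100 × matches / alignment
columns, which makes terminal length differences count against
similarity. Alignments are computed with `Biostrings::pairwiseAlignment()`;
gap counts are derived from the score identity
(gaps = (matches − mismatches − score)/2), which, unlike the `nindel()`
accessor, includes terminal gaps. Ties among equal-scoring alignments are
resolved by the aligner's deterministic traceback; only the counts, not
the gap placement, feed the method.

*Combination order and idempotence.* Types are processed I → II → III →
IV with counts re-validated against the current library state, and the
sweep over the four types is repeated until no further combination
applies. The fixed point guarantees that running the phase twice changes
nothing, which a single pass cannot (an earlier combination can raise a
source's count above a pair that previously failed the "more common"
test). When one derived member could combine with several sources of one
type, the default rule follows the more common source (an exact tie
skips the member); `conflict = "strict"` never combines such members.

*Clustering tie-breaks.* A read equally similar to two clusters joins
the one with more reads, then the lexicographically smallest label; the
same rule picks a cluster's dominant among count ties. Modal labels are
opaque group keys: if sequence x's modal label is L while L's own modal
label is M, x and L stay separate - no transitive merging. These choices
make a run fully reproducible given a seed.

*Sequence-level processing.* Reads are processed as unique sequences
with counts; the random "focal read" order is realised by drawing
sequences without replacement with probability proportional to their
read counts. Because all reads sharing a sequence must co-cluster, this
reproduces read-level sampling exactly while keeping each replicate
linear in unique sequences.

*Splitting.* A residual ambiguous cluster of `n` reads with top two
correct-length counts d and s yields sub-clusters of `round(n·d/(d+s))`
and the remainder; sequences of unexpected length are skipped when
choosing the pair (the third most frequent sequence stands in). Clusters
with fewer than two correct-length sequences are kept whole as small,
with a warning.

*Degenerate inputs.* Empty libraries yield empty cluster sets;
single-sequence libraries skip clustering (γ start is clamped to γ end);
correlations are reported absent rather than fabricated when fewer than
three informative points or zero variance remain.

*Seeding.* One global seed derives per-sample seeds by a stable string
hash of the sample id, so adding or removing one sample never perturbs
the other samples' clusters.

*Filter order.* Barcode identification precedes the length filter. The
order only affects how discards are attributed in the preparation
report, not the final libraries; fixing barcode-first gives unambiguous
accounting.

## The synthetic-data generator

`simulate_run()` emulates the kind of run the method targets: a pool of
213-bp alleles at most 90% similar to each other (optionally with
designated 2-bp-apart pairs to exercise the similar-allele problem, and
a designated low-efficiency subset emulating a weakly amplifying
divergent locus), samples carrying 2-12 alleles, library sizes of
80-1000 reads, and per-read errors calibrated so 82% of reads are
error-free - homopolymer indels (a run of identical bases expanded or
contracted by one, probability 0.12 per read) dominating substitutions
(probability ≈ 0.068), matching pyrosequencing's error profile. Chimeras
are formed, at a configurable low rate, as single crossovers between two
co-amplified templates at a uniform breakpoint. Every read carries a
provenance record, so recovery can be scored exactly
(`recovery_report()`), distinguishing *missing* alleles (zero reads in
the library, unrecoverable in principle) from *dropped-and-lost* alleles
(reads present but no call).

What the generator does **not** emulate: flowgram-level 454 noise,
position- and motif-dependent substitution spectra, quality-score
structure, chimera formation biased toward late PCR cycles, and
template-specific amplification interactions. Passing the simulation
checks therefore demonstrates the algorithm's correctness under its own
assumptions - clustered artifact clouds around true alleles with a known
error budget - not performance on any particular instrument's quirks.

## Validation problem sizes

The test-suite and acceptance runs use: the worked-example arithmetic at
a 330-read library; zero-noise round trips (6 samples × 300 reads, 6
alleles); the calibrated error mix at 20 samples × 400 reads with 6
alleles per sample (θ = 1/22, δ = 4.55, ε = 3); chimera screens on
constructed four- and five-sample genotype sets; and efficiency
diagnostics at 16 samples × 400 reads with one allele at relative
efficiency 0.2. These sizes sit at the small end of a real run and were
chosen so the whole validation completes in minutes while keeping every
per-sample quantity (reads per allele, cluster shares) at realistic
magnitudes.

## Known limitations

- The published worked example's input library is distributed through
  the original study's data archive and is not redistributed here;
  `load_fixture("sample_x", path = ...)` loads a user-downloaded copy,
  and the corresponding acceptance test can only run with that file in
  place.
- Pair enumeration is quadratic in unique sequences; libraries are
  subsampled (default cap 1000 reads) rather than indexed, so results
  are exactly reproducible.
- Zygosity and locus assignment are out of scope: the output is a
  presence/absence genotype per sample.
- Chimera screening considers exact single crossovers by default
  (`max_mismatch = 0`); heavily mutated chimeras are expected to be
  removed earlier by the size criterion instead.
- The phase-2 rules target indel-dominated error profiles; for
  substitution-dominated chemistries most pairs are type V and the phase
  is effectively a no-op, which is safe but confers no benefit.
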