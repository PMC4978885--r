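---
title: "Tracer k-mer graph clustering for comparative LTR retrotransposon abundance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracer k-mer graph clustering for comparative LTR retrotransposon abundance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Plant genomes vary enormously in size, and much of that variation is
carried by long terminal repeat (LTR) retrotransposons of the *gypsy* and
*copia* superfamilies.  Estimating how much of a genome each
retrotransposon sublineage occupies — and comparing those estimates across
related species — is hard precisely where it matters: large, repeat-rich
genomes that cannot be assembled from low-coverage short reads.

`ltrtracer` implements a reference-guided, assembly-free estimator.
Low-coverage single-end reads are clustered by all-by-all sequence
similarity; reads from a repeat family collapse into large clusters whose
read counts are proportional to the family's genomic abundance, while
single-copy DNA stays in clusters too small to pass a size threshold.  To
give clusters an identity, a panel of full-length reference elements is
cut into overlapping 100 bp "tracer" k-mers that enter the clustering
alongside the reads.  A cluster that captures tracers inherits the
superfamily and sublineage of those tracers, so per-cluster read counts
convert directly into per-sublineage genome proportions that are
comparable across species clustered against the same panel.

## The clustering model

Two sequences are joined by an edge when their best overlap (free
end-gap) alignment — scored match $+1$, mismatch $-2$, gap $-3$, against
the partner and its reverse complement — reaches **identity ≥ 0.90**
computed over the aligned columns (internal gaps included) and an overlap
of at least **55 % of the shorter sequence**.  Clusters are the connected
components of this graph; sequences without edges are singleton clusters.
These thresholds, and every other default below, follow the graph-based
repeat-clustering practice the estimator reproduces.

The genomic **repetitive fraction** is the proportion of sampled reads in
clusters whose *read* count reaches `ceiling(1e-4 * n_sampled)` — 0.01 %
of the sampled reads, i.e. 300 reads when 3 M are sampled.  Tracer k-mers
never count toward the sample size, the size threshold, or any numerator:
they are annotation probes, and counting them would inflate the abundance
of panel-like families.  With that exclusion the per-sublineage
proportions plus the unassigned-repeat proportion sum *exactly* to the
repetitive fraction of the same run, a bookkeeping identity the test
suite asserts.

Sampling variation is quantified by replicate runs: each run draws a
fresh random subsample (default five runs of 3 M reads) and the profile
is reported as mean ± SE over runs.

### Tracer decomposition

Each panel element of length $L$ yields $\lfloor (L-100)/15 \rfloor + 1$
k-mers of 100 bp at offsets $0, 15, 30, \dots$ — an 85 bp overlap between
consecutive k-mers.  Because 100 % identity over an 85 % overlap far
exceeds the 90 %/55 % edge rule, the tracer set of one element always
forms a single connected component, giving every element an unbroken
annotation backbone.  No 3′-anchored tail k-mer is emitted when $L-100$
is not divisible by 15; up to 14 terminal bases of an element are
untraced.  A 4,300 bp element therefore yields exactly 281 tracers and a
16,180 bp element 1,073.

### Exactness of the scaled-up implementation

`build_similarity_graph()` materialises every edge and is the reference
implementation.  `cluster_sequences()` computes the same connected
components at scale with three exact accelerations, each of which is
provably lossless rather than heuristic:

1. **Shared-k-mer prescreen.**  Any pair meeting the thresholds has, in
   its optimal alignment, matched runs whose lengths pigeonhole into at
   least 5 shared canonical 8-mers when sequences are ≥ 100 bases (4 at
   ≥ 92, 3 at ≥ 80); shared k-mers are counted as
   $\sum_v \min(\text{mult}_i(v), \text{mult}_j(v))$ so low-complexity
   repeats cannot defeat the bound.  Pairs below the floor are skipped.
   Below 80 bases no useful bound exists and the prescreen is not
   applied (a warning is raised on the fast path).
2. **Banded necessary-score test.**  A qualifying alignment scores at
   least $0.55\,L_{\min}(0.9 \cdot 1 + 0.1 \cdot (-3))$ and lies within
   a bounded diagonal band around its own seed k-mers, all of which the
   prescreen observed; a banded score-only dynamic program over that band
   therefore rejects a candidate only when no qualifying alignment can
   exist.  Survivors get the full alignment.
3. **Union-find shortcut.**  A candidate pair already in one component
   cannot change the partition and is skipped before alignment.

The equality of the two routes — edges and components — is asserted by
tests on simulated read sets against the brute-force all-pairs graph.

## The synthetic-data generator

Because the original sequencing data are genome-scale, validation runs on
synthetic species genomes with known composition.  The generator
emulates:

* a reference panel of full-length elements (two identical terminal LTRs,
  default length `min(400, L/4)`, flanking a random internal region);
  element lengths span 4.3–16.2 kb, the range implied by 281–1,073
  tracers per element;
* species genomes: a uniform-random background receiving `copies`
  mutated copies of each family at uniform random positions.  Mutation is
  substitution-only, in two stages: a species consensus at
  `panel_divergence − copy_divergence/2` substitutions/site from the
  exemplar (shared by all copies), then independent copy mutation at
  `copy_divergence/2`, so pairwise copy divergence ≈ `copy_divergence`
  and copy-to-panel divergence ≈ `panel_divergence`.  Defaults are
  `copy_divergence = 0.03`, `panel_divergence = 0.02`, matching young,
  recently amplified element families;
* uniform 100 bp single-end reads with per-base substitution errors
  (default $10^{-3}$) and flat Phred-38 qualities.

The truth table records each family's exact base fraction, so recovery
tests have a ground truth with no estimation error of its own.

What the generator deliberately does **not** model: indels and solo-LTR
formation (substitution-only mutation keeps identity arithmetic exact; an
indel-bearing variant would exercise the gapped aligner but break the
closed-form divergence oracles), insertion-age distributions, nested
insertions, GC-biased coverage, and satellite/low-complexity DNA (a
percent-scale genome component excluded from the analysis).  Passing
recovery tests therefore show the estimator is correct under idealised
read sampling — they do not certify behaviour under coverage bias or
structural variation in real libraries.

### Choice of validation scale

Recovery runs use genomes of tens of megabases read at ≈ 0.1–0.2×
coverage with 20k–50k sampled reads.  Low coverage matters for realism:
the size threshold separates repeats from single-copy DNA only when
single-copy loci rarely accumulate enough overlapping reads to chain into
a qualifying cluster.  At these scales the binomial sampling error
(≈ 0.2 percentage points at 50k reads) dominates the estimator's residual
biases (junction-spanning reads at copy boundaries), and the recovery
criterion of three binomial standard errors is met with margin.

## Preprocessing

Quality trimming applies, in fixed order: strip terminal bases with
quality < 30; trim ends while any terminal 4 bp window has mean quality
< 25; discard reads shorter than 80 bases.  The first two rules are
iterated to a fixpoint because window trimming can expose a fresh
sub-threshold terminal base — without that iteration trimming would not
be idempotent.  Organelle (chloroplast) reads are removed by 31-mer
containment against the organelle reference: a read is dropped when at
least half of its k-mers (either strand) occur in the reference.  This
reproduces the effect of alignment-based filtering with a single
interpretable parameter and no external aligner; at 31 bp a k-mer hit is
already a near-exact local match, and error-free organelle reads are
removed completely (a tested invariant).  Read subsampling is uniform
without replacement, deterministic per seed, and reports the realised
count when fewer reads are available than requested.

## The read-mapping comparison

The alternative quantification strategy maps each read to the panel
element with the fewest mismatches over an ungapped full-length
placement (both strands, exact-seed accelerated with a seed length chosen
so that any placement within the mismatch budget must contain an exact
seed).  Stringent mapping allows 3 mismatches per 100 aligned bases;
relaxed, 6.

The divergence-bias assay simulates genomes whose TE copies sit at
increasing divergence from the panel while true abundance stays fixed,
then quantifies both ways.  Mapping density falls steeply with divergence
(at 4 % divergence an average read already carries more mismatches than
the stringent budget), producing a strongly negative Spearman rank
correlation of density against divergence; tracer clustering stays flat,
because reads need only 90 % identity to *any* cluster member, not to the
reference itself.  The default divergence grid spans 0–0.08
substitutions/site.  That cap is a design decision worth stating plainly:
beyond ≈ 0.10, reads can no longer form edges with tracers at all under
the 90 % identity rule, so tracer capture itself — not just mapping —
degrades.  The flat-density behaviour of clustering is a property of the
congeneric regime the method targets, not an unconditional guarantee.

## Comparative statistics

Genome sizes in picograms convert at 1 pg = 978 Mb; expected coverage is
$C = LN/G$ with $L$ the read length (default 100; configurable because
the effective post-trim length is usually a little lower), $N$ counting
both mates of each pair, and $G$ the 1C length.  Coverage is reported at
two decimals with round-half-even.  Cross-species association between
genome size and repetitive fraction is measured two ways: an ordinary
Pearson product–moment correlation, and a phylogenetically adjusted
correlation through Felsenstein's independent contrasts (computed via
`ape::pic`), correlated through the origin with $n-2$ degrees of freedom
for $n$ tips.  Trees are pruned with `drop.tip` semantics: removed tips
collapse their degree-2 nodes and sum branch lengths, so surviving
root-to-tip distances are unchanged.  Polytomies are rejected by default;
an opt-in flag resolves them with zero-length branches, with the caveat
that contrasts across zero-length sibling branches are not
standardisable.

The package ships the study species table (names, 2C values, read-pair
counts, repetitive fractions) and a *synthetic* stand-in topology for the
eight-species tree (the hybrid-origin *H. anomalus* excluded), with unit
branch lengths as placeholders — the published source tree's branch
lengths are not available, so contrast correlations computed on the
bundled tree illustrate the machinery rather than reproduce a published
value.  The Pearson correlation over the nine (2C, repetitive %) pairs,
by contrast, is fully determined by the table: $r = 0.9121$,
$P = 0.0006$.

A consistency note on coverage: with $L = 100$ the bundled table's
printed coverages are reproduced exactly for *H. annuus* (0.67) and
*H. divaricatus* (0.29) and to within 0.02 for the remaining rows, the
residual being consistent with a post-trim average read length slightly
under 100 that was never published.

## Numerical and degenerate-input conventions

* All randomness flows through R's RNG under an explicit seed argument;
  every simulator and every pipeline run is byte-reproducible, and the
  temporary seed never disturbs the caller's RNG state.
* Alignment tie-breaks are fixed (diagonal > up > left; best end cell by
  deterministic scan order), and clusters are ordered by decreasing size
  then lexicographically smallest member, so cluster tables are
  bit-identical across runs.
* Cluster annotation takes the majority tracer sublineage (ties to the
  lexicographically smallest label) and flags clusters whose top
  sublineage holds < 80 % of tracers; clusters mixing superfamilies are
  always flagged, making single-linkage chaining artefacts visible
  rather than silently resolved.
* `superfamily_ratio` on a zero copia total returns `NA` with a warning;
  `repetitive_fraction` requires a positive sampled count; empty tracer
  sets yield an all-`unassigned` annotation rather than an error.
* The minimum cluster size uses `ceiling`, so 0.01 % of 2.4 M reads is
  240 — the threshold scales with the realised sample.

## Known limitations

* Single-linkage components can chain distinct families through chimeric
  junction reads when insertions are adjacent; the ambiguity flag marks
  affected clusters but does not split them.  (A community-detection
  pass within components would be the natural extension.)
* At sampled-read counts small enough that 0.01 % is below ~5 reads the
  size threshold stops filtering single-copy overlaps; validation scales
  keep coverage low so this regime is avoided.
* Abundance estimates inherit the panel's reach: families absent from or
  > ~10 % diverged from the panel fall into the unassigned fraction.
* The bundled tree is a placeholder topology; contrast results on it are
  illustrative only.
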