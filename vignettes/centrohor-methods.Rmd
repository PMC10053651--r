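---
title: "Annotating centromeric higher-order repeats with centrohor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating centromeric higher-order repeats with centrohor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centrohor)
```

## The annotation problem

Centromeric satellite DNA is organized hierarchically: a basic repeat unit of
roughly 100-400 bp (the *monomer*; ~171 bp in human alpha satellite) tandemly
repeats along arrays of up to several megabases, and in many centromeres an
ordered run of several distinct monomers itself repeats with very high
(95-100%) unit-to-unit identity, forming a *higher-order repeat* (HOR).
Real arrays additionally contain *local-nested HORs* (LN-HORs): HOR units in
which a sub-span of consecutive monomers is itself tandemly amplified, e.g.
`1-2-3-(4-5)x3-6`. Methods built on the assumption that each monomer occurs
exactly once per HOR unit fragment such regions into partial annotations;
`centrohor` is designed to recover them as single structured units.

The pipeline has four stages:

1. **Block decomposition.** The array is segmented into monomer-sized blocks
   by a dynamic program over states $(i, j)$ — $i$ array bases consumed, $j$
   template bases aligned in the current block — with match $+1$,
   mismatch/indel $-1$ and a free restart from the template end to its start
   at every position. The array ends are treated semi-globally, so terminal
   blocks may be partial; terminal fragments shorter than 60% of the template
   are trimmed. Only the forward strand is aligned: an inverted HOR surfaces
   as a second HOR with the reversed monomer pattern rather than being folded
   onto the forward one.
2. **Block similarity.** For blocks $b_1, b_2$,
   $S = 1 - \mathrm{ed}(b_1, b_2) / \max(b_1.\mathrm{len}, b_2.\mathrm{len})$
   with unit-cost Levenshtein distance, computed by a bit-parallel algorithm
   and verified in the test suite against R's `adist`. Identical blocks are
   collapsed before the all-pairs computation; the full matrix is exactly
   recoverable through the member map.
3. **Monomer inference.** For each threshold $t$ in a schedule
   ($t_0 = 0.94$, step $0.005$, strictly below 1), a graph joins block
   representatives whose similarity strictly exceeds $t$; Louvain community
   detection (resolution 1) yields the monomers, and the array is rewritten
   as a monomer-ID sequence. Multiplicities of collapsed identical blocks
   enter as edge weights ($m_i m_j$, plus self-loops $\binom{m_i}{2}$), which
   makes clustering on the collapsed graph equivalent to clustering the full
   per-block graph. IDs are numbered by first occurrence along the array, so
   labels are reproducible.
4. **Hierarchical tandem repeat mining and HOR assembly** (below), followed
   by threshold selection: the threshold whose HORs cover the largest
   fraction of the monomer sequence wins, ties going to the lowest threshold
   (the most permissive monomer definition consistent with maximal
   structure).

## Hierarchical tandem repeat mining

The monomer sequence is mined bottom-up. With the unit length starting at 1,
all maximal tandem runs (at least two consecutive copies, not extendable by
a full unit on either side) are detected; runs whose region is contained in
another run of the same round are shifted phases of the same tract and are
dropped, and among remaining same-round overlaps the leftmost run wins, with
later runs trimmed by whole units (a remainder survives only with at least
two full units). Each new run is then checked against the *top layer* of
previously saved repeats in original coordinates, with four outcomes: no
overlap saves the run; containment inside an old repeat discards it; a run
covering old repeats replaces them (the old repeats become its children);
partial overlap removes the conflicting flank units and keeps the remainder
if at least two full units survive, applied independently per flank.

Accepted runs are *compressed to a single copy of their unit*: the repeated
region is replaced by one occurrence of the unit, which records the repeat
count, the covered span and the per-copy token content. This choice is what
makes local nesting visible at the next level: an HOR unit whose sub-span
was amplified becomes symbol-identical to a canonical unit after
compression, so canonical and nested units join the same outer tandem run,
and the amplification survives as a child record with its own copy number.
A unit containing a nested span therefore counts that span once — the
CEN15-style unit `1-2-3-4-5-(6-7-8-9)xn-10-11` has unit length 11, which is
the length used in HOR names. After every compression the unit length
resets to 1; when no unit length up to the bound (default 40) updates the
layer, mining stops. Termination is guaranteed because each compression
strictly shortens the working sequence.

Because token spans always partition the original coordinates, a candidate
run that would cut a compressed region in half necessarily overlaps the old
repeat partially and is trimmed or discarded, so expanding the final state
always reproduces the input exactly (`expand_layer`); this losslessness is
asserted property-style in the tests.

## HOR assembly, scoring and naming

Top-layer repeats whose units are rotations of one another are merged into
one HOR (canonical form: lexicographically smallest rotation). Each HOR is
scored

$$\mathrm{HORscore} = cr \times pr, \qquad
  cr = \mathrm{HOR.len} / \mathrm{m.len}, \qquad
  pr = \mathrm{HOR.rn} / (\mathrm{HOR.len} / \mathrm{HORunit.len}),$$

where `HOR.len` is the covered length in *expanded* monomer symbols (so `cr`
is true sequence coverage), `m.len` the monomer-sequence length, `HOR.rn`
the total repeat count and `HORunit.len` the unit length with nested spans
counted once. `pr` equals 1 exactly when instances tile their span without
nesting and drops below 1 with increasing local nesting or over-compression,
balancing coverage against nested degree. Ranking is by descending score
with deterministic tie-breaks (longer `HOR.len`, then smaller
`HORunit.len`, then first occurrence), and names follow `R<rank>L<unit
length>`. Reports highlight the top five HORs with repeat numbers greater
than 10; output files always carry every HOR.

```{r example}
ds <- simulate_hor_array(171, 0.2, 0.01, mode = "ln", seed = 7)
ann <- annotate_array(ds$dna, ds$raw_template, seed = 7)
ann
head(vapply(ann$hors[[1]]$instances, `[[`, character(1), "pattern"))
evaluate_annotation(ann, ds)[c("AN", "canonical_units", "ln_units",
                               "exact_match")]
```

## The simulator and what it does (not) emulate

`simulate_hor_array()` reproduces the benchmark design the package is tested
under: a five-monomer HOR unit repeated 40 times; monomer sizes 100-400 bp;
five templates diverged from one random raw template by substituting exactly
`round(d * size)` distinct positions with `d` in 10-30%; per-instance
divergence of 0.5-2.5% applied the same way; and in LN mode, 20 of the 40
units carry a tandem amplification of 1-4 consecutive monomers to a total of
2-5 copies, confined within the unit. The annotator always receives the raw
(undiverged) template, matching the single-template input contract.

Deliberate simplifications, and hence limits on what passing tests show
about real arrays: mutations are substitutions at distinct positions (no
indels, no transition/transversion structure, no CpG effects), monomer
lengths are uniform within a dataset, there are no array edges mid-monomer,
no inversions, no hybrid monomers and no higher-level layering of several
distinct HOR families. Real centromeres violate most of these; the
simulation validates the mining logic and the interconnection of monomer
inference with HOR coverage, not robustness to assembly artefacts.
`copies = 2` means two total copies, i.e. one extra repeat of the span.

Grid runs derive one RNG stream per dataset from the master seed, so any
cell is re-runnable in isolation and the whole grid is reproducible
bit-for-bit for a fixed seed.

## Numerical and design choices

* Similarities are fractions in $[0,1]$ internally; percent-valued
  parameters are divided by 100 at the interface boundary (the CLI accepts
  `--min-similarity 94`).
* The edge rule is a strict inequality (`similarity > threshold`), and the
  schedule stops at the largest value strictly below 1.
* Substitution counts use R's `round()` (banker's rounding at `.5`, so a
  1.5% divergence on a 100 bp monomer substitutes 2 positions and 2.5%
  substitutes 2).
* Louvain randomness is pinned by a per-threshold seed derived from the run
  seed; with the study's divergence ranges the graphs decompose into
  disjoint near-cliques and the partition is stable across seeds.
* The minimum similarity default of 0.94 reflects reported human HOR
  unit-to-unit identities of 95-100%; arrays from other genomes may need a
  lower floor, at the cost of merging recently diverged monomers.
* The enrichment test assigns instances to 25 equal-width bins by midpoint,
  builds its background from 100 uniform re-placements of the observed
  per-class totals, and reports one-sided upper-tail normal p-values with
  no multiple-testing correction; bins with zero background variance are
  `NA`. The normal approximation requires non-trivial per-bin counts — with
  only a handful of instances per bin the discreteness of counts inflates
  the nominal 5% rate, which is why the calibration check in the test suite
  uses 500 instances over 25 bins (1,000 null draws).

## Problem sizes in the checks

The test suite and the acceptance script run the full benchmark: 360
canonical and 360 LN datasets (the 4 x 3 x 3 grid with 10 replicates),
each decomposed, swept over 12 thresholds, mined and evaluated — about 720
end-to-end annotations per run — plus property checks (200 random sequences
against a brute-force tandem enumerator, losslessness of expansion,
edit-distance agreement with `adist`) and the enrichment calibration. These
sizes were chosen to match the benchmark design exactly while remaining
comfortable on a single CPU.

## Known limitations

Hybrid monomers (blocks genuinely intermediate between two monomer classes)
are assigned to a single community; strand inference and reverse-complement
folding are out of scope; approximate tandem units (mismatched copies within
a run) are not detected, since runs are defined over exact monomer-ID
equality and all sequence-level divergence must be absorbed by the monomer
communities; and unit lengths beyond the mining bound (default 40) are
invisible.
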