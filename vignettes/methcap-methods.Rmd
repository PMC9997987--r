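---
title: "Conversion-aware capture design and evaluation: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conversion-aware capture design and evaluation: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methcap)
```

## The problem

Targeted methylation sequencing couples a cytosine-conversion chemistry with
hybridization capture. Enzymatic methyl-seq (TET2 protection followed by
APOBEC deamination) and bisulfite treatment both rewrite unmethylated
cytosines to thymines on the sequenced strand, so a library fragment no
longer matches the reference genome it came from: a locus with $m$ CpG sites
can present up to $2^m$ distinct post-conversion sequences per strand,
depending on which sites were methylated. Capture baits must therefore be
designed in *converted* sequence space, and their specificity must be judged
against *converted* genomes. methcap implements that design loop and the
analytics used to evaluate the resulting libraries against whole-genome or
reduced-representation callsets.

## The conversion model

Three whole-sequence transforms span the space the screen works in:

* `unmodified` — identity;
* `sense_unmethylated` — every `C` becomes `T` (a fully unmethylated,
  fully converted sense strand);
* `antisense_unmethylated` — every `G` becomes `A` (how a fully converted
  antisense strand reads in sense coordinates).

Per bait, the design enumerates nine sequences: the unmodified original plus
the Cartesian product of four methylation patterns (all CpGs methylated, a
random half, the complementary half, none) with the two strands. The random
split is a single seeded draw per candidate — the seed is derived from
(design seed, candidate id), so overlapping candidates get independent
splits and the whole design is reproducible. Whether the original vendor
pipeline drew its "random 50%" per bait or per target region is not
documented anywhere we could find; per-bait is the more conservative choice
(more distinct permutations enter the screen).

Two modelling decisions deserve emphasis:

* **Non-CpG cytosines always convert**, even in "methylated" variants.
  CHG/CHH methylation in vertebrate blood DNA sits at the conversion error
  floor (well under 1%), so the sequence a methylated locus actually
  presents has its non-CpG cytosines read as T. A bait that kept them as C
  would hybridize worse, not better.
* **Antisense variants are emitted in the reverse-complement frame** — the
  literal oligo a synthesizer would receive — rather than as G→A edits in
  sense coordinates. The two are informationally equivalent; the emitted
  frame makes the FASTA directly orderable.

`N` passes through every transform unchanged, and all transforms preserve
case, because lowercase carries the soft-masking annotation (see below).

## Tiling and composition filters

Candidates of length 80 nt are tiled at 2x density (step = half the bait
length) from the 5' end of each target: offsets $0, 40, 80, \dots$ while the
bait still fits. The count is $\lfloor (L-80)/40 \rfloor + 1$ for targets of
length $L \ge 80$. The upstream vendor's phase and end handling are not
documented, so an `anchor_end` flag (default off) optionally adds one bait
flush with the 3' end; with it, every base of a sufficiently long target is
covered and interior bases are covered twice.

Composition filters mirror standard capture-design practice, with boundary
semantics chosen to match how the bounds are conventionally written:

| filter | bound | boundary case |
|---|---|---|
| repeat masking | mask fraction `< 0.25` (strict) | exactly 25% masked fails |
| GC content | `0.10 <= GC <= 0.80` (inclusive) | 10% and 80% pass |
| cross-hybridization | max hits `<= 10` (inclusive) | 10 passes, 11 fails |

Masking reaches the designer as soft-masked (lowercase) or hard-masked (`N`)
sequence; `compute_mask_fraction()` counts both signals and unions them with
any explicit mask intervals. GC and mask fractions are computed on the
**unmodified** candidate: conversion distorts GC by design, and the filter is
meant to act on the native design space. Candidates containing more than
`n_max` ambiguous bases (default 0) are dropped before filtering because
synthesizers reject them.

## The specificity screen

Each genome in the screening panel contributes three conversion variants
(unmodified, all-C→T, all-G→A) — four genomes give the canonical
12-variant set — and every one of the nine bait permutations is searched
against every genome variant. The per-candidate statistic that feeds the
filter is the **maximum** hit count over all (permutation × genome variant)
pairs.

The conventional tool for this job is BLAST, but published descriptions of
such screens never pin down the task, word size or E-value model, so methcap
defines a deterministic, fully specified hit criterion instead and makes no
claim of numerical equivalence with any BLAST configuration:

> A *hit* is a cluster of local alignments with score at least `min_score`
> (default 40) under unit scoring (match +1, mismatch −1, gap −2), searching
> both orientations of the bait; alignments whose genome intervals overlap
> are merged and counted once; per-pair counts are capped at `max_tabulated`
> (default 500, echoing screens that tabulate only the top hits).

The implementation is seed-and-extend: exact k-mer seeds (default k = 12)
indexed over the genome variant, grouped by genome locality and then split
by diagonal — two seeds can only support the same alignment if their
diagonals differ by at most the total number of gaps a qualifying alignment
can afford, which is $(L \cdot \text{match} - \text{min\_score}) / |\text{gap}|$
(20 for the defaults at $L = 80$) — and finally extended by a banded
Smith–Waterman whose band covers that same gap budget, so banding loses no
qualifying alignment that contains a seed. A two-hit rule (`min_seeds`,
default 2) requires at least two seed matches per cluster before extension;
isolated random 12-mer matches cannot reach score 40, while genuine
near-identical cross-hybridization targets carry dozens of seeds. The
assumption the search rests on is therefore: *every alignment worth counting
contains at least `min_seeds` exact k-mers*. `min_seeds = 1` restores plain
single-hit seeding (used for spot checks in the tests). The test suite
verifies the whole pipeline against an exhaustive, unseeded, unbanded
Smith–Waterman oracle with identical tie rules (diagonal > gap-in-genome >
gap-in-bait) on a hundred seeded fixtures, including planted conversion-space
hits that are invisible in the unmodified genome.

What the screen does *not* do: no E-value statistics, no affine gap model,
no translated search, no persistent index. The point is a reproducible,
oracle-checkable criterion, not BLAST emulation.

## Evaluation analytics

The evaluation half consumes Bismark-style coverage files (chrom, 1-based
position, methylation percent, methylated and unmethylated counts) and
region sets, and reproduces the standard comparison workflow:

* **Depth filtering**: "above 5x" is read inclusively (depth ≥ 5), matching
  the usual "5x or above" phrasing in figure legends; a `strict` flag gives
  the `> 5` reading. Duplicate sites arising from overlapping regions are
  collapsed, and conflicting duplicate counts are a hard error, not a silent
  average.
* **Intersection** uses the single coordinate bridge in the package: a
  1-based site $p$ lies in a 0-based half-open region $[s, e)$ iff
  $s < p \le e$.
* **Matching** keys on (chrom, pos) without strand — coverage files carry no
  strand, so callsets are treated as destranded positions. If an upstream
  pipeline emitted stranded records, the same genomic CpG on opposite
  strands would count as two sites; that is a documented limitation.
* **Correlation** is the plain product-moment correlation of matched site
  percentages; fewer than two sites or zero variance raises an error rather
  than returning a silent 0.
* **Region means** are unweighted means of site percentages (`bedtools map
  -o mean` semantics), not depth-weighted; empty regions are `NA`, not 0.
* **Paired t-tests** compare per-region means between replicate libraries;
  degenerate zero-variance differences are reported explicitly (t = 0, p = 1
  when the mean difference is 0; ±Inf with a warning otherwise).
* **Conversion controls**: the unmethylated spike-in (lambda) reports
  *residual methylation* — the conversion error — over all cytosine
  contexts; the CpG-methylated spike-in (pUC19) reports *retained
  methylation*, i.e. 100 minus the over-conversion rate; CHG/CHH levels are
  pooled over the sample's own chromosomes with controls excluded. All four
  are pooled count ratios, $100 \sum m / \sum (m+u)$, not means of
  per-site percentages. The deliberately asymmetric names (`lambda_error`,
  `puc19_retention`) avoid the ambiguity of calling both a "conversion
  rate".
* **Random promoter tracks**: fixed-length tracks are placed uniformly over
  all eligible placements (chromosomes weigh in by placeable length, tracks
  may overlap each other), intersected with promoter regions, and
  deduplicated by coordinates — the standard construction for comparing
  methods outside the capture panel.

## The synthetic world

The generators state one explicit generative model:

* genome: i.i.d. uniform ACGT, optional soft-masked runs at a target
  fraction;
* targets: non-overlapping fixed-length placements (promoter-like, default
  4 kb, the canonical putative-promoter span);
* methylation: every plus-strand CpG draws a true level — Beta(1, 9)
  (mean 0.1) inside targets, Beta(7, 3) (mean 0.7) outside — giving the
  bimodal promoter-low / background-high contrast a method comparison needs;
  control chromosomes are forced to 0 (lambda-like) and 1 (pUC19-like);
* observation: per-base depth is Poisson — 150x inside targets and 2x
  outside by default, the on/off-target contrast of a well-performing
  capture — and methylated calls are Binomial(depth, $q$) with
  $q = p(1 - \text{overconversion}) + (1-p)\,\text{conversion\_error}$,
  defaults 0.012 and 0.023 (the scale of published EM-seq control
  measurements: ~1.2% lambda error, ~97.7% pUC19 retention);
* duplication, when enabled, inflates reported depths and counts by
  $1/(1-d)$ to emulate a non-deduplicated callset.

Depths are drawn once per base and shared between the depth track and the
callset, so coverage summaries and site depths are mutually consistent. In
the conversion-recovery tests the control chromosomes are placed *inside*
the target list, mirroring the practical recommendation that capture designs
include control baits so conversion can be estimated from deep alignments.

What the generators do **not** emulate: read-level errors and mapping
artifacts, fragment-level correlation between neighbouring CpGs, CpG-island
density structure, RRBS restriction-site bias, and hmC/mC distinction. A
green test therefore establishes that the *analytics* are correct under the
stated model, not that any laboratory protocol performs to a given standard.

## Numerical and degenerate-input choices

* Percent/count conflicts in coverage files resolve in favour of counts
  (percent is derived data); disagreement beyond 0.01 warns.
* Zero-depth coverage records are kept but flagged with a warning.
* GC of an all-`N` sequence is reported as 0 with a warning rather than NaN.
* All randomness flows through one global seed and a deterministic
  seed-derivation hash (command → module → item), so partial re-runs are
  stable; every CLI run writes a JSON manifest with parameters, seed,
  package version and input checksums.
* Target placement retries from derived sub-seeds if rejection sampling
  jams, keeping the output a pure function of the seed.

## Known limitations

* The hit criterion is a stand-in with its own well-defined semantics;
  counts are not comparable to any specific BLAST configuration, and the
  two-hit seeding assumption means an alignment with fewer than two exact
  12-mers (possible only at extreme divergence near the score threshold)
  would be missed.
* Site matching is strand-agnostic by design; stranded callsets must be
  destranded upstream.
* No melting-temperature, secondary-structure or pool-rebalancing scoring:
  the composition filters are sequence-level only.
* The evaluation computes tables and statistics, not figures.
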