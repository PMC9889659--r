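---
title: "Tiling-window methylome analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tiling-window methylome analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methtiler)
```

# The problem

Fungal genomes carry sparse cytosine methylation whose level and genomic
placement change between developmental stages. With one nanopore-derived
methylome per stage — per-site tables of methylated and total read counts
for every cytosine, but no biological replicates — the questions are:
how methylated is each stage globally per sequence context (CG, CHG,
CHH); where does methylation sit relative to genes and transposable
elements (TEs); and which regions differ between stages strongly enough
to call differentially methylated.

`methtiler` answers these with a deliberately simple, fully specified
pipeline whose every stage is testable against an independent oracle or
a planted ground truth.

# Context classification

Each cytosine is classified on its own strand reading 5′→3′: a C
followed by G is CG; otherwise, C followed by H,G is CHG and by H,H is
CHH, with H ∈ {A, C, T}. On the minus strand the same rule is applied to
the complement reading toward decreasing coordinates (i.e. at genomic G
positions). Two choices deserve note:

* **Unclassifiable cytosines are excluded, not guessed.** A terminal C
  whose trinucleotide runs off the contig, or one whose required
  downstream bases include N or another ambiguity code, has no defined
  context. Such sites are counted and reported; the partition property
  (#CG + #CHG + #CHH + #excluded = #strand-resolved cytosines) is
  enforced by test.
* **Strands are kept separate.** Complementary CG sites are *not*
  merged, matching the per-strand output of nanopore methylation
  callers. Whether an upstream study merged them is generally
  unknowable from its outputs; keeping strands resolved loses nothing
  (merging is a trivial aggregation) and avoids silently halving site
  counts.

Promoters are derived strand-awarely as −1000/+500 bp around the TSS
(the TSS of a minus-strand gene is its highest coordinate), clipped to
the contig. These bounds are the conventional promoter window for
compact fungal genomes and are configurable.

# Methylation levels

The default level statistic is **reads-weighted**:
Σ methylated / Σ coverage over qualifying sites. The alternative
(`weighting = "sites"`, the unweighted mean of per-site frequencies)
over-weights low-coverage sites, whose frequencies are noisiest; with
Poisson-distributed nanopore coverage the reads-weighted form is the
maximum-likelihood pooled estimate and satisfies a useful exact
identity: the coverage-weighted mean of windowed levels reproduces the
global level, which the test suite asserts.

Sites qualify at `min_coverage = 4` everywhere by default — the same
per-site bar the DMR caller uses — so that global levels, tracks,
profiles and DMR inputs all describe the same site population. Windows
or bins without qualifying sites are reported as missing (`NA`), never
as zero: zero is a real methylation level.

# Metagene profiles

Profiles use 20 fixed-width flank bins per side over 2 kb flanks and 60
length-scaled body bins. No binning is canonical for this plot type;
these defaults resolve TSS/TES-proximal structure for genes of ≥ 1 kb
while keeping ≥ 10 sites per bin in a typical fungal site density, and
all three numbers are arguments. Sites in the windows of two features
contribute to both (standard metagene practice; ownership rules would
be arbitrary). Minus-strand features are reversed so bin 0 is always
5′-most; the profile of a reverse-complemented genome with mirrored
annotation is identical by construction and by test.

# DMR calling

The caller is a non-overlapping tiling-window scan. Filters, in order:

1. **Site filter**: a window needs ≥ 5 cytosines of the context, each
   covered by ≥ 4 reads in *both* samples. Counts are pooled over these
   qualifying cytosines only.
2. **Fold filter**: pooled levels must satisfy
   (max + 0.01) ≥ 2 × (min + 0.01). The pseudocount makes the 2-fold
   criterion defined at level 0; 0.01 is small against biologically
   interesting levels (≥ 0.05) yet prevents 0.004-vs-0.001 windows from
   passing on noise.
3. **Significance**: two-sided Fisher's exact test on the pooled 2×2
   read-count table, raw p < 0.05.

Three parameters are genuinely open in this design and were fixed as
follows:

* **Window size 1000 bp.** With the ≥ 5-cytosine/≥ 4-read filter, 1 kb
  windows retain testable cytosines across a sparsely methylated
  genome while staying below typical fungal gene size, so a DMR
  localizes to a promoter or body rather than spanning both.
* **Fisher's exact test.** With a single pooled methylome per stage
  there is no replicate-based variance estimate; the exact test on
  pooled counts is the standard replicate-free choice for two-sample
  count tables. The implementation sums hypergeometric point
  probabilities ≤ the observed table's (relative tolerance 1e−7 for
  float ties; an all-zero margin gives p = 1 by convention) and is
  verified against brute-force enumeration and `stats::fisher.test` to
  1e−9.
* **Raw p by default.** Windowed Fisher p-values at a 0.05 threshold
  control per-window error, not FDR; a Benjamini–Hochberg option
  (`adjust = "bh"`) is available for users who want the stricter
  criterion, but the default mirrors the common practice this pipeline
  reproduces.

Adjacent significant windows are *not* merged: without a principled
merging rule, reporting windows as-is keeps counts interpretable.

Direction is labelled from sample A's perspective (`hyper_in_A` /
`hypo_in_A`); with A = mycelium and B = conidia this reads as
hyper-/hypomethylated in the mycelium. Swapping inputs flips every
label and preserves p-values exactly (tested).

DMRs are then annotated: one compartment per DMR by majority
base-pair overlap with precedence promoter > TE > gene body on ties
(IGR when nothing overlaps); DMGs by ≥ 1 bp promoter–DMR overlap,
half-open semantics, each gene once per (context, direction); and a TE
enrichment score log2((DMR∩TE / DMR) / (TE / genome)), undefined for an
empty stratum or TE-free genome and −Inf when a non-empty stratum has
zero TE overlap.

# GO over-representation

Given a gene→GO mapping, each term annotated to ≥ 1 background gene is
tested with the one-sided hypergeometric tail (enrichment); a two-sided
option exists. The background defaults to all annotated genes — the
universe actually eligible to become DMGs. Annotations are taken as
given: no propagation to GO ancestors, which would require the ontology
graph and is upstream of this package's scope.

# The synthetic methylome

The generator defines the conditions under which the pipeline is
validated, so its defaults are fixed once:

| parameter | default | rationale |
|---|---|---|
| genome | 1 Mb, 4 contigs, GC 0.5 (tiny preset: 200 kb, 2 contigs) | fungal-like GC; enough 1-kb windows (~1000 / ~200) for recovery tests |
| genes | ~300/Mb, 0.8–2.5 kb, random strand | fungal gene density and size |
| TEs | 4.5% of genome, 0.2–2 kb, intergenic | small TE complement typical of compact fungal assemblies |
| stage-A base probability | CG/CHG/CHH = 0.05/0.012/0.008 | echoes the empirical ordering CG ≫ CHG > CHH at low-percent magnitudes |
| compartment multipliers | TE ×8, gene body ×0.5 | TE-elevated, body-depleted methylation |
| stage-B scale | 0.6 | a conidia-like stage below the mycelium-like stage in every context |
| coverage | Poisson(30), zero-coverage sites dropped | typical nanopore depth; matches real frequency-table semantics |
| planted DMRs | 10 CG windows, fold 6, window-aligned | strong but not saturated effect; stage-A p = min(1, 6 × stage-B p) |

Per site, coverage is Poisson and the methylated count Binomial given
the site's true probability; the truth object records per-site
probabilities, compartments and planted windows. One RNG stream per
draw, seed recorded in the bundle's `params.txt`, so fixtures
regenerate bit-identically.

What the simulator does **not** emulate: read-level (per-molecule)
patterns, sequence-dependent caller error, spatial autocorrelation of
methylation beyond compartments, or partially methylated domains.
Passing recovery tests therefore demonstrates that the *statistics and
bookkeeping* are correct under the stated sampling model — not that the
caller is robust to every artefact of real nanopore data.

# Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere internally; GFF3
  converts on read, BED writes need no conversion. One convention, no
  off-by-one drift.
* Nanopore frequency-table positions are treated as 0-based by default
  (`coordinate_base` flag available), following the upstream callers'
  convention.
* Zero-coverage rows in site tables are dropped with a reported count,
  not errors.
* Nx/Lx ties: contigs sorted descending with a stable sort, so equal
  lengths keep input order. GC% excludes N and ambiguity codes from the
  denominator (the assembly-QC convention; published GC figures for the
  same assembly often disagree at the second decimal precisely because
  of such conventions).
* Undefined quantities (level of an empty window, enrichment of an
  empty stratum) are `NA`, distinct from the mathematically meaningful
  −Inf of a zero-overlap enrichment.

# Problem sizes in the test suite

The suite validates on the tiny preset (200 kb, ~100k strand-resolved
cytosine sites, 200 windows) for every end-to-end property, plus one
1 Mb run (~1000 windows, 10 planted + ~990 null) for DMR recovery at
scale; Fisher equivalence uses 1000 random tables with totals ≤ 200.
These sizes give the recovery and calibration statistics enough
resolution (binomial 3-σ bands) while keeping the whole suite quick on
a single core.

# Known limitations

* No replicate-aware variance model: with replicated designs a
  beta-binomial or methylKit/DSS-style approach would be preferable.
* No smoothing or window merging; DMR boundaries are window boundaries.
* GO testing ignores the ontology DAG.
* The per-site model treats sites independently; real methylomes are
  spatially correlated, so the null run's false-positive budget is a
  lower bound on what correlated noise could produce.

# A minimal session

```{r example, eval = FALSE}
params <- sim_params_tiny(seed = 7)
sim <- simulate_genome(params)
meth <- simulate_methylome(sim$genome, sim$features, params)

global_methylation_level(meth$sample_a, "CG")
dmrs <- call_dmrs(meth$sample_a, meth$sample_b, sim$genome, "CG")
proms <- promoter_intervals(sim$features$genes)
assign_dmr_compartments(dmrs, sim$features, proms)$proportions
differentially_methylated_genes(dmrs, sim$features$genes, proms)
```
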