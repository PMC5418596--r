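---
title: "Methods: smoothed DMR calling, Fisher-exact differential expression, and profile statistics"
author: "methylDMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: smoothed DMR calling, Fisher-exact differential expression, and profile statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylDMR)
```

methylDMR compares a mutant plant methylome, transcriptome and
small-RNA complement against its wild type. This vignette explains the
statistical procedures, the choices made where the procedures were
genuinely open, and what the synthetic benchmark does and does not show.

## The DMR model

### Smoothing

Per-cytosine bisulfite counts are noisy at ordinary coverage: a 20×
cytosine has a rate standard error of ~0.1, so single-cytosine tests
alone produce unstable differential calls. The caller therefore smooths
the *methylated* and *unmethylated read counts separately*, within each
library, with a Savitzky–Golay filter: a quadratic least-squares fit
over a sliding window of 11 cytosines, evaluated at the window centre.
Smoothing counts rather than rates means low-coverage cytosines
contribute little weight, and the rate computed from smoothed counts is
implicitly coverage-weighted.

Three choices deserve comment:

* **Window definition.** The 11 "adjacent values" are the 11 nearest
  cytosines *of the same context in genomic order* (index-adjacent), not
  a fixed bp span. A fixed-width filter over per-cytosine series is only
  well defined index-wise; a bp window would make the effective filter
  length vary wildly with cytosine density.
* **Boundaries.** At track ends a centred 11-window does not exist; the
  fit uses the truncated window of available cytosines (degree reduced
  if fewer than three points remain). This keeps the filter exact on
  polynomials up to degree 2 at *every* position, which is the
  property the test suite asserts at 1e-9.
* **Clamping.** Quadratic fits can undershoot below zero next to sharp
  spikes; counts are physically non-negative, so fitted values are
  clamped at 0 before any rate is formed (`clamp = FALSE` exposes the
  raw fit).

Replicates are combined by smoothing each library independently and
summing the smoothed counts position-wise across a genotype's
libraries; positions absent from one library enter as zero counts
(zero-coverage cytosines are legitimate smoothing neighbours and are
retained throughout). Pooling raw counts before a single smoothing pass
is available via `smoothGenotype(pool = TRUE)` but is not the default:
smoothing within each library first respects library-specific coverage
structure.

### DMC test

For each cytosine with a defined smoothed rate in both genotypes, the
rounded smoothed counts form a 2×2 table (mutant meth/unmeth vs. WT
meth/unmeth) tested with a two-sided Fisher's exact test. A DMC
requires *P* ≤ 0.1 **and** |rate difference| > 0.1 (strict), with rates
taken from the *unrounded* smoothed counts. The rate difference carries
the direction (hyper/hypo); the test itself is two-sided, since a
one-sided choice would have to be made per cytosine from the very
difference being tested.

Rounding is *half away from zero* (`roundHalfUp()`), applied exactly
where counts enter a Fisher test — the DMC table and the region-averaged
table — and nowhere else. Centralising the rule avoids the
round-half-even surprises of `base::round()` in ties like 4.5.

The Fisher p-value is the standard conditional one: the sum of
hypergeometric probabilities of all tables with the observed margins
that are no more probable than the observed table, with a 1 + 1e-7
relative tie tolerance (the `stats::fisher.test()` convention). The
in-package implementation is a vectorised `dhyper()` sum because the
caller tests up to tens of thousands of cytosines per run;
`stats::fisher.test()` serves as an independent cross-check in the test
suite, which also verifies exact agreement with full enumeration for
all tables with margins ≤ 40.

### Merging, region test, filtering

Same-type DMCs merge into a candidate region when consecutive DMCs are
at most 160 bp (CG), 240 bp (CHG) or 70 bp (CHH) apart and no
opposite-type DMC lies strictly between them. Chaining is transitive
over valid consecutive links and single-pass over position-sorted DMCs;
every DMC ends up in exactly one candidate (singletons included — the
filters remove them later).

Each candidate region is re-tested at region level: the smoothed meth
and unmeth counts are *averaged* over all cytosines of the region's
context inside its span (cytosines with zero smoothed coverage
contribute zeros — they are real positions of the region), the averages
are rounded, and the same Fisher test applies. Region rates and their
difference come from the unrounded averages; this aggregate difference
(not the mean of per-DMC differences) is the quantity the downstream
filter thresholds, because it is the quantity actually tested.

Region p-values are BH-adjusted **within each context**, mirroring the
per-context reporting of plant methylation analyses; a genome-wide
correction would couple the contexts' very different candidate counts.
Final DMRs require ≥ 5 DMCs, ≥ 50 bp, FDR ≤ 0.05 and an absolute region
difference ≥ 0.40 (CG) or 0.20 (CHG/CHH).

A DMR maps to an annotated feature when at least one nucleotide
overlaps (`max(starts) ≤ min(ends)`, 1-based inclusive); overlaps are
computed with `GenomicRanges::findOverlaps()` behind the package's own
interface. Coordinates are 1-based inclusive everywhere internally; BED
conversion happens only at I/O boundaries. Cytosines on opposite
strands are independent records — no symmetric-CG merging is performed,
consistent with a strictly per-cytosine procedure; the decision is
localised in the reader, and strand-merged input can simply be supplied
if desired.

## Differential expression

Expression is RPKM (reads per kilobase per million mapped reads). Per
replicate pair, each locus' counts are contrasted against the rest of
the library in a 2×2 Fisher test — the table construction treats the
library total as fixed, which matches RPKM's normalisation — and
p-values are BH-adjusted across the loci of that pair. Calls require
log2(RPKM mutant/WT) > 2 and FDR < 0.01, both strict; a locus is
finally up/down only when every replicate pair agrees.

Two open points are resolved as follows:

* **Zero counts.** The log2 ratio is undefined at zero WT expression. A
  pseudocount of 1 read is added to both genotypes *for the ratio only*;
  the Fisher test always sees raw counts. The pseudocount is
  configurable and biases the ratio conservatively toward zero.
* **Windowed tracks.** The 100-kb log2 tracks assign each locus to the
  window containing its midpoint (windows tile from position 1), and a
  window emits NA when empty or when either genotype's mean RPKM is
  zero — at zero numerator the log2 ratio is −∞, which would be as
  misleading in a plotted track as a zero denominator.

Compartment enrichment of a locus set (e.g. finally-up loci) uses a
one-sample two-sided proportion z-test of the set's pericentromeric
fraction against the genome-wide background fraction,
z = (p̂ − p₀)/√(p₀(1−p₀)/n). This is the natural reading of a reported
z-score for a subset-vs-all comparison; it treats the background
proportion as fixed, appropriate because the background (all annotated
loci) is orders of magnitude larger than the subset.

## Profiles

Methylation metaprofiles align stranded features at the 5′ or 3′ end
and average methylation in 100-bp bins across 3-kb flanks, strand-aware
(upstream of a − feature is genomically downstream). Bin values are
coverage-weighted rates (Σmeth/Σtotal) by default, robust to
low-coverage cytosines; `weighted = FALSE` averages per-cytosine rates
instead, since either convention is defensible. Bins with no covered
cytosine emit NA, including flank bins running past chromosome ends.

Small-RNA counts are normalised to reads per million 18–26-nt mapped
reads in the same library — an in-range total rather than the full
library, so the normaliser is not distorted by degradation products
outside the siRNA range. The scaled TE profile uses 1-nt flank bins and
2,000 equal body bins; body position *o* in a TE of length *L* maps to
bin ⌊o·2000/L⌋ (capped at the last bin). The bin index is computed with
exact integer arithmetic — ⌊o/L·2000⌋ in floating point misassigns
positions when the division is inexact. TEs shorter than the bin count
simply leave some body bins without positions; such bins take their
mean over the TEs that do populate them.

## The synthetic benchmark

The generator emulates the statistical structure the analysis assumes,
at desk scale:

* **Genome.** 2 chromosomes × 1 Mb; a central pericentromeric
  compartment covering 40% of each chromosome; 150 PCGs and 125 TEs per
  chromosome with log-normal lengths, TEs placed at a 4:1 het:eu
  density ratio (PCGs 1:4). Cytosine densities are 40,000 CG, 30,000
  CHG and 70,000 CHH sites per Mb — CG spacing ~25 bp, comparable to a
  compact plant genome such as Arabidopsis, and dense enough that a
  300-bp region holds the ≥ 5 DMCs the filters presuppose.
* **Methylome.** Coverage ~ Poisson(20) per library, two libraries per
  genotype. Methylated counts are beta-binomial around compartment- and
  context-specific base rates (het: CG 0.85, CHG 0.55, CHH 0.15; eu:
  CG 0.20, CHG 0.05, CHH 0.03) with intraclass correlation 0.05, so the
  null-DMR property is exercised under realistic between-library
  overdispersion, not an idealised binomial. Injected intervals
  override the base rate for their context.
* **Expression.** Log-normal per-locus baselines (median 100 reads),
  negative binomial counts (dispersion 0.05), injected loci upregulated
  8-fold and biased toward pericentromeric TEs. Library sizes include
  2e6 background reads outside the analysed loci: real libraries are
  dominated by reads elsewhere, and without this term, injecting strong
  loci would deflate mutant RPKM genome-wide through the library-size
  normalisation — a distortion of the generator, not of the caller.
* **Small RNA.** Multinomial size-class totals (21-nt/24-nt/other),
  locus weights proportional to length with 24-nt reads concentrated on
  TEs, uniform spread within a locus.

A single master seed fans out into labelled child seeds per component,
so adding a generator does not shift existing random streams, and every
output is bit-reproducible given (spec, seed).

### What the tests show — and what they do not

The acceptance suite verifies, at these conditions: exact agreement of
smoothing and Fisher code with brute-force references; exact merging on
dense DMC configurations (exhaustive over all type assignments and
contexts on a position grid straddling every gap ceiling, up to 6
DMCs); ≥ 95% of WT-vs-WT simulations yielding zero DMRs (20 seeds, 1 Mb,
20×); recovery of 30 injected CG hypo-DMRs (0.85→0.10, 300–800 bp) with
recall and precision ≥ 0.9 and mean per-boundary displacement ≤ 160 bp
(the CG merge distance); analogous DE recovery/null properties; and
flatness/strand-symmetry of profiles. Problem sizes (1–2 Mb genomes,
10–20 replicate seeds, margins ≤ 40 for the exhaustive Fisher check)
were chosen to keep the full suite in the minutes range while leaving
each property statistically sharp.

Passing these tests shows the procedures are implemented correctly and
behave as designed under the generator's assumptions. It does **not**
show that the thresholds are optimal for real data: the generator has
no sequence composition, no bisulfite conversion failure, no mapping
bias, no copy-number variation, and its cytosine placement is uniform
within compartments rather than clustered. Boundary accuracy in
particular is flattered by step-like injected rate changes; biological
DMR edges are gradual.

## Known limitations

* The Fisher DE test ignores biological overdispersion; it is
  anticonservative for highly variable loci and is retained because the
  replicate-intersection rule and the 4-fold ratio threshold, not the
  p-value, do most of the filtering. Dispersion-based models (DESeq2,
  edgeR) are deliberately out of scope.
* BH within context (DMRs) and within replicate pair (DE) are fixed
  grouping choices; other groupings change borderline calls.
* The per-cytosine caller assumes both genotypes were profiled on the
  same cytosine universe; positions missing from one genotype's tracks
  are skipped, not imputed.
* `fisherExactTwoSided()` enumerates the conditional support, so a
  single test with row totals in the millions is slower than a normal
  approximation; for the locus-vs-library DE tables (support bounded by
  locus counts) this is immaterial.
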