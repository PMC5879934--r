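---
title: "DamID-seq analysis on GATC fragments: models, parameters and design choices"
author: "damidflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DamID-seq analysis on GATC fragments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(damidflow)
```

## The measurement and its coordinate system

DamID profiles protein–DNA contacts by fusing the protein of interest to
E. coli Dam methyltransferase. Contact leaves adenine methylation at GATC
sites; methylated fragments are cut by DpnI-family enzymes, amplified and
sequenced. Because amplification starts and ends at GATC, the native
resolution unit is the *GATC fragment*: the interval between consecutive
GATC motifs. `build_fragment_map()` derives this partition from the genome
(forward strand only — GATC is its own reverse complement) and every
downstream quantity lives on it. Coordinates are 0-based half-open
internally, BED on disk, with GFF3 converted on input.

A genuine DamID read must begin with GATC; `filter_and_count_reads()`
discards reads that do not, and anchors survivors to the fragment boundary
matching their 5′ mapped position (plus-strand reads at a left boundary,
minus-strand reads at the final base of the GATC closing a fragment on the
right — the convention that matches DpnII fragment ends; the source
protocol does not dictate one). Multi-mapping reads are dropped by default
(`multimap = "drop"`), since the original pipeline's handling is not
documented; the flag keeps them if desired. In routine use, per-fragment
count tables are accepted directly, so alignment is never required.

## The signal model

For one factor and genotype, the signal at fragment *i* is a two-sided
Fisher exact test comparing the fragment's share of reads in the Dam-fusion
library against the Dam-alone control, on the 2×2 table

    [ count_x,   total_x   - count_x   ]
    [ count_dam, total_dam - count_dam ]

reported as −log10(P) with direction carried separately: sign +1 when the
fusion proportion exceeds the control (enrichment), −1 when below
(depletion). The two-sided convention follows the standard rule (tables
with probability at most the observed one, within relative tolerance 1e-7,
accumulate into P); `fisher_fragment_test()` is validated against an
independent hypergeometric enumeration and `stats::fisher.test` over every
table with channel totals up to 60.

Replicates are *summed* per channel before testing — pooled profiles use
all reads, while the replicates individually are reserved for FDR
calibration (below). A companion normalized ratio
log2((count_x + ψ)/total_x ÷ (count_dam + ψ)/total_dam) with pseudocount
ψ = 0.5 supports the ratio criterion in peak calling; the Fisher test uses
raw counts, whose margins self-normalize. −log10(P) is capped at 300 so
serialized tracks never contain infinities. Near zero ratio at low counts,
the pseudocount can flip the ratio's sign relative to the raw-proportion
sign; the two always agree away from that regime, which is where peaks
live.

## FDR calibration from replicate noise

Two biological replicates of the same construct measure the same biology,
so any "peak" in a replicate-1-vs-replicate-2 Fisher track
(`noise_track()`) is experimental noise. `calibrate_fdr()` counts merged
peaks on the signal track and on the noise track under identical compound
criteria across a grid of P cutoffs (50 log-spaced points from 1e-3 to
1e-12) and estimates FDR(t) = n_noise(t) / max(n_signal(t), 1). The
working threshold t\* is the loosest grid point with FDR ≤ 0.05; when no
point qualifies the tightest point is used with a warning — the honest
answer when noise never dies away on the grid, which happens when planted
or real peaks are few. The noise comparison uses the Dam-fusion replicates
(worst-case noise; a flag selects Dam-alone). Both tracks are counted as
merged intervals, symmetrically.

`call_peaks()` then applies the compound criteria: enrichment sign,
P ≤ min(t\*, 1e-3) and log2 ratio strictly greater than 1. Adjacent
eligible fragments merge into one peak; a single ineligible fragment
breaks a peak (fragments are the resolution unit, so no gap bridging). The
summit is the fragment with the largest −log10(P), leftmost on ties, and
the summit fragment's midpoint is the peak's position for all distance
computations. `depleted_regions()` mirrors the procedure on the negative
side.

## Annotation, targets, dynamics

Gene models carry one TSS per transcript (alternative TSSs are separate
transcripts) plus 5′UTR/CDS/intron/3′UTR blocks; the promoter is the
400 bp immediately upstream of the TSS, strand-aware. Summits are
classified by the precedence promoter > 5′UTR > CDS > intron > 3′UTR
(the categories overlap across transcripts, so a total order makes the
call single-valued; a `merge_exon` flag collapses the exonic categories).
Expected occupancy probabilities for the binomial enrichment test come
from the base-pair coverage of each category — made disjoint by the same
precedence — divided by genome size, recomputed per run, never cached.

Distances are summit-to-TSS, unsigned by default (Fig-style histograms in
1 kb bins over 10 kb), signed and strand-oriented on request. A transcript
is a **direct target** of a factor when it is at least 8-fold
down-regulated in that factor's mutant (FPKM fold with pseudocount 1, and
the upstream significance flag where present) *and* a peak summit lies
within 1 kb of one of its TSSs; down-regulated transcripts without such a
peak are **indirect**; everything else is unaffected. "Next to the TSS"
for co-binding enrichment reuses the identical 1 kb criterion. 2×2
comparisons use chi-square without Yates correction, switching to the
Fisher exact test whenever an expected cell falls below 5; across factor
pairs, Benjamini–Hochberg q-values can be added with `p.adjust`.

For binding dynamics, presence means a peak summit within ±300 bp of the
TSS (summit mode is the default; an interval-overlap mode exists), read
across the genotype series bam → aly → can → wt. The presence pattern maps
deterministically to groups: I = (1,1,1,1) and II = (1,0,0,0) are anchored
definitions; III = (0,0,0,1), IV = (0,0,1,1), V = (1,1,0,0),
VI = (1,0,1,1) are shipped conventions satisfying the structural
constraints (III/IV acquire binding in spermatocytes, V/VI are
spermatogonial) and are fully configurable, because only the first two are
printed unambiguously in the source material. Unmatched patterns are
"minor", optionally Hamming-merged to the nearest canonical pattern with
ties staying minor. Deterministic pattern mapping replaces clustering:
reproducible and parameter-free. Tissue-specific transcripts follow the
rule: positive log2(tissue/whole-fly mean) in the target tissue and
negative or null (NA, treated as null expression, never as zero) in every
other tissue.

## The synthetic-data generator

`simulate_damid_experiment()` produces every input with known truth.
Defaults are the package's study conditions: one 1 Mb chromosome of
uniform random sequence (GATC density 1/256, the natural motif frequency;
~4000 fragments), 300 non-overlapping 1.5 kb genes, two biological
replicates per channel at 2×10⁵ reads, an 8-fold enrichment rate ratio at
bound fragments, and negative-binomial counts with overdispersion 0.05
(variance μ + 0.05 μ²). Poisson replicates would make the replicate-noise
track degenerate, so the NB default is what makes FDR calibration a real
test. Dam-alone rates are fragment length × a lognormal accessibility
(SD 0.5) shared by channels and replicates; the fusion channel multiplies
bound fragments by the effect size. Binding is planted on the fragment
containing each bound gene's TSS — the fragment-level resolution of the
assay. Expression couples to truth: direct targets are guaranteed ≥8-fold
down in the cognate mutant after the pseudocount (wild-type FPKM floored
at 40 for designated genes so the fold is achievable), repressed genes
≥4-fold up, everything else mild lognormal noise; the tissue matrix plants
its specific fractions exactly and forces all other rows to violate the
rule, so recovery can be scored exactly. All generation is deterministic
under the seed.

What the generator does *not* emulate: mappability and copy-number
variation, GC bias, PCR duplicates, chromatin-state-dependent Dam
background beyond the lognormal accessibility, and genuine read-level data
(a toy GATC-read emitter exists only for testing the read filter). Passing
tests therefore demonstrate correctness of the statistics and plumbing
under a realistic noise model, not robustness to every artifact of real
libraries.

## Numerical choices and validation scale

The Fisher P is computed by grouping fragments by their table margins and
accumulating the sorted hypergeometric pmf once per group — exact,
vectorized, and identical to `fisher.test` to better than 1e-10 relative
error. Validation simulations use ~4000 fragments at depth 2×10⁵ per
channel: null calibration and planted-recovery runs over 10–20 seeds, the
exhaustive Fisher sweep over all tables with margins ≤ 60, and dynamics
recovery over the four-genotype series — sizes chosen so the full suite
and the acceptance script each complete in minutes on a laptop while
leaving the statistical assertions well-powered.

Two behaviors deserve explicit note. First, the exact test is
*conservative* at finite counts: at depth 2×10⁵ over 4000 fragments the
null fraction of fragments with P < 0.05 is ≈ 0.040–0.044, not 0.05 —
discreteness of the hypergeometric support (at k = 100 reads and balanced
margins the achievable size is 0.035). The test never exceeds its nominal
level, which is the direction that matters for FDR control; a band
symmetric around 0.05 is not attainable by any faithful implementation of
this statistic. Calibration checks accordingly use Poisson counting noise
(`dispersion = 0`), the sampling model under which the exact test's
calibration is defined, while the NB default exercises the replicate-FDR
machinery. Second, when few fragments are truly bound, the FDR curve can
plateau above the cutoff within the grid; `calibrate_fdr()` then reports
the tightest threshold with a warning rather than fabricating a passing
one.

## Limitations

Fragment-level testing cannot resolve binding within a fragment, and very
long fragments dilute summit-to-TSS distances. The replicate-based FDR
needs two genuine biological replicates; with one replicate only a fixed
threshold can be forced. Group definitions III–VI are conventions; analyses
that depend on their exact membership should treat the mapping as a
configurable input. Differential expression is consumed from upstream
tables (Cuffdiff-style), never recomputed; motif analysis and 3D genome
structure are out of scope.
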