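---
title: "Methods: copy number, tumor fraction and fragmentomics of cfDNA with cfdnaflow"
author: "cfdnaflow authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy number, tumor fraction and fragmentomics of cfDNA with cfdnaflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfdnaflow)
```

# Scope

cfdnaflow analyses shallow whole-genome sequencing of cell-free DNA (cfDNA)
from liquid biopsies — plasma or urine, long-read (single-end) or short-read
(paired-end) — and reports four families of results:

1. **Copy number and tumor fraction**: binned, GC-corrected coverage; a
   hidden Markov model over integer copy-number states; the tumor fraction
   (TF) as one minus the fitted normal fraction, with detection called above
   3% TF.
2. **Fragmentomics**: fragment-size distributions, size-stratum proportions,
   5' fragment-end trinucleotide composition, and its Gini diversity index.
3. **Nucleosome profiling**: GC-weighted, window-normalised coverage around
   site sets — transcription start sites (TSS), where accessible chromatin
   depletes cfDNA coverage, against nucleosome-rich regions (NRR) as a
   negative control.
4. **Xenograft deconvolution**: graft (human, tumor) versus host (mouse,
   non-tumor) read assignment from per-read mapping qualities against the two
   genomes.

Patient sequencing data of this kind are controlled-access, so the package
ships a first-class synthetic generator that reproduces the statistical
structure the analyses rely on. Everything downstream is tested against that
generator's known truth.

# The synthetic cfDNA generator

`makeToyReference()` draws random contigs whose GC content follows a smooth
low-frequency sinusoid between configurable bounds (default 0.35–0.55, chosen
so that whole bins stay inside the default GC mask of the copy-number module,
as they do for most of a real mammalian genome). The stored GC track is
recomputed from the realised sequence, so a FASTA round trip reproduces it
exactly.

`plasmaSizeModel()` is a truncated-normal mixture with modes at 167, 334, 501
and 668 bp — the mono- to tetra-nucleosome ladder of plasma cfDNA. The
default weights (0.46, 0.30, 0.14, 0.10) put 54% of the mass above 300 bp,
the long-fragment share that long-read sequencing recovers from plasma; the
default mode standard deviations (10, 10, 12, 14 bp) keep the components
sharp enough that the mass of each component stays on its own side of the
300 bp stratum boundary. Tumor-labelled fragments subtract a per-mode shift,
by default 20 bp at the mono-nucleosome mode, growing to beyond 100 bp at the
multi-nucleosome modes — the monotone increase reported for tumor-derived
cfDNA; the exact multi-nucleosome shifts are not established quantities, so
they are free parameters here (defaults 20/60/110/130 bp).
`urineSizeModel()` is a single truncated-normal mode (mean 81, sd 30,
truncated at 20 bp) whose realised median is about 82 bp with no nucleosomal
periodicity, as described for urinary cfDNA.

`simulateSample()` draws labelled fragments: tumor labels with probability
TF; tumor placement density proportional to local copy number over the
configured segmental profile (`cn / ploidy`), normal placement uniform;
5' trinucleotide usage follows a 64-entry bias table by rejection against the
actual reference sequence, so every emitted motif is literally the reference
at the fragment's 5' terminus (reverse-complemented on the minus strand);
coverage depletion around TSS-like sites is planted by rejection-thinning
fragments whose midpoint falls within a configurable half-width (default
100 bp) of a site, kept with a configurable probability (default 0.3) — the
dip is an empirical observation, not a mechanism, so thinning is the simplest
generative stand-in. An optional fragment-GC sampling weight `1 + slope * gc`
plants GC bias for testing the corrections. Truth labels ride in the read
names' sidecar table and the `label` metadata column, surviving round trips
through SAM/TSV.

What the generator does **not** emulate: sequencing errors and base
qualities, adapters and barcodes, mappability structure, duplicated reads
(duplicate flags are consumed, not generated), chimeric or split alignments,
and the biological covariance between fragment length and genomic position.
Green tests therefore demonstrate that the estimators recover planted truth
under the stated statistical structure — not that they are robust to every
artefact of real sequencing data.

# Copy number and tumor fraction

Fragments surviving the post-alignment filters (mapped, primary,
non-supplementary, non-duplicate, mapq ≥ 5) are counted into fixed-width bins
by fragment midpoint — unambiguous for long fragments spanning bin
boundaries. On real genomes 1 Mbp bins are conventional; the toy references
use 10 kb bins so that a desk-scale simulation still yields 3,000 bins.

Counts are divided by a loess fit of count on GC (span 0.75, robust
`symmetric` family, with GC-decile median scaling as the fallback under 200
bins) and by mappability, then expressed as `log2(corrected / median)`. Bins
with mappability < 0.9 or GC outside [0.3, 0.6] are masked (both
configurable). A panel of normals, when given, contributes a per-bin median
log2 that is subtracted and a mask that is unioned.

The estimation model is a two-component mixture: a fraction `n` of normal
(diploid) cells plus `1 - n` tumor cells with integer copy number `c_k`
against tumor ploidy `phi`, giving the expected bin log2 ratio

```
m_k(n, phi) = log2( (2 n + (1 - n) c_k) / (2 n + (1 - n) phi) )
```

The HMM has states `c_k` in 0..3 (no subclonal states), Gaussian emissions
centred at `m_k`, sticky transitions (self-transition 0.99, uniform
off-diagonal), and a start distribution that puts 70% of its mass on the
neutral state — so a flat profile segments as a single neutral segment rather
than by an arbitrary tie-break. The emission standard deviation is estimated
robustly as `mad(diff(x)) / sqrt(2)` (successive differences straddle segment
boundaries only rarely, so the estimate ignores copy-number structure), with
a floor of 0.01; it can be fixed in `hmmConfig()`.

Gaussian emissions rather than a Student-t are a deliberate simplification:
they preserve the estimator's structure while keeping the exhaustive-path
oracle (all `4^T` paths at `T <= 8`) exact and fast, and the forward
log-likelihood is checked against that oracle to 1e-9.

The normal fraction is optimised separately from each restart value
`n0 = 0.95, 0.99, 0.995, 0.999` (the defaults the sensitivity analysis of
this application calls for), and the restart with the highest forward
log-likelihood is reported, TF = 1 - n. Each restart runs a deterministic
pattern search in TF space: from `1 - n0`, with an initial step of 0.02 that
doubles (cap 0.16) while improving and halves otherwise, down to a tolerance
of 1e-4. The expansion matters: the likelihood in TF is multimodal where a
deletion can be explained either as copy 1 at the true TF or as copy 0 at a
lower TF, and a purely contracting search can stall between those basins.
The search is deterministic, so a fixed configuration always reproduces the
same estimate. Ploidy starts at 2 and is not re-estimated by default; the
maximum-a-posteriori Viterbi path is segmented into runs of equal state.

A sample is called "detected" when TF exceeds 3%, the conventional threshold
for shallow-coverage TF estimation.

# Fragmentomics

Fragment lengths are the aligned reference span for single-end data and the
absolute template length of the leftmost properly paired mate for paired-end
data. Histograms run to 5,000 bp by default, with longer fragments tallied to
an overflow bucket excluded from density, median and mode. The three analysis
strata are half-open — `< 150`, `[150, 300)`, `>= 300` bp — and partition any
input.

End motifs are the reference trinucleotide at the fragment's 5' terminus
(reverse complement of the 3 rightmost bases on the minus strand). Reading
the reference rather than the read bases makes the motif robust to long-read
base errors and consistent between layouts; fragments whose terminus lies
within 3 bp of a contig edge are skipped and counted, and motifs containing N
are tallied outside the 64.

The diversity of the 64 motif proportions is summarised by a
mean-absolute-difference Gini index,
`G = sum_ij |p_i - p_j| / (2 K sum(p))`, which is 0 for uniform usage,
`(K - 1) / K` for one-hot usage, and invariant to count rescaling and
category permutation. Published fragment-end tooling does not print its exact
estimator, so this package defines the form above explicitly and verifies it
against the O(K^2) pairwise definition; all qualitative uses (comparisons of
diversity across strata and protocols) are invariant to that choice of form.

# Nucleosome profiling

The fragment-GC bias curve is the observed distribution of fragment GC
divided by the distribution expected if same-length fragments were placed
uniformly (lengths summarised by deciles, placements on a deterministic
grid), loess-smoothed and normalised to mean 1 over observed bins; under no
bias it is flat, and a planted preference for high-GC fragments is recovered
as a proportional rate ratio. This expected-distribution construction
replaces k-mer-based machinery whose internals are not specified for this
application; it preserves the correction's contract (flat under the null,
removes planted bias). With fewer than 1,000 fragments the curve falls back
to flat and is flagged low-confidence.

Each fragment contributes `1 / rate(gc)` to every position its span covers
within ±1,000 bp of each site; minus-strand sites are flipped so downstream
is positive; the summed profile is divided by its own window mean, making the
emitted window mean exactly 1. "Central coverage" is the mean over ±500 bp —
the window the textual definition of the statistic describes — rather than a
narrower peak window; both half-widths are configurable, and a midpoint
counting mode is available. Site lists are taken as given (deduplicated,
collapsed to their 5' position); mappability-based site pre-filtering is
upstream of this package.

# Xenograft assignment

Reads aligned against both genomes are assigned to the genome with the
strictly greater primary-alignment mapping quality; reads present in only one
genome go there. Equal qualities are called `ambiguous` and excluded from
*both* genomes: the upstream shell-pipeline formulation of this comparison
would retain ties in both genomes and hence double-count them, but a read has
exactly one origin, so this package routes ties to neither and reports their
count. Reads whose best alignment is below mapq 5 are `unassigned`. The calls
partition the input read names, and swapping the genomes swaps the calls.

# Numerical and design choices

- Coordinates are 0-based half-open internally and in the TSV dialect;
  conversion to 1-based closed happens only at the GRanges/SAM boundary.
- All sampling (simulation, downsampling, admixture) flows through explicit
  integer seeds; a fixed seed gives byte-identical FASTA/SAM/TSV output.
  Determinism is promised within this package, not bit-compatibility with
  seqtk/samtools sampling streams; the conventional seeds of the depth-ladder
  and admixture workflow (95; 17–41; 75–51; 45–69) are honoured as defaults
  in examples and tests.
- Downsampling is without replacement and order-preserving, so downsampling
  to the full size is the identity and subsets nest.
- Degenerate inputs fail loudly with typed conditions: empty bin series,
  all-zero motif vectors, all-masked profiles, infeasible admixture counts
  (naming the deficient component), identical xenograft references.
- Zero corrected counts floor the log2 ratio at -8 rather than -Inf.

# Problem sizes used in the checks

The study-scale checks simulate 3 contigs × 10 Mb binned at 10 kb (3,000
bins) with about 40% of the genome aberrant (gains and losses on three
contigs) and ~800,000 fragments per sample — matching a shallow-WGS workload
of roughly 1 M reads per sample. Tumor-fraction recovery is checked at TF 0,
0.10, 0.20 and 0.40 (10 replicates each, |TF̂ − TF| ≤ 0.05); the depth ladder
at TF 0.15 over 1 M / 500 k / 100 k / 50 k fragments; nucleosome profiling at
100,000 fragments around 500 sites on a 1 Mb contig. At these simulation
conditions detection remains solid across the whole ladder — the planted
aberrant fraction is generous — so the ladder check asserts monotonicity and
detection at full depth rather than a specific limit of detection.

# Limitations

- The Gaussian-emission HMM is a desk-scale stand-in for heavier-tailed
  emission models; on real data with outlier bins a Student-t emission is
  more robust.
- TF estimates at very low coverage (tens of fragments per bin) are biased
  toward zero by the skew of log-ratios of small counts.
- The GC correction regresses on bin GC only; real shallow-WGS pipelines also
  model mappability tracks and blacklist regions, which are accepted here as
  optional inputs but not derived.
- The generator's fragments are independent; real cfDNA exhibits positional
  autocorrelation (nucleosome phasing) beyond the planted TSS dips.
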