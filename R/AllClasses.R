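## Central S4 containers. Genomic intervals are held as GRanges (1-based,
## closed, as everywhere in Bioconductor); the simulator works internally in
## 0-based half-open coordinates and converts at object boundaries.

#' Toy reference genome
#'
#' A small synthetic reference: one or more contigs of A/C/G/T with a stored
#' per-window GC track recomputed from the realised sequence (so the track is
#' always consistent with what [writeReference()] emits as FASTA).
#'
#' @slot seqs A [Biostrings::DNAStringSet] with uniquely named contigs.
#' @slot gcWindow Window width (bp) of the GC track.
#' @slot gcTrack Named list, one numeric vector per contig, GC fraction per
#'   window, values in \[0, 1\].
#' @exportClass ToyReference
setClass("ToyReference",
  slots = c(seqs = "DNAStringSet", gcWindow = "integer", gcTrack = "list"))

setValidity("ToyReference", function(object) {
  nm <- names(object@seqs)
  if (is.null(nm) || anyDuplicated(nm)) return("contig names must be unique")
  if (!identical(sort(nm), sort(names(object@gcTrack))))
    return("gcTrack must have one entry per contig")
  rng <- range(unlist(object@gcTrack, use.names = FALSE), na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) return("GC track values must lie in [0, 1]")
  TRUE
})

#' Fragment-size mixture model
#'
#' cfDNA fragment lengths are modelled as a mixture of truncated normal
#' components. Plasma defaults place modes at 167 bp and multiples thereof
#' (mono- to tetra-nucleosome); urine defaults are a single short mode with
#' median about 82 bp and no periodicity. Tumor-labelled fragments subtract a
#' per-mode shift (default -20 bp at the mono-nucleosome mode, growing beyond
#' -100 bp at multi-nucleosome modes).
#'
#' @slot kind `"plasma"` or `"urine"`.
#' @slot modes data.frame with columns `mean`, `sd`, `weight` (weights sum to 1).
#' @slot tumorShift Numeric, bp subtracted from each mode mean for tumor
#'   fragments; same length as `nrow(modes)`.
#' @slot minLength,maxLength Truncation bounds in bp (defaults 20 and 5000).
#' @exportClass SizeModel
setClass("SizeModel",
  slots = c(kind = "character", modes = "data.frame", tumorShift = "numeric",
            minLength = "numeric", maxLength = "numeric"))

setValidity("SizeModel", function(object) {
  m <- object@modes
  if (!all(c("mean", "sd", "weight") %in% names(m)))
    return("modes needs columns mean, sd, weight")
  if (any(m$weight < 0)) return("mode weights must be nonnegative")
  if (abs(sum(m$weight) - 1) > 1e-8) return("mode weights must sum to 1")
  if (length(object@tumorShift) != nrow(m))
    return("tumorShift must have one entry per mode")
  if (any(m$mean - object@tumorShift < object@minLength))
    return("tumor-shifted mode means fall below minLength")
  if (object@minLength >= object@maxLength) return("minLength must be < maxLength")
  TRUE
})

#' Segmental copy-number truth
#'
#' Ground-truth somatic copy-number profile used by the simulator and as the
#' reference model for tumor-fraction estimation: non-overlapping segments with
#' integer copy number against a background ploidy (default 2). Copy numbers
#' are restricted to 0..3 by default, matching the copy-number state space of
#' the estimation HMM.
#'
#' @slot segments A [GenomicRanges::GRanges] with integer metadata column `cn`.
#' @slot ploidy Background (normal) ploidy.
#' @exportClass CNAProfile
setClass("CNAProfile", slots = c(segments = "GRanges", ploidy = "numeric"))

setValidity("CNAProfile", function(object) {
  seg <- object@segments
  if (length(seg) && is.null(mcols(seg)$cn)) return("segments need a 'cn' column")
  if (length(seg) && any(mcols(seg)$cn < 0)) return("copy numbers must be >= 0")
  if (length(seg) > 1) {
    hits <- findOverlaps(seg, seg)
    if (length(hits) > length(seg)) return("segments must not overlap")
  }
  if (object@ploidy <= 0) return("ploidy must be positive")
  TRUE
})

#' Simulation configuration
#'
#' Everything needed to draw one labelled synthetic cfDNA sample: the toy
#' reference, size model, copy-number truth, tumor fraction, fragment count,
#' 5' trinucleotide end-motif bias, TSS-like depletion sites with a
#' keep-probability, an optional fragment-GC sampling bias, and the seed.
#'
#' @slot reference A [ToyReference-class].
#' @slot sizeModel A [SizeModel-class].
#' @slot cna A [CNAProfile-class] (may hold zero segments).
#' @slot tumorFraction Expected fraction of tumor-labelled fragments, in \[0,1\].
#' @slot nFragments Number of fragments to emit.
#' @slot motifBias Named numeric(64): relative sampling weight per 5'
#'   trinucleotide (uniform by default).
#' @slot depletionSites [GenomicRanges::GRanges] of site midpoints around which
#'   fragments are thinned.
#' @slot depletionHalfWidth Half-width (bp) of the thinned window.
#' @slot depletionKeepProb Probability a fragment whose midpoint falls inside a
#'   depletion window is kept.
#' @slot gcBiasSlope Fragment sampling weight is `1 + slope * gc`; 0 disables.
#' @slot seed Integer seed; a fixed seed gives byte-identical output.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  slots = c(reference = "ToyReference", sizeModel = "SizeModel",
            cna = "CNAProfile", tumorFraction = "numeric",
            nFragments = "numeric", motifBias = "numeric",
            depletionSites = "GRanges", depletionHalfWidth = "numeric",
            depletionKeepProb = "numeric", gcBiasSlope = "numeric",
            seed = "integer"))

setValidity("SimulationConfig", function(object) {
  if (object@tumorFraction < 0 || object@tumorFraction > 1)
    return("tumorFraction must be in [0, 1]")
  if (object@nFragments < 0) return("nFragments must be nonnegative")
  if (length(object@motifBias) != 64 || any(object@motifBias < 0) ||
      sum(object@motifBias) <= 0)
    return("motifBias must be 64 nonnegative weights, not all zero")
  if (object@depletionKeepProb < 0 || object@depletionKeepProb > 1)
    return("depletionKeepProb must be in [0, 1]")
  TRUE
})

#' A set of aligned cfDNA fragments
#'
#' The common currency between modules: one record per fragment (one aligned
#' read for single-end data, one properly paired template for paired-end data),
#' held as a GRanges with metadata columns `name`, `mapq`, `flag` (SAM bit
#' flag) and optional truth `label` ("tumor"/"normal"/"graft"/"host"). Fragment
#' length is the range width. Unmapped records (retained until
#' [filterFragments()]) sit on the pseudo-contig `"*"`.
#'
#' @slot fragments The [GenomicRanges::GRanges] backing store.
#' @slot layout `"single_end"` or `"paired_end"`.
#' @exportClass FragmentSet
setClass("FragmentSet",
  slots = c(fragments = "GRanges", layout = "character"))

setValidity("FragmentSet", function(object) {
  mc <- mcols(object@fragments)
  need <- c("name", "mapq", "flag")
  if (!all(need %in% names(mc)))
    return("fragment metadata must include name, mapq, flag")
  if (!object@layout %in% c("single_end", "paired_end"))
    return("layout must be 'single_end' or 'paired_end'")
  TRUE
})

#' Genome-wide bin profile
#'
#' Fixed-width genomic bins (default 1 Mbp on real genomes; configurable for
#' toy references) with raw fragment counts, GC fraction, mappability, mask
#' status and, after [correctAndNormalize()], the corrected log2 ratio.
#'
#' @slot bins GRanges with metadata `count`, `gc`, `mappability`, `masked` and
#'   (after correction) `log2ratio`.
#' @slot binWidth Bin width in bp.
#' @slot nOffReference Fragments whose midpoint fell outside the binned genome.
#' @exportClass BinProfile
setClass("BinProfile",
  slots = c(bins = "GRanges", binWidth = "numeric", nOffReference = "integer"))

#' Panel of normals
#'
#' Per-bin median log2 ratio and dispersion across control samples, on the
#' same binning as the target samples, with a shared bin mask.
#'
#' @slot bins GRanges with metadata `medianLog2`, `dispersion`, `masked`.
#' @slot binWidth Bin width in bp.
#' @slot nSamples Number of control samples.
#' @exportClass PanelOfNormals
setClass("PanelOfNormals",
  slots = c(bins = "GRanges", binWidth = "numeric", nSamples = "integer"))

#' Copy-number HMM configuration
#'
#' States are integer copy numbers 0..3 (no subclonal states); the normal
#' fraction is optimised locally from each restart value in
#' `c(0.95, 0.99, 0.995, 0.999)` and the restart with the highest
#' log-likelihood is reported; initial ploidy is 2 and is not re-estimated by
#' default. Emissions are Gaussian around the expected log2 ratio of each
#' state; transitions are sticky with a configurable self-transition
#' probability.
#'
#' @slot states Integer copy-number states, ascending.
#' @slot restarts Normal-fraction restart values in (0, 1).
#' @slot ploidy Initial (and default final) ploidy.
#' @slot estimatePloidy Whether to co-optimise ploidy (off by default).
#' @slot selfTransition Self-transition probability.
#' @slot emissionSd Fixed emission sd, or `NA` to estimate robustly from the
#'   data (median absolute successive difference / sqrt(2)).
#' @slot tfThreshold Detection threshold on tumor fraction (default 0.03).
#' @slot maxIter,tol Local-search iteration cap and step tolerance.
#' @slot log2Floor Floor used where the expected log2 ratio diverges
#'   (zero-copy state at tumor fraction 1).
#' @exportClass HMMConfig
setClass("HMMConfig",
  slots = c(states = "numeric", restarts = "numeric", ploidy = "numeric",
            estimatePloidy = "logical", selfTransition = "numeric",
            emissionSd = "numeric", tfThreshold = "numeric",
            maxIter = "numeric", tol = "numeric", log2Floor = "numeric"))

setValidity("HMMConfig", function(object) {
  if (is.unsorted(object@states)) return("states must be ascending")
  if (any(object@restarts <= 0 | object@restarts >= 1))
    return("restarts must lie in (0, 1)")
  if (object@selfTransition <= 0 || object@selfTransition >= 1)
    return("selfTransition must lie in (0, 1)")
  TRUE
})

#' Tumor-fraction estimate
#'
#' Result of [fitTumorFraction()]: the selected normal fraction and tumor
#' fraction TF = 1 - n, the per-restart log-likelihood table, the
#' maximum-a-posteriori copy-number state path over unmasked bins, and the
#' detection call (TF > 3% by default).
#'
#' @slot normalFraction,tumorFraction,ploidy Fitted parameters.
#' @slot logLik Log-likelihood of the selected restart.
#' @slot restartTable data.frame: restart, fitted n, log-likelihood, selected.
#' @slot statePath Integer copy number per unmasked bin.
#' @slot binIndex Indices of the unmasked bins the path refers to.
#' @slot detected TRUE when tumorFraction exceeds the detection threshold.
#' @slot emissionSd Emission sd used.
#' @slot converged FALSE when the local search hit its iteration cap.
#' @exportClass TumorFractionEstimate
setClass("TumorFractionEstimate",
  slots = c(normalFraction = "numeric", tumorFraction = "numeric",
            ploidy = "numeric", logLik = "numeric", restartTable = "data.frame",
            statePath = "integer", binIndex = "integer", detected = "logical",
            emissionSd = "numeric", converged = "logical"))

#' Fragment-size histogram
#'
#' Integer-bp counts up to `lMax` (default 5000); longer fragments are tallied
#' to an overflow bucket and excluded from the density, median and mode.
#'
#' @slot counts Numeric vector; `counts[l]` is the number of fragments of
#'   length `l` bp.
#' @slot overflow Fragments longer than `lMax`.
#' @slot total In-range fragment count.
#' @slot medianLength,modeLength Summaries of in-range lengths (`NA` when
#'   empty).
#' @slot lMax Histogram ceiling in bp.
#' @exportClass SizeHistogram
setClass("SizeHistogram",
  slots = c(counts = "numeric", overflow = "numeric", total = "numeric",
            medianLength = "numeric", modeLength = "numeric", lMax = "numeric"))

#' Fragment 5' end-motif profile
#'
#' Counts and proportions of the 64 trinucleotides at fragment 5' ends (read
#' from the reference; reverse-complemented on the minus strand), the Gini
#' diversity index over the 64 proportions, and single-base 5' proportions.
#' Motifs containing N and fragments too close to a contig edge are tallied
#' separately and excluded from the 64.
#'
#' @slot counts Named numeric(64).
#' @slot nN Fragments whose motif contained an N.
#' @slot nSkipped Fragments skipped (terminus within 3 bp of a contig edge).
#' @slot gini Gini diversity index of the 64 proportions.
#' @slot base5 Named numeric(4): proportion of fragments starting with each base.
#' @slot stratum Label of the size stratum ("all" when unstratified).
#' @exportClass EndMotifProfile
setClass("EndMotifProfile",
  slots = c(counts = "numeric", nN = "numeric", nSkipped = "numeric",
            gini = "numeric", base5 = "numeric", stratum = "character"))

#' Site set for coverage profiling
#'
#' Named, strand-aware single-position sites (e.g. transcription start sites,
#' or nucleosome-rich control regions), deduplicated.
#'
#' @slot sites GRanges of width-1 positions with strand.
#' @slot name Site-set name (e.g. "TSS", "NRR").
#' @exportClass SiteSet
setClass("SiteSet", slots = c(sites = "GRanges", name = "character"))

#' Fragment-GC bias curve
#'
#' Relative observation rate of fragments as a function of their GC fraction:
#' observed GC distribution over expected (uniform placement of same-length
#' fragments), smoothed and normalised to mean 1.
#'
#' @slot mids GC-bin midpoints.
#' @slot rate Relative rate per bin (positive; mean 1 over observed bins).
#' @slot nFragments Fragments used.
#' @slot lowConfidence TRUE when too few fragments were available and a flat
#'   curve was substituted.
#' @exportClass GCBiasCurve
setClass("GCBiasCurve",
  slots = c(mids = "numeric", rate = "numeric", nFragments = "numeric",
            lowConfidence = "logical"))

#' Normalised coverage profile around a site set
#'
#' GC-weighted, site-averaged coverage at relative positions around site
#' centres (minus-strand sites flipped so downstream is positive), normalised
#' so the mean over the full window is 1. Central coverage is the mean over
#' +/- 500 bp by default; the window mean is over +/- 1000 bp.
#'
#' @slot positions Relative positions (bp).
#' @slot coverage Normalised coverage per position.
#' @slot centralCoverage Mean over the central window.
#' @slot windowMean Mean over the full window (1 by construction).
#' @slot nSites,nFragments Sites used and fragments contributing.
#' @slot siteSetName Name of the profiled site set.
#' @slot centralHalfWidth,windowHalfWidth Window definitions in bp.
#' @exportClass CoverageProfile
setClass("CoverageProfile",
  slots = c(positions = "integer", coverage = "numeric",
            centralCoverage = "numeric", windowMean = "numeric",
            nSites = "numeric", nFragments = "numeric",
            siteSetName = "character", centralHalfWidth = "numeric",
            windowHalfWidth = "numeric"))

#' Xenograft read assignment
#'
#' Per-read genome-of-origin call from the mapping-quality comparison of
#' alignments against two genomes: reads aligned to only one genome (mapq >= 5)
#' go to that genome; reads aligned to both go to the genome with strictly
#' greater mapq; equal mapq is `ambiguous`; reads whose best alignment is below
#' the mapq cutoff are `unassigned`.
#'
#' @slot table data.frame: `name`, `mapqA`, `mapqB` (NA when absent), `call`.
#' @slot genomeA,genomeB Genome labels.
#' @slot minMapq Mapping-quality cutoff (default 5).
#' @exportClass AssignmentResult
setClass("AssignmentResult",
  slots = c(table = "data.frame", genomeA = "character", genomeB = "character",
            minMapq = "numeric"))
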