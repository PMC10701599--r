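## Xenograft graft/host read assignment: compare per-read mapping qualities
## between alignments against two genomes and call the genome of origin.

#' Assign reads to their genome of origin
#'
#' Each read name present in either alignment set receives exactly one call:
#' reads aligned to only one genome go to that genome (if mapq >= `minMapq`);
#' reads aligned to both go to the genome with the strictly greater mapq;
#' equal mapping qualities are called `ambiguous` and excluded from both
#' genomes (a read has one origin, so ties are routed to neither rather than
#' double-counted); reads whose best alignment falls below `minMapq` are
#' `unassigned`. The calls partition the input read names, and swapping the
#' two genomes swaps the calls while leaving ambiguous/unassigned fixed.
#'
#' @param alignmentsA,alignmentsB [FragmentSet-class] objects of primary
#'   alignments against the two genomes.
#' @param minMapq Mapping-quality cutoff (default 5).
#' @param genomeA,genomeB Labels used in the calls.
#' @return An [AssignmentResult-class].
#' @export
assignByBestGenome <- function(alignmentsA, alignmentsB, minMapq = 5,
                               genomeA = "genomeA", genomeB = "genomeB") {
  getTab <- function(fs, which) {
    nm <- mcols(fragments(fs))$name
    if (anyDuplicated(nm))
      inputError(sprintf(
        "duplicate primary alignments for read '%s' in %s",
        nm[duplicated(nm)][1], which))
    setNames(mcols(fragments(fs))$mapq, nm)
  }
  qa <- getTab(alignmentsA, genomeA)
  qb <- getTab(alignmentsB, genomeB)
  names_all <- union(names(qa), names(qb))
  mapqA <- unname(qa[names_all]); mapqB <- unname(qb[names_all])
  call <- character(length(names_all))
  onlyA <- !is.na(mapqA) & is.na(mapqB)
  onlyB <- is.na(mapqA) & !is.na(mapqB)
  both <- !is.na(mapqA) & !is.na(mapqB)
  call[onlyA] <- ifelse(mapqA[onlyA] >= minMapq, genomeA, "unassigned")
  call[onlyB] <- ifelse(mapqB[onlyB] >= minMapq, genomeB, "unassigned")
  winA <- both & mapqA > mapqB
  winB <- both & mapqB > mapqA
  tie <- both & mapqA == mapqB
  call[winA] <- ifelse(mapqA[winA] >= minMapq, genomeA, "unassigned")
  call[winB] <- ifelse(mapqB[winB] >= minMapq, genomeB, "unassigned")
  call[tie] <- "ambiguous"
  new("AssignmentResult",
      table = data.frame(name = names_all, mapqA = mapqA, mapqB = mapqB,
                         call = call, stringsAsFactors = FALSE),
      genomeA = genomeA, genomeB = genomeB, minMapq = minMapq)
}

#' Per-origin size summary
#'
#' Computes size histograms and the proportion of long (>= 300 bp) fragments
#' separately for the reads assigned to each genome.
#'
#' @param result An [AssignmentResult-class].
#' @param fragmentsA,fragmentsB The [FragmentSet-class] alignment sets the
#'   assignment was computed from (fragment lengths are taken from the
#'   assigned genome's alignment).
#' @param lMax Histogram ceiling in bp.
#' @param longCutoff Length cutoff for the long-fragment proportion.
#' @return Named list per genome with `histogram` ([SizeHistogram-class]),
#'   `proportionLong`, and `n`.
#' @export
originSizeSummary <- function(result, fragmentsA, fragmentsB, lMax = 5000,
                              longCutoff = 300) {
  tab <- result@table
  one <- function(fs, genome) {
    nm <- mcols(fragments(fs))$name
    keep <- nm %in% tab$name[tab$call == genome]
    sub <- subsetFragments(fs, which(keep))
    if (length(sub) == 0)
      return(list(histogram = sizeHistogram(numeric(0), lMax = lMax),
                  proportionLong = NA_real_, n = 0))
    list(histogram = sizeHistogram(sub, lMax = lMax),
         proportionLong = proportionInRange(sub, longCutoff, Inf),
         n = length(sub))
  }
  out <- list(one(fragmentsA, result@genomeA),
              one(fragmentsB, result@genomeB))
  names(out) <- c(result@genomeA, result@genomeB)
  out
}
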