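## Fragmentomics: size distributions, size-range proportions, 5' end-motif
## composition and the Gini diversity index, overall and per size stratum.

#' Fragment-size histogram
#'
#' Integer-bp counts up to `lMax` (default 5000); longer fragments go to an
#' overflow bucket excluded from density, median and mode.
#'
#' @param x A [FragmentSet-class] or a numeric vector of lengths in bp.
#' @param lMax Histogram ceiling in bp.
#' @return A [SizeHistogram-class].
#' @export
sizeHistogram <- function(x, lMax = 5000) {
  len <- if (is(x, "FragmentSet")) fragmentLengths(x) else as.numeric(x)
  if (any(len <= 0)) inputError("fragment lengths must be positive")
  over <- sum(len > lMax)
  len <- len[len <= lMax]
  counts <- tabulate(len, nbins = lMax)
  md <- if (length(len)) median(len) else NA_real_
  mo <- if (length(len)) which.max(counts) else NA_real_
  new("SizeHistogram", counts = as.numeric(counts), overflow = as.numeric(over),
      total = as.numeric(length(len)), medianLength = as.numeric(md),
      modeLength = as.numeric(mo), lMax = as.numeric(lMax))
}

#' Density of a size histogram
#'
#' @param hist A [SizeHistogram-class].
#' @return Numeric vector summing to 1 (all zero when empty).
#' @export
sizeDensity <- function(hist) {
  if (hist@total == 0) return(rep(0, length(hist@counts)))
  hist@counts / hist@total
}

#' Proportion of fragments in a length range
#'
#' Fraction of in-range fragment lengths with `lo <= length < hi` (overflow
#' fragments are excluded when a histogram is given, matching its density).
#'
#' @param x A [SizeHistogram-class], [FragmentSet-class], or numeric lengths.
#' @param lo,hi Range bounds in bp (`hi` may be `Inf`).
#' @return A proportion in `[0, 1]`.
#' @export
proportionInRange <- function(x, lo, hi = Inf) {
  if (lo >= hi) inputError("lo must be < hi")
  if (is(x, "SizeHistogram")) {
    if (x@total == 0) return(NA_real_)
    sel <- seq_along(x@counts) >= lo & seq_along(x@counts) < hi
    return(sum(x@counts[sel]) / x@total)
  }
  len <- if (is(x, "FragmentSet")) fragmentLengths(x) else as.numeric(x)
  if (!length(len)) return(NA_real_)
  mean(len >= lo & len < hi)
}

#' Gini diversity index
#'
#' Mean-absolute-difference Gini over `K` categories:
#' `G = sum_ij |p_i - p_j| / (2 K sum(p))`. `G = 0` for uniform usage and
#' approaches `(K - 1) / K` as all mass concentrates on one category. The
#' index is invariant to rescaling of the count vector and to permutation of
#' categories.
#'
#' @param p Nonnegative counts or proportions over the categories.
#' @return The Gini index in `[0, (K - 1) / K]`.
#' @examples
#' giniIndex(rep(1, 64))             # 0
#' giniIndex(c(1, rep(0, 63)))       # 63/64
#' @export
giniIndex <- function(p) {
  if (any(p < 0)) inputError("proportions must be nonnegative")
  tot <- sum(p)
  if (tot <= 0) inputError("all-zero vector has no diversity index")
  k <- length(p)
  ps <- sort(p)
  sum((2 * seq_len(k) - k - 1) * ps) / (k * tot)
}

#' Fragment 5' end-motif profile
#'
#' For each fragment the trinucleotide at its 5' terminus is read from the
#' reference: the 3 bases starting at the leftmost coordinate on the plus
#' strand, or the reverse complement of the 3 bases ending at the rightmost
#' coordinate on the minus strand. Motifs are tallied over the 64
#' trinucleotides per size stratum, with the Gini diversity index and
#' single-base 5' proportions (the "fragments starting with a T" quantity).
#' Fragments whose terminus lies within 3 bp of a contig edge are skipped and
#' counted; motifs containing N are tallied separately.
#'
#' @param fs A [FragmentSet-class].
#' @param reference A [ToyReference-class] covering the fragments.
#' @param strata Named list of `c(lo, hi)` ranges (e.g. [sizeStrata()]), or
#'   `NULL` for a single "all" stratum.
#' @return A named list of [EndMotifProfile-class], one per stratum.
#' @export
endMotifProfile <- function(fs, reference, strata = NULL) {
  if (is.null(strata)) strata <- list(all = c(0, Inf))
  gr <- fragments(fs)
  seqlens <- setNames(width(refSequences(reference)),
                      names(refSequences(reference)))
  ctg <- as.character(seqnames(gr))
  known <- ctg %in% names(seqlens)
  start0 <- start(gr) - 1L
  end0 <- end(gr)
  str <- as.character(GenomicRanges::strand(gr))
  str[str == "*"] <- "+"
  feasible <- known &
    ifelse(str == "+", start0 >= 0 & start0 + 3 <= seqlens[ctg],
           end0 - 3 >= 0 & end0 <= seqlens[ctg])
  motif <- rep(NA_character_, length(gr))
  i <- which(feasible)
  if (length(i))
    motif[i] <- motifFromReference(reference, ctg[i], start0[i], end0[i],
                                   str[i])
  len <- fragmentLengths(fs)
  tri <- trinucleotides()
  lapply(setNames(names(strata), names(strata)), function(sn) {
    rng <- strata[[sn]]
    inS <- len >= rng[1] & len < rng[2]
    m <- motif[inS]
    skipped <- sum(inS & !feasible)
    m <- m[!is.na(m)]
    isN <- !(m %in% tri)
    counts <- table(factor(m[!isN], levels = tri))
    counts <- setNames(as.numeric(counts), tri)
    base5 <- vapply(BASES, function(b)
      sum(counts[substr(names(counts), 1, 1) == b]), numeric(1))
    tot <- sum(counts)
    if (tot > 0) base5 <- base5 / tot
    g <- if (tot > 0) giniIndex(counts) else NA_real_
    new("EndMotifProfile", counts = counts, nN = as.numeric(sum(isN)),
        nSkipped = as.numeric(skipped), gini = g, base5 = base5,
        stratum = sn)
  })
}
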