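## Nucleosome profiling: fragment-GC bias estimation and GC-weighted,
## site-averaged, window-normalised coverage around site sets (TSS and
## nucleosome-rich control regions), for single-end long-read or paired-end
## fragments alike.

#' Estimate the fragment-GC bias curve
#'
#' Compares the observed distribution of fragment GC fractions against the
#' distribution expected if fragments of the same lengths were placed
#' uniformly on the reference (lengths summarised by deciles, placements on a
#' deterministic position grid). The observed/expected ratio is loess-smoothed
#' and normalised to mean 1 over the observed bins. With fewer than
#' `minFragments` fragments a flat curve is returned and flagged.
#'
#' @param fs A filtered [FragmentSet-class] (mapq >= 5).
#' @param reference A [ToyReference-class].
#' @param nBins Number of GC bins (default 50).
#' @param minFragments Below this, fall back to a flat low-confidence curve.
#' @return A [GCBiasCurve-class].
#' @export
estimateGCBias <- function(fs, reference, nBins = 50, minFragments = 1000) {
  mids <- (seq_len(nBins) - 0.5) / nBins
  flat <- function(lowConf) new("GCBiasCurve", mids = mids,
                                rate = rep(1, nBins),
                                nFragments = as.numeric(length(fs)),
                                lowConfidence = lowConf)
  if (length(fs) < minFragments) return(flat(TRUE))
  gr <- fragments(fs)
  gc <- fragmentGC(reference, as.character(seqnames(gr)), start(gr) - 1L,
                   end(gr))
  binOf <- function(g) pmin(nBins, pmax(1L, as.integer(ceiling(g * nBins))))
  obs <- tabulate(binOf(gc), nbins = nBins)
  obs <- obs / sum(obs)
  ## expected GC distribution from uniform placement of same-length fragments
  len <- width(gr)
  qs <- unique(as.integer(round(quantile(len, probs = seq(0.05, 0.95, 0.1)))))
  shares <- rep(1 / length(qs), length(qs))
  seqs <- refSequences(reference)
  seqlens <- width(seqs)
  expc <- numeric(nBins)
  for (j in seq_along(qs)) {
    lj <- qs[j]
    for (i in seq_along(seqs)) {
      maxS <- seqlens[i] - lj + 1
      if (maxS < 1) next
      pos <- unique(as.integer(round(seq(1, maxS,
                                         length.out = min(2000, maxS)))))
      g <- viewGC(seqs[[i]], pos, pos + lj - 1L)
      h <- tabulate(binOf(g), nbins = nBins)
      expc <- expc + shares[j] * (seqlens[i] / sum(seqlens)) * h / sum(h)
    }
  }
  use <- expc > 0 & obs > 0
  if (sum(use) < 3) return(flat(TRUE))
  ratio <- obs[use] / expc[use]
  sm <- tryCatch(
    predict(loess(ratio ~ mid, data.frame(ratio = ratio, mid = mids[use]),
                  weights = obs[use], span = 0.5, degree = 1),
            newdata = data.frame(mid = mids[use])),
    error = function(e) ratio)
  rate <- rep(1, nBins)
  rate[use] <- pmax(sm, 0.05)
  rate <- rate / sum(rate[use] * obs[use] / sum(obs[use]))  # mean 1 observed
  rate[!use] <- 1
  new("GCBiasCurve", mids = mids, rate = rate,
      nFragments = as.numeric(length(fs)), lowConfidence = FALSE)
}

#' Look up relative rates on a GC bias curve
#'
#' @param curve A [GCBiasCurve-class].
#' @param gc Fragment GC fractions.
#' @return Relative observation rates (positive).
#' @export
gcBiasRate <- function(curve, gc) {
  nBins <- length(curve@mids)
  curve@rate[pmin(nBins, pmax(1L, as.integer(ceiling(gc * nBins))))]
}

#' Normalised coverage profile around a site set
#'
#' Each fragment contributes weight `1 / rate(gc)` (1 without a bias curve) to
#' every position its span covers within +/- `windowHalfWidth` of each site;
#' minus-strand sites are flipped so downstream is positive; the summed
#' profile is divided by its own window mean, so the emitted profile has mean
#' 1 by construction. In single-end layout the full aligned span is the
#' fragment; `mode = "midpoint"` counts fragment midpoints instead of spans.
#'
#' @param fs A filtered [FragmentSet-class].
#' @param sites A [SiteSet-class] (non-empty).
#' @param gcCurve Optional [GCBiasCurve-class]; needs `reference`.
#' @param reference A [ToyReference-class]; required with `gcCurve`.
#' @param windowHalfWidth,centralHalfWidth Window definitions in bp
#'   (defaults 1000 and 500).
#' @param mode `"span"` (default) or `"midpoint"`.
#' @return A [CoverageProfile-class].
#' @export
siteCoverageProfile <- function(fs, sites, gcCurve = NULL, reference = NULL,
                                windowHalfWidth = 1000,
                                centralHalfWidth = 500,
                                mode = c("span", "midpoint")) {
  mode <- match.arg(mode)
  if (!length(sites@sites)) inputError("site set is empty")
  w <- as.integer(windowHalfWidth)
  npos <- 2L * w + 1L
  gr <- fragments(fs)
  if (mode == "midpoint")
    gr <- GRanges(seqnames(gr),
                  IRanges(floor((start(gr) + end(gr)) / 2), width = 1),
                  strand = GenomicRanges::strand(gr))
  weight <- rep(1, length(gr))
  if (!is.null(gcCurve) && !gcCurve@lowConfidence) {
    if (is.null(reference))
      inputError("reference is required to apply a GC bias curve")
    frg <- fragments(fs)
    gc <- fragmentGC(reference, as.character(seqnames(frg)),
                     start(frg) - 1L, end(frg))
    weight <- 1 / gcBiasRate(gcCurve, gc)
  }
  s <- sites@sites
  win <- suppressWarnings(
    GRanges(seqnames(s), IRanges(start(s) - w, start(s) + w)))
  hits <- findOverlaps(gr, win, ignore.strand = TRUE)
  if (!length(hits))
    stop(sprintf("no fragments overlap any window of site set '%s'",
                 sites@name))
  q <- queryHits(hits); sj <- subjectHits(hits)
  ws <- start(win)[sj]
  relS <- pmax(start(gr)[q], ws) - ws + 1L
  relE <- pmin(end(gr)[q], end(win)[sj]) - ws + 1L
  flip <- as.character(GenomicRanges::strand(s))[sj] == "-"
  if (any(flip)) {
    newS <- ifelse(flip, npos + 1L - relE, relS)
    newE <- ifelse(flip, npos + 1L - relS, relE)
    relS <- newS; relE <- newE
  }
  wt <- weight[q]
  delta <- numeric(npos + 1L)
  addAt <- rowsum(c(wt, -wt), c(relS, relE + 1L))
  delta[as.integer(rownames(addAt))] <- addAt[, 1]
  cov <- cumsum(delta)[seq_len(npos)]
  wm <- mean(cov)
  if (wm <= 0) stop(sprintf("zero coverage around site set '%s'", sites@name))
  covN <- cov / wm
  rel <- seq(-w, w)
  central <- mean(covN[abs(rel) <= centralHalfWidth])
  new("CoverageProfile", positions = as.integer(rel), coverage = covN,
      centralCoverage = central, windowMean = mean(covN),
      nSites = as.numeric(length(s)),
      nFragments = as.numeric(length(unique(q))), siteSetName = sites@name,
      centralHalfWidth = as.numeric(centralHalfWidth),
      windowHalfWidth = as.numeric(windowHalfWidth))
}

#' Summarise coverage profiles across samples
#'
#' Tabulates central coverage and window mean per sample and site set, and,
#' when several samples are given, the pairwise Pearson correlation of their
#' coverage profiles over matched site sets.
#'
#' @param profiles Named list (one entry per sample) of named lists (one entry
#'   per site set) of [CoverageProfile-class] objects; site-set names must
#'   match across samples.
#' @return List with `summary` (data.frame) and `correlations` (matrix, `NULL`
#'   for a single sample).
#' @export
profileSummaries <- function(profiles) {
  if (!length(profiles)) inputError("need at least one profile")
  if (is.null(names(profiles)))
    names(profiles) <- paste0("sample", seq_along(profiles))
  setsOf <- lapply(profiles, names)
  if (length(unique(vapply(setsOf, paste, character(1), collapse = ","))) > 1)
    inputError("site sets differ across samples")
  summary <- do.call(rbind, lapply(names(profiles), function(sm) {
    do.call(rbind, lapply(names(profiles[[sm]]), function(ss) {
      p <- profiles[[sm]][[ss]]
      data.frame(sample = sm, siteSet = ss,
                 centralCoverage = p@centralCoverage,
                 windowMean = p@windowMean, nSites = p@nSites,
                 nFragments = p@nFragments, stringsAsFactors = FALSE)
    }))
  }))
  correlations <- NULL
  if (length(profiles) > 1) {
    vecs <- vapply(profiles, function(pl)
      unlist(lapply(pl, function(p) p@coverage)),
      numeric(sum(vapply(profiles[[1]], function(p) length(p@coverage),
                         numeric(1)))))
    correlations <- stats::cor(vecs)
  }
  list(summary = summary, correlations = correlations)
}
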