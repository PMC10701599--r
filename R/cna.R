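## Copy-number analysis from shallow coverage: genome binning, GC/mappability
## correction, panel-of-normals normalisation, and a sticky-transition
## Gaussian-emission HMM over integer copy-number states whose emission means
## follow the two-component (normal + tumor) mixture model. The normal
## fraction is optimised locally from each restart value and the restart with
## the highest forward log-likelihood is reported; tumor fraction is 1 - n,
## with detection called above 3%.

#' Bin fragments genome-wide
#'
#' Tiles every contig at a fixed bin width and counts each fragment into the
#' bin holding its midpoint (unambiguous even for fragments spanning a bin
#' boundary). Per-bin GC is computed from the reference; mappability defaults
#' to 1 everywhere unless a track is supplied. Fragments off the binned genome
#' are tallied to `nOffReference`, so counted + off-reference equals the input
#' size.
#'
#' @param fs A filtered [FragmentSet-class] (see [filterFragments()]).
#' @param binWidth Bin width in bp (1 Mbp on real genomes; smaller for toy
#'   references).
#' @param reference A [ToyReference-class] covering the fragments.
#' @param mappability Optional GRanges with a `score` column; per-bin
#'   mappability is the mean score of overlapping ranges.
#' @return A [BinProfile-class].
#' @export
binFragments <- function(fs, binWidth, reference, mappability = NULL) {
  seqs <- refSequences(reference)
  seqlens <- setNames(width(seqs), names(seqs))
  binsPer <- ceiling(seqlens / binWidth)
  bins <- GRanges(rep(names(seqlens), binsPer),
                  IRanges(start = unlist(lapply(binsPer, function(k)
                            (seq_len(k) - 1) * binWidth + 1)),
                          end = unlist(lapply(seq_along(binsPer), function(i)
                            pmin(seq_len(binsPer[i]) * binWidth,
                                 seqlens[i])))))
  GenomeInfoDb::seqlevels(bins) <- names(seqlens)
  suppressWarnings(GenomeInfoDb::seqlengths(bins) <- seqlens)
  gr <- fragments(fs)
  mid <- floor((start(gr) - 1 + end(gr)) / 2)  # 0-based midpoint
  ctg <- as.character(seqnames(gr))
  onRef <- ctg %in% names(seqlens) & mid >= 0 & mid < seqlens[ctg]
  offset <- c(0, cumsum(binsPer))[seq_along(binsPer)]
  names(offset) <- names(seqlens)
  idx <- offset[ctg[onRef]] + mid[onRef] %/% binWidth + 1
  counts <- tabulate(idx, nbins = length(bins))
  gc <- unlist(lapply(seq_along(seqs), function(i) {
    k <- binsPer[i]
    starts <- (seq_len(k) - 1) * binWidth + 1
    ends <- pmin(seq_len(k) * binWidth, seqlens[i])
    viewGC(seqs[[i]], starts, ends)
  }), use.names = FALSE)
  mapp <- rep(1, length(bins))
  if (!is.null(mappability)) {
    hits <- findOverlaps(bins, mappability)
    sc <- tapply(mcols(mappability)$score[subjectHits(hits)],
                 queryHits(hits), mean)
    mapp[as.integer(names(sc))] <- as.numeric(sc)
  }
  mcols(bins)$count <- counts
  mcols(bins)$gc <- gc
  mcols(bins)$mappability <- mapp
  mcols(bins)$masked <- FALSE
  new("BinProfile", bins = bins, binWidth = as.numeric(binWidth),
      nOffReference = as.integer(sum(!onRef)))
}

#' GC/mappability correction and log2 normalisation
#'
#' Masks bins with low mappability or extreme GC, divides counts by a smooth
#' GC-bias curve (loess of count on GC; GC-decile median scaling when fewer
#' than 200 usable bins) and by mappability, and stores
#' `log2(corrected / median(corrected))`. With a panel of normals the per-bin
#' panel median log2 is subtracted and the panel mask applied.
#'
#' @param profile A [BinProfile-class] from [binFragments()].
#' @param pon Optional [PanelOfNormals-class] on the same binning.
#' @param gcRange Bins with GC outside this range are masked.
#' @param minMappability Bins below this mappability are masked.
#' @param log2Floor Value used where the corrected count is zero.
#' @return The [BinProfile-class] with `log2ratio` filled in.
#' @export
correctAndNormalize <- function(profile, pon = NULL, gcRange = c(0.3, 0.6),
                                minMappability = 0.9, log2Floor = -8) {
  bins <- profile@bins
  count <- mcols(bins)$count
  gc <- mcols(bins)$gc
  mapp <- mcols(bins)$mappability
  masked <- mapp < minMappability | gc < gcRange[1] | gc > gcRange[2]
  if (!is.null(pon)) {
    if (length(pon@bins) != length(bins))
      inputError("panel of normals is on a different binning")
    masked <- masked | mcols(pon@bins)$masked
  }
  use <- !masked
  if (!any(use)) stop("all bins masked; cannot normalise")
  if (sum(count[use]) == 0) stop("no fragments in unmasked bins")
  mu <- rep(NA_real_, length(bins))
  if (sum(use) >= 200) {
    fit <- loess(count ~ gc, data = data.frame(count = count[use],
                                               gc = gc[use]),
                 span = 0.75, degree = 2, family = "symmetric")
    mu[use] <- predict(fit, newdata = data.frame(gc = gc[use]))
  } else {
    dec <- cut(gc[use], breaks = unique(quantile(gc[use],
               probs = seq(0, 1, 0.1))), include.lowest = TRUE)
    med <- tapply(count[use], dec, median)
    mu[use] <- as.numeric(med[dec])
  }
  mu[!is.na(mu) & mu <= 0] <- NA
  corrected <- count / mu / pmax(mapp, 1e-6)
  ok <- use & is.finite(corrected)
  med <- median(corrected[ok & corrected > 0])
  l2 <- rep(NA_real_, length(bins))
  l2[ok] <- ifelse(corrected[ok] > 0, log2(corrected[ok] / med), log2Floor)
  masked[use & is.na(mu)] <- TRUE
  l2[masked] <- NA_real_
  if (!is.null(pon))
    l2[!masked] <- l2[!masked] - mcols(pon@bins)$medianLog2[!masked]
  mcols(bins)$log2ratio <- l2
  mcols(bins)$masked <- masked
  new("BinProfile", bins = bins, binWidth = profile@binWidth,
      nOffReference = profile@nOffReference)
}

#' Build a panel of normals
#'
#' Per-bin median corrected log2 ratio and dispersion (MAD) across control
#' samples; a bin is masked when masked in more than half of the controls.
#'
#' @param profiles List of corrected [BinProfile-class] objects on identical
#'   binning.
#' @return A [PanelOfNormals-class].
#' @export
buildPanelOfNormals <- function(profiles) {
  if (!length(profiles)) inputError("need at least one control profile")
  nb <- length(profiles[[1]]@bins)
  mat <- vapply(profiles, function(p) {
    if (length(p@bins) != nb) inputError("profiles are on different binnings")
    mcols(p@bins)$log2ratio
  }, numeric(nb))
  mat <- matrix(mat, nrow = nb)
  maskMat <- vapply(profiles, function(p) mcols(p@bins)$masked, logical(nb))
  maskMat <- matrix(maskMat, nrow = nb)
  bins <- granges(profiles[[1]]@bins)
  mcols(bins)$medianLog2 <- apply(mat, 1, median, na.rm = TRUE)
  mcols(bins)$dispersion <- apply(mat, 1, mad, na.rm = TRUE)
  mcols(bins)$masked <- rowMeans(maskMat) > 0.5 |
    !is.finite(mcols(bins)$medianLog2)
  mcols(bins)$medianLog2[mcols(bins)$masked] <- 0
  new("PanelOfNormals", bins = bins, binWidth = profiles[[1]]@binWidth,
      nSamples = length(profiles))
}

#' Expected log2 ratio of a copy-number state
#'
#' Under a two-component mixture of normal cells (fraction `n`, diploid) and
#' tumor cells (fraction `1 - n`, copy number `cK` against tumor ploidy
#' `phi`), the expected bin log2 ratio is
#' `log2((n * 2 + (1 - n) * cK) / (n * 2 + (1 - n) * phi))`. It is 0 whenever
#' `cK == phi`, increases with `cK`, and shrinks toward 0 as `n` approaches 1.
#'
#' @param n Normal fraction in `[0, 1]` (vectorised).
#' @param cK Integer copy number (vectorised).
#' @param phi Tumor ploidy (> 0).
#' @param floor Value returned where the numerator is 0 (`cK = 0`, `n = 0`).
#' @return Expected log2 ratio(s).
#' @examples
#' expectedLog2Ratio(0, 4, 2)     # one doubling = 1
#' expectedLog2Ratio(0.9, 3, 2)   # log2(2.1 / 2)
#' @export
expectedLog2Ratio <- function(n, cK, phi = 2, floor = -8) {
  if (any(n < 0 | n > 1)) inputError("n must be in [0, 1]")
  if (any(cK < 0)) inputError("cK must be >= 0")
  if (any(phi <= 0)) inputError("phi must be > 0")
  num <- n * 2 + (1 - n) * cK
  den <- n * 2 + (1 - n) * phi
  if (any(den <= 0)) inputError("denominator must be positive")
  out <- ifelse(num > 0, log2(num / den), floor)
  out
}

#' Copy-number HMM configuration
#'
#' @param states Integer copy-number states (default 0..3; no subclonal
#'   states).
#' @param restarts Normal-fraction restart values (default
#'   `c(0.95, 0.99, 0.995, 0.999)`).
#' @param ploidy Initial ploidy (default 2; not re-estimated unless
#'   `estimatePloidy`).
#' @param estimatePloidy Co-optimise ploidy (off by default).
#' @param selfTransition Self-transition probability (default 0.99).
#' @param emissionSd Fixed emission sd; `NA` estimates it from the data as
#'   `mad(diff(x)) / sqrt(2)`.
#' @param tfThreshold Detection threshold on tumor fraction (default 0.03).
#' @param maxIter,tol Local-search controls.
#' @param log2Floor Floor for diverging expected log2 ratios.
#' @return An [HMMConfig-class].
#' @export
hmmConfig <- function(states = 0:3, restarts = c(0.95, 0.99, 0.995, 0.999),
                      ploidy = 2, estimatePloidy = FALSE,
                      selfTransition = 0.99, emissionSd = NA_real_,
                      tfThreshold = 0.03, maxIter = 200, tol = 1e-4,
                      log2Floor = -8) {
  new("HMMConfig", states = as.numeric(states), restarts = restarts,
      ploidy = ploidy, estimatePloidy = estimatePloidy,
      selfTransition = selfTransition, emissionSd = emissionSd,
      tfThreshold = tfThreshold, maxIter = maxIter, tol = tol,
      log2Floor = log2Floor)
}

## Start distribution: the neutral state (cK == phi, if present) gets 70% of
## the start mass, the remainder is shared equally. Keeps a flat profile on a
## single neutral segment instead of an arbitrary tie-break.
hmmStartProbs <- function(states, phi) {
  k <- length(states)
  p <- rep(1 / k, k)
  neutral <- which(states == phi)
  if (length(neutral) == 1 && k > 1) {
    p[] <- 0.3 / (k - 1)
    p[neutral] <- 0.7
  }
  p
}

#' Forward log-likelihood of a bin series
#'
#' Scaled forward algorithm for the sticky-transition HMM with Gaussian
#' emissions centred at [expectedLog2Ratio()] of each state. Transitions are
#' uniform off the diagonal: self-transition `s`, each other state
#' `(1 - s) / (K - 1)`.
#'
#' @param log2s Numeric vector of corrected log2 ratios (finite).
#' @param n Normal fraction.
#' @param phi Tumor ploidy.
#' @param config An [HMMConfig-class].
#' @param sd Emission standard deviation.
#' @return The forward log-likelihood (finite).
#' @export
hmmLoglik <- function(log2s, n, phi, config = hmmConfig(), sd = 0.2) {
  if (!length(log2s)) inputError("empty bin series")
  means <- expectedLog2Ratio(n, config@states, phi, config@log2Floor)
  k <- length(means)
  s <- config@selfTransition
  off <- if (k > 1) (1 - s) / (k - 1) else 0
  start <- hmmStartProbs(config@states, phi)
  logEmis <- vapply(seq_len(k), function(j)
    dnorm(log2s, means[j], sd, log = TRUE), numeric(length(log2s)))
  logEmis <- matrix(logEmis, ncol = k)
  ll <- 0
  mx <- max(logEmis[1, ])
  a <- start * exp(logEmis[1, ] - mx)
  ct <- sum(a)
  ll <- ll + log(ct) + mx
  a <- a / ct
  tt <- nrow(logEmis)
  if (tt > 1) for (t in 2:tt) {
    pred <- a * (s - off) + off          # row sums of a %*% P, uniform off-diag
    mx <- max(logEmis[t, ])
    a <- pred * exp(logEmis[t, ] - mx)
    ct <- sum(a)
    ll <- ll + log(ct) + mx
    a <- a / ct
  }
  ll
}

## Viterbi state path (indices into config@states).
hmmViterbi <- function(log2s, n, phi, config, sd) {
  means <- expectedLog2Ratio(n, config@states, phi, config@log2Floor)
  k <- length(means)
  s <- config@selfTransition
  off <- if (k > 1) (1 - s) / (k - 1) else 0
  logS <- log(s); logOff <- if (off > 0) log(off) else -Inf
  start <- log(hmmStartProbs(config@states, phi))
  tt <- length(log2s)
  logEmis <- vapply(seq_len(k), function(j)
    dnorm(log2s, means[j], sd, log = TRUE), numeric(tt))
  logEmis <- matrix(logEmis, ncol = k)
  v <- start + logEmis[1, ]
  back <- matrix(0L, nrow = tt, ncol = k)
  if (tt > 1) for (t in 2:tt) {
    best <- which.max(v)
    second <- if (k > 1) which.max(replace(v, best, -Inf)) else best
    stay <- v + logS
    ## best predecessor j != k comes from the global (or second-best) max
    fromOther <- ifelse(seq_len(k) == best, v[second], v[best]) + logOff
    takeStay <- stay >= fromOther
    v <- ifelse(takeStay, stay, fromOther) + logEmis[t, ]
    back[t, ] <- ifelse(takeStay, seq_len(k),
                        ifelse(seq_len(k) == best, second, best))
  }
  path <- integer(tt)
  path[tt] <- which.max(v)
  if (tt > 1) for (t in seq(tt, 2)) path[t - 1] <- back[t, path[t]]
  path
}

## Deterministic shrinking-step local search for the tumor fraction,
## started at tf0; returns list(tf, loglik, converged).
searchTumorFraction <- function(x, tf0, phi, config, sd,
                                tfMax = 0.95) {
  cache <- new.env(parent = emptyenv())
  eval1 <- function(tf) {
    key <- sprintf("%.10f", tf)
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- hmmLoglik(x, 1 - tf, phi, config, sd)
    cache[[key]] <- val
    val
  }
  tf <- min(max(tf0, 0), tfMax)
  cur <- eval1(tf)
  step <- 0.02
  iter <- 0
  ## pattern search: the step expands while improving (so the search can jump
  ## across shallow dips between copy-number labellings) and contracts
  ## geometrically otherwise, down to the tolerance
  while (step >= config@tol && iter < config@maxIter) {
    iter <- iter + 1
    cand <- c(max(0, tf - step), min(tfMax, tf + step))
    vals <- vapply(cand, eval1, numeric(1))
    j <- which.max(vals)
    if (vals[j] > cur + 1e-12) {
      tf <- cand[j]
      cur <- vals[j]
      step <- min(step * 2, 0.16)
    } else step <- step / 2
  }
  list(tf = tf, loglik = cur, converged = iter < config@maxIter)
}

#' Estimate tumor fraction from a corrected bin profile
#'
#' For each normal-fraction restart value the tumor fraction is locally
#' optimised by a deterministic shrinking-step search of the forward
#' log-likelihood; the restart with the highest log-likelihood is selected
#' and reported, TF = 1 - n. A sample is called detected when TF exceeds the
#' 3% threshold. The returned estimate carries the full restart table and the
#' maximum-a-posteriori copy-number path over unmasked bins.
#'
#' @param profile A corrected [BinProfile-class].
#' @param config An [HMMConfig-class].
#' @return A [TumorFractionEstimate-class].
#' @export
fitTumorFraction <- function(profile, config = hmmConfig()) {
  bins <- profile@bins
  l2 <- mcols(bins)$log2ratio
  if (is.null(l2)) inputError("profile lacks corrected log2 ratios; run correctAndNormalize()")
  idx <- which(!mcols(bins)$masked & is.finite(l2))
  if (!length(idx)) inputError("no usable bins")
  x <- l2[idx]
  sd <- config@emissionSd
  if (is.na(sd)) {
    sd <- if (length(x) > 1) mad(diff(x)) / sqrt(2) else 0.2
    sd <- max(sd, 0.01)
  }
  phi <- config@ploidy
  fits <- lapply(config@restarts, function(n0)
    searchTumorFraction(x, 1 - n0, phi, config, sd))
  tab <- data.frame(
    restart = config@restarts,
    normalFraction = vapply(fits, function(f) 1 - f$tf, numeric(1)),
    tumorFraction = vapply(fits, function(f) f$tf, numeric(1)),
    logLik = vapply(fits, function(f) f$loglik, numeric(1)))
  sel <- which.max(tab$logLik)
  tab$selected <- seq_len(nrow(tab)) == sel
  tf <- tab$tumorFraction[sel]
  if (!all(vapply(fits, function(f) f$converged, logical(1))))
    warning("tumor-fraction search hit the iteration cap; best-so-far reported")
  path <- hmmViterbi(x, 1 - tf, phi, config, sd)
  new("TumorFractionEstimate",
      normalFraction = 1 - tf, tumorFraction = tf, ploidy = phi,
      logLik = tab$logLik[sel], restartTable = tab,
      statePath = as.integer(config@states[path]), binIndex = as.integer(idx),
      detected = tf > config@tfThreshold, emissionSd = sd,
      converged = all(vapply(fits, function(f) f$converged, logical(1))))
}

#' Segment the MAP copy-number path
#'
#' Merges runs of identical copy-number states over the unmasked bins into
#' segments (runs broken at contig boundaries); segments partition the
#' unmasked bins.
#'
#' @param profile The corrected [BinProfile-class] the estimate was fitted on.
#' @param estimate A [TumorFractionEstimate-class].
#' @return A [GenomicRanges::GRanges] with metadata `cn`, `meanLog2`, `nBins`.
#' @export
viterbiSegments <- function(profile, estimate) {
  bins <- profile@bins[estimate@binIndex]
  st <- estimate@statePath
  ctg <- as.character(seqnames(bins))
  newSeg <- c(TRUE, st[-1] != st[-length(st)] |
                ctg[-1] != ctg[-length(ctg)])
  segId <- cumsum(newSeg)
  l2 <- mcols(bins)$log2ratio
  segs <- GRanges(
    vapply(split(ctg, segId), `[`, character(1), 1),
    IRanges(vapply(split(start(bins), segId), min, numeric(1)),
            vapply(split(end(bins), segId), max, numeric(1))))
  mcols(segs)$cn <- as.integer(vapply(split(st, segId), `[`, integer(1), 1))
  mcols(segs)$meanLog2 <- as.numeric(vapply(split(l2, segId), mean,
                                            numeric(1)))
  mcols(segs)$nBins <- as.integer(lengths(split(st, segId)))
  segs
}
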