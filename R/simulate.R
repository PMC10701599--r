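## Synthetic cfDNA generator: toy references, size mixtures, copy-number-aware
## fragment placement, end-motif bias, TSS-like depletion, xenograft pairs.
## Internally 0-based half-open; GRanges/SAM conversion at the boundary.

#' Generate a toy reference genome
#'
#' Draws random contigs whose GC content varies smoothly (a low-frequency
#' sinusoid per contig) between `gcLow` and `gcHigh`. The stored GC track is
#' recomputed from the realised sequence, so re-reading the emitted FASTA
#' reproduces it exactly.
#'
#' @param nContigs Number of contigs (>= 1).
#' @param contigLength Length of each contig in bp.
#' @param gcLow,gcHigh GC bounds in `[0, 1]`, `gcLow <= gcHigh`.
#' @param seed Integer seed; fixed seed gives byte-identical sequence.
#' @param gcWindow GC track window width in bp (default 1000).
#' @return A [ToyReference-class].
#' @examples
#' ref <- makeToyReference(2, 50000, 0.35, 0.55, seed = 7)
#' range(unlist(gcTrack(ref)))
#' @export
makeToyReference <- function(nContigs = 1, contigLength = 1e6,
                             gcLow = 0.35, gcHigh = 0.55, seed = 1,
                             gcWindow = 1000) {
  if (nContigs < 1) inputError("nContigs must be >= 1")
  if (contigLength < 1) inputError("contigLength must be positive")
  if (gcLow < 0 || gcHigh > 1 || gcLow > gcHigh)
    inputError("need 0 <= gcLow <= gcHigh <= 1")
  codes <- vapply(BASES, function(b) as.integer(charToRaw(b)), integer(1))
  withSeed(seed, {
    seqs <- lapply(seq_len(nContigs), function(i) {
      L <- as.integer(contigLength)
      nW <- ceiling(L / gcWindow)
      mid <- (gcLow + gcHigh) / 2
      amp <- (gcHigh - gcLow) / 2
      freq <- runif(1, 1.5, 4)
      phase <- runif(1, 0, 1)
      target <- mid + amp * sin(2 * pi * (freq * seq_len(nW) / nW + phase))
      p <- rep(target, each = gcWindow)[seq_len(L)]
      isGC <- runif(L) < p
      pick <- runif(L) < 0.5  # G vs C, or A vs T
      code <- integer(L)
      code[isGC & pick] <- codes["G"]
      code[isGC & !pick] <- codes["C"]
      code[!isGC & pick] <- codes["A"]
      code[!isGC & !pick] <- codes["T"]
      rawToChar(as.raw(code))
    })
    names(seqs) <- paste0("chr", seq_len(nContigs))
    dss <- DNAStringSet(unlist(seqs))
    track <- lapply(seq_along(dss), function(i) {
      L <- width(dss)[i]
      starts <- seq(1L, L, by = gcWindow)
      ends <- pmin(starts + gcWindow - 1L, L)
      viewGC(dss[[i]], starts, ends)
    })
    names(track) <- names(dss)
    new("ToyReference", seqs = dss, gcWindow = as.integer(gcWindow),
        gcTrack = track)
  })
}

#' Write a toy reference as FASTA
#'
#' @param ref A [ToyReference-class].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
writeReference <- function(ref, path) {
  writeXStringSet(refSequences(ref), filepath = path)
  invisible(path)
}

#' Read a FASTA back into a ToyReference
#'
#' Recomputes the GC track from sequence, so the round trip
#' `readReference(writeReference(ref))` reproduces `gcTrack(ref)`.
#'
#' @param path FASTA path.
#' @param gcWindow GC track window width in bp.
#' @return A [ToyReference-class].
#' @export
readReference <- function(path, gcWindow = 1000) {
  dss <- readDNAStringSet(path)
  names(dss) <- sub("\\s.*$", "", names(dss))
  track <- lapply(seq_along(dss), function(i) {
    L <- width(dss)[i]
    starts <- seq(1L, L, by = gcWindow)
    ends <- pmin(starts + gcWindow - 1L, L)
    viewGC(dss[[i]], starts, ends)
  })
  names(track) <- names(dss)
  new("ToyReference", seqs = dss, gcWindow = as.integer(gcWindow),
      gcTrack = track)
}

#' Fragment-size models
#'
#' `plasmaSizeModel()` places truncated-normal modes at 167, 334, 501 and
#' 668 bp (mono- to tetra-nucleosome); default weights give 54% of mass above
#' 300 bp, the long-fragment share recovered by long-read sequencing of
#' plasma. `urineSizeModel()` is a single short mode whose truncated median is
#' about 82 bp, with no nucleosomal periodicity. Tumor-labelled fragments
#' subtract `tumorShift` from each mode mean: -20 bp at the mono-nucleosome
#' mode, growing past -100 bp for multi-nucleosome modes.
#'
#' @param weights Mixture weights over the four plasma modes (sum to 1).
#' @param sds Per-mode standard deviations in bp.
#' @param tumorShift Per-mode shift (bp) applied to tumor fragments.
#' @param minLength,maxLength Truncation bounds in bp.
#' @return A [SizeModel-class].
#' @export
plasmaSizeModel <- function(weights = c(0.46, 0.30, 0.14, 0.10),
                            sds = c(10, 10, 12, 14),
                            tumorShift = c(20, 60, 110, 130),
                            minLength = 20, maxLength = 5000) {
  modes <- data.frame(mean = c(167, 334, 501, 668), sd = sds,
                      weight = weights / sum(weights))
  new("SizeModel", kind = "plasma", modes = modes, tumorShift = tumorShift,
      minLength = minLength, maxLength = maxLength)
}

#' @rdname plasmaSizeModel
#' @param mean,sd Urine mode location and spread in bp.
#' @export
urineSizeModel <- function(mean = 81, sd = 30, tumorShift = 20,
                           minLength = 20, maxLength = 5000) {
  modes <- data.frame(mean = mean, sd = sd, weight = 1)
  new("SizeModel", kind = "urine", modes = modes, tumorShift = tumorShift,
      minLength = minLength, maxLength = maxLength)
}

#' @rdname plasmaSizeModel
#' @param modes data.frame with columns `mean`, `sd`, `weight`.
#' @param kind Model label.
#' @export
sizeModel <- function(modes, tumorShift = rep(0, nrow(modes)),
                      kind = "custom", minLength = 20, maxLength = 5000) {
  modes$weight <- modes$weight / sum(modes$weight)
  new("SizeModel", kind = kind, modes = modes, tumorShift = tumorShift,
      minLength = minLength, maxLength = maxLength)
}

## Draw lengths with the *current* RNG stream; labels vectorised.
drawLengthsRaw <- function(model, labels) {
  n <- length(labels)
  m <- model@modes
  comp <- sample.int(nrow(m), n, replace = TRUE, prob = m$weight)
  mu <- m$mean[comp] - ifelse(labels == "tumor", model@tumorShift[comp], 0)
  len <- round(rnorm(n, mu, m$sd[comp]))
  bad <- which(len < model@minLength | len > model@maxLength)
  guard <- 0
  while (length(bad) && guard < 100) {
    len[bad] <- round(rnorm(length(bad), mu[bad], m$sd[comp[bad]]))
    bad <- bad[len[bad] < model@minLength | len[bad] > model@maxLength]
    guard <- guard + 1
  }
  if (length(bad))  # pathological sd: clamp the stragglers
    len[bad] <- pmin(pmax(len[bad], model@minLength), model@maxLength)
  as.integer(len)
}

#' Sample fragment lengths from a size model
#'
#' @param model A [SizeModel-class].
#' @param label `"tumor"` (applies the per-mode shift) or `"normal"`.
#' @param n Number of lengths.
#' @param seed Integer seed.
#' @return Integer vector of lengths in bp, within the model's truncation
#'   bounds.
#' @examples
#' len <- sampleFragmentLengths(plasmaSizeModel(), "normal", 1000, seed = 1)
#' @export
sampleFragmentLengths <- function(model, label, n, seed = 1) {
  if (!label %in% c("tumor", "normal"))
    inputError("label must be 'tumor' or 'normal'")
  if (n < 1) inputError("n must be >= 1")
  withSeed(seed, drawLengthsRaw(model, rep(label, n)))
}

#' Construct a copy-number truth profile
#'
#' @param contig,start,end,cn Parallel vectors of segment coordinates
#'   (1-based, closed) and integer copy numbers; may be empty.
#' @param ploidy Background ploidy (default 2).
#' @return A [CNAProfile-class].
#' @examples
#' cnaProfile("chr1", 2e6, 6e6, 3)
#' @export
cnaProfile <- function(contig = character(), start = integer(),
                       end = integer(), cn = integer(), ploidy = 2) {
  seg <- GRanges(contig, IRanges(as.numeric(start), as.numeric(end)))
  mcols(seg)$cn <- as.integer(cn)
  new("CNAProfile", segments = seg, ploidy = ploidy)
}

#' Assemble a simulation configuration
#'
#' @param reference A [ToyReference-class].
#' @param sizeModel A [SizeModel-class] (plasma defaults).
#' @param cna A [CNAProfile-class]; defaults to no aberrations.
#' @param tumorFraction Expected tumor-labelled fraction in `[0, 1]`.
#' @param nFragments Fragments to emit.
#' @param motifBias Named numeric(64) of relative 5' trinucleotide weights.
#' @param depletionSites GRanges of site positions to thin around (may be
#'   empty); must lie on the reference.
#' @param depletionHalfWidth Half-width in bp of the thinned window.
#' @param depletionKeepProb Keep probability inside a depletion window.
#' @param gcBiasSlope Sampling weight `1 + slope * gc(fragment)`; 0 disables.
#' @param seed Integer seed.
#' @return A [SimulationConfig-class].
#' @export
simulationConfig <- function(reference, sizeModel = plasmaSizeModel(),
                             cna = NULL, tumorFraction = 0, nFragments = 1e5,
                             motifBias = uniformMotifBias(),
                             depletionSites = GRanges(),
                             depletionHalfWidth = 100,
                             depletionKeepProb = 0.3, gcBiasSlope = 0,
                             seed = 1) {
  if (is.null(cna)) cna <- cnaProfile()
  if (tumorFraction < 0 || tumorFraction > 1)
    inputError("tumorFraction must be in [0, 1]")
  seqlens <- setNames(width(refSequences(reference)),
                      names(refSequences(reference)))
  if (length(depletionSites)) {
    off <- !(as.character(seqnames(depletionSites)) %in% names(seqlens)) |
      end(depletionSites) > seqlens[as.character(seqnames(depletionSites))]
    if (any(off)) inputError("depletion site list falls off the reference")
  }
  if (length(cna@segments)) {
    off <- !(as.character(seqnames(cna@segments)) %in% names(seqlens)) |
      end(cna@segments) > seqlens[as.character(seqnames(cna@segments))]
    if (any(off)) inputError("CNA segments fall off the reference")
  }
  if (is.null(names(motifBias))) names(motifBias) <- trinucleotides()
  motifBias <- motifBias[trinucleotides()]
  new("SimulationConfig", reference = reference, sizeModel = sizeModel,
      cna = cna, tumorFraction = tumorFraction,
      nFragments = as.numeric(nFragments), motifBias = motifBias,
      depletionSites = depletionSites,
      depletionHalfWidth = depletionHalfWidth,
      depletionKeepProb = depletionKeepProb, gcBiasSlope = gcBiasSlope,
      seed = as.integer(seed))
}

## Piecewise-constant placement density over the genome for tumor fragments:
## copy-number segments weighted cn/ploidy, background weighted 1.
placementTable <- function(config) {
  seqlens <- setNames(width(refSequences(config@reference)),
                      names(refSequences(config@reference)))
  seg <- config@cna@segments
  pieces <- data.frame(contig = names(seqlens), start0 = 0,
                       end0 = as.numeric(seqlens), w = 1)
  if (length(seg)) {
    gr <- GRanges(names(seqlens), IRanges(1, seqlens))
    rest <- GenomicRanges::setdiff(gr, seg, ignore.strand = TRUE)
    pieces <- rbind(
      data.frame(contig = as.character(seqnames(rest)),
                 start0 = start(rest) - 1, end0 = as.numeric(end(rest)), w = 1),
      data.frame(contig = as.character(seqnames(seg)),
                 start0 = start(seg) - 1, end0 = as.numeric(end(seg)),
                 w = mcols(seg)$cn / config@cna@ploidy))
  }
  pieces$len <- pieces$end0 - pieces$start0
  pieces[pieces$len > 0, , drop = FALSE]
}

## 5' trinucleotide of fragments given 0-based start and exclusive end.
## Plus strand: 3 bases from the 5' terminus (leftmost); minus strand:
## reverse complement of the 3 rightmost bases.
motifFromReference <- function(ref, contig, start0, end0, strand) {
  seqs <- refSequences(ref)
  out <- character(length(contig))
  for (ct in unique(contig)) {
    i <- which(contig == ct)
    plus <- strand[i] == "+"
    s <- ifelse(plus, start0[i] + 1, end0[i] - 2)   # 1-based motif start
    v <- Views(seqs[[ct]], start = s, end = s + 2)
    m <- as.character(v)
    m[!plus] <- revcompMotifs(m[!plus])
    out[i] <- m
  }
  out
}

## Fragment GC given 0-based half-open coordinates.
fragmentGC <- function(ref, contig, start0, end0) {
  seqs <- refSequences(ref)
  out <- numeric(length(contig))
  for (ct in unique(contig)) {
    i <- which(contig == ct)
    out[i] <- viewGC(seqs[[ct]], start0[i] + 1, end0[i])
  }
  out
}

#' Simulate a labelled cfDNA sample
#'
#' Draws `nFragments` fragments: tumor labels with probability `tumorFraction`;
#' lengths from the size model (tumor shift applied); tumor fragments placed
#' with density proportional to local copy number (`cn / ploidy`), normal
#' fragments uniformly; random strand; fragments thinned (kept with
#' `depletionKeepProb`) when their midpoint falls within the depletion
#' half-width of a depletion site; 5' trinucleotides follow `motifBias` by
#' rejection against the reference sequence; optional fragment-GC sampling
#' bias. Records are coordinate-sorted; truth labels ride in the `label`
#' metadata column and can be written as a sidecar TSV.
#'
#' @param config A [SimulationConfig-class].
#' @return A [FragmentSet-class] with metadata `name`, `mapq` (60), `flag`,
#'   `label`, `motif`.
#' @examples
#' ref <- makeToyReference(1, 2e5, seed = 1)
#' fs <- simulateSample(simulationConfig(ref, nFragments = 500, seed = 3))
#' fs
#' @export
simulateSample <- function(config) {
  validObject(config)
  ref <- config@reference
  seqlens <- setNames(width(refSequences(ref)), names(refSequences(ref)))
  n <- as.integer(config@nFragments)
  if (n == 0)
    return(newFragmentSet(character(), integer(), integer(), character(),
                          integer(), character(), seqlens = seqlens))
  pieces <- placementTable(config)
  bias <- config@motifBias / max(config@motifBias)
  uniformBias <- length(unique(config@motifBias)) == 1
  depl <- config@depletionSites
  deplWindows <- if (length(depl))
    GRanges(seqnames(depl),
            IRanges(pmax(1, start(depl) - config@depletionHalfWidth),
                    end(depl) + config@depletionHalfWidth))
  else NULL

  withSeed(config@seed, {
    acc <- list()
    got <- 0
    guard <- 0
    while (got < n && guard < 60) {
      guard <- guard + 1
      m <- as.integer(min(2e6, max(1000, ceiling((n - got) * 1.4))))
      lab <- ifelse(runif(m) < config@tumorFraction, "tumor", "normal")
      len <- drawLengthsRaw(config@sizeModel, lab)
      ## tumor placement by copy-weighted pieces, normal uniform
      piT <- sample.int(nrow(pieces), m, replace = TRUE,
                        prob = pieces$w * pieces$len)
      piN <- sample.int(nrow(pieces), m, replace = TRUE, prob = pieces$len)
      pi <- ifelse(lab == "tumor", piT, piN)
      ctg <- pieces$contig[pi]
      u <- runif(m)
      start0 <- floor(pieces$start0[pi] + u * pieces$len[pi])
      ## keep the fragment on its contig
      start0 <- pmin(start0, seqlens[ctg] - len)
      keep <- start0 >= 0
      ## depletion thinning by fragment midpoint
      if (!is.null(deplWindows) && config@depletionKeepProb < 1) {
        midp <- GRanges(ctg, IRanges(start0 + floor(len / 2) + 1, width = 1))
        inWin <- countOverlapsSimple(midp, deplWindows) > 0
        keep <- keep & (!inWin | runif(m) < config@depletionKeepProb)
      }
      strand <- ifelse(runif(m) < 0.5, "+", "-")
      end0 <- start0 + len
      idx <- which(keep)
      motif <- rep(NA_character_, m)
      motif[idx] <- motifFromReference(ref, ctg[idx], start0[idx], end0[idx],
                                       strand[idx])
      if (!uniformBias) {
        w <- bias[motif[idx]]
        w[is.na(w)] <- 0  # N-containing or off-table motifs rejected
        idx <- idx[runif(length(idx)) < w]
      }
      if (config@gcBiasSlope != 0 && length(idx)) {
        gc <- fragmentGC(ref, ctg[idx], start0[idx], end0[idx])
        w <- pmax(0, 1 + config@gcBiasSlope * gc)
        idx <- idx[runif(length(idx)) < w / max(1 + max(0, config@gcBiasSlope),
                                                1e-9)]
      }
      if (length(idx)) {
        acc[[length(acc) + 1]] <- data.frame(
          contig = ctg[idx], start0 = start0[idx], end0 = end0[idx],
          strand = strand[idx], label = lab[idx], motif = motif[idx],
          stringsAsFactors = FALSE)
        got <- got + length(idx)
      }
    }
    if (got < n)
      stop("simulation could not reach the requested fragment count; ",
           "check depletion/bias settings")
    df <- do.call(rbind, acc)[seq_len(n), ]
    df$name <- sprintf("frag%07d", seq_len(n))
    o <- order(df$contig, df$start0, df$end0, df$name)
    df <- df[o, ]
    fs <- newFragmentSet(df$contig, df$start0 + 1, df$end0, df$strand,
                         mapq = 60L, name = df$name,
                         flag = ifelse(df$strand == "-", 16L, 0L),
                         label = df$label, seqlens = seqlens)
    mcols(fs@fragments)$motif <- df$motif
    fs
  })
}

## Light overlap counter (avoids pulling in countOverlaps generics confusion).
countOverlapsSimple <- function(query, subject) {
  hits <- findOverlaps(query, subject)
  tabulate(queryHits(hits), nbins = length(query))
}

#' Truth table of a labelled FragmentSet
#'
#' @param fs A [FragmentSet-class] carrying a `label` column.
#' @return data.frame with columns `name`, `label`.
#' @export
truthTable <- function(fs) {
  data.frame(name = mcols(fragments(fs))$name,
             label = mcols(fragments(fs))$label, stringsAsFactors = FALSE)
}

#' Simulate a xenograft two-genome experiment
#'
#' Graft reads are simulated on genome A and host reads on genome B; every
#' read aligns to its genome of origin at `mapqModel$true`. A configurable
#' fraction of reads additionally cross-maps to the other genome at the lower
#' `mapqModel$cross`, at a uniform position with the same fragment length.
#'
#' @param configGraft,configHost [SimulationConfig-class] objects on two
#'   distinct references (`nFragments` may be 0 for either).
#' @param crossMappingFraction Fraction of reads that also align to the other
#'   genome.
#' @param mapqModel List with `true` and `cross` mapping qualities.
#' @param seed Integer seed.
#' @return List with `alignmentsA`, `alignmentsB` ([FragmentSet-class]s) and
#'   `truth` (data.frame `name`, `origin`).
#' @export
simulateXenograftPair <- function(configGraft, configHost,
                                  crossMappingFraction = 0,
                                  mapqModel = list(true = 60, cross = 10),
                                  seed = 1) {
  seqA <- refSequences(configGraft@reference)
  seqB <- refSequences(configHost@reference)
  if (identical(as.character(seqA), as.character(seqB)))
    inputError("graft and host references are identical; origin undefined")
  configGraft@seed <- deriveSeed(seed, 11L)
  configHost@seed <- deriveSeed(seed, 23L)
  graft <- simulateSample(configGraft)
  host <- simulateSample(configHost)
  grG <- fragments(graft); grH <- fragments(host)
  if (length(grG)) {
    mcols(grG)$label <- "graft"
    mcols(grG)$name <- sprintf("g%07d", seq_along(grG))
    mcols(grG)$mapq <- as.integer(mapqModel$true)
  }
  if (length(grH)) {
    mcols(grH)$label <- "host"
    mcols(grH)$name <- sprintf("h%07d", seq_along(grH))
    mcols(grH)$mapq <- as.integer(mapqModel$true)
  }
  crossPlace <- function(src, targetRef, crossSeed) {
    ## uniform placement of cross-mapping reads on the other genome
    n <- length(src)
    if (n == 0) return(GRanges())
    seqlens <- setNames(width(refSequences(targetRef)),
                        names(refSequences(targetRef)))
    withSeed(crossSeed, {
      len <- width(src)
      ctg <- names(seqlens)[sample.int(length(seqlens), n, replace = TRUE,
                                       prob = seqlens)]
      len <- pmin(len, seqlens[ctg])
      start0 <- floor(runif(n) * (seqlens[ctg] - len + 1))
      gr <- GRanges(ctg, IRanges(start0 + 1, width = len),
                    strand = sample(c("+", "-"), n, replace = TRUE))
      GenomeInfoDb::seqlevels(gr) <- names(seqlens)
      suppressWarnings(GenomeInfoDb::seqlengths(gr) <- seqlens)
      mcols(gr) <- mcols(src)
      mcols(gr)$mapq <- as.integer(mapqModel$cross)
      mcols(gr)$flag <- ifelse(as.character(GenomicRanges::strand(gr)) == "-",
                               16L, 0L)
      gr
    })
  }
  withSeed(deriveSeed(seed, 37L), {
    hostCross <- grH[runif(length(grH)) < crossMappingFraction]
    graftCross <- grG[runif(length(grG)) < crossMappingFraction]
  })
  alignA <- c(grG, crossPlace(hostCross, configGraft@reference,
                              deriveSeed(seed, 41L)))
  alignB <- c(grH, crossPlace(graftCross, configHost@reference,
                              deriveSeed(seed, 43L)))
  truth <- rbind(
    data.frame(name = mcols(grG)$name,
               origin = rep("graft", length(grG)), stringsAsFactors = FALSE),
    data.frame(name = mcols(grH)$name,
               origin = rep("host", length(grH)), stringsAsFactors = FALSE))
  list(alignmentsA = new("FragmentSet", fragments = alignA,
                         layout = "single_end"),
       alignmentsB = new("FragmentSet", fragments = alignB,
                         layout = "single_end"),
       truth = truth)
}
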