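## Ingest: load aligned records, apply the post-alignment filters, extract
## fragment lengths for single- and paired-end layouts, and build
## downsampled / size-selected / admixed fragment sets.

#' Load aligned records into a FragmentSet
#'
#' SAM input is converted to BAM on the fly (Rsamtools) and read with
#' `scanBam`; the TSV fragment-table dialect is read directly. In single-end
#' layout each alignment yields one record whose length is the aligned
#' reference span (CIGAR walk); unmapped records are retained on the
#' pseudo-contig `"*"` until [filterFragments()]. In paired-end layout each
#' properly paired template yields exactly one record (taken from the leftmost
#' mate, template length > 0) with length = |template length|; orphans and
#' non-proper pairs are dropped.
#'
#' @param path SAM, BAM or fragment-TSV path.
#' @param layout `"single_end"` or `"paired_end"`.
#' @return A [FragmentSet-class].
#' @export
loadFragments <- function(path, layout = c("single_end", "paired_end")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) inputError(paste("no such file:", path))
  if (grepl("\\.tsv$", path, ignore.case = TRUE))
    return(readFragmentsTSV(path, layout))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE))
    bam <- asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  param <- ScanBamParam(what = c("qname", "flag", "rname", "strand", "pos",
                                 "mapq", "cigar", "isize"))
  rec <- tryCatch(scanBam(BamFile(bam), param = param)[[1]],
                  error = function(e) stop(errorCondition(
                    paste0("failed to parse '", path, "': ",
                           conditionMessage(e)),
                    class = c("cfdnaflow_format_error", "error"))))
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  flag <- rec$flag
  if (layout == "single_end") {
    unmapped <- bitwAnd(flag, 4L) > 0L | is.na(rec$pos)
    span <- rep(1L, length(flag))
    span[!unmapped] <- cigarWidthAlongReferenceSpace(rec$cigar[!unmapped])
    contig <- as.character(rec$rname)
    contig[unmapped] <- "*"
    start <- ifelse(unmapped, 1L, rec$pos)
    end <- ifelse(unmapped, 1L, rec$pos + span - 1L)
    strand <- as.character(rec$strand)
    strand[is.na(strand) | strand == "*"] <- "+"
    mapq <- rec$mapq
    mapq[is.na(mapq)] <- 0L
    seqlens <- c(hdr, "*" = 1)
    fs <- newFragmentSet(contig, start, end, strand, mapq, rec$qname,
                         flag = flag, layout = "single_end",
                         seqlens = seqlens[unique(c(names(hdr),
                                                    unique(contig)))])
    return(fs)
  }
  ## paired-end: one record per properly paired template
  keep <- bitwAnd(flag, 1L) > 0L & bitwAnd(flag, 2L) > 0L &
    !is.na(rec$isize) & rec$isize > 0L & bitwAnd(flag, 256L) == 0L &
    bitwAnd(flag, 2048L) == 0L & !is.na(rec$pos)
  newFragmentSet(as.character(rec$rname)[keep], rec$pos[keep],
                 rec$pos[keep] + rec$isize[keep] - 1L,
                 rep("+", sum(keep)), rec$mapq[keep], rec$qname[keep],
                 flag = flag[keep], layout = "paired_end", seqlens = hdr)
}

#' Post-alignment filters
#'
#' Removes unmapped reads, secondary and supplementary alignments, marked PCR
#' duplicates, and alignments with mapping quality below `minMapq` (default 5,
#' i.e. quality < 5 removed). Record order is preserved; the operation is
#' idempotent.
#'
#' @param fs A [FragmentSet-class].
#' @param minMapq Minimum mapping quality retained.
#' @return The filtered [FragmentSet-class].
#' @export
filterFragments <- function(fs, minMapq = 5) {
  gr <- fragments(fs)
  if (length(gr) == 0) return(fs)
  flag <- mcols(gr)$flag
  mapq <- mcols(gr)$mapq
  mapq[is.na(mapq)] <- -1L
  keep <- bitwAnd(flag, 4L) == 0L &      # unmapped
    bitwAnd(flag, 256L) == 0L &          # secondary
    bitwAnd(flag, 2048L) == 0L &         # supplementary
    bitwAnd(flag, 1024L) == 0L &         # duplicate
    mapq >= minMapq &
    as.character(seqnames(gr)) != "*"
  subsetFragments(fs, which(keep))
}

#' Downsample a fragment set
#'
#' Sampling is without replacement and reproducible under `seed`; with a
#' `count` the result has exactly that many records, with a `fraction` each
#' record is kept independently with that probability. Relative record order
#' is preserved, so downsampling to the full size is the identity.
#'
#' @param fs A [FragmentSet-class].
#' @param count Exact number of records to keep.
#' @param fraction Keep probability (used when `count` is missing).
#' @param seed Integer seed.
#' @return The downsampled [FragmentSet-class].
#' @export
downsampleFragments <- function(fs, count = NULL, fraction = NULL, seed = 1) {
  n <- length(fs)
  if (!is.null(count)) {
    if (count > n)
      inputError(sprintf("requested %d records but only %d available",
                         count, n))
    idx <- withSeed(seed, sort(sample.int(n, count)))
  } else if (!is.null(fraction)) {
    if (fraction < 0 || fraction > 1) inputError("fraction must be in [0, 1]")
    idx <- withSeed(seed, which(runif(n) < fraction))
  } else inputError("give either count or fraction")
  subsetFragments(fs, idx)
}

#' Size strata presets
#'
#' The three analysis strata: shorter than 150 bp, 150 to 300 bp, and 300 bp
#' or longer. Half-open `[lo, hi)` ranges; together they partition any input.
#'
#' @return Named list of `c(lo, hi)` pairs.
#' @export
sizeStrata <- function() {
  list("lt150" = c(0, 150), "150to300" = c(150, 300), "ge300" = c(300, Inf))
}

#' Select fragments by length range
#'
#' Keeps fragments with `lo <= length < hi`.
#'
#' @param fs A [FragmentSet-class].
#' @param lo,hi Range bounds in bp (`hi` may be `Inf`).
#' @return The selected [FragmentSet-class].
#' @export
selectSizeRange <- function(fs, lo, hi) {
  if (lo >= hi) inputError("lo must be < hi")
  len <- fragmentLengths(fs)
  subsetFragments(fs, which(len >= lo & len < hi))
}

#' Build an in-silico admixture
#'
#' Combines fragments from several sources into one set of a given total
#' size, either with exact per-component counts or with per-record component
#' proportions (realised counts then multinomial around the targets). Each
#' component is sampled without replacement; reproducible under `seed`.
#'
#' @param sources Named list of [FragmentSet-class] objects.
#' @param counts Exact per-component counts (sums to the output size).
#' @param proportions Per-component proportions (sum to 1; used with `total`).
#' @param total Output size in proportion mode.
#' @param seed Integer seed.
#' @return A combined [FragmentSet-class].
#' @export
buildAdmixture <- function(sources, counts = NULL, proportions = NULL,
                           total = NULL, seed = 45) {
  if (is.null(names(sources)))
    names(sources) <- paste0("component", seq_along(sources))
  k <- length(sources)
  if (is.null(counts)) {
    if (is.null(proportions) || is.null(total))
      inputError("give counts, or proportions plus total")
    if (abs(sum(proportions) - 1) > 1e-8)
      inputError("proportions must sum to 1")
    counts <- withSeed(deriveSeed(seed, 3L),
      tabulate(sample.int(k, total, replace = TRUE, prob = proportions),
               nbins = k))
  }
  avail <- vapply(sources, length, numeric(1))
  short <- which(counts > avail)
  if (length(short))
    inputError(sprintf("component '%s' has %d records but %d were requested",
                       names(sources)[short[1]], avail[short[1]],
                       counts[short[1]]))
  parts <- lapply(seq_len(k), function(i)
    fragments(downsampleFragments(sources[[i]], count = counts[i],
                                  seed = deriveSeed(seed, i))))
  combined <- suppressWarnings(do.call(c, unname(parts)))
  new("FragmentSet", fragments = combined, layout = sources[[1]]@layout)
}
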