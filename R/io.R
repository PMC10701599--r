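## Readers/writers for the plain formats the package exchanges with the rest
## of a sequencing toolchain: SAM/BAM (via Rsamtools), a TSV fragment-table
## dialect, BED site lists (via rtracklayer), and truth-table sidecars.

#' Write a FragmentSet as SAM
#'
#' Emits a coordinate-sorted SAM with `@SQ` lines taken from the fragment
#' seqinfo (or `reference`). Sequence and quality are omitted (`*`); the CIGAR
#' is a full-length match, so the reference span round-trips exactly.
#'
#' @param fs A [FragmentSet-class].
#' @param path Output SAM path.
#' @param reference Optional [ToyReference-class] supplying contig lengths
#'   when the fragment seqinfo has none.
#' @return `path`, invisibly.
#' @export
writeFragmentsSAM <- function(fs, path, reference = NULL) {
  gr <- fragments(fs)
  seqlens <- seqlengths(gr)
  if (any(is.na(seqlens)) && !is.null(reference))
    seqlens <- setNames(width(refSequences(reference)),
                        names(refSequences(reference)))
  if (any(is.na(seqlens)))
    inputError("contig lengths unavailable; pass `reference`")
  o <- order(as.factor(seqnames(gr)), start(gr), end(gr))
  gr <- gr[o]
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlens), seqlens))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*",
                  mcols(gr)$name, mcols(gr)$flag,
                  as.character(seqnames(gr)), start(gr), mcols(gr)$mapq,
                  width(gr))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname writeFragmentsSAM
#' @details `writeFragmentsBAM()` writes the SAM then converts to a sorted,
#'   indexed BAM with [Rsamtools::asBam()].
#' @export
writeFragmentsBAM <- function(fs, path, reference = NULL) {
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam))
  writeFragmentsSAM(fs, sam, reference)
  asBam(sam, sub("\\.bam$", "", path), overwrite = TRUE, indexDestination = TRUE)
  invisible(path)
}

#' Write / read the TSV fragment-table dialect
#'
#' Columns: `contig`, `start` (0-based), `end` (exclusive), `mapq`, `strand`,
#' `name`, and optionally `label`.
#'
#' @param fs A [FragmentSet-class].
#' @param path TSV path.
#' @return `writeFragmentsTSV`: `path` invisibly; `readFragmentsTSV`: a
#'   [FragmentSet-class].
#' @export
writeFragmentsTSV <- function(fs, path) {
  gr <- fragments(fs)
  df <- data.frame(contig = as.character(seqnames(gr)), start = start(gr) - 1L,
                   end = end(gr), mapq = mcols(gr)$mapq,
                   strand = as.character(GenomicRanges::strand(gr)),
                   name = mcols(gr)$name, stringsAsFactors = FALSE)
  if (!is.null(mcols(gr)$label)) df$label <- mcols(gr)$label
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFragmentsTSV
#' @param layout Fragment layout recorded on the returned set.
#' @export
readFragmentsTSV <- function(path, layout = "single_end") {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("contig", "start", "end", "mapq", "strand", "name")
  if (!all(need %in% names(df)))
    inputError(paste("fragment TSV must have columns:",
                     paste(need, collapse = ", ")))
  newFragmentSet(df$contig, df$start + 1L, df$end, df$strand, df$mapq,
                 df$name, label = if ("label" %in% names(df)) df$label
                 else NA_character_, layout = layout)
}

#' Write a truth table sidecar
#'
#' @param fs A labelled [FragmentSet-class].
#' @param path TSV path (`name`, `label`).
#' @export
writeTruthTable <- function(fs, path) {
  write.table(truthTable(fs), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a BED site list into a SiteSet
#'
#' BED input (0-based half-open; name in column 4, strand in column 6) is read
#' with rtracklayer; sites are collapsed to their 5' position (start for `+`
#' or unstranded, end for `-`) and deduplicated.
#'
#' @param path BED path.
#' @param name Site-set name (defaults to the file stem).
#' @return A [SiteSet-class].
#' @export
readSites <- function(path, name = sub("\\.bed$", "", basename(path))) {
  gr <- rtracklayer::import(path, format = "BED")
  siteSet(gr, name = name)
}

#' Construct a SiteSet from a GRanges
#'
#' @param gr GRanges of sites (any width; collapsed to the 5' position).
#' @param name Site-set name.
#' @return A [SiteSet-class].
#' @export
siteSet <- function(gr, name = "sites") {
  minus <- as.character(GenomicRanges::strand(gr)) == "-"
  pos <- ifelse(minus, end(gr), start(gr))
  out <- GRanges(seqnames(gr), IRanges(pos, width = 1),
                 strand = GenomicRanges::strand(gr))
  out <- unique(out)
  new("SiteSet", sites = out, name = name)
}
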