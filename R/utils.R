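## Internal helpers shared across modules.

## Run expr with a locally seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed), kind = "Mersenne-Twister")
  }
  force(expr)
}

## Derive a sub-seed deterministically, kept within 32-bit integer range.
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483629L) + 1L
}

BASES <- c("A", "C", "G", "T")

## The 64 trinucleotides in lexicographic order.
trinucleotides <- function() {
  g <- expand.grid(b3 = BASES, b2 = BASES, b1 = BASES,
                   stringsAsFactors = FALSE)
  sort(paste0(g$b1, g$b2, g$b3))
}

## Reverse complement of a character vector of motifs (vectorised, small k).
revcompMotifs <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

## Uniform motif-bias table.
uniformMotifBias <- function() setNames(rep(1, 64), trinucleotides())

## Construct a FragmentSet from parallel vectors (1-based closed coordinates).
newFragmentSet <- function(contig, start, end, strand, mapq, name,
                           flag = 0L, label = NA_character_,
                           layout = "single_end", seqlens = NULL) {
  n <- length(start)
  contig <- rep_len(as.character(contig), n)
  strand <- rep_len(as.character(strand), n)
  mapq <- rep_len(mapq, n)
  name <- rep_len(as.character(name), n)
  flag <- rep_len(flag, n)
  label <- rep_len(label, n)
  gr <- GRanges(contig, IRanges(start, end), strand = strand)
  if (!is.null(seqlens)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlens)
    suppressWarnings(GenomeInfoDb::seqlengths(gr) <- seqlens)
  }
  mcols(gr)$name <- name
  mcols(gr)$mapq <- as.integer(mapq)
  mcols(gr)$flag <- as.integer(flag)
  mcols(gr)$label <- label
  new("FragmentSet", fragments = gr, layout = layout)
}

## Subset a FragmentSet, preserving layout.
subsetFragments <- function(fs, idx) {
  new("FragmentSet", fragments = fs@fragments[idx], layout = fs@layout)
}

## GC fraction of a window set on one DNAString, via Views (no copying).
viewGC <- function(seq, starts, ends) {
  v <- Views(seq, start = starts, end = ends)
  as.numeric(letterFrequency(v, "GC")) / (ends - starts + 1)
}

## Assert helper producing consistent condition classes.
inputError <- function(msg) stop(errorCondition(msg,
  class = c("cfdnaflow_input_error", "error")))
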