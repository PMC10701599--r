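#' @rdname FragmentSet-class
#' @param object,x An object.
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))

#' @rdname FragmentSet-class
#' @export
setGeneric("fragmentLengths", function(x) standardGeneric("fragmentLengths"))

#' @rdname TumorFractionEstimate-class
#' @export
setGeneric("tumorFraction", function(x) standardGeneric("tumorFraction"))

#' @rdname TumorFractionEstimate-class
#' @export
setGeneric("isDetected", function(x) standardGeneric("isDetected"))

#' @rdname TumorFractionEstimate-class
#' @export
setGeneric("restartTable", function(x) standardGeneric("restartTable"))

#' @rdname BinProfile-class
#' @export
setGeneric("binTable", function(x) standardGeneric("binTable"))

#' @rdname ToyReference-class
#' @export
setGeneric("gcTrack", function(x) standardGeneric("gcTrack"))

#' @rdname ToyReference-class
#' @export
setGeneric("refSequences", function(x) standardGeneric("refSequences"))

#' @rdname CoverageProfile-class
#' @export
setGeneric("centralCoverage", function(x) standardGeneric("centralCoverage"))

#' @rdname EndMotifProfile-class
#' @export
setGeneric("motifProportions", function(x) standardGeneric("motifProportions"))

#' @rdname AssignmentResult-class
#' @export
setGeneric("assignmentTable", function(x) standardGeneric("assignmentTable"))

## ---- accessors ----

#' @rdname FragmentSet-class
#' @export
setMethod("fragments", "FragmentSet", function(x) x@fragments)

#' @rdname FragmentSet-class
#' @export
setMethod("fragmentLengths", "FragmentSet", function(x) {
  len <- mcols(x@fragments)$templateLength
  if (is.null(len)) len <- width(x@fragments)
  len
})

#' @rdname FragmentSet-class
#' @export
setMethod("length", "FragmentSet", function(x) length(x@fragments))

#' @rdname TumorFractionEstimate-class
#' @export
setMethod("tumorFraction", "TumorFractionEstimate", function(x) x@tumorFraction)

#' @rdname TumorFractionEstimate-class
#' @export
setMethod("isDetected", "TumorFractionEstimate", function(x) x@detected)

#' @rdname TumorFractionEstimate-class
#' @export
setMethod("restartTable", "TumorFractionEstimate", function(x) x@restartTable)

#' @rdname BinProfile-class
#' @export
setMethod("binTable", "BinProfile", function(x) {
  gr <- x@bins
  data.frame(contig = as.character(seqnames(gr)), start = start(gr) - 1L,
             end = end(gr), as.data.frame(mcols(gr)),
             stringsAsFactors = FALSE)
})

#' @rdname ToyReference-class
#' @export
setMethod("gcTrack", "ToyReference", function(x) x@gcTrack)

#' @rdname ToyReference-class
#' @export
setMethod("refSequences", "ToyReference", function(x) x@seqs)

#' @rdname CoverageProfile-class
#' @export
setMethod("centralCoverage", "CoverageProfile", function(x) x@centralCoverage)

#' @rdname EndMotifProfile-class
#' @export
setMethod("motifProportions", "EndMotifProfile", function(x) {
  tot <- sum(x@counts)
  if (tot == 0) return(setNames(rep(NA_real_, 64), names(x@counts)))
  x@counts / tot
})

#' @rdname AssignmentResult-class
#' @export
setMethod("assignmentTable", "AssignmentResult", function(x) x@table)

## ---- show methods ----

setMethod("show", "ToyReference", function(object) {
  cat("ToyReference:", length(object@seqs), "contig(s),",
      sum(width(object@seqs)), "bp total; GC window", object@gcWindow, "bp\n")
  gc <- unlist(object@gcTrack, use.names = FALSE)
  cat("  GC range:", sprintf("%.3f-%.3f", min(gc), max(gc)), "\n")
})

setMethod("show", "FragmentSet", function(object) {
  cat("FragmentSet: ", length(object@fragments), " fragments (",
      object@layout, ")\n", sep = "")
  if (length(object@fragments)) {
    len <- fragmentLengths(object)
    cat("  length: median", median(len), "bp, range",
        paste(range(len), collapse = "-"), "bp\n")
    lab <- mcols(object@fragments)$label
    if (!is.null(lab) && !all(is.na(lab)))
      cat("  labels:", paste(sprintf("%s=%d", names(table(lab)), table(lab)),
                             collapse = ", "), "\n")
  }
})

setMethod("show", "BinProfile", function(object) {
  cat("BinProfile:", length(object@bins), "bins of", object@binWidth, "bp;",
      sum(mcols(object@bins)$count), "fragments counted,",
      object@nOffReference, "off-reference\n")
  if (!is.null(mcols(object@bins)$log2ratio))
    cat("  corrected log2 ratio: median",
        sprintf("%.4f", median(mcols(object@bins)$log2ratio[
          !mcols(object@bins)$masked], na.rm = TRUE)), "\n")
})

setMethod("show", "TumorFractionEstimate", function(object) {
  cat(sprintf(
    "TumorFractionEstimate: TF = %.4f (normal fraction %.4f, ploidy %g)\n",
    object@tumorFraction, object@normalFraction, object@ploidy))
  cat(sprintf("  log-likelihood %.2f; detected: %s\n", object@logLik,
              object@detected))
})

setMethod("show", "EndMotifProfile", function(object) {
  cat(sprintf("EndMotifProfile [%s]: %d motifs tallied, Gini = %.4f\n",
              object@stratum, sum(object@counts), object@gini))
})

setMethod("show", "CoverageProfile", function(object) {
  cat(sprintf(
    "CoverageProfile [%s]: %d sites, %d fragments; central (+/-%d bp) = %.4f\n",
    object@siteSetName, object@nSites, object@nFragments,
    object@centralHalfWidth, object@centralCoverage))
})

setMethod("show", "AssignmentResult", function(object) {
  tab <- table(factor(object@table$call,
                      levels = c(object@genomeA, object@genomeB,
                                 "ambiguous", "unassigned")))
  cat("AssignmentResult:", nrow(object@table), "reads;",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})
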