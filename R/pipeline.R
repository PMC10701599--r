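## End-to-end orchestration: from aligned records (or a simulation config) to
## tumor fraction, fragmentomics, and nucleosome profiles, with a
## machine-readable JSON report.

#' Assemble a run configuration
#'
#' Input is either a [SimulationConfig-class] (`simulation`) or a fragment
#' file plus reference FASTA. Site sets may be [SiteSet-class] objects or BED
#' paths. All referenced paths are checked at validation time; the seed is
#' recorded in the report.
#'
#' @param simulation A [SimulationConfig-class], or `NULL` when reading files.
#' @param fragmentPath SAM/BAM/TSV fragment path (used when `simulation` is
#'   `NULL`).
#' @param referencePath Reference FASTA path (used when `simulation` is
#'   `NULL`).
#' @param layout Fragment layout for file input.
#' @param binWidth Copy-number bin width in bp.
#' @param hmm An [HMMConfig-class].
#' @param strata Size strata (named list of `c(lo, hi)`).
#' @param siteSets Named list of [SiteSet-class] or BED paths.
#' @param gcCorrection Apply the fragment-GC bias curve to coverage profiles.
#' @param outputDir Directory for per-module outputs and the JSON report
#'   (`NULL` keeps everything in memory).
#' @param seed Integer seed for any sampling the run performs.
#' @return A validated run-configuration list.
#' @export
runConfig <- function(simulation = NULL, fragmentPath = NULL,
                      referencePath = NULL, layout = "single_end",
                      binWidth = 1e6, hmm = hmmConfig(),
                      strata = sizeStrata(), siteSets = list(),
                      gcCorrection = TRUE, outputDir = NULL, seed = 1) {
  if (is.null(simulation)) {
    if (is.null(fragmentPath) || is.null(referencePath))
      inputError("give a simulation config, or fragmentPath + referencePath")
    for (p in c(fragmentPath, referencePath))
      if (!file.exists(p)) inputError(paste("no such file:", p))
  }
  siteSets <- lapply(siteSets, function(s)
    if (is.character(s)) readSites(s) else s)
  list(simulation = simulation, fragmentPath = fragmentPath,
       referencePath = referencePath, layout = layout, binWidth = binWidth,
       hmm = hmm, strata = strata, siteSets = siteSets,
       gcCorrection = gcCorrection, outputDir = outputDir,
       seed = as.integer(seed))
}

#' Run the pipeline end to end
#'
#' Executes ingest (filtering) -> copy-number/tumor-fraction -> fragmentomics
#' -> nucleosome profiling and collects a machine-readable report: tumor
#' fraction and detection flag, restart table, size-strata proportions, Gini
#' diversity per stratum, central coverage per site set, a file manifest,
#' package version and seed. Rerunning with the same configuration and seed
#' reproduces every numeric field. A stage failure is recorded in the report
#' and downstream stages are skipped.
#'
#' @param config A [runConfig()] list.
#' @return The report, invisibly also written to
#'   `file.path(outputDir, "report.json")` when an output directory is set.
#' @export
runEndToEnd <- function(config) {
  report <- list(tool = "cfdnaflow",
                 version = as.character(packageVersion("cfdnaflow")),
                 seed = config$seed, binWidth = config$binWidth,
                 stages = list(), files = character(0))
  failed <- FALSE
  stage <- function(name, expr) {
    if (failed) {
      report$stages[[name]] <<- "skipped"
      return(NULL)
    }
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      report$stages[[name]] <<- paste("error:", conditionMessage(res))
      failed <<- TRUE
      NULL
    } else {
      report$stages[[name]] <<- "ok"
      res
    }
  }
  outDir <- config$outputDir
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  emit <- function(name, writer) {
    if (is.null(outDir)) return(invisible(NULL))
    p <- file.path(outDir, name)
    writer(p)
    report$files <<- c(report$files, p)
  }

  ## ingest
  ing <- stage("ingest", {
    if (!is.null(config$simulation)) {
      ref <- config$simulation@reference
      fs <- simulateSample(config$simulation)
    } else {
      ref <- readReference(config$referencePath)
      fs <- loadFragments(config$fragmentPath, config$layout)
    }
    list(ref = ref, fs = filterFragments(fs))
  })

  ## copy number + tumor fraction
  cna <- stage("cna", {
    prof <- binFragments(ing$fs, config$binWidth, ing$ref)
    prof <- correctAndNormalize(prof)
    est <- fitTumorFraction(prof, config$hmm)
    segs <- viterbiSegments(prof, est)
    emit("bins.tsv", function(p) write.table(binTable(prof), p, sep = "\t",
                                             quote = FALSE, row.names = FALSE))
    emit("segments.tsv", function(p) write.table(
      data.frame(contig = as.character(seqnames(segs)), start = start(segs) - 1L,
                 end = end(segs), as.data.frame(mcols(segs))),
      p, sep = "\t", quote = FALSE, row.names = FALSE))
    list(profile = prof, estimate = est, segments = segs)
  })
  if (!is.null(cna)) {
    report$tumorFraction <- tumorFraction(cna$estimate)
    report$detected <- isDetected(cna$estimate)
    report$restartTable <- restartTable(cna$estimate)
  }

  ## fragmentomics
  frg <- stage("fragmentomics", {
    hist <- sizeHistogram(ing$fs)
    props <- vapply(config$strata, function(r)
      proportionInRange(ing$fs, r[1], r[2]), numeric(1))
    motifs <- endMotifProfile(ing$fs, ing$ref, config$strata)
    list(hist = hist, props = props, motifs = motifs)
  })
  if (!is.null(frg)) {
    report$strataProportions <- as.list(frg$props)
    report$giniPerStratum <- lapply(frg$motifs, function(m) m@gini)
    report$medianFragmentLength <- frg$hist@medianLength
    report$modeFragmentLength <- frg$hist@modeLength
  }

  ## nucleosome profiling
  if (length(config$siteSets)) {
    nuc <- stage("nucleoprofile", {
      curve <- if (config$gcCorrection)
        estimateGCBias(ing$fs, ing$ref) else NULL
      lapply(config$siteSets, function(ss)
        siteCoverageProfile(ing$fs, ss, gcCurve = curve,
                            reference = ing$ref))
    })
    if (!is.null(nuc))
      report$centralCoverage <- lapply(nuc, centralCoverage)
  }

  if (!is.null(outDir)) {
    write_json(report, file.path(outDir, "report.json"), auto_unbox = TRUE,
               digits = NA, pretty = TRUE)
    report$files <- c(report$files, file.path(outDir, "report.json"))
  }
  if (failed)
    warning("one or more pipeline stages failed; see report$stages")
  report
}

#' Limit-of-detection depth ladder
#'
#' Simulates replicate samples at a fixed tumor fraction, downsamples each to
#' a descending ladder of read depths, refits the tumor fraction at every
#' depth, and tabulates the fraction of replicates with a detected tumor
#' signal (TF > threshold) per depth.
#'
#' @param config A [runConfig()] list whose `simulation` holds at least
#'   `max(depths)` fragments.
#' @param depths Read depths, descending (default 1e6, 5e5, 1e5, 5e4).
#' @param replicates Replicates per depth.
#' @param seed Integer seed; replicate r uses a derived seed.
#' @return List with `table` (data.frame depth, detectionRate, nReplicates)
#'   and `detail` (data.frame depth, replicate, tumorFraction, detected).
#' @export
runLodLadder <- function(config, depths = c(1e6, 5e5, 1e5, 5e4),
                         replicates = 10, seed = 1) {
  if (is.null(config$simulation))
    inputError("runLodLadder needs a simulation-based run configuration")
  if (is.unsorted(rev(depths))) inputError("depths must be descending")
  if (replicates < 1) inputError("replicates must be >= 1")
  sim <- config$simulation
  ref <- sim@reference
  detail <- list()
  for (r in seq_len(replicates)) {
    sim@seed <- deriveSeed(seed, 1000L + r)
    parent <- filterFragments(simulateSample(sim))
    for (d in depths) {
      if (d > length(parent)) {
        warning(sprintf("depth %g exceeds available fragments (%d); skipped",
                        d, length(parent)))
        next
      }
      sub <- downsampleFragments(parent, count = d,
                                 seed = deriveSeed(seed, 2000L + 7L * r + d %% 997))
      prof <- correctAndNormalize(binFragments(sub, config$binWidth, ref))
      est <- fitTumorFraction(prof, config$hmm)
      detail[[length(detail) + 1]] <- data.frame(
        depth = d, replicate = r, tumorFraction = tumorFraction(est),
        detected = isDetected(est))
    }
  }
  detail <- do.call(rbind, detail)
  tab <- aggregate(detected ~ depth, detail, mean)
  names(tab)[2] <- "detectionRate"
  tab$nReplicates <- aggregate(detected ~ depth, detail, length)$detected
  tab <- tab[order(-tab$depth), ]
  rownames(tab) <- NULL
  list(table = tab, detail = detail)
}
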