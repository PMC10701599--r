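test_that("degenerate GC bounds yield pure AT / pure GC references", {
  at <- makeToyReference(1, 10000, 0, 0, seed = 1)
  expect_true(all(unlist(gcTrack(at)) == 0))
  expect_false(grepl("[GC]", as.character(refSequences(at)[[1]])))
  gc <- makeToyReference(1, 10000, 1, 1, seed = 1)
  expect_true(all(unlist(gcTrack(gc)) == 1))
  expect_false(grepl("[AT]", as.character(refSequences(gc)[[1]])))
})

test_that("GC track is reproduced by direct counting on the emitted FASTA", {
  ref <- makeToyReference(2, 1e5, 0.3, 0.6, seed = 7)
  gcAll <- unlist(gcTrack(ref))
  expect_gte(mean(gcAll), 0.3)
  expect_lte(mean(gcAll), 0.6)
  fa <- tempfile(fileext = ".fa")
  writeReference(ref, fa)
  back <- readReference(fa, gcWindow = 1000)
  expect_equal(gcTrack(back), gcTrack(ref))
  ## direct counting, independent of the package GC code
  seq1 <- strsplit(as.character(refSequences(back)[[1]]), "")[[1]]
  manual <- mean(seq1[1:1000] %in% c("G", "C"))
  expect_equal(gcTrack(ref)$chr1[1], manual)
})

test_that("invalid reference parameters are rejected", {
  expect_error(makeToyReference(1, -5), class = "cfdnaflow_input_error")
  expect_error(makeToyReference(0, 100), class = "cfdnaflow_input_error")
  expect_error(makeToyReference(1, 100, 0.7, 0.2),
               class = "cfdnaflow_input_error")
})

test_that("a zero-variance single mode returns constant lengths", {
  m <- sizeModel(data.frame(mean = 167, sd = 0, weight = 1))
  expect_true(all(sampleFragmentLengths(m, "normal", 100, seed = 1) == 167))
})

test_that("unknown fragment label is rejected", {
  expect_error(sampleFragmentLengths(plasmaSizeModel(), "plasma", 10),
               class = "cfdnaflow_input_error")
})

test_that("plasma lengths show the nucleosomal modes and long-fragment mass", {
  len <- sampleFragmentLengths(plasmaSizeModel(), "normal", 1e5, seed = 2)
  counts <- tabulate(len, nbins = 800)
  expect_lte(abs(which.max(counts) - 167), 2)
  ## local maxima within 3 bp of every configured mode
  for (mode in c(167, 334, 501, 668)) {
    win <- counts[(mode - 25):(mode + 25)]
    expect_lte(abs(which.max(win) - 26), 3)
  }
  ## configured >300 bp mass (0.30 + 0.14 + 0.10) recovered within 3 SE
  p <- 0.54
  se <- sqrt(p * (1 - p) / 1e5)
  expect_lte(abs(mean(len >= 300) - p), 3 * se)
  ## tumor shift moves the mono-nucleosome mode down by 20 bp
  lt <- sampleFragmentLengths(plasmaSizeModel(), "tumor", 1e5, seed = 2)
  ct <- tabulate(lt, nbins = 800)
  expect_lte(abs(which.max(ct) - 147), 2)
})

test_that("urine lengths are short, unimodal, median near 82 bp", {
  len <- sampleFragmentLengths(urineSizeModel(), "normal", 1e5, seed = 3)
  expect_lte(abs(median(len) - 82), 3)
  ## single short mode, no nucleosomal periodicity above 150 bp
  h <- tabulate(pmin(len %/% 10 + 1, 50), nbins = 50)
  pk <- which.max(h)
  expect_lt(pk * 10, 150)
  expect_lt(max(h[21:50]), 0.02 * h[pk])   # no secondary mode at 200-500 bp
  expect_lt(mean(len > 150), 0.02)
})

test_that("simulated samples honor tumor fraction and placement density", {
  ref <- tinyRef()
  fs0 <- simulateSample(simulationConfig(ref, tumorFraction = 0,
                                         nFragments = 5000, seed = 5))
  expect_equal(sum(truthTable(fs0)$label == "tumor"), 0)
  ## TF respected within 3 binomial SE
  tf <- 0.3
  fs <- simulateSample(simulationConfig(ref, tumorFraction = tf,
                                        nFragments = 2e4, seed = 6))
  se <- sqrt(tf * (1 - tf) / 2e4)
  expect_lte(abs(mean(truthTable(fs)$label == "tumor") - tf), 3 * se)
  ## TF=1 with one c=4 segment: density in segment ~ 2x background
  cna <- cnaProfile("chr1", 50001, 100000, 4L)
  fs1 <- simulateSample(simulationConfig(ref, cna = cna, tumorFraction = 1,
                                         nFragments = 4e4, seed = 7))
  gr <- fragments(fs1)
  mid <- (GenomicRanges::start(gr) + GenomicRanges::end(gr)) / 2
  inSeg <- mid > 50000 & mid <= 100000
  densIn <- sum(inSeg) / 50000
  densOut <- sum(!inSeg) / 150000
  expect_lt(abs(densIn / densOut - 2), 0.2)
})

test_that("stored 5' motifs match the emitted FASTA and obey motif bias", {
  ref <- tinyRef()
  fs <- simulateSample(simulationConfig(ref, nFragments = 500, seed = 8))
  fa <- tempfile(fileext = ".fa")
  writeReference(ref, fa)
  seq1 <- as.character(Biostrings::readDNAStringSet(fa)[[1]])
  gr <- fragments(fs)
  idx <- seq(1, length(gr), by = 7)
  for (i in idx) {
    s <- GenomicRanges::start(gr)[i]; e <- GenomicRanges::end(gr)[i]
    str <- as.character(GenomicRanges::strand(gr)[i])
    expected <- if (str == "+") substr(seq1, s, s + 2) else
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(substr(seq1, e - 2, e))))
    expect_identical(S4Vectors::mcols(gr)$motif[i], expected)
  }
  ## degenerate bias: all mass on one motif
  bias <- setNames(c(1, rep(0, 63)), cfdnaflow:::trinucleotides())
  fsb <- simulateSample(simulationConfig(ref, nFragments = 300, seed = 9,
                                         motifBias = bias))
  expect_true(all(S4Vectors::mcols(fragments(fsb))$motif == "AAA"))
})

test_that("simulation output is byte-identical under a fixed seed", {
  ref <- makeToyReference(1, 5e4, 0.35, 0.55, seed = 12)
  ref2 <- makeToyReference(1, 5e4, 0.35, 0.55, seed = 12)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  writeReference(ref, f1); writeReference(ref2, f2)
  expect_identical(readLines(f1), readLines(f2))
  cfg <- function() simulationConfig(ref, nFragments = 1000, seed = 42)
  s1 <- tempfile(fileext = ".sam"); s2 <- tempfile(fileext = ".sam")
  t1 <- tempfile(fileext = ".tsv"); t2 <- tempfile(fileext = ".tsv")
  a <- simulateSample(cfg()); b <- simulateSample(cfg())
  writeFragmentsSAM(a, s1); writeFragmentsSAM(b, s2)
  writeFragmentsTSV(a, t1); writeFragmentsTSV(b, t2)
  expect_identical(readLines(s1), readLines(s2))
  expect_identical(readLines(t1), readLines(t2))
})

test_that("off-reference site lists and bad TF are rejected", {
  ref <- tinyRef()
  offSites <- GenomicRanges::GRanges("chrX", IRanges::IRanges(10, 10))
  expect_error(simulationConfig(ref, depletionSites = offSites),
               class = "cfdnaflow_input_error")
  expect_error(simulationConfig(ref, tumorFraction = 1.2),
               class = "cfdnaflow_input_error")
})

test_that("xenograft pairs are labelled, cross-mapped and reject identical genomes", {
  refA <- makeToyReference(1, 1e5, 0.35, 0.55, seed = 21)
  refB <- makeToyReference(1, 1e5, 0.35, 0.55, seed = 22)
  cfgA <- simulationConfig(refA, nFragments = 1500, seed = 1)
  cfgB <- simulationConfig(refB, nFragments = 1000, seed = 2)
  ## cross-mapping 0: every read in exactly one genome's alignments
  xp0 <- simulateXenograftPair(cfgA, cfgB, crossMappingFraction = 0, seed = 3)
  nmA <- S4Vectors::mcols(fragments(xp0$alignmentsA))$name
  nmB <- S4Vectors::mcols(fragments(xp0$alignmentsB))$name
  expect_length(intersect(nmA, nmB), 0)
  expect_setequal(c(nmA, nmB), xp0$truth$name)
  ## host n = 0: truth all graft
  cfgB0 <- simulationConfig(refB, nFragments = 0, seed = 2)
  xpg <- simulateXenograftPair(cfgA, cfgB0, seed = 4)
  expect_true(all(xpg$truth$origin == "graft"))
  ## cross-mapping fraction recovered within 3 SE
  xp <- simulateXenograftPair(
    simulationConfig(refA, nFragments = 6000, seed = 1),
    simulationConfig(refB, nFragments = 4000, seed = 2),
    crossMappingFraction = 0.2, seed = 3)
  nmA <- S4Vectors::mcols(fragments(xp$alignmentsA))$name
  nmB <- S4Vectors::mcols(fragments(xp$alignmentsB))$name
  frac <- length(intersect(nmA, nmB)) / 10000
  expect_lte(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / 10000))
  ## identical references rejected
  expect_error(simulateXenograftPair(cfgA, cfgA, seed = 1),
               class = "cfdnaflow_input_error")
})
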