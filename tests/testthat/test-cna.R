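test_that("expected log2 ratio has its closed forms and monotonicities", {
  expect_equal(expectedLog2Ratio(1, 0, 2), 0)
  expect_equal(expectedLog2Ratio(1, 3, 2), 0)
  expect_equal(expectedLog2Ratio(0, 4, 2), 1)
  expect_equal(expectedLog2Ratio(0.9, 3, 2), log2(2.1 / 2))
  expect_equal(expectedLog2Ratio(0.5, 2, 2), 0)  # cK == phi
  ## monotone increasing in cK; |m| shrinks toward 0 as n -> 1
  for (n in seq(0, 0.95, by = 0.05)) {
    m <- expectedLog2Ratio(n, 0:6, 2)
    expect_true(all(diff(m) > 0) || n == 1)
  }
  for (cK in c(0, 1, 3)) {
    m <- abs(expectedLog2Ratio(seq(0.1, 0.999, length.out = 30), cK, 2))
    expect_true(all(diff(m) < 1e-12))
  }
  ## zero-copy floor
  expect_equal(expectedLog2Ratio(0, 0, 2, floor = -8), -8)
  expect_error(expectedLog2Ratio(-0.1, 2, 2), class = "cfdnaflow_input_error")
})

test_that("fragments are counted to bins by midpoint with conservation", {
  ref <- tinyRef()  # one 200 kb contig
  ## 10 fragments inside bin 3 (20-30 kb at width 10 kb)
  fs <- manualFragments("chr1", seq(21000, 27000, length.out = 10),
                        seq(21000, 27000, length.out = 10) + 166,
                        seqlen = 2e5)
  prof <- binFragments(fs, 1e4, ref)
  counts <- binTable(prof)$count
  expect_equal(counts[3], 10)
  expect_equal(sum(counts), 10)
  ## fragment straddling a boundary goes to the bin holding its midpoint
  straddle <- manualFragments("chr1", 9941, 10040, seqlen = 2e5)  # mid 9990
  expect_equal(binTable(binFragments(straddle, 1e4, ref))$count[1], 1)
  straddle2 <- manualFragments("chr1", 9953, 10052, seqlen = 2e5) # mid 10002
  expect_equal(binTable(binFragments(straddle2, 1e4, ref))$count[2], 1)
  ## off-reference records are tallied, total conserved
  off <- manualFragments(c("chr1", "chrZ"), c(100, 100), c(266, 266))
  poff <- binFragments(off, 1e4, ref)
  expect_equal(sum(binTable(poff)$count), 1)
  expect_equal(poff@nOffReference, 1L)
  ## uniform placement is Poisson-consistent per bin
  fsU <- filterFragments(simulateSample(
    simulationConfig(ref, nFragments = 2e4, seed = 31)))
  cU <- binTable(binFragments(fsU, 1e4, ref))$count
  expect_true(all(abs(cU - 1000) < 4 * sqrt(1000)))
})

test_that("GC correction flattens planted bias and self-PoN zeroes log2", {
  ref <- makeToyReference(2, 1e6, 0.35, 0.55, seed = 13)
  ## null: flat copy number, no GC bias -> median log2 ~ 0
  fs0 <- filterFragments(simulateSample(
    simulationConfig(ref, nFragments = 1e5, seed = 14)))
  p0 <- correctAndNormalize(binFragments(fs0, 5e3, ref))
  bt0 <- binTable(p0)
  expect_lt(abs(median(bt0$log2ratio[!bt0$masked])), 0.05)
  ## planted count ~ (1 + gc): correlation collapses after correction
  fsB <- filterFragments(simulateSample(
    simulationConfig(ref, nFragments = 2e5, seed = 15, gcBiasSlope = 1)))
  pB <- binFragments(fsB, 5e3, ref)
  btB <- binTable(pB)
  rPre <- cor(btB$count, btB$gc)
  pBc <- correctAndNormalize(pB)
  btBc <- binTable(pBc)
  use <- !btBc$masked
  rPost <- cor(2^btBc$log2ratio[use], btBc$gc[use])
  expect_gt(rPre, 0.5)
  expect_lt(abs(rPost), 0.1)
  ## panel of normals equal to the sample itself -> exact zeros
  pon <- buildPanelOfNormals(list(p0))
  pSelf <- correctAndNormalize(binFragments(fs0, 5e3, ref), pon = pon)
  btS <- binTable(pSelf)
  expect_true(all(abs(btS$log2ratio[!btS$masked]) < 1e-12))
})

test_that("forward log-likelihood matches closed form on one bin", {
  cfg <- hmmConfig(states = 2, restarts = 0.99, selfTransition = 0.5)
  x <- 0.123
  expect_equal(hmmLoglik(x, 0.9, 2, cfg, sd = 0.1),
               dnorm(x, 0, 0.1, log = TRUE))
  expect_error(hmmLoglik(numeric(0), 0.9, 2, cfg, sd = 0.1),
               class = "cfdnaflow_input_error")
})

test_that("forward and Viterbi match exhaustive enumeration on short series", {
  cfg <- hmmConfig()
  set.seed(101)
  for (i in 1:30) {
    tt <- sample(2:8, 1)
    n <- runif(1, 0.6, 0.99)
    sd <- runif(1, 0.05, 0.3)
    truthState <- sample(0:3, tt, replace = TRUE)
    x <- rnorm(tt, oracleMeans(n, truthState, 2), sd)
    expect_equal(hmmLoglik(x, n, 2, cfg, sd),
                 oracleForward(x, n, 2, 0:3, 0.99, sd), tolerance = 1e-9)
    expect_equal(cfdnaflow:::hmmViterbi(x, n, 2, cfg, sd),
                 unname(oracleViterbi(x, n, 2, 0:3, 0.99, sd)))
  }
})

test_that("tumor fraction is recovered and the restart rule is honored", {
  ref <- makeToyReference(2, 2.5e6, 0.35, 0.55, seed = 16)
  cna <- cnaProfile(c("chr1", "chr2"), c(5e5, 8e5) + 1, c(1.5e6, 1.8e6),
                    c(3L, 1L))
  fs <- filterFragments(simulateSample(
    simulationConfig(ref, cna = cna, tumorFraction = 0.2,
                     nFragments = 3e5, seed = 17)))
  est <- fitTumorFraction(correctAndNormalize(binFragments(fs, 5e3, ref)))
  expect_lte(abs(tumorFraction(est) - 0.2), 0.05)
  expect_true(isDetected(est))
  tab <- restartTable(est)
  expect_equal(which(tab$selected), which.max(tab$logLik))
  expect_equal(tumorFraction(est), tab$tumorFraction[which.max(tab$logLik)])
  expect_equal(tumorFraction(est), 1 - est@normalFraction)
})

test_that("a flat profile yields one neutral segment per contig", {
  ref <- makeToyReference(2, 1e6, 0.35, 0.55, seed = 18)
  fs <- filterFragments(simulateSample(
    simulationConfig(ref, nFragments = 2e5, seed = 19)))
  prof <- correctAndNormalize(binFragments(fs, 5e3, ref))
  est <- fitTumorFraction(prof)
  expect_false(isDetected(est))
  segs <- viterbiSegments(prof, est)
  expect_equal(length(segs), 2L)  # one per contig
  expect_true(all(S4Vectors::mcols(segs)$cn == 2L))
})

test_that("a planted gain segment is recovered by the MAP path", {
  ref <- makeToyReference(1, 1e6, 0.35, 0.55, seed = 23)
  cna <- cnaProfile("chr1", 4e5 + 1, 6e5, 3L)  # 20 bins at width 10 kb
  fs <- filterFragments(simulateSample(
    simulationConfig(ref, cna = cna, tumorFraction = 0.4,
                     nFragments = 2e5, seed = 24)))
  prof <- correctAndNormalize(binFragments(fs, 1e4, ref))
  est <- fitTumorFraction(prof)
  segs <- viterbiSegments(prof, est)
  gains <- segs[S4Vectors::mcols(segs)$cn == 3L]
  expect_gte(length(gains), 1L)
  ov <- GenomicRanges::intersect(
    gains, GenomicRanges::GRanges("chr1", IRanges::IRanges(4e5 + 1, 6e5)))
  expect_gte(sum(IRanges::width(ov)) / 2e5, 0.8)
  ## segments partition the unmasked bins
  expect_equal(sum(S4Vectors::mcols(segs)$nBins), length(est@binIndex))
})
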