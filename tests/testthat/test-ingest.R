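test_that("single-end and paired-end layouts extract the right fragments", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:100000",
    "se1\t0\tchr1\t100\t60\t167M\t*\t0\t0\t*\t*"), sam)
  se <- loadFragments(sam, "single_end")
  expect_equal(length(se), 1L)
  expect_equal(fragmentLengths(se), 167L)

  pe <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:100000",
    "p1\t99\tchr1\t100\t60\t50M\t=\t217\t167\t*\t*",
    "p1\t147\tchr1\t217\t60\t50M\t=\t100\t-167\t*\t*",
    "p2\t99\tchr1\t300\t60\t50M\t=\t450\t200\t*\t*",
    "p2\t147\tchr1\t450\t60\t50M\t=\t300\t-200\t*\t*",
    "p3\t99\tchr1\t600\t60\t50M\t=\t700\t150\t*\t*",
    "p3\t147\tchr1\t700\t60\t50M\t=\t600\t-150\t*\t*",
    "orph1\t0\tchr1\t800\t60\t50M\t*\t0\t0\t*\t*",
    "orph2\t0\tchr1\t900\t60\t50M\t*\t0\t0\t*\t*"), pe)
  fs <- loadFragments(pe, "paired_end")
  expect_equal(length(fs), 3L)
  expect_setequal(fragmentLengths(fs), c(167L, 200L, 150L))
  expect_error(loadFragments("/nonexistent.sam"),
               class = "cfdnaflow_input_error")
})

test_that("post-alignment filters keep exactly the passing records", {
  sam <- writeSixRecordSAM(tempfile(fileext = ".sam"))
  fs <- loadFragments(sam, "single_end")
  expect_equal(length(fs), 6L)
  kept <- filterFragments(fs)
  expect_equal(length(kept), 1L)
  expect_equal(S4Vectors::mcols(fragments(kept))$name, "r_pass")
  ## mapq boundary: < 5 removed, exactly 5 kept
  fs5 <- manualFragments("chr1", c(10, 20), c(100, 110), mapq = c(4, 5))
  expect_equal(S4Vectors::mcols(fragments(filterFragments(fs5)))$mapq, 5L)
  ## idempotence and order preservation
  again <- filterFragments(kept)
  expect_identical(fragments(again), fragments(kept))
  all10 <- manualFragments("chr1", 1:10 * 100, 1:10 * 100 + 99)
  expect_equal(length(filterFragments(all10)), 10L)
  expect_identical(S4Vectors::mcols(fragments(filterFragments(all10)))$name,
                   S4Vectors::mcols(fragments(all10))$name)
  ## empty in, empty out
  expect_equal(length(filterFragments(manualFragments("chr1", integer(0),
                                                      integer(0)))), 0L)
})

test_that("downsampling is exact, seeded and order-preserving", {
  fs <- manualFragments("chr1", 1:1000 * 10, 1:1000 * 10 + 99)
  expect_identical(fragments(downsampleFragments(fs, count = 1000)),
                   fragments(fs))
  a <- downsampleFragments(fs, count = 100, seed = 95)
  b <- downsampleFragments(fs, count = 100, seed = 95)
  expect_identical(fragments(a), fragments(b))
  expect_equal(length(a), 100L)
  ## subset relation and downsample(k) twice = identity
  expect_true(all(S4Vectors::mcols(fragments(a))$name %in%
                    S4Vectors::mcols(fragments(fs))$name))
  expect_identical(fragments(downsampleFragments(a, count = 100, seed = 7)),
                   fragments(a))
  ## fraction mode hits the expected size
  fr <- downsampleFragments(fs, fraction = 0.5, seed = 1)
  expect_lte(abs(length(fr) - 500), 3 * sqrt(1000 * 0.25))
  expect_error(downsampleFragments(fs, count = 2000),
               class = "cfdnaflow_input_error")
})

test_that("size strata are half-open and partition any input", {
  fs <- manualFragments("chr1", rep(100, 4), 100 + c(100, 150, 300, 400) - 1)
  lt <- selectSizeRange(fs, 0, 150)
  expect_equal(fragmentLengths(lt), 100L)
  expect_equal(length(selectSizeRange(fs, 0, Inf)), 4L)
  expect_error(selectSizeRange(fs, 300, 300), class = "cfdnaflow_input_error")
  ## partition over simulated plasma lengths
  len <- sampleFragmentLengths(plasmaSizeModel(), "normal", 10000, seed = 4)
  fsL <- manualFragments("chr1", rep(1000, 10000), 1000 + len - 1)
  sizes <- vapply(sizeStrata(), function(r)
    length(selectSizeRange(fsL, r[1], r[2])), numeric(1))
  expect_equal(sum(sizes), 10000)
  ## no overlap between strata
  nms <- lapply(sizeStrata(), function(r)
    S4Vectors::mcols(fragments(selectSizeRange(fsL, r[1], r[2])))$name)
  expect_length(intersect(nms[[1]], nms[[2]]), 0)
  expect_length(intersect(nms[[2]], nms[[3]]), 0)
})

test_that("admixtures meet exact component counts and honor seeds", {
  tum <- manualFragments("chr1", 1:500 * 10, 1:500 * 10 + 99,
                         name = sprintf("t%04d", 1:500), label = "tumor")
  nor <- manualFragments("chr1", 1:2000 * 10, 1:2000 * 10 + 99,
                         name = sprintf("n%04d", 1:2000), label = "normal")
  ## identity: one component, target = size
  one <- buildAdmixture(list(t = tum), counts = 500)
  expect_equal(length(one), 500L)
  ## 15% / 85% exact counts via the truth labels
  mix <- buildAdmixture(list(tumor = tum, normal = nor),
                        counts = c(300, 1700), seed = 45)
  expect_equal(length(mix), 2000L)
  expect_equal(sum(truthTable(mix)$label == "tumor"), 300)
  ## infeasible counts name the deficient component
  expect_error(buildAdmixture(list(tumor = tum, normal = nor),
                              counts = c(600, 100)),
               regexp = "tumor", class = "cfdnaflow_input_error")
  ## replicate admixtures with seeds 45..69: distinct but reproducible
  reps <- lapply(45:69, function(s)
    truthTable(buildAdmixture(list(tumor = tum, normal = nor),
                              proportions = c(0.15, 0.85), total = 400,
                              seed = s)))
  expect_equal(length(unique(vapply(reps, function(r)
    paste(r$name, collapse = ","), character(1)))), 25L)
  again <- truthTable(buildAdmixture(list(tumor = tum, normal = nor),
                                     proportions = c(0.15, 0.85), total = 400,
                                     seed = 52))
  expect_identical(again, reps[[8]])
  ## proportion mode within 3 binomial SE
  pt <- mean(reps[[1]]$label == "tumor")
  expect_lte(abs(pt - 0.15), 3 * sqrt(0.15 * 0.85 / 400))
})
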