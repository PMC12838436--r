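# Junction algebra, clustering, depth segmentation, the derivative walk
# and the mosaic estimator.

test_that("junction orientation algebra: deletions are (+,-), inversions like-oriented", {
  ref <- makeReference(1, 60000, 0.45, seed = 2)
  del <- svRoundTrip(ref, derivativePlan(data.frame(
    chrom = "chr1", start = c(0, 40000), end = c(20000, 60000),
    orientation = "+")), list(chrom = "chr1", pos = 0, dir = 1))
  expect_equal(nrow(del$junctions), 1L)
  expect_equal(del$junctions$ori_a, "+")
  expect_equal(del$junctions$ori_b, "-")
  inv <- svRoundTrip(ref, derivativePlan(data.frame(
    chrom = "chr1", start = c(0, 20000, 40000),
    end = c(20000, 40000, 60000), orientation = c("+", "-", "+"))),
    list(chrom = "chr1", pos = 0, dir = 1))
  expect_true(all(inv$junctions$ori_a == inv$junctions$ori_b))
})

test_that("clustering merges jittered junctions at the median and applies min_support", {
  j <- function(pa, pb, id) data.frame(
    chrom_a = "chr1", pos_a = pa, ori_a = "+", chrom_b = "chr1",
    pos_b = pb, ori_b = "-", read_id = id, inserted_seq = "")
  six <- do.call(rbind, lapply(1:6, function(i) j(1000L, 2000L,
                                                  sprintf("r%d", i))))
  cl <- clusterJunctions(six, min_support = 3)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$support, 6L)
  two <- six[1:2, ]
  cl2 <- clusterJunctions(two, min_support = 3)
  expect_equal(nrow(cl2), 0L)
  expect_equal(attr(cl2, "n_dropped"), 1L)
  jit <- do.call(rbind, lapply(1:5, function(i)
    j(1000L + c(-3L, -1L, 0L, 2L, 3L)[i], 2000L + c(3L, 0L, -2L, 1L, -3L)[i],
      sprintf("r%d", i))))
  cl3 <- clusterJunctions(jit, pos_tolerance = 10)
  expect_equal(nrow(cl3), 1L)
  expect_equal(cl3$pos_a, median(jit$pos_a))
  expect_equal(cl3$pos_b, median(jit$pos_b))
})

test_that("depth segmentation recovers planted copy-number steps", {
  # depth statistics are exercised with shorter reads: depth noise
  # scales with read length, and the binning machinery is what is under
  # test here
  ref <- makeReference(1, 60000, 0.45, seed = 7)
  cfg <- function(s) simulationConfig(coverage = 40, seed = s,
                                      read_length_median = 2000,
                                      read_length_n50 = 3000)
  x0 <- simulateSample(ref, config = cfg(3))
  cn0 <- segmentCopyNumber(x0, 2000)
  expect_true(all(abs(cn0$copy_number - 2) < 0.5))
  # heterozygous deletion drops to ~1 copy
  del <- derivativePlan(data.frame(chrom = "chr1", start = c(0, 40000),
                                   end = c(20000, 60000),
                                   orientation = "+"))
  x1 <- simulateSample(ref, plans = list(del), config = cfg(3))
  cn1 <- segmentCopyNumber(x1, 2000)
  mid <- cn1[cn1$start <= 25000 & cn1$end >= 35000, ]
  expect_true(any(abs(mid$copy_number - 1) < 0.45))
  expect_error(segmentCopyNumber(x1, 50), "bin_size")
})

test_that("the derivative walk reproduces every planted rearrangement class", {
  # chr2/chr3 are untouched diploid ballast so the copy-number median is
  # not dominated by the large planted duplications
  ref <- makeReference(3, 100000, 0.45, seed = 21)
  L <- 100000L
  cases <- list(
    DEL = list(plan = derivativePlan(data.frame(
                 chrom = "chr1", start = c(0, 60000), end = c(40000, L),
                 orientation = "+")),
               anchor = list(chrom = "chr1", pos = 0, dir = 1),
               truth = c(40000, 60000)),
    DUP = list(plan = derivativePlan(data.frame(
                 chrom = "chr1", start = c(0, 40000), end = c(60000, L),
                 orientation = "+")),
               anchor = list(chrom = "chr1", pos = 0, dir = 1),
               truth = c(40000, 60000)),
    INV = list(plan = derivativePlan(data.frame(
                 chrom = "chr1", start = c(0, 40000, 60000),
                 end = c(40000, 60000, L), orientation = c("+", "-", "+"))),
               anchor = list(chrom = "chr1", pos = 0, dir = 1),
               truth = c(40000, 40000, 60000, 60000)),
    `DEL-INV-DUP` = list(plan = derivativePlan(data.frame(
                 chrom = "chr1", start = c(15850, 15000),
                 end = c(65850, L), orientation = c("-", "+"))),
               anchor = list(chrom = "chr1", pos = 65850, dir = -1),
               truth = c(15000, 15850)),
    `DUP-TRP/INV-DUP` = list(plan = derivativePlan(data.frame(
                 chrom = "chr1", start = c(0, 40000, 50000),
                 end = c(60000, 60000, L), orientation = c("+", "-", "+"))),
               anchor = list(chrom = "chr1", pos = 0, dir = 1),
               truth = c(40000, 50000, 60000, 60000)),
    RING = list(plan = derivativePlan(data.frame(
                 chrom = "chr1", start = 10000, end = 90000,
                 orientation = "+"), circular = TRUE),
               anchor = list(chrom = "chr1", pos = 10000, dir = 1),
               truth = c(10000, 90000)))
  for (nm in names(cases)) {
    cs <- cases[[nm]]
    rt <- svRoundTrip(ref, cs$plan, cs$anchor, bin_size = 2000)
    expect_equal(motifLabel(rt$derivative), nm, label = nm)
    got <- sort(c(rt$junctions$pos_a, rt$junctions$pos_b))
    expect_equal(got, cs$truth, tolerance = 0, label = paste(nm, "breakpoints"))
  }
  # ring closes on itself
  ring <- svRoundTrip(ref, cases$RING$plan, cases$RING$anchor)
  expect_true(ring$derivative@circular)
})

test_that("a two-chromosome junction yields an unbalanced translocation", {
  ref2 <- makeReference(2, 60000, 0.45, seed = 22)
  plan <- derivativePlan(data.frame(chrom = c("chr1", "chr2"),
                                    start = c(0, 30000),
                                    end = c(25000, 60000),
                                    orientation = "+"), name = "derT")
  rt <- svRoundTrip(ref2, plan, list(chrom = "chr1", pos = 0, dir = 1))
  expect_equal(motifLabel(rt$derivative), "UNBALANCED_TRANSLOCATION")
  segs <- as.data.frame(segments(rt$derivative))
  expect_equal(segs$chrom, c("chr1", "chr2"))
})

test_that("breakpoint deletions at inversion junctions are annotated", {
  ref <- makeReference(1, 100000, 0.45, seed = 21)
  plan <- derivativePlan(data.frame(chrom = "chr1",
                                    start = c(0, 47600, 60000),
                                    end = c(40000, 60000, 100000),
                                    orientation = c("+", "-", "+")))
  rt <- svRoundTrip(ref, plan, list(chrom = "chr1", pos = 0, dir = 1))
  expect_equal(motifLabel(rt$derivative), "INV")
  expect_match(paste(rt$derivative@annotations, collapse = " "),
               "7600 bp deletion")
})

test_that("no junctions gives a REFERENCE derivative spanning the anchor chromosome", {
  empty <- data.frame(chrom_a = character(0), pos_a = integer(0),
                      ori_a = character(0), chrom_b = character(0),
                      pos_b = integer(0), ori_b = character(0),
                      support = integer(0))
  d <- buildDerivative(empty, NULL, list(chrom = "chr1", pos = 0, dir = 1),
                       seqlengths = c(chr1 = 50000L))
  expect_equal(motifLabel(d), "REFERENCE")
  s <- as.data.frame(segments(d))
  expect_equal(s$start, 0L)
  expect_equal(s$end, 50000L)
})

test_that("mosaic fraction arithmetic and sampling behaviour", {
  expect_equal(estimateMosaicFraction(6, 28)$percent, 42L)
  expect_equal(estimateMosaicFraction(6, 28)$fraction, 12 / 28)
  expect_equal(estimateMosaicFraction(14, 28)$percent, 100L)
  expect_equal(estimateMosaicFraction(0, 28)$percent, 0L)
  expect_true(is.na(estimateMosaicFraction(0, 0)$fraction))
  # 200 binomial replicates at a true fraction of 0.4
  withr::with_seed(40, {
    est <- vapply(1:200, function(i) {
      n <- 60L
      supp <- stats::rbinom(1, n, 0.2)
      estimateMosaicFraction(supp, n)$fraction
    }, numeric(1))
    expect_lt(abs(mean(est) - 0.4), 0.03)
  })
})

test_that("simulated mosaic rings estimate their planted cell fraction", {
  ref <- makeReference(1, 100000, 0.45, seed = 21)
  plan <- derivativePlan(data.frame(chrom = "chr1", start = 10000,
                                    end = 90000, orientation = "+"),
                         circular = TRUE, cell_fraction = 0.4)
  est <- vapply(1:5, function(s) {
    rt <- svRoundTrip(ref, plan, list(chrom = "chr1", pos = 10000, dir = 1),
                      coverage = 34, seed = s)
    mosaicFraction(rt$derivative)
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.4), 0.12)
})

test_that("CN step boundaries coincide with recovered junctions", {
  ref <- makeReference(1, 100000, 0.45, seed = 21)
  rt <- svRoundTrip(ref, derivativePlan(data.frame(
    chrom = "chr1", start = c(0, 60000), end = c(40000, 100000),
    orientation = "+")), list(chrom = "chr1", pos = 0, dir = 1),
    coverage = 40, read_length_median = 2000, read_length_n50 = 3000)
  cn <- rt$cn
  # the widest ~1-copy segment is the planted deletion; both of its
  # boundaries must sit within a bin of a recovered junction
  loss <- cn[cn$copy_number <= 1.5, ]
  expect_gte(nrow(loss), 1L)
  loss <- loss[which.max(loss$end - loss$start), ]
  bp <- sort(c(rt$junctions$pos_a, rt$junctions$pos_b))
  expect_lt(min(abs(loss$start - bp)), 1000 + 50)
  expect_lt(min(abs(loss$end - bp)), 1000 + 50)
})

test_that("junction VCF export writes paired breakends", {
  jn <- data.frame(chrom_a = "chr1", pos_a = 1000L, ori_a = "+",
                   chrom_b = "chr1", pos_b = 2000L, ori_b = "-",
                   support = 5L)
  f <- tempfile(fileext = ".vcf")
  junctionsToVcf(jn, f, c(chr1 = 50000L))
  v <- readLines(f)
  body <- v[!startsWith(v, "#")]
  expect_equal(length(body), 2L)
  expect_match(body[1], "N\\[chr1:2001\\[")
  expect_match(body[2], "\\]chr1:1000\\]N")
  expect_match(body[1], "SVTYPE=BND")
})
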