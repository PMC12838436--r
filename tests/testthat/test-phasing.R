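# Haplotype assignment, cis/trans phasing and paralog copy number.

test_that("clean reads are assigned 100% correctly at 5 het SNVs (up to label swap)", {
  ref <- makeReference(1, 30000, 0.45, seed = 2)
  pos5 <- c(5000, 9000, 14000, 20000, 26000)
  vdf <- snvTable(ref, pos5)
  h <- list(haplotypeSpec(1, variants = vdf, weight = 0.5),
            haplotypeSpec(2, weight = 0.5))
  x <- simulateSample(ref, haplotypes = h,
                      config = simulationConfig(coverage = 25, seed = 8))
  asg <- assignHaplotypes(x, asVcfVariants(vdf))
  tr <- groundTruth(x)
  truth <- tr$haplotype[match(names(asg), tr$read_id)]
  ok <- !is.na(asg)
  expect_gt(sum(ok), 10)
  agree <- mean(asg[ok] == truth[ok])
  expect_equal(max(agree, 1 - agree), 1)
  # label-swap symmetry of downstream cis/trans calls
  v1 <- asVcfVariants(vdf[1, ]); v2 <- asVcfVariants(vdf[3, ])
  swapped <- ifelse(is.na(asg), NA_integer_, 3L - asg)
  p1 <- phasePair(x, v1, v2, haplotype_tags = asg)
  p2 <- phasePair(x, v1, v2, haplotype_tags = swapped)
  expect_equal(p1$phase, p2$phase)
})

test_that("single-read, single-site and exact-tie rules", {
  A <- S4Vectors::DataFrame(
    read_id = "r1", chrom = "chr1", pos = 1L, strand = "+", mapq = 60L,
    cigar = "10M", seq = "ACGTACGTAC", qstart = 1L, qend = 10L,
    supplementary = FALSE, hp = NA_integer_)
  A$meth <- list(data.frame(chrom = character(0), pos = integer(0),
                            prob = numeric(0)))
  x <- new("LongReadSet", alignments = A, truth = S4Vectors::DataFrame(),
           seqlengths = c(chr1 = 100L))
  v <- data.frame(chrom = "chr1", pos = 3L, ref = "G", alt = "C")
  asg <- assignHaplotypes(x, v)
  expect_equal(unname(asg["r1"]), 1L)
  # two-site read tied between consensuses stays unassigned
  A2 <- rbind(A, A)
  A2$read_id <- c("r1", "r2")
  A2$seq <- c("ACGTACGTAC", "CCGTACGTAC")  # r2: alt at site1, ref at site2
  A2$meth <- list(data.frame(chrom = character(0), pos = integer(0),
                             prob = numeric(0)),
                  data.frame(chrom = character(0), pos = integer(0),
                             prob = numeric(0)))
  x2 <- new("LongReadSet", alignments = A2, truth = S4Vectors::DataFrame(),
            seqlengths = c(chr1 = 100L))
  v2 <- data.frame(chrom = "chr1", pos = c(1L, 5L), ref = c("A", "A"),
                   alt = c("C", "T"))
  asg2 <- assignHaplotypes(x2, v2, min_informative = 1L)
  expect_equal(unname(asg2["r1"]), 1L)
  expect_true(is.na(asg2["r2"]))
})

test_that("variant pairs 585 bp apart phase by direct spanning reads", {
  ref <- makeReference(1, 20000, 0.45, seed = 3)
  vdf <- snvTable(ref, c(8000, 8585))
  # trans: one alt per haplotype
  h <- list(haplotypeSpec(1, variants = vdf[1, ], weight = 0.5),
            haplotypeSpec(2, variants = vdf[2, ], weight = 0.5))
  x <- simulateSample(ref, haplotypes = h,
                      config = simulationConfig(coverage = 30, seed = 5))
  v <- asVcfVariants(vdf)
  pr <- phasePair(x, v[1, ], v[2, ])
  expect_equal(pr$phase, "trans")
  expect_equal(pr$mode, "direct")
  expect_gte(pr$n_trans_support, 3)
  # cis: both alts on the same haplotype
  h2 <- list(haplotypeSpec(1, variants = vdf, weight = 0.5),
             haplotypeSpec(2, weight = 0.5))
  x2 <- simulateSample(ref, haplotypes = h2,
                       config = simulationConfig(coverage = 30, seed = 5))
  expect_equal(phasePair(x2, v[1, ], v[2, ])$phase, "cis")
  # no coverage at a variant
  far <- list(chrom = "chr1", pos = 19999L, ref = "A", alt = "T")
  x3 <- x
  ends <- x3@alignments$pos +
    vapply(x3@alignments$cigar, lorediag:::cigarRefLength, numeric(1))
  x3@alignments <- x3@alignments[ends < 15000, ]
  pr3 <- phasePair(x3, v[1, ], far)
  expect_equal(pr3$phase, "unknown")
})

test_that("variants 105 kb apart phase through haplotype tags", {
  ref <- makeReference(1, 120000, 0.45, seed = 6)
  # scatter of phased het SNVs provides the tagging backbone; the two
  # clinically relevant variants sit 105 kb apart
  vdf <- snvTable(ref, c(5000, 110000))
  h <- list(haplotypeSpec(1, variants = vdf[1, ], weight = 0.5),
            haplotypeSpec(2, variants = vdf[2, ], weight = 0.5))
  x <- simulateSample(ref, haplotypes = h,
                      config = simulationConfig(coverage = 30, seed = 9))
  v <- asVcfVariants(vdf)
  pr <- phasePair(x, v[1, ], v[2, ])
  expect_equal(pr$mode, "tag_routed")
  expect_equal(pr$phase, "trans")
})

test_that("phasing accuracy holds across replicates, clean and noisy", {
  ref <- makeReference(1, 20000, 0.45, seed = 3)
  vdf <- snvTable(ref, c(8000, 8585))
  v <- asVcfVariants(vdf)
  h <- list(haplotypeSpec(1, variants = vdf[1, ], weight = 0.5),
            haplotypeSpec(2, variants = vdf[2, ], weight = 0.5))
  clean <- vapply(1:10, function(s)
    phasePair(simulateSample(ref, haplotypes = h,
                             config = simulationConfig(coverage = 30,
                                                       seed = s)),
              v[1, ], v[2, ])$phase, character(1))
  expect_true(all(clean == "trans"))
  noisy <- vapply(1:20, function(s)
    phasePair(simulateSample(ref, haplotypes = h,
                             config = simulationConfig(
                               coverage = 30, seed = s,
                               substitution_rate = 0.03,
                               insertion_rate = 0.01,
                               deletion_rate = 0.01)),
              v[1, ], v[2, ])$phase, character(1))
  expect_gte(mean(noisy == "trans"), 0.95)
})

test_that("paralog clusters resolve copy number by gene", {
  ref <- makeReference(1, 20000, 0.45, seed = 3)
  gene_pos <- 10000L
  markers <- c(9000L, 9500L, 10500L, 11000L)
  mkspec <- function(k, n_copies) {
    mv <- markers[seq_len(k - 1)]
    vdf <- if (length(mv)) snvTable(ref, mv) else NULL
    haplotypeSpec(k, variants = vdf, weight = 1 / n_copies)
  }
  fam <- list(family_id = "SMN", genes = c("SMN1", "SMN2"),
              region = list(chrom = "chr1", start = 8500L, end = 11500L),
              gene_site = list(
                pos = gene_pos + 1L,
                alleles = list(SMN1 = altOf(baseAt(ref, gene_pos)),
                               SMN2 = baseAt(ref, gene_pos))),
              marker_sites = markers + 1L)
  # 0 SMN1 / 4 SMN2 planted copies: coverage doubled (4 copies vs the
  # diploid baseline of 30X)
  x4 <- simulateSample(ref, haplotypes = lapply(1:4, mkspec, n_copies = 4),
                       config = simulationConfig(coverage = 60, seed = 9))
  pc <- paralogCopyNumber(x4, fam, baseline_depth = 30)
  expect_equal(unname(pc$per_gene_copies["SMN1"]), 0L)
  expect_equal(unname(pc$per_gene_copies["SMN2"]), 4L)
  expect_equal(pc$total_copies, 4L)
  # 2/2: plant the SMN1-defining allele on two copies
  mkspec12 <- function(k) {
    mv <- markers[seq_len(k - 1)]
    vdf <- snvTable(ref, sort(c(mv, if (k <= 2) gene_pos)))
    haplotypeSpec(k, variants = vdf, weight = 1 / 4)
  }
  x22 <- simulateSample(ref, haplotypes = lapply(1:4, mkspec12),
                        config = simulationConfig(coverage = 60, seed = 10))
  pc2 <- paralogCopyNumber(x22, fam, baseline_depth = 30)
  expect_equal(unname(pc2$per_gene_copies["SMN1"]), 2L)
  expect_equal(unname(pc2$per_gene_copies["SMN2"]), 2L)
  # single-gene family with 2 copies
  fam1 <- fam
  fam1$genes <- "SMN2"
  fam1$gene_site$alleles <- list(SMN2 = baseAt(ref, gene_pos))
  x2 <- simulateSample(ref, haplotypes = lapply(1:2, mkspec, n_copies = 2),
                       config = simulationConfig(coverage = 30, seed = 11))
  pc3 <- paralogCopyNumber(x2, fam1, baseline_depth = 30)
  expect_equal(unname(pc3$per_gene_copies["SMN2"]), 2L)
  # zero reads over the region is a no-call
  empty <- x2
  empty@alignments <- empty@alignments[0, ]
  expect_true(is.na(paralogCopyNumber(empty, fam1)$total_copies))
})
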