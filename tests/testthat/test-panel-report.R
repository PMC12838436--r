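# Panel triage, SV frequency database, cohort aggregation, reporting.

# minimal derivative with controllable junctions/CN for triage tests
mkDer <- function(junctions, cn = NULL, segs = NULL) {
  if (is.null(cn))
    cn <- data.frame(chrom = character(0), start = integer(0),
                     end = integer(0), copy_number = numeric(0),
                     n_bins = integer(0))
  if (is.null(segs))
    segs <- data.frame(chrom = character(0), start = integer(0),
                       end = integer(0), orientation = character(0))
  new("DerivativeChromosome",
      segments = S4Vectors::DataFrame(segs), circular = FALSE,
      motifLabel = "DEL", mosaicFraction = NA_real_,
      junctionsUsed = S4Vectors::DataFrame(junctions),
      cnSegments = S4Vectors::DataFrame(cn),
      annotations = character(0))
}

jrow <- function(pa, pb, n = 1L) do.call(rbind, lapply(seq_len(n),
  function(i) data.frame(chrom_a = "chr1", pos_a = pa + (i - 1L) * 3000L,
                         ori_a = "+", chrom_b = "chr1",
                         pos_b = pb + (i - 1L) * 3000L, ori_b = "-",
                         support = 5L)))

panelFix <- list(panel_id = "NDD",
                 genes = "GENE1",
                 regions = data.frame(chrom = "chr1", start = 50000L,
                                      end = 70000L, gene = "GENE1"))

test_that("two-tier triage: size rule, panel rule, breakpoint-count rule", {
  big <- mkDer(jrow(100000L, 115000L),
               cn = data.frame(chrom = "chr1", start = 100000L,
                               end = 115000L, copy_number = 1, n_bins = 15L))
  small_in <- mkDer(jrow(60000L, 62000L),
                    cn = data.frame(chrom = "chr1", start = 60000L,
                                    end = 62000L, copy_number = 1,
                                    n_bins = 2L))
  small_out <- mkDer(jrow(200000L, 202000L),
                     cn = data.frame(chrom = "chr1", start = 200000L,
                                     end = 202000L, copy_number = 1,
                                     n_bins = 2L))
  complex5 <- mkDer(jrow(200000L, 201500L, n = 5L),
                    cn = data.frame(chrom = "chr1", start = 200000L,
                                    end = 208000L, copy_number = 1,
                                    n_bins = 8L))
  res <- filterSvsByPanel(list(big = big, small_in = small_in,
                               small_out = small_out, complex5 = complex5),
                          panelFix, size_threshold = 10000)
  expect_setequal(names(res$kept), c("big", "small_in", "complex5"))
  expect_equal(res$drop_log$id, "small_out")
  expect_match(res$drop_log$reason, "outside_panel")
  # rules recorded per kept derivative
  expect_equal(res$kept_rules[match("big", names(res$kept))],
               "genome_wide_size")
  expect_equal(res$kept_rules[match("complex5", names(res$kept))],
               "breakpoint_count")
  # idempotence
  res2 <- filterSvsByPanel(res$kept, panelFix, size_threshold = 10000)
  expect_setequal(names(res2$kept), names(res$kept))
  expect_equal(nrow(res2$drop_log), 0L)
  # empty panel warns and drops sub-threshold SVs
  expect_warning(
    res3 <- filterSvsByPanel(list(s = small_in), NULL,
                             size_threshold = 10000),
    "no panel")
  expect_equal(length(res3$kept), 0L)
})

test_that("affected span weights copy-number change and counts inversions", {
  balanced_inv <- mkDer(
    rbind(data.frame(chrom_a = "chr1", pos_a = 10000L, ori_a = "+",
                     chrom_b = "chr1", pos_b = 22000L, ori_b = "+",
                     support = 5L),
          data.frame(chrom_a = "chr1", pos_a = 10000L, ori_a = "-",
                     chrom_b = "chr1", pos_b = 22000L, ori_b = "-",
                     support = 5L)),
    segs = data.frame(chrom = "chr1", start = c(0L, 10000L, 22000L),
                      end = c(10000L, 22000L, 50000L),
                      orientation = c("+", "-", "+")))
  expect_equal(affectedSpan(balanced_inv), 12000)
  del <- mkDer(jrow(1000L, 4000L),
               cn = data.frame(chrom = "chr1", start = 1000L, end = 4000L,
                               copy_number = 1, n_bins = 3L))
  expect_equal(affectedSpan(del), 3000)
})

test_that("the SV database counts distinct samples and filters common junctions", {
  j1 <- jrow(1000L, 2000L)
  sets <- c(lapply(1:50, function(i) j1),
            list(unique_sample = jrow(500000L, 501000L)))
  names(sets) <- c(sprintf("s%02d", 1:50), "unique_sample")
  # pad the cohort to 100 samples with empty junction sets
  empty <- j1[0, ]
  sets <- c(sets, stats::setNames(lapply(1:49, function(i) empty),
                                  sprintf("e%02d", 1:49)))
  db <- buildSvDb(sets)
  expect_equal(db$n_samples, 100L)
  common <- annotateFrequency(j1, db)
  expect_equal(common$db_frequency, 0.5)
  rare <- annotateFrequency(jrow(500000L, 501000L), db)
  expect_equal(rare$db_frequency, 0.01)
  # threshold filter removes the common junction, keeps the rare one
  q <- rbind(j1, jrow(500000L, 501000L))
  kept <- filterUniqueJunctions(q, db, max_frequency = 0.05,
                                query_sample = "unique_sample")
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$pos_a, 500000L)
  # jittered duplicates within tolerance collapse to one signature
  jit_sets <- list(a = jrow(1000L, 2000L), b = jrow(1010L, 1990L),
                   c = jrow(995L, 2005L))
  db2 <- buildSvDb(jit_sets, tolerance = 50)
  expect_equal(nrow(db2$entries), 1L)
  expect_equal(db2$entries$n_samples_seen, 3L)
})

test_that("cohort aggregation counts variants, individuals and yields", {
  f <- table2Fixture()
  s <- aggregateCohort(f, cohort_size = 100)
  expect_equal(s@nVariants, 17L)
  expect_equal(s@nIndividuals, 13L)
  ty <- as.data.frame(s@byType)
  expect_equal(ty$n_individuals[ty$variant_type == "SNV/INDEL"], 2L)
  expect_equal(ty$n_individuals[ty$variant_type == "SV"], 7L)
  expect_equal(ty$n_individuals[ty$variant_type == "STR"], 3L)
  expect_equal(ty$n_individuals[ty$variant_type == "OTHER"], 1L)
  # empty table
  s0 <- aggregateCohort(f[0, ], 100)
  expect_equal(unname(s0@yields["diagnostic_yield_P_LP"]), 0)
  # 29 of 100 individuals with P/LP gives a 29% yield
  synth <- data.frame(individual_id = sprintf("I%03d", 1:29),
                      variant_id = sprintf("v%03d", 1:29),
                      variant_type = "SNV/INDEL", gene = "G",
                      classification = rep(c("P", "LP"), length.out = 29),
                      added_value_note = "", reported = TRUE)
  s29 <- aggregateCohort(synth, 100)
  expect_equal(unname(s29@yields["diagnostic_yield_P_LP"]), 29)
  # individuals with both P/LP and VUS count once, under the best class
  dup <- rbind(synth,
               data.frame(individual_id = "I001", variant_id = "vx",
                          variant_type = "SV", gene = "G2",
                          classification = "VUS_hot",
                          added_value_note = "", reported = TRUE))
  sdup <- aggregateCohort(dup, 100)
  expect_equal(unname(sdup@yields["diagnostic_yield_P_LP"]), 29)
  expect_equal(unname(sdup@yields["hot_VUS_yield"]), 0)
  # yield invariant to row order and duplicated records
  shuf <- synth[rev(seq_len(nrow(synth))), ]
  expect_equal(aggregateCohort(rbind(shuf, synth[1, ]), 100)@yields,
               s29@yields)
  bad <- synth; bad$classification[1] <- "PATHO"
  expect_error(aggregateCohort(bad, 100), "unknown classification")
  expect_error(aggregateCohort(synth, 10), "cohort_size")
})

test_that("reports exclude NR findings from the clinical section and are deterministic", {
  f <- table2Fixture()
  s <- aggregateCohort(f, 100)
  r1 <- renderReport(s, f)
  r2 <- renderReport(s, f)
  expect_identical(r1, r2)
  n_nr <- sum(!f$reported)
  expect_gt(n_nr, 0)
  clin_hdr <- grep("Clinical section", r1, value = TRUE)
  expect_match(clin_hdr, sprintf("\\(%d reported", nrow(f) - n_nr))
  audit_hdr <- grep("Audit section", r1, value = TRUE)
  expect_match(audit_hdr, sprintf("\\(%d findings", nrow(f)))
  # NR variant ids appear only below the audit header
  nr_ids <- f$variant_id[!f$reported]
  first_hit <- min(grep(nr_ids[1], r1, fixed = TRUE))
  expect_gt(first_hit, grep("Audit section", r1))
})
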