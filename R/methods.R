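#' @describeIn LongReadSet-class Alignment records as a DataFrame.
#' @export
setMethod("alignments", "LongReadSet", function(x) x@alignments)

#' @describeIn LongReadSet-class Planted ground truth sidecar.
#' @export
setMethod("groundTruth", "LongReadSet", function(x) x@truth)

#' @describeIn LongReadSet-class Number of distinct reads.
#' @export
setMethod("length", "LongReadSet",
          function(x) length(unique(x@alignments$read_id)))

#' @describeIn LongReadSet-class Reference sequence lengths.
#' @importFrom GenomicRanges seqnames
#' @export
seqLengths <- function(x) x@seqlengths

setMethod("show", "LongReadSet", function(object) {
  a <- object@alignments
  cat("LongReadSet with", length(unique(a$read_id)), "reads,",
      nrow(a), "alignment records on",
      length(object@seqlengths), "sequence(s)\n")
  if (nrow(a)) {
    nsupp <- sum(a$supplementary)
    nmeth <- sum(vapply(a$meth, nrow, integer(1)) > 0)
    cat("  supplementary alignments:", nsupp,
        "| rows with CpG calls:", nmeth, "\n")
  }
  if (nrow(object@truth))
    cat("  ground-truth sidecar present (", nrow(object@truth), "reads )\n")
})

#' @describeIn StrProfile-class Per-read repeat calls.
#' @export
setMethod("readCalls", "StrProfile", function(x) x@readCalls)

#' @describeIn StrProfile-class Per-haplotype summary table.
#' @export
setMethod("profileSummary", "StrProfile", function(x) x@summary)

setMethod("show", "StrProfile", function(object) {
  loc <- object@locus
  cat("StrProfile:", loc$gene[1], paste0("(", loc$motif[1], ")"),
      "locus", loc$locus_id[1], "\n")
  cat("  spanning reads:", nrow(object@readCalls),
      "| pooled median:", object@overallMedian, "\n")
  s <- object@summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  haplotype %s: median %s (range %s-%s, n=%d) -> %s\n",
                s$haplotype[i], s$median[i], s$min[i], s$max[i],
                s$n_reads[i], s$classification[i]))
  if (!is.na(object@promoterMethylation))
    cat("  promoter methylation fraction:",
        round(object@promoterMethylation, 3), "\n")
})

#' @describeIn DerivativeChromosome-class Ordered oriented segments.
#' @export
setMethod("segments", "DerivativeChromosome", function(x, ...) x@segments)

#' @describeIn DerivativeChromosome-class Rearrangement motif label.
#' @export
setMethod("motifLabel", "DerivativeChromosome", function(x) x@motifLabel)

#' @describeIn DerivativeChromosome-class Estimated mosaic cell fraction.
#' @export
setMethod("mosaicFraction", "DerivativeChromosome", function(x) x@mosaicFraction)

#' @describeIn DerivativeChromosome-class Junctions consumed by the walk.
#' @export
setMethod("junctionsUsed", "DerivativeChromosome", function(x) x@junctionsUsed)

setMethod("show", "DerivativeChromosome", function(object) {
  cat("DerivativeChromosome:", object@motifLabel,
      if (object@circular) "(circular)" else "", "\n")
  if (!is.na(object@mosaicFraction))
    cat("  mosaic fraction:", round(object@mosaicFraction, 3), "\n")
  cat(renderSubway(object), sep = "\n")
  if (length(object@annotations))
    cat("  notes:", paste(object@annotations, collapse = "; "), "\n")
})

setMethod("show", "CohortSummary", function(object) {
  cat("CohortSummary:", object@nVariants, "variants in",
      object@nIndividuals, "individuals (cohort size",
      object@cohortSize, ")\n")
  y <- object@yields
  for (nm in names(y)) cat(sprintf("  %s: %.1f%%\n", nm, y[[nm]]))
})
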