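#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' LongReadSet: aligned long reads with methylation and ground truth
#'
#' Container for a set of aligned long reads. Each alignment record
#' (primary or supplementary) is one row of the `alignments` DataFrame;
#' chimeric reads share a `read_id` across rows. Per-CpG methylation
#' probability calls ride on the primary row as a list column. When the
#' set was produced by [simulateSample()], the `truth` slot carries the
#' planted per-read ground truth (haplotype and source template).
#'
#' Alignment columns: `read_id`, `chrom`, `pos` (1-based leftmost),
#' `strand`, `mapq`, `cigar`, `seq` (SAM orientation), `qstart`/`qend`
#' (1-based interval in the original read), `supplementary` (logical),
#' `hp` (haplotype tag, NA when untagged), `meth` (list of data.frames
#' with 0-based `pos` and `prob` per CpG call).
#'
#' @slot alignments A [S4Vectors::DataFrame] of alignment records.
#' @slot truth A DataFrame of per-read ground truth (zero rows when
#'   reads were loaded from a file without a sidecar).
#' @slot seqlengths Named integer vector of reference sequence lengths.
#' @export
setClass("LongReadSet",
  representation(alignments = "DataFrame",
                 truth = "DataFrame",
                 seqlengths = "integer"))

setValidity("LongReadSet", function(object) {
  need <- c("read_id", "chrom", "pos", "strand", "mapq", "cigar", "seq",
            "qstart", "qend", "supplementary", "hp", "meth")
  miss <- setdiff(need, colnames(object@alignments))
  if (length(miss))
    return(paste("alignments missing columns:", paste(miss, collapse = ", ")))
  if (nrow(object@alignments) &&
      !all(object@alignments$strand %in% c("+", "-")))
    return("strand must be '+' or '-'")
  if (is.null(names(object@seqlengths)))
    return("seqlengths must be named")
  TRUE
})

#' StrProfile: haplotype-resolved repeat profile at one locus
#'
#' @slot locus A one-row DataFrame describing the catalog locus.
#' @slot readCalls DataFrame of per-read calls (`read_id`, `repeat_count`,
#'   `haplotype`, `interruptions` list column, `tract_sequence`).
#' @slot summary DataFrame with one row per haplotype group
#'   (`haplotype`, `n_reads`, `median`, `min`, `max`, `classification`).
#' @slot overallMedian Pooled median repeat count (NA when no spanning
#'   reads -- a no-call, not an error).
#' @slot promoterMethylation Promoter methylation fraction in [0,1] or NA.
#' @export
setClass("StrProfile",
  representation(locus = "DataFrame",
                 readCalls = "DataFrame",
                 summary = "DataFrame",
                 overallMedian = "numeric",
                 promoterMethylation = "numeric"))

#' DerivativeChromosome: a reconstructed derivative as oriented segments
#'
#' @slot segments DataFrame of ordered, oriented segments (`chrom`,
#'   `start`, `end` 0-based half-open, `orientation`).
#' @slot circular Logical; TRUE for ring chromosomes.
#' @slot motifLabel Rearrangement motif label.
#' @slot mosaicFraction Estimated cell fraction in [0,1] (NA when not
#'   estimated; 1 means constitutional).
#' @slot junctionsUsed DataFrame of the junctions consumed by the walk.
#' @slot cnSegments DataFrame of read-depth copy-number segments used to
#'   corroborate the structure (may have zero rows).
#' @slot annotations Character vector of free-text annotations (for
#'   example a breakpoint deletion at an inversion junction).
#' @export
setClass("DerivativeChromosome",
  representation(segments = "DataFrame",
                 circular = "logical",
                 motifLabel = "character",
                 mosaicFraction = "numeric",
                 junctionsUsed = "DataFrame",
                 cnSegments = "DataFrame",
                 annotations = "character"))

.MOTIF_LABELS <- c("DEL", "DUP", "INV", "DEL-INV-DUP", "DUP-TRP/INV-DUP",
                   "RING", "UNBALANCED_TRANSLOCATION", "COMPLEX",
                   "REFERENCE", "COMPLEX_UNRESOLVED")

setValidity("DerivativeChromosome", function(object) {
  if (!object@motifLabel %in% .MOTIF_LABELS)
    return(paste("unknown motif label:", object@motifLabel))
  if (nrow(object@segments) &&
      !all(object@segments$orientation %in% c("+", "-")))
    return("segment orientation must be '+' or '-'")
  TRUE
})

#' CohortSummary: aggregated cohort findings
#'
#' @slot nVariants Number of distinct variants.
#' @slot nIndividuals Number of distinct individuals with findings.
#' @slot cohortSize Cohort denominator for yields.
#' @slot byBestClass DataFrame of individual counts by best classification.
#' @slot byType DataFrame of per-variant-type tallies (both variant and
#'   individual views).
#' @slot yields Named numeric vector of percentage yields.
#' @export
setClass("CohortSummary",
  representation(nVariants = "integer",
                 nIndividuals = "integer",
                 cohortSize = "integer",
                 byBestClass = "DataFrame",
                 byType = "DataFrame",
                 yields = "numeric"))
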