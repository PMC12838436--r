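# Interpretation plumbing: gene-panel filtering of SVs, a local
# SV-frequency database over cohort junction calls, and cohort findings
# aggregation/reporting.

.CLASS_LEVELS <- c("P", "LP", "VUS_hot", "VUS", "LB", "B")

#' Read a gene panel from BED with a gene-symbol column
#'
#' @param path BED path (`chrom start end gene`).
#' @param panel_id Identifier attached to the panel.
#' @return list with `panel_id`, `genes` (character) and `regions`
#'   (data.frame chrom/start/end/gene, 0-based half-open).
#' @export
readPanelBed <- function(path, panel_id = basename(path)) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  colnames(bed)[1:4] <- c("chrom", "start", "end", "gene")
  list(panel_id = panel_id, genes = unique(bed$gene), regions = bed)
}

#' Affected span of a derivative
#'
#' Sum of |copy number - 2|-weighted copy-number segment lengths plus
#' the lengths of inverted derivative segments, so balanced inversions
#' are sized by what they invert rather than scoring zero.
#'
#' @param derivative A [DerivativeChromosome].
#' @return Span in bp.
#' @export
affectedSpan <- function(derivative) {
  cn <- as.data.frame(derivative@cnSegments)
  s <- as.data.frame(derivative@segments)
  cnspan <- if (nrow(cn))
    sum(abs(round(cn$copy_number) - 2) * (cn$end - cn$start)) else 0
  invspan <- if (nrow(s))
    sum((s$end - s$start)[s$orientation == "-"]) else 0
  cnspan + invspan
}

#' Two-tier SV triage: genome-wide above a size threshold, panel-based
#' below it
#'
#' A derivative is kept when its affected span reaches
#' `size_threshold`, when any breakpoint or segment intersects a panel
#' region (padded by `pad`), or when it involves more than two
#' breakpoints. Every dropped derivative is logged with the rule that
#' dropped it.
#'
#' @param derivatives List of [DerivativeChromosome] objects (named or
#'   not).
#' @param panel Panel from [readPanelBed()] (or a compatible list).
#' @param size_threshold Genome-wide tier threshold in bp (default
#'   10000).
#' @param pad Padding around panel regions in bp.
#' @return list(`kept` = sublist of derivatives, `kept_rules` =
#'   character vector of the rule that kept each, `drop_log` =
#'   data.frame id/reason).
#' @export
filterSvsByPanel <- function(derivatives, panel, size_threshold = 10000L,
                             pad = 2000L) {
  stopifnot(size_threshold > 0)
  ids <- names(derivatives)
  if (is.null(ids)) ids <- as.character(seq_along(derivatives))
  empty_panel <- is.null(panel) || nrow(panel$regions) == 0L
  kept <- list(); kept_rules <- character(0)
  drop <- data.frame(id = character(0), reason = character(0))
  warned <- FALSE
  for (k in seq_along(derivatives)) {
    d <- derivatives[[k]]
    ju <- as.data.frame(d@junctionsUsed)
    n_breakpoints <- 2L * nrow(ju)
    rule <- NULL
    if (affectedSpan(d) >= size_threshold) {
      rule <- "genome_wide_size"
    } else if (n_breakpoints > 2L) {
      rule <- "breakpoint_count"
    } else if (!empty_panel) {
      pts <- rbind(
        data.frame(chrom = ju$chrom_a, pos = ju$pos_a),
        data.frame(chrom = ju$chrom_b, pos = ju$pos_b))
      segs <- as.data.frame(d@segments)
      hit <- FALSE
      for (i in seq_len(nrow(panel$regions))) {
        rg <- panel$regions[i, ]
        if (any(pts$chrom == rg$chrom & pts$pos >= rg$start - pad &
                pts$pos < rg$end + pad)) { hit <- TRUE; break }
      }
      if (hit) rule <- "panel_intersect"
    } else if (empty_panel) {
      if (!warned) {
        warning("no panel regions supplied; sub-threshold SVs dropped",
                call. = FALSE)
        warned <- TRUE
      }
    }
    if (is.null(rule)) {
      drop <- rbind(drop, data.frame(
        id = ids[k],
        reason = if (empty_panel) "below_size_threshold_no_panel"
                 else "below_size_threshold_outside_panel"))
    } else {
      kept[[length(kept) + 1L]] <- d
      names(kept)[length(kept)] <- ids[k]
      kept_rules <- c(kept_rules, rule)
    }
  }
  list(kept = kept, kept_rules = kept_rules, drop_log = drop)
}

#' @noRd
.matchJunction <- function(j, entries, tolerance) {
  which(entries$chrom_a == j$chrom_a & entries$chrom_b == j$chrom_b &
        entries$ori_a == j$ori_a & entries$ori_b == j$ori_b &
        abs(entries$pos_a - j$pos_a) <= tolerance &
        abs(entries$pos_b - j$pos_b) <= tolerance)
}

#' Build a local SV-frequency database from cohort junction sets
#'
#' Junction signatures are merged across samples with the same
#' positional tolerance used for clustering, and each signature records
#' the set of samples carrying it.
#'
#' @param cohort_junction_sets Named list (sample id -> clustered
#'   junction data.frame).
#' @param tolerance Signature matching tolerance in bp (default 50, the
#'   clustering default).
#' @return list with `entries` (data.frame incl. `samples` list column,
#'   `n_samples_seen`, `frequency`) and `n_samples`.
#' @export
buildSvDb <- function(cohort_junction_sets, tolerance = 50L) {
  stopifnot(!is.null(names(cohort_junction_sets)))
  entries <- NULL
  samples <- list()
  for (sid in names(cohort_junction_sets)) {
    jn <- as.data.frame(cohort_junction_sets[[sid]])
    for (i in seq_len(nrow(jn))) {
      j <- jn[i, ]
      hit <- if (is.null(entries)) integer(0)
             else .matchJunction(j, entries, tolerance)
      if (length(hit)) {
        samples[[hit[1L]]] <- union(samples[[hit[1L]]], sid)
      } else {
        add <- j[, c("chrom_a", "pos_a", "ori_a", "chrom_b", "pos_b",
                     "ori_b")]
        entries <- rbind(entries, add)
        samples[[length(samples) + 1L]] <- sid
      }
    }
  }
  n <- length(cohort_junction_sets)
  if (is.null(entries)) {
    entries <- data.frame(chrom_a = character(0), pos_a = integer(0),
                          ori_a = character(0), chrom_b = character(0),
                          pos_b = integer(0), ori_b = character(0))
  }
  entries$n_samples_seen <- vapply(samples, length, integer(1))
  entries$frequency <- entries$n_samples_seen / n
  entries$samples <- samples
  rownames(entries) <- NULL
  list(entries = entries, n_samples = n)
}

#' Annotate junctions with database frequency
#'
#' @param junctions Clustered junction data.frame.
#' @param db Database from [buildSvDb()].
#' @param tolerance Matching tolerance (bp).
#' @return `junctions` with `db_frequency` and `db_samples` columns.
#' @export
annotateFrequency <- function(junctions, db, tolerance = 50L) {
  jn <- as.data.frame(junctions)
  jn$db_frequency <- 0
  jn$db_samples <- vector("list", nrow(jn))
  for (i in seq_len(nrow(jn))) {
    hit <- .matchJunction(jn[i, ], db$entries, tolerance)
    if (length(hit)) {
      jn$db_frequency[i] <- db$entries$frequency[hit[1L]]
      jn$db_samples[[i]] <- db$entries$samples[[hit[1L]]]
    }
  }
  jn
}

#' Keep junctions that are rare in the cohort database
#'
#' @param junctions Clustered junction data.frame.
#' @param db Database from [buildSvDb()].
#' @param max_frequency Junctions at or above this cohort frequency are
#'   filtered out unless seen only in `query_sample`.
#' @param query_sample Sample id of the query (its own db entry does not
#'   count against it).
#' @param tolerance Matching tolerance (bp).
#' @return The retained junction rows (with frequency annotation).
#' @export
filterUniqueJunctions <- function(junctions, db, max_frequency = 0.05,
                                  query_sample = NULL, tolerance = 50L) {
  ann <- annotateFrequency(junctions, db, tolerance)
  keep <- vapply(seq_len(nrow(ann)), function(i) {
    others <- setdiff(unlist(ann$db_samples[[i]]), query_sample)
    length(others) == 0L || ann$db_frequency[i] < max_frequency
  }, logical(1))
  ann[keep, , drop = FALSE]
}

#' Aggregate cohort findings
#'
#' Counts distinct variants and distinct individuals, assigns each
#' individual their best classification (P > LP > VUS_hot > VUS > LB >
#' B), computes percentage yields over the cohort size, and tallies per
#' variant type in both views (variants and individuals) since a
#' category breakdown can legitimately be read either way.
#'
#' @param findings data.frame in the [table2Fixture()] layout.
#' @param cohort_size Denominator for yields (>= number of distinct
#'   individuals).
#' @return A [CohortSummary].
#' @export
aggregateCohort <- function(findings, cohort_size) {
  findings <- as.data.frame(findings)
  bad <- setdiff(unique(findings$classification), .CLASS_LEVELS)
  if (length(bad))
    stop("unknown classification label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  # dedupe on (individual, variant)
  key <- paste(findings$individual_id, findings$variant_id)
  findings <- findings[!duplicated(key), , drop = FALSE]
  inds <- unique(findings$individual_id)
  if (cohort_size < length(inds))
    stop("cohort_size smaller than the number of individuals",
         call. = FALSE)
  rank <- match(findings$classification, .CLASS_LEVELS)
  best <- vapply(inds, function(id)
    .CLASS_LEVELS[min(rank[findings$individual_id == id])], character(1))
  bytab <- table(factor(best, levels = .CLASS_LEVELS))
  byBest <- data.frame(classification = names(bytab),
                       n_individuals = as.integer(bytab))
  types <- unique(findings$variant_type)
  byType <- do.call(rbind, lapply(types, function(tp) {
    sel <- findings$variant_type == tp
    data.frame(variant_type = tp, n_variants = sum(sel),
               n_individuals = length(unique(findings$individual_id[sel])))
  }))
  if (is.null(byType))
    byType <- data.frame(variant_type = character(0),
                         n_variants = integer(0),
                         n_individuals = integer(0))
  n_plp <- sum(best %in% c("P", "LP"))
  n_hot <- sum(best == "VUS_hot")
  yields <- c(
    diagnostic_yield_P_LP = 100 * n_plp / cohort_size,
    hot_VUS_yield = 100 * n_hot / cohort_size,
    any_finding_yield = 100 * length(inds) / cohort_size)
  new("CohortSummary",
      nVariants = nrow(findings),
      nIndividuals = length(inds),
      cohortSize = as.integer(cohort_size),
      byBestClass = S4Vectors::DataFrame(byBest),
      byType = S4Vectors::DataFrame(byType),
      yields = yields)
}

#' Render a deterministic findings report
#'
#' The clinical section lists reported findings only; non-reported (NR)
#' records are excluded there but retained in the audit section. Two
#' identical inputs render byte-identical reports.
#'
#' @param summary A [CohortSummary].
#' @param findings The findings data.frame the summary was built from.
#' @param path Optional file to write the text report to; a TSV of the
#'   clinical section is written next to it as `<path>.tsv`.
#' @return Character vector of report lines, invisibly when `path` is
#'   given.
#' @export
renderReport <- function(summary, findings, path = NULL) {
  findings <- as.data.frame(findings)
  o <- order(findings$individual_id, findings$variant_id)
  findings <- findings[o, , drop = FALSE]
  clin <- findings[findings$reported, , drop = FALSE]
  audit <- findings
  fmt_row <- function(r) sprintf("  %-12s %-28s %-10s %-8s %s",
    r$individual_id, r$variant_id, r$variant_type, r$classification,
    r$added_value_note)
  lines <- c(
    "== Cohort findings report ==",
    sprintf("Variants: %d | Individuals: %d | Cohort size: %d",
            summary@nVariants, summary@nIndividuals, summary@cohortSize),
    sprintf("Diagnostic yield (P/LP): %.1f%% | hot VUS: %.1f%%",
            summary@yields[["diagnostic_yield_P_LP"]],
            summary@yields[["hot_VUS_yield"]]),
    "",
    "-- Variant type tallies --",
    vapply(seq_len(nrow(summary@byType)), function(i)
      sprintf("  %-10s %3d variants %3d individuals",
              summary@byType$variant_type[i],
              summary@byType$n_variants[i],
              summary@byType$n_individuals[i]), character(1)),
    "",
    sprintf("-- Clinical section (%d reported findings) --", nrow(clin)),
    vapply(seq_len(nrow(clin)), function(i) fmt_row(clin[i, ]),
           character(1)),
    "",
    sprintf("-- Audit section (%d findings incl. non-reported) --",
            nrow(audit)),
    vapply(seq_len(nrow(audit)), function(i) fmt_row(audit[i, ]),
           character(1)))
  if (!is.null(path)) {
    writeLines(lines, path)
    utils::write.table(clin, paste0(path, ".tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    return(invisible(lines))
  }
  lines
}
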