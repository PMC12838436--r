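# STR expansion profiling: per-read repeat counting at catalog loci,
# interruption-motif detection, haplotype-resolved sizing and
# classification against locus thresholds.
#
# Counting is anchor-based greedy tiling: locate the two flank anchors
# in the read, then tile the tract left-to-right with the canonical
# motif. The method is deterministic and verifiable against an
# exhaustive window-by-window oracle, which is all that is needed at
# per-locus scale; no HMM is involved.

#' Default STR locus catalog
#'
#' A configurable catalog with FMR1-like (CGG; thresholds 44/54/200
#' units) and ATXN1-like (CAG with CAT interruptions; thresholds
#' 35/44/48 units) entries. Coordinates refer to the synthetic reference
#' used in examples and tests; load a real catalog with
#' [readStrCatalog()] for other references.
#'
#' @param fmr1_start,atxn1_start 0-based tract starts on chr1 used when
#'   building synthetic references around these loci.
#' @param fmr1_units,atxn1_units Reference repeat counts (tract length =
#'   units * motif length).
#' @param flank_len Anchor length in bp.
#' @return data.frame with one row per locus: `locus_id`, `gene`,
#'   `chrom`, `start`, `end` (0-based half-open), `motif`, `normal_max`,
#'   `intermediate_max`, `premutation_max`, `flank_len`.
#' @export
defaultStrCatalog <- function(fmr1_start = 4000L, atxn1_start = 4000L,
                              fmr1_units = 20L, atxn1_units = 20L,
                              flank_len = 30L) {
  data.frame(
    locus_id = c("FMR1_CGG", "ATXN1_CAG"),
    gene = c("FMR1", "ATXN1"),
    chrom = c("chr1", "chr1"),
    start = c(fmr1_start, atxn1_start),
    end = c(fmr1_start + 3L * fmr1_units, atxn1_start + 3L * atxn1_units),
    motif = c("CGG", "CAG"),
    normal_max = c(44, 35),
    intermediate_max = c(54, 44),
    premutation_max = c(200, 48),
    flank_len = flank_len,
    stringsAsFactors = FALSE)
}

#' Read an STR catalog from BED + JSON sidecar
#'
#' The BED carries `chrom start end locus_id`; the JSON sidecar is a map
#' from locus_id to `gene`, `motif`, `thresholds` (normal_max,
#' intermediate_max, premutation_max) and `flank_len`.
#'
#' @param bed_path,json_path Paths to the two files.
#' @return Catalog data.frame as in [defaultStrCatalog()].
#' @export
readStrCatalog <- function(bed_path, json_path) {
  bed <- utils::read.table(bed_path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  colnames(bed)[1:4] <- c("chrom", "start", "end", "locus_id")
  side <- jsonlite::read_json(json_path)
  rows <- lapply(seq_len(nrow(bed)), function(i) {
    id <- bed$locus_id[i]
    s <- side[[id]]
    if (is.null(s)) stop("locus missing from JSON sidecar: ", id,
                         call. = FALSE)
    data.frame(locus_id = id, gene = s$gene, chrom = bed$chrom[i],
               start = bed$start[i], end = bed$end[i], motif = s$motif,
               normal_max = s$thresholds[[1]],
               intermediate_max = s$thresholds[[2]],
               premutation_max = s$thresholds[[3]],
               flank_len = if (is.null(s$flank_len)) 30L else s$flank_len,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write an STR catalog as BED + JSON sidecar
#' @param catalog Catalog data.frame.
#' @param bed_path,json_path Output paths.
#' @export
writeStrCatalog <- function(catalog, bed_path, json_path) {
  utils::write.table(catalog[, c("chrom", "start", "end", "locus_id")],
                     bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  side <- lapply(seq_len(nrow(catalog)), function(i)
    list(gene = catalog$gene[i], motif = catalog$motif[i],
         thresholds = c(catalog$normal_max[i], catalog$intermediate_max[i],
                        catalog$premutation_max[i]),
         flank_len = catalog$flank_len[i]))
  names(side) <- catalog$locus_id
  jsonlite::write_json(side, json_path, auto_unbox = TRUE)
  invisible(NULL)
}

#' Tile a repeat tract with the canonical motif
#'
#' Greedy left-to-right tiling. A window with at most `max_unit_mismatch`
#' mismatches to the canonical motif counts as a canonical unit; any
#' other full-length window is recorded as an interruption with its
#' observed motif. Both kinds count toward the total, so
#' `repeat_count = canonical + interrupting` units. A trailing partial
#' unit is floored (dropped).
#'
#' @param tract Tract sequence between the flank anchors.
#' @param motif Canonical repeat unit (reference strand).
#' @param max_unit_mismatch Mismatch budget per unit for a window to
#'   still count as canonical (default 0, so single-base interruption
#'   motifs such as AGG within CGG or CAT within CAG are reported).
#' @return list with `repeat_count`, `interruptions` (data.frame of
#'   0-based `unit_index` and `observed_motif`).
#' @export
tileTract <- function(tract, motif, max_unit_mismatch = 0L) {
  k <- nchar(motif)
  stopifnot(k >= 1L)
  n <- nchar(tract)
  count <- 0L
  idx <- integer(0); obs <- character(0)
  i <- 1L
  while (i + k - 1L <= n) {
    w <- substr(tract, i, i + k - 1L)
    if (strMismatch(w, motif) > max_unit_mismatch) {
      idx <- c(idx, count)
      obs <- c(obs, w)
    }
    count <- count + 1L
    i <- i + k
  }
  list(repeat_count = count,
       interruptions = data.frame(unit_index = idx, observed_motif = obs,
                                  stringsAsFactors = FALSE))
}

#' @noRd
.locusFlanks <- function(locus, reference) {
  ci <- match(locus$chrom, names(reference))
  if (is.na(ci)) stop("locus chrom not in reference", call. = FALSE)
  fl <- locus$flank_len
  left <- as.character(Biostrings::subseq(reference[[ci]],
                                          locus$start - fl + 1L, locus$start))
  right <- as.character(Biostrings::subseq(reference[[ci]],
                                           locus$end + 1L, locus$end + fl))
  list(left = left, right = right)
}

#' @noRd
.findAnchor <- function(subject, pattern, flank_len) {
  budget <- floor(flank_len / 8)
  m <- Biostrings::matchPattern(pattern, subject, max.mismatch = budget,
                                with.indels = TRUE)
  m
}

#' Count repeats in one read at a catalog locus
#'
#' Locates both flank anchors in the (reference-oriented) read sequence
#' -- exact first, then fuzzy at one mismatch/indel per 8 bp of anchor --
#' and tiles the tract between them with [tileTract()]. Reads that do
#' not span both anchors yield a non-spanning condition.
#'
#' @param read A one-row slice of `alignments(x)`, or a list with `seq`
#'   and `strand` (sequence in SAM/reference orientation) or a raw
#'   read-orientation string plus `strand = "-"` to request
#'   reverse-complementing.
#' @param locus One catalog row.
#' @param reference DNAStringSet providing the flank sequences.
#' @param max_unit_mismatch Passed to [tileTract()].
#' @return list(`read_id`, `repeat_count`, `interruptions`, `haplotype`,
#'   `tract_sequence`) or a condition of class `lorediag_nonspanning`.
#' @export
countRepeatsInRead <- function(read, locus, reference,
                               max_unit_mismatch = 0L) {
  if (is.character(read)) {
    sq <- read
  } else if (is(read, "DataFrame") || is.data.frame(read)) {
    # stored sequences follow the SAM convention and are already
    # reference-oriented; no reverse-complement needed
    sq <- as.character(read$seq)
  } else {
    # plain list: sequence in read orientation, reverse-complement
    # reverse-strand reads before tiling
    sq <- read$seq
    if (identical(read$strand, "-")) sq <- revcompStr(sq)
  }
  fl <- .locusFlanks(locus, reference)
  subject <- Biostrings::DNAString(sq)
  ml <- .findAnchor(subject, fl$left, locus$flank_len)
  mr <- .findAnchor(subject, fl$right, locus$flank_len)
  if (length(ml) == 0L || length(mr) == 0L) {
    cond <- structure(class = c("lorediag_nonspanning", "condition"),
                      list(message = "read does not span both anchors",
                           call = sys.call()))
    return(cond)
  }
  le <- max(BiocGenerics::end(ml))
  rs <- BiocGenerics::start(mr)
  rs <- min(rs[rs > le], Inf)
  if (!is.finite(rs)) {
    cond <- structure(class = c("lorediag_nonspanning", "condition"),
                      list(message = "anchors out of order in read",
                           call = sys.call()))
    return(cond)
  }
  tract <- if (rs - 1L >= le + 1L) substr(sq, le + 1L, rs - 1L) else ""
  tl <- tileTract(tract, locus$motif, max_unit_mismatch)
  hp <- if (!is.character(read) && !is.null(read$hp)) read$hp else NA_integer_
  list(read_id = if (!is.character(read) && !is.null(read$read_id))
         as.character(read$read_id) else NA_character_,
       repeat_count = tl$repeat_count,
       interruptions = tl$interruptions,
       haplotype = as.integer(hp),
       tract_sequence = tract)
}

# exact 1-D two-cluster split minimising within-cluster sum of squares;
# deterministic scan over the sorted order
#' @noRd
.twoClusterSplit <- function(x) {
  o <- order(x)
  xs <- x[o]
  n <- length(xs)
  best <- NULL; best_ss <- Inf
  for (cut in 1:(n - 1L)) {
    a <- xs[1:cut]; b <- xs[(cut + 1L):n]
    ss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (ss < best_ss - 1e-12) { best_ss <- ss; best <- cut }
  }
  grp <- integer(n)
  grp[o] <- rep(c(1L, 2L), c(best, n - best))
  grp
}

#' Profile a locus from spanning reads
#'
#' Applies [countRepeatsInRead()] to every primary alignment, groups the
#' spanning calls by haplotype (HP tags, an explicit assignment vector,
#' or -- failing both -- an unsupervised two-cluster split accepted only
#' when the two cluster medians differ by more than max(2 units, 10%)),
#' and summarises per-haplotype median/min/max with an expansion
#' classification.
#'
#' @param x A [LongReadSet] (or a DataFrame of alignment rows).
#' @param locus One catalog row.
#' @param reference DNAStringSet.
#' @param haplotype_assignments Optional named vector read_id -> 1/2
#'   overriding HP tags.
#' @param min_spanning_reads Minimum spanning calls for a profile
#'   (default 3); fewer yields a no-call profile, not an error.
#' @param max_unit_mismatch Passed to the per-read counter.
#' @param promoter_methylation Optional numeric in [0,1] to attach (see
#'   [strPromoterStatus()]).
#' @return A [StrProfile].
#' @export
profileLocus <- function(x, locus, reference, haplotype_assignments = NULL,
                         min_spanning_reads = 3L, max_unit_mismatch = 0L,
                         promoter_methylation = NA_real_) {
  a <- if (is(x, "LongReadSet")) x@alignments else x
  prim <- a[!a$supplementary, , drop = FALSE]
  calls <- list()
  for (i in seq_len(nrow(prim))) {
    res <- countRepeatsInRead(prim[i, ], locus, reference,
                              max_unit_mismatch)
    if (inherits(res, "lorediag_nonspanning")) next
    calls[[length(calls) + 1L]] <- res
  }
  cl <- S4Vectors::DataFrame(
    read_id = vapply(calls, `[[`, character(1), "read_id"),
    repeat_count = vapply(calls, `[[`, integer(1), "repeat_count"),
    haplotype = vapply(calls, `[[`, integer(1), "haplotype"),
    tract_sequence = vapply(calls, `[[`, character(1), "tract_sequence"))
  cl$interruptions <- lapply(calls, `[[`, "interruptions")
  if (!is.null(haplotype_assignments) && nrow(cl))
    cl$haplotype <- as.integer(haplotype_assignments[cl$read_id])

  locdf <- S4Vectors::DataFrame(locus)
  nocall <- function() new("StrProfile", locus = locdf, readCalls = cl,
    summary = S4Vectors::DataFrame(haplotype = character(0),
      n_reads = integer(0), median = numeric(0), min = numeric(0),
      max = numeric(0), classification = character(0)),
    overallMedian = NA_real_, promoterMethylation = promoter_methylation)
  if (nrow(cl) < min_spanning_reads) return(nocall())
  counts <- cl$repeat_count
  grp <- as.character(cl$haplotype)
  if (all(is.na(cl$haplotype))) {
    if (length(counts) >= 4L) {
      g <- .twoClusterSplit(counts)
      m1 <- stats::median(counts[g == 1L]); m2 <- stats::median(counts[g == 2L])
      if (abs(m1 - m2) > max(2, 0.1 * max(m1, m2))) {
        grp <- as.character(g)
      } else grp <- rep("pooled", length(counts))
    } else grp <- rep("pooled", length(counts))
  } else {
    grp[is.na(grp)] <- "unassigned"
  }
  sm <- do.call(rbind, lapply(sort(unique(grp)), function(g) {
    v <- counts[grp == g]
    data.frame(haplotype = g, n_reads = length(v),
               median = stats::median(v), min = min(v), max = max(v),
               stringsAsFactors = FALSE)
  }))
  sm$classification <- vapply(sm$median, function(m)
    classifyExpansion(m, locus), character(1))
  new("StrProfile", locus = locdf, readCalls = cl,
      summary = S4Vectors::DataFrame(sm),
      overallMedian = stats::median(counts),
      promoterMethylation = promoter_methylation)
}

#' Classify a repeat size against locus thresholds
#'
#' Boundaries are inclusive on the lower class: a median exactly equal
#' to `normal_max` is normal; anything above `premutation_max` is a full
#' mutation.
#'
#' @param x A [StrProfile] (classifies every haplotype median) or a
#'   single numeric median.
#' @param locus Catalog row supplying the thresholds (required for the
#'   numeric form).
#' @return Character classification(s) in
#'   {normal, intermediate, premutation, full}.
#' @export
classifyExpansion <- function(x, locus = NULL) {
  if (is(x, "StrProfile")) {
    loc <- as.data.frame(x@locus)
    return(vapply(x@summary$median, classifyExpansion, character(1),
                  locus = loc))
  }
  if (is.null(locus)) stop("locus thresholds required", call. = FALSE)
  th <- c(locus$normal_max, locus$intermediate_max, locus$premutation_max)
  if (any(is.na(th)))
    stop("catalog is missing thresholds for locus ", locus$locus_id,
         call. = FALSE)
  if (x <= th[1]) "normal"
  else if (x <= th[2]) "intermediate"
  else if (x <= th[3]) "premutation"
  else "full"
}
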