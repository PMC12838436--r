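# Structural-variant reconstruction from split reads.
#
# Breakpoint junctions are extracted from supplementary-alignment
# chains, clustered, corroborated by binned read-depth copy number, and
# assembled into derivative chromosomes by a greedy reference walk.
# Junction ends are encoded by the retained flank: orientation "+"
# means the derivative keeps reference bases at coordinates <= pos
# (pos is the 0-based exclusive end of the retained segment);
# orientation "-" means it keeps bases >= pos (pos is the 0-based first
# retained base). This avoids the ambiguity of bracketed breakend
# strings; an export to VCF breakend notation is provided.

#' Extract raw junctions from split alignments
#'
#' Walks each read's alignment chain in read order and emits one
#' junction per adjacent alignment pair. Soft-clips of at least
#' `min_clip` bp without a partner alignment are counted but not
#' emitted.
#'
#' @param x A [LongReadSet].
#' @param min_clip Minimum unmatched soft-clip worth logging (bp).
#' @param min_mapq Alignments below this MAPQ are ignored.
#' @return data.frame of raw junctions (`chrom_a`, `pos_a`, `ori_a`,
#'   `chrom_b`, `pos_b`, `ori_b`, `read_id`, `inserted_seq`), ends in
#'   canonical (lexicographic) order. The number of unmatched clipped
#'   reads is attached as attribute `n_clipped_only`.
#' @export
extractJunctions <- function(x, min_clip = 20L, min_mapq = 0L) {
  a <- x@alignments
  a <- a[a$mapq >= min_mapq, , drop = FALSE]
  out <- list()
  n_clipped_only <- 0L
  for (ii in split(seq_len(nrow(a)), a$read_id)) {
    if (length(ii) < 2L) {
      if (length(ii) == 1L) {
        cl <- cigarClips(a$cigar[ii])
        if (max(cl) >= min_clip) n_clipped_only <- n_clipped_only + 1L
      }
      next
    }
    ii <- ii[order(a$qstart[ii])]
    for (k in seq_len(length(ii) - 1L)) {
      i1 <- ii[k]; i2 <- ii[k + 1L]
      rl1 <- cigarRefLength(a$cigar[i1])
      rl2 <- cigarRefLength(a$cigar[i2])
      # departing end of the first alignment (in read direction)
      if (a$strand[i1] == "+") {
        ea <- list(chrom = a$chrom[i1], pos = a$pos[i1] - 1L + rl1,
                   ori = "+")
      } else {
        ea <- list(chrom = a$chrom[i1], pos = a$pos[i1] - 1L, ori = "-")
      }
      # arriving end of the second alignment
      if (a$strand[i2] == "+") {
        eb <- list(chrom = a$chrom[i2], pos = a$pos[i2] - 1L, ori = "-")
      } else {
        eb <- list(chrom = a$chrom[i2], pos = a$pos[i2] - 1L + rl2,
                   ori = "+")
      }
      gap <- a$qstart[i2] - a$qend[i1] - 1L
      ins <- ""
      if (gap > 0L) {
        orig <- if (a$strand[i1] == "+") a$seq[i1]
                else revcompStr(a$seq[i1])
        ins <- substr(orig, a$qend[i1] + 1L, a$qstart[i2] - 1L)
      }
      # canonical ordering of the two ends
      if (ea$chrom > eb$chrom ||
          (ea$chrom == eb$chrom && ea$pos > eb$pos)) {
        tmp <- ea; ea <- eb; eb <- tmp
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom_a = ea$chrom, pos_a = ea$pos, ori_a = ea$ori,
        chrom_b = eb$chrom, pos_b = eb$pos, ori_b = eb$ori,
        read_id = a$read_id[i1], inserted_seq = ins,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(chrom_a = character(0), pos_a = integer(0),
                         ori_a = character(0), chrom_b = character(0),
                         pos_b = integer(0), ori_b = character(0),
                         read_id = character(0),
                         inserted_seq = character(0))
  attr(res, "n_clipped_only") <- n_clipped_only
  res
}

#' Cluster raw junctions
#'
#' Raw junctions with compatible orientations whose two ends fall within
#' `pos_tolerance` merge (single linkage per end); the cluster position
#' is the per-end median and the support is the union of read ids.
#' Clusters below `min_support` are dropped but counted.
#'
#' @param raw Output of [extractJunctions()].
#' @param pos_tolerance Maximum per-end distance for merging (bp).
#' @param min_support Minimum distinct supporting reads (default 3).
#' @return data.frame of clustered junctions with `support` (distinct
#'   read count) and `support_reads` (list column); dropped-cluster
#'   count in attribute `n_dropped`.
#' @export
clusterJunctions <- function(raw, pos_tolerance = 50L, min_support = 3L) {
  stopifnot(pos_tolerance >= 0)
  key <- paste(raw$chrom_a, raw$chrom_b, raw$ori_a, raw$ori_b)
  out <- list(); dropped <- 0L
  for (g in split(seq_len(nrow(raw)), key)) {
    sub <- raw[g, , drop = FALSE]
    o <- order(sub$pos_a, sub$pos_b)
    sub <- sub[o, , drop = FALSE]
    grp <- cumsum(c(1L, diff(sub$pos_a) > pos_tolerance))
    for (gg in split(seq_len(nrow(sub)), grp)) {
      s2 <- sub[gg, , drop = FALSE]
      o2 <- order(s2$pos_b)
      s2 <- s2[o2, , drop = FALSE]
      grp2 <- cumsum(c(1L, diff(s2$pos_b) > pos_tolerance))
      for (g3 in split(seq_len(nrow(s2)), grp2)) {
        s3 <- s2[g3, , drop = FALSE]
        reads <- unique(s3$read_id)
        if (length(reads) < min_support) { dropped <- dropped + 1L; next }
        ins <- s3$inserted_seq[nzchar(s3$inserted_seq)]
        out[[length(out) + 1L]] <- data.frame(
          chrom_a = s3$chrom_a[1L],
          pos_a = as.integer(round(stats::median(s3$pos_a))),
          ori_a = s3$ori_a[1L],
          chrom_b = s3$chrom_b[1L],
          pos_b = as.integer(round(stats::median(s3$pos_b))),
          ori_b = s3$ori_b[1L],
          support = length(reads),
          inserted_seq = if (length(ins)) ins[[1L]] else "",
          stringsAsFactors = FALSE)
        out[[length(out)]]$support_reads <- list(reads)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(chrom_a = character(0), pos_a = integer(0),
                         ori_a = character(0), chrom_b = character(0),
                         pos_b = integer(0), ori_b = character(0),
                         support = integer(0), inserted_seq = character(0))
  attr(res, "n_dropped") <- dropped
  res
}

#' Binned read-depth copy number
#'
#' Per-bin depth (aligned reference bases per position) normalised to
#' the genome median and doubled gives the copy-number estimate;
#' adjacent bins within 0.35 copies of the running segment mean merge
#' into segments.
#'
#' @param x A [LongReadSet].
#' @param bin_size Bin width in bp (>= 100).
#' @return data.frame of segments: `chrom`, `start`, `end` (0-based
#'   half-open), `copy_number`, `n_bins`.
#' @importFrom IRanges IRanges coverage
#' @export
segmentCopyNumber <- function(x, bin_size = 1000L) {
  stopifnot(bin_size >= 100L)
  a <- x@alignments
  bins <- list()
  for (ch in names(x@seqlengths)) {
    len <- x@seqlengths[[ch]]
    rows <- a$chrom == ch
    if (any(rows)) {
      st <- a$pos[rows]
      wd <- vapply(a$cigar[rows], cigarRefLength, numeric(1))
      cov <- IRanges::coverage(IRanges::IRanges(start = st, width = wd),
                               width = len)
    } else cov <- S4Vectors::Rle(0L, len)
    nb <- ceiling(len / bin_size)
    starts <- (seq_len(nb) - 1L) * bin_size
    ends <- pmin(len, starts + bin_size)
    v <- as.numeric(cov)
    depth <- vapply(seq_len(nb), function(i)
      mean(v[(starts[i] + 1L):ends[i]]), numeric(1))
    bins[[ch]] <- data.frame(chrom = ch, start = starts, end = ends,
                             depth = depth, stringsAsFactors = FALSE)
  }
  bdf <- do.call(rbind, bins)
  med <- stats::median(bdf$depth)
  if (med <= 0) stop("zero-depth genome: cannot normalise copy number",
                     call. = FALSE)
  bdf$cn <- 2 * bdf$depth / med
  # greedy merge
  segs <- list()
  cur <- NULL
  flush <- function(cur) data.frame(chrom = cur$chrom, start = cur$start,
                                    end = cur$end,
                                    copy_number = cur$sum / cur$n,
                                    n_bins = cur$n)
  for (i in seq_len(nrow(bdf))) {
    if (!is.null(cur) && bdf$chrom[i] == cur$chrom &&
        abs(bdf$cn[i] - cur$sum / cur$n) <= 0.35) {
      cur$end <- bdf$end[i]; cur$sum <- cur$sum + bdf$cn[i]
      cur$n <- cur$n + 1L
    } else {
      if (!is.null(cur)) segs[[length(segs) + 1L]] <- flush(cur)
      cur <- list(chrom = bdf$chrom[i], start = bdf$start[i],
                  end = bdf$end[i], sum = bdf$cn[i], n = 1L)
    }
  }
  if (!is.null(cur)) segs[[length(segs) + 1L]] <- flush(cur)
  do.call(rbind, segs)
}

#' Count reads spanning a breakpoint
#'
#' Distinct reads with any alignment overlapping `pos` within `window`
#' bp -- this includes the junction-supporting reads themselves, giving
#' the denominator of the mosaic-fraction estimator.
#'
#' @param x A [LongReadSet].
#' @param chrom,pos Breakpoint (0-based).
#' @param window Overlap window in bp.
#' @export
countSpanningReads <- function(x, chrom, pos, window = 10L) {
  a <- x@alignments
  st <- a$pos - 1L
  en <- st + vapply(a$cigar, cigarRefLength, numeric(1))
  hit <- a$chrom == chrom & st < pos + window & en > pos - window
  length(unique(a$read_id[hit]))
}

#' Mosaic cell-fraction estimate from junction reads
#'
#' Under the model that the derivative replaces one of the two homologs
#' in carrier cells, the expected fraction of junction-supporting reads
#' among reads spanning the breakpoint is cell_fraction / 2, so the
#' estimator doubles the observed fraction (capped at 1). The percent
#' is truncated, not rounded, to an integer; the raw fraction is also
#' returned.
#'
#' @param support Number of junction-supporting reads.
#' @param spanning_read_count Total reads spanning the breakpoint
#'   (including the supporting ones).
#' @return list(`fraction`, `percent`); both NA when
#'   `spanning_read_count` is zero (no-call).
#' @examples
#' estimateMosaicFraction(6, 28)$percent   # 42
#' @export
estimateMosaicFraction <- function(support, spanning_read_count) {
  if (spanning_read_count == 0L)
    return(list(fraction = NA_real_, percent = NA_integer_))
  stopifnot(support >= 0, support <= spanning_read_count)
  f <- min(1, 2 * support / spanning_read_count)
  list(fraction = f, percent = as.integer(floor(100 * f)))
}

# candidate junction ends reachable from (chrom, pos) heading dir
#' @noRd
.nextJunction <- function(jn, used, chrom, pos, dir, strict) {
  cand <- list()
  for (i in seq_len(nrow(jn))) {
    if (used[i] <= 0L) next
    for (side in c("a", "b")) {
      ch <- jn[[paste0("chrom_", side)]][i]
      p <- jn[[paste0("pos_", side)]][i]
      o <- jn[[paste0("ori_", side)]][i]
      if (ch != chrom) next
      if (dir > 0 && o == "+" &&
          (p > pos || (!strict && p >= pos)))
        cand[[length(cand) + 1L]] <- list(i = i, side = side, pos = p,
                                          dist = p - pos)
      if (dir < 0 && o == "-" &&
          (p < pos || (!strict && p <= pos)))
        cand[[length(cand) + 1L]] <- list(i = i, side = side, pos = p,
                                          dist = pos - p)
    }
  }
  if (length(cand) == 0L) return(NULL)
  d <- vapply(cand, `[[`, numeric(1), "dist")
  sup <- vapply(cand, function(cc) jn$support[cc$i], numeric(1))
  partner <- vapply(cand, function(cc) {
    other <- if (cc$side == "a") "b" else "a"
    paste0(jn[[paste0("chrom_", other)]][cc$i], ":",
           jn[[paste0("pos_", other)]][cc$i])
  }, character(1))
  # nearest first; ties by higher support, then lexicographic partner
  o <- order(d, -sup, partner)
  cand[[o[1L]]]
}

#' Assemble a derivative chromosome from junctions
#'
#' Greedy walk: starting from `start_anchor`, travel along the reference
#' until an unused junction end facing the walk is reached, jump to its
#' partner (flipping direction as the partner's orientation dictates)
#' and continue; the walk terminates at a chromosome end or when it
#' re-enters its starting state (a ring, `circular = TRUE`). Each
#' junction is consumed once per traversal. Walks exceeding
#' `max_segments` return a complex-unresolved derivative rather than an
#' error.
#'
#' @param junctions Clustered junction data.frame
#'   ([clusterJunctions()]).
#' @param cn_segments Optional copy-number segments
#'   ([segmentCopyNumber()]) stored for corroboration/classification.
#' @param start_anchor list(`chrom`, `pos` (0-based), `dir` (+1 to walk
#'   toward higher coordinates, -1 toward lower)).
#' @param seqlengths Named reference lengths (for telomere
#'   termination); defaults to an attribute lookup or the maximum
#'   junction position.
#' @param reads Optional [LongReadSet] used to estimate the mosaic
#'   fraction at each junction via [estimateMosaicFraction()].
#' @param max_segments Walk-length guard (default 50).
#' @param max_uses How many times one junction may be traversed.
#' @return A [DerivativeChromosome]; classify with
#'   [classifyRearrangement()].
#' @export
buildDerivative <- function(junctions, cn_segments = NULL, start_anchor,
                            seqlengths = NULL, reads = NULL,
                            max_segments = 50L, max_uses = 1L) {
  jn <- as.data.frame(junctions)
  if (is.null(seqlengths)) {
    if (!is.null(reads)) seqlengths <- reads@seqlengths
    else stop("seqlengths required when no reads are given", call. = FALSE)
  }
  if (is.null(jn$support)) jn$support <- 1L
  used <- rep(as.integer(max_uses), nrow(jn))
  chrom <- start_anchor$chrom
  pos <- start_anchor$pos
  dir <- start_anchor$dir
  init <- c(chrom, pos, dir)
  segs <- list(); jused <- integer(0)
  circular <- FALSE; unresolved <- FALSE
  strict <- FALSE   # first hop may take a junction at the anchor itself
  repeat {
    if (length(segs) >= max_segments) { unresolved <- TRUE; break }
    nx <- .nextJunction(jn, used, chrom, pos, dir, strict)
    strict <- TRUE
    if (is.null(nx)) {
      # run to the telomere
      endpos <- if (dir > 0) unname(seqlengths[[chrom]]) else 0L
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = chrom, start = min(pos, endpos), end = max(pos, endpos),
        orientation = if (dir > 0) "+" else "-",
        stringsAsFactors = FALSE)
      break
    }
    segs[[length(segs) + 1L]] <- data.frame(
      chrom = chrom, start = min(pos, nx$pos), end = max(pos, nx$pos),
      orientation = if (dir > 0) "+" else "-", stringsAsFactors = FALSE)
    used[nx$i] <- used[nx$i] - 1L
    jused <- c(jused, nx$i)
    other <- if (nx$side == "a") "b" else "a"
    chrom <- jn[[paste0("chrom_", other)]][nx$i]
    pos <- jn[[paste0("pos_", other)]][nx$i]
    # partner "+" retains the left flank: continue walking downward;
    # partner "-" retains the right flank: continue upward
    dir <- if (jn[[paste0("ori_", other)]][nx$i] == "+") -1L else 1L
    if (identical(c(chrom, pos, dir), init)) { circular <- TRUE; break }
  }
  segdf <- if (length(segs)) do.call(rbind, segs)
           else data.frame(chrom = character(0), start = integer(0),
                           end = integer(0), orientation = character(0))
  ju <- jn[unique(jused), , drop = FALSE]
  mosaic <- NA_real_
  if (!is.null(reads) && nrow(ju)) {
    est <- vapply(seq_len(nrow(ju)), function(i) {
      sp <- countSpanningReads(reads, ju$chrom_a[i], ju$pos_a[i])
      e <- estimateMosaicFraction(min(ju$support[i], sp), sp)
      if (is.na(e$fraction)) NA_real_ else e$fraction
    }, numeric(1))
    ju$mosaic_fraction <- est
    ju$mosaic_percent <- as.integer(floor(100 * est))
    mosaic <- est[which.max(ju$support)]
  }
  label <- if (unresolved) "COMPLEX_UNRESOLVED"
           else if (nrow(ju) == 0L) "REFERENCE"
           else "COMPLEX"          # refined by classifyRearrangement()
  der <- new("DerivativeChromosome",
             segments = S4Vectors::DataFrame(segdf),
             circular = circular, motifLabel = label,
             mosaicFraction = mosaic,
             junctionsUsed = S4Vectors::DataFrame(ju),
             cnSegments = S4Vectors::DataFrame(
               if (is.null(cn_segments))
                 data.frame(chrom = character(0), start = integer(0),
                            end = integer(0), copy_number = numeric(0),
                            n_bins = integer(0))
               else as.data.frame(cn_segments)),
             annotations = character(0))
  if (!unresolved) der <- classifyRearrangement(der)
  der
}

#' Classify a derivative's rearrangement motif
#'
#' Pattern matching on the junction orientations, the chromosomes
#' involved and the copy-number profile: a single (+,-) junction with a
#' loss is a deletion; (-,+) with a gain a tandem duplication; a
#' matched (+,+)/(-,-) junction pair with neutral copy number an
#' inversion (a gap between the paired breakpoints with a loss is
#' annotated as a breakpoint deletion); a like-oriented junction next
#' to a terminal loss plus adjacent gain is DEL-INV-DUP; gains reaching
#' triplication beside a duplication with an inverted junction is
#' DUP-TRP/INV-DUP; a circular walk is a RING; one junction bridging
#' two chromosomes is an unbalanced translocation; anything else is
#' COMPLEX.
#'
#' @param derivative A [DerivativeChromosome].
#' @param cn_segments Optional copy-number segments overriding the ones
#'   stored in the derivative.
#' @param cn_window Only copy-number segments within this distance of a
#'   junction end corroborate the motif; distant depth fluctuations
#'   (long-read depth is bursty) are ignored.
#' @return The derivative with `motifLabel` (and possibly annotations)
#'   updated.
#' @export
classifyRearrangement <- function(derivative, cn_segments = NULL,
                                  cn_window = 10000L) {
  cn <- if (!is.null(cn_segments)) as.data.frame(cn_segments)
        else as.data.frame(derivative@cnSegments)
  ju <- as.data.frame(derivative@junctionsUsed)
  ann <- derivative@annotations
  if (nrow(cn) && nrow(ju)) {
    near <- vapply(seq_len(nrow(cn)), function(i) {
      any((ju$chrom_a == cn$chrom[i] &
           ju$pos_a >= cn$start[i] - cn_window &
           ju$pos_a <= cn$end[i] + cn_window) |
          (ju$chrom_b == cn$chrom[i] &
           ju$pos_b >= cn$start[i] - cn_window &
           ju$pos_b <= cn$end[i] + cn_window))
    }, logical(1))
    cn <- cn[near, , drop = FALSE]
  }
  losses <- cn[cn$copy_number <= 1.5, , drop = FALSE]
  gains <- cn[cn$copy_number >= 2.5, , drop = FALSE]
  trp <- cn[cn$copy_number >= 3.5, , drop = FALSE]
  nj <- nrow(ju)
  chroms <- unique(c(ju$chrom_a, ju$chrom_b))
  like <- nj > 0 & ju$ori_a == ju$ori_b
  label <- "COMPLEX"
  if (derivative@motifLabel == "COMPLEX_UNRESOLVED") {
    return(derivative)
  } else if (nj == 0L) {
    label <- "REFERENCE"
  } else if (derivative@circular) {
    label <- "RING"
  } else if (length(chroms) > 1L) {
    label <- if (nj == 1L) "UNBALANCED_TRANSLOCATION" else "COMPLEX"
  } else if (nj == 1L && !like[1L]) {
    label <- if (ju$ori_a[1L] == "+") "DEL" else "DUP"
  } else if (nj == 1L && like[1L]) {
    label <- if (nrow(losses) && nrow(gains)) "DEL-INV-DUP" else "COMPLEX"
  } else if (nj == 2L && all(like)) {
    if (any(ju$ori_a == "+") && any(ju$ori_a == "-")) {
      if (nrow(trp) && nrow(gains) > nrow(trp)) {
        label <- "DUP-TRP/INV-DUP"
      } else {
        label <- "INV"
        jplus <- ju[ju$ori_a == "+", ]
        jminus <- ju[ju$ori_a == "-", ]
        gap1 <- abs(jminus$pos_a - jplus$pos_a)
        gap2 <- abs(jminus$pos_b - jplus$pos_b)
        if (nrow(losses)) {
          for (g in c(gap1, gap2)) if (g > 100)
            ann <- c(ann, sprintf(
              "%d bp deletion at inversion breakpoint", g))
        }
      }
    }
  }
  derivative@motifLabel <- label
  derivative@annotations <- unique(ann)
  methods::validObject(derivative)
  derivative
}

#' Text "subway" rendering of a derivative
#'
#' @param derivative A [DerivativeChromosome].
#' @return Character vector of lines.
#' @export
renderSubway <- function(derivative) {
  s <- as.data.frame(derivative@segments)
  if (nrow(s) == 0L) return("  (empty derivative)")
  seg <- sprintf("[%s:%s-%s %s]", s$chrom,
                 format(s$start, big.mark = ",", trim = TRUE),
                 format(s$end, big.mark = ",", trim = TRUE),
                 s$orientation)
  line <- paste(seg, collapse = " -> ")
  if (derivative@circular) line <- paste(line, "-> (back to start)")
  paste0("  der: ", line)
}

#' Export junctions as VCF breakend records
#'
#' @param junctions Clustered junction data.frame.
#' @param path Output VCF path.
#' @param seqlengths Named reference lengths for the header.
#' @param sample_id Sample name recorded in the header.
#' @return `path`, invisibly.
#' @export
junctionsToVcf <- function(junctions, path, seqlengths,
                           sample_id = "sample") {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(seqlengths),
                   seqlengths),
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate id\">",
           "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Supporting reads\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"))
  lines <- character(0)
  jn <- as.data.frame(junctions)
  bnd <- function(ori_self, chrom_mate, pos_mate1, ori_mate, t = "N") {
    mate <- paste0(chrom_mate, ":", pos_mate1)
    if (ori_self == "+") {
      if (ori_mate == "-") paste0(t, "[", mate, "[")
      else paste0(t, "]", mate, "]")
    } else {
      if (ori_mate == "+") paste0("]", mate, "]", t)
      else paste0("[", mate, "[", t)
    }
  }
  for (i in seq_len(nrow(jn))) {
    # 1-based VCF positions: a "+" end's 0-based exclusive boundary is
    # the 1-based last retained base; a "-" end needs +1
    pa1 <- if (jn$ori_a[i] == "+") jn$pos_a[i] else jn$pos_a[i] + 1L
    pb1 <- if (jn$ori_b[i] == "+") jn$pos_b[i] else jn$pos_b[i] + 1L
    ida <- sprintf("bnd_%d_a", i); idb <- sprintf("bnd_%d_b", i)
    sup <- if (!is.null(jn$support)) jn$support[i] else 1L
    lines <- c(lines,
      sprintf("%s\t%d\t%s\tN\t%s\t.\tPASS\tSVTYPE=BND;MATEID=%s;SUPPORT=%d",
              jn$chrom_a[i], pa1, ida,
              bnd(jn$ori_a[i], jn$chrom_b[i], pb1, jn$ori_b[i]), idb, sup),
      sprintf("%s\t%d\t%s\tN\t%s\t.\tPASS\tSVTYPE=BND;MATEID=%s;SUPPORT=%d",
              jn$chrom_b[i], pb1, idb,
              bnd(jn$ori_b[i], jn$chrom_a[i], pa1, jn$ori_a[i]), ida, sup))
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}
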