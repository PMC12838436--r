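# CIGAR parsing and query/reference coordinate maps.
#
# These are the minimal alignment-walking primitives the rest of the
# package needs: query/reference lengths, clip offsets, and a per-base
# map between reference positions and positions in the stored (SAM
# orientation) sequence.

#' Parse a CIGAR string
#'
#' @param cigar A single CIGAR string.
#' @return A data.frame with columns `op` and `len`.
#' @keywords internal
parseCigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*" || cigar == "")
    return(data.frame(op = character(0), len = integer(0)))
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (length(lens) != length(ops)) stop("malformed CIGAR: ", cigar)
  data.frame(op = ops, len = lens, stringsAsFactors = FALSE)
}

#' @keywords internal
cigarQueryLength <- function(cigar) {
  cg <- parseCigar(cigar)
  sum(cg$len[cg$op %in% c("M", "I", "S", "=", "X")])
}

#' @keywords internal
cigarRefLength <- function(cigar) {
  cg <- parseCigar(cigar)
  sum(cg$len[cg$op %in% c("M", "D", "N", "=", "X")])
}

# leading/trailing clip lengths (S or H) in stored orientation
#' @keywords internal
cigarClips <- function(cigar) {
  cg <- parseCigar(cigar)
  lead <- 0L; trail <- 0L
  n <- nrow(cg)
  i <- 1L
  while (i <= n && cg$op[i] %in% c("S", "H")) { lead <- lead + cg$len[i]; i <- i + 1L }
  j <- n
  while (j >= 1L && cg$op[j] %in% c("S", "H")) { trail <- trail + cg$len[j]; j <- j - 1L }
  c(lead = lead, trail = trail)
}

#' Reference/query base map of one alignment
#'
#' Expands an alignment into parallel vectors of 0-based reference
#' positions and 1-based positions in the stored sequence, covering
#' aligned (M/=/X) bases only.
#'
#' @param pos 1-based leftmost reference position of the alignment.
#' @param cigar CIGAR string.
#' @return list with integer vectors `rpos` (0-based reference) and
#'   `qpos` (1-based index into the stored SEQ).
#' @keywords internal
alignmentMap <- function(pos, cigar) {
  cg <- parseCigar(cigar)
  r <- pos - 1L   # 0-based
  q <- 1L
  rpos <- vector("list", nrow(cg))
  qpos <- vector("list", nrow(cg))
  for (i in seq_len(nrow(cg))) {
    op <- cg$op[i]; len <- cg$len[i]
    if (op %in% c("M", "=", "X")) {
      rpos[[i]] <- r + seq_len(len) - 1L
      qpos[[i]] <- q + seq_len(len) - 1L
      r <- r + len; q <- q + len
    } else if (op %in% c("D", "N")) {
      r <- r + len
    } else if (op %in% c("I", "S")) {
      q <- q + len
    } # H, P consume nothing here
  }
  list(rpos = unlist(rpos), qpos = unlist(qpos))
}

#' Extract the read allele over a reference interval
#'
#' Returns the stored-sequence substring aligned between two reference
#' anchor positions, including any inserted bases in between. Used for
#' genotype extraction at SNV/indel sites.
#'
#' @param seq Stored sequence (SAM orientation).
#' @param pos 1-based alignment start.
#' @param cigar CIGAR string.
#' @param start0 0-based reference start of the interval (inclusive).
#' @param end0 0-based reference end (exclusive).
#' @return The read bases spanning the interval, or NA_character_ when the
#'   alignment does not fully cover `[start0, end0]` plus one anchor base
#'   on each side.
#' @keywords internal
readSegmentAt <- function(seq, pos, cigar, start0, end0) {
  map <- alignmentMap(pos, cigar)
  if (length(map$rpos) == 0L) return(NA_character_)
  i1 <- match(start0, map$rpos)
  # first aligned base at or beyond end0 gives the right boundary
  i2 <- which(map$rpos >= end0)
  if (is.na(i1) || length(i2) == 0L) return(NA_character_)
  i2 <- i2[1L]
  # demand the flanking anchor bases are aligned so indels are bounded
  if (map$rpos[i2] != end0) return(NA_character_)
  q1 <- map$qpos[i1]
  q2 <- map$qpos[i2] - 1L
  if (q2 < q1) return("")
  substr(seq, q1, q2)
}
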