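# SAM export/import for LongReadSet.
#
# The writer emits plain coordinate-sorted SAM with supplementary
# alignment (SA) chains, haplotype (HP) tags and modified-base
# methylation tags (MM/ML, "C+m" convention, probabilities scaled to
# 0-255). Reading goes through Rsamtools (SAM -> BAM -> scanBam) so the
# emitted files are validated against the standard toolchain.

#' @noRd
.mmTagsForRow <- function(seq, pos, cigar, strand, meth, chrom) {
  if (nrow(meth) == 0L) return(NULL)
  map <- alignmentMap(pos, cigar)
  m <- meth[meth$chrom == chrom, , drop = FALSE]
  hit <- match(m$pos, map$rpos)
  ok <- !is.na(hit)
  if (!any(ok)) return(NULL)
  q <- map$qpos[hit[ok]]
  prob <- m$prob[ok]
  n <- nchar(seq)
  q_orig <- if (strand == "+") q else n - q + 1L
  o <- order(q_orig)
  q_orig <- q_orig[o]; prob <- prob[o]
  orig <- if (strand == "+") seq else revcompStr(seq)
  cpos <- which(strsplit(orig, "", fixed = TRUE)[[1]] == "C")
  rank <- match(q_orig, cpos)
  keep <- !is.na(rank)
  if (!any(keep)) return(NULL)
  rank <- rank[keep]; prob <- prob[keep]
  deltas <- diff(c(0L, rank)) - 1L
  list(mm = paste0("MM:Z:C+m,", paste(deltas, collapse = ","), ";"),
       ml = paste0("ML:B:C,", paste(pmin(255L, pmax(0L,
                     as.integer(round(prob * 255)))), collapse = ",")))
}

#' Write a LongReadSet as coordinate-sorted SAM
#'
#' @param x A LongReadSet.
#' @param path Output SAM path.
#' @param truth_path Optional path for the ground-truth sidecar TSV; when
#'   NULL and truth is present, `<path>.truth.tsv` is used.
#' @return `path`, invisibly.
#' @export
writeSam <- function(x, path, truth_path = NULL) {
  stopifnot(is(x, "LongReadSet"))
  a <- x@alignments
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(x@seqlengths), x@seqlengths),
           "@PG\tID:lorediag\tPN:lorediag")
  o <- order(match(a$chrom, names(x@seqlengths)), a$pos, a$read_id)
  a <- a[o, ]
  # SA chains: all rows of the same read except self, in read order
  by_read <- split(seq_len(nrow(a)), a$read_id)
  lines <- character(nrow(a))
  for (i in seq_len(nrow(a))) {
    flag <- (a$strand[i] == "-") * 16L + a$supplementary[i] * 2048L
    tags <- character(0)
    sibs <- setdiff(by_read[[a$read_id[i]]], i)
    if (length(sibs)) {
      sibs <- sibs[order(a$qstart[sibs])]
      sa <- paste0(a$chrom[sibs], ",", a$pos[sibs], ",", a$strand[sibs],
                   ",", a$cigar[sibs], ",", a$mapq[sibs], ",0;",
                   collapse = "")
      tags <- c(tags, paste0("SA:Z:", sa))
    }
    if (!is.na(a$hp[i])) tags <- c(tags, paste0("HP:i:", a$hp[i]))
    mt <- .mmTagsForRow(a$seq[i], a$pos[i], a$cigar[i], a$strand[i],
                        a$meth[[i]], a$chrom[i])
    if (!is.null(mt)) tags <- c(tags, mt$mm, mt$ml)
    lines[i] <- paste(c(a$read_id[i], flag, a$chrom[i], a$pos[i],
                        a$mapq[i], a$cigar[i], "*", 0L, 0L, a$seq[i], "*",
                        tags), collapse = "\t")
  }
  writeLines(c(hdr, lines), path)
  if (nrow(x@truth)) {
    if (is.null(truth_path)) truth_path <- paste0(path, ".truth.tsv")
    utils::write.table(as.data.frame(x@truth), truth_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @noRd
.parseMmMl <- function(seq, pos, cigar, strand, mm, ml, chrom) {
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      prob = numeric(0))
  if (is.null(mm) || is.na(mm) || !nzchar(mm)) return(empty)
  body <- sub("^C\\+m[.?]?,", "", sub(";$", "", mm))
  if (!nzchar(body)) return(empty)
  deltas <- as.integer(strsplit(body, ",", fixed = TRUE)[[1]])
  ranks <- cumsum(deltas + 1L)
  orig <- if (strand == "+") seq else revcompStr(seq)
  cpos <- which(strsplit(orig, "", fixed = TRUE)[[1]] == "C")
  if (max(ranks) > length(cpos)) return(empty)
  q_orig <- cpos[ranks]
  n <- nchar(seq)
  q <- if (strand == "+") q_orig else n - q_orig + 1L
  map <- alignmentMap(pos, cigar)
  hit <- match(q, map$qpos)
  ok <- !is.na(hit)
  if (!any(ok)) return(empty)
  prob <- as.numeric(ml) / 255
  data.frame(chrom = chrom, pos = map$rpos[hit[ok]], prob = prob[ok])
}

#' Read aligned long reads from SAM or BAM
#'
#' Converts SAM to BAM through Rsamtools and imports alignment records,
#' supplementary flags, HP haplotype tags and MM/ML methylation tags.
#'
#' @param path SAM or BAM file.
#' @param truth_path Optional ground-truth sidecar TSV written by
#'   [writeSam()].
#' @return A [LongReadSet].
#' @export
readSam <- function(path, truth_path = NULL) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                            indexDestination = TRUE)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq"),
    tag = c("SA", "HP", "MM", "ML"))
  b <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(b$qname)
  strand <- ifelse(bitwAnd(b$flag, 16L) > 0L, "-", "+")
  supp <- bitwAnd(b$flag, 2048L) > 0L
  seqs <- as.character(b$seq)
  qlen <- nchar(seqs)
  qs <- integer(n); qe <- integer(n)
  meths <- vector("list", n)
  hp <- b$tag$HP
  if (is.null(hp)) hp <- rep(NA_integer_, n)
  mm <- b$tag$MM; ml <- b$tag$ML
  for (i in seq_len(n)) {
    cl <- cigarClips(b$cigar[i])
    s1 <- cl["lead"] + 1L
    e1 <- qlen[i] - cl["trail"]
    if (strand[i] == "+") { qs[i] <- s1; qe[i] <- e1 }
    else { qs[i] <- qlen[i] - e1 + 1L; qe[i] <- qlen[i] - s1 + 1L }
    meths[[i]] <- .parseMmMl(seqs[i], b$pos[i], b$cigar[i], strand[i],
                             if (is.null(mm)) NA else mm[[i]],
                             if (is.null(ml)) NA else ml[[i]],
                             as.character(b$rname[i]))
  }
  A <- S4Vectors::DataFrame(
    read_id = b$qname, chrom = as.character(b$rname), pos = b$pos,
    strand = strand, mapq = b$mapq, cigar = b$cigar, seq = seqs,
    qstart = qs, qend = qe, supplementary = supp,
    hp = as.integer(hp))
  A$meth <- meths
  truth <- S4Vectors::DataFrame()
  if (!is.null(truth_path) && file.exists(truth_path))
    truth <- S4Vectors::DataFrame(utils::read.delim(truth_path))
  sl <- as.integer(hdr); names(sl) <- names(hdr)
  new("LongReadSet", alignments = A, truth = truth, seqlengths = sl)
}
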