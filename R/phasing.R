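# Read-backed phasing: haplotype assignment from heterozygous sites,
# cis/trans resolution of variant pairs, and paralog haplotype
# separation for copy-number resolution of near-identical gene families.

#' @noRd
.alleleAtVariant <- function(row, v) {
  # v: list(pos [1-based, VCF], ref, alt)
  start0 <- v$pos - 1L
  end0 <- start0 + nchar(v$ref)
  seg <- readSegmentAt(row$seq, row$pos, row$cigar, start0, end0)
  if (is.na(seg)) return(NA_character_)
  if (seg == v$ref) "ref" else if (seg == v$alt) "alt" else "other"
}

#' @noRd
.alleleMatrix <- function(a, variants) {
  out <- matrix(NA_character_, nrow(a), nrow(variants))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(variants))) {
      if (a$chrom[i] != variants$chrom[j]) next
      out[i, j] <- .alleleAtVariant(a[i, ],
        list(pos = variants$pos[j], ref = variants$ref[j],
             alt = variants$alt[j]))
    }
  }
  out
}

#' Assign reads to haplotypes from heterozygous sites
#'
#' Greedy agreement partitioning: the read covering the most
#' heterozygous sites seeds haplotype 1; every other read joins the
#' partition whose consensus alleles it matches at the majority of
#' shared sites (the second partition's consensus is the allelic
#' complement). Reads sharing fewer than `min_informative` determinate
#' sites with the growing consensus, or tied exactly, stay unassigned.
#'
#' @param x A [LongReadSet].
#' @param het_variants data.frame of heterozygous sites: `chrom`, `pos`
#'   (1-based as in VCF), `ref`, `alt`.
#' @param min_informative Minimum shared determinate sites (default 1).
#' @return Named integer vector read_id -> 1, 2 or NA (unassigned).
#'   Haplotype labels are arbitrary up to a 1<->2 swap.
#' @export
assignHaplotypes <- function(x, het_variants, min_informative = 1L) {
  a <- x@alignments
  a <- a[!a$supplementary, , drop = FALSE]
  het_variants <- as.data.frame(het_variants)
  stopifnot(nrow(het_variants) >= 1L)
  M <- .alleleMatrix(a, het_variants)
  M[M == "other"] <- NA_character_
  reads <- as.character(a$read_id)
  ncov <- rowSums(!is.na(M))
  assign <- stats::setNames(rep(NA_integer_, length(reads)), reads)
  if (all(ncov == 0L)) return(assign)
  ord <- order(-ncov, reads)
  seed <- ord[1L]
  consensus <- M[seed, ]                  # haplotype 1 alleles
  assign[seed] <- 1L
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (i in ord) {
      if (!is.na(assign[i])) next
      shared <- which(!is.na(M[i, ]) & !is.na(consensus))
      if (length(shared) < min_informative) next
      agree <- sum(M[i, shared] == consensus[shared])
      m <- length(shared)
      if (agree * 2L == m) next           # exact tie stays unassigned
      assign[i] <- if (agree * 2L > m) 1L else 2L
      # grow consensus at newly covered sites
      newsites <- which(!is.na(M[i, ]) & is.na(consensus))
      if (length(newsites)) {
        al <- M[i, newsites]
        if (assign[i] == 2L)
          al <- ifelse(al == "alt", "ref", "alt")
        consensus[newsites] <- al
        changed <- TRUE
      }
      changed <- changed || TRUE
    }
    # a full pass with no new consensus growth terminates; plain
    # assignments without growth need no second pass
    if (!any(is.na(assign[ord][ncov[ord] > 0L]))) break
  }
  assign
}

#' Phase a variant pair (cis / trans)
#'
#' Reads covering both positions vote directly: a read carrying both
#' alternate alleles or neither votes cis; exactly one votes trans.
#' When no read covers both, votes are routed through haplotype tags
#' (each variant is located on a haplotype by majority of tagged reads;
#' same haplotype = cis). Direct evidence outranks tag-routed evidence:
#' when both exist and disagree the phase is unknown with a conflict
#' flag. A phase is declared only when winning votes >= `min_support`
#' and the conflict fraction <= `max_conflict`.
#'
#' @param x A [LongReadSet].
#' @param variant_a,variant_b Lists/one-row data.frames with `chrom`,
#'   `pos` (1-based), `ref`, `alt`.
#' @param haplotype_tags Optional named vector read_id -> 1/2 (defaults
#'   to the HP tags carried by the reads).
#' @param min_support Minimum winning votes (default 3).
#' @param max_conflict Maximum tolerated conflicting-vote fraction
#'   (default 0.1).
#' @return list with `phase` ("cis", "trans" or "unknown"),
#'   `n_reads_both`, `n_cis_support`, `n_trans_support`,
#'   `conflict_fraction`, `mode` ("direct", "tag_routed" or "none"),
#'   `reason`.
#' @export
phasePair <- function(x, variant_a, variant_b, haplotype_tags = NULL,
                      min_support = 3L, max_conflict = 0.1) {
  a <- x@alignments
  a <- a[!a$supplementary, , drop = FALSE]
  va <- as.list(as.data.frame(variant_a))
  vb <- as.list(as.data.frame(variant_b))
  al_a <- vapply(seq_len(nrow(a)), function(i)
    if (a$chrom[i] == va$chrom) .alleleAtVariant(a[i, ], va)
    else NA_character_, character(1))
  al_b <- vapply(seq_len(nrow(a)), function(i)
    if (a$chrom[i] == vb$chrom) .alleleAtVariant(a[i, ], vb)
    else NA_character_, character(1))
  det_a <- al_a %in% c("ref", "alt")
  det_b <- al_b %in% c("ref", "alt")
  both <- det_a & det_b
  n_both <- sum(both)
  cis_v <- sum(both & ((al_a == "alt") == (al_b == "alt")))
  trans_v <- sum(both & ((al_a == "alt") != (al_b == "alt")))

  decide <- function(cis, trans) {
    win <- max(cis, trans); lose <- min(cis, trans)
    conflict <- if (win + lose > 0) lose / (win + lose) else NA_real_
    if (win >= min_support && !is.na(conflict) && conflict <= max_conflict)
      list(phase = if (cis > trans) "cis" else "trans",
           conflict = conflict)
    else list(phase = "unknown", conflict = conflict)
  }

  direct <- if (n_both > 0L) decide(cis_v, trans_v) else NULL

  # tag routing
  tags <- haplotype_tags
  if (is.null(tags))
    tags <- stats::setNames(as.integer(a$hp), as.character(a$read_id))
  routed <- NULL
  locate <- function(al, det) {
    hp <- tags[as.character(a$read_id)]
    use <- det & !is.na(hp)
    n1 <- sum(use & al == "alt" & hp == 1L) + 0
    n2 <- sum(use & al == "alt" & hp == 2L) + 0
    # reads showing ref on a haplotype argue the alt is on the other
    r1 <- sum(use & al == "ref" & hp == 1L)
    r2 <- sum(use & al == "ref" & hp == 2L)
    v1 <- n1 + r2; v2 <- n2 + r1
    list(hap = if (v1 > v2) 1L else if (v2 > v1) 2L else NA_integer_,
         win = max(v1, v2), lose = min(v1, v2))
  }
  la <- locate(al_a, det_a); lb <- locate(al_b, det_b)
  if (!is.na(la$hap) && !is.na(lb$hap)) {
    cis_r <- 0L; trans_r <- 0L
    support <- min(la$win, lb$win)
    if (la$hap == lb$hap) cis_r <- support else trans_r <- support
    conflict_r <- (la$lose + lb$lose) /
      max(1L, la$win + la$lose + lb$win + lb$lose)
    routed <- if (support >= min_support && conflict_r <= max_conflict)
      list(phase = if (cis_r > 0L) "cis" else "trans",
           conflict = conflict_r)
    else list(phase = "unknown", conflict = conflict_r)
  }

  res <- list(phase = "unknown", n_reads_both = n_both,
              n_cis_support = cis_v, n_trans_support = trans_v,
              conflict_fraction = NA_real_, mode = "none",
              reason = "")
  if (!any(det_a) || !any(det_b)) {
    res$reason <- "no coverage"
    return(res)
  }
  if (!is.null(direct) && direct$phase != "unknown") {
    if (!is.null(routed) && routed$phase != "unknown" &&
        routed$phase != direct$phase) {
      res$reason <- "direct and tag-routed evidence disagree"
      res$conflict_fraction <- 1
      return(res)
    }
    res$phase <- direct$phase
    res$conflict_fraction <- direct$conflict
    res$mode <- "direct"
    return(res)
  }
  if (!is.null(routed)) {
    res$phase <- routed$phase
    res$conflict_fraction <- routed$conflict
    res$mode <- "tag_routed"
    if (routed$phase == "unknown") res$reason <- "insufficient support"
    return(res)
  }
  res$reason <- if (n_both > 0L) "insufficient support"
                else "no spanning reads and no usable haplotype tags"
  if (!is.null(direct)) res$conflict_fraction <- direct$conflict
  res
}
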