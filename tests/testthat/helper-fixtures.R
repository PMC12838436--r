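# Shared fixture builders. Everything is generated in code at test time;
# seeds are fixed so the suite is reproducible.

# reference with the catalog repeat tract written into the locus interval
strFixtureReference <- function(locus, ref_len = 12000L, seed = 101L) {
  ref <- makeReference(1, ref_len, 0.45, seed = seed)
  tract <- strrep(locus$motif, (locus$end - locus$start) / nchar(locus$motif))
  Biostrings::subseq(ref[[1]], locus$start + 1L, locus$end) <-
    Biostrings::DNAString(tract)
  ref
}

baseAt <- function(reference, pos0, chrom = 1L) {
  as.character(Biostrings::subseq(reference[[chrom]], pos0 + 1L, pos0 + 1L))
}

altOf <- function(b) setdiff(c("A", "C", "G", "T"), b)[1L]

# a heterozygous SNV data.frame (0-based positions) for haplotypeSpec()
snvTable <- function(reference, pos0, chrom = "chr1") {
  refb <- vapply(pos0, function(p) baseAt(reference, p), character(1))
  data.frame(chrom = chrom, pos = pos0, ref = refb,
             alt = vapply(refb, altOf, character(1)),
             stringsAsFactors = FALSE)
}

# the same variants in 1-based VCF convention for the phasing API
asVcfVariants <- function(vdf) {
  out <- vdf
  out$pos <- out$pos + 1L
  out
}

# simulate, extract, cluster, segment and walk in one go
svRoundTrip <- function(reference, plan, anchor, coverage = 30,
                        seed = 13L, bin_size = 1000L, ...) {
  x <- simulateSample(reference, plans = list(plan),
                      config = simulationConfig(coverage = coverage,
                                                seed = seed, ...))
  cl <- clusterJunctions(extractJunctions(x))
  cn <- segmentCopyNumber(x, bin_size)
  d <- buildDerivative(cl, cn, anchor, seqlengths = seqLengths(x),
                       reads = x)
  list(reads = x, junctions = cl, cn = cn, derivative = d)
}

# independent per-window repeat-tiling oracle: compares every aligned
# k-window against the motif, no greedy state
oracleTileTract <- function(tract, motif, max_unit_mismatch = 0L) {
  k <- nchar(motif)
  n_units <- nchar(tract) %/% k
  idx <- integer(0); obs <- character(0)
  for (u in seq_len(n_units)) {
    w <- substr(tract, (u - 1L) * k + 1L, u * k)
    mm <- sum(strsplit(w, "")[[1]] != strsplit(motif, "")[[1]])
    if (mm > max_unit_mismatch) {
      idx <- c(idx, u - 1L)
      obs <- c(obs, w)
    }
  }
  list(repeat_count = n_units,
       interruptions = data.frame(unit_index = idx, observed_motif = obs,
                                  stringsAsFactors = FALSE))
}
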