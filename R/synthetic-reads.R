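# Synthetic reference and aligned long-read simulation.
#
# Everything downstream (STR profiling, methylation, phasing, SV
# reconstruction) is exercised against reads generated here, with a
# mandatory ground-truth sidecar so recovery can be scored exactly.

#' Generate a random reference sequence set
#'
#' @param n_chroms Number of chromosomes.
#' @param length_per_chrom Length of each chromosome in bp (>= 10000).
#' @param gc_fraction Target GC content in (0, 1).
#' @param seed Integer seed; output is deterministic for a fixed seed.
#' @return A [Biostrings::DNAStringSet] named chr1, chr2, ...
#' @examples
#' ref <- makeReference(1, 20000, 0.41, seed = 7)
#' @export
makeReference <- function(n_chroms = 1L, length_per_chrom = 100000L,
                          gc_fraction = 0.41, seed = 1L) {
  if (!is.numeric(length_per_chrom) || length_per_chrom <= 0)
    stop("length_per_chrom must be positive", call. = FALSE)
  if (length_per_chrom < 10000)
    stop("length_per_chrom must be >= 10000", call. = FALSE)
  if (gc_fraction <= 0 || gc_fraction >= 1)
    stop("gc_fraction must be in (0, 1)", call. = FALSE)
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2,
         gc_fraction / 2, (1 - gc_fraction) / 2)
  withSeed(seed, {
    seqs <- vapply(seq_len(n_chroms), function(i) {
      paste(sample(c("A", "C", "G", "T"), length_per_chrom,
                   replace = TRUE, prob = p), collapse = "")
    }, character(1))
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- paste0("chr", seq_len(n_chroms))
    out
  })
}

#' Write a reference to FASTA with a .fai index sidecar
#'
#' @param reference A DNAStringSet.
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
writeReference <- function(reference, path) {
  Biostrings::writeXStringSet(reference, path)
  Rsamtools::indexFa(path)
  invisible(path)
}

#' Describe one haplotype of a simulated sample
#'
#' @param haplotype_id 1 or 2 for a diploid sample (higher ids allowed
#'   for multi-copy paralog simulations).
#' @param variants NULL or a data.frame with columns `chrom` (optional,
#'   default chr1), `pos` (0-based reference offset), `ref`, `alt`.
#'   Positions must be strictly increasing per chromosome.
#' @param str_allele NULL or a list with `locus_id`, `repeat_count`
#'   (integer units) and optional `interruptions` data.frame
#'   (`unit_index` 0-based, `motif`).
#' @param methyl_level Methylation probability in [0,1]: a single value
#'   applied to every simulated region, or a named vector keyed by
#'   region_id (unlisted regions fall back to the sample background).
#' @param weight Fraction of cells carrying this haplotype; the weights
#'   of a sample's haplotype set must sum to 1.
#' @export
haplotypeSpec <- function(haplotype_id, variants = NULL, str_allele = NULL,
                          methyl_level = 0.5, weight = 0.5) {
  # 1 or 2 for diploid samples; higher ids are allowed so multi-copy
  # (paralog) loci can be simulated as one template per gene copy
  stopifnot(is.numeric(haplotype_id), haplotype_id >= 1,
            haplotype_id == as.integer(haplotype_id))
  if (!is.null(variants)) {
    variants <- as.data.frame(variants)
    if (is.null(variants$chrom)) variants$chrom <- "chr1"
    stopifnot(all(c("pos", "ref", "alt") %in% colnames(variants)))
    for (ch in unique(variants$chrom)) {
      p <- variants$pos[variants$chrom == ch]
      if (any(diff(p) <= 0))
        stop("variant positions must be strictly increasing", call. = FALSE)
    }
  }
  if (!is.null(str_allele)) {
    stopifnot(is.list(str_allele), str_allele$repeat_count >= 0)
  }
  if (any(methyl_level < 0 | methyl_level > 1))
    stop("methyl_level must be in [0,1]", call. = FALSE)
  stopifnotScalarNum(weight, "weight", 0, 1)
  structure(list(haplotype_id = as.integer(haplotype_id),
                 variants = variants, str_allele = str_allele,
                 methyl_level = methyl_level, weight = weight),
            class = "HaplotypeSpec")
}

#' Describe a derivative chromosome to plant in simulated reads
#'
#' @param segments data.frame with `chrom`, `start`, `end` (0-based
#'   half-open, start < end) and `orientation` ("+" or "-"). Segments are
#'   concatenated in order to form the derivative molecule.
#' @param circular TRUE for a ring chromosome (the molecule closes on
#'   itself; reads crossing the origin carry the ring junction).
#' @param cell_fraction Fraction of cells carrying the derivative in
#'   place of one homolog, in [0,1].
#' @param replaces Which haplotype (1 or 2) the derivative replaces in
#'   carrier cells.
#' @param name Template name recorded in the ground-truth sidecar.
#' @export
derivativePlan <- function(segments, circular = FALSE, cell_fraction = 1,
                           replaces = 2L, name = "der1") {
  segments <- as.data.frame(segments)
  stopifnot(all(c("chrom", "start", "end", "orientation") %in%
                colnames(segments)))
  if (any(segments$start >= segments$end))
    stop("segment intervals must satisfy start < end", call. = FALSE)
  if (!all(segments$orientation %in% c("+", "-")))
    stop("orientation must be '+' or '-'", call. = FALSE)
  stopifnotScalarNum(cell_fraction, "cell_fraction", 0, 1)
  structure(list(segments = segments, circular = isTRUE(circular),
                 cell_fraction = cell_fraction,
                 replaces = as.integer(replaces), name = name),
            class = "DerivativePlan")
}

#' Simulation configuration
#'
#' Defaults emulate the sequencing characteristics of routine-DNA
#' nanopore genome runs: 5 kb median read length, 16 kb N50, 34X
#' coverage. Read lengths are drawn from a log-normal whose two
#' parameters are pinned by the (median, N50) pair: the length-biased
#' median of a log-normal(mu, sigma) is exp(mu + sigma^2), so
#' sigma = sqrt(log(N50/median)).
#'
#' @param coverage Target mean depth (X).
#' @param read_length_median,read_length_n50 Read length statistics, bp.
#' @param substitution_rate,insertion_rate,deletion_rate Per-base error
#'   probabilities in [0,1).
#' @param methyl_call_noise Standard deviation of emitted per-CpG
#'   methylation probabilities around 0/1.
#' @param seed Integer seed driving all randomness of one simulation.
#' @param min_read_length Reads shorter than this are discarded.
#' @param min_block Alignment blocks with fewer aligned bases are not
#'   emitted (their bases stay soft-clipped), mimicking the minimum
#'   anchor an aligner needs.
#' @export
simulationConfig <- function(coverage = 34, read_length_median = 5000,
                             read_length_n50 = 16000,
                             substitution_rate = 0, insertion_rate = 0,
                             deletion_rate = 0, methyl_call_noise = 0.05,
                             seed = 1L, min_read_length = 300L,
                             min_block = 30L) {
  stopifnotScalarNum(coverage, "coverage", 1e-9, Inf)
  for (r in c(substitution_rate, insertion_rate, deletion_rate))
    if (r < 0 || r >= 1) stop("error rates must be in [0,1)", call. = FALSE)
  if (read_length_median > read_length_n50)
    stop("read_length_median must be <= read_length_n50", call. = FALSE)
  structure(list(coverage = coverage,
                 read_length_median = read_length_median,
                 read_length_n50 = read_length_n50,
                 substitution_rate = substitution_rate,
                 insertion_rate = insertion_rate,
                 deletion_rate = deletion_rate,
                 methyl_call_noise = methyl_call_noise,
                 seed = as.integer(seed),
                 min_read_length = as.integer(min_read_length),
                 min_block = as.integer(min_block)),
            class = "SimulationConfig")
}

# ---- internal template machinery --------------------------------------

#' @noRd
.buildTract <- function(motif, repeat_count, interruptions = NULL) {
  units <- rep(motif, repeat_count)
  if (!is.null(interruptions) && nrow(as.data.frame(interruptions))) {
    interruptions <- as.data.frame(interruptions)
    stopifnot(all(interruptions$unit_index < repeat_count),
              all(nchar(interruptions$motif) == nchar(motif)))
    units[interruptions$unit_index + 1L] <- interruptions$motif
  }
  paste(units, collapse = "")
}

# One template = one molecule class on one (or, for derivatives, several)
# chromosomes. Parallel per-base vectors:
#   map:    0-based reference position or NA (inserted/substituted-tract bases)
#   chromi: integer chromosome index or NA
#   blk:    block id; junctions exist only between blocks
#' @noRd
.newTemplate <- function(name, seq, map, chromi, blk, dirs, hap = NA_integer_,
                         circular = FALSE) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  stopifnot(length(map) == n, length(chromi) == n, length(blk) == n)
  # block table
  r <- rle(blk)
  b_end <- cumsum(r$lengths)
  b_start <- b_end - r$lengths + 1L
  blocks <- data.frame(id = r$values, t_start = b_start, t_end = b_end,
                       dir = dirs[r$values])
  # CpG catalog on the template (C directly followed by G)
  is_cg <- which(chars[-n] == "C" & chars[-1L] == "G")
  cpg <- data.frame(t = is_cg,
                    chromi = chromi[is_cg],
                    rfwd = map[is_cg],
                    rrev = map[is_cg + 1L])
  list(name = name, seq = seq, chars = chars, map = map, chromi = chromi,
       blk = blk, blocks = blocks, cpg = cpg, hap = hap,
       circular = circular, len = n, level = NULL)
}

#' @noRd
.haplotypeTemplate <- function(reference, chrom_idx, spec, str_catalog) {
  chrom <- names(reference)[chrom_idx]
  refseq <- as.character(reference[[chrom_idx]])
  reflen <- nchar(refseq)
  edits <- NULL
  if (!is.null(spec$variants)) {
    v <- spec$variants[spec$variants$chrom == chrom, , drop = FALSE]
    if (nrow(v)) edits <- v[, c("pos", "ref", "alt")]
  }
  if (!is.null(spec$str_allele)) {
    sa <- spec$str_allele
    loc <- str_catalog[str_catalog$locus_id == sa$locus_id, , drop = FALSE]
    if (nrow(loc) == 0L)
      stop("str_allele references unknown locus: ", sa$locus_id,
           call. = FALSE)
    if (loc$chrom[1] == chrom) {
      tract <- .buildTract(loc$motif[1], sa$repeat_count, sa$interruptions)
      ed <- data.frame(pos = loc$start[1],
                       ref = substr(refseq, loc$start[1] + 1L, loc$end[1]),
                       alt = tract)
      edits <- rbind(edits, ed)
    }
  }
  seq_pieces <- character(0); map_pieces <- list()
  if (is.null(edits) || nrow(edits) == 0L) {
    seq <- refseq
    map <- 0:(reflen - 1L)
  } else {
    edits <- edits[order(edits$pos), , drop = FALSE]
    cur <- 0L; sp <- list(); mp <- list(); k <- 0L
    for (i in seq_len(nrow(edits))) {
      p <- edits$pos[i]; rf <- edits$ref[i]; al <- edits$alt[i]
      if (p < cur) stop("overlapping variants at ", p, call. = FALSE)
      if (p + nchar(rf) > reflen)
        stop("variant outside reference at ", p, call. = FALSE)
      if (substr(refseq, p + 1L, p + nchar(rf)) != rf)
        stop("ref allele mismatch at ", p, call. = FALSE)
      if (p > cur) {
        k <- k + 1L; sp[[k]] <- substr(refseq, cur + 1L, p)
        mp[[k]] <- cur:(p - 1L)
      }
      k <- k + 1L; sp[[k]] <- al
      mp[[k]] <- if (nchar(al) == nchar(rf)) p:(p + nchar(al) - 1L)
                 else rep(NA_integer_, nchar(al))
      cur <- p + nchar(rf)
    }
    if (cur < reflen) {
      k <- k + 1L; sp[[k]] <- substr(refseq, cur + 1L, reflen)
      mp[[k]] <- cur:(reflen - 1L)
    }
    seq <- paste(unlist(sp), collapse = "")
    map <- unlist(mp)
  }
  n <- nchar(seq)
  .newTemplate(name = sprintf("hap%d_%s", spec$haplotype_id, chrom),
               seq = seq, map = map,
               chromi = rep(chrom_idx, n), blk = rep(1L, n), dirs = "+",
               hap = spec$haplotype_id)
}

#' @noRd
.derivativeTemplate <- function(reference, plan) {
  sp <- list(); mp <- list(); ci <- list(); bk <- list(); dirs <- character(0)
  for (i in seq_len(nrow(plan$segments))) {
    sg <- plan$segments[i, ]
    ix <- match(sg$chrom, names(reference))
    if (is.na(ix)) stop("plan segment on unknown chrom: ", sg$chrom,
                        call. = FALSE)
    reflen <- length(reference[[ix]])
    if (sg$start < 0 || sg$end > reflen)
      stop("plan segment outside reference bounds: ",
           sg$chrom, ":", sg$start, "-", sg$end, call. = FALSE)
    piece <- as.character(Biostrings::subseq(reference[[ix]],
                                             sg$start + 1L, sg$end))
    m <- sg$start:(sg$end - 1L)
    if (sg$orientation == "-") {
      piece <- revcompStr(piece)
      m <- rev(m)
    }
    sp[[i]] <- piece; mp[[i]] <- m
    ci[[i]] <- rep(ix, length(m)); bk[[i]] <- rep(i, length(m))
    dirs <- c(dirs, sg$orientation)
  }
  .newTemplate(name = plan$name, seq = paste(unlist(sp), collapse = ""),
               map = unlist(mp), chromi = unlist(ci), blk = unlist(bk),
               dirs = dirs, hap = NA_integer_, circular = plan$circular)
}

# annotate template CpGs with the per-molecule methylation level
#' @noRd
.levelCpgs <- function(tpl, reference, regions, methyl_level, background) {
  lv <- rep(background, nrow(tpl$cpg))
  if (!is.null(regions) && nrow(regions) && nrow(tpl$cpg)) {
    scalar <- is.null(names(methyl_level)) && length(methyl_level) == 1L
    for (i in seq_len(nrow(regions))) {
      rg <- regions[i, ]
      ix <- match(rg$chrom, names(reference))
      hit <- !is.na(tpl$cpg$rfwd) & tpl$cpg$chromi == ix &
             tpl$cpg$rfwd >= rg$start & tpl$cpg$rfwd < rg$end
      level <- if (scalar) methyl_level
               else if (rg$region_id %in% names(methyl_level))
                 methyl_level[[rg$region_id]]
               else background
      lv[hit] <- level
    }
  }
  tpl$level <- lv
  tpl
}

#' @noRd
.asRegionDf <- function(regions) {
  if (is.null(regions)) return(NULL)
  if (is(regions, "GRanges")) {
    df <- data.frame(region_id = if (!is.null(regions$region_id))
                       regions$region_id else as.character(seq_along(regions)),
                     chrom = as.character(GenomicRanges::seqnames(regions)),
                     start = GenomicRanges::start(regions) - 1L,
                     end = GenomicRanges::end(regions))
    return(df)
  }
  regions <- as.data.frame(regions)
  stopifnot(all(c("chrom", "start", "end") %in% colnames(regions)))
  if (is.null(regions$region_id))
    regions$region_id <- as.character(seq_len(nrow(regions)))
  regions
}

# ---- read emission ----------------------------------------------------

# Build the alignment rows and methylation calls for one molecule.
# idx: 1-based template positions in molecule order (may wrap for rings).
#' @noRd
.emitRead <- function(tpl, idx, config, read_id, mol_strand) {
  n0 <- length(idx)
  noisy <- (config$substitution_rate + config$insertion_rate +
            config$deletion_rate) > 0
  ch <- tpl$chars[idx]; mp <- tpl$map[idx]; ci <- tpl$chromi[idx]
  bk <- tpl$blk[idx]
  nb <- max(tpl$blk)
  if (tpl$circular) {
    # a read crossing the ring origin carries the ring junction: split it
    # into two alignment blocks
    wr <- which(diff(idx) < 0L)
    if (length(wr))
      bk[(wr[1L] + 1L):n0] <- bk[(wr[1L] + 1L):n0] + nb
  }
  if (noisy) {
    keep <- stats::runif(n0) >= config$deletion_rate
    ch <- ch[keep]; mp <- mp[keep]; ci <- ci[keep]; bk <- bk[keep]
    nk <- length(ch)
    if (nk == 0L) return(NULL)
    sub <- stats::runif(nk) < config$substitution_rate
    if (any(sub)) ch[sub] <- sample(c("A", "C", "G", "T"), sum(sub),
                                    replace = TRUE)
    ins <- stats::runif(nk) < config$insertion_rate
    if (any(ins)) {
      ord <- rep(seq_len(nk), times = 1L + ins)
      dup <- duplicated(ord) & c(FALSE, diff(ord) == 0L)
      ch <- ch[ord]; mp <- mp[ord]; ci <- ci[ord]; bk <- bk[ord]
      ch[dup] <- sample(c("A", "C", "G", "T"), sum(dup), replace = TRUE)
      mp[dup] <- NA_integer_
    }
  }
  n <- length(ch)
  if (n < config$min_read_length) return(NULL)
  readseq <- paste(ch, collapse = "")

  # one candidate alignment row per block run
  runs <- rle(bk)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  rows <- list()
  for (k in seq_along(runs$values)) {
    p1 <- starts[k]; p2 <- ends[k]
    sub_mp <- mp[p1:p2]
    aligned <- !is.na(sub_mp)
    if (sum(aligned) < config$min_block) next
    origid <- ((runs$values[k] - 1L) %% nb) + 1L
    d <- tpl$blocks$dir[match(origid, tpl$blocks$id)]
    # CIGAR ops in template order over this block
    a <- sub_mp[aligned]
    sgn <- if (d == "+") 1L else -1L
    ops <- character(0); lens <- integer(0)
    # interleave M runs, D gaps and I runs by walking boundaries
    na_rle <- rle(is.na(sub_mp))
    ne <- cumsum(na_rle$lengths); ns <- ne - na_rle$lengths + 1L
    last_ref <- NA_integer_
    for (j in seq_along(na_rle$values)) {
      if (na_rle$values[j]) {             # inserted bases
        ops <- c(ops, "I"); lens <- c(lens, na_rle$lengths[j])
      } else {
        seg <- sub_mp[ns[j]:ne[j]]
        if (!is.na(last_ref)) {
          gap <- (seg[1L] - last_ref) * sgn - 1L
          if (gap > 0L) { ops <- c(ops, "D"); lens <- c(lens, gap) }
        }
        # split M runs at internal jumps (deletion edits inside a block)
        dd <- diff(seg) * sgn
        brk <- which(dd != 1L)
        seg_starts <- c(1L, brk + 1L)
        seg_ends <- c(brk, length(seg))
        for (m in seq_along(seg_starts)) {
          if (m > 1L) {
            g <- (seg[seg_starts[m]] - seg[seg_ends[m - 1L]]) * sgn - 1L
            if (g > 0L) { ops <- c(ops, "D"); lens <- c(lens, g) }
          }
          ops <- c(ops, "M")
          lens <- c(lens, seg_ends[m] - seg_starts[m] + 1L)
        }
        last_ref <- seg[length(seg)]
      }
    }
    if (d == "-") { ops <- rev(ops); lens <- rev(lens) }
    lead <- if (d == "+") p1 - 1L else n - p2
    trail <- n - lead - (p2 - p1 + 1L)
    cig <- paste0(if (lead > 0L) paste0(lead, "S") else "",
                  paste0(lens, ops, collapse = ""),
                  if (trail > 0L) paste0(trail, "S") else "")
    s_row <- if (d == "+") mol_strand else if (mol_strand == "+") "-" else "+"
    qs <- if (mol_strand == "+") p1 else n - p2 + 1L
    qe <- if (mol_strand == "+") p2 else n - p1 + 1L
    rows[[length(rows) + 1L]] <- list(
      chromi = ci[p1:p2][aligned][1L],
      pos = min(a) + 1L,                  # 1-based
      strand = s_row,
      cigar = cig,
      seq = if (d == "+") readseq else revcompStr(readseq),
      qstart = qs, qend = qe,
      alen = sum(aligned))
  }
  if (length(rows) == 0L) return(NULL)

  # methylation calls from template CpGs falling in the molecule span
  meth <- data.frame(chrom = character(0), pos = integer(0),
                     prob = numeric(0))
  if (nrow(tpl$cpg)) {
    if (tpl$circular && idx[1L] > idx[n0]) {
      inc <- tpl$cpg$t >= idx[1L] | tpl$cpg$t <= idx[n0]
    } else {
      inc <- tpl$cpg$t >= idx[1L] & tpl$cpg$t <= idx[n0]
    }
    cp <- tpl$cpg[inc, , drop = FALSE]
    lv <- tpl$level[inc]
    rp <- if (mol_strand == "+") cp$rfwd else cp$rrev
    ok <- !is.na(rp)
    cp <- cp[ok, , drop = FALSE]; lv <- lv[ok]; rp <- rp[ok]
    if (nrow(cp)) {
      state <- stats::runif(nrow(cp)) < lv
      e <- pmin(0.49, abs(stats::rnorm(nrow(cp), 0, config$methyl_call_noise)))
      prob <- ifelse(state, 1 - e, e)
      meth <- data.frame(chrom = cp$chromi, pos = as.integer(rp),
                         prob = prob)
    }
  }
  list(rows = rows, meth = meth, n_bases = n, readseq = readseq)
}

#' Simulate an aligned long-read sample
#'
#' Draws reads from haplotype and derivative-chromosome templates until
#' the target coverage is reached, planting variants, STR alleles,
#' per-haplotype CpG methylation and rearrangement junctions. Reads that
#' span a planted junction are emitted as primary + supplementary
#' alignment pairs with consistent soft-clips. Every read's true origin
#' is recorded in the ground-truth sidecar.
#'
#' @param reference DNAStringSet from [makeReference()] (or any named
#'   DNAStringSet).
#' @param haplotypes List of [haplotypeSpec()] objects (default: two
#'   plain haplotypes at weight 0.5 each). Weights must sum to 1.
#' @param plans List of [derivativePlan()] objects.
#' @param config A [simulationConfig()].
#' @param regions NULL, a data.frame (`region_id`, `chrom`, `start`,
#'   `end`) or GRanges of methylation regions.
#' @param str_catalog STR catalog data.frame (see [defaultStrCatalog()]);
#'   required when a haplotype plants an STR allele.
#' @param background_methyl CpG methylation probability outside the
#'   given regions.
#' @return A [LongReadSet] with ground truth attached.
#' @export
simulateSample <- function(reference, haplotypes = NULL, plans = list(),
                           config = simulationConfig(), regions = NULL,
                           str_catalog = NULL, background_methyl = 0.5) {
  stopifnot(is(reference, "DNAStringSet"))
  if (is.null(haplotypes))
    haplotypes <- list(haplotypeSpec(1L, weight = 0.5),
                       haplotypeSpec(2L, weight = 0.5))
  w <- vapply(haplotypes, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-9)
    stop("haplotype weights must sum to 1", call. = FALSE)
  regions <- .asRegionDf(regions)
  seqlens <- vapply(seq_along(reference), function(i) length(reference[[i]]),
                    integer(1))
  names(seqlens) <- names(reference)

  withSeed(config$seed, {
    # templates per (chromosome, haplotype) + one per derivative plan
    hap_tpl <- list()
    for (ci in seq_along(reference)) {
      for (h in seq_along(haplotypes)) {
        tpl <- .haplotypeTemplate(reference, ci, haplotypes[[h]], str_catalog)
        tpl <- .levelCpgs(tpl, reference, regions,
                          haplotypes[[h]]$methyl_level, background_methyl)
        hap_tpl[[sprintf("%d_%d", ci, h)]] <- tpl
      }
    }
    der_tpl <- lapply(plans, function(p) {
      tpl <- .derivativeTemplate(reference, p)
      .levelCpgs(tpl, reference, regions, background_methyl,
                 background_methyl)
    })

    # one global molecule-class table; sampling probability is cell
    # weight x template length (DNA mass), so planted cell fractions
    # translate into matching per-base depth fractions
    tpl_list <- list(); probs <- numeric(0)
    for (ci in seq_along(reference)) {
      for (h in seq_along(haplotypes)) {
        ph <- w[h]
        for (pi in seq_along(plans)) {
          p <- plans[[pi]]
          if (p$replaces == haplotypes[[h]]$haplotype_id &&
              p$segments$chrom[1L] == names(reference)[ci]) {
            dt <- der_tpl[[pi]]
            tpl_list[[length(tpl_list) + 1L]] <- dt
            probs <- c(probs, ph * p$cell_fraction * dt$len)
            ph <- ph * (1 - p$cell_fraction)
          }
        }
        ht <- hap_tpl[[sprintf("%d_%d", ci, h)]]
        tpl_list[[length(tpl_list) + 1L]] <- ht
        probs <- c(probs, ph * ht$len)
      }
    }
    probs <- probs / sum(probs)

    sigma <- if (config$read_length_n50 > config$read_length_median)
      sqrt(log(config$read_length_n50 / config$read_length_median)) else 0.01
    mulog <- log(config$read_length_median)

    target <- config$coverage * sum(seqlens)
    total <- 0; rid <- 0L
    aln <- list(); meths <- list(); truths <- list()
    max_iter <- ceiling(10 * target / config$read_length_median) + 1000L
    iter <- 0L
    while (total < target && iter < max_iter) {
      iter <- iter + 1L
      L <- round(stats::rlnorm(1, mulog, sigma))
      if (L < config$min_read_length) next
      tpl <- tpl_list[[sample.int(length(tpl_list), 1L, prob = probs)]]
      Tn <- tpl$len
      if (tpl$circular) {
        L <- min(L, Tn)
        s0 <- sample.int(Tn, 1L) - 1L
        idx <- ((s0 + seq_len(L) - 1L) %% Tn) + 1L
      } else {
        s0 <- sample.int(Tn + L - 1L, 1L) - L   # in [-(L-1), Tn-1]
        lo <- max(0L, s0); hi <- min(Tn, s0 + L)
        if (hi - lo < config$min_read_length) next
        idx <- (lo + 1L):hi
      }
      mol_strand <- sample(c("+", "-"), 1L)
      rid <- rid + 1L
      read_id <- sprintf("read%06d", rid)
      em <- .emitRead(tpl, idx, config, read_id, mol_strand)
      if (is.null(em)) { rid <- rid - 1L; next }
      total <- total + em$n_bases
      # primary = longest aligned block
      alens <- vapply(em$rows, `[[`, numeric(1), "alen")
      prim <- which.max(alens)
      for (k in seq_along(em$rows)) {
        r <- em$rows[[k]]
        aln[[length(aln) + 1L]] <- data.frame(
          read_id = read_id,
          chrom = names(reference)[r$chromi],
          pos = r$pos, strand = r$strand, mapq = 60L, cigar = r$cigar,
          seq = r$seq, qstart = r$qstart, qend = r$qend,
          supplementary = k != prim,
          hp = tpl$hap,
          stringsAsFactors = FALSE)
        meths[[length(meths) + 1L]] <- if (k == prim) {
          m <- em$meth
          if (nrow(m)) m$chrom <- names(reference)[m$chrom]
          m
        } else data.frame(chrom = character(0), pos = integer(0),
                          prob = numeric(0))
      }
      truths[[length(truths) + 1L]] <- data.frame(
        read_id = read_id, source = tpl$name,
        haplotype = tpl$hap, mol_strand = mol_strand,
        tpl_start = idx[1L] - 1L, read_length = em$n_bases,
        n_alignments = length(em$rows),
        stringsAsFactors = FALSE)
    }
    adf <- do.call(rbind, aln)
    A <- S4Vectors::DataFrame(adf)
    A$meth <- meths
    # coordinate sort
    o <- order(match(A$chrom, names(reference)), A$pos, A$read_id)
    A <- A[o, ]
    new("LongReadSet", alignments = A,
        truth = S4Vectors::DataFrame(do.call(rbind, truths)),
        seqlengths = seqlens)
  })
}
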