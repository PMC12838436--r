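# Region-level CpG methylation aggregation and imprinting calls.
#
# Per-read modified-base probability calls are thresholded into
# methylated / unmethylated / discarded, aggregated over a region
# (optionally per haplotype), and compared against a control pool by
# z-score -- the screen used to flag imprinted-region aberrations such
# as the hypermethylated Prader-Willi genes.

#' Aggregate per-read CpG calls over a region
#'
#' A call with probability >= `prob_threshold` counts methylated, one
#' with probability <= 1 - `prob_threshold` counts unmethylated, and
#' anything in between is discarded (symmetric confidence band).
#'
#' @param x A [LongReadSet].
#' @param region A list or one-row data.frame with `chrom`, `start`,
#'   `end` (0-based half-open).
#' @param prob_threshold Confidence threshold, default 0.8.
#' @param haplotype_filter NULL, or 1/2 to restrict to reads carrying
#'   that haplotype tag.
#' @return list(`fraction`, `n_calls`); fraction is NA with n_calls 0
#'   when no calls survive (a no-call).
#' @export
regionMethylationFraction <- function(x, region, prob_threshold = 0.8,
                                      haplotype_filter = NULL) {
  a <- x@alignments
  if (!is.null(haplotype_filter))
    a <- a[!is.na(a$hp) & a$hp == haplotype_filter, , drop = FALSE]
  meth <- 0L; unmeth <- 0L
  for (i in seq_len(nrow(a))) {
    m <- a$meth[[i]]
    if (nrow(m) == 0L) next
    keep <- m$chrom == region$chrom & m$pos >= region$start &
            m$pos < region$end
    p <- m$prob[keep]
    meth <- meth + sum(p >= prob_threshold)
    unmeth <- unmeth + sum(p <= 1 - prob_threshold)
  }
  n <- meth + unmeth
  list(fraction = if (n > 0L) meth / n else NA_real_, n_calls = n)
}

#' Simulate a control-pool fraction table
#'
#' Draws per-sample methylation fractions from a normal distribution
#' truncated to [0,1], one row per (sample, region), in the layout the
#' z-score caller consumes.
#'
#' @param region_ids Character vector of region ids.
#' @param n_controls Number of control samples.
#' @param mean,sd Normal parameters of the control fractions (recycled
#'   over regions).
#' @param seed Integer seed.
#' @return data.frame with `sample_id`, `region_id`, `fraction`,
#'   `n_calls`.
#' @export
simulateControlPool <- function(region_ids, n_controls = 30L, mean = 0.5,
                                sd = 0.04, seed = 1L) {
  mean <- rep_len(mean, length(region_ids))
  sd <- rep_len(sd, length(region_ids))
  withSeed(seed, {
    rows <- lapply(seq_along(region_ids), function(i) {
      f <- pmin(1, pmax(0, stats::rnorm(n_controls, mean[i], sd[i])))
      data.frame(sample_id = sprintf("control%03d", seq_len(n_controls)),
                 region_id = region_ids[i], fraction = f,
                 n_calls = 500L, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Read a control pool TSV (sample_id, region_id, fraction, n_calls)
#' @param path TSV path.
#' @export
readControlPool <- function(path) utils::read.delim(path)

#' Imprinting z-scores against a control pool
#'
#' For each region, z = (case - control mean) / control sd, with the
#' sample (n-1) standard deviation of the control fractions. With the
#' default `score` convention ("methylated_fraction") hypermethylation
#' yields positive z; scoring "unmethylated_fraction" flips the sign
#' (both conventions are found in the wild, so the one used is echoed in
#' the output).
#'
#' @param case_fractions Named numeric vector (region_id -> fraction) or
#'   data.frame with `region_id`, `fraction`.
#' @param control_table data.frame as from [simulateControlPool()] /
#'   [readControlPool()].
#' @param min_controls Minimum pool size per region (default 5); a
#'   smaller pool is a configuration error.
#' @param z_hyper,z_hypo Call thresholds on z (defaults +3 / -3).
#' @param score "methylated_fraction" or "unmethylated_fraction".
#' @return A [S4Vectors::DataFrame] with one row per region:
#'   `region_id`, `case_fraction`, `n_controls`, `control_mean`,
#'   `control_sd`, `z`, `call`, `score`.
#' @export
imprintingZscores <- function(case_fractions, control_table,
                              min_controls = 5L, z_hyper = 3,
                              z_hypo = -3,
                              score = c("methylated_fraction",
                                        "unmethylated_fraction")) {
  score <- match.arg(score)
  if (is.data.frame(case_fractions)) {
    cf <- stats::setNames(case_fractions$fraction,
                          case_fractions$region_id)
  } else cf <- case_fractions
  rows <- lapply(names(cf), function(rid) {
    ctl <- control_table$fraction[control_table$region_id == rid]
    if (length(ctl) < min_controls)
      stop("control pool too small for region ", rid, " (",
           length(ctl), " < ", min_controls, ")", call. = FALSE)
    case <- cf[[rid]]
    if (score == "unmethylated_fraction") {
      ctl <- 1 - ctl; case <- 1 - case
    }
    mu <- mean(ctl); sdev <- stats::sd(ctl)
    if (is.na(case)) {
      z <- NA_real_; call <- "no_call"
    } else if (sdev == 0) {
      z <- NA_real_; call <- "no_call"
    } else {
      z <- (case - mu) / sdev
      hyper <- if (score == "methylated_fraction") z >= z_hyper
               else z <= z_hypo
      hypo <- if (score == "methylated_fraction") z <= z_hypo
              else z >= z_hyper
      call <- if (hyper) "hypermethylated"
              else if (hypo) "hypomethylated" else "normal"
    }
    data.frame(region_id = rid, case_fraction = cf[[rid]],
               n_controls = length(ctl), control_mean = mu,
               control_sd = sdev, z = z, call = call, score = score,
               stringsAsFactors = FALSE)
  })
  S4Vectors::DataFrame(do.call(rbind, rows))
}

#' Promoter methylation status for an STR locus
#'
#' Fraction >= 0.7 is hypermethylated, <= 0.3 unmethylated, anything in
#' between intermediate. The hypermethylated/unmethylated distinction
#' separates silenced full expansions from active premutation alleles.
#'
#' @param x A [LongReadSet].
#' @param promoter_region list/one-row data.frame with `chrom`, `start`,
#'   `end`.
#' @param prob_threshold Per-call confidence threshold.
#' @param haplotype_filter Optional haplotype restriction.
#' @return list(`status`, `fraction`, `n_calls`); status in
#'   {hypermethylated, unmethylated, intermediate, no_call}.
#' @export
strPromoterStatus <- function(x, promoter_region, prob_threshold = 0.8,
                              haplotype_filter = NULL) {
  r <- regionMethylationFraction(x, promoter_region, prob_threshold,
                                 haplotype_filter)
  status <- if (r$n_calls == 0L) "no_call"
            else if (r$fraction >= 0.7) "hypermethylated"
            else if (r$fraction <= 0.3) "unmethylated"
            else "intermediate"
  list(status = status, fraction = r$fraction, n_calls = r$n_calls)
}
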