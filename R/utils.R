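# Internal helpers shared across modules.

#' Run code with a temporarily fixed RNG state
#'
#' Restores the caller's RNG state on exit so simulation helpers are
#' reproducible without clobbering the session seed.
#' @noRd
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

#' @noRd
revcompStr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# mismatches between two equal-length strings (vector of chars is avoided
# for speed on short words)
#' @noRd
strMismatch <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("strMismatch: unequal lengths")
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' @noRd
stopifnotScalarNum <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}

# run-length encode a character vector of CIGAR ops into a CIGAR string
#' @noRd
opsToCigar <- function(ops) {
  if (length(ops) == 0L) return("")
  r <- rle(ops)
  paste0(r$lengths, r$values, collapse = "")
}
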