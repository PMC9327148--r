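## Small internal helpers shared across modules.  All genomic coordinates in
## this package are 0-based half-open; conversion happens only in io_formats.

BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a DNA string
#'
#' Uppercase DNA over \{A,C,G,T,N\}.
#'
#' @param seq character scalar.
#' @return character scalar, the reverse complement.
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

## substring by 0-based half-open span
subseq0 <- function(seq, start, end) {
  substr(seq, start + 1L, end)
}

## seq as character vector of single bases
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

## random DNA of given length and GC fraction (uses current RNG state)
random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

## Derive a per-stage substream seed from one master seed.  Keeps results
## independent across stages while reproducible from a single integer.
stage_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## validate an interval data.frame (chrom, start, end, optional strand)
check_intervals <- function(x) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) && any(x$start < 0L | x$end <= x$start)) {
    stop("invalid interval: need 0 <= start < end")
  }
  invisible(x)
}

## midpoint of 0-based half-open interval (integer floor)
interval_midpoint <- function(start, end) {
  as.integer(floor((start + end) / 2))
}
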