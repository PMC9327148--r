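## Consensus model for a quasi-dimeric SINE: a pol III promoter head
## (A box / B box), n tandem direct-repeat units (F = R by construction),
## and a short 3' body segment carrying one conserved motif.  Each repeat
## unit carries an AG|GT dual-function splice site and a CTGAT-like branch
## motif, so that GT-AG excision between the homologous sites of adjacent
## units removes exactly one unit length (231 nt -> 185 nt by default).

ABOX <- "TGGCTCAGTGG"
BBOX <- "GTTCGAGAC"
BRANCH <- "CTGAT"

#' Consensus specification for the synthetic SINE family
#'
#' Defaults assemble a 231-nt head-body: 110-nt head, two 46-nt direct
#' repeats, and a 29-nt 3' segment holding the conserved motif
#' \code{GGAGTTCCC} exactly once.  Within each repeat unit, \code{AGGT}
#' (acceptor AG immediately followed by donor GT) sits at
#' \code{aggt_offset} and a \code{CTGAT} branch motif at
#' \code{branch_offset}.
#'
#' @param head_len length of the promoter head (nt).
#' @param repeat_unit_len length of one direct-repeat unit (nt).
#' @param n_repeats number of tandem repeat units.
#' @param body3_len length of the 3' body segment after the repeats (nt).
#' @param aggt_offset 0-based offset of the \code{AGGT} dual site within a
#'   repeat unit.
#' @param branch_offset 0-based offset of the branch motif within a unit.
#' @param motif conserved body motif (used by motif-fallback calibration).
#' @param motif_offset 0-based offset of the motif within the body3 segment.
#' @param abox_offset,bbox_offset 0-based offsets of the promoter boxes
#'   within the head.
#' @param gc GC fraction used for the random portions of the consensus.
#' @return object of class \code{consensus_spec}.
#' @export
consensus_spec <- function(head_len = 110L, repeat_unit_len = 46L,
                           n_repeats = 2L, body3_len = 29L,
                           aggt_offset = 20L, branch_offset = 35L,
                           motif = "GGAGTTCCC", motif_offset = 18L,
                           abox_offset = 8L, bbox_offset = 75L,
                           gc = 0.56) {
  spec <- list(
    head_len = as.integer(head_len),
    repeat_unit_len = as.integer(repeat_unit_len),
    n_repeats = as.integer(n_repeats),
    body3_len = as.integer(body3_len),
    aggt_offset = as.integer(aggt_offset),
    branch_offset = as.integer(branch_offset),
    motif = motif, motif_offset = as.integer(motif_offset),
    abox_offset = as.integer(abox_offset),
    bbox_offset = as.integer(bbox_offset),
    gc = gc
  )
  spec$total_len <- spec$head_len + spec$n_repeats * spec$repeat_unit_len +
    spec$body3_len
  class(spec) <- "consensus_spec"
  validate_consensus_spec(spec)
  spec
}

validate_consensus_spec <- function(spec) {
  with(spec, {
    if (head_len < abox_offset + nchar(ABOX) ||
        head_len < bbox_offset + nchar(BBOX)) {
      stop("promoter boxes do not fit in the head")
    }
    if (aggt_offset < 2L || aggt_offset + 4L > repeat_unit_len) {
      stop("AGGT dual site does not fit in the repeat unit")
    }
    if (branch_offset + nchar(BRANCH) > repeat_unit_len) {
      stop("branch motif does not fit in the repeat unit")
    }
    ## the dual site and the branch motif must not collide
    if (max(aggt_offset, branch_offset) <
        min(aggt_offset + 4L, branch_offset + nchar(BRANCH))) {
      stop("dual-site offset collides with the branch motif")
    }
    if (motif_offset + nchar(motif) > body3_len) {
      stop("conserved motif offset collides with the body3 boundary")
    }
    if (n_repeats < 1L) stop("need at least one repeat unit")
  })
  invisible(spec)
}

## place a fixed motif inside a random segment
embed_at <- function(segment, motif, offset) {
  paste0(substr(segment, 1L, offset),
         motif,
         substr(segment, offset + nchar(motif) + 1L, nchar(segment)))
}

#' Build the head-body consensus sequence
#'
#' Deterministic for \code{(spec, seed)}.  The assembled sequence contains
#' no \code{AAAA} run (so a downstream poly(A)-based tail splitter cannot
#' fire inside the head-body) and the conserved motif exactly once.
#'
#' @param spec a [consensus_spec()].
#' @param seed integer seed.
#' @return character scalar of length \code{spec$total_len}.
#' @export
build_consensus <- function(spec = consensus_spec(), seed = 1L) {
  validate_consensus_spec(spec)
  with_seed(stage_seed(seed, "consensus"), {
    for (attempt in 1:2000) {
      head <- embed_at(embed_at(random_dna(spec$head_len, spec$gc),
                                ABOX, spec$abox_offset),
                       BBOX, spec$bbox_offset)
      unit <- embed_at(embed_at(random_dna(spec$repeat_unit_len, spec$gc),
                                "AGGT", spec$aggt_offset),
                       BRANCH, spec$branch_offset)
      body3 <- embed_at(random_dna(spec$body3_len, spec$gc),
                        spec$motif, spec$motif_offset)
      cons <- paste0(head, strrep(unit, spec$n_repeats), body3)
      ok <- !grepl("AAAA", cons, fixed = TRUE) &&
        length(gregexpr(spec$motif, cons, fixed = TRUE)[[1L]]) == 1L &&
        gregexpr(spec$motif, cons, fixed = TRUE)[[1L]][1L] > 0L
      if (ok) return(cons)
    }
    stop("could not build a consensus satisfying the motif constraints")
  })
}

## 0-based half-open spans of the consensus parts, for annotation and tests
consensus_spans <- function(spec = consensus_spec()) {
  reps <- lapply(seq_len(spec$n_repeats) - 1L, function(i) {
    s <- spec$head_len + i * spec$repeat_unit_len
    c(start = s, end = s + spec$repeat_unit_len)
  })
  list(
    head = c(start = 0L, end = spec$head_len),
    repeats = reps,
    body3 = c(start = spec$head_len + spec$n_repeats * spec$repeat_unit_len,
              end = spec$total_len)
  )
}
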