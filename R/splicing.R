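## Splice-signal enrichment on consensus coordinates, the sampling-based
## hot-site threshold, and the GT-AG excision model.

#' Select elements whose exon overlap is informative for splice signals
#'
#' Keeps elements with at least one exon boundary strictly inside the
#' element span, drops any element overlapping a UTR or RNA-gene interval,
#' and requires overlap with a CDS interval.
#'
#' @param elements calibrated elements table.
#' @param annotation \code{gene_annotation} feature table.
#' @return subset of \code{elements}.
#' @export
select_cds_partial_overlaps <- function(elements, annotation) {
  exons <- annotation[annotation$kind == "exon", ]
  utr_rna <- annotation[annotation$kind %in%
                          c("five_prime_utr", "three_prime_utr", "rna_gene"), ]
  cds <- annotation[annotation$kind == "CDS", ]
  keep <- vapply(seq_len(nrow(elements)), function(i) {
    e <- elements[i, ]
    ex <- exons[exons$chrom == e$chrom, ]
    boundary_inside <- any(ex$start > e$start & ex$start < e$end) ||
      any(ex$end > e$start & ex$end < e$end)
    if (!boundary_inside) return(FALSE)
    ur <- utr_rna[utr_rna$chrom == e$chrom, ]
    if (nrow(ur) && any(ur$start < e$end & ur$end > e$start)) return(FALSE)
    cd <- cds[cds$chrom == e$chrom, ]
    nrow(cd) > 0L && any(cd$start < e$end & cd$end > e$start)
  }, logical(1L))
  elements[keep, ]
}

#' Mark splice signals on elements
#'
#' For every exon boundary strictly inside an element: the donor side (exon
#' end on the transcript strand) yields a 5' signal when the next two
#' transcript-strand bases are GT; the acceptor side (exon start) yields a
#' 3' signal when the two preceding bases are AG.  Acceptors of minus-
#' strand transcripts are reported as kind \code{T} (3' signal in the
#' reverse complement).  Boundaries without the canonical dinucleotide are
#' kept with kind suffix \code{nc} and excluded from profiles by default.
#'
#' @param elements (selected) elements table.
#' @param annotation \code{gene_annotation} feature table.
#' @param genome named character vector.
#' @return \code{data.table}: \code{element_id, element_offset, kind,
#'   transcript_id, chrom, pos}.
#' @export
mark_splice_signals <- function(elements, annotation, genome) {
  exons <- annotation[annotation$kind == "exon", ]
  out <- list()
  emit <- function(e, pos, kind, tid) {
    offset <- if (!is.null(e$strand) && identical(e$strand, "-")) {
      e$end - pos
    } else {
      pos - e$start
    }
    data.table::data.table(element_id = e$element_id,
                           element_offset = as.integer(offset),
                           kind = kind, transcript_id = tid,
                           chrom = e$chrom, pos = as.integer(pos))
  }
  for (i in seq_len(nrow(elements))) {
    e <- elements[i, ]
    s <- genome[[e$chrom]]
    ex <- exons[exons$chrom == e$chrom, ]
    for (r in seq_len(nrow(ex))) {
      x <- ex[r, ]
      tid <- x$transcript_id
      if (x$strand != "-") {
        ## + transcript: donor after exon end, acceptor before exon start
        if (x$end > e$start && x$end < e$end) {
          canonical <- subseq0(s, x$end, x$end + 2L) == "GT"
          out[[length(out) + 1L]] <-
            emit(e, x$end, if (canonical) "5" else "5nc", tid)
        }
        if (x$start > e$start && x$start < e$end) {
          canonical <- subseq0(s, x$start - 2L, x$start) == "AG"
          out[[length(out) + 1L]] <-
            emit(e, x$start, if (canonical) "3" else "3nc", tid)
        }
      } else {
        ## - transcript: donor before exon (genomic) start, acceptor after
        ## exon (genomic) end; canonical dinucleotides read on the - strand
        if (x$start > e$start && x$start < e$end) {
          canonical <- subseq0(s, x$start - 2L, x$start) == "AC"
          out[[length(out) + 1L]] <-
            emit(e, x$start, if (canonical) "5" else "5nc", tid)
        }
        if (x$end > e$start && x$end < e$end) {
          canonical <- subseq0(s, x$end, x$end + 2L) == "CT"
          out[[length(out) + 1L]] <-
            emit(e, x$end, if (canonical) "T" else "Tnc", tid)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.table::data.table(element_id = character(),
                                  element_offset = integer(),
                                  kind = character(),
                                  transcript_id = character(),
                                  chrom = character(), pos = integer()))
  }
  data.table::rbindlist(out)
}

#' Project element offsets onto consensus coordinates
#'
#' Globally aligns the element (head-body) sequence to the consensus and
#' translates each element offset through the alignment columns; offsets
#' landing on consensus-gap columns are assigned to the next consensus
#' column 3'.  Elements whose distance to the consensus is >= 0.5 are
#' dropped with a warning.
#'
#' @param signals signal table from [mark_splice_signals()] (or a vector of
#'   0-based element offsets).
#' @param element_seq element (head-body) sequence.
#' @param consensus consensus string.
#' @param max_distance drop threshold on alignment distance.
#' @return integer vector of 1-based consensus positions (NA where the
#'   offset lies beyond the aligned span).
#' @export
project_to_consensus <- function(signals, element_seq, consensus,
                                 max_distance = 0.5) {
  offsets <- if (is.data.frame(signals)) signals$element_offset else signals
  aln <- global_align(element_seq, consensus)
  if (aln$distance >= max_distance) {
    warning("element too diverged from consensus; signals dropped")
    return(rep(NA_integer_, length(offsets)))
  }
  a <- seq_chars(aln$aligned_a)   # element
  b <- seq_chars(aln$aligned_b)   # consensus
  e_idx <- cumsum(a != "-")       # element bases consumed through column
  c_idx <- cumsum(b != "-")       # consensus bases consumed through column
  vapply(offsets, function(o) {
    ## column where element base o (0-based) is consumed
    col <- match(o + 1L, e_idx)
    if (is.na(col)) return(NA_integer_)
    ## if consensus has a gap here, move 3' to the next consensus base
    while (col <= length(b) && b[col] == "-") col <- col + 1L
    if (col > length(b)) return(NA_integer_)
    c_idx[col]
  }, integer(1L))
}

#' Per-position splice-signal profile on the consensus
#'
#' @param consensus_pos integer vector of 1-based consensus positions (one
#'   per signal), or a data.frame with a \code{consensus_pos} column and a
#'   \code{kind} column (non-canonical \code{*nc} kinds are excluded).
#' @param window 1-based inclusive consensus window; default the
#'   93-position direct-repeat window of the default consensus.
#' @return list of class \code{splice_profile}: \code{window, counts}
#'   (named by position), \code{n_signals}.
#' @export
signal_profile <- function(consensus_pos, window = c(110L, 202L)) {
  if (is.data.frame(consensus_pos)) {
    sig <- as.data.frame(consensus_pos)
    if ("kind" %in% names(sig)) {
      sig <- sig[!grepl("nc$", sig$kind), , drop = FALSE]
    }
    consensus_pos <- sig$consensus_pos
  }
  consensus_pos <- consensus_pos[!is.na(consensus_pos)]
  inside <- consensus_pos >= window[1L] & consensus_pos <= window[2L]
  pos <- window[1L]:window[2L]
  counts <- tabulate(consensus_pos[inside] - window[1L] + 1L,
                     nbins = length(pos))
  names(counts) <- pos
  structure(list(window = window, counts = counts,
                 n_signals = sum(counts)),
            class = "splice_profile")
}

#' Sampling null for the per-position signal count
#'
#' Drops \code{n_signals} signals uniformly onto \code{n_positions}
#' positions, \code{reps} times; all (replicate, position) counts are
#' pooled and the threshold k is the smallest integer whose empirical
#' exceedance probability P(count > k) is at most \code{alpha}.
#'
#' @param n_positions number of consensus positions sampled over.
#' @param n_signals number of signals dropped per replicate.
#' @param reps number of replicates.
#' @param alpha significance level on the pooled exceedance probability.
#' @param seed integer seed.
#' @param per_replicate_max alternative reading: threshold on the
#'   distribution of the per-replicate maximum count instead of the pooled
#'   counts (off by default).
#' @return list of class \code{null_threshold}: \code{n_positions,
#'   n_signals, reps, alpha, k, tail_prob_at_k, exceedance} (function of k).
#' @export
null_threshold <- function(n_positions = 93L, n_signals = 188L,
                           reps = 10000L, alpha = 0.01, seed = 1L,
                           per_replicate_max = FALSE) {
  stopifnot(n_positions > 0L, n_signals > 0L, reps > 0L)
  counts <- with_seed(stage_seed(seed, "null_threshold"), {
    draws <- sample.int(n_positions, n_signals * reps, replace = TRUE)
    rep_idx <- rep(seq_len(reps), each = n_signals)
    tabulate((rep_idx - 1L) * n_positions + draws,
             nbins = reps * n_positions)
  })
  pool <- if (per_replicate_max) {
    apply(matrix(counts, nrow = n_positions), 2L, max)
  } else {
    counts
  }
  exceed <- function(k) mean(pool > k)
  k <- 0L
  while (exceed(k) > alpha) k <- k + 1L
  structure(list(
    n_positions = n_positions, n_signals = n_signals, reps = reps,
    alpha = alpha, k = k, tail_prob_at_k = exceed(k),
    pooled_counts = tabulate(pool + 1L) / length(pool)
  ), class = "null_threshold")
}

#' Hot splice sites
#'
#' Positions whose signal count exceeds the null threshold k (strict
#' \code{>} by default; \code{inclusive = TRUE} uses \code{>= k}).
#'
#' @param profile a \code{splice_profile}.
#' @param threshold a \code{null_threshold} (or integer k).
#' @param inclusive use \code{count >= k} instead of \code{count > k}.
#' @return integer vector of 1-based consensus positions.
#' @export
hot_sites <- function(profile, threshold, inclusive = FALSE) {
  k <- if (inherits(threshold, "null_threshold")) threshold$k else threshold
  cnt <- profile$counts
  hit <- if (inclusive) cnt >= k else cnt > k
  as.integer(names(cnt)[hit])
}

#' Locate the dual-function AG|GT sites in the consensus
#'
#' Each repeat unit carries an AG|GT site: the AG can close an upstream
#' exon (acceptor) and the GT open a downstream intron (donor).  For each
#' adjacent pair of repeat copies this yields a donor (GT start in the
#' earlier copy) and an acceptor (AG end in the later copy), 0-based on the
#' head-body consensus, exactly one repeat-unit length apart.
#'
#' @param spec a [consensus_spec()].
#' @param all_pairs also return non-adjacent repeat pairings.
#' @return \code{data.table}: \code{from_repeat, to_repeat, donor,
#'   acceptor, span}.
#' @export
find_dual_sites <- function(spec = consensus_spec(), all_pairs = FALSE) {
  if (spec$n_repeats < 2L) stop("dual-site pairing needs >= 2 repeat copies")
  site <- function(i) spec$head_len + (i - 1L) * spec$repeat_unit_len +
    spec$aggt_offset + 2L
  pairs <- data.table::CJ(from_repeat = seq_len(spec$n_repeats),
                          to_repeat = seq_len(spec$n_repeats))
  pairs <- pairs[to_repeat > from_repeat]
  if (!all_pairs) pairs <- pairs[to_repeat == from_repeat + 1L]
  pairs[, donor := site(from_repeat)]
  pairs[, acceptor := site(to_repeat)]
  pairs[, span := acceptor - donor]
  pairs[]
}

#' Excise a segment between a donor GT and an acceptor AG
#'
#' Models the GT-AG rule: the returned product is
#' \code{seq[0:donor) + seq[acceptor:end)}.  Requires \code{GT} at the
#' donor and \code{AG} immediately before the acceptor; optionally requires
#' a CTGAT-like branch motif (at most one mismatch) inside the excised
#' segment.
#'
#' @param seq sequence to splice.
#' @param donor_pos 0-based position of the G of the donor GT (first
#'   excised base).
#' @param acceptor_pos 0-based position just after the acceptor AG (first
#'   retained base).
#' @param check_branch require a branch motif in the excised segment.
#' @return the spliced sequence.
#' @export
excise_by_splice <- function(seq, donor_pos, acceptor_pos,
                             check_branch = FALSE) {
  if (donor_pos >= acceptor_pos) stop("donor must lie 5' of the acceptor")
  if (subseq0(seq, donor_pos, donor_pos + 2L) != "GT") {
    stop("no GT at the donor position")
  }
  if (subseq0(seq, acceptor_pos - 2L, acceptor_pos) != "AG") {
    stop("no AG before the acceptor position")
  }
  if (check_branch) {
    segment <- subseq0(seq, donor_pos, acceptor_pos)
    if (!has_fuzzy_motif(segment, BRANCH, max_mismatch = 1L)) {
      stop("no branch-site motif in the excised segment")
    }
  }
  paste0(subseq0(seq, 0L, donor_pos),
         subseq0(seq, acceptor_pos, nchar(seq)))
}

## is a motif present allowing up to max_mismatch substitutions?
has_fuzzy_motif <- function(seq, motif, max_mismatch = 1L) {
  n <- nchar(seq); m <- nchar(motif)
  if (n < m) return(FALSE)
  mch <- seq_chars(motif)
  ch <- seq_chars(seq)
  for (i in seq_len(n - m + 1L)) {
    if (sum(ch[i:(i + m - 1L)] != mch) <= max_mismatch) return(TRUE)
  }
  FALSE
}
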