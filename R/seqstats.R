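## Composition statistics, CpG-island classification, nucleotide
## diversity, pairwise divergence and the molecular clock.

#' Composition statistics of a sequence
#'
#' N bases are excluded from all counts and from the effective length.  The
#' observed/expected CpG ratio is the Gardiner-Garden ratio
#' \eqn{n_{CpG} L / (n_C n_G)}; when \eqn{n_C n_G = 0} the ratio is 0 and
#' flagged undefined.
#'
#' @param seq DNA string.
#' @return object of class \code{composition_stats}: \code{length, gc, n_c,
#'   n_g, n_cpg, oe, oe_defined}.
#' @export
composition <- function(seq) {
  stopifnot(nchar(seq) > 0L)
  ch <- seq_chars(seq)
  ch <- ch[ch != "N"]
  if (!length(ch)) stop("all-N sequence")
  L <- length(ch)
  n_c <- sum(ch == "C")
  n_g <- sum(ch == "G")
  n_cpg <- sum(ch[-L] == "C" & ch[-1L] == "G")
  oe_defined <- n_c * n_g > 0
  structure(list(
    length = L, gc = (n_c + n_g) / L, n_c = n_c, n_g = n_g, n_cpg = n_cpg,
    oe = if (oe_defined) n_cpg * L / (n_c * n_g) else 0,
    oe_defined = oe_defined
  ), class = "composition_stats")
}

#' CpG-island predicate
#'
#' A sequence qualifies when it is at least 200 bp long, at least 50% GC,
#' and has an observed/expected CpG ratio strictly above 0.6.
#'
#' @param stats a \code{composition_stats} object (or a sequence, which is
#'   passed through [composition()]).
#' @return logical.
#' @export
is_cpg_island <- function(stats) {
  if (is.character(stats)) stats <- composition(stats)
  stats$length >= 200L && stats$gc >= 0.5 && stats$oe > 0.6
}

#' Pairwise divergence (p-distance)
#'
#' Base changes per site between two sequences: differing columns divided
#' by compared columns, where columns containing a gap (or N) in either
#' sequence are excluded (pairwise deletion).  Unaligned input is globally
#' aligned first.
#'
#' @param seq_a,seq_b sequences; gap character \code{-} allowed when
#'   \code{aligned}.
#' @param aligned if TRUE the inputs are equal-length aligned rows.
#' @param correction \code{"none"} (uncorrected p-distance, default) or
#'   \code{"jc"} (Jukes-Cantor).
#' @return numeric divergence D.
#' @export
p_distance <- function(seq_a, seq_b, aligned = FALSE,
                       correction = c("none", "jc")) {
  correction <- match.arg(correction)
  if (!aligned) {
    aln <- global_align(seq_a, seq_b)
    seq_a <- aln$aligned_a; seq_b <- aln$aligned_b
  } else if (nchar(seq_a) != nchar(seq_b)) {
    stop("aligned sequences must have equal length")
  }
  a <- seq_chars(seq_a); b <- seq_chars(seq_b)
  use <- a != "-" & b != "-" & a != "N" & b != "N"
  if (!any(use)) stop("zero comparable columns")
  d <- sum(a[use] != b[use]) / sum(use)
  if (correction == "jc") {
    if (d >= 0.75) stop("p-distance too large for Jukes-Cantor correction")
    d <- -3 / 4 * log(1 - 4 * d / 3)
  }
  d
}

#' Molecular-clock divergence time
#'
#' \eqn{t = D / (2\alpha)} with the substitution rate \eqn{\alpha} per site
#' per year (default 4.6e-9).
#'
#' @param D divergence (base changes per site).
#' @param alpha substitution rate per site per year.
#' @return list: \code{D, alpha, t_years, t_my} (million years).
#' @export
divergence_time <- function(D, alpha = 4.6e-9) {
  stopifnot(all(D >= 0))
  if (alpha <= 0) stop("alpha must be positive")
  t <- D / (2 * alpha)
  list(D = D, alpha = alpha, t_years = t, t_my = t / 1e6)
}

#' Nucleotide diversity of an alignment
#'
#' Mean pairwise p-distance over all unordered pairs of rows, with per-pair
#' pairwise deletion (default) or complete deletion of any column holding a
#' gap or N in any row.
#'
#' @param aligned_seqs character vector of equal-length aligned rows.
#' @param deletion \code{"pairwise"} or \code{"complete"}.
#' @return list: \code{pi, n_seqs, n_pairs}.
#' @export
nucleotide_diversity <- function(aligned_seqs,
                                 deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  n <- length(aligned_seqs)
  if (n < 2L) stop("need at least 2 sequences")
  if (length(unique(nchar(aligned_seqs))) != 1L) {
    stop("aligned sequences must have equal length")
  }
  if (deletion == "complete") {
    m <- do.call(rbind, lapply(aligned_seqs, seq_chars))
    keep <- colSums(m == "-" | m == "N") == 0L
    if (!any(keep)) stop("zero comparable columns")
    aligned_seqs <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  }
  pairs <- utils::combn(n, 2L)
  d <- apply(pairs, 2L, function(ij) {
    p_distance(aligned_seqs[ij[1L]], aligned_seqs[ij[2L]], aligned = TRUE)
  })
  list(pi = mean(d), n_seqs = n, n_pairs = ncol(pairs))
}

#' Majority-rule consensus of an alignment
#'
#' Per column, the most frequent non-gap base; columns with gap fraction
#' >= 0.5 are dropped; ties resolved in the fixed base order A < C < G < T.
#'
#' @param aligned_seqs character vector of equal-length aligned rows.
#' @return consensus string.
#' @export
consensus_from_alignment <- function(aligned_seqs) {
  if (!length(aligned_seqs)) stop("empty alignment")
  m <- do.call(rbind, lapply(aligned_seqs, seq_chars))
  cols <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    if (mean(col == "-") >= 0.5) return("")
    tab <- table(factor(col[col != "-"], levels = BASES))
    BASES[which.max(tab)]    # which.max takes the first max: A < C < G < T
  }, character(1L))
  paste(cols[cols != ""], collapse = "")
}

#' Composition summary of calibrated elements
#'
#' Per-element length, GC, OE and CpG-island flag, for the whole interior
#' and the head-body / tail / TSD regions.
#'
#' @param elements calibrated elements table.
#' @param genome named character vector.
#' @return \code{data.table}, one row per element.
#' @export
element_stats <- function(elements, genome) {
  one <- function(seq) {
    if (is.na(seq) || !nchar(seq)) {
      return(list(length = NA_integer_, gc = NA_real_, oe = NA_real_))
    }
    cs <- composition(seq)
    list(length = cs$length, gc = cs$gc, oe = cs$oe)
  }
  rows <- lapply(seq_len(nrow(elements)), function(i) {
    e <- elements[i, ]
    s <- genome[[e$chrom]]
    whole <- subseq0(s, e$start, e$end)
    hb <- subseq0(s, e$headbody_start, e$headbody_end)
    tl <- if (e$tail_end > e$tail_start) {
      subseq0(s, e$tail_start, e$tail_end)
    } else NA_character_
    w <- composition(whole)
    data.table::data.table(
      element_id = e$element_id, length = w$length, gc = w$gc, oe = w$oe,
      cpg_island = is_cpg_island(w),
      hb_length = one(hb)$length, hb_gc = one(hb)$gc, hb_oe = one(hb)$oe,
      tail_gc = one(tl)$gc,
      tsd_gc = if (!is.na(e$tsd_seq)) composition(e$tsd_seq)$gc else NA_real_
    )
  })
  data.table::rbindlist(rows)
}
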