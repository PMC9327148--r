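## Calibration: resolve exact element boundaries from target site
## duplications (TSD), split head-body from the poly(A) tail, assign the
## length class, flag tandem/nested structures, and categorize elements
## relative to genes.  Coordinates: 0-based half-open throughout.

#' Scan a genome for approximate matches to a consensus
#'
#' Seed-and-extend re-implementation of a BLAST-like search: exact
#' \code{word_size}-mer seeds (both strands), projection of each seed to a
#' candidate full-length window, merging of overlapping candidates, and
#' verification by global alignment against the consensus with terminal gap
#' columns ignored.
#'
#' @param genome named character vector of chromosome sequences.
#' @param consensus consensus string.
#' @param word_size exact seed length.
#' @param min_identity minimum identity (matches / trimmed columns).
#' @param min_len minimum trimmed match length (bp).
#' @return \code{data.table} of raw hits: \code{chrom, start, end, strand,
#'   identity, source}.
#' @export
scan_hits <- function(genome, consensus, word_size = 12L,
                      min_identity = 0.7, min_len = 100L) {
  stopifnot(nchar(consensus) >= word_size)
  res <- list()
  for (chrom in names(genome)) {
    subject <- Biostrings::DNAString(genome[[chrom]])
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") consensus else revcomp(consensus)
      np <- nchar(pat)
      starts <- seq_len(np - word_size + 1L)
      words <- substring(pat, starts, starts + word_size - 1L)
      keep <- !grepl("N", words, fixed = TRUE)
      if (!any(keep)) next
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(words[keep]))
      m <- Biostrings::matchPDict(pd, subject)
      qpos <- rep(starts[keep], lengths(m)) - 1L      # 0-based in pattern
      gpos <- unlist(lapply(m, Biostrings::start)) - 1L  # 0-based in genome
      if (!length(gpos)) next
      cand_start <- pmax(0L, gpos - qpos)
      cand <- data.table::data.table(start = cand_start,
                                     end = pmin(nchar(genome[[chrom]]),
                                                cand_start + np))
      cand <- merge_intervals(unique(cand))
      for (r in seq_len(nrow(cand))) {
        s <- max(0L, cand$start[r] - 20L)
        e <- min(nchar(genome[[chrom]]), cand$end[r] + 20L)
        region <- subseq0(genome[[chrom]], s, e)
        aln <- global_align(region, pat)
        tr <- trim_terminal_gaps(aln)
        if (tr$n_columns >= min_len &&
            tr$n_matches / tr$n_columns >= min_identity) {
          res[[length(res) + 1L]] <- data.table::data.table(
            chrom = chrom, start = s + tr$a_start, end = s + tr$a_end,
            strand = strand,
            identity = tr$n_matches / tr$n_columns, source = "scan"
          )
        }
      }
    }
  }
  if (!length(res)) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), strand = character(),
                                  identity = numeric(), source = character()))
  }
  hits <- data.table::rbindlist(res)
  ## overlapping +/- hits: keep the higher-identity one
  data.table::setorder(hits, chrom, start, -identity)
  keep <- rep(TRUE, nrow(hits))
  last_end <- -1L; last_chrom <- ""
  for (i in seq_len(nrow(hits))) {
    if (hits$chrom[i] == last_chrom && hits$start[i] < last_end) {
      keep[i] <- FALSE
    } else {
      last_end <- hits$end[i]; last_chrom <- hits$chrom[i]
    }
  }
  hits[keep][order(chrom, start)]
}

## merge overlapping 0-based intervals in a data.table(start, end)
merge_intervals <- function(x) {
  if (nrow(x) <= 1L) return(x)
  data.table::setorder(x, start, end)
  out_start <- x$start[1L]; out_end <- x$end[1L]
  ss <- integer(0); ee <- integer(0)
  for (i in 2:nrow(x)) {
    if (x$start[i] <= out_end) {
      out_end <- max(out_end, x$end[i])
    } else {
      ss <- c(ss, out_start); ee <- c(ee, out_end)
      out_start <- x$start[i]; out_end <- x$end[i]
    }
  }
  data.table::data.table(start = c(ss, out_start), end = c(ee, out_end))
}

## identity over an alignment with terminal gap columns removed; returns
## the trimmed column stats and the 0-based span of sequence a covered
trim_terminal_gaps <- function(aln) {
  a <- seq_chars(aln$aligned_a); b <- seq_chars(aln$aligned_b)
  non_term <- which(a != "-" & b != "-")
  if (!length(non_term)) {
    return(list(n_columns = 0L, n_matches = 0L, a_start = 0L, a_end = 0L))
  }
  lo <- min(non_term); hi <- max(non_term)
  cols <- lo:hi
  n_matches <- sum(a[cols] == b[cols] & a[cols] != "-" & a[cols] != "N")
  list(n_columns = length(cols), n_matches = n_matches,
       a_start = sum(a[seq_len(lo - 1L)] != "-"),
       a_end = sum(a[seq_len(hi)] != "-"))
}

#' Find the target site duplication flanking a raw hit
#'
#' Implements the step-wise k-mer search: every 8-mer whose start lies
#' within \code{search_window} of the hit start is looked up in the 3' flank
#' (hit end to hit end + \code{flank}); an exact match is extended in both
#' directions while the two copies agree, and the longest extended
#' duplication wins (ties: the candidate whose left copy starts most 5').
#' Candidates containing N are discarded.
#'
#' @param genome named character vector.
#' @param hit list or one-row data.frame with \code{chrom, start, end}.
#' @param flank 3'-flank search length (bp).
#' @param seed_k seed k-mer size (bp); also the minimum TSD length.
#' @param search_window offsets (relative to the hit start) where candidate
#'   left-copy 8-mers may start.
#' @param max_tsd_len candidates whose extended duplication exceeds this
#'   length are discarded: a duplication spanning hundreds of bases is the
#'   shared body of adjacent element copies, not a target site duplication.
#' @return list with \code{sequence, left (start,end), right (start,end),
#'   length}, or \code{NULL} when no duplication is found.
#' @export
find_tsd <- function(genome, hit, flank = 200L, seed_k = 8L,
                     search_window = c(-30L, 15L), max_tsd_len = 40L) {
  s <- genome[[hit$chrom]]
  L <- nchar(s)
  hs <- hit$start; he <- hit$end
  cand_starts <- seq(max(0L, hs + search_window[1L]),
                     min(L - seed_k, hs + search_window[2L]))
  ## allow the same slack before the (approximate) hit end as after the
  ## hit start, so a right TSD clipped by an overshooting hit is still seen
  win_s <- max(he + search_window[1L] / 2L, hs + 50L)
  win_e <- min(L, he + flank)
  if (win_e - win_s < seed_k) return(NULL)
  right_region <- subseq0(s, win_s, win_e)
  best <- NULL
  seen <- character(0)
  for (p in cand_starts) {
    kmer <- subseq0(s, p, p + seed_k)
    if (grepl("N", kmer, fixed = TRUE)) next
    hits_r <- gregexpr(kmer, right_region, fixed = TRUE)[[1L]]
    if (hits_r[1L] == -1L) next
    for (q0 in hits_r) {
      q <- win_s + q0 - 1L                 # 0-based start of right copy
      ext <- extend_duplication(s, p, p + seed_k, q, q + seed_k)
      key <- paste(ext$lstart, ext$rstart)
      if (key %in% seen) next
      seen <- c(seen, key)
      dup <- subseq0(s, ext$lstart, ext$lend)
      if (grepl("N", dup, fixed = TRUE)) next
      ## an AAAA-bearing duplication is poly(A) tail, not a target site
      if (grepl("AAAA", dup, fixed = TRUE)) next
      len <- ext$lend - ext$lstart
      if (len > max_tsd_len) next
      if (is.null(best) || len > best$length ||
          (len == best$length && ext$lstart < best$left[1L])) {
        best <- list(sequence = dup,
                     left = c(start = ext$lstart, end = ext$lend),
                     right = c(start = ext$rstart, end = ext$rend),
                     length = len)
      }
    }
  }
  best
}

## grow an exact duplication (both copies jointly) while bases agree and
## the copies stay disjoint
extend_duplication <- function(s, lstart, lend, rstart, rend) {
  L <- nchar(s)
  while (lstart > 0L && rstart > lend &&
         substr(s, lstart, lstart) == substr(s, rstart, rstart)) {
    lstart <- lstart - 1L; rstart <- rstart - 1L
  }
  while (rend < L && lend < rstart &&
         substr(s, lend + 1L, lend + 1L) == substr(s, rend + 1L, rend + 1L)) {
    lend <- lend + 1L; rend <- rend + 1L
  }
  list(lstart = lstart, lend = lend, rstart = rstart, rend = rend)
}

#' Split an element interior into head-body and tail
#'
#' The boundary is the start of the first \code{AAAA} run at or after
#' \code{min_headbody}; when no \code{AAAA} exists, the first poly(A) run
#' (>= 6 A allowing one mismatch) after the conserved motif is used
#' (method \code{motif_fallback}); when neither fires the tail is empty and
#' the method is \code{none}.
#'
#' @param element_seq interior sequence of one element.
#' @param min_headbody earliest allowed boundary offset (prevents
#'   body-internal A runs from truncating the element).
#' @param motif conserved body motif used by the fallback.
#' @return list with 0-based half-open \code{headbody} and \code{tail}
#'   spans (relative to the element) and \code{method}.
#' @export
split_headbody_tail <- function(element_seq, min_headbody = 150L,
                                motif = "GGAGTTCCC") {
  n <- nchar(element_seq)
  boundary <- NA_integer_
  method <- "none"
  aaaa <- gregexpr("AAAA", element_seq, fixed = TRUE)[[1L]]
  aaaa <- aaaa[aaaa >= min_headbody + 1L]   # 1-based; offset >= min_headbody
  if (length(aaaa) && aaaa[1L] != -1L) {
    boundary <- aaaa[1L] - 1L
    method <- "aaaa"
  } else {
    mpos <- regexpr(motif, element_seq, fixed = TRUE)[1L]
    if (mpos != -1L) {
      pa <- find_polya(element_seq, from = mpos - 1L + nchar(motif))
      if (!is.na(pa)) {
        boundary <- pa
        method <- "motif_fallback"
      }
    }
  }
  if (is.na(boundary)) {
    return(list(headbody = c(start = 0L, end = n),
                tail = c(start = n, end = n), method = "none"))
  }
  list(headbody = c(start = 0L, end = boundary),
       tail = c(start = boundary, end = n), method = method)
}

## first run of >= 6 A allowing 1 mismatch, at or after 0-based `from`;
## returns the 0-based run start or NA
find_polya <- function(seq, from, run_len = 6L, max_mismatch = 1L) {
  ch <- seq_chars(seq)
  n <- length(ch)
  for (i in seq(from + 1L, n - run_len + 1L)) {
    if (i < 1L) next
    if (sum(ch[i:(i + run_len - 1L)] != "A") <= max_mismatch &&
        ch[i] == "A") {
      return(i - 1L)
    }
  }
  NA_integer_
}

## extend an A-dominated run from 0-based `from`: the end is the farthest
## position (up to max_len) where the stretch still ends on an A and keeps
## a cumulative A fraction >= min_frac; robust to scattered contamination
find_tail_end <- function(seq, from, max_len = 60L, min_frac = 0.8) {
  ch <- seq_chars(seq)
  n <- length(ch)
  hi <- min(n, from + max_len)
  if (from + 1L > hi) return(from)
  isA <- ch[(from + 1L):hi] == "A"
  frac <- cumsum(isA) / seq_along(isA)
  ok <- which(isA & frac >= min_frac)
  if (!length(ok)) return(from)
  from + max(ok)
}

#' Calibrate one raw hit into an exact element
#'
#' When a TSD is found, the element interior is the span between the two
#' TSD copies; otherwise the conserved-motif/poly(A) fallback fixes the 3'
#' boundary and the raw hit start is kept as the 5' boundary.  The interior
#' is then split into head-body and tail and the length class assigned
#' (class I: head-body in \[210, 260\]; class II: \[165, 209\]).
#'
#' @inheritParams find_tsd
#' @param min_headbody,motif forwarded to [split_headbody_tail()].
#' @return one-row \code{data.table} (a calibrated element), or \code{NULL}
#'   with attribute-free rejection when the span is shorter than 50 bp.
#' @export
calibrate <- function(genome, hit, flank = 200L, seed_k = 8L,
                      search_window = c(-30L, 15L), max_tsd_len = 40L,
                      min_headbody = 150L, motif = "GGAGTTCCC") {
  tsd <- find_tsd(genome, hit, flank, seed_k, search_window, max_tsd_len)
  s <- genome[[hit$chrom]]
  if (!is.null(tsd)) {
    full <- c(tsd$left[["end"]], tsd$right[["start"]])
    method <- "tsd"
  } else {
    start <- hit$start
    sp <- split_headbody_tail(subseq0(s, start, min(nchar(s),
                                                    hit$end + flank)),
                              min_headbody, motif)
    if (sp$method == "none") {
      full <- c(start, hit$end)
    } else {
      tail_end <- find_tail_end(subseq0(s, start, nchar(s)),
                                sp$tail[["start"]])
      full <- c(start, start + tail_end)
    }
    method <- "motif_fallback"
  }
  if (full[2L] - full[1L] < 50L) {
    return(NULL)
  }
  interior <- subseq0(s, full[1L], full[2L])
  sp <- split_headbody_tail(interior, min_headbody, motif)
  hb_len <- sp$headbody[["end"]] - sp$headbody[["start"]]
  class <- if (hb_len >= 210L && hb_len <= 260L) "I"
           else if (hb_len >= 165L && hb_len <= 209L) "II"
           else "other"
  data.table::data.table(
    chrom = hit$chrom, start = full[1L], end = full[2L],
    strand = if (!is.null(hit$strand)) hit$strand else "+",
    tsd_seq = if (is.null(tsd)) NA_character_ else tsd$sequence,
    tsd_len = if (is.null(tsd)) 0L else tsd$length,
    tsd_left_start = if (is.null(tsd)) NA_integer_ else tsd$left[["start"]],
    tsd_right_end = if (is.null(tsd)) NA_integer_ else tsd$right[["end"]],
    headbody_start = full[1L] + sp$headbody[["start"]],
    headbody_end = full[1L] + sp$headbody[["end"]],
    tail_start = full[1L] + sp$tail[["start"]],
    tail_end = full[1L] + sp$tail[["end"]],
    headbody_len = hb_len,
    tail_len = sp$tail[["end"]] - sp$tail[["start"]],
    class = class, method = method
  )
}

#' Calibrate a set of raw hits
#'
#' @param genome named character vector.
#' @param hits data.frame of raw hits (\code{chrom, start, end}, optional
#'   \code{strand}), e.g. from [scan_hits()] or [read_bed()].
#' @param ... forwarded to [calibrate()].
#' @return \code{data.table} of calibrated elements with
#'   \code{element_id}; rejected hits are counted in the
#'   \code{n_rejected} attribute.
#' @export
calibrate_elements <- function(genome, hits, ...) {
  rows <- list()
  n_rejected <- 0L
  for (i in seq_len(nrow(hits))) {
    el <- calibrate(genome, as.list(hits[i, ]), ...)
    if (is.null(el)) n_rejected <- n_rejected + 1L else {
      rows[[length(rows) + 1L]] <- el
    }
  }
  out <- data.table::rbindlist(rows)
  if (nrow(out)) {
    data.table::setorder(out, chrom, start)
    out[, element_id := sprintf("el%04d", .I)]
    data.table::setcolorder(out, "element_id")
    out[, tandem_group := NA_character_]
    out[, nested_parent := NA_character_]
  }
  data.table::setattr(out, "n_rejected", n_rejected)
  out[]
}

#' Flag tandem groups and nested elements
#'
#' Tandem groups are maximal runs of same-chromosome elements separated by
#' at most \code{max_gap} bp that share one outer TSD pair (verified by
#' running the TSD search over the merged span).  An element whose span
#' lies strictly inside another's is flagged with its \code{nested_parent}.
#' The result is independent of input row order.
#'
#' @param elements calibrated elements ([calibrate_elements()]).
#' @param genome named character vector (for the outer-TSD check).
#' @param max_gap maximum gap between tandem members (bp).
#' @param ... forwarded to [find_tsd()] for the outer-TSD check.
#' @return the elements table with \code{tandem_group} and
#'   \code{nested_parent} filled in.
#' @export
detect_structures <- function(elements, genome, max_gap = 10L, ...) {
  el <- data.table::copy(data.table::as.data.table(elements))
  data.table::setorder(el, chrom, start, end)
  el[, tandem_group := NA_character_]
  el[, nested_parent := NA_character_]
  ## nested: strict containment
  for (i in seq_len(nrow(el))) {
    inside <- which(el$chrom == el$chrom[i] &
                    el$start < el$start[i] & el$end > el$end[i])
    if (length(inside)) {
      ## the smallest containing element is the parent
      j <- inside[which.min(el$end[inside] - el$start[inside])]
      el$nested_parent[i] <- el$element_id[j]
    }
  }
  ## tandem: runs of non-nested elements with small gaps + shared outer TSD
  gid <- 0L
  top <- which(is.na(el$nested_parent))
  for (chrom in unique(el$chrom)) {
    idx <- top[el$chrom[top] == chrom]
    if (length(idx) < 2L) next
    ## boundary noise can make members abut or slightly overlap; the
    ## shared-outer-TSD check below is what actually gates a group
    gap_ok <- el$start[idx[-1L]] - el$end[idx[-length(idx)]] <= max_gap
    run_id <- cumsum(c(TRUE, !gap_ok))
    for (r in split(idx, run_id)) {
      if (length(r) < 2L) next
      merged <- list(chrom = chrom, start = min(el$start[r]),
                     end = max(el$end[r]))
      outer <- find_tsd(genome, merged, ...)
      if (!is.null(outer)) {
        gid <- gid + 1L
        el$tandem_group[r] <- sprintf("tg%03d", gid)
      }
    }
  }
  el[]
}

#' Categorize elements relative to genes
#'
#' Elements overlapping a gene span are \code{intragenic}; otherwise the
#' element midpoint is binned by its strand-aware distance upstream of the
#' nearest TSS: \code{< 1 kb} upstream, proximal (\code{[1, 2) kb}),
#' distal (\code{[2, 100] kb}), or \code{other}.
#'
#' @param elements calibrated elements (or any interval table with
#'   \code{element_id, chrom, start, end}).
#' @param annotation a \code{gene_annotation} feature table.
#' @return \code{data.table}: \code{element_id, category, nearest_gene,
#'   midpoint_distance}.
#' @export
position_annotation <- function(elements, annotation) {
  genes <- annotation[annotation$kind == "gene", ]
  out <- data.table::data.table(
    element_id = elements$element_id,
    category = "other", nearest_gene = NA_character_,
    midpoint_distance = NA_integer_
  )
  for (i in seq_len(nrow(elements))) {
    e <- elements[i, ]
    g <- genes[genes$chrom == e$chrom, ]
    if (!nrow(g)) next
    ov <- g$start < e$end & g$end > e$start
    if (any(ov)) {
      out$category[i] <- "intragenic"
      out$nearest_gene[i] <- g$gene_id[which(ov)[1L]]
      next
    }
    mid <- interval_midpoint(e$start, e$end)
    tss <- ifelse(g$strand == "-", g$end - 1L, g$start)
    d_up <- ifelse(g$strand == "-", mid - tss, tss - mid)
    up <- which(d_up > 0L)
    if (!length(up)) next
    j <- up[which.min(d_up[up])]
    d <- d_up[j]
    out$nearest_gene[i] <- g$gene_id[j]
    out$midpoint_distance[i] <- d
    out$category[i] <-
      if (d < 1000L) "upstream_lt1kb"
      else if (d < 2000L) "proximal"
      else if (d <= 100000L) "distal"
      else "other"
  }
  out[]
}
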