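## Synthetic genomes with implanted SINE copies and exact ground truth.

#' Generate an i.i.d. background genome
#'
#' @param length sequence length (>= 1).
#' @param gc_fraction target GC fraction in (0, 1).
#' @param seed integer seed.
#' @param name chromosome name.
#' @return named character vector of length 1 (the chromosome).
#' @export
generate_background <- function(length, gc_fraction = 0.42, seed = 1L,
                                name = "chr1") {
  stopifnot(length >= 1, gc_fraction > 0, gc_fraction < 1)
  with_seed(stage_seed(seed, "background"), {
    setNames(random_dna(length, gc_fraction), name)
  })
}

## poly(A) tail: starts with AAAA, then A with `contamination` non-A rate;
## rejected until overall A fraction >= 0.8
make_tail <- function(len, contamination = 0.1) {
  stopifnot(len >= 4L)
  repeat {
    rest <- sample(c("A", "C", "G", "T"), len - 4L, replace = TRUE,
                   prob = c(1 - contamination, rep(contamination / 3, 3)))
    tail_seq <- paste0("AAAA", paste(rest, collapse = ""))
    if (mean(seq_chars(tail_seq) == "A") >= 0.8) return(tail_seq)
  }
}

## TSD from background-like composition, constrained to contain no AAAA run
make_tsd <- function(len, gc) {
  repeat {
    s <- random_dna(len, gc)
    if (!grepl("AAAA", s, fixed = TRUE)) return(s)
  }
}

## apply point substitutions at a per-site rate; returns sequence and count
mutate_seq <- function(seq, sub_rate) {
  if (sub_rate <= 0) return(list(seq = seq, n_sub = 0L))
  ch <- seq_chars(seq)
  hit <- which(runif(length(ch)) < sub_rate)
  for (i in hit) ch[i] <- sample(setdiff(BASES, ch[i]), 1L)
  list(seq = paste(ch, collapse = ""), n_sub = length(hit))
}

## one element interior (mutated head-body + tail); class II via excision
make_interior <- function(consensus, spec, sub_rate, spliced,
                          tail_len_range, tail_contamination) {
  hb <- consensus
  if (spliced) {
    ds <- find_dual_sites(spec)
    hb <- excise_by_splice(hb, ds$donor[1L], ds$acceptor[1L])
  }
  mut <- mutate_seq(hb, sub_rate)
  tail_len <- sample(seq(tail_len_range[1L], tail_len_range[2L]), 1L)
  tail_seq <- make_tail(tail_len, tail_contamination)
  list(
    seq = paste0(mut$seq, tail_seq),
    hb_len = nchar(mut$seq), tail_len = tail_len,
    n_sub = mut$n_sub, class = if (spliced) "II" else "I"
  )
}

#' Implant SINE copies into a background genome
#'
#' Each implant is TSD + mutated head-body + poly(A) tail + TSD at a
#' uniformly chosen non-overlapping site.  With probability
#' \code{spliced_prob} the head-body first loses the inter-site segment
#' between the dual-function splice sites (class II); with
#' \code{tandem_prob} two elements share one outer TSD pair; with
#' \code{nested_prob} a complete second element (with its own TSD pair) is
#' inserted into the host's tail.  The two background bases flanking each
#' implanted block are forced to differ from the adjacent interior bases so
#' that the implanted TSD is the maximal exact duplication, as for a real
#' insertion into unrelated sequence.
#'
#' @param background named character vector (one chromosome), from
#'   [generate_background()].
#' @param consensus head-body consensus string from [build_consensus()].
#' @param n number of elements to implant.
#' @param spec the [consensus_spec()] used to build \code{consensus}.
#' @param tsd_len_range integer range of TSD lengths (bp).
#' @param tail_len_range integer range of poly(A) tail lengths (bp).
#' @param sub_rate per-site substitution rate applied to the head-body.
#' @param tandem_prob,nested_prob,spliced_prob structural variant rates.
#' @param tail_contamination non-A rate inside tails (first 4 bases kept A).
#' @param min_gap minimum background gap between implanted blocks (bp).
#' @param seed integer seed.
#' @return list with \code{genome} (named character vector) and
#'   \code{truth} (\code{data.table}, one row per element; coordinates
#'   0-based half-open; the interior span excludes the TSD copies).
#' @export
implant_elements <- function(background, consensus, n,
                             spec = consensus_spec(),
                             tsd_len_range = c(8L, 20L),
                             tail_len_range = c(10L, 50L),
                             sub_rate = 0.02,
                             tandem_prob = 0.05, nested_prob = 0.05,
                             spliced_prob = 0.15,
                             tail_contamination = 0.1,
                             min_gap = 200L, seed = 1L) {
  stopifnot(length(background) == 1L)
  if (tsd_len_range[1L] > tsd_len_range[2L] ||
      tail_len_range[1L] > tail_len_range[2L]) {
    stop("inverted length range")
  }
  chrom <- names(background) %||% "chr1"
  bg <- seq_chars(background[[1L]])
  bg_len <- length(bg)
  gc_bg <- mean(bg %in% c("C", "G"))
  max_span <- 2L * tsd_len_range[2L] +
    2L * (spec$total_len + tail_len_range[2L]) + 4L * tsd_len_range[2L]
  if (n * max_span >= bg_len / 2) {
    stop("background too short for ", n, " implants")
  }

  with_seed(stage_seed(seed, "implant"), {
    ## -- build blocks ----------------------------------------------------
    blocks <- list()     # each: list(seq, elements = list of relative truth)
    i <- 1L
    next_group <- 1L
    while (i <= n) {
      tsd_len <- sample(seq(tsd_len_range[1L], tsd_len_range[2L]), 1L)
      tsd <- make_tsd(tsd_len, gc_bg)
      kind <- sample(c("tandem", "nested", "plain"), 1L,
                     prob = c(tandem_prob, nested_prob,
                              max(0, 1 - tandem_prob - nested_prob)))
      spliced1 <- runif(1) < spliced_prob
      int1 <- make_interior(consensus, spec, sub_rate, spliced1,
                            tail_len_range, tail_contamination)
      if (kind == "tandem" && i < n) {
        int2 <- make_interior(consensus, spec, sub_rate,
                              runif(1) < spliced_prob,
                              tail_len_range, tail_contamination)
        seq <- paste0(tsd, int1$seq, int2$seq, tsd)
        els <- list(
          c(int1, list(rel_start = tsd_len, tsd = tsd,
                       tandem_group = next_group, nested_parent = NA)),
          c(int2, list(rel_start = tsd_len + nchar(int1$seq), tsd = tsd,
                       tandem_group = next_group, nested_parent = NA))
        )
        next_group <- next_group + 1L
        i <- i + 2L
      } else if (kind == "nested" && i < n) {
        inner_tsd_len <- sample(seq(tsd_len_range[1L], tsd_len_range[2L]), 1L)
        inner_tsd <- make_tsd(inner_tsd_len, gc_bg)
        int_in <- make_interior(consensus, spec, sub_rate,
                                runif(1) < spliced_prob,
                                tail_len_range, tail_contamination)
        inner_block <- paste0(inner_tsd, int_in$seq, inner_tsd)
        ## insert into the host tail, at least 4 nt into it (keeps the
        ## host's AAAA tail anchor intact)
        host_tail_start <- int1$hb_len
        k <- host_tail_start + sample(4:int1$tail_len, 1L)
        host_seq <- int1$seq
        ## flank-base guards for the inner TSD (see note in @description)
        first_in <- substr(int_in$seq, 1L, 1L)
        last_in <- substr(int_in$seq, nchar(int_in$seq), nchar(int_in$seq))
        lguard <- substr(host_seq, k, k)
        if (lguard == last_in) {
          substr(host_seq, k, k) <- setdiff(c("C", "G", "T"), last_in)[1L]
        }
        rguard <- substr(host_seq, k + 1L, k + 1L)
        if (rguard == first_in) {
          substr(host_seq, k + 1L, k + 1L) <-
            setdiff(c("C", "G", "T"), first_in)[1L]
        }
        seq_host <- paste0(substr(host_seq, 1L, k), inner_block,
                           substr(host_seq, k + 1L, nchar(host_seq)))
        seq <- paste0(tsd, seq_host, tsd)
        host <- utils::modifyList(
          int1, list(seq = seq_host)
        )
        els <- list(
          c(host, list(rel_start = tsd_len, tsd = tsd,
                       tandem_group = NA, nested_parent = NA)),
          c(int_in, list(rel_start = tsd_len + k + inner_tsd_len,
                         tsd = inner_tsd,
                         tandem_group = NA, nested_parent = 0L))
        )
        i <- i + 2L
      } else {
        seq <- paste0(tsd, int1$seq, tsd)
        els <- list(c(int1, list(rel_start = tsd_len, tsd = tsd,
                                 tandem_group = NA, nested_parent = NA)))
        i <- i + 1L
      }
      blocks[[length(blocks) + 1L]] <- list(seq = seq, elements = els)
    }

    ## -- place blocks ----------------------------------------------------
    lens <- vapply(blocks, function(b) nchar(b$seq), integer(1L))
    placed <- place_non_overlapping(bg_len, lens, min_gap)
    ord <- order(placed)
    blocks <- blocks[ord]
    placed <- placed[ord]
    lens <- lens[ord]

    ## -- assemble genome and truth ---------------------------------------
    out_parts <- character(0)
    truth_rows <- list()
    cursor <- 0L            # 0-based position consumed in background
    eid <- 0L
    for (b in seq_along(blocks)) {
      at <- placed[b]
      blk <- blocks[[b]]
      pre <- bg[seq_len(at - cursor) + cursor]   # background [cursor, at)
      ## maximality guards: background base before/after the block must
      ## differ from the adjacent interior base
      interior_first <- substr(blk$seq, nchar(blk$elements[[1L]]$tsd) + 1L,
                               nchar(blk$elements[[1L]]$tsd) + 1L)
      last_el <- blk$elements[[length(blk$elements)]]
      tsd_last <- blk$elements[[1L]]$tsd  # outer TSD is always the first one
      interior_last <- substr(blk$seq, nchar(blk$seq) - nchar(tsd_last),
                              nchar(blk$seq) - nchar(tsd_last))
      if (length(pre) && pre[length(pre)] == interior_last) {
        pre[length(pre)] <- setdiff(c("C", "G", "T"), interior_last)[1L]
      }
      out_parts <- c(out_parts, paste(pre, collapse = ""), blk$seq)
      cursor <- at
      ## the block sits between bg[at] and bg[at + 1]; force the base after
      ## the block to differ from the first interior base
      if (at + 1L <= bg_len && bg[at + 1L] == interior_first) {
        bg[at + 1L] <- setdiff(c("C", "G", "T"), interior_first)[1L]
      }
      for (e in blk$elements) {
        eid <- eid + 1L
        truth_rows[[eid]] <- data.table::data.table(
          element_id = NA_character_, block = b,
          rel_start = e$rel_start, len = nchar(e$seq),
          hb_len = e$hb_len, tail_len = e$tail_len,
          class = e$class, tsd_seq = e$tsd, tsd_len = nchar(e$tsd),
          tandem_group = e$tandem_group,
          nested_parent_rel = e$nested_parent,
          n_sub = e$n_sub, spliced = e$class == "II", seq = e$seq
        )
      }
    }
    out_parts <- c(out_parts, paste(bg[seq(cursor + 1L, bg_len)],
                                    collapse = ""))
    genome_seq <- paste(out_parts, collapse = "")

    ## absolute block starts: offset accumulated from placements
    offs <- cumsum(c(0L, lens))[seq_along(lens)]  # inserted bases before blk
    abs_start <- placed + offs                     # 0-based start of block
    truth <- data.table::rbindlist(truth_rows)
    truth[, start := abs_start[block] + rel_start]
    truth[, end := start + len]
    truth[, chrom := chrom]
    truth[, strand := "+"]
    truth[, element_id := sprintf("el%04d", .I)]
    ## resolve nested parent ids (parent is the previous row in same block)
    truth[, nested_parent := NA_character_]
    for (r in which(!is.na(truth$nested_parent_rel))) {
      truth$nested_parent[r] <- truth$element_id[r - 1L]
    }
    truth[, tandem_group := ifelse(is.na(tandem_group), NA_character_,
                                   sprintf("tg%03d", tandem_group))]
    truth[, `:=`(
      tsd_left_start = start - tsd_len, tsd_left_end = start,
      tsd_right_start = end, tsd_right_end = end + tsd_len,
      headbody_start = start, headbody_end = start + hb_len,
      tail_start = start + hb_len, tail_end = end
    )]
    ## tandem members share one *outer* TSD pair
    if (any(!is.na(truth$tandem_group))) {
      truth[!is.na(tandem_group), `:=`(
        tsd_left_start = min(start) - tsd_len,
        tsd_left_end = min(start),
        tsd_right_start = max(end),
        tsd_right_end = max(end) + tsd_len
      ), by = tandem_group]
    }
    ## nested inner elements: the host's recorded span contains the inner
    ## block, and its tail_end is its own end
    truth[, c("block", "rel_start", "len", "nested_parent_rel") := NULL]
    data.table::setcolorder(truth, c("element_id", "chrom", "start", "end",
                                     "strand", "class"))
    list(genome = setNames(genome_seq, chrom), truth = truth[])
  })
}

## choose non-overlapping 0-based insertion points (between bg[at] and
## bg[at+1]) for blocks of given lengths, with at least min_gap background
## bases between blocks and a min_gap margin at both chromosome ends
place_non_overlapping <- function(bg_len, lens, min_gap) {
  n <- length(lens)
  ## order-statistics construction: sample n points in the slack space and
  ## re-add the mandatory spacing, giving uniform spacings >= min_gap
  avail <- bg_len - 2L * min_gap - (n - 1L) * min_gap
  if (avail < n) stop("could not place implants without overlap")
  u <- sort(sample.int(avail, n))
  min_gap + u + (seq_len(n) - 1L) * min_gap
}
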