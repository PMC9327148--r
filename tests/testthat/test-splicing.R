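## hand-built annotation pieces used by the selection/marking tests
ann_row <- function(gene, kind, start, end, strand = "+",
                    tid = paste0(gene, ".t1")) {
  data.table::data.table(gene_id = gene, transcript_id = tid,
                         chrom = "chr1", start = start, end = end,
                         strand = strand, kind = kind)
}

test_that("select_cds_partial_overlaps applies all three filter rules", {
  el <- data.table::data.table(
    element_id = c("in_intron", "cds_ok", "utr_hit"),
    chrom = "chr1",
    start = c(1000L, 5000L, 9000L),
    end = c(1300L, 5300L, 9300L)
  )
  ann <- rbind(
    ## element fully inside an intron: exons at 800-950 and 1500-1700
    ann_row("g1", "exon", 800L, 950L), ann_row("g1", "exon", 1500L, 1700L),
    ann_row("g1", "CDS", 800L, 950L),
    ## exon start inside the element, CDS overlap only
    ann_row("g2", "exon", 5100L, 5600L), ann_row("g2", "CDS", 5100L, 5600L),
    ## exon boundary inside but also overlapping a 3' UTR
    ann_row("g3", "exon", 9100L, 9600L), ann_row("g3", "CDS", 9100L, 9400L),
    ann_row("g3", "three_prime_utr", 9100L, 9200L)
  )
  sel <- select_cds_partial_overlaps(el, ann)
  expect_equal(sel$element_id, "cds_ok")
})

test_that("mark_splice_signals classifies donors, acceptors and strand", {
  set.seed(12)
  left <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  ## + strand: exon ends at 100 followed by GT; exon starts at 140
  ## preceded by AG; - strand acceptor: exon ends at 180 followed by CT
  g <- setNames(paste0(
    substr(left, 1, 100), "GT",
    strrep("C", 36), "AG",
    strrep("G", 40), "CT", strrep("A", 3), "CC", strrep("G", 60)), "chr1")
  el <- data.table::data.table(element_id = "e1", chrom = "chr1",
                               start = 50L, end = 230L, strand = "+")
  ann <- rbind(
    ann_row("gp", "exon", 20L, 100L),            # donor at 100, GT follows
    ann_row("gp", "exon", 140L, 200L),           # acceptor at 140, AG before
    ann_row("gm", "exon", 150L, 180L, strand = "-"),  # - acceptor at 180
    ann_row("gnc", "exon", 10L, 185L)            # boundary at 185, no GT
  )
  sig <- mark_splice_signals(el, ann, g)
  expect_equal(sig$kind[sig$pos == 100], "5")
  expect_equal(sig$kind[sig$pos == 140], "3")
  expect_equal(sig$kind[sig$pos == 180 & sig$transcript_id == "gm.t1"], "T")
  expect_equal(sig$kind[sig$transcript_id == "gnc.t1"], "5nc")
  ## offsets are measured from the element 5' end
  expect_equal(sig$element_offset[sig$pos == 100], 50L)
  ## non-canonical signals excluded from profiles by default
  sig$consensus_pos <- sig$element_offset + 1L
  prof <- signal_profile(sig, window = c(1L, 200L))
  expect_equal(prof$n_signals, 3L)
})

test_that("project_to_consensus translates offsets through the alignment", {
  cons <- fx_consensus()
  ## unmutated element: consensus_pos = offset + 1
  expect_equal(project_to_consensus(c(0L, 132L, 230L), cons, cons),
               c(1L, 133L, 231L))
  ## 3-nt deletion 5' of the signal shifts the projection by +3
  del <- paste0(substr(cons, 1, 50), substr(cons, 54, 231))
  expect_equal(project_to_consensus(129L, del, cons), 133L)
  ## an element-only insertion maps onto the next consensus column 3'
  ins <- paste0(substr(cons, 1, 100), "TTTT", substr(cons, 101, 231))
  expect_equal(project_to_consensus(c(101L, 102L), ins, cons),
               c(101L, 101L))
  ## too-diverged elements are dropped with a warning
  set.seed(13)
  junk <- paste(sample(c("A", "C", "G", "T"), 231, TRUE), collapse = "")
  expect_warning(out <- project_to_consensus(10L, junk, cons), "diverged")
  expect_true(is.na(out))
})

test_that("signal_profile counts within the window", {
  prof <- signal_profile(rep(120L, 7), window = c(110L, 202L))
  expect_equal(unname(prof$counts[as.character(120)]), 7L)
  expect_equal(prof$n_signals, 7L)
  expect_equal(sum(prof$counts), prof$n_signals)

  expect_equal(signal_profile(integer(0))$n_signals, 0L)

  ## edge positions included, one past the edge excluded
  prof <- signal_profile(c(110L, 202L, 203L, 109L), window = c(110L, 202L))
  expect_equal(prof$n_signals, 2L)
})

test_that("null_threshold reproduces the printed threshold", {
  nt <- null_threshold(n_positions = 93L, n_signals = 188L, reps = 10000L,
                       alpha = 0.01, seed = 1L)
  expect_equal(nt$k, 6L)
  expect_lte(nt$tail_prob_at_k, 0.01)
})

test_that("null_threshold matches the exact binomial on a tiny case", {
  ## 2 signals on 2 positions: count ~ Binomial(2, 1/2);
  ## P(>0) = 0.75 > 0.5, P(>1) = 0.25 <= 0.5 -> k = 1
  nt <- null_threshold(n_positions = 2L, n_signals = 2L, reps = 40000L,
                       alpha = 0.5, seed = 2L)
  expect_equal(nt$k, 1L)
  expect_lt(abs(nt$tail_prob_at_k - 0.25), 3 * sqrt(0.25 * 0.75 / 80000))
})

test_that("pooled null counts follow Binomial(n_signals, 1/n_positions)", {
  nt <- null_threshold(reps = 10000L, seed = 3L)
  obs <- nt$pooled_counts * nt$reps * nt$n_positions
  kmax <- length(obs) - 1L
  expected <- stats::dbinom(0:kmax, nt$n_signals, 1 / nt$n_positions)
  expected[kmax + 1L] <- expected[kmax + 1L] +
    stats::pbinom(kmax, nt$n_signals, 1 / nt$n_positions,
                  lower.tail = FALSE)
  expected <- expected * sum(obs)
  keep <- expected >= 5
  chi2 <- sum((obs[keep] - expected[keep])^2 / expected[keep])
  p <- stats::pchisq(chi2, df = sum(keep) - 1L, lower.tail = FALSE)
  expect_gt(p, 0.001)
})

test_that("hot_sites applies strict and inclusive rules", {
  prof <- structure(list(window = c(1L, 40L),
                         counts = setNames(rep(0L, 40), 1:40),
                         n_signals = 15L), class = "splice_profile")
  prof$counts[c("10", "20", "30")] <- c(7L, 6L, 2L)
  expect_equal(hot_sites(prof, 6L), 10L)
  expect_equal(hot_sites(prof, 6L, inclusive = TRUE), c(10L, 20L))
  prof$counts[] <- 0L
  expect_equal(length(hot_sites(prof, 6L)), 0L)
})

test_that("find_dual_sites pairs adjacent repeat copies", {
  ds <- find_dual_sites(fx_spec())
  expect_equal(nrow(ds), 1L)
  expect_equal(ds$acceptor - ds$donor, 46L)
  ## three repeats: two adjacent pairings (three with all_pairs)
  spec3 <- consensus_spec(n_repeats = 3L, body3_len = 29L)
  expect_equal(nrow(find_dual_sites(spec3)), 2L)
  expect_equal(nrow(find_dual_sites(spec3, all_pairs = TRUE)), 3L)
  expect_error(find_dual_sites(consensus_spec(n_repeats = 1L)), ">= 2")
})

test_that("excise_by_splice implements the GT-AG rule exactly", {
  spec <- fx_spec()
  cons <- fx_consensus()
  ds <- find_dual_sites(spec)
  prod <- excise_by_splice(cons, ds$donor[1], ds$acceptor[1],
                           check_branch = TRUE)
  expect_equal(nchar(prod), 185L)
  ## flanks conserved byte-exactly outside [donor, acceptor)
  expect_identical(substr(prod, 1, ds$donor[1]),
                   substr(cons, 1, ds$donor[1]))
  expect_identical(substr(prod, ds$donor[1] + 1, nchar(prod)),
                   substr(cons, ds$acceptor[1] + 1, nchar(cons)))
  ## the product is the F/R chimera: F up to the dual site, R after it
  f <- substr(cons, spec$head_len + 1, spec$head_len + 46)
  r <- substr(cons, spec$head_len + 47, spec$head_len + 92)
  chimera <- paste0(substr(f, 1, spec$aggt_offset + 2),
                    substr(r, spec$aggt_offset + 3, 46))
  expect_identical(substr(prod, spec$head_len + 1, spec$head_len + 46),
                   chimera)

  expect_error(excise_by_splice(cons, ds$donor[1] + 1, ds$acceptor[1]),
               "GT")
  expect_error(excise_by_splice(cons, ds$donor[1], ds$acceptor[1] + 3),
               "AG")
  expect_error(excise_by_splice(cons, ds$acceptor[1], ds$donor[1]), "5'")
})

test_that("tandem-transcript excision yields a quasi-oligomer", {
  spec <- fx_spec()
  cons <- fx_consensus()
  hb2 <- paste0(cons, cons)          # two-element transcript (head-bodies)
  ## donor in element 1's R copy, acceptor in element 2's F copy
  donor1 <- spec$head_len + spec$repeat_unit_len + spec$aggt_offset + 2L
  acceptor2 <- 231L + spec$head_len + spec$aggt_offset + 2L
  prod <- excise_by_splice(hb2, donor1, acceptor2)
  ## exact length bookkeeping: one repeat unit is gained over a monomer
  expect_equal(nchar(prod), 2L * 231L - (acceptor2 - donor1))
  expect_equal(nchar(prod), 231L + 46L)
  ## the product carries three tandem identical repeat copies
  u <- substr(cons, spec$head_len + 1, spec$head_len + 46)
  expect_identical(substr(prod, spec$head_len + 1, spec$head_len + 138),
                   strrep(u, 3))
})

test_that("signals concentrated at the dual sites become the hot sites", {
  cons <- fx_consensus()
  spec <- fx_spec()
  bg <- generate_background(300000L, 0.42, seed = 51L)
  imp <- implant_elements(bg, cons, n = 40L, spec = spec, sub_rate = 0.005,
                          tandem_prob = 0, nested_prob = 0,
                          spliced_prob = 0, seed = 52L)
  ann <- synthesize_annotation(imp$genome, imp$truth, n_genes = 30L,
                               exon_in_element_prob = 0.85,
                               proximal_frac = 0.05, distal_frac = 0.05,
                               spec = spec, seed = 53L)
  el <- calibrate_elements(imp$genome,
                           imp$truth[, c("chrom", "start", "end")])
  sel <- select_cds_partial_overlaps(el, ann)
  sig <- mark_splice_signals(sel, ann, imp$genome)
  sig$consensus_pos <- NA_integer_
  for (eid in unique(sig$element_id)) {
    e <- el[el$element_id == eid, ]
    hb <- substr(imp$genome[[1]], e$headbody_start + 1, e$headbody_end)
    idx <- which(sig$element_id == eid)
    off <- sig$element_offset[idx] - (e$headbody_start - e$start)
    sig$consensus_pos[idx] <- project_to_consensus(off, hb, cons)
  }
  prof <- signal_profile(sig)
  nt <- null_threshold(reps = 2000L, seed = 54L)
  hs <- hot_sites(prof, nt)
  ds <- find_dual_sites(spec)
  expect_setequal(hs, c(ds$donor[1] + 1L, ds$acceptor[1] + 1L))
})
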