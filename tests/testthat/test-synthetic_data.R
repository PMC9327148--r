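test_that("build_consensus obeys the structural contract", {
  spec <- fx_spec()
  cons <- build_consensus(spec, seed = 1L)
  expect_equal(nchar(cons), 231L)
  ## F and R copies are identical and 46 nt apart
  f <- substr(cons, spec$head_len + 1, spec$head_len + 46)
  r <- substr(cons, spec$head_len + 47, spec$head_len + 92)
  expect_identical(f, r)
  ## conserved motif occurs exactly once; no AAAA anywhere
  expect_equal(lengths(regmatches(cons, gregexpr("GGAGTTCCC", cons))), 1L)
  expect_false(grepl("AAAA", cons))
  ## dual site AGGT at the stated offset in each repeat copy
  expect_identical(substr(cons, spec$head_len + 21, spec$head_len + 24),
                   "AGGT")
  expect_identical(substr(cons, spec$head_len + 67, spec$head_len + 70),
                   "AGGT")
  ## deterministic
  expect_identical(cons, build_consensus(spec, seed = 1L))
  expect_false(identical(cons, build_consensus(spec, seed = 2L)))
})

test_that("consensus_spec rejects colliding placements", {
  expect_error(consensus_spec(aggt_offset = 33L), "collides")
  expect_error(consensus_spec(motif_offset = 25L), "collides")
})

test_that("generate_background matches its GC target", {
  bg <- generate_background(10000L, 0.4, seed = 1L)
  gc <- mean(strsplit(bg[[1]], "")[[1]] %in% c("C", "G"))
  se <- sqrt(0.4 * 0.6 / 10000)
  expect_lt(abs(gc - 0.4), 3 * se)
  expect_equal(nchar(generate_background(1L, 0.5, seed = 1L)[[1]]), 1L)
  expect_false(identical(generate_background(1000L, 0.5, seed = 1L),
                         generate_background(1000L, 0.5, seed = 2L)))
})

test_that("implant truth is byte-exact and classes follow splicing", {
  cons <- fx_consensus()
  bg <- generate_background(60000L, 0.42, seed = 10L)
  imp <- implant_elements(bg, cons, n = 8L, spec = fx_spec(),
                          sub_rate = 0, tandem_prob = 0, nested_prob = 0,
                          spliced_prob = 0, seed = 11L)
  g <- imp$genome[[1]]
  tr <- imp$truth
  expect_true(all(tr$class == "I"))
  expect_true(all(tr$headbody_end - tr$headbody_start == 231L))
  ## re-extracting truth spans reproduces the element byte-exactly
  for (i in seq_len(nrow(tr))) {
    expect_identical(substr(g, tr$start[i] + 1, tr$end[i]), tr$seq[i])
    expect_identical(substr(g, tr$tsd_left_start[i] + 1, tr$tsd_left_end[i]),
                     tr$tsd_seq[i])
    expect_identical(substr(g, tr$tsd_right_start[i] + 1,
                            tr$tsd_right_end[i]), tr$tsd_seq[i])
  }
  ## tails are A-rich
  tails <- substring(g, tr$tail_start + 1, tr$tail_end)
  a_frac <- vapply(strsplit(tails, ""), function(x) mean(x == "A"),
                   numeric(1))
  expect_true(all(a_frac >= 0.8))
  ## determinism
  imp2 <- implant_elements(bg, cons, n = 8L, spec = fx_spec(),
                           sub_rate = 0, tandem_prob = 0, nested_prob = 0,
                           spliced_prob = 0, seed = 11L)
  expect_identical(imp$genome, imp2$genome)
  expect_equal(imp$truth, imp2$truth)
})

test_that("spliced implants are class II and match excise_by_splice", {
  cons <- fx_consensus()
  spec <- fx_spec()
  bg <- generate_background(40000L, 0.42, seed = 12L)
  imp <- implant_elements(bg, cons, n = 5L, spec = spec, sub_rate = 0,
                          tandem_prob = 0, nested_prob = 0,
                          spliced_prob = 1, seed = 13L)
  tr <- imp$truth
  expect_true(all(tr$class == "II"))
  expect_true(all(tr$headbody_end - tr$headbody_start == 185L))
  ## cross-module consistency: class II head-body equals the GT-AG
  ## excision product of the class I consensus
  ds <- find_dual_sites(spec)
  prod <- excise_by_splice(cons, ds$donor[1], ds$acceptor[1])
  g <- imp$genome[[1]]
  for (i in seq_len(nrow(tr))) {
    expect_identical(substr(g, tr$headbody_start[i] + 1, tr$headbody_end[i]),
                     prod)
  }
})

test_that("tandem implants share one outer TSD pair", {
  cons <- fx_consensus()
  bg <- generate_background(40000L, 0.42, seed = 14L)
  imp <- implant_elements(bg, cons, n = 2L, spec = fx_spec(), sub_rate = 0,
                          tandem_prob = 1, nested_prob = 0,
                          spliced_prob = 0, seed = 15L)
  tr <- imp$truth
  expect_equal(nrow(tr), 2L)
  expect_equal(length(unique(tr$tandem_group)), 1L)
  expect_false(any(is.na(tr$tandem_group)))
  g <- imp$genome[[1]]
  ## one shared TSD on the outer flanks only
  expect_identical(substr(g, tr$tsd_left_start[1] + 1, tr$tsd_left_end[1]),
                   tr$tsd_seq[1])
  expect_identical(substr(g, tr$tsd_right_start[2] + 1,
                          tr$tsd_right_end[2]), tr$tsd_seq[1])
  expect_equal(tr$tsd_left_start[1], tr$tsd_left_start[2])
  expect_equal(tr$tsd_right_end[1], tr$tsd_right_end[2])
  ## members are adjacent
  expect_equal(tr$start[2], tr$end[1])
})

test_that("implant rejects inverted ranges and oversized loads", {
  cons <- fx_consensus()
  bg <- generate_background(5000L, 0.42, seed = 1L)
  expect_error(implant_elements(bg, cons, n = 1L, tsd_len_range = c(20, 8)),
               "inverted")
  expect_error(implant_elements(bg, cons, n = 10L), "too short")
})

test_that("synthesized annotation respects element coupling", {
  w <- fx_world()
  ann <- w$annotation
  gt <- attr(ann, "gene_truth")
  expect_s3_class(ann, "gene_annotation")
  ## exonized genes: both intron boundaries inside the element, canonical
  ## GT / AG at the boundaries
  g <- w$genome[[1]]
  ex_genes <- gt$gene_id[gt$class == "exonized"]
  expect_gt(length(ex_genes), 0L)
  exons <- ann[ann$kind == "exon" & ann$gene_id %in% ex_genes, ]
  for (gid in ex_genes) {
    e <- w$truth[w$truth$element_id == gt$element_id[gt$gene_id == gid], ]
    ex <- exons[exons$gene_id == gid, ]
    donor <- min(ex$end)           # end of first exon
    acceptor <- max(ex$start)      # start of second exon
    expect_true(donor > e$start && donor < e$end)
    expect_true(acceptor > e$start && acceptor < e$end)
    expect_identical(substr(g, donor + 1, donor + 2), "GT")
    expect_identical(substr(g, acceptor - 1, acceptor), "AG")
  }
  ## proximal genes: the coupled element midpoint is 1-2 kb upstream
  pos <- position_annotation(w$truth, ann)
  prox <- gt[gt$class == "proximal" & !is.na(gt$element_id), ]
  expect_gt(nrow(prox), 0L)
  for (i in seq_len(nrow(prox))) {
    cat_i <- pos$category[pos$element_id == prox$element_id[i]]
    expect_equal(cat_i, "proximal")
  }
})

test_that("exon_in_element_prob = 0 places no exon boundary in elements", {
  w <- fx_world()
  ann <- synthesize_annotation(w$genome, w$truth, n_genes = 10L,
                               exon_in_element_prob = 0,
                               proximal_frac = 0.3, distal_frac = 0.2,
                               spec = fx_spec(), seed = 21L)
  exons <- ann[ann$kind == "exon", ]
  tr <- w$truth
  inside <- vapply(seq_len(nrow(exons)), function(r) {
    any(exons$start[r] > tr$start & exons$start[r] < tr$end) ||
      any(exons$end[r] > tr$start & exons$end[r] < tr$end)
  }, logical(1))
  expect_false(any(inside))
})

test_that("simulated methylomes have the stated moments", {
  w <- fx_world()
  ## law-of-large-numbers check: huge depth, no overdispersion or
  ## individual effects -> tissue means differ by ~ delta in DM elements
  me <- simulate_methylomes(w$genome, w$truth, w$annotation,
                            n_individuals = 2L,
                            depth_range = c(10000L, 10000L),
                            background_mean = 0.85,
                            dm_fraction = 1, delta = 0.4,
                            overdispersion = 0, indiv_sd = 0,
                            n_background_cpg = 0L, seed = 31L)
  expect_gt(nrow(me$dm_truth), 0L)
  em <- element_methylation(filter_cpgs(me$records, max_depth = 1e6),
                            w$truth)
  em <- merge(em, me$design, by = c("sample_id", "tissue"))
  for (eid in me$dm_truth$element_id) {
    d <- em[em$element_id == eid, ]
    diff <- mean(d$level[d$tissue == "muscle"]) -
      mean(d$level[d$tissue == "testis"])
    expect_lt(abs(diff - 0.4), 0.02)
  }
  ## delta = 0: no systematic difference
  me0 <- simulate_methylomes(w$genome, w$truth, w$annotation,
                             n_individuals = 2L,
                             depth_range = c(10000L, 10000L),
                             dm_fraction = 1, delta = 0,
                             overdispersion = 0, indiv_sd = 0,
                             n_background_cpg = 0L, seed = 32L)
  em0 <- element_methylation(filter_cpgs(me0$records, max_depth = 1e6),
                             w$truth)
  diffs <- tapply(em0$level, list(em0$element_id, em0$tissue), mean)
  expect_lt(max(abs(diffs[, "muscle"] - diffs[, "testis"])), 0.02)
  ## determinism and error contract
  me2 <- simulate_methylomes(w$genome, w$truth, w$annotation,
                             n_individuals = 2L,
                             depth_range = c(10000L, 10000L),
                             dm_fraction = 1, delta = 0.4,
                             overdispersion = 0, indiv_sd = 0,
                             n_background_cpg = 0L, seed = 31L)
  expect_equal(me$records, me2$records)
  expect_error(simulate_methylomes(w$genome, w$truth, w$annotation,
                                   background_mean = 0.3, delta = 0.4),
               "below 0")
})

test_that("expression coupling drives the Spearman sign", {
  w <- fx_world()
  me <- simulate_methylomes(w$genome, w$truth, w$annotation,
                            dm_fraction = 0.6, delta = 0.4,
                            overdispersion = 0.02, indiv_sd = 0.1,
                            depth_range = c(30L, 60L), seed = 33L)
  em <- element_methylation(filter_cpgs(me$records), w$truth)
  gt <- attr(w$annotation, "gene_truth")
  prox <- gt[gt$class == "proximal" & !is.na(gt$element_id), ]
  coupling <- data.frame(element_id = prox$element_id,
                         gene_id = prox$gene_id,
                         sign = rep(c("+", "-"), length.out = nrow(prox)))
  expr <- simulate_expression(w$annotation, em, coupling,
                              beta = 3, noise_sd = 1e-4, seed = 34L)
  corr <- correlate_expression(em, expr, coupling, p_threshold = 0.01)
  m <- merge(corr, coupling, by = c("element_id", "gene_id"))
  expect_true(all(sign(m$rho) == ifelse(m$sign.y == "+", 1, -1)))
  ## beta = 0: no coupling
  coupling0 <- transform(coupling, sign = "0")
  expr0 <- simulate_expression(w$annotation, em, coupling0,
                               beta = 0, noise_sd = 0.1, seed = 35L)
  corr0 <- correlate_expression(em, expr0, coupling0, p_threshold = 0.01)
  expect_true(all(is.na(corr0$sign)))
})
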