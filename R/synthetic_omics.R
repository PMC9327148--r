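## Paired-tissue beta-binomial methylomes and methylation-coupled
## expression, with ground truth.

#' Simulate paired-tissue methylomes over an implanted genome
#'
#' CpGs are all CG dinucleotides inside element interiors plus uniformly
#' sprinkled background CpGs.  Per CpG, sample and individual: depth is
#' uniform over \code{depth_range} and the methylated count beta-binomial
#' with mean \code{background_mean} on the logit scale shifted by a
#' per-individual random effect (the paired structure); for
#' differentially methylated (DM) elements the mean drops by \code{delta}
#' in the hypomethylated tissue (the second of \code{tissues}).  DM
#' elements are drawn from elements proximal to a gene.
#'
#' @param genome named character vector.
#' @param truth implant truth table.
#' @param annotation feature table (to determine proximal elements).
#' @param n_individuals number of paired individuals.
#' @param tissues length-2 character; the second tissue is hypomethylated
#'   in DM elements.
#' @param depth_range integer depth range (uniform).
#' @param background_mean methylation mean of the hypermethylated
#'   background.
#' @param dm_fraction fraction of proximal elements made DM.
#' @param delta methylation difference of DM elements between tissues.
#' @param overdispersion beta-binomial overdispersion rho in [0, 1).
#' @param indiv_sd sd of the per-individual random effect (logit scale).
#' @param n_background_cpg number of background (non-element) CpGs.
#' @param seed integer seed.
#' @return list: \code{records} (combined methylation records),
#'   \code{design} (\code{sample_id, individual, tissue}),
#'   \code{dm_truth} (\code{element_id, delta} signed as tissue1 -
#'   tissue2), \code{proximal} (element ids).
#' @export
simulate_methylomes <- function(genome, truth, annotation,
                                n_individuals = 8L,
                                tissues = c("muscle", "testis"),
                                depth_range = c(10L, 60L),
                                background_mean = 0.85,
                                dm_fraction = 0.3, delta = 0.4,
                                overdispersion = 0.05, indiv_sd = 0.2,
                                n_background_cpg = 200L, seed = 1L) {
  if (background_mean - delta < 0) stop("background_mean - delta below 0")
  stopifnot(delta >= 0, delta <= 1, length(tissues) == 2L)
  chrom <- names(genome)[1L]
  s <- genome[[1L]]
  ## CpG positions: CGs inside element interiors
  cpg <- list()
  for (i in seq_len(nrow(truth))) {
    e <- truth[i, ]
    hits <- gregexpr("CG", subseq0(s, e$start, e$end), fixed = TRUE)[[1L]]
    if (hits[1L] != -1L) {
      cpg[[length(cpg) + 1L]] <- data.table::data.table(
        pos = e$start + hits - 1L, element_id = e$element_id)
    }
  }
  cpg <- data.table::rbindlist(cpg)
  ## a CpG can sit in a host and its nested insert; keep one row per pos
  cpg <- cpg[!duplicated(pos)]

  pos_cat <- position_annotation(truth, annotation)
  proximal <- pos_cat$element_id[pos_cat$category == "proximal"]

  with_seed(stage_seed(seed, "methylomes"), {
    ## background CpGs outside elements
    bg_cg <- gregexpr("CG", s, fixed = TRUE)[[1L]] - 1L
    in_el <- bg_cg %in% cpg$pos
    bg_pick <- sample(bg_cg[!in_el],
                      min(n_background_cpg, sum(!in_el)))
    all_cpg <- rbind(cpg,
                     data.table::data.table(pos = bg_pick,
                                            element_id = NA_character_))
    data.table::setorder(all_cpg, pos)

    n_dm <- round(dm_fraction * length(proximal))
    dm_ids <- if (n_dm > 0L) sample(proximal, n_dm) else character(0)
    u <- rnorm(n_individuals, 0, indiv_sd)

    rho <- overdispersion
    n_cpg <- nrow(all_cpg)
    recs <- list()
    for (i in seq_len(n_individuals)) {
      for (t in tissues) {
        mu0 <- ifelse(!is.na(all_cpg$element_id) &
                        all_cpg$element_id %in% dm_ids & t == tissues[2L],
                      background_mean - delta, background_mean)
        mu <- stats::plogis(stats::qlogis(mu0) + u[i])
        depth <- sample(seq(depth_range[1L], depth_range[2L]),
                        n_cpg, replace = TRUE)
        if (rho > 0) {
          ab <- (1 - rho) / rho
          p <- rbeta(n_cpg, mu * ab, (1 - mu) * ab)
        } else {
          p <- mu
        }
        k <- rbinom(n_cpg, depth, p)
        sid <- paste0("ind", i, "_", t)
        recs[[length(recs) + 1L]] <- data.table::data.table(
          chrom = chrom, pos = all_cpg$pos, sample_id = sid, tissue = t,
          n_meth = k, n_total = depth
        )
      }
    }
    design <- data.table::CJ(individual = paste0("ind",
                                                 seq_len(n_individuals)),
                             tissue = tissues, sorted = FALSE)
    design[, sample_id := paste0(individual, "_", tissue)]
    list(
      records = data.table::rbindlist(recs),
      design = design[, c("sample_id", "individual", "tissue")],
      dm_truth = data.table::data.table(element_id = dm_ids,
                                        delta = rep(delta,
                                                    length(dm_ids))),
      proximal = proximal
    )
  })
}

#' Simulate expression coupled to element methylation
#'
#' For each coupled gene, log expression is
#' \code{baseline + sign * beta * m} where \code{m} is the flanked
#' element's methylation level in that sample, plus Gaussian noise; values
#' are exponentiated to FPKM-like scale.  Uncoupled genes get
#' \code{baseline} plus noise.
#'
#' @param annotation feature table (supplies the gene universe).
#' @param element_meth per-element per-sample methylation means
#'   ([element_methylation()] output, or the same columns computed from
#'   truth).
#' @param coupling data.frame \code{element_id, gene_id, sign} with sign
#'   in \code{+, -, 0}.
#' @param beta coupling strength on the log scale.
#' @param noise_sd Gaussian noise sd on the log scale.
#' @param baseline baseline log expression.
#' @param seed integer seed.
#' @return numeric matrix genes x samples (FPKM-like).
#' @export
simulate_expression <- function(annotation, element_meth, coupling,
                                beta = 3, noise_sd = 0.1, baseline = 2,
                                seed = 1L) {
  em <- data.table::as.data.table(element_meth)
  samples <- sort(unique(em$sample_id))
  genes <- unique(annotation$gene_id)
  with_seed(stage_seed(seed, "expression"), {
    logm <- matrix(baseline, length(genes), length(samples),
                   dimnames = list(genes, samples))
    for (i in seq_len(nrow(coupling))) {
      gid <- coupling$gene_id[i]
      eid <- coupling$element_id[i]
      sgn <- switch(coupling$sign[i], "+" = 1, "-" = -1, 0)
      if (!gid %in% genes) next
      d <- em[element_id == eid]
      m <- d$level[match(samples, d$sample_id)]
      m[is.na(m)] <- mean(d$level)
      logm[gid, ] <- baseline + sgn * beta * m
    }
    logm <- logm + matrix(rnorm(length(logm), 0, noise_sd),
                          nrow(logm), ncol(logm))
    exp(logm)
  })
}
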