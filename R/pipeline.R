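## End-to-end orchestration: simulate -> calibrate -> stats -> distances ->
## splice -> methylation, with one master seed, per-stage substreams, and a
## JSON manifest.  Configuration is an R list (or a JSON file); every
## threshold defaults to the values used throughout the package.

#' Default pipeline configuration
#'
#' @return nested list of defaults; see [run_pipeline()].
#' @export
default_config <- function() {
  list(
    seed = 1L,
    stages = c("simulate", "calibrate", "stats", "distances", "splice",
               "methylation"),
    simulate = list(
      genome_length = 120000L, gc = 0.42, n_elements = 30L,
      sub_rate = 0.02, tandem_prob = 0.05, nested_prob = 0.05,
      spliced_prob = 0.15, n_genes = 25L, exon_in_element_prob = 0.3,
      n_individuals = 8L, dm_fraction = 0.5, delta = 0.4,
      depth_range = c(30L, 60L), background_mean = 0.85,
      overdispersion = 0.02, indiv_sd = 0.1,
      beta = 3, noise_sd = 0.1
    ),
    thresholds = list(
      min_depth = 10L, max_depth = 300L, max_missing = 0.5,
      p_threshold = 0.01, min_abs_diff = 0.3, min_cpg = 10L,
      reps = 10000L, alpha = 0.01, alpha_clock = 4.6e-9,
      max_pca_seqs = 40L
    ),
    inputs = list()
  )
}

load_config <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  base <- default_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  for (k in names(config)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(config[[k]])) {
      utils::modifyList(base[[k]], config[[k]])
    } else {
      config[[k]]
    }
  }
  base
}

#' Run the pipeline
#'
#' Stages run in dependency order; each later stage requires the outputs
#' of the earlier ones (either from this run or via \code{config$inputs}
#' paths).  All randomness flows from \code{config$seed} through named
#' per-stage substreams, so a rerun with the same configuration is
#' identical.
#'
#' @param config configuration list or path to a JSON config; see
#'   [default_config()].
#' @param out_dir output directory (created).
#' @return invisibly, a list of in-memory stage results; files and a
#'   \code{manifest.json} are written under \code{out_dir}.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  cfg <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed
  stages <- cfg$stages
  th <- cfg$thresholds
  res <- list(config = cfg)
  spec <- consensus_spec()
  t0 <- Sys.time()

  if ("simulate" %in% stages) {
    sim <- cfg$simulate
    consensus <- build_consensus(spec, seed = seed)
    bg <- generate_background(sim$genome_length, sim$gc, seed = seed)
    imp <- implant_elements(bg, consensus, n = sim$n_elements, spec = spec,
                            sub_rate = sim$sub_rate,
                            tandem_prob = sim$tandem_prob,
                            nested_prob = sim$nested_prob,
                            spliced_prob = sim$spliced_prob, seed = seed)
    ann <- synthesize_annotation(imp$genome, imp$truth,
                                 n_genes = sim$n_genes,
                                 exon_in_element_prob =
                                   sim$exon_in_element_prob,
                                 spec = spec, seed = seed)
    me <- simulate_methylomes(imp$genome, imp$truth, ann,
                              n_individuals = sim$n_individuals,
                              depth_range = sim$depth_range,
                              background_mean = sim$background_mean,
                              dm_fraction = sim$dm_fraction,
                              delta = sim$delta,
                              overdispersion = sim$overdispersion,
                              indiv_sd = sim$indiv_sd, seed = seed)
    ## couple DM elements to their proximal genes with random signs
    gt <- attr(ann, "gene_truth")
    prox_genes <- gt[gt$class == "proximal" & !is.na(gt$element_id), ]
    coupling <- data.table::data.table(
      element_id = prox_genes$element_id, gene_id = prox_genes$gene_id)
    coupling[, sign := ifelse(
      element_id %in% me$dm_truth$element_id,
      with_seed(stage_seed(seed, "coupling"),
                sample(c("+", "-"), .N, replace = TRUE)), "0")]
    em_true <- element_methylation(filter_cpgs(me$records), imp$truth)
    expr <- simulate_expression(ann, em_true, coupling,
                                beta = sim$beta, noise_sd = sim$noise_sd,
                                seed = seed)
    write_fasta(imp$genome, file.path(out_dir, "genome.fa"))
    write_fasta(c(consensus = consensus),
                file.path(out_dir, "consensus.fa"))
    data.table::fwrite(imp$truth, file.path(out_dir, "truth.tsv"),
                       sep = "\t")
    write_gtf(ann, file.path(out_dir, "annotation.gtf"))
    dir.create(file.path(out_dir, "meth"), showWarnings = FALSE)
    for (sid in unique(me$records$sample_id)) {
      write_methylation_table(me$records[me$records$sample_id == sid, ],
                              file.path(out_dir, "meth",
                                        paste0(sid, ".bedgraph")))
    }
    data.table::fwrite(me$design, file.path(out_dir, "design.tsv"),
                       sep = "\t")
    data.table::fwrite(coupling, file.path(out_dir, "coupling.tsv"),
                       sep = "\t")
    write_expression_matrix(expr, file.path(out_dir, "expression.tsv"))
    res$simulate <- list(genome = imp$genome, truth = imp$truth,
                         consensus = consensus, annotation = ann,
                         methylomes = me, coupling = coupling,
                         expression = expr)
  }

  need <- function(stage, what) {
    if (is.null(what)) stop("missing upstream output for stage ", stage)
    what
  }

  if ("calibrate" %in% stages) {
    genome <- need("calibrate", res$simulate$genome %||% {
      if (!is.null(cfg$inputs$genome)) read_fasta(cfg$inputs$genome)
    })
    consensus <- need("calibrate", res$simulate$consensus %||% {
      if (!is.null(cfg$inputs$consensus)) {
        read_fasta(cfg$inputs$consensus)[[1L]]
      }
    })
    hits <- if (!is.null(cfg$inputs$hits)) {
      read_bed(cfg$inputs$hits)
    } else {
      scan_hits(genome, consensus)
    }
    el <- calibrate_elements(genome, hits)
    el <- detect_structures(el, genome)
    data.table::fwrite(el, file.path(out_dir, "elements.tsv"), sep = "\t")
    write_bed(el, file.path(out_dir, "elements.bed"),
              name_field = "element_id")
    res$calibrate <- el
  }

  if ("stats" %in% stages) {
    el <- need("stats", res$calibrate)
    genome <- res$simulate$genome
    st <- element_stats(el, genome)
    data.table::fwrite(st, file.path(out_dir, "stats.tsv"), sep = "\t")
    res$stats <- st
  }

  if ("distances" %in% stages) {
    el <- need("distances", res$calibrate)
    genome <- res$simulate$genome
    n_use <- min(nrow(el), th$max_pca_seqs)
    use <- el[seq_len(n_use), ]
    seqs <- setNames(
      vapply(seq_len(nrow(use)), function(i) {
        subseq0(genome[[use$chrom[i]]], use$headbody_start[i],
                use$headbody_end[i])
      }, character(1L)),
      use$element_id)
    dm <- distance_matrix(seqs)
    pe <- pca_embed(dm, k = 2L)
    write_distance_matrix(dm, file.path(out_dir, "distances.tsv"),
                          pe, file.path(out_dir, "pca.tsv"))
    res$distances <- list(dm = dm, pca = pe)
  }

  if ("splice" %in% stages) {
    el <- need("splice", res$calibrate)
    ann <- need("splice", res$simulate$annotation)
    genome <- res$simulate$genome
    consensus <- res$simulate$consensus
    sel <- select_cds_partial_overlaps(el, ann)
    sig <- mark_splice_signals(sel, ann, genome)
    if (nrow(sig)) {
      sig[, consensus_pos := NA_integer_]
      for (eid in unique(sig$element_id)) {
        e <- el[el$element_id == eid, ]
        hb <- subseq0(genome[[e$chrom]], e$headbody_start, e$headbody_end)
        idx <- which(sig$element_id == eid)
        off <- sig$element_offset[idx] -
          (e$headbody_start - e$start)      # offsets relative to head-body
        sig$consensus_pos[idx] <-
          project_to_consensus(off, hb, consensus)
      }
    }
    prof <- signal_profile(sig)
    nt <- null_threshold(reps = th$reps, alpha = th$alpha, seed = seed)
    hs <- hot_sites(prof, nt)
    data.table::fwrite(sig, file.path(out_dir, "signals.tsv"), sep = "\t")
    data.table::fwrite(
      data.table::data.table(consensus_pos = as.integer(names(prof$counts)),
                             count = prof$counts),
      file.path(out_dir, "profile.tsv"), sep = "\t")
    data.table::fwrite(data.table::data.table(hot_site = hs),
                       file.path(out_dir, "hotsites.tsv"), sep = "\t")
    res$splice <- list(signals = sig, profile = prof, threshold = nt,
                       hot_sites = hs)
  }

  if ("methylation" %in% stages) {
    el <- need("methylation", res$calibrate)
    me <- need("methylation", res$simulate$methylomes)
    ann <- need("methylation", res$simulate$annotation)
    expr <- res$simulate$expression
    coupling <- res$simulate$coupling
    filt <- filter_cpgs(me$records, th$min_depth, th$max_depth,
                        th$max_missing)
    em <- element_methylation(filt, el)
    dm <- differential_elements(em, me$design,
                                min_cpg = th$min_cpg,
                                p_threshold = th$p_threshold,
                                min_abs_diff = th$min_abs_diff)
    pos <- position_annotation(el, ann)
    enr <- tryCatch(dm_position_enrichment(dm, pos),
                    error = function(e) list(error = conditionMessage(e)))
    corr <- correlate_expression(em, expr, coupling,
                                 p_threshold = th$p_threshold)
    gs <- global_summary(em, me$design)
    data.table::fwrite(dm, file.path(out_dir, "dm.tsv"), sep = "\t")
    data.table::fwrite(corr, file.path(out_dir, "corr.tsv"), sep = "\t")
    jsonlite::write_json(
      list(enrichment = enr[names(enr) != "table"],
           tissue_mean = as.list(gs$tissue_mean),
           tissue_cv_pct = as.list(gs$tissue_cv_pct),
           t_p_value = gs$p_value),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
    res$methylation <- list(filtered = filt, element_meth = em, dm = dm,
                            positions = pos, enrichment = enr,
                            correlations = corr, summary = gs)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("sinescope")),
    r_version = as.character(getRversion()),
    seed = seed, stages = stages, thresholds = th,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    outputs = {
      fs <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
      fs <- fs[basename(fs) != "manifest.json"]
      as.list(setNames(unname(tools::md5sum(fs)),
                       sub(paste0(out_dir, "/"), "", fs, fixed = TRUE)))
    }
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}

## minimal CLI: sinescope <stage|run> --config cfg.json --out dir --seed N
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: sinescope <simulate|calibrate|stats|distances|splice|",
            "methylation|run> [--config cfg.json] [--out dir] [--seed N]")
    return(invisible(1L))
  }
  cmd <- args[1L]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1L] else default
  }
  cfg <- if (!is.null(opt("--config"))) load_config(opt("--config")) else
    default_config()
  if (!is.null(opt("--seed"))) cfg$seed <- as.integer(opt("--seed"))
  all_stages <- c("simulate", "calibrate", "stats", "distances", "splice",
                  "methylation")
  cfg$stages <- if (cmd == "run") all_stages else {
    if (!cmd %in% all_stages) stop("unknown command: ", cmd)
    all_stages[seq_len(match(cmd, all_stages))]
  }
  run_pipeline(cfg, out_dir = opt("--out", "sinescope_run"))
  invisible(0L)
}
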