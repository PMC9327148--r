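## Synthetic gene annotation coupled to implanted elements: genes with
## exon/CDS/UTR structure, a configurable fraction of exon boundaries
## inside elements at the dual-function splice sites, genes with elements
## planted 1-2 kb (proximal) or 2-100 kb (distal) upstream, and a few RNA
## genes.

#' Synthesize a gene annotation over an implanted genome
#'
#' Gene classes, drawn per gene: \emph{exonized} genes (probability
#' \code{exon_in_element_prob}) place an intron exactly between the
#' dual-function AG|GT sites of a class-I element, so both exon boundaries
#' fall strictly inside the element next to canonical GT/AG dinucleotides;
#' \emph{proximal}/\emph{distal} genes put their TSS 1-2 kb / 2-100 kb
#' downstream of an element midpoint; the rest are placed uniformly.  A
#' fraction \code{rna_gene_frac} of the uncoupled genes is emitted as RNA
#' genes.  Genes never overlap each other.
#'
#' @param genome named character vector (one chromosome).
#' @param truth implant truth table ([implant_elements()]).
#' @param n_genes number of genes.
#' @param exon_in_element_prob fraction of genes exonizing an element.
#' @param proximal_frac,distal_frac fractions of genes with an upstream
#'   element.
#' @param rna_gene_frac fraction of uncoupled genes emitted as RNA genes.
#' @param spec the [consensus_spec()] used for the implants.
#' @param seed integer seed.
#' @return \code{gene_annotation} feature table (as from [read_gtf()]),
#'   with attribute \code{gene_truth}: \code{data.table} of
#'   \code{gene_id, class, element_id}.
#' @export
synthesize_annotation <- function(genome, truth, n_genes = 30L,
                                  exon_in_element_prob = 0.3,
                                  proximal_frac = 0.3, distal_frac = 0.15,
                                  rna_gene_frac = 0.05,
                                  spec = consensus_spec(), seed = 1L) {
  stopifnot(length(genome) == 1L)
  chrom <- names(genome)
  glen <- nchar(genome[[1L]])
  if (glen < n_genes * 4000L) stop("genome too small for ", n_genes, " genes")
  ds <- find_dual_sites(spec)[1L, ]
  with_seed(stage_seed(seed, "annotation"), {
    ## every element span is claimed up front, so genes only overlap an
    ## element when the exonized construction explicitly allows it; focal
    ## (upstream) and exonized elements come from one shared pool
    used <- data.table::data.table(start = truth$start, end = truth$end,
                                   tag = truth$element_id)
    feats <- list()
    gtruth <- list()
    pool <- truth$element_id
    free_elements <- truth$element_id[truth$class == "I" &
                                        is.na(truth$nested_parent)]
    classes <- sample(c("exonized", "proximal", "distal", "plain"),
                      n_genes, replace = TRUE,
                      prob = c(exon_in_element_prob, proximal_frac,
                               distal_frac,
                               max(0.01, 1 - exon_in_element_prob -
                                     proximal_frac - distal_frac)))
    overlaps_used <- function(s, e, ignore_tag = NA_character_) {
      hit <- used$start < e & used$end > s
      if (!is.na(ignore_tag)) hit <- hit & !(used$tag %in% ignore_tag)
      any(hit)
    }
    claim <- function(s, e) {
      used <<- rbind(used, data.table::data.table(start = s, end = e,
                                                  tag = NA_character_))
    }
    gi <- 0L
    for (cls in classes) {
      gi <- gi + 1L
      gid <- sprintf("g%03d", gi)
      tid <- paste0(gid, ".t1")
      made <- FALSE
      for (attempt in 1:50) {
        if (cls == "exonized" && length(intersect(free_elements, pool))) {
          eid <- sample(intersect(free_elements, pool), 1L)
          e <- truth[truth$element_id == eid, ]
          donor <- e$headbody_start + ds$donor
          acceptor <- e$headbody_start + ds$acceptor
          ## substitutions may have destroyed the canonical dinucleotides
          g <- genome[[1L]]
          if (subseq0(g, donor, donor + 2L) != "GT" ||
              subseq0(g, acceptor - 2L, acceptor) != "AG") next
          ex1_start <- donor - sample(80:200, 1L)
          ex2_end <- acceptor + sample(80:300, 1L)
          if (ex1_start < 0L || ex2_end > glen ||
              overlaps_used(ex1_start, ex2_end, ignore_tag = eid)) next
          claim(ex1_start, ex2_end)
          pool <- setdiff(pool, eid)
          feats[[length(feats) + 1L]] <- data.table::data.table(
            gene_id = gid, transcript_id = c(NA, tid, tid, tid, tid),
            chrom = chrom,
            start = c(ex1_start, ex1_start, acceptor, ex1_start, acceptor),
            end = c(ex2_end, donor, ex2_end, donor, ex2_end),
            strand = "+",
            kind = c("gene", "exon", "exon", "CDS", "CDS")
          )
          gtruth[[length(gtruth) + 1L]] <- data.table::data.table(
            gene_id = gid, class = cls, element_id = eid)
          made <- TRUE
          break
        } else if (cls %in% c("proximal", "distal") && length(pool)) {
          eid <- sample(pool, 1L)
          e <- truth[truth$element_id == eid, ]
          mid <- interval_midpoint(e$start, e$end)
          d <- if (cls == "proximal") sample(1000:1999, 1L) else
            sample(2000:20000, 1L)
          strand <- sample(c("+", "-"), 1L, prob = c(0.7, 0.3))
          span <- sample(1500:4000, 1L)
          if (strand == "+") {
            gstart <- mid + d; gend <- gstart + span
          } else {
            gend <- mid - d + 1L; gstart <- gend - span
          }
          if (gstart < 0L || gend > glen ||
              overlaps_used(gstart, gend)) next
          claim(gstart, gend)
          pool <- setdiff(pool, eid)   # the focal element stays intergenic
          if (cls == "proximal") {
            ## guard corridor: no later gene may put its TSS nearer to the
            ## focal element than this gene's
            if (strand == "+") {
              claim(max(0L, mid - 2000L), gstart)
            } else {
              claim(gend, min(glen, mid + 2000L))
            }
          }
          feats[[length(feats) + 1L]] <-
            make_coding_gene(gid, tid, chrom, gstart, gend, strand)
          gtruth[[length(gtruth) + 1L]] <- data.table::data.table(
            gene_id = gid, class = cls, element_id = eid)
          made <- TRUE
          break
        } else {
          span <- sample(1500:4000, 1L)
          gstart <- sample(glen - span - 1L, 1L)
          gend <- gstart + span
          if (overlaps_used(gstart, gend)) next
          claim(gstart, gend)
          strand <- sample(c("+", "-"), 1L, prob = c(0.7, 0.3))
          if (runif(1) < rna_gene_frac) {
            feats[[length(feats) + 1L]] <- data.table::data.table(
              gene_id = gid, transcript_id = c(NA, tid),
              chrom = chrom, start = gstart, end = gend,
              strand = strand, kind = c("gene", "rna_gene")
            )
            gtruth[[length(gtruth) + 1L]] <- data.table::data.table(
              gene_id = gid, class = "rna_gene", element_id = NA_character_)
          } else {
            feats[[length(feats) + 1L]] <-
              make_coding_gene(gid, tid, chrom, gstart, gend, strand)
            gtruth[[length(gtruth) + 1L]] <- data.table::data.table(
              gene_id = gid, class = "plain", element_id = NA_character_)
          }
          made <- TRUE
          break
        }
      }
      if (!made) {
        gtruth[[length(gtruth) + 1L]] <- data.table::data.table(
          gene_id = gid, class = "unplaced", element_id = NA_character_)
      }
    }
    ann <- data.table::rbindlist(feats)
    data.table::setorder(ann, start)
    data.table::setattr(ann, "class", c("gene_annotation", class(ann)))
    data.table::setattr(ann, "gene_truth", data.table::rbindlist(gtruth))
    ann[]
  })
}

## a simple 2-4 exon coding gene with terminal UTRs
make_coding_gene <- function(gid, tid, chrom, gstart, gend, strand) {
  span <- gend - gstart
  n_exons <- sample(2:4, 1L)
  ## split the span into alternating exons/introns
  cuts <- sort(sample(seq(100L, span - 100L), 2L * n_exons - 2L))
  bounds <- c(0L, cuts, span) + gstart
  exon_s <- bounds[seq(1L, length(bounds) - 1L, by = 2L)]
  exon_e <- bounds[seq(2L, length(bounds), by = 2L)]
  utr5_len <- max(0L, min(50L, exon_e[1L] - exon_s[1L] - 10L))
  utr3_len <- max(0L, min(50L, exon_e[n_exons] - exon_s[n_exons] - 10L))
  if (strand == "-") { tmp <- utr5_len; utr5_len <- utr3_len; utr3_len <- tmp }
  cds_s <- exon_s; cds_e <- exon_e
  cds_s[1L] <- exon_s[1L] + utr5_len
  cds_e[n_exons] <- exon_e[n_exons] - utr3_len
  dt <- data.table::data.table(
    gene_id = gid,
    transcript_id = c(NA, rep(tid, 2L * n_exons + 2L)),
    chrom = chrom,
    start = c(gstart, exon_s, cds_s, exon_s[1L], cds_e[n_exons]),
    end = c(gend, exon_e, cds_e, cds_s[1L], exon_e[n_exons]),
    strand = strand,
    kind = c("gene", rep("exon", n_exons), rep("CDS", n_exons),
             if (strand == "+") c("five_prime_utr", "three_prime_utr")
             else c("three_prime_utr", "five_prime_utr"))
  )
  dt[dt$end > dt$start, ]
}
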