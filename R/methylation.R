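## Paired-tissue differential-methylation pipeline: CpG filtering,
## element-level means, Wilcoxon differential tests with effect-size
## criteria, methylation-expression correlation, positional enrichment and
## global summaries.

#' Filter CpGs on depth and missingness
#'
#' A sample's value at a CpG is missing when its depth lies outside
#' \code{[min_depth, max_depth]} (depths below 10 and above 300 removed, so
#' 10 and 300 survive); a CpG is dropped when its missing fraction across
#' samples exceeds \code{max_missing} (strictly).  Retained CpGs keep only
#' their non-missing samples.  The operation is idempotent.
#'
#' @param records combined methylation records (\code{chrom, pos,
#'   sample_id, tissue, n_meth, n_total}).
#' @param min_depth,max_depth inclusive depth bounds.
#' @param max_missing largest tolerated missing fraction.
#' @param n_samples total number of samples the missing fraction refers to
#'   (default: distinct sample ids present in \code{records}).
#' @return filtered records with a \code{level} column.
#' @export
filter_cpgs <- function(records, min_depth = 10L, max_depth = 300L,
                        max_missing = 0.5, n_samples = NULL) {
  dt <- data.table::as.data.table(records)
  if (is.null(n_samples)) n_samples <- length(unique(dt$sample_id))
  dt <- dt[n_total >= min_depth & n_total <= max_depth]
  dt[, n_kept := length(unique(sample_id)), by = c("chrom", "pos")]
  dt <- dt[(1 - n_kept / n_samples) <= max_missing]
  dt[, n_kept := NULL]
  dt[, level := n_meth / n_total]
  dt[]
}

#' Per-element, per-sample mean methylation
#'
#' Unweighted mean of per-CpG levels over the CpGs inside each element
#' span; elements with fewer than \code{min_cpg} retained CpG sites are
#' omitted.
#'
#' @param filtered filtered CpG records ([filter_cpgs()]).
#' @param elements element table (\code{element_id, chrom, start, end}).
#' @param min_cpg minimum number of retained CpG sites per element.
#' @return \code{data.table}: \code{element_id, sample_id, tissue, level,
#'   n_cpg_sample, n_cpg_element} (sites with data for the sample /
#'   retained sites in the element).
#' @export
element_methylation <- function(filtered, elements, min_cpg = 1L) {
  dt <- data.table::as.data.table(filtered)
  el <- data.table::as.data.table(elements)[
    , c("element_id", "chrom", "start", "end"), with = FALSE]
  el[, `:=`(istart = start, iend = end - 1L)]
  dt[, `:=`(istart = pos, iend = pos)]
  data.table::setkey(el, chrom, istart, iend)
  ov <- data.table::foverlaps(dt, el, type = "within", nomatch = NULL)
  if (!nrow(ov)) {
    return(data.table::data.table(element_id = character(),
                                  sample_id = character(),
                                  tissue = character(), level = numeric(),
                                  n_cpg_sample = integer(),
                                  n_cpg_element = integer()))
  }
  ov[, n_cpg_element := length(unique(pos)), by = element_id]
  out <- ov[, list(level = mean(level), n_cpg_sample = .N,
                   n_cpg_element = n_cpg_element[1L]),
            by = c("element_id", "sample_id", "tissue")]
  out[n_cpg_element >= min_cpg][order(element_id, sample_id)]
}

#' Differentially methylated elements between two tissues
#'
#' An element is differentially methylated (DM) when it has at least
#' \code{min_cpg} retained CpGs, the paired Wilcoxon signed-rank p-value is
#' below \code{p_threshold}, and the absolute difference of tissue means
#' exceeds \code{min_abs_diff} (set \code{min_abs_diff = 0} for the relaxed
#' criterion without an effect-size filter).
#'
#' @param element_meth per-element per-sample means
#'   ([element_methylation()]).
#' @param design data.frame \code{sample_id, individual, tissue}.
#' @param tissues length-2 character: tissues compared (effect =
#'   mean(tissue 1) - mean(tissue 2)).
#' @param min_cpg minimum retained CpG sites per element.
#' @param p_threshold significance threshold.
#' @param min_abs_diff strict lower bound on |effect|.
#' @param paired paired (by individual) signed-rank test, or an unpaired
#'   rank-sum test.
#' @return \code{data.table}: \code{element_id, n_cpg, n_pairs, W,
#'   p_value, effect, dm}.
#' @export
differential_elements <- function(element_meth, design,
                                  tissues = c("muscle", "testis"),
                                  min_cpg = 10L, p_threshold = 0.01,
                                  min_abs_diff = 0.3, paired = TRUE) {
  em <- data.table::as.data.table(element_meth)
  des <- data.table::as.data.table(design)
  em <- merge(em, des[, c("sample_id", "individual")], by = "sample_id")
  rows <- lapply(split(em, em$element_id), function(d) {
    wide <- data.table::dcast(d, individual ~ tissue, value.var = "level")
    if (!all(tissues %in% names(wide))) return(NULL)
    x <- wide[[tissues[1L]]]
    y <- wide[[tissues[2L]]]
    ok <- !is.na(x) & !is.na(y)
    if (paired) {
      if (sum(ok) < 2L) return(NULL)
      ts <- wilcoxon_signed_rank(x[ok], y[ok])
      W <- ts$W; p <- ts$p_value; np <- ts$n_pairs
    } else {
      ht <- stats::wilcox.test(x[!is.na(x)], y[!is.na(y)], exact = FALSE)
      W <- unname(ht$statistic); p <- ht$p.value; np <- sum(ok)
    }
    effect <- mean(x[ok]) - mean(y[ok])
    data.table::data.table(
      element_id = d$element_id[1L], n_cpg = d$n_cpg_element[1L],
      n_pairs = np, W = W, p_value = p, effect = effect,
      dm = d$n_cpg_element[1L] >= min_cpg & p < p_threshold &
        abs(effect) > min_abs_diff
    )
  })
  data.table::rbindlist(rows)
}

#' Methylation-expression correlation for coupled element/gene pairs
#'
#' Spearman correlation across samples between an element's methylation
#' and its neighbouring gene's expression.
#'
#' @param element_meth per-element per-sample means.
#' @param expr expression matrix (genes x samples).
#' @param pairs data.frame \code{element_id, gene_id}.
#' @param p_threshold significance threshold used to call the sign.
#' @return \code{data.table}: \code{element_id, gene_id, rho, p_value,
#'   sign} (sign NA where p >= threshold).
#' @export
correlate_expression <- function(element_meth, expr, pairs,
                                 p_threshold = 0.01) {
  em <- data.table::as.data.table(element_meth)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    eid <- pairs$element_id[i]; gid <- pairs$gene_id[i]
    d <- em[element_id == eid]
    if (!nrow(d) || !gid %in% rownames(expr)) return(NULL)
    samples <- intersect(d$sample_id, colnames(expr))
    if (length(samples) < 4L) return(NULL)
    mvec <- d$level[match(samples, d$sample_id)]
    evec <- expr[gid, samples]
    ct <- spearman(mvec, evec)
    data.table::data.table(
      element_id = eid, gene_id = gid, rho = ct$rho, p_value = ct$p_value,
      sign = if (!is.na(ct$p_value) && ct$p_value < p_threshold) {
        ct$sign
      } else NA_character_
    )
  })
  data.table::rbindlist(rows)
}

#' Positional enrichment of differential methylation
#'
#' Fisher's exact test of DM status against a positional category
#' (proximal vs all other elements by default).
#'
#' @param dm_table output of [differential_elements()].
#' @param positions output of [position_annotation()].
#' @param category the focal category.
#' @return list: \code{table} (2x2), \code{odds_ratio}, \code{p_value}.
#' @export
dm_position_enrichment <- function(dm_table, positions,
                                   category = "proximal") {
  m <- merge(data.table::as.data.table(dm_table),
             data.table::as.data.table(positions), by = "element_id")
  tab <- matrix(c(
    sum(m$dm & m$category == category),
    sum(m$dm & m$category != category),
    sum(!m$dm & m$category == category),
    sum(!m$dm & m$category != category)
  ), nrow = 2L, byrow = TRUE,
  dimnames = list(c("DM", "not_DM"), c(category, "other")))
  ft <- fisher_enrichment(tab)
  list(table = tab, odds_ratio = ft$odds_ratio, p_value = ft$p_value)
}

#' Global methylation summary per tissue
#'
#' Per-sample mean element methylation, per-tissue mean and coefficient of
#' variation (percent, across individuals), and a paired t-test between
#' the two tissues.
#'
#' @param element_meth per-element per-sample means.
#' @param design data.frame \code{sample_id, individual, tissue}.
#' @param tissues length-2 character.
#' @return list: \code{sample_means, tissue_mean, tissue_cv_pct,
#'   t_statistic, p_value}.
#' @export
global_summary <- function(element_meth, design,
                           tissues = c("muscle", "testis")) {
  em <- merge(data.table::as.data.table(element_meth),
              data.table::as.data.table(design),
              by = c("sample_id", "tissue"))
  sm <- em[, list(mean_level = mean(level)),
           by = c("sample_id", "individual", "tissue")]
  if (length(unique(sm$individual)) < 2L) stop("need >= 2 individuals")
  wide <- data.table::dcast(sm, individual ~ tissue,
                            value.var = "mean_level")
  x <- wide[[tissues[1L]]]; y <- wide[[tissues[2L]]]
  d <- x - y
  if (sd(d) < 1e-10 * max(1, abs(mean(d)))) {
    ## degenerate: constant difference (t.test would error)
    tt <- list(statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
               p.value = if (mean(d) == 0) 1 else 0)
  } else {
    tt <- stats::t.test(x, y, paired = TRUE)
  }
  cvp <- function(v) if (mean(v) == 0) 0 else 100 * sd(v) / mean(v)
  list(
    sample_means = sm,
    tissue_mean = setNames(c(mean(x), mean(y)), tissues),
    tissue_cv_pct = setNames(c(cvp(x), cvp(y)), tissues),
    t_statistic = unname(tt$statistic),
    p_value = tt$p.value
  )
}

#' Restrict elements to a set of regions
#'
#' Keeps elements whose span overlaps at least one region by >= 1 bp.
#'
#' @param elements element table.
#' @param regions interval table (\code{chrom, start, end}), e.g. from
#'   [read_bed()].
#' @return subset of \code{elements}.
#' @export
restrict_to_regions <- function(elements, regions) {
  keep <- vapply(seq_len(nrow(elements)), function(i) {
    e <- elements[i, ]
    any(regions$chrom == e$chrom & regions$start < e$end &
          regions$end > e$start)
  }, logical(1L))
  elements[keep, ]
}
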