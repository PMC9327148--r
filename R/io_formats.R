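## io_formats: readers and writers for the plain-text formats the pipeline
## touches.  One coordinate convention everywhere inside the package:
## 0-based half-open.  GTF (1-based inclusive) and BED (0-based half-open)
## are converted at the file boundary and nowhere else.

#' Read a FASTA file
#'
#' Sequences are uppercased on load (soft-masking folded away) and validated
#' against the alphabet \{A,C,G,T,N\}; an offending character is reported with
#' its line number.
#'
#' @param path path to a FASTA file.
#' @return named character vector, one uppercase sequence per record, in file
#'   order.  Names are the first whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- startsWith(lines, ">")
  if (!any(hdr)) stop("no records in FASTA file: ", path)
  bad <- which(!hdr & grepl("[^ACGTNacgtn]", lines) & nzchar(lines))
  if (length(bad)) {
    stop("non-IUPAC character in ", path, " at line ", bad[1L])
  }
  rec <- cumsum(hdr)
  if (any(rec == 0L & nzchar(lines))) stop("sequence before first header")
  names_ <- sub("^>(\\S*).*$", "\\1", lines[hdr])
  seqs <- vapply(
    split(lines[!hdr], rec[!hdr]),
    function(x) toupper(paste(x, collapse = "")),
    character(1L)
  )
  ## records with no sequence lines at all
  out <- setNames(character(length(names_)), names_)
  out[as.integer(names(seqs))] <- seqs
  if (any(!nzchar(out))) {
    stop("empty sequence for record: ", names_[!nzchar(out)][1L])
  }
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read an Ensembl-dialect GTF into a feature table
#'
#' GTF coordinates (1-based inclusive) are converted to the internal 0-based
#' half-open convention.  Only the closed feature set
#' \code{gene, exon, CDS, five_prime_utr, three_prime_utr, rna_gene} is kept;
#' the number of ignored features is reported via a message.
#'
#' @param path path to a GTF file.
#' @return a \code{data.table} of class \code{gene_annotation} with columns
#'   \code{gene_id, transcript_id, chrom, start, end, strand, kind}.
#' @export
read_gtf <- function(path) {
  dt <- data.table::fread(
    path, sep = "\t", header = FALSE, quote = "", fill = TRUE,
    col.names = c("chrom", "source", "kind", "start1", "end1",
                  "score", "strand", "frame", "attr")
  )
  dt <- dt[!startsWith(chrom, "#")]
  if (any(dt$end1 < dt$start1)) {
    stop("GTF line with end < start at row ", which(dt$end1 < dt$start1)[1L])
  }
  gid <- sub('.*gene_id "([^"]+)".*', "\\1", dt$attr)
  if (any(!grepl('gene_id "', dt$attr, fixed = TRUE))) {
    stop("GTF record without gene_id at row ",
         which(!grepl('gene_id "', dt$attr, fixed = TRUE))[1L])
  }
  tid <- ifelse(grepl('transcript_id "', dt$attr, fixed = TRUE),
                sub('.*transcript_id "([^"]+)".*', "\\1", dt$attr), NA_character_)
  keep_kinds <- c("gene", "exon", "CDS", "five_prime_utr",
                  "three_prime_utr", "rna_gene")
  n_ignored <- sum(!dt$kind %in% keep_kinds)
  if (n_ignored > 0L) {
    message("read_gtf: ignored ", n_ignored, " features outside the kind set")
  }
  out <- data.table::data.table(
    gene_id = gid, transcript_id = tid, chrom = dt$chrom,
    start = dt$start1 - 1L, end = dt$end1, strand = dt$strand,
    kind = dt$kind
  )[kind %in% keep_kinds]
  data.table::setattr(out, "class", c("gene_annotation", class(out)))
  out[]
}

#' Write a feature table as GTF
#'
#' @param annotation a feature table as returned by [read_gtf()] or
#'   [synthesize_annotation()].
#' @param path output path.
#' @export
write_gtf <- function(annotation, path) {
  check_intervals(annotation)
  attr_str <- paste0(
    'gene_id "', annotation$gene_id, '";',
    ifelse(is.na(annotation$transcript_id), "",
           paste0(' transcript_id "', annotation$transcript_id, '";'))
  )
  lines <- paste(annotation$chrom, "sinescope", annotation$kind,
                 annotation$start + 1L, annotation$end, ".",
                 annotation$strand, ".", attr_str, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph-with-counts methylation table
#'
#' Expects the MethylDackel-style dialect: tab-separated
#' \code{chrom, start, end, level, n_meth, n_total} with 0-based half-open
#' coordinates; \code{start} is taken as the CpG position (C of the CpG on
#' the + strand) unchanged.  The level column is ignored (recomputed from
#' counts downstream).
#'
#' @param path path to the table.
#' @param sample_id sample identifier attached to every record.
#' @param tissue tissue label attached to every record.
#' If a seventh column holds strands, records on the G (\code{-} strand) are
#' folded onto the C position (\code{pos - 1}) and counts summed, so a CpG is
#' one unit; without a strand column positions are taken as given.
#'
#' @return \code{data.table} with columns \code{chrom, pos, sample_id,
#'   tissue, n_meth, n_total}.
#' @param destrand fold - strand records onto the C position when a strand
#'   column is present (default TRUE).
#' @export
read_methylation_table <- function(path, sample_id, tissue, destrand = TRUE) {
  dt <- data.table::fread(path, header = FALSE)
  if (ncol(dt) < 6L) stop("expected >= 6 columns in ", path)
  names(dt)[1:6] <- c("chrom", "start", "end", "level", "n_meth", "n_total")
  bad <- which(dt$n_meth > dt$n_total | dt$n_meth < 0)
  if (length(bad)) {
    stop("n_meth > n_total in ", path, " at line ", bad[1L])
  }
  pos <- dt$start
  if (ncol(dt) >= 7L && all(dt[[7L]] %in% c("+", "-")) && destrand) {
    pos <- ifelse(dt[[7L]] == "-", pos - 1L, pos)
  }
  out <- data.table::data.table(
    chrom = dt$chrom, pos = pos,
    sample_id = sample_id, tissue = tissue,
    n_meth = dt$n_meth, n_total = dt$n_total
  )
  out <- out[, list(n_meth = sum(n_meth), n_total = sum(n_total)),
             by = c("chrom", "pos", "sample_id", "tissue")]
  out[]
}

#' Write methylation records for one sample as bedGraph-with-counts
#'
#' @param records per-sample methylation records (columns \code{chrom, pos,
#'   n_meth, n_total}).
#' @param path output path.
#' @export
write_methylation_table <- function(records, path) {
  lvl <- ifelse(records$n_total > 0,
                round(100 * records$n_meth / records$n_total, 2), 0)
  out <- data.table::data.table(records$chrom, records$pos, records$pos + 1L,
                                lvl, records$n_meth, records$n_total)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write intervals as BED6
#'
#' Internal coordinates are already BED's 0-based half-open, so they are
#' emitted unchanged.
#'
#' @param intervals data.frame with \code{chrom, start, end} and optional
#'   \code{strand}.
#' @param path output path.
#' @param name_field column of \code{intervals} supplying the BED name, or a
#'   character vector of names.
#' @param score_field column supplying the score (default constant 0).
#' @export
write_bed <- function(intervals, path, name_field = NULL, score_field = NULL) {
  check_intervals(intervals)
  n <- nrow(intervals)
  pick <- function(field, default) {
    if (is.null(field)) return(rep(default, n))
    if (length(field) == 1L && is.character(field) &&
        field %in% names(intervals)) return(intervals[[field]])
    field
  }
  nm <- pick(name_field, ".")
  sc <- pick(score_field, 0)
  strand <- if ("strand" %in% names(intervals)) intervals$strand else rep(".", n)
  out <- data.table::data.table(intervals$chrom, intervals$start,
                                intervals$end, nm, sc, strand)
  if (n == 0L) {
    file.create(path)
  } else {
    data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  }
  invisible(path)
}

#' Read a BED file into the internal interval convention
#'
#' @param path path to a BED3+ file.
#' @return \code{data.table} with \code{chrom, start, end, name, score,
#'   strand} (missing BED columns filled with defaults).
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0L) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), name = character(),
                                  score = numeric(), strand = character()))
  }
  dt <- data.table::fread(path, header = FALSE)
  names(dt)[1:3] <- c("chrom", "start", "end")
  if (ncol(dt) < 4L) dt$name <- "." else names(dt)[4L] <- "name"
  if (ncol(dt) < 5L) dt$score <- 0 else names(dt)[5L] <- "score"
  if (ncol(dt) < 6L) dt$strand <- "." else names(dt)[6L] <- "strand"
  check_intervals(dt)
  dt[, c("chrom", "start", "end", "name", "score", "strand")]
}

#' Read a plain TSV expression matrix
#'
#' Rows are genes (first column \code{gene_id}), columns are samples, values
#' FPKM-like.
#'
#' @param path path to the TSV.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_matrix <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- dt[[1L]]
  m
}

#' Write an expression matrix as TSV
#'
#' @param mat numeric matrix, genes x samples.
#' @param path output path.
#' @export
write_expression_matrix <- function(mat, path) {
  dt <- data.table::data.table(gene_id = rownames(mat))
  for (j in colnames(mat)) dt[[j]] <- mat[, j]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
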