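## Needleman-Wunsch global alignment, genetic-distance matrices, and PCA
## embedding of element sequences.

#' Global (Needleman-Wunsch) alignment of two sequences
#'
#' Linear gap penalty; traceback ties broken in the fixed order
#' diagonal > up > left.  N never counts as a match.  The distance is
#' identity-based, \eqn{1 - matches/columns}, bounded in \[0, 1\] and
#' comparable across lengths; the raw score is retained.
#'
#' @param a,b sequences over \{A,C,G,T,N\}.
#' @param match,mismatch,gap scoring parameters.
#' @return list of class \code{alignment_result}: \code{aligned_a,
#'   aligned_b, score, n_columns, n_matches, distance}.
#' @export
global_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  if (!nchar(a) || !nchar(b)) stop("empty sequence")
  r <- .nw_align_cpp(a, b, match, mismatch, gap)
  ca <- seq_chars(r$aligned_a)
  cb <- seq_chars(r$aligned_b)
  n_matches <- sum(ca == cb & ca != "-" & ca != "N")
  structure(list(
    aligned_a = r$aligned_a, aligned_b = r$aligned_b, score = r$score,
    n_columns = length(ca), n_matches = n_matches,
    distance = 1 - n_matches / length(ca)
  ), class = "alignment_result")
}

#' Pairwise Needleman-Wunsch distance matrix
#'
#' @param seqs (named) character vector of sequences.
#' @param ... forwarded to [global_align()].
#' @return list of class \code{distance_matrix}: \code{ids}, symmetric
#'   \code{matrix} with zero diagonal.
#' @export
distance_matrix <- function(seqs, ...) {
  n <- length(seqs)
  if (n < 2L) stop("need at least 2 sequences")
  ids <- names(seqs) %||% paste0("s", seq_len(n))
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      d <- global_align(seqs[[i]], seqs[[j]], ...)$distance
      m[i, j] <- d
      m[j, i] <- d
    }
  }
  structure(list(ids = ids, matrix = m), class = "distance_matrix")
}

#' PCA embedding of a distance matrix
#'
#' Rows of the distance matrix are observations, columns features
#' (the FactoMineR-style use of a distance matrix as plain input data).
#' Columns are centred and, when \code{standardize}, scaled to unit
#' variance (zero-variance columns left unscaled).  Component signs are
#' fixed by making each component's largest-magnitude loading positive.
#'
#' @param dm a \code{distance_matrix} (or plain numeric matrix).
#' @param k number of components returned.
#' @param standardize scale columns to unit variance.
#' @return list of class \code{pca_embedding}: \code{coordinates} (n x k),
#'   \code{explained_variance} (all components, non-increasing),
#'   \code{loadings}.
#' @export
pca_embed <- function(dm, k = 2L, standardize = TRUE) {
  x <- if (inherits(dm, "distance_matrix")) dm$matrix else as.matrix(dm)
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 observations")
  if (k >= n) stop("k must be smaller than the number of observations")
  x <- scale(x, center = TRUE, scale = FALSE)
  if (standardize) {
    s <- apply(x, 2L, sd)
    s[s == 0] <- 1
    x <- sweep(x, 2L, s, "/")
  }
  sv <- svd(x)
  ev <- sv$d^2 / (n - 1)
  load <- sv$v
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  for (j in seq_len(ncol(load))) {
    i_max <- which.max(abs(load[, j]))
    if (load[i_max, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- rownames(x)
  structure(list(
    coordinates = scores[, seq_len(k), drop = FALSE],
    explained_variance = ev,
    loadings = load
  ), class = "pca_embedding")
}

#' Write a distance matrix and PCA coordinates to TSV
#'
#' @param dm a \code{distance_matrix}.
#' @param path output TSV (square matrix with id header).
#' @param pca optional \code{pca_embedding} written next to it.
#' @param pca_path output TSV for the coordinates.
#' @export
write_distance_matrix <- function(dm, path, pca = NULL, pca_path = NULL) {
  m <- data.table::as.data.table(dm$matrix, keep.rownames = "id")
  data.table::fwrite(m, path, sep = "\t")
  if (!is.null(pca) && !is.null(pca_path)) {
    k <- ncol(pca$coordinates)
    hdr <- paste0("# explained_variance: ",
                  paste(signif(pca$explained_variance[seq_len(k)], 6),
                        collapse = ", "))
    writeLines(hdr, pca_path)
    co <- data.table::as.data.table(pca$coordinates, keep.rownames = "id")
    names(co)[-1L] <- paste0("PC", seq_len(k))
    data.table::fwrite(co, pca_path, sep = "\t", append = TRUE,
                       col.names = TRUE)
  }
  invisible(path)
}
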