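## Exact small-sample tests used by the methylation module.  Each has an
## exact path (equivalent to full enumeration, verified against brute-force
## oracles in the test suite) and a large-sample approximation.

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped before ranking; ties get average ranks.
#' W is the sum of positive ranks.  For n <= \code{exact_n} the two-sided p
#' is exact (the full distribution over all 2^n sign assignments, computed
#' by convolution); beyond that a normal approximation with tie correction
#' is used.  Two-sided p = 2 min(P(W <= w), P(W >= w)), capped at 1.
#'
#' @param x first paired vector, or the vector of differences.
#' @param y optional second paired vector.
#' @param exact_n largest n for which the exact distribution is used.
#' @return list: \code{W, p_value, n_pairs, method}.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_n = 25L) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  n_pairs <- length(d)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(W = 0, p_value = 1, n_pairs = n_pairs,
                method = "degenerate"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_n) {
    ## exact distribution of W over all sign assignments: polynomial
    ## product of (1 + z^{2 r_i}) on a half-rank integer grid
    ir <- as.integer(round(2 * r))
    coef <- numeric(sum(ir) + 1L)
    coef[1L] <- 1
    for (ri in ir) {
      shifted <- c(numeric(ri), coef[seq_len(length(coef) - ri)])
      coef <- coef + shifted
    }
    coef <- coef / 2^n
    w2 <- as.integer(round(2 * W))
    p_le <- sum(coef[seq_len(w2 + 1L)])
    p_ge <- sum(coef[seq(w2 + 1L, length(coef))])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(W = W, p_value = p, n_pairs = n_pairs, method = method)
}

#' Spearman rank correlation with exact small-n p-value
#'
#' rho is the Pearson correlation of average-tie ranks.  For
#' n <= \code{exact_n} the two-sided p is the exact permutation probability
#' of \eqn{|rho| \ge |rho_{obs}|}; otherwise the t approximation is used.
#'
#' @param x,y equal-length sample vectors (n >= 4).
#' @param exact_n largest n for which all n! permutations are enumerated.
#' @return list: \code{rho, p_value, n, sign, method}; \code{rho} is NA
#'   (flagged by \code{method = "degenerate"}) when either vector has zero
#'   variance.
#' @export
spearman <- function(x, y, exact_n = 9L) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4L) stop("need at least 4 paired observations")
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                sign = NA_character_, method = "degenerate"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_n) {
    perms <- permutations(n)
    ## rho is linear in sum(rx * ry[perm]); enumerate that statistic
    s_obs <- sum(rx * ry)
    s_perm <- as.vector(matrix(ry[perms], nrow = nrow(perms)) %*% rx)
    p <- mean(abs(s_perm - mean(s_perm)) >= abs(s_obs - mean(s_perm)) - 1e-9)
    method <- "exact"
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t"
  }
  list(rho = rho, p_value = p, n = n,
       sign = if (rho >= 0) "+" else "-", method = method)
}

## all permutations of 1:n as an (n! x n) integer matrix
permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    blk <- cbind(rep(k, nrow(sub)), matrix(rest[sub], nrow(sub)))
    out[row:(row + nrow(sub) - 1L), ] <- blk
    row <- row + nrow(sub)
  }
  out
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided conditional test: the p-value sums the hypergeometric
#' probabilities of all tables (with the observed margins) whose
#' probability does not exceed the observed one (within a relative
#' tolerance of 1e-7).
#'
#' @param tab 2x2 matrix of nonnegative counts with positive margins.
#' @return list: \code{odds_ratio} (sample OR), \code{p_value}.
#' @export
fisher_enrichment <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero margin in the 2x2 table")
  }
  m <- sum(tab[1L, ])          # white balls (row 1)
  n_ <- sum(tab[2L, ])         # black balls
  k <- sum(tab[, 1L])          # drawn
  a <- tab[1L, 1L]
  support <- max(0L, k - n_):min(k, m)
  dens <- dhyper(support, m, n_, k)
  p_obs <- dhyper(a, m, n_, k)
  p <- sum(dens[dens <= p_obs * (1 + 1e-7)])
  or <- (tab[1L, 1L] * tab[2L, 2L]) / (tab[1L, 2L] * tab[2L, 1L])
  list(odds_ratio = or, p_value = min(1, p))
}
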