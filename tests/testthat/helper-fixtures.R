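## Shared fixtures, built once per test run.  Everything is generated in
## code; no data files.

fx <- new.env()

fx_spec <- function() {
  if (is.null(fx$spec)) fx$spec <- consensus_spec()
  fx$spec
}

fx_consensus <- function() {
  if (is.null(fx$cons)) fx$cons <- build_consensus(fx_spec(), seed = 1L)
  fx$cons
}

## a small implanted world: 30 clean-ish elements, some spliced
fx_world <- function() {
  if (is.null(fx$world)) {
    bg <- generate_background(150000L, 0.42, seed = 2L)
    imp <- implant_elements(bg, fx_consensus(), n = 30L, spec = fx_spec(),
                            sub_rate = 0.01, tandem_prob = 0,
                            nested_prob = 0, spliced_prob = 0.1, seed = 3L)
    ann <- synthesize_annotation(imp$genome, imp$truth, n_genes = 25L,
                                 exon_in_element_prob = 0.3,
                                 proximal_frac = 0.4,
                                 spec = fx_spec(), seed = 4L)
    fx$world <- list(genome = imp$genome, truth = imp$truth,
                     annotation = ann)
  }
  fx$world
}

## mutate a sequence at a fixed rate (test-local helper, independent of
## the package's internal mutator)
mutate_at <- function(seq, rate, seed) {
  set.seed(seed)
  ch <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

## ---- independent oracles ------------------------------------------------

## exhaustive alignment-path enumeration (no dynamic programming): the
## maximum score over every global alignment, by recursion over all
## extension choices
nw_enum_oracle <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0) {
      s <- if (substr(a, i, i) == substr(b, j, j) &&
               substr(a, i, i) != "N") match else mismatch
      best <- max(best, rec(i - 1, j - 1) + s)
    }
    if (i > 0) best <- max(best, rec(i - 1, j) + gap)
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    best
  }
  rec(nchar(a), nchar(b))
}

## memoised top-down variant, usable at length 5
nw_memo_oracle <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  n <- nchar(a); m <- nchar(b)
  memo <- matrix(NA_real_, n + 1, m + 1)
  rec <- function(i, j) {
    if (!is.na(memo[i + 1, j + 1])) return(memo[i + 1, j + 1])
    v <- if (i == 0 && j == 0) 0 else {
      best <- -Inf
      if (i > 0 && j > 0) {
        s <- if (substr(a, i, i) == substr(b, j, j)) match else mismatch
        best <- max(best, rec(i - 1, j - 1) + s)
      }
      if (i > 0) best <- max(best, rec(i - 1, j) + gap)
      if (j > 0) best <- max(best, rec(i, j - 1) + gap)
      best
    }
    memo[i + 1, j + 1] <<- v
    v
  }
  rec(n, m)
}

## all strings over an alphabet up to a length
all_strings <- function(alphabet, max_len) {
  out <- character(0)
  for (l in seq_len(max_len)) {
    g <- do.call(expand.grid, rep(list(alphabet), l))
    out <- c(out, apply(g, 1, paste, collapse = ""))
  }
  out
}

## exact signed-rank p by enumerating all 2^n sign assignments
wilcoxon_enum_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(do.call(expand.grid, rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

## exact Spearman p by enumerating all permutations of y
spearman_enum_oracle <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho_obs <- cor(rx, ry)
  perm_rec <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perm_rec(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  rhos <- vapply(perm_rec(seq_len(n)),
                 function(p) cor(rx, ry[p]), numeric(1))
  mean(abs(rhos - mean(rhos)) >= abs(rho_obs - mean(rhos)) - 1e-9)
}

## two-sided Fisher p from first principles (choose(), not dhyper)
fisher_enum_oracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  prob <- vapply(support, function(a) {
    choose(m, a) * choose(n, k - a) / choose(m + n, k)
  }, numeric(1))
  p_obs <- prob[support == tab[1, 1]]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
}
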