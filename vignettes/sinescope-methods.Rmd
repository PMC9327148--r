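---
title: "Models and methods behind sinescope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sinescope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sinescope)
```

`sinescope` analyses a SINE retrotransposon family — the porcine PRE1
family is the motivating case — from boundary calibration through
splice-signal enrichment to paired-tissue methylation. This vignette
explains the models, the tunable parameters, what the synthetic data
generator does and does not emulate, and the numerical choices made
where the design was genuinely open. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## Coordinates

Everything inside the package is 0-based half-open. GTF (1-based
inclusive) and BED (0-based half-open) are converted only in
`read_gtf()` / `write_bed()`, so there is a single place to audit
off-by-one behaviour. CpG positions are keyed to the C of the CpG on the
+ strand; when a methylation table carries a strand column, records on
the G are folded onto `pos - 1` and counts summed.

## The consensus model

The class-I head–body consensus is 231 nt: a 110-nt RNA polymerase III
promoter head (A box, B box), two tandem 46-nt direct repeats F and R
that are identical by construction, and a 29-nt 3′ segment carrying the
conserved motif `GGAGTTCCC` exactly once. Each repeat unit carries
`AGGT` at unit offset 20 — the acceptor `AG` immediately followed by the
donor `GT`, the dual-function splice site — and a `CTGAT` branch motif
at offset 35, which lands inside the segment excised between the two
dual sites. Because F and R are homologous, the donor in F and the
acceptor in R are exactly one unit length (46 nt) apart, so GT-AG
excision shortens the head–body by exactly 46 nt: 231 → 185, the
class I → class II length relation. The excised product is a chimera of
F (5′ part) and R (3′ part), not the deletion of one whole repeat — the
package asserts this byte-exactly in its tests.

Free positions of the consensus are drawn at GC 0.56 (the head–body GC
content scale of the family) under two rejection constraints: no `AAAA`
run anywhere (the tail splitter must not fire inside the head–body) and
a unique occurrence of the conserved motif.

## TSD calibration

A retrotransposon insertion duplicates its target site, leaving
identical copies flanking the element. Calibration searches, for every
8-mer starting within `search_window = [-30, +15]` of a rough hit's
start, an exact match in the 3′ flank (up to `flank = 200` nt past the
hit end); a match is extended in both directions while the two copies
agree, and the longest extended duplication wins, with ties resolved to
the most 5′ left copy. The element interior is the span between the two
copies. Design choices the source method leaves open:

* The 3′ search window starts 15 nt *before* the approximate hit end:
  rough hits overshooting the element would otherwise clip the right
  TSD copy out of the window.
* Candidate duplications longer than `max_tsd_len = 40` are discarded.
  Adjacent near-identical tandem copies make the shared element body
  itself an exact duplication several hundred bases long; that is
  homology, not a target-site duplication.
* Candidate duplications containing an `AAAA` run are discarded. The
  poly(A) tails of neighbouring copies generate spurious A-run
  duplications, and within this family's anatomy an `AAAA`-bearing
  stretch is tail, not target site.
* Candidates containing `N` are discarded: exact matching is undefined
  over `N`.

The head–body/tail boundary is the first `AAAA` at or after
`min_headbody = 150` (preventing body-internal A-runs from truncating
the element); without any `AAAA`, the first ≥6-A run with at most one
mismatch after the conserved motif is used (`motif_fallback`). Class
bins are I = [210, 260] and II = [165, 209] head–body bp: the family's
two modes are 231 and 185, and the cut at 209/210 is the midpoint shift
of half a repeat unit. Elements under 1 kb upstream of a TSS get their
own positional category (`upstream_lt1kb`) rather than being silently
dropped; proximal is [1, 2) kb and distal [2, 100] kb upstream of the
nearest TSS, strand-aware, with intragenic taking precedence.

`detect_structures()` groups runs of elements separated by at most
`max_gap = 10` bp — allowing small overlaps, since fallback-calibrated
3′ boundaries are noisy — and confirms a tandem group only when the TSD
search over the merged span finds one shared outer duplication pair.
Nesting is strict span containment, with the smallest container as
parent.

## Sequence statistics

The observed/expected CpG ratio is the Gardiner–Garden form
`n_CpG · L / (n_C · n_G)`; a sequence is called a CpG island when
L ≥ 200, GC ≥ 0.5 and OE strictly > 0.6. Divergence D is the
uncorrected p-distance under pairwise deletion (gap or N columns
excluded per pair); a Jukes–Cantor correction is available behind a
flag but off by default, because the upstream method's "base change per
site" is not further specified. The molecular clock is `t = D / (2α)`
with α = 4.6 × 10⁻⁹ per site per year, reported in years and My.
Nucleotide diversity is the mean pairwise p-distance; complete deletion
is available as an alternative.

## Alignment, distances, PCA

The Needleman–Wunsch core (C++) uses +1/−1/−2 linear gap scoring — the
source method does not state its parameterisation, so a minimal
standard scheme is used and exposed as arguments — with traceback ties
broken diagonal > up > left, and `N` never counting as a match. The
reported distance is 1 − matches/columns, bounded in [0, 1] and
comparable across lengths; the raw score is retained for users who want
a score-derived reading. `pca_embed()` treats distance-matrix rows as
observations (the same use of a distance matrix as plain input that
FactoMineR-style PCA makes), centres and optionally standardises
columns (zero-variance columns are left unscaled), and fixes component
signs by making each component's largest-magnitude loading positive so
tests are reproducible.

## Splice-signal enrichment

Only elements with at least one exon boundary strictly inside their
span, no UTR or RNA-gene overlap, and CDS overlap are scanned. Exon
ends followed by `GT` on the transcript strand are 5′ signals; exon
starts preceded by `AG` are 3′ signals; acceptors of minus-strand
transcripts are reported as kind `T`. Non-canonical boundaries are kept
in the output with an `nc` suffix but excluded from profiles: the
enrichment counts splice *signals*, which are canonical by definition.
Signals are projected onto consensus coordinates through global
alignment (offsets on consensus-gap columns move to the next consensus
column 3′; elements at distance ≥ 0.5 from the consensus are dropped
with a warning).

The null model drops 188 signals uniformly onto 93 positions (the
sampling is over 93 positions although the direct-repeat region is
spoken of as 92 bp; the package follows the printed sampling
parameters), 10,000 times, pools all (replicate, position) counts, and
sets k to the smallest integer with pooled exceedance probability
P(count > k) ≤ α = 0.01; this yields k = 6 with
P(count > 6) ≈ 0.0045, matching the analytic Binomial(188, 1/93) tail.
The alternative per-replicate-maximum reading is available behind a
flag but is inconsistent with the printed 0.01. Hot sites default to
the strict rule count > k; an inclusive `>= k` flag covers the other
reading of "at least six", and the default is documented here
deliberately because the two phrasings in the source disagree.

## Methylation

Depth bounds are inclusive ([10, 300] survive: "less than 10 and more
than 300" are removed), and the missing-rate rule is strict (> 50%
removed). Element means are unweighted over CpG levels, not
depth-weighted. The paired Wilcoxon signed-rank test drops zero
differences, uses average ranks for ties, and computes the exact
two-sided p (2·min(P≤, P≥), capped at 1) by convolution over the
half-rank grid for n ≤ 25 — numerically identical to enumerating all
2ⁿ sign assignments, which the test suite verifies — with a
tie-corrected normal approximation beyond. With 8 pairs the smallest
attainable p is 2/256 ≈ 0.0078, which is why a P < 0.01 threshold
controls the false-positive rate by construction at this design size.
Pairing is by individual (each animal contributes both tissues); an
unpaired fallback exists behind a flag. Spearman p-values are exact by
permutation enumeration for n ≤ 9 and t-approximate beyond; Fisher's
test is the conditional two-sided hypergeometric (tables with
probability ≤ observed, within 1e-7 relative tolerance).

## The synthetic world

The generator states one world and the tests measure it; none of its
defaults were tuned against test outcomes.

* Implants: TSDs 8–20 bp drawn from background composition but
  containing no `AAAA` (a TSD that looks like tail would confuse any
  tail splitter, including the real pipeline's); tails 10–50 nt with
  10% non-A contamination (first four bases kept `A` as the splitter
  anchor, overall A fraction ≥ 0.8); substitutions at 2% by default;
  tandem pairs share one outer TSD pair; nested copies insert a
  complete element into the host tail; spliced (class II) copies are
  made by the package's own excision operation, which gives a free
  cross-module consistency check. The two background bases flanking an
  implant are forced to differ from the adjacent interior bases so the
  implanted TSD is the *maximal* exact duplication — exactly what a
  real insertion into unrelated sequence looks like, and necessary for
  boundary-exactness to be well defined.
* Methylomes: all CpGs inside elements plus sprinkled background CpGs;
  depth uniform in [10, 60]; beta-binomial with background mean 0.85
  (the family is hypermethylated; no printed value exists, so this is a
  configurable stand-in), overdispersion 0.05 and a per-individual
  logit-scale random effect (sd 0.2) giving the paired structure.
  Differentially methylated elements are drawn from proximal elements
  and lowered by δ in the second tissue.
* Expression: log-expression of a coupled gene is baseline ± β times
  the element's per-sample methylation plus Gaussian noise,
  exponentiated to an FPKM-like scale.

What the generator does **not** emulate: read-level bisulfite data and
conversion errors, alignment artifacts, genome-scale copy numbers
(hundreds of thousands), lineage structure among subfamilies, and real
linkage between methylation and sequence context. A green test
therefore establishes that the pipeline's logic recovers planted
structure under the stated noise model — not that it reproduces the
published genome-scale counts, which require the real genome and the
deposited sequencing data and are out of scope.

## Numerical and reproducibility choices

* All randomness flows from one integer seed through per-stage
  substreams (`stage_seed`), so stages are independently reproducible;
  reruns with the same configuration are byte-identical (asserted on
  manifest checksums).
* The pipeline configuration is JSON (the environment provides
  jsonlite; no YAML parser is pre-installed); unknown keys are
  rejected and every threshold is echoed into the manifest.
* Degenerate inputs: all-N sequences, zero comparable alignment
  columns, zero-variance correlation vectors, all-zero Wilcoxon
  differences and zero Fisher margins all have defined, tested
  behaviour (error or flagged result, never silent NA propagation).
* Known limitations: `scan_hits` merges abutting copies into one hit
  (calibration then resolves only the TSD-delimited part), fallback 3′
  boundaries are approximate by nature of the poly(A) heuristic, and
  TSD recovery for tandem members is intentionally delegated to the
  merged-span outer search in `detect_structures`.
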