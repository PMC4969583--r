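---
title: "Discriminative peptide motif discovery from display repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminative peptide motif discovery from display repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Screening a random peptide display library against the antibodies in a serum
specimen, then deep-sequencing the bound library members, yields a list of
unique peptides per specimen — an antibody specificity repertoire of
typically several million 12-mers. Disease-specific binding signals hide in
these lists as short, partially degenerate amino-acid motifs shared by many
bound peptides of affected individuals but not of controls. `imune`
implements a pattern-counting route to those motifs: instead of aligning
peptides to each other, it counts a fully enumerated space of short
templates in every sample and asks, template by template, whether case
samples carry statistically more copies than chance predicts while control
samples do not.

## The model

### Patterns and their expected counts

A *pattern* is an ordered template of $k$ defined residues interleaved with
wildcards, with defined first and last positions, $3 \le k \le 5$ and span
$L \le 10$. The space of such templates over 20 residues has

$$\sum_{k=3}^{5}\ \sum_{L=k}^{10} \binom{L-2}{k-2}\, 20^k = 416{,}928{,}000$$

members. Under the null model — peptide positions independent, residue $a$
used with the sample's overall frequency $f(a)$ — the expected number of
offset matches in $N$ unique peptides of length $\ell$ is

$$E = N\,(\ell - L + 1) \prod_{j \in \text{defined}} f(a_j),$$

wildcards contributing a factor of one. Observed counts $O$ are totals over
offsets (not peptides), which keeps $O$ and $E$ on the same scale; at
realistic match rarity the two conventions differ negligibly. Enrichment is
$R = O/E$ and significance is the Poisson exceedance
$p = P(X \ge O),\, X \sim \mathrm{Poisson}(E)$, computed through the
regularized incomplete gamma function so that far tails ($p < 10^{-300}$)
remain ordered. The tail includes the observed count, so $O = 0$ gives
$p = 1$: an unobserved pattern is maximally non-significant, which is what
the control-side conditions need.

The per-sample frequencies $f$ are estimated from the sample's own retained
peptides. Ideally one would use the unselected library's frequencies, but
those are generally unavailable; using the selected peptides is slightly
conservative for strongly selected residues.

### Why at most five defined positions

$E$ shrinks geometrically in $k$. At the repertoire-size lower limit
$N = 1.5\times 10^6$ with uniform frequencies, the worst allowed template
($k = 5$, $L = 10$) still has $E = 1.5\times10^6 \cdot 3 \cdot 0.05^5 =
1.40625 \ge 1$. Keeping $E \ge 1$ matters doubly: the Poisson test has
resolution, and — just as importantly for scoring — a single chance match
cannot masquerade as a large enrichment. The synthetic cohorts used in the
test-suite respect the same floor at their smaller $N$ by using a reduced
residue alphabet (see below).

### Selection methods and run modes

Three methods decide whether a pattern is retained, all parameterized by a
`selection_criterion()`:

* **Poisson**: $p < p_\text{sig}$ (default $10^{-4}$) in at least a fraction
  (default 50%) of case samples *and* $p > p_\text{nonsig}$ (default 0.0313)
  in at least a fraction (default 100%) of controls. The 0.0313 default is
  the printed form of $0.50/16$: with 16 discovery case samples, a pattern
  clearing that bar in *every* control has at most a 50% family-wise chance
  of having enriched anywhere by luck.
* **Standard deviation**: enrichment at least `sd_multiplier` (default 4)
  sample standard deviations above the control mean, in the required
  fraction of cases. Zero-variance control sets are handled by flooring the
  SD at `sd_floor` (default 0.01 enrichment units) — the degenerate case is
  real on desk-scale data where every control count can be identical.
* **ROC**: some threshold simultaneously reaches the required sensitivity
  and specificity; ties across the group boundary require a strict
  separator.

Required fractions convert to counts by rounding up ("at least 50% of 16"
means ≥ 8). The five standard run modes map these methods onto a cohort:
case-enriched Poisson (i) and SD (ii), the control-enriched mirror images
(iii, iv), and a combined-cohort Poisson run (v, default sensitivity 0.8)
which states no non-significance condition — accordingly `select_poisson()`
treats an empty control vector as vacuously satisfied rather than an error.

### Counting strategy

Testing $4.2\times10^8$ patterns against millions of peptides is the wrong
direction. The scan inverts it: each 12-mer contains exactly 1,074
(layout, offset) sub-pattern instances at the default bounds, and emitting
those into an accumulator makes the work $N \times 1{,}074$ per sample.
Small restricted alphabets use a dense array indexed by layout and packed
residue codes; larger alphabets fall back to a hash, and the pattern space
can additionally be processed in deterministic first-residue shards
(`run_config(shards = )`) with results identical to a single pass — the
memory contract when a full 20-letter accumulator would not fit. Patterns
are carried as packed integer keys until the (much smaller) candidate set is
materialized as notation strings.

Candidates are prefiltered to patterns observed — for the Poisson method,
significant — in at least the required number of case samples. The filter is
exact, not an approximation: every selection method requires positive
enrichment in that many case samples, and an unobserved pattern has $R = 0$,
$p = 1$.

## Motif clustering

Retained patterns are partitioned into *motif seeds* (patterns containing no
other retained pattern) and *children* (everything else; each child contains
one or more seeds). Seeds are related by ungapped PAM30 alignment over all
frames, scoring only positions where both patterns are defined; a pair is
related at score ≥ 5, and the equivalent motif-level threshold is 10. The
one-sided case (defined column against wildcard) contributes zero — the
symmetric, conservative reading of a rule whose source only fixes the
neither-defined case.

A seed's motif is built from all patterns connected to it (children, related
seeds, their children), each anchored at its best-scoring frame against the
seed (ties take the smallest offset), weighted by its summed enrichment over
the case samples. Residue $a$ enters column $j$ when

* its weighted frequency in that column is at least 1.5× its expected
  frequency, and
* the Poisson exceedance of its weighted count, at rate (total alignment
  weight × expected frequency), is below $10^{-4}$ — evaluated through the
  gamma tail so non-integer weighted counts pose no problem.

Two design choices here were genuinely open and deserve their rationale:

* **Column frequency denominator.** Frequencies are taken over the *total*
  weight of all aligned patterns — the rows of the alignment, blanks
  included — not over the weight of patterns that happen to define the
  column. The per-column denominator looks natural but degenerates: an outer
  column covered by a single high-weight pattern has frequency 1.0 there and
  passes any ratio test, so motifs sprout junk columns and can grow past 20
  positions. With the whole-alignment denominator a residue only qualifies
  when a substantial share of the connected patterns agrees on it, and
  reconstructed motifs match the planted epitopes cleanly.
* **Ordering tie-breaks.** Seeds (and merged motifs) are ranked by
  connected-pattern count. On desk-scale cohorts the relatedness graph is
  dense and these counts tie almost universally; a purely lexicographic
  tie-break can then promote a *sparse* seed — one whose defined positions
  are few and far apart — whose related seeds cannot anchor at their true
  register because no alignment frame overlaps their defined positions. The
  resulting consensus is a frame-shifted chimera. Ties therefore break
  toward seeds with more direct children (their members anchor at exact
  containment frames) before falling back to lexicographic order.

Ranked motifs are reduced to a non-redundant list by walking down the
ranking and keeping each motif whose source seed was not already consumed by
a kept motif (a kept motif consumes its source seed and its related seeds).
On a cohort dominated by one epitope this list is intentionally short —
often a single motif — so classification panels are drawn from the leading
*distinct* variants of the full ranked list (`motif_panel()`), mirroring how
variant panels are used in practice.

## Motif scoring and classification

Because expected counts must stay near or above one, motif enrichment per
sample is evaluated over exactly `min(5, defined columns)` defined columns:
every subset of that size is reduced to a motif spanning its outermost
chosen columns and the maximum enrichment over subsets is reported
(`motif_enrichment_top5()`). The search is exhaustive — at most
$\binom{10}{5} = 252$ subsets — and maximization is per sample (a global
subset is available by fixing the subset externally). Subsets whose span
exceeds the peptide length are simply not scoreable and are skipped; only a
motif with no scoreable subset errors. A subset that can never match in a
sample (a required residue set with zero total frequency) scores 0 rather
than undefined: such residues cannot have been observed.

A sample classifies positive under `panel_rule()` when one panel motif
reaches the primary enrichment threshold (default 15) and a *different*
motif reaches the secondary threshold (default 5). The defaults are the
empirical separation band between affected and control repertoires for the
gliadin-like epitope family; the secondary threshold sits at the lower edge
of the "moderate" band.

## The synthetic-cohort generator

`cohort_spec()` / `simulate_cohort()` generate cohorts with i.i.d.-residue
background peptides (rejection-resampled to uniqueness) and planted
motif-bearing peptides: bracket columns realized uniformly, flanks drawn
from the background profile, offsets uniform. Plants *replace* background
peptides so that $N$ stays fixed and enrichment effects are isolated from
library-size effects. Everything derives from one integer seed;
`make_cohort()` writes byte-identical files for equal seeds. An optional
per-residue substitution noise is deliberately absent by default — the
error-collapse stage (`build_nonredundant_set()`, greedy Hamming-distance
absorption with a pigeonhole partition index) is exercised by its own unit
fixtures instead.

The bundled study conditions are an 8-case / 8-control cohort,
$N = 10^5$ unique 12-mers per sample, the epitope `QPEQPF[PS]E` spiked into
0.5% of case peptides, and a background uniform over the epitope's five
residues plus two decoys (`{Q,P,E,F,S} ∪ {W,K}`). The 7-letter background is
not a convenience: at $N = 10^5$ it keeps five-position expected counts at
$10^5 (1/7)^5 (\ell - L + 1) \approx 18$–$48$, the scaled-down analogue of
the $1.5\times10^6 \times 0.05^5$ floor above. With a full 20-letter
background at this $N$, expected counts drop to ~0.1 and single chance
matches would hand control samples enrichments above the classification
thresholds — no implementation of these statistics could separate the
groups, and passing tests would say nothing about real data. What the
7-letter world does *not* emulate: real repertoires' non-uniform residue
usage, position effects, correlated peptide families, and sequencing error;
recovery there demonstrates the machinery, not clinical performance.

Problem sizes in the test-suite follow the same logic scaled to the
property being checked: oracle comparisons run at $N \le 400$, scan
behaviour at $N = 4$–$5\times10^3$, end-to-end recovery at $N = 10^5$, and
null calibration (no plant, five seeds, nothing retained) at
$N = 2\times10^4$.

## Numerical choices and degenerate inputs

* Poisson tails via `ppois(..., lower.tail = FALSE)` / `pgamma()` in log
  space; agreement with a summed-pmf oracle to $10^{-10}$ relative error is
  part of the test-suite.
* Read collapse is greedy by descending read count, ties lexicographic;
  candidates are absorbed by the first retained neighbour within distance.
  The partition index splits peptides into `max_mutations + 1` segments so
  at least one segment of any near-duplicate matches exactly.
* Sharded scans and restricted-alphabet scans are bit-identical to their
  single-pass / filtered counterparts (tested).
* Zero-frequency residues: expected counts of 0 mark a pattern unobservable
  in that sample; such patterns are excluded from selection there and score
  0 in motif enrichment.
* A seed whose alignment produces no qualifying column falls back to the
  seed itself as a singleton-column motif.

## Limitations

* The collapse operates on amino-acid Hamming distance; codon-level error
  structure is not modelled.
* No multiple-testing correction across the $4.2\times10^8$ patterns —
  specificity is controlled empirically through the control group, so
  control cohort size and cleanliness carry the error-rate burden.
* Motif construction anchors every connected pattern to a single seed
  frame; internally repetitive epitopes can still leave minority registers
  in the alignment, which the column rules usually, but not always, filter.
* The `[PS]`-style alternative columns are the hardest feature to recover
  at low spike depth: each alternative carries roughly half the column's
  weight, so the bracket column is typically the first casualty (recovery
  of 7 of 8 columns in the bundled conditions).
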