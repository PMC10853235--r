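---
title: "Methods: benchmarking, merging and prioritising MEI calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benchmarking, merging and prioritising MEI calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meibench)
```

## The problem

Mobile element insertions (MEIs) — new germline copies of Alu, LINE-1 (L1)
or SVA retrotransposons — are a rare but recurrent cause of Mendelian
disease. Short-read callers detect them from clusters of discordant read
pairs (DP) and split/clipped reads (SR), but the callers disagree with each
other, emit heterogeneous formats (VCF, BED, tool-specific text), and
produce many false positives on exome (ES) capture data, where only
fragments of an inserted element are sequenced. `meibench` implements the
computational layer *downstream* of the callers: putting call sets into one
data model, scoring them against truth sets, filtering them on read
support, merging them across tools and samples, and running the
rare-disease prioritisation cascade that turns a cohort's merged call sets
into a short list of candidate diagnostic insertions.

Running the callers themselves, aligning reads, visual IGV review and
wet-lab validation are out of scope; the package starts at call sets and
ends at a candidate report.

## Data model and coordinate conventions

Every call is reduced to a single 1-based breakpoint. BED-style inputs
convert as `start + 1`; interval calls (some callers report wide insertion
intervals) use the interval midpoint. All chromosome names are compared
after stripping a `chr` prefix, so mixed GRCh37 dialects interoperate.
Window arithmetic is inclusive at both ends everywhere — matching, target
restriction, merging and cohort overlap all treat "± k bp" as a closed
interval — because a single consistent convention is a precondition for the
conservation laws the tests assert (TP + FP = predictions,
detected + FN = references).

Calls lacking SR or DP fields get 0, which fails read-support filters.
This is the conservative choice for benchmarking: support that a tool did
not report is not assumed to exist.

## Matching predictions to truth

A truth insertion is localised best by its target site duplication (TSD),
the short duplicated sequence created on insertion. The matching window is
therefore the TSD interval padded by 10 bp when the TSD is known, and
± 50 bp around the bare breakpoint otherwise. A prediction matches a
reference if its breakpoint falls in the window on the same chromosome and,
by default, the element classes agree (an `unknown` prediction matches any
class). Class agreement is the stricter reading and is switchable
(`require_class = FALSE`), since per-class accounting does not by itself
fix the matching rule.

Assignment is greedy and deterministic: each prediction goes to the nearest
reference breakpoint among its in-window candidates, ties broken by the
lower reference coordinate, then the lower reference index. A reference may
absorb several predictions — all count as true-positive *predictions*
(precision is defined at the prediction level) while the reference counts
as detected once (sensitivity is defined at the reference level). This
keeps both definitions literal and the conservation laws exact. The
interval-indexed implementation (IRanges) is checked pair-for-pair against
an index-free brute-force scan on a thousand random instances in the test
suite.

Precision is TP/(TP+FP), sensitivity TP/(TP+FN) at the reference level,
and the F-score their harmonic mean, defined as 0 when the denominator is
0. With zero predictions, precision is reported as `NA` (undefined) rather
than 0.

## Read-support filtering

Two strategies are provided. The *common* filter is fixed: at least 5
supporting reads (SR + DP) of which 2 split reads on exome data, at least
10 of which 2 on genome data. Caller-specific flags can additionally drop
calls (e.g. MELT's `ac0`, no ALT evidence at genotyping). The *optimised*
strategy grid-searches threshold combinations on a training benchmark and
selects the highest F-score, with a fully specified tie-break (higher
precision, then lower total-support threshold, then lower SR threshold),
because F ties are common on small truth sets. The default grid crosses
total support {2, 3, 5, 8, 10} with SR {0, 1, 2, 4} and optionally a
quality floor at the data median; callers report incomparable quality
scores, so quality is abstracted to a single "larger is better" real.
`evaluate_on_holdout()` applies a trained spec to held-out data with no
refitting.

## Merging call sets

Merging uses single-linkage clustering per chromosome (and per element
class by default): breakpoints are sorted and a new site starts when the
gap to the previous breakpoint exceeds the tolerance (50 bp by default,
inclusive). Transitive chains can therefore span more than the tolerance
end-to-end; consecutive member breakpoints never do. This is the simplest
deterministic reading of "± 50 bp tolerance" and is the same overlap rule
the cohort frequency computation needs. The site's representative
breakpoint is the lower median of member breakpoints; in class-agnostic
mode the site class is a majority vote, ties yielding `unknown`.
Class-aware merging is the default so co-located Alu and L1 calls stay
distinct sites, matching per-class site accounting; the naive union-find
single linkage is the test oracle.

## The prioritisation cascade

`prioritize()` applies, in order: (1) restriction to exome target regions
(breakpoint within ± 50 bp of a capture interval), (2) removal of sites
carried by any unaffected sample, (3) exclusion of known insertion
polymorphisms (dbRIP-style catalogue, ± 50 bp, class-aware), (4) a
carrier-frequency filter, (5) a gene-panel filter, optionally restricted to
exonic/splice-region hits. Surviving counts are logged per stage so a
cascade audit is reproducible.

Design choices where the procedure is underdetermined:

* **Frequency** is carrier count over *all* cohort samples (affected and
  unaffected), computed from the full occurrence table regardless of what
  earlier stages removed, and compared strictly (`< max_freq`). The
  boundary is excluded: 3 carriers in 10,000 samples is exactly 0.03% and
  is *not* retained under a 0.03% cutoff. Frequency is per sample, not per
  family (switchable by supplying family-collapsed metadata).
* **Choosing `max_freq`**: a cutoff like 0.03% is meaningful in cohorts of
  several thousand samples, where it passes singleton carriers (1/6247 =
  0.016%) while removing recurrent polymorphisms. In small cohorts the same
  percentage excludes even singletons — at n = 500 any carried site has
  frequency ≥ 0.2% — so simulation studies at n = 500 in this package use
  `max_freq = 0.3%`, which preserves the cutoff's intent (singletons pass,
  recurrent sites fail) at that cohort size.
* **Unaffected exclusion** removes a site carried by *any* unaffected
  sample, the literal strong reading; a pathogenic insertion shared with a
  healthy parent is therefore lost at this stage, which is the documented
  cost of the rule.
* **Splice regions** are defined as ± 8 bp of an exon boundary. No
  standard width exists; 8 bp covers the canonical donor/acceptor motifs
  and is configurable in the gene annotation.
* The known-site pad reuses the ± 50 bp convention for consistency with
  merging and frequency overlap.

## Diagnostic-yield statistics

Yield is reported as a binomial proportion with a Wald
(normal-approximation) interval clipped at zero,
`p ± z·sqrt(p(1−p)/n)`, rendered as percent with half-up rounding to three
decimals. The Wald form was adopted because it is how rare-event
diagnostic yields are conventionally reported, including the clipped zero
lower bound at small counts, which an exact (Clopper–Pearson) interval
does not produce. Cohort comparisons use the two-sided Fisher exact test in its
probability-mass definition (sum over tables with probability not
exceeding the observed), delegated to `stats::fisher.test` and verified in
the tests against full hypergeometric enumeration. Clinical sensitivity is
the per-tool fraction of validated diagnostic cases detected; concordance
is the fraction detected by every tool.

```{r stats}
wald_ci(3, 6247)
wald_ci(7, 33509)
fisher_exact_2x2(3, 6247 - 3, 7, 33509 - 7)
```

## What the simulator emulates — and what it does not

The generator exists so every stage is testable without external data. It
emulates, with configurable parameters:

* truth sets with the germline MEI class mix (88% Alu, 9% L1, 3% SVA by
  default) and TSD intervals of 5–20 bp, known for 80% of sites;
* per-tool behaviour: class-specific sensitivity, breakpoint jitter
  (rounded normal, sd 2 bp by default — split-read callers are
  near-base-precise), uniform false positives at a per-Mb rate, and
  negative-binomial read support (over-dispersion typical of capture data)
  split into SR/DP by a binomial fraction. False-positive calls draw
  support from a distribution with half the true-call mean, reflecting the
  sparser evidence behind spurious clusters;
* cohorts: a gene model (30 genes × 5 exons of 200 bp on a 10 Mb region —
  exome-scale, keeping per-sample call counts in the tens as on real
  capture data), two gene panels, polymorphic sites segregating at
  configured carrier frequencies (0.5–5% by default, also serving as the
  known-polymorphism catalogue), and pathogenic spike-ins placed inside
  exons of panel genes of distinct affected samples.

Two placements are deliberately unrealistic to keep ground-truth labels
unambiguous, and are the main caveat on what passing tests show: false
positives avoid the matching windows of truth sites, and cohort false
positives additionally avoid target regions. Real exome false positives
*do* fall in target regions; the end-to-end "exactly the spiked sites"
recovery therefore demonstrates the cascade's logic, not its false-positive
burden on real data. Likewise the simulator has no linkage structure, no
read-level errors, no capture-kit variability, and emits no insertion
sequence, so it cannot exercise sequence-based validation at all.

Default study sizes (chosen once, as the package's own conditions): truth
sets of 1,000–2,000 sites for parameter recovery, 500-sample cohorts with
300 affected, 50 polymorphic sites and one spike for the end-to-end runs,
with 50 replicate cohorts in the recovery study.

## Numerical and degenerate-input choices

* All generators are deterministic under a seed and restore the caller's
  RNG state.
* Empty call sets, empty truth sets and empty site lists are legal
  everywhere; metrics that would divide by zero return `NA` markers and
  F = 0.
* Breakpoints are integer; the BED midpoint rule rounds down on half
  positions.
* Point-in-interval queries merge overlapping intervals and use a sorted
  lookup; matching uses IRanges overlap indexing. Both paths are oracle-
  checked in the tests.
* Percent rendering rounds half-up (3 decimals for CI bounds, 2 for
  rates), matching how yields are conventionally printed.

## Known limitations

* No genotyping of insertions (het/hom), no inheritance-model inference
  beyond what carrier metadata gives, no second-hit logic for recessive
  genes, and no pathogenicity assessment: the candidate report is where a
  human review starts.
* The optimised filter searches a generic threshold grid; caller-specific
  parameter spaces must be supplied by the user as custom grids.
* Only three generic input dialects (VCF, BED, canonical TSV) are parsed;
  exotic tool outputs need a column map.
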