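---
title: "Correlation strategies, odds-ratio scoring and selection-integration for miRNA-target detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation strategies, odds-ratio scoring and selection-integration for miRNA-target detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtpcor)
```

## The model

miRNAs repress their targets post-transcriptionally, so across a set of
paired samples a miRNA's expression profile should anti-correlate with
the profiles of the genes it regulates. `mtpcor` formalizes the space of
choices implicit in this idea. A *strategy* picks, for each side of a
candidate pair, a representative profile:

* **C** — the feature's own CPM profile (counts per million; raw counts
  are normalized as `value / colsum * 1e6` per sample),
* **E** — the eigengene of the feature's co-expression module: the first
  principal component of the module's member-by-sample matrix after
  per-feature standardization (mean 0, population sd 1), unit norm,
* **H** — the module's hub profile: the CPM row of the member with
  maximal |kME| (absolute correlation with the eigengene).

Seven gene x miRNA combinations are evaluated (`Cg_Cm`, `Eg_Cm`,
`Hg_Cm`, `Eg_Em`, `Eg_Hm`, `Hg_Em`, `Hg_Hm`). Combinations correlating a
miRNA module representative with individual gene CPM profiles are
excluded from the set, as no published workflow uses them. Under a module
strategy, the module-level correlation is broadcast to every member pair,
which is the only reading under which all strategies produce pair-level
detections.

Detection applies a strict threshold to the Pearson correlation of the
two representatives: `r < t` over the anti-correlation grid
t = -0.90, -0.85, ..., -0.50, or `r > t` over 0.50, ..., 0.90 in the
positive mode (`corr_type = "higher"`). Boundary values are excluded and
missing or degenerate correlations (unassigned features under a module
strategy, zero-variance profiles) are never detected.

## Scoring against a pair database

Each detection set is compared with a database of predicted/validated
pairs over a pair universe via the 2x2 table (a, b, S_d, R): detected and
in the database, detected only, in the database only, neither. The score
is the cross-product odds ratio `OR = (a*R) / (b*S_d)` with a one-sided
(greater) Fisher's exact test: the question is over-representation of
database pairs among detections, and a two-sided test would penalize
depletion, which is not of interest. Precision, recall, specificity and
accuracy are reported alongside (any 0/0 is `NA`).

Two universes are used. The *overall* universe is all expressed-miRNA x
candidate-gene pairs, pooled: it rewards strategies that work for the
well-annotated miRNAs, because those dominate both numerator and
denominator. The *specific* universe is one miRNA's pairs with the
candidate genes, so the same miRNA appears in numerator and denominator
and uneven database coverage across miRNAs cancels. Database pairs whose
features are not expressed lie outside both universes and are excluded
before counting.

When reporting ORs, a Haldane-Anscombe correction (0.5 added to every
cell if any cell is zero) keeps strict-threshold tables finite — at
strict thresholds `b = 0` is routine. The exact test always uses the
uncorrected table. ORs are undefined (`NA`) when the universe or its
database slice is empty.

## Selection-integration

For each miRNA, all (strategy, threshold) combinations with a finite OR
and `p < alpha` (default 0.05) are ranked by OR descending. Ties are
broken by stricter threshold first (higher |t|: equal OR at a stricter
cut means higher-confidence pairs), then by the canonical strategy order
above, then by smaller p-value; the ordering is total, so selection is
deterministic. The top combination is selected; a miRNA with no
significant combination yields no targets rather than a best-effort
guess. The integrated mTP set is the union over miRNAs of the selected
detection sets, annotated with correlation and database membership
(`db_only = TRUE` restricts to database pairs, the subset a functional
analysis would use).

No multiple-testing correction is applied by default, matching how such
strategy comparisons are usually reported; this is a real caveat at 63
combinations per miRNA, and `fdr = TRUE` filters on Benjamini-Hochberg
adjusted p-values across a miRNA's combinations instead.

### Robustness protocol

Databases grow and change, so the ranking's stability matters. For each
of `n_reps = 40` replicates, `floor(0.75 * |db|)` pairs are kept
(uniform, without replacement, seeded `base_seed + replicate` so
replicates are order-independent and individually reproducible),
specific ORs are recomputed from the cached correlations — only the
database changes — all combinations are re-ranked, and the rank of the
full-database top combination is recorded (`NA` if it fell below
significance). Fraction and replicate count are configurable; floor
rounding resolves non-integer subsample sizes.

## The synthetic generator

`generate_dataset()` emulates the statistical structure the strategies
assume, not sequencing itself. Co-expression is induced by latent
Gaussian sample factors: each module has a latent profile; a member's
log-scale signal is `loading * latent + sqrt(1 - loading^2) * noise`
(loading 0.8 for background modules); log-expression is the signal times
a log-scale sd of 0.3 around a per-feature lognormal baseline
(`exp(N(log 200, 1))`), exponentiated and rounded to 4 decimals so TSV
round-trips are exact. The mild log-scale sd keeps observed CPM-scale
pair correlations close to the configured latent coupling; with stronger
dispersion, exponentiation plus CPM compositional effects attenuate a
configured coupling of -0.9 well below the detection grid.

Two planted architectures:

* `regulation = "feature"` — each of the 3 regulator miRNAs (the DEM set)
  has 15 target genes whose profiles load 0.9 on the (sign-flipped)
  regulator latent and 0.3 on their module latent. The signal lives in
  individual profiles, so `Cg_Cm` should win.
* `regulation = "module"` — each regulator couples to a dedicated gene
  module's latent (cor 0.9); members load only 0.55 on that latent, so
  individual profiles sit at or below the detection grid while the
  eigengene, which averages member noise away, sits well above it.
  Regulated modules are 4x the planted-target count: a module driven by a
  miRNA through a subset of direct targets, with co-expressed non-targets
  as the usual cost of module strategies. Smaller regulated modules (just
  the 15 targets) make the sample PC1 unreliable at 12 samples and
  dissolve the architecture. Module-summary strategies (`Eg_Cm`/`Hg_Cm`)
  should win here; at this sample size the hub is a noisy surrogate of
  the eigengene (its kME is typically above 0.9), so the two are
  near-interchangeable and architecture recovery is judged at the level
  of the gene-side representative class.

Defaults describe a small disease study: 12 samples, 500 genes in 5
modules, 60 miRNAs in 3 modules, 10% of features unassigned (module
`"0"`), regulators left unassigned on the miRNA side, database = 80% of
planted pairs plus 1500 decoy pairs (about 5% of the 60 x 500 universe,
echoing predicted-database density). `null_dataset()` forces coupling 0:
no planted pairs, decoys only — the configuration used for calibration
checks. Everything is deterministic given `seed`, with the global RNG
state left untouched.

What the generator does **not** emulate: read-level sampling and
count overdispersion (values are scaled lognormal, since the method
consumes CPM correlations, the correlation structure matters and the
marginal family does not), clustering error (module assignments reflect
the generative truth exactly, isolating the method from upstream WGCNA
choices), batch effects, and miRNAs regulating overlapping target sets.
Tests passing on these data therefore validate the method's logic and
calibration, not its behavior under real-data artifacts.

## Numerical and interface choices

* **Eigengene sign**: oriented so its correlation with the mean
  standardized member profile is non-negative; if that correlation is
  numerically zero (|r| <= 1e-10, e.g. a two-member anti-correlated
  module whose PC1 is orthogonal to the mean profile), the first non-zero
  entry is made positive. Recomputation is bit-identical.
* **Standardization** uses the population sd (divisor n); constant member
  profiles are dropped from the PCA with a warning, an all-constant
  module is skipped and its members excluded from the representative map.
* **Hub definition**: max-|kME| member, ties broken by lexicographically
  smallest feature ID. Whether production workflows use max-kME or
  intramodular connectivity is not documented in print; max-|kME| is the
  convention here and is stated prominently rather than guessed further.
* **ID matching** is exact and case-sensitive; `lowercase_ids = TRUE`
  normalizes all IDs at load time. miRNA nomenclature differs across
  databases and miRBase releases; normalization must be explicit, never
  silent. DEG/DEM IDs absent from the matrices are dropped with a
  warning.
* **Candidate sets**: the miRNA side defaults to DEMs
  (`mirna_set = "expressed"` widens it), the gene side to all expressed
  genes (`gene_set = "deg"` narrows it); the specific universe follows
  the candidate gene set.
* At least 3 samples are required (Pearson correlation is degenerate
  below that); gene and miRNA matrices must share the same sample order.
* All tables are plain TSV (UTF-8, `#` comments, no quoting); empty
  results still produce headers-only files so the output layout is fixed.

## Problem sizes used in validation

The test suite and the acceptance script validate at the generator's
default sizes: exact-test agreement with enumeration over all 2x2 tables
with margins <= 12; eigengene agreement with an independent SVD oracle on
100 random modules up to 10 x 10; null calibration over 50 seeded null
datasets (60 miRNAs x 500 genes each); architecture recovery over 20
(feature) and 40 (module) seeded datasets; and the subsampling protocol
at 40 replicates. These sizes give stable Monte-Carlo estimates while a
full run of the suite stays fast.

## Known limitations

Pearson correlation only (no rank or partial correlation); no
consensus/voting integration across strategies; no confidence intervals
on odds ratios; per-miRNA ranking with unadjusted p-values by default;
database quality bounds what an odds ratio against it can mean — a
"decoy" pair may be a true but unannotated target, and conversely. The
OR-based ranking is unstable when detection counts are tiny (one or two
pairs can produce a large, significant OR); the robustness protocol is
the tool for judging whether a selection survives database perturbation.
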