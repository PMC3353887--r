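---
title: "Methods: ortholog projection, network significance and toxicity calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ortholog projection, network significance and toxicity calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthotox)
```

`orthotox` analyses screens that transfer DNA-damage survival phenotypes
from the yeast deletion collection to human cells through orthology. This
vignette documents the statistical procedures, every tunable constant, the
assumptions behind the synthetic-data generator, and the design decisions
taken where the underlying methodology left genuine freedom.

## Homology projection

Ortholog evidence arrives as (yeast ORF, human gene, source) triples from
two databases with partially overlapping coverage. `merge_ortholog_sources()`
defaults to the **union** of distinct (yeast, human) pairs, with source
labels collapsed per pair: for a discovery screen, recall matters more
than requiring both databases to agree, and the intersection remains
available as an option. Identifiers are upper-cased; no alias resolution
is attempted, because identifier mapping errors should surface rather than
be silently patched.

`project_phenotypes()` uses an **any-ortholog rule**: a human gene is a
modulator homolog as soon as one of its yeast orthologs is sensitive to at
least one agent. A gene orthologous to both a sensitive and an
insensitive yeast gene is therefore a modulator homolog; this keeps the
modulator / non-modulator partition disjoint and exhaustive over all
human genes with at least one screened ortholog. Yeast ORFs absent from
the phenotype table are dropped with a warning count — treating an
unscreened gene as insensitive would silently convert missingness into
evidence. Homologs of yeast genes sensitive to *every* agent form the
core set, which the selection stage treats specially.

## Induced-LCC significance

The connectivity statistic is the size of the largest connected component
(LCC) of the subgraph induced by the modulator homologs on the
interactome. Because query genes can be missing from the network, the
LCC fraction is reported against both denominators (genes mapped into the
network, and the full query); when no query gene maps, the result is an
explicit undefined marker, never 0. Ties between equally large
components are broken by the lexicographically smallest member so results
are order-independent.

`permutation_test_lcc()` draws node sets of the same mapped size and
recomputes the LCC:

* **uniform** null (default): nodes sampled uniformly without
  replacement;
* **degree-matched** null: sampling within geometric degree bins
  (1, 2, 3–4, 5–8, …, isolated nodes in their own bin), offered because
  hub genes inflate connectivity. Which null is appropriate depends on
  whether hub membership itself is considered signal; both are reported
  in the documentation and the uniform null is the package default.

The p-value is the add-one estimator $(n_{\ge} + 1)/(N + 1)$. When no
permutation reaches the observed LCC the result is flagged
`p_is_upper_bound` and is never reported as zero — a Monte-Carlo test can
only bound, not measure, very small p-values. Two numerical consequences
are worth stating. First, the estimator is slightly conservative, and the
LCC size is a discrete statistic, so under a true null the p-values are
*super-uniform* (stochastically larger than uniform) rather than exactly
uniform; the test suite checks validity (the empirical CDF never exceeds
the uniform CDF beyond Monte-Carlo error) together with a bounded
Kolmogorov–Smirnov distance, not exact uniformity. Second, permutations
are mutually independent and seeded, so results are reproducible and
embarrassingly parallel in principle; the implementation is serial, which
is adequate at the problem sizes below.

Functional enrichment of subnetworks uses the upper-tail hypergeometric
probability $P(X \ge k)$ per annotation term, with Benjamini–Hochberg
adjusted values attached alongside the raw p-values.

## Candidate selection

`select_candidates()` is an ordered rule pipeline with a per-gene audit
trail (`trace`), because a selection that mixes hard filters with
judgement calls is only trustworthy when every exclusion can be traced to
the first failing rule. The order is deliberate:

1. core-set homologs (all-agent-sensitive orthologs) are auto-included
   *before* any exclusion — the core set is included for its phenotype
   strength regardless of functional category;
2. restriction to LCC members (`require_in_lcc`, default on);
3. exclusion by category (defaults: DNA repair, cell cycle control,
   ribosomal protein) — the screen targets novel biology, not known
   repair factors;
4. expression filter: microarray intensity strictly greater than 100
   units (a gene missing from the expression table counts as not
   expressed, logged);
5. ranking by (core, one-to-one orthology, preferred category, network
   degree) descending, gene symbol as the final deterministic tiebreak.
   "Several interactions" is a *rank* criterion, not a cutoff, since no
   defensible threshold exists;
6. truncation so that the final list, including addons, never exceeds
   `max_candidates` (default 45);
7. unconditional append of the `telomere_addon` genes, flagged — telomere
   capping is not conserved by homology, so shelterin-type genes can only
   enter by explicit biological decision, which the package treats as
   configuration rather than inference.

A gene is *one-to-one* when at least one of its yeast orthologs maps to
exactly one human gene in the merged table. The relative weighting of
the preference criteria is lexicographic by construction; this is a
choice, exposed through the rank columns in the output so users can
re-rank.

## Toxicity calling

`relative_survival()` converts colony counts to plating-efficiency
normalized survival: PE is the mean untreated colonies-per-seeded-cell of
each line × agent, each replicate's relative survival is
(colonies/seeded)/PE, capped at 1. Zero-colony replicates receive a
0.5-colony continuity correction (flagged) so log2 ratios stay finite;
survival of exactly zero is unmeasurable in a colony assay, only bounded
by the seeding density.

`build_noise_region()` defines the screen's detection limits: per agent
and dose, every control line (non-targeting shRNA, plus shRNA clones
whose knockdown failed — residual mRNA ≥ 60% — and which therefore
control for off-target effects of shRNA expression) contributes
log2(line mean / non-targeting mean); the region is the min–max interval
and always contains 0.

`call_toxicity()` then requires, at one or more treatment doses, both

* a two-sided **Welch t-test on log2 replicate survivals** against the
  non-targeting control with p < `alpha` (default 0.05), and
* an **excess** beyond the nearest noise-region boundary of at least
  `low_threshold_log2 = 0.26` in absolute value, i.e. a 20% survival
  change beyond anything the control lines show
  ($\log_2 1.20 = 0.263$); the high tier requires
  `high_threshold_log2 = 0.32` ($\log_2 1.25 = 0.322$, a 25% change).

The call takes the qualifying dose with the largest |excess|; positive
excess is resistance, negative is sensitivity. Three choices deserve
justification. The thresholds are interpreted as fold changes of
relative survival, because 0.26 and 0.32 are exactly the log2 of 1.20 and
1.25 — the alternative reading (an absolute survival difference of 0.20)
is inconsistent with those log2 values. The excess is measured from the
noise-region *edge*, not from the control mean, so a call asserts the
line left the region the controls span. The t-test is Welch on log2
values: log2 space matches the thresholds and makes multiplicative noise
homoscedastic, and unequal variances between clonal lines are the rule,
not the exception. Whether the t-test should pool replicates across days
or compare raw rather than log survivals is underdetermined; Welch on
log2 is the documented package convention. **No multiple-testing
correction is applied across lines or doses** — the per-dose test is a
screening filter whose specificity comes mostly from the conjunctive
|excess| gate, and the false-call rate under a pure null is well below
alpha (the test suite measures it). Knockdown QC is a strict boundary:
residual mRNA < 0.60 counts as silenced; a line at exactly 0.60 joins
the control pool.

Screen percentages are rounded to the whole percent with halves away
from zero (`round_half_up()`), which is how such tables are convention-
ally reported. The screen-vs-random-selection comparison is a two-sided
Fisher's exact test on the modulator / non-modulator contingency table;
`fisher_exact_2x2()` flags tables with a zero margin (p defined as 1)
instead of failing. The text heatmap uses `++ + . - --`; the middle dot
and true minus of print figures are rendered as ASCII so TSV output is
encoding-robust. One ambiguity is inherited knowingly: figure legends in
this literature sometimes list the same symbol for high and low
sensitivity; the package renders high sensitivity as `--` by symmetry
with `++`.

## Autophagy scoring

A cell is autophagic when it has strictly more than 5 LC3 puncta (the
threshold is configurable; the strict reading of "more than 5" is taken
literally). Condition comparisons use two-sided Fisher's exact tests on
autophagic/non-autophagic counts — counts are small and the exact test
costs nothing — with chi-square as a large-sample option, fold induction
relative to the untreated reference, and stars at p < 0.05 / p < 0.01.

## The synthetic-data generator

`sim_config()` + `simulate_*()` generate every pipeline input. One master
seed drives a per-generator sub-stream (seed + a stable generator index),
so identical configurations are byte-reproducible and adding a generator
never perturbs the others. What the generator emulates, and the defaults:

* **Orthology**: 30% of yeast genes have a human ortholog (coverage in
  real databases is of that order for the deletion collection); 20% of
  those map to two human genes; each of the two sources independently
  retains 80% of true pairs, giving realistic partial overlap.
* **Phenotypes**: each gene × agent sensitive with probability 0.30 —
  genome-wide damage screens report that roughly a third of deletion
  strains affect recovery — plus a 28-gene core sensitive to all agents.
* **Interactome**: preferential-attachment background (mean degree 4)
  over 2,000 genes, names assigned by random permutation so degree does
  not correlate with gene identity; a planted module of 30 modulator
  homologs wired at probability 0.3 provides the connectivity signal
  (1 gives a clique, 0 the null).
* **Survival**: true relative survival $2^{-\lambda d + e}$ with
  per-agent log2 kill slope $\lambda$ calibrated so the top of the
  default dose ladder (0, 0.5, 1, 2 abstract equitoxic units) leaves
  ~10% control survival; multiplicative log-normal replicate noise
  (mean 1), truncation at 1. Observations are emitted as integer colony
  counts with cells seeded chosen in the 50–5,000 range so ~150 control
  colonies are expected at every dose, and plating efficiency 0.5. The
  default replicate CV is 0.10 — colony assays rarely publish their
  replicate noise, so this is a deliberate, exposed guess, not an
  assertion; the caller-recovery studies in the tests and acceptance
  script use CV = 0.05 with 3 replicates as their stated condition.
* **Knockdown qRT-PCR**: silenced lines draw residuals in
  \[0.10, 0.50\], non-silenced controls in \[0.65, 0.95\], placing both
  groups clear of the 0.60 boundary.
* **Puncta**: a two-component Poisson mixture, basal mean 1 and induced
  mean 15, with a configurable induced fraction per condition. In the
  rapamycin-style test the untreated induced fraction is 0.25 and the
  treated fraction 1.0 — strong autophagy inducers switch essentially
  every cell — giving a fourfold induction with enough counted events
  (200 cells/condition) for the fold to be stable.

What the generator does **not** emulate: day-to-day batch effects and
plate position effects in colony assays; dose-dependent effect sizes
(injected shifts are constant across doses); correlated sensitivities
between agents beyond the all-agent core; literature-derived annotation
structure (terms are assigned independently); and the heavy-tailed
degree correlations of curated interactomes. Passing tests therefore
demonstrate that the statistical machinery is correct and well
calibrated under its stated noise model — not that real screens meet
that model.

## Problem sizes and determinism

The test suite runs the recovery study at 200 effect lines (±0.5 log2)
plus 200 null lines, one agent, 3 replicates, CV 0.05; the null
calibration of the permutation test at 200 seeded simulations of a
200-gene network with 99 permutations each; the exhaustive permutation
check on a 10-node graph over all query sizes against full subset
enumeration; and the exact-test sweeps over all 2×2 tables with total
≤ 40 and all hypergeometric configurations for universes of 8 and 12
(plus randomized larger ones). These sizes were chosen so each property
is measured with comfortable statistical margin while the whole suite
stays quick on a laptop. End-to-end determinism is asserted by running
the full pipeline twice and comparing written stage outputs byte for
byte.

## Known limitations

* Absolute homolog counts from any particular database era are not
  reproducible and are not a target; the pipeline's claims are about
  procedures, rates and calibration.
* The caller is per-dose and nonparametric in dose: no LD50 or
  four-parameter logistic fits, and no borrowing of strength across
  doses.
* The permutation test reports bounds for p-values smaller than
  1/(N+1); analytic tail extrapolation is out of scope.
* The degree-matched null uses binned degree matching, not edge
  rewiring; very high-degree nodes in small bins can constrain the
  sample space.
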