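# orthotox

Cross-species projection of DNA-damage survival phenotypes, and the
statistics of the RNAi screen that validates it.

Genome-wide yeast deletion screens show that a large fraction of genes —
far beyond the canonical repair pathways — modulate survival after DNA
damage. `orthotox` implements the computational arm of the strategy that
carries those phenotypes into human cells, for researchers analysing
ortholog-guided knockdown screens:

1. **Homology projection.** Two ortholog tables (e.g. Ensembl-style and
   Inparanoid-style) are merged and yeast damage-sensitivity calls for a
   panel of agents (MMS, 4-NQO, t-BuOOH, UV) are projected onto human
   genes, partitioning homologs into *toxicity-modulator* and
   *non-modulator* sets.
2. **Network connectivity.** The modulator homologs are mapped onto a
   protein–protein interaction network; the size of the largest connected
   component (LCC) induced by the set is tested against a permutation null
   (uniform or degree-matched node sampling), with the add-one estimator
   `p = (n_geq + 1) / (n_perm + 1)` and explicit upper-bound semantics
   when no permutation reaches the observed size. Hypergeometric
   functional enrichment of subnetworks is included.
3. **Candidate selection.** An ordered, fully audited rule pipeline:
   homologs of yeast genes sensitive to *every* agent are auto-included;
   the pool is restricted to LCC members; genes with established DNA
   repair / cell cycle / ribosomal annotations are excluded; genes must be
   expressed (microarray intensity strictly above 100); survivors are
   ranked by one-to-one orthology, preferred functional category and
   network degree.
4. **Toxicity calling from clonogenic survival.** Colony counts are
   normalized to plating efficiency; control lines (non-targeting shRNA
   plus non-silenced clones, residual mRNA ≥ 60%) define a per-dose
   *noise region* of log2 survival ratios; a knockdown line is called at
   a dose when a two-sided Welch t-test on log2 replicate survivals gives
   p < 0.05 **and** its log2 ratio exceeds the noise-region boundary by
   at least `log2(1.20) = 0.26` (high tier: `log2(1.25) = 0.32`). Calls
   fall in five categories (`++`, `+`, `.`, `-`, `--`), summarised per
   screen with a two-sided Fisher's exact comparison against a
   random-gene screen.
5. **Autophagy scoring.** Per-cell LC3 puncta counts are thresholded
   (autophagic = strictly more than 5 puncta), with Fisher-exact condition
   comparisons, fold induction and figure-legend stars.
6. **Synthetic data.** Every input above can be simulated with configured
   effect sizes and noise (`sim_config()` + `simulate_*()`), so the whole
   pipeline is testable end to end without any external download.

All user-facing functions take data frames and return tibbles; results
carry `tidy()` / `glance()` methods and `autoplot()` figures.

## Worked example

A fully simulated run: 600 yeast genes projected through two 80%-coverage
ortholog sources onto a 1,200-gene interactome with a planted 30-gene
modulator module, then a 12-line knockdown screen in which half the lines
carry a true ±0.5 log2 survival shift.

```r
library(orthotox)

cfg <- pipeline_config(
  sim = sim_config(n_yeast_genes = 600, n_human_genes = 1200,
                   replicate_cv = 0.05, effect_log2 = 0.5, seed = 1),
  n_permutations = 1000, n_test_lines = 12,
  autophagy_conditions = c(untreated = 0.05, MMS = 0.25), seed = 11)
report <- run_pipeline(cfg)
report
#> <run_report>
#>   217 merged ortholog pairs -> 166 modulator homologs
#>   LCC 58 (35% of mapped genes), permutation p = 0.004
#>   28 candidates, 12 lines called, 50% modulating (25% sens, 25% res, 50% high)

report$permutation
#> <lcc_permutation>
#>   observed LCC 58 (of 166 in network), null uniform: mean 17.1, max 62
#>   p = 0.004 (3 of 1000 permutations >= observed)

format_call_matrix(report$calls)
#> # A tibble: 12 x 5
#>    line      MMS   `4NQO` tBuOOH UV
#>  1 shHSG0154 .     .      .      .
#>  2 shHSG0226 ++    ++     ++     ++
#>  3 shHSG0443 --    --     --     --
#>  ...
```

Reading the output: the 166 modulator homologs are far more interconnected
than random gene sets of the same size (58 of them in one component
against a null mean of 17, permutation p = 0.004), the selection rules
reduce them to 28 candidates, and the caller recovers exactly the six
lines that were simulated with a true effect — `++` marks high
resistance, `--` high sensitivity, `.` no significant modulation beyond
the control noise region. `write_report(report, dir)` writes every stage
as TSV plus a markdown summary; `autoplot(report$permutation)`,
`autoplot(report$calls)` and `plot_survival_curves()` draw the standard
figures.

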