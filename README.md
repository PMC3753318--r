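# sunhka

Sequence-based scan for positive selection during crop domestication and
improvement, built around the maximum-likelihood multilocus
Hudson–Kreitman–Aguadé test (ML-HKA).

## The problem

Domestication reduces diversity genome-wide (the domestication
bottleneck), and continued breeding narrows it further in elite lines.
Superimposed on that background are *locus-specific* losses caused by
directional selection. Separating the two requires comparing each
candidate locus against a panel of putatively neutral loci: under
neutrality, within-species polymorphism and between-species divergence are
both proportional to the locus mutation rate, so a locus that has lost
polymorphism but not divergence is a selection candidate.

`sunhka` implements this design for a stratified panel — wild accessions,
landraces (early domesticates), improved cultivars, plus one outgroup
sequence per locus — as used in candidate-gene studies of cultivated
sunflower. Running the test separately in each gene pool dates the
selection: diversity lost in landraces *and* cultivars points to
domestication, loss confined to cultivars points to modern improvement.

## The model

For locus *i* with sample size *n<sub>i</sub>*, segregating sites
*S<sub>i</sub>* and mean outgroup divergence *D<sub>i</sub>* (both counted
on the same completely-deleted site set) are modelled as independent
Poisson draws:

    S_i ~ Poisson( k_i · θ_i · a_{n_i} ),      a_n = Σ_{j=1}^{n−1} 1/j
    D_i ~ Poisson( θ_i · ( T + (1 + k_i)/2 ) )

with θ<sub>i</sub> the whole-locus population mutation parameter, *T* the
species divergence time (units of 2N generations) shared across loci, and
*k<sub>i</sub>* a selection parameter scaling the focal species'
coalescent depth — *k* < 1 signals a sweep, *k* > 1 balancing selection.
The neutral model fixes every *k* = 1; the selection model frees *k* at
one focal locus. Twice the log-likelihood difference is referred to a
χ² distribution with 2 degrees of freedom (the convention of the
sequence-based domestication scans this package follows; `df` is a knob).
Storey q-values control the FDR across all candidate × pool tests, and
significant loci are screened for fixed non-synonymous differences rare in
the wild pool.

A coalescent (infinite-sites) generator produces study-shaped synthetic
data — count tables and full FASTA alignments — with a genome-wide
bottleneck and locus-specific sweeps planted by role.

## Worked example

Test a candidate with no polymorphism but ordinary divergence against a
seven-locus neutral panel:

```r
library(sunhka)
cts <- data.frame(
  locus = c("cand", sprintf("neut%d", 1:7)),
  S = c(0L, 16L, 21L, 13L, 25L, 17L, 20L, 14L),
  D = c(61L, 55L, 64L, 49L, 70L, 58L, 66L, 52L),
  L = 700L, n = 8L)
fit1 <- mlhka(cts, focal = "cand")
fit1
#> ML-HKA selection (focal: cand) model, 8 loci
#>   lnL = -40.6555,  T-hat = 7.52,  k-hat = 1e-04
anova(mlhka(cts), fit1)
#> ML-HKA likelihood-ratio test
#>                 n_free     lnL   LRT df    p_value
#> neutral              9 -55.896
#> selection(cand)     10 -40.656 30.48  2 2.4058e-07
```

The candidate's selection parameter is driven to the lower bound (`k-hat =
1e-4`: total diversity loss) and neutrality is rejected (LRT = 30.5,
P = 2.4e-07). `scan_candidates()` runs this test for every candidate in
every pool, attaches q-values and timing classes; `run_pipeline()` goes
from a directory of FASTA alignments to the full report.

Re-analysing the bundled published per-locus θ values for the 34-locus
sunflower panel:

```r
s <- summarize_diversity(sunflower_scan_published(long = TRUE))
s[s$pool == "landrace", ]
#>            role     pool n_loci mean_theta loss_vs_wild_pct loss_pct_nearest5
#> 2       neutral landrace      7    0.01111             30.4                30
#> 5 domestication landrace     13    0.00424             60.4                60
#> 8   improvement landrace     14    0.00875             44.1                45
```

Domestication genes lost ~60% of their wild diversity in the landraces,
improvement genes ~45% — the asymmetry expected from how the two classes
were originally identified.

## Layout

- `R/` — sequence I/O, diversity statistics, the ML-HKA fit and test,
  scan orchestration, Storey q-values, variant screen, coalescent
  generator, reporting
- `vignettes/selection-scan.Rmd` — model, assumptions, numerical choices,
  generator design, limitations
- `inst/extdata/sunflower_scan_published.tsv` — bundled published
  per-locus values
- `inst/scripts/sunhka-scan.R` — thin command-line wrapper over
  `run_pipeline()` / `simulate_study()`
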