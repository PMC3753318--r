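---
title: "Methods: the ML-HKA selection scan and its synthetic-data generator"
author: "sunhka"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the ML-HKA selection scan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sunhka)
```

## The model

The multilocus HKA framework compares within-species polymorphism to
between-species divergence. Under neutrality both are proportional to a
locus's mutation rate, so their ratio is informative about selection even
when mutation rates vary across loci. `sunhka` fits the maximum-likelihood
form: for locus $i$ with sample size $n_i$,

$$S_i \sim \mathrm{Pois}\!\left(k_i\,\theta_i\,a_{n_i}\right), \qquad
  D_i \sim \mathrm{Pois}\!\left(\theta_i\,(T + \tfrac{1+k_i}{2})\right),$$

where $a_n = \sum_{j=1}^{n-1} 1/j$, $\theta_i$ is the whole-locus
population mutation parameter ($4N\mu$ summed over sites), $T$ is the
species divergence time shared by all loci (units of $2N$ generations),
and $k_i$ scales the focal species' coalescent depth at locus $i$. The
$(1+k_i)/2$ term carries the ancestral-polymorphism contribution to
divergence: a swept locus ($k \to 0$) loses polymorphism and roughly half
of one $\theta$'s worth of expected divergence, never its
divergence proper. The neutral model constrains every $k_i = 1$; the
selection model frees $k$ at one focal locus within $[10^{-4}, 100]$.

Assumptions worth keeping in view:

* **Counts are Poisson.** The model conditions away the genealogy; the
  extra variance of $S$ caused by tree-length fluctuation (the classical
  HKA variance term $\theta^2 \sum 1/j^2$) is not represented. See
  *Operating characteristics* below for what this does on sequence-level
  data.
* **Free recombination between loci, none within.** Loci contribute
  independent terms.
* **Infinite sites.** Multi-allelic columns count once in $S$; divergence
  counts any mismatch as one event, with no multiple-hit correction
  (`jc_correction` is deliberately absent from the likelihood path — HKA
  operates on raw counts).
* **One sequence per accession.** Phasing of heterozygous SNP sites is
  out of scope; each FASTA record is treated as one haplotype.

## The test and its staging

Each candidate locus is tested against the neutral panel **separately in
each gene pool** (wild, landrace, improved): each pool is a separate
dataset, and $T$ is re-estimated per pool rather than shared, because the
derived pools' effective sizes (hence their time scales) differ from
wild. Before any candidate is tested, the panel itself is validated
leave-one-out (`validate_neutral_panel()`): each neutral locus is run as
the focal locus against the remaining six, and the panel passes when no
test rejects at $\alpha = 0.05$.

The likelihood-ratio statistic $2(\ln L_1 - \ln L_0)$ is referred to
$\chi^2$ with **2 degrees of freedom by default**. One free selection
parameter argues for $df = 1$; the scans this package reproduces used
$df = 2$, and reproducing them takes precedence. `df` is an argument
everywhere (`hka_test(..., df = 1)`), and the choice is conservative —
measured per-test type-I error on count data is about 0.02 at
$\alpha = 0.05$ (a consequence of which is that a seven-locus
leave-one-out panel check passes all seven tests roughly
$0.98^7 \approx 87\%$ of the time, not at higher rates one might guess
from the nominal level).

Timing of selection is classified from the per-pool P-values, rules
applied in order: landrace **and** improved significant →
`domestication`; improved but not landrace → `improvement`; otherwise a
significant wild test → `wild-flagged` (an anomaly — selection is
measured relative to wild ancestry, so wild-only significance dates
nothing, and it is surfaced rather than suppressed); otherwise `none`.
Classification uses raw P-values at $\alpha = 0.05$ (as the scan
tradition does), with q-value-based classification available
(`timing_on = "q"`).

## Multiple testing

Storey q-values are computed across all candidate × pool tests jointly
(the scan's 81-test family in the bundled study; per-pool stratification
is available via `fdr_scope`). The null proportion $\pi_0$ is estimated on
the grid $\lambda = 0.05, 0.10, \ldots, 0.90$ by
$\hat\pi_0(\lambda) = \#\{p > \lambda\}/(m(1-\lambda))$, smoothed with a
cubic smoothing spline (3 df) and read off at $\lambda = 0.9$, clamped to
$(0, 1]$; with fewer than 10 P-values the fixed-$\lambda = 0.5$ estimator
is used instead. With $\hat\pi_0 = 1$ the step-up minimum reduces exactly
to Benjamini–Hochberg, which the tests assert to $10^{-12}$. When
re-analysing published tables, printed P-values of `0.0000` are floored at
$10^{-5}$ — they cannot be exactly zero, and the floor is far below every
decision threshold in use.

## Site handling

All statistics use **complete deletion**: a column containing a gap or an
`N` in any sequence of the analysis set is dropped. For the HKA counts of
a given pool, the analysis set is the pool *plus the outgroup*, so $S$ and
$D$ are counted on the same site set and their lengths stay
commensurable. For purely within-pool diversity summaries
(`diversity_stats()`), deletion is within the pool only, so the two
$L_{net}$ values can differ — a published per-pool table convention.
IUPAC ambiguity codes other than `N` become `N` with a warning (routine in
Sanger data) rather than an error. $D$ is the mean Hamming distance of
ingroup sequences to the single outgroup sequence; the Poisson likelihood
needs an integer, so the rounded value enters the fit and the exact mean
is kept alongside (`D_exact`).

Loci that a pool cannot test ($L_{net} = 0$ or $n < 2$) are excluded from
that pool's scan with a message naming them — the data-level analogue of
dropping unsequencable genes from a study.

## Numerical choices in the fit

The per-locus $\theta_i$ enter the likelihood through one Poisson mean
each and are profiled out in closed form: given $(T, k)$,
$\hat\theta_i = (S_i + D_i)/(k_i a_{n_i} + T + (1+k_i)/2)$, floored at
$10^{-9}$ so expected counts stay positive. This reduces the neutral fit
to a one-dimensional search over $\log T$ (101-point coarse grid on
$\log T \in [\log 10^{-5}, \log 10^{5}]$, then Brent refinement) and the
selection fit to two dimensions over $(\log T, \log k)$: deterministic
starts at the neutral $\hat T$ crossed with $k \in \{10^{-4}, 0.01, 0.1,
1, 10, 100\}$ plus seeded uniform jitter up to `n_starts = 8`, each
polished with box-constrained L-BFGS-B (Nelder–Mead fallback). Multi-start
guards the $S = 0$ boundary, where $\hat k$ sits on the lower bound. The
optimizer is validated against an exhaustive staged grid search (an
independent oracle that grid-searches $\theta$ too) to within $10^{-3}$
log-likelihood units on a fixture set. Fitting never perturbs the
caller's RNG stream: seeded jitter is drawn under a saved-and-restored
`.Random.seed`, so fits can run inside simulation loops.

Degenerate outcomes are handled explicitly: an LRT below $-10^{-6}$
(selection fit worse than neutral) warns and clamps to zero; non-positive
Poisson means are hard errors rather than `-Inf` surprises.

## The synthetic-data generator

The generator emulates the study design it is meant to exercise: 7
neutral loci, 13 domestication candidates and 14 improvement candidates;
8 wild, 6 landrace and 6 improved sequences plus one outgroup; 700 bp
loci; per-site $\theta = 0.01$ in wild; outgroup divergence $T = 8$;
genome-wide bottleneck scalings 0.6 (landrace) and 0.5 (improved), chosen
to match the observed neutral-gene diversity ratios in the bundled table
(0.0111/0.0160 and 0.0086/0.0160); sweep factor $k = 0.05$ at selected
loci, applied in landrace + improved for domestication candidates and in
improved only for improvement candidates. Sweeps are modelled as $\theta$
scaling, not explicit hitchhiking trajectories — matching how the test
detects them. All conventions live in one place: $\theta$ is per site and
equals $4N\mu$, time is in units of $2N$ generations, a branch of length
$t$ carries $\mathrm{Pois}(\theta_{locus}\, t/2)$ mutations.

Two levels of realism are provided deliberately:

* `simulate_counts()` draws $(S, D)$ directly from the Poisson model —
  the exact generative twin of the fitted likelihood. Parameter-recovery,
  type-I-error and power properties are measured here, because they
  isolate the inferential machinery from model misspecification.
* `simulate_alignment()` / `simulate_study()` draw standard
  $n$-coalescent genealogies per pool (independent across pools, exactly
  the independence the likelihood assumes), place infinite-sites
  mutations on branches, and attach the outgroup on a lineage of length
  $2T + 2/n_{wild}$ so that expected wild–outgroup divergence is
  $\theta(T+1)$. The generator's moments are verified against coalescent
  theory in the tests ($E[S] = \theta a_n$,
  $\mathrm{Var}[S] = \theta a_n + \theta^2 \sum 1/j^2$, $E[\pi] = \theta$
  per site).

What the sequence-level generator does **not** emulate: intra-locus
recombination (spec'd out of scope), migration/introgression, a shared
genealogy across pools, sequencing error, or indel processes. The absence
of recombination matters for interpretation: every locus is a single
non-recombining genealogy, which *maximizes* the genealogical variance of
$S$ — real Sanger loci in an outcrossing species with fast LD decay sit
between this worst case and the Poisson ideal.

## Operating characteristics

The package's own test suite measures (rather than asserts from theory):

* type-I error of the $df = 2$ test on 500 neutral count-level datasets
  (7 neutral + 1 focal locus at the default $\theta$ and $T$): well under
  the nominal 0.05;
* power against a $k = 0.05$ sweep with expected neutral $S \approx 10$:
  above 0.80 over 200 replicates;
* end-to-end timing recovery (candidate significant at FDR < 0.05 *and*
  classified with the planted timing) on three full 34-locus studies:
  above 0.70 on both the count-level twin and the FASTA route.

On full-sequence studies the Poisson likelihood is anti-conservative —
the genealogical variance it ignores inflates rejections in pools where
nothing was planted (typically the wild pool), which is why sequence-level
recovery runs noisier than the count-level twin and why panels
occasionally fail their leave-one-out check on perfectly neutral data.
This is a property of the method, not of the implementation; the
count-level twin isolates the latter. Passing these tests therefore
shows the machinery is correct and calibrated *under its own model*; on
real data the same caveat applies to any ML-HKA analysis without
recombination-aware null distributions.

## Variant screen

For loci significant after FDR correction, `call_pool_variants()` emits
every column with more than one allele among non-missing ingroup calls
(per-column missing-data handling, not complete deletion — a variant
observable in 10 of 20 sequences is still a variant). A pool is "fixed"
at a column only when monomorphic over at least `min_called = 4`
non-missing calls, guarding fixation claims made from one or two
sequences. Coding effects come from translating the affected codon under
each allele with the standard genetic code, with codon context taken from
the column-majority consensus; gap alleles are reported structurally as
`indel`, never as synonymous/non-synonymous. The screen then reports
fixed non-synonymous differences in the improved pool whose allele
frequency among wild sequences is below 0.20 — the pattern of a new or
rare variant driven to fixation during improvement. The published
"novel variant" criterion is not operationalized beyond these two
filters.

## Problem sizes and determinism

Simulation-based checks in the tests use 100–500 replicates for error
rates, 200 for power, and three full studies for end-to-end recovery —
sizes at which binomial noise is comfortably inside the asserted margins
while the whole suite runs in a few minutes. Every stochastic component
takes an explicit integer seed (`sim_config(seed = ...)` is mandatory;
optimizer jitter is seeded and RNG-isolated), so scans, pipelines and the
acceptance script are bit-reproducible: two runs with the same
configuration and seed produce byte-identical tables.

## Known limitations

* $df = 2$ is a reproduced convention, not a derived one; with $df = 1$
  the test is more powerful and still conservative on count data.
* The Poisson likelihood understates the variance of $S$ (and mildly of
  $D$); see *Operating characteristics*.
* Divergence uses raw mismatch counts; for distant outgroups a
  multiple-hit correction would be needed before the counts enter the
  likelihood.
* The timing classes inherit the per-pool tests' errors: a domestication
  sweep whose landrace test lands just above $\alpha$ is dated
  `improvement`.
* Whether published scans applied the FDR correction jointly or per pool
  is ambiguous; the joint default reproduces the published significant-set
  size, and `fdr_scope = "per-pool"` is available.
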