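Package: sunhka
Title: Maximum-Likelihood HKA Selection Scan for Domestication Candidate Genes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Sequence-based scan for positive selection during crop
    domestication and improvement, built around the maximum-likelihood
    multilocus Hudson-Kreitman-Aguade (ML-HKA) test. Computes per-locus
    diversity statistics (segregating sites, nucleotide diversity,
    Watterson's theta, haplotype counts, outgroup divergence) from
    aligned Sanger-style sequences, fits the ML-HKA Poisson likelihood
    with a per-locus selection parameter, validates a neutral-locus
    panel leave-one-out, tests candidate loci separately in wild,
    landrace and improved gene pools, controls the false discovery rate
    with Storey q-values, classifies the timing of selection
    (domestication versus improvement), and screens significant loci for
    fixed non-synonymous differences. Includes a coalescent
    (infinite-sites) synthetic-data generator emulating a stratified
    wild/landrace/improved/outgroup study design with a genome-wide
    bottleneck and locus-specific sweeps.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, Biostrings, yaml
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
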