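Package: ribocell
Title: Monte-Carlo Simulation of Ribozyme Co-Spread in Naked and Protocell
    RNA-World Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An agent-based Monte-Carlo model of early RNA-world evolution with
    resolution at the level of individual nucleotides and membrane amphiphiles.
    Three functionally distinct ribozymes -- a replicase (Rep), a nucleotide
    synthetase (Nsr) and an amphiphile synthetase (Asr) -- replicate by
    template-directed ligation on a toroidal lattice and may co-spread in
    naked, pseudo-protocell and true-protocell regimes. The package provides
    the full event model (nucleotide and amphiphile turnover, RNA degradation,
    random and template-directed ligation with mutation, membrane assembly,
    protocell growth, division, fusion and breakage), census and snapshot
    tables as tibbles, FASTA export of the strand pool, inoculation protocols,
    and parameter-sweep machinery for spreading-chance experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    yaml,
    generics,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
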