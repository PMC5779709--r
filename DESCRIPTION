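Package: markernet
Title: Bayesian Inference of Phylogenetic Networks from Bi-Allelic Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Exact computation of the likelihood of a rooted phylogenetic
    network given unlinked bi-allelic markers (SNPs, AFLPs), integrating out
    gene trees analytically under the multispecies network coalescent via
    labeled partial likelihoods.  Includes a reversible-jump MCMC sampler
    over network topologies and their parameters (divergence times,
    per-branch population mutation rates, inheritance probabilities) with
    Metropolis-coupled pre-burn-in, a matching coalescent simulator of
    bi-allelic markers on networks (haploid, diploid co-dominant and
    dominant encodings, linked-site blocks, rate variation), and a rich
    Newick dialect reader/writer carrying per-branch population mutation
    rates and inheritance probabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ape,
    phangorn,
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
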