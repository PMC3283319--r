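Package: dcjsim
Title: Constrained Double-Cut-and-Join Simulation of Genome Rearrangement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic simulation of multichromosomal genome rearrangement under
    the double-cut-and-join (DCJ) operation and a family of one-parameter
    constrained extensions (dosage-sensitivity partition constraint, maximum
    inter-chromosomal fragment size, maximum inversion length, and Bernoulli
    thinning of inter-chromosomal moves). Includes micro-synteny (adjacency) and
    macro-synteny (chromosome-context) conservation statistics computed on marker
    subsets with z-score based homology assignment between chromosomes, chi-square
    fitting of model parameters to observed synteny conservation, neighbor-joining
    trees from rearrangement distances, and multi-species conservation experiments
    on star and resolved phylogenies. A fast order-statistic tree engine with lazy
    reversal supports genome-scale runs; a naive reference engine provides an
    independent oracle for testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: Rcpp, ape, stats, utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
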