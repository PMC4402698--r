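Package: pedcmp
Title: Isomorphism and Similarity for Two-Generation Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing unlabeled two-generation pedigrees. Provides
    a pedigree data model with PED-style input/output and axiom validation,
    decomposition of a two-generation pedigree into mating families counted
    as (female, male) child pairs, an exact polynomial-time isomorphism test
    for monogamous pedigrees, a gadget construction turning bipartite graphs
    into two-generation pedigrees, and solvers for the Minimum Common Integer
    Partition (MCIP) and Minimum Common Integer Pair Partition (MCIPP)
    problems used to score pedigree similarity: a subtraction-based heuristic
    with certified size bounds, fixed-parameter bounded branching searches,
    and brute-force reference oracles. Seeded generators produce pedigrees,
    bipartite graph pairs, and partition instances with planted solutions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
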