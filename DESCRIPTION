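Package: hsp70cycle
Title: Non-Equilibrium Steady States and Ultra-Affinity in the Hsp70 Chaperone Cycle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic and stochastic tools for the four-state Hsp70
    (DnaK) chaperone cycle. Computes effective nucleotide-exchange rates by
    coarse-graining nucleotide binding against a chemostatted ATP/ADP pool,
    enforces thermodynamic (detailed-balance) closure of the cycle, solves
    the mass-action steady state under chaperone and substrate conservation,
    and evaluates the equilibrium and non-equilibrium effective dissociation
    constants together with the ATP hydrolysis flux. Parameter-sweep engines
    map how hydrolysis acceleration, binding-timescale separation and
    substrate stoichiometry drive the dissociation constant below its
    equilibrium range ("ultra-affinity"). An exact Gillespie simulator of
    the cycle in a finite volume serves as an independent stochastic oracle
    and as a generator of synthetic binding-titration data for
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    minpack.lm,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
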