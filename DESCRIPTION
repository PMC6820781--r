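Package: famex
Title: Characterization of Unstable TTTTA/TTTCA Pentanucleotide Repeat Expansions
Version: 0.1.0
Authors@R:
    person("famex", "developers", email = "famex@example.org", role = c("aut", "cre"))
Description: Tools for characterizing unstable TTTTA/TTTCA pentanucleotide
    repeat expansions of the kind underlying familial adult myoclonic
    epilepsy (FAME). Provides motif-level decomposition of long reads
    spanning a configured repeat locus, a short-read screen for expansion
    evidence, analysis of molecular-combing (fiber FISH) signal
    measurements including allele classification, expansion size
    estimation and micro-rearrangement accounting, dating of a shared
    core haplotype, genotype-phenotype correlation, and a synthetic-data
    generator emulating somatic mosaicism, nanopore-like read errors,
    short paired reads and combing measurement noise so that every stage
    is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
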