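Package: fbppheno
Title: Genotype-Biochemical Phenotype Analysis of FBP1 Missense Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for fructose-1,6-bisphosphatase (FBP1)
    missense variants: germline candidate-variant filtering and trio
    compound-heterozygosity detection from VCF/PED input, HGVS coding-to-
    protein coordinate mapping, Kyte-Doolittle hydropathy and amino-acid
    class analysis, structure-context annotation against the FBPase dimer
    (binding-site membership and pocket distances), a three-way functional
    classification of missense mutations (active-site hits, misfolding-
    prone pocket-proximal substitutions, likely non-pathogenic), and the
    genotype-phenotype concordance and correlation statistics over a
    curated biochemical phenotype panel. Includes simulators for trio
    variant sets, toy protein structures, and phenotype tables with known
    ground truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR,
    bio3d,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
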