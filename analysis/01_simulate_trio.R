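#!/usr/bin/env Rscript
# Simulate a family trio with one planted FBP1 compound heterozygote plus
# filter fodder, and write it as VCF/PED for the downstream stages.

suppressPackageStartupMessages(library(fbppheno))
dir.create("results", showWarnings = FALSE)

spec <- trio_sim_spec(n_genes = 20, n_variants = 60, n_comphet = 1,
                      n_fail = 6, comphet_genes = "FBP1", seed = 7)
trio <- simulate_trio(spec)
write_trio_vcf(trio, "results/simulated_trio.vcf", "results/simulated_trio.ped")
write.table(trio$truth$comphet, "results/simulated_trio_truth.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Simulated", nrow(trio$variants), "variants across", spec$n_genes, "genes.\n")
cat("Planted compound heterozygote in", trio$truth$comphet$gene, ":\n")
cat("  paternal", trio$truth$comphet$paternal_variant,
    "/ maternal", trio$truth$comphet$maternal_variant, "\n")
cat("Planted filter violators:",
    paste(unname(trio$truth$fail), collapse = ", "), "\n")
cat("Wrote results/simulated_trio.vcf, .ped and _truth.tsv\n")
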