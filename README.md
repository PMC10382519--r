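# fbppheno

Genotype–biochemical-phenotype analysis of missense mutations in *FBP1*,
the gene for fructose-1,6-bisphosphatase (FBPase). FBPase deficiency is a
rare autosomal recessive gluconeogenesis defect presenting as fasting
hypoglycemia with lactic acidosis; its missense mutations act through at
least two distinct mechanisms — direct substitution of catalytic residues,
and protein misfolding with ER retention and degradation. This package is
for genetics/biochemistry analysts who want that mechanistic triage to be
computable, testable and reproducible end to end.

## What it computes

Starting from a sequenced family trio (VCF + PED) and a curated
biochemical phenotype panel, the pipeline:

1. **Filters germline candidates** — adopt a variant when depth ≥ 8,
   alternate reads ≥ 4 and VAF ∈ [0.4, 0.6] (heterozygous) or ≥ 0.95
   (homozygous); exclude unidirectional-only support, indels in simple
   repeats, synonymous SNVs, and variants above frequency 0.001 in any
   population database.
2. **Detects compound heterozygosity** — within each gene, pairs (a, b)
   with a het in proband + father and absent from the mother, b het in
   proband + mother and absent from the father.
3. **Maps coordinates** — HGVS `c.`→`p.` arithmetic
   (protein position = ⌈cds_pos / 3⌉) and codon translation.
4. **Scores physicochemistry** — Kyte–Doolittle hydropathy Δh and a
   five-way amino-acid class system; a substitution "changes
   hydrophobicity" when the class polarity flips or |Δh| ≥ θ (default
   θ = 3.0).
5. **Annotates structure context** — minimum heavy-atom distances to the
   substrate/metal/AMP sites of the FBPase dimer, and a substrate-pocket
   proximity flag (radius 12 Å).
6. **Classifies** each mutation, with strict rule precedence:
   * **Type 1** — pivotal functional-site residue (direct activity loss);
   * **Type 2** — hydrophobicity change *and* pocket-proximal
     (misfolding → ER aggregation, decreased expression);
   * **Type 3** — neither (likely non-pathogenic);
   and checks concordance with the phenotype-side signature (activity,
   expression ratio, localization).
7. **Computes the panel statistics** — Pearson r/R²/p for aggregation vs
   expression and for HSP70/HSP90 binding vs aggregation, plus a
   Beer–Lambert utility converting NADP-coupled A340 series to FBPase
   specific activity (mmol/min/mg).

Simulators (`simulate_trio()`, `simulate_phenotypes()`,
`toy_structure()`) generate every input with planted ground truth, so the
whole pipeline is tested without any external download.

## Worked example

```r
library(fbppheno)

res <- run_panel(run_config())
table(res$classification$genotype_category)
#> 1 2 3
#> 4 9 2
res$concordance$agreement
#> [1] 1

pearson_cor(fbp1_panel()$aggregation_pct, fbp1_panel()$expression_ratio)
#> Pearson r = -0.9432 (R^2 = 0.8897), p = 1.37e-07, n = 15
```

The 15-mutation panel splits into 4 active-site (Type 1), 9
misfolding-prone (Type 2) and 2 likely non-pathogenic (Type 3) mutations,
the genotype rules agree with the biochemical phenotype for all 15, and
aggregation is strongly negatively correlated with residual protein
expression (R² ≈ 0.89) — the statistical signature of degradation-driven
expression loss.

Trio analysis on the packaged patient-style fixture:

```r
trio <- read_trio_vcf(system.file("extdata", "fbp1_trio.vcf", package = "fbppheno"),
                      system.file("extdata", "fbp1_trio.ped", package = "fbppheno"))
filt <- lapply(trio, function(t) subset(germline_filter(t), pass))
detect_compound_het(filt$proband, filt$father, filt$mother)
#>   gene paternal_variant maternal_variant ... paternal_hgvs maternal_hgvs
#> 1 FBP1   9:97368740:C:T   9:97365012:A:G ...      c.491G>A      c.581T>C
```

One compound heterozygote: the paternal c.491G>A (p.G164D) and maternal
c.581T>C (p.F194S) alleles of *FBP1*, each classified Type 2.

The numbered drivers under `analysis/` run the same stages as a narrative
workflow (simulate a trio → filter/call → map coordinates → classify the
panel → correlations), writing their tables under `results/`.

## Packaged data

All packaged tables are plain TSV under `inst/extdata/`: the 15-mutation
phenotype panel, the Kyte–Doolittle scale with class labels, the
functional-site annotation, a **synthetic** per-position structure-context
table (invented distances encoding the published qualitative geometry —
see its header and the methods vignette), and a small trio VCF/PED
fixture. The methods vignette
(`vignettes/fbp1-classification-methods.Rmd`) documents every model
assumption, threshold calibration and simulator design choice.
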