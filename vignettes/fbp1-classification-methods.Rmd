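---
title: "Methods: classifying FBP1 missense mutations by genotype and biochemical phenotype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying FBP1 missense mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbppheno)
```

## The scientific problem

Fructose-1,6-bisphosphatase (FBPase, gene *FBP1*) deficiency is a rare
autosomal recessive defect of gluconeogenesis presenting as fasting
hypoglycemia with lactic acidosis. Pathogenic missense mutations fall into
mechanistically distinct groups: some substitute catalytically pivotal
residues in the enzyme's functional motifs and abolish activity directly;
others destabilize folding, so the mutant protein is retained in the
endoplasmic reticulum, degraded through ERAD, and visible in cells as
aggregates with reduced steady-state expression and elevated chaperone
(HSP70/HSP90) binding; a third group is biochemically silent. The package
implements the full analysis path from a sequenced family trio to that
three-way classification and its phenotype-side validation:

1. **Variant filtering and trio analysis** — germline candidate filters and
   compound-heterozygosity detection from VCF/PED input.
2. **Coordinate mapping** — HGVS c. to p. arithmetic and codon translation.
3. **Physicochemistry** — Kyte-Doolittle hydropathy and a five-way
   amino-acid class system.
4. **Structure context** — distances of mutated residues to the substrate,
   metal and AMP sites of the FBPase dimer and a pocket-proximity flag.
5. **Classification** — genotype-side rules and phenotype-side signatures,
   plus their concordance.
6. **Statistics** — Pearson correlations over the curated panel and the
   enzyme-activity normalization utility.

## Germline filter and compound-heterozygosity model

A candidate variant is adopted when read depth is at least 8, at least 4
reads support the alternate allele, and the variant allele fraction (VAF)
is either inside the heterozygous window [0.4, 0.6] or at the homozygous
level. Variants are excluded when supported only by unidirectional reads,
when they are indels inside simple repeats, when synonymous, or when any
population database reports them above frequency 0.001. Two choices need
stating:

* **Homozygous VAF.** The literal criterion is VAF = 1; exact equality
  almost never holds for finite read counts, so `filter_config()` uses
  `vaf >= 0.95` as "homozygous", configurable. This is a deliberate
  departure from the literal rule text.
* **Exhaustive reason codes.** Every failing rule is reported, in a fixed
  order, rather than the first one — this makes planted-truth tests and
  fixture debugging unambiguous.
* **Parental samples.** Whether the VAF adoption rule binds the parents as
  well as the proband is not pinned down by the source material; the
  default applies the same filter to all samples, and the flag
  `vaf_rule_on_parents` records the choice.

Compound-heterozygosity calling is purely pedigree-combinatorial: within a
gene, report every pair (a, b) with a heterozygous in proband and father
and absent from the mother, and b heterozygous in proband and mother and
absent from the father. Genes carrying a homozygous proband call are left
to a recessive-homozygous analysis and not reported here. Strand phase is
never inferred from reads — the trans configuration follows from the
parental origins.

One arithmetic fact about the filter is worth recording: a variant that
violates *only* the minimum-variant-reads rule cannot exist while the VAF
rule is active. With fewer than 4 supporting reads, a VAF in [0.4, 0.6]
forces depth below 8 (failing the depth rule), and a homozygous VAF forces
depth equal to the alternate count, again below the depth minimum. The trio
simulator therefore plants single-rule violators for the six rules that can
fail in isolation (depth via a homozygous depth-7 variant, VAF,
unidirectional support, indel-in-repeat, synonymous, known-variant), and
the alternate-read rule is exercised jointly with the others in unit tests.

## Hydropathy and the "change in hydrophobicity" predicate

The packaged scale is Kyte-Doolittle; all indices printed in the curated
panel agree with it. Each residue carries one of five class labels
(hydrophobic-aliphatic, hydrophobic-aromatic, hydrophilic-acidic,
hydrophilic-basic, hydrophilic-neutral). Labels for residues appearing in
the panel are taken from it verbatim; the remaining residues (C, M, T, Q,
H, I, Y) follow common biochemistry conventions, with cysteine and
methionine grouped with the aliphatic hydrophobics by their positive
Kyte-Doolittle indices and tyrosine kept with the aromatics.

A substitution "changes hydrophobicity" when either

* the hydrophobic/hydrophilic prefix of the class flips (R158W, G164D,
  G164S, A177D, F194S, G207R, G260R, P284R, G294E), or
* the absolute index shift is at least `theta` even within one polarity.

The second route exists for G294V: glycine (-0.4) and valine (4.2) are both
hydrophobic, yet the 4.6-unit shift is large enough to perturb folding. The
default `theta = 3.0` is the smallest round value that captures that shift
while leaving V325A (4.2 to 1.8, a 2.4-unit shift) unchanged. The predicate
is symmetric in direction — R158W (hydrophilic to hydrophobic) counts the
same way as the hydrophobic-to-hydrophilic majority.

The same route also fires for P120L (-1.6 to 3.8, a 5.4-unit shift within
the aliphatic class). This is intentional and harmless: P120 is a linker
residue between the metal and substrate sites, so the classifier assigns it
Type 1 before hydropathy is ever consulted (rule precedence below), and no
published grouping of P120L depends on the predicate.

## Structure context

`parse_structure()` reads PDB-format coordinates (via `bio3d`, after a
fixed-column validation pass that reports malformed records by line
number). `min_distance()` is the minimum Euclidean distance over all
heavy-atom pairs between a query residue and a target residue set or
ligand; hydrogens are excluded so the metric is robust to crystal
structures solved without them, and by default the minimum is taken across
all chains of the dimer, which captures inter-subunit pockets (a per-chain
policy is available). A query residue inside its own target set is at
distance 0 by convention.

Because this package ships no third-party coordinate files, the per-position
context used for the 15-mutation panel is a **synthetic curated table**
(`fbp1_structure_context_synthetic.tsv`, and flagged as such in its
header). It encodes the qualitative geometry of the published dimer
analysis — the misfolding-prone positions cluster around the substrate
binding pocket, the two likely non-pathogenic positions (207, 325) are
distant, the active-site residues sit at distance 0 in their own sites —
with plausible but invented distances. The **pocket radius** (default 12 A)
was calibrated once against this panel so that every misfolding-prone
position is proximal and positions 207/325 are not; it is a package
decision, since the source analysis gives only the qualitative statement.
All geometry tests run on fully synthetic structures built by
`toy_structure()`, where every distance is known by construction; feeding a
real dimer structure through `parse_structure()`/`build_context()` is a
user-facing path (an alignment-derived numbering offset can be supplied
when the structure's numbering differs from the human protein's).

Secondary-structure labels are transcribed per position from the curated
panel (alpha-helix, beta-strand, turn, or ND where no call was published);
the package does not compute assignments from coordinates.

The AMP-site residue list is a minimal synthetic stand-in (the complete
database curation is not reproduced); no test or packaged classification
depends on its membership, and it deliberately avoids all panel positions.

## Classification rules and their precedence

Genotype side (`classify_genotype()`), in strict precedence order:

1. **Pivotal-site hit** — the position belongs to the annotated metal,
   substrate, or AMP site or the linker between them: **Type 1**.
2. **Misfolding-prone** — the substitution changes hydrophobicity *and* the
   position is pocket-proximal: **Type 2**.
3. **Default** — **Type 3**, likely non-pathogenic.

The precedence is the single most load-bearing inference in the package:
E281K flips the charge class (acidic to basic) yet is Type 1, which is only
consistent if site membership dominates hydropathy. G207R shows the
converse: a polarity flip that stays Type 3 because the residue is far from
the pocket — the structural criterion, not hydropathy alone, separates
Types 2 and 3.

Phenotype side (`classify_phenotype()`): Type 1 is decreased activity with
preserved expression and diffuse cytoplasmic localization; Type 2 is
decreased activity with decreased expression and ER-associated aggregation;
Type 3 is unchanged activity with preserved expression and diffuse
localization. Any other combination returns `"unclassified"` — the three
signatures do not tile the space of possible records, and silent coercion
would hide exactly the interesting discordances. When only numeric columns
are available, the cutoffs sit in the gaps of the curated panel: expression
"decreased" below 0.7 (Type 2 maximum 0.6 vs Type 1 minimum 0.9),
"aggregated" at >= 40% of cells (Type 2 minimum 42.7 vs 33.6 elsewhere),
and chaperone binding "elevated" when *both* HSP70 and HSP90 ratios reach
3.0 (the conjunction matters: one Type 3 mutant touches 3.1 on HSP70
alone). All are configurable through `phenotype_thresholds()`.

Truncating mutations are out of scope: whether frameshifts behave like the
misfolding class is an open mechanistic question, and the classifier
refuses rather than guesses (`parse_hgvs()` rejects non-substitution
notation explicitly).

## Statistics

`pearson_cor()` returns the product-moment r, R^2 and the two-sided p-value
from the exact t transform (delegating to `stats::cor.test`); no
multiple-testing correction is applied to the two panel correlations, which
mirrors how they are reported. The panel correlations are computed on the
15 per-mutation values, not per-replicate measurements — the published
per-replicate data are not available, and the choice is recorded here.

`fbpase_activity()` converts an A340-vs-time series from the NADP-coupled
assay into a specific activity. The normalization formula is not printed in
the source protocol, so the package adopts plain Beer-Lambert dimensional
analysis with epsilon(NADPH, 340 nm) = 6220 / M / cm and the protocol's
assay constants (300 uL reaction, 40 ug protein, 1 cm path) as defaults:
activity = slope / (epsilon x path) x volume / protein, in mmol/min/mg. A
negative fitted slope is clipped to zero activity with a warning flag. The
published wild-type and mutant activities are wet-lab measurements consumed
as fixture data, never recomputed.

## What the simulators emulate — and what they do not

`simulate_trio()` generates a proband/father/mother variant set with
planted truth: compound-het pairs in chosen genes (clean read support,
VAF about 0.5, the trans configuration by construction), single-rule filter
violators in the proband, and clean background variants in Mendelian
configurations that are *uninformative* for compound heterozygosity
(trio-shared, both-parents-untransmitted, or private to one parent). The
background deliberately avoids the proband-plus-one-parent configuration so
that planted truth is the unique correct answer; real exomes, of course,
contain such variants in abundance (the published proband had 111 filtered
candidates genome-wide), so passing the recovery test shows the pedigree
logic is exact, not that real-data specificity is high. Read-level error
models, mapping artifacts and genotype-likelihood uncertainty are
explicitly not simulated.

`simulate_phenotypes()` draws a latent "misfolding severity" per mutation
and maps it to both readouts — aggregation rising, expression falling —
which mirrors the causal picture (misfolding causes aggregation *and*
degradation-driven expression loss) and makes the clamping explicit. The
standardized pair is constructed at the exact target correlation;
aggregation is then placed at 50 +/- 16 percentage points clamped to
[0, 100] and expression at 0.8 +/- 0.3 truncated at 0, so clamping events
are about three standard deviations out and the realized correlation is
attenuated only marginally (the calibration tests require the mean realized
r over 200 replicates of n = 1000 to sit within 0.02 of targets from -0.9
to 0.5). `noise_sd` adds independent measurement noise *on top of* the
target structure and therefore attenuates the realized correlation; it
defaults to 0. No distributional detail for any measurement is available
from the source material — all simulation distributions are artifact
choices, calibrated for testability, and should not be read as models of
assay noise.

Random-number generation uses R's default Mersenne-Twister generator,
seeded once per simulation call from the spec, so every fixture is
reproducible from its spec alone.

## Problem sizes and numerical choices

The test suite runs the trio recovery property over 100 seeds at 40
variants across 12 genes per trio, simulator calibration over 200
replicates of n = 1000 at four targets, geometry oracles on models up to
500 atoms, and CDS translation properties on random sequences up to 999 nt
— sizes chosen so the whole suite completes in well under a minute while
the Monte-Carlo envelopes stay tight. Distance computation uses the
squared-distance cross-product expansion with a final `sqrt` on the
minimum, clipped at zero to guard against negative round-off. Correlation
equality against the two-pass textbook formula is asserted at 1e-12;
PDB round-trips at the format's 1e-3 A field precision.

## Known limitations

* The packaged structure context is a synthetic curation, not measured
  geometry; substituting a real dimer structure changes the distances and
  may require re-calibrating the pocket radius.
* The classifier covers single-residue missense substitutions only.
* Gene assignment, strand support and repeat membership are consumed as
  input annotations, never recomputed from alignments.
* The phenotype-side thresholds are calibrated on a 15-mutation panel;
  they are separations of that panel, not population-validated cutoffs.
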