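# ceRNAclip

Inference and validation of lncRNA:miRNA competing endogenous RNA (ceRNA,
"miRNA sponge") circuits from comparative Argonaute CLIP occupancy and
RNA-seq derepression data — for computational biologists analysing Ago2
HITS-CLIP libraries across genotypes (wild type, a seed-site point mutant,
a miRNA family knockout) together with matched expression profiling.

## What it computes

A sponge circuit makes two linked predictions, and the package tests both:

**CLIP side.** A candidate sponge lncRNA is heavily Ago2-bound, its
strongest peak contains a canonical seed site of the focal miRNA family
(8mer > 7mer-m8 > 7mer-A1 > 6mer matching), and binding at that site —
but nowhere else in the transcript — collapses when the site is mutated or
the family deleted. The core statistic is the per-3'UTR normalized
seed-site occupancy fraction

f(s, g) = reads at site s (full 8-mer overlap) / reads in the site's 3'UTR,

compared between genotypes by a paired two-sided t-test on logit-scale
differences (fractions clamped at ε = 10⁻³), over sites with CLIP support
in both genotypes. Sponging predicts f up in the site mutant (freed miRNA
redistributes onto mRNA targets) and collapsed in the knockout, while
control miRNA families stay flat (Benjamini–Hochberg across families).

**Expression side.** The bound target set should shift toward *lower*
expression in the sponge mutant and *higher* expression in the knockout:
two-sample Kolmogorov–Smirnov tests on log2 fold-change ECDFs of targets
versus all other tested genes, a concordance partition of targets by the
two sign conditions, and hierarchical clustering of samples on a
threshold-defined costimulation-responsive gene set (log2FC > 1.5,
adjusted p < 0.001).

Supporting machinery: BED6/GFF3/FASTA/TSV I/O, interval subtraction
(repeat masking), overlap counting and coverage, annotation-level
occupancy ranking with class median ratios, a simplified zero-truncated
negative binomial peak caller with signal masking, a documented
median-of-ratios + Welch-t differential-expression engine, and a
synthetic-data generator that plants every circuit effect with known
parameters so the whole chain is testable by recovery.

## Worked example

Run the full pipeline on a simulated study with planted effects
(sponge lncRNA `lnc001`, 100 target genes, occupancy gain ×1.5 in the
site mutant, expression effects of 0.5 log2 units):

```r
library(ceRNAclip)
cfg <- pipeline_config(
  simulate = list(n_mrna = 1000, n_lncrna = 10, n_target_genes = 100,
                  n_families = 3, n_control_sites = 50),
  seed = 42)
report <- run_pipeline(cfg, out_dir = "run42")
print(report)
```

```
ceRNA circuit report
  candidate sponge lncRNA: lnc001 (rank 1 of 10 by CLIP reads)
  median UTR / median lncRNA read totals: 2.89
  supported focal sites: 100 in 100 genes
  occupancy shift (scr vs WT): paired occupancy test: n=100 sites, mean fraction 0.5188 -> 0.6097 (+17.5%), t=7.254 (df=99), p=9.17e-11
  occupancy shift (ko vs WT):  paired occupancy test: n=100 sites, mean fraction 0.5188 -> 0.1062 (-79.5%), t=-14.306 (df=99), p=7.81e-26
  target derepression KS (WT vs scr): KS shift test: D=0.7686, p=0 (targets n=100 above background n=910)
  target derepression KS (fl vs ko):  KS shift test: D=0.8100, p=0 (targets n=100 below background n=910)
  concordance: 100 targets; down-in-mutant 98 (98%), up-in-ko 98 (98%), both 96 (96%), either 100 (100%)
  costimulation gene set: 137 genes
```

Reading the output: the planted sponge is recovered as the top-ranked
lncRNA by total CLIP reads; supported focal-family sites occupy on average
51.9% of their UTRs' reads in wild type, rising to 61.0% in the site
mutant (+17.5%, paired p = 9×10⁻¹¹, the freed-miRNA signature) and
collapsing to 10.6% (−79.5%) in the knockout; target-gene expression
shifts in the predicted opposite directions in the two contrasts (KS
D ≈ 0.77–0.81), with 96% of targets concordant in both. The control
families in `report$family_screen` stay null (adjusted p = 0.96 and 0.63).
Per-stage tables (occupancy totals, peaks, fractions, DE, clusters) and a
deterministic `report.txt` are written to the output directory; a thin
command-line wrapper lives at `inst/scripts/cerna-pipeline.R`.

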