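# nucmir

Analysis of microRNA expression, subcellular localization and target
inference across mouse granulopoiesis (LSK progenitors → promyelocytes →
myelocytes → granulocytes), for researchers working with TLDA-style
RT-qPCR panels, nuclear/cytoplasmic fractionations and matched mRNA
expression data.

The package implements four connected analysis arms:

1. **CT-based miRNA differential expression** — relative expression
   E = 2^(CT_ref − CT_test), detectability at CT < 30, the inclusive
   2-fold rule over all stage pairs, exact Wilcoxon signed-rank tests on
   ΔCT, hierarchical clustering of highly expressed (CT < 25) assays on
   correlation distance, and cross-species fold-change concordance
   (Spearman ρ plus fold–fold R²).
2. **Moderated-t mRNA differential expression** — empirical-Bayes variance
   shrinkage: gene variances modelled as s₀²·F(d_g, d₀), the prior
   (d₀, s₀²) estimated by moment matching on log variances via trigamma
   inversion, posterior variance s̃² = (d₀s₀² + d_g s_g²)/(d₀ + d_g), and
   t = log2FC / (s̃·√(1/n₁+1/n₂)) on d₀ + d_g degrees of freedom.
3. **Seed-match target inference** — 8mer / 7mer-m8 / 7mer-A1 sites
   (TargetScan conventions, 8mer > 7mer-m8 > 7mer-A1 precedence at a
   locus) intersected with anti-correlated expression changes, plus
   stage-specific miRNA-peak/gene-trough pairing.
4. **Nuclear biology** — fractionation marker QC (SnoRNA-like and Y1-like
   markers), cytoplasmic-contamination regression (nuclear CT on
   cytoplasmic CT; implied carry-over = 2^(−intercept)), N:C-ratio
   nuclear-enrichment calling against cytoplasmic control miRNAs, and a
   duplex minimum-free-energy scan (nearest-neighbour stacking DP in
   C++, dinucleotide-preserving shuffle calibration, Gumbel fit) of
   pri-miRNA transcripts for binding sites of nuclear-enriched miRNAs.

A synthetic-data module (`sim_config()`, `simulate_ct_experiment()`,
`simulate_transcriptome()`, `simulate_pri_targets()`) generates every
input with planted ground truth, and `run_pipeline()` orchestrates the
whole analysis with TSV reports and a deterministic JSON summary. A thin
command-line front end ships in `inst/cli/nucmir`
(`nucmir simulate | de | targets | fractions | priscan | run`).

## Worked example

```r
library(nucmir)

# the delta-CT worked example: CT 20.432 vs 21.599
relative_expression(20.432, 21.599)
#> [1] 2.245443        # ~2.2-fold higher expression in the test sample

# simulate a small experiment with planted truth, then analyze it
cfg <- sim_config(n_mirnas = 60, n_genes = 80, n_de_mirnas = 10,
                  n_nuclear_enriched = 3, n_true_target_pairs = 10,
                  utr_length_range = c(150, 300), seed = 1)
sim <- simulate_ct_experiment(cfg)

de <- mirna_differential(collapse_replicates(sim$whole))
length(attr(de, "de_entities"))
#> [1] 10              # all 10 planted differential miRNAs recovered

fp <- fraction_pairs(sim$fractions)
marker_qc(fp)[1:3, ]
#>   cell_type         assay              class      fold pass
#> 1       LSK SnoRNA-like-1     nuclear_marker 53.873331 TRUE
#> 2       LSK SnoRNA-like-2     nuclear_marker 20.707581 TRUE
#> 3       LSK     Y1-like-1 cytoplasmic_marker  5.708657 TRUE

unlist(contamination_regression(fp, "promyelocyte")[c("slope", "r_squared")])
#>     slope r_squared
#> 1.0592789 0.8742083  # nuclear signal tracks cytoplasmic: carry-over

calls <- call_nuclear_enriched(fp)
subset(calls, call == "nuclear_enriched" & cell_type == "promyelocyte" &
         nc_ratio > 1)[, c("assay", "nc_ratio", "p_value")]
#>       assay nc_ratio      p_value
#> 2   miR-001 1.748364 4.568504e-03
#> 66  miR-017 2.197354 1.924743e-06
#> 186 miR-047 1.920983 2.150395e-08
sim$truth$nuclear_enriched$assay
#> [1] "miR-017" "miR-047" "miR-001"   # the three planted nuclear miRNAs
```

The three assays planted at a true N:C ratio of 2 are recovered with
ratios near 2 and p-values well below 0.05 against the cytoplasmic
controls (baseline ratio ≈ 0.096). Null assays sit near the 0.1
carry-over line; ones that drift above it can also reach significance —
the methods vignette (`vignettes/nucmir-methods.Rmd`) discusses when the
published calling rule is and is not statistically reliable.

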