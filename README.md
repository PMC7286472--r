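# lncmod

Stage-associated lncRNA coexpression modules and hub screening for
microarray expression data.

Intraductal papillary mucinous neoplasm (IPMN) of the pancreas progresses
through ordered stages — normal duct, adenoma, carcinoma in situ, invasive
carcinoma — and long noncoding RNAs (lncRNAs) are candidate drivers of that
progression. Standard microarray annotation ignores most lncRNAs, so the
workflow implemented here first *reannotates* the array's 25-mer probes
against a transcriptome with biotype metadata, keeps only genes supported by
at least four perfectly and specifically matching probes with an
lncRNA-class biotype, and averages multi-probe signals per gene. On the
resulting lncRNA expression matrix it runs a weighted coexpression network
analysis: a soft-thresholded adjacency `a_ij = |cor(x_i, x_j)|^β` with β
chosen as the smallest power reaching scale-free fit R² ≥ 0.80, the
topological overlap matrix

```
TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij),   l_ij = Σ_u a_iu a_uj
```

average-linkage clustering of `1 − TOM` with modules of ≥ 30 genes, module
eigengenes (first principal components), module significance
(MS = mean |gene–trait correlation|), and selection of the stage-associated
module by the agreement of the MS and eigengene–trait criteria. Hub lncRNAs
are the module genes passing the dual rule |cor.Standard| > 0.8 AND
|cor.Weighted| > 0.8, where cor.Weighted blends the standardized gene
profile with its module eigengene. Downstream statistics cover the per-gene
one-way ANOVA across the four stages, hypergeometric gene-set
over-representation with Benjamini–Hochberg FDR, and Kaplan–Meier /
log-rank survival comparisons after median dichotomization.

Every step is exercisable on synthetic data with planted ground truth:
latent-factor modules with a chosen stage effect, planted hub genes with
exact gene–trait correlation, a probe universe with mismatch / multi-mapping
/ sparse / wrong-biotype decoys, and survival tables with a known hazard
ratio. The package is for computational biologists who want the network
pipeline as tested, scriptable functions rather than a collection of web
tools.

## Worked example

```r
library(lncmod)

cfg <- pipeline_config(
  sim  = sim_config(n_hubs = c(3L, 0L, 0L), seed = 7L),  # planted design
  seed = 7L)
rep <- run_full_pipeline(cfg, output_dir = "pipeline_out")

rep$power
#> [1] 3
rep$selected_module
#> [1] 1
rep$truth_comparison[, c("reannotation_precision", "reannotation_recall",
                         "module_ari", "selected_matches_planted",
                         "hub_sensitivity")]
#>   reannotation_precision reannotation_recall module_ari
#> 1                      1                   1  0.9153168
#>   selected_matches_planted hub_sensitivity
#> 1                     TRUE               1
head(rep$hubs[, c("gene", "cor.Standard", "cor.Weighted")], 3)
#>       gene cor.Standard cor.Weighted
#> 1 GENE0003   -0.8733954   -0.8115229
#> 2 GENE0002   -0.8813127   -0.8105724
#> 3 GENE0001   -0.8748932   -0.8037296
```

The simulated probe universe is reannotated with precision and recall 1.0
(every decoy probe set rejected, every clean lncRNA kept), the three planted
modules are recovered from the topological-overlap dendrogram (adjusted Rand
index 0.92 over module genes), the module whose latent factor was planted
with stage correlation −0.75 is selected by both the MS and eigengene–trait
criteria, and all three planted hub genes pass the dual 0.8 screen with
negative trait correlations, mirroring a protective stage association.
`pipeline_out/` holds every intermediate table (QC report, power scan,
module assignment, screening statistics, hub list, ANOVA, enrichment, KM
curves) plus a run log with the seed and all tunables.

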