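# sclcsubtyper

Proteomic subtype characterization of small-cell lung cancer (SCLC) cell
lines, as a tested, reusable R pipeline.

SCLC is classified into four molecular subtypes by the dominant expression of
the transcription regulators *ASCL1* (SCLC-A), *NEUROD1* (SCLC-N), *POU2F3*
(SCLC-P) and *YAP1* (SCLC-Y). Given label-free quantitative proteomes of a
cell-line panel (protein × measurement intensity matrices plus sample
annotation), the package answers the questions a subtyping study asks:

* **Preprocessing** — log2 transform, median normalization to the global
  median, replicate aggregation (median over technical injections, mean over
  vials), 80% valid-value filtering, per-protein batch-effect regression,
  left-censored imputation from `Normal(μ − 1.8σ, (0.3σ)²)`, and detection of
  on/off proteins (present in ≥ 85% of one subtype's samples and ≤ 15% of
  every other's, or vice versa).
* **NE / EMT scores** — per sample,
  `NE score = mean Z(NE markers) − mean Z(non-NE markers)` and
  `EMT score = mean Z(mesenchymal) − mean Z(epithelial)`.
* **Differential expression** — per-protein one-way ANOVA with BH-FDR and
  Tukey HSD post hoc p-values; a protein is subtype-specific when
  `FDR < 0.05` and all three Tukey p-values of that subtype against the
  others are `< 0.05`.
* **Enrichment** — hypergeometric ORA; pre-ranked GSEA on
  `log2FC × (−log10 p)` with gene-label permutation NES; the
  subtype-characteristic filter (`p < 0.01` in all three comparisons with a
  unanimous NES sign) and the cross-omics concordance rule (`p < 0.1`, same
  signs, in the other omics layer); ssGSEA (rank-normalized, weight 0.75,
  area under the running sum, min–max scaled).
* **Unsupervised structure** — consensus clustering (1000 × 0.8/0.8
  subsampling, PAM on the Pearson distance, K = 2..7, silhouette-based K
  selection) and PVCA variance attribution.
* **Marker selection** — sparse PLS-DA with per-component keepX selection,
  centroid-distance classification, balanced error rate, repeated stratified
  3-fold CV tuning and feature-stability estimates.
* **Annotation** — secretome/surfaceome/plasma/druggable database-overlap
  rules and protein-abundance vs ln(IC50) drug-sensitivity correlation.

A first-class synthetic-data module (`simulation_config()`,
`generate_dataset()`, `inject_missingness()`, `generate_genesets()`) emulates
the study geometry — 26 cell lines (8/7/4/7 per subtype), two batches, three
technical replicates, planted subtype-specific proteins, batch/culture
effects, NE/EMT marker structure and logistic left-censored missingness —
with a complete ground-truth table, so every stage is validated by recovery
tests. The 26-line cell-line characteristics table ships in
`inst/extdata/sclc_cell_lines.tsv`.

## Worked example

```r
library(sclcsubtyper)

cfg <- simulation_config(seed = 42)           # the default stated world
ds  <- generate_dataset(cfg)
raw <- inject_missingness(ds$matrix, cfg$missing_midpoint,
                          cfg$missing_slope, seed = 43)
raw
#> IntensityMatrix: 2200 proteins x 156 samples [raw-linear, stage=raw]
#>   cells: 283920 observed, 59280 missing, 0 imputed

norm  <- log2_median_normalize(raw)
vial  <- aggregate_replicates(norm, ds$annotation, level = "vial")
corr  <- correct_batch(vial$matrix, vial$annotation)
cellm <- aggregate_replicates(corr, vial$annotation)
imp   <- impute_normal(filter_valid(cellm), seed = 44)
imp
#> IntensityMatrix: 2174 proteins x 26 samples [log2, stage=imputed]
#>   cells: 56203 observed, 0 missing, 321 imputed

sigs <- truth_signatures(ds$truth)
assoc <- score_association(signature_score(imp, sigs$ne),
                           signature_score(imp, sigs$emt))
sprintf("NE vs EMT: r = %.2f, p = %.2g, n = %d", assoc$r, assoc$p, assoc$n)
#> "NE vs EMT: r = -0.77, p = 3.7e-06, n = 26"

ann <- unique(ds$annotation[, c("cell_line", "subtype")])
de  <- anova_tukey(imp, ann$subtype[match(colnames(imp$values),
                                          ann$cell_line)])
nrow(subtype_specific(de, "Y"))
#> 125
```

The negative NE–EMT correlation reproduces the planted coupling
(neuroendocrine-high lines are epithelial-like, SCLC-Y lines mesenchymal).
Of the 125 SCLC-Y-specific calls, 49 are the planted Y proteins (of 50);
the remainder are marker- and culture-block proteins that genuinely separate
SCLC-Y in the simulated world, since all SCLC-Y lines grow adherently.

An end-to-end run with TSV/JSON outputs and a reproducible md5 manifest:

```r
cfg <- pipeline_config(sd_thr = 0.75, reps = 200, gsea_nperm = 100,
                       repeats = 10, seed = 1)
run_pipeline(cfg, "sclc_run")     # or: exec/sclc-subtyper run --out sclc_run
```

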