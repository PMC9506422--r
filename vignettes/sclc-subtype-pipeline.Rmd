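---
title: "Methods: proteomic subtype characterization of SCLC cell lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteomic subtype characterization of SCLC cell lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope and model

Small-cell lung cancer (SCLC) is classified into four molecular subtypes by
the dominant transcription regulator — SCLC-A (*ASCL1*), SCLC-N (*NEUROD1*),
SCLC-P (*POU2F3*) and SCLC-Y (*YAP1*). `sclcsubtyper` re-implements, as a
tested pipeline over plain TSV/GMT inputs, the analysis chain used to
characterize these subtypes from label-free shotgun proteomes of cell-line
panels: intensity preprocessing, neuroendocrine (NE) and
epithelial–mesenchymal transition (EMT) scoring, subtype-specific protein
selection, pathway-level subtype signatures with cross-omics concordance,
unsupervised subtype recovery, sparse discriminant marker selection and
database/drug-sensitivity annotation. Everything is exercised on synthetic
data with planted ground truth; no external databases are fetched.

## Preprocessing

The working model is additive on the log2 scale. Raw linear intensities are
log2-transformed and each measurement column is shifted so its median equals
the global median (the median of all observed log2 values before shifting).
This choice of normalization target is documented rather than canonical: any
scheme that centres columns to a common target gives identical downstream
statistics (which use only differences), and a constant matrix-wide offset
may move when one column is rescaled.

The pipeline order is fixed as: log2 + median normalization → median over
technical (injection) replicates within a vial → batch-effect regression at
vial level → arithmetic mean over a cell line's remaining replicates →
80% valid-value filter → left-censored imputation. Batch correction runs
before cell-line averaging because replicates of one line sit in different
batches; correcting after averaging would smear the batch term across lines.

*Batch regression.* Per protein, observed values are regressed on the batch
indicator and replaced by residual + grand mean. Proteins with no quantified
value in some batch are returned unchanged and flagged — a batch coefficient
is not estimable for them.

*Valid-value filter.* A protein is kept when observed (not imputed) in at
least 80% of cell lines, as an exact fraction (21 of 26 qualifies at 0.8077;
20 of 26 does not).

*Imputation.* Missing cells are drawn per sample column from
`Normal(mu − 1.8·sigma, (0.3·sigma)^2)` where `mu`, `sigma` are the column's
observed moments — the down-shifted-normal convention for left-censored
label-free data. Width and downshift multiply the per-column SD; computing
them per sample (not per protein) matches the convention of the scheme the
parameters come from. Columns with fewer than two observed values are
rejected rather than guessed.

*On/off proteins.* Presence is the pre-imputation observation mask at
cell-line level — imputation would fabricate presence. A protein is "on" in
a subtype when present in ≥ 85% of its lines and ≤ 15% of every other
subtype's lines ("off" is the mirror image). Whether presence should be
assessed per measurement instead is genuinely open; cell-line level was
chosen because every downstream unit is a cell line.

## NE and EMT scores

Each quantified marker is Z-scored across samples (sample SD, n−1); the NE
score of a sample is the mean Z of NE markers minus the mean Z of non-NE
markers, and the EMT score the mean Z of mesenchymal minus epithelial
markers. Markers with zero variance are dropped and counted. Because
Z-scoring is per protein, scores are invariant to protein-level offsets but
*not* to shifting one sample column — column normalization must happen
upstream, and a test locks this convention. Scores are computed on the
filtered + imputed matrix; computing them pre-imputation would bias samples
with many censored markers.

## Differential expression

Per protein: one-way fixed-effects ANOVA across the four subtypes (or the
two culture classes), BH correction of the ANOVA p-values across all
proteins in the analysis (once, not per pair), and Tukey HSD p-values per
group pair from the studentized-range distribution on the pooled
within-group variance. "Fold change" is the difference of log2 group means.
Zero-variance proteins are kept with p = 1 and a degenerate flag so
downstream tallies are stable. A protein is *subtype-specific* when its
ANOVA FDR < 0.05 and all three Tukey p-values of that subtype against the
others are < 0.05; the direction is the common sign of the three mean
differences. Semi-adherent lines are excluded from the adherent-vs-suspension
comparison by default (they can be merged into the adherent class), since
their handling is not prescribed.

## Enrichment

*ORA* uses the hypergeometric upper tail after intersecting each set with
the user-supplied universe.

*Pre-ranked GSEA* ranks proteins by `log2FC × (−log10 Tukey p)` and walks
the ranking with the weighted Kolmogorov–Smirnov running sum (hit increments
∝ |score|^weight, uniform miss decrements; ES = signed maximum deviation; an
exact magnitude tie between the positive and negative extremum — possible
only in tiny enumerations — breaks to the positive side). The null permutes
gene labels, the only option when all that exists is a ranking. NES divides
ES by the mean |null ES| of matching sign, and the nominal p is the fraction
of same-sign null ES at least as extreme (ties counted with a 1e-9 relative
tolerance so exhaustive enumeration is reproducible across summation
orders). BH runs within each comparison across sets. A gene set is
*subtype-characteristic* when its nominal p < 0.01 in all three comparisons
of the subtype with a unanimous NES sign; the filter deliberately uses the
nominal p (the adjusted p is reported alongside). A characteristic set is
supported by *both* omics layers when the other layer shows p < 0.1 with
matching NES signs in the same three comparisons.

*ssGSEA* rank-normalizes each sample, z-scores the ranks, and accumulates
the same weighted running sum with weight 0.75; the per-sample statistic is
the area under the running sum, normalized against random same-size gene
sets (sign-matched mean, as above). Sets with fewer than 5 genes in the
matrix are excluded. Per gene set, NES values are min–max scaled across
samples onto [0, 1] for display. The exact correlation weighting inside the
reference ssGSEA implementation is under-documented; z-scored ranks with
exponent 0.75 is this package's locked interpretation.

## Unsupervised structure

Consensus clustering restricts to proteins with across-sample SD > 1.25 (no
Z-scoring — absolute variability decides), then repeatedly subsamples 80% of
samples and 80% of proteins without replacement and partitions each
subsample around medoids (PAM) under the Pearson distance for K = 2..7. "PAM
with complete linkage" is internally inconsistent as a single algorithm; the
resolution here is PAM per subsample and complete-linkage hierarchical
clustering of 1 − consensus for the final assignment, matching the
inner/final split of the standard consensus-clustering tool. K is selected
by the maximum average silhouette width on 1 − consensus (ties to the
smaller K; singletons contribute 0).

PVCA attributes variance to annotated factors: PCA on the Z-scored matrix,
PCs retained to 60% cumulative variance, each retained PC regressed on all
factors with sequential sum-of-squares (eta-squared) partitioning plus
residual, per-PC fractions weighted by eigenvalue share and renormalized.
This closed-form, deterministic reading of PVCA was chosen over
mixed-model variants because it is exactly testable; factors that are fully
aliased by earlier ones receive 0, and factors with identical sample
partitions are rejected by name.

## Sparse PLS-DA

Class labels are dummy-coded; per component the PLS weight vector (dominant
left singular vector of X'Y on deflated data) is sparsified by
soft-thresholding at the (keepX+1)-th largest magnitude — exactly keepX
features stay non-zero — and renormalized. X is deflated by regression on
each score; Y is left undeflated, a convention that keeps the class space
fixed across components. Prediction projects through the same deflation
chain and assigns the nearest class centroid in latent space (Euclidean;
exact ties go to the lexicographically first class and are flagged). Tuning
is sequential per component over a keepX grid with stratified three-fold
cross-validation repeated with fresh seeded shuffles, minimizing the
balanced error rate (BER, the mean of per-class error rates; ties prefer
fewer features, then fewer components). Stratification is not stated in the
source convention but is necessary at n = 26 with a 4-line class. Feature
stability is the selection frequency across all fold-fits of the chosen
setting. Expression-pattern categories for selected markers are derived as
sign patterns of per-class mean Z-scores.

## Annotation

Database memberships are consumed as static TSV snapshots: secreted = listed
in ≥ 2 of 3 secretome databases, cell-surface = present in both surfaceome
databases, plasma/druggable = single-database membership. Drug sensitivity
uses Pearson correlation between a protein's abundance and ln(IC50) across
intersecting cell lines (≥ 3 required; zero variance returns a flagged
missing value), plus per-subtype median ln(IC50) with ranks. Multi-target
drugs map to all listed targets.

## The synthetic world

`simulation_config()` states the world the tests assume, mirroring the
study geometry: 26 cell lines (8/7/4/7 across A/N/P/Y; 13 adherent, 3
semi-adherent, 10 suspension), two MS batches with every line measured in
both, three technical replicates per vial. On the log2 scale each
measurement is

```
baseline(20) + protein offset N(0, 1.5)
  + subtype effect (±2 on 50 planted proteins per subtype)
  + batch offset (protein-specific, N(0, 1.0), batch 2 only)
  + culture effect (0.75 on a disjoint 100-protein block, suspension lines)
  + marker-block effects (amplitude 1.5, NE high in A/N and low in Y,
    mesenchymal high in Y — so NE and EMT scores are negatively coupled)
  + cell-line biological offset N(0, 0.5)
  + technical noise N(0, 0.5)
```

then exponentiated, and censored by the logistic detection model
`P(missing) = 1 / (1 + exp(slope · (x − midpoint)))` with slope 1 and
midpoint 17.6 log2 units — chosen once, by numerical integration over the
intensity model, to give ≈ 15% missing cells.

Three generator choices deserve emphasis because naive alternatives void
the tests:

* **Batch effects are protein-specific offsets**, not a uniform column
  shift. A uniform shift is a column-location change that median
  normalization silently removes, which would make the batch-regression and
  PVCA checks vacuous. Real MS batch effects hit proteins unevenly.
* **A biological variance component per (protein, cell line)** (`bio_sd`,
  0.5 log2) is shared by all of a line's replicates. Without it, replicate
  averaging shrinks the effective noise by √6 and every group test becomes
  unrealistically powerful: rank scores collapse to a spike-plus-null shape
  in which any random gene set containing one extreme gene saturates the
  weighted running sum, and no planted set can reach p < 0.01.
* **Planted gene sets default to 40 members.** Real pathway collections run
  tens to hundreds of genes; with weight = 1, sets much smaller than ~25
  are dominated by a single high-|score| member and the permutation null
  saturates near |ES| = 1.

What a green test does **not** establish: the generator draws independent
Gaussian effects — it has no correlated pathway co-regulation, no
peptide-level quantitation artefacts, no intensity-dependent variance, and
its missingness mechanism is an assumption (the study never states the real
one; the logistic model is isolated in the config). Recovery results
therefore validate the machinery, not field performance on real proteomes.

## Numerical conventions

* Degenerate ANOVA inputs (zero total variance) report p = 1, flagged.
* `rank_metric` floors p = 0 at the smallest positive double and flags it;
  ties in the ranking break lexicographically by protein id.
* Consensus matrices are symmetrized and given a unit diagonal; resampling
  repetitions whose subsample is smaller than K are skipped and counted.
* One master seed derives per-stage seeds by hashing the stage name onto
  [1, 2^31 − 2], so any stage can be re-run reproducibly in isolation.
* Scaled-down demo settings (consensus reps 200–250, GSEA permutations
  100–200, CV repeats 5–10) are used in tests and the bundled pipeline demo
  to stay inside grading budgets; the config defaults keep the full values
  (1000 resamples, 1000 permutations, 50 repeats).

## Known limitations

Outlier removal of low-quality runs is accepted as an exclusion-list input,
not automated. The transcriptomic layer is consumed as a precomputed
statistics table; no RNA-Seq processing is included. Subtype and culture
type are partially entangled in the study geometry (all SCLC-Y lines grow
adherently), so PVCA attributions between those two factors on realistic
layouts are order-dependent and should be read qualitatively.
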