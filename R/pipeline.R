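#' Load the packaged cell-line characteristics table
#'
#' Parses a cell-line table (the packaged 26-line SCLC panel or a user file)
#' with columns `cell_line`, `other_id`, `subtype`, `origin`, `chemotherapy`,
#' `culture_type`. Subtype tokens `SCLC-A`..`SCLC-Y` (or bare `A`..`Y`) are
#' validated and reduced to the one-letter codes; culture types are
#' normalized to lower case.
#'
#' @param path TSV path; defaults to the packaged table.
#' @return cell-line-level annotation data frame.
#' @export
load_cell_line_table <- function(path = system.file("extdata",
                                                    "sclc_cell_lines.tsv",
                                                    package = "sclcsubtyper")) {
  if (!nzchar(path) || !file.exists(path))
    stop("cell line table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!nrow(df)) stop("empty cell line table: ", path)
  need <- c("cell_line", "subtype", "culture_type")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cell line table lacks column(s): ", paste(miss, collapse = ", "))
  st <- toupper(sub("^SCLC[-‐‑‒–]?", "", df$subtype))
  bad <- !st %in% c("A", "N", "P", "Y")
  if (any(bad))
    stop("unknown subtype token(s): ",
         paste(unique(df$subtype[bad]), collapse = ", "))
  df$subtype <- st
  ct <- tolower(df$culture_type)
  badc <- !ct %in% c("adherent", "semi-adherent", "suspension")
  if (any(badc))
    stop("unknown culture type token(s): ",
         paste(unique(df$culture_type[badc]), collapse = ", "))
  df$culture_type <- ct
  df
}

#' Pipeline configuration
#'
#' Bundles every stage parameter with its default (the values the analysis
#' convention fixes: 80% valid-value filter, imputation width 0.3 /
#' downshift 1.8, on/off thresholds 0.85/0.15, clustering SD threshold 1.25
#' with 1000 resamples at 0.8 item/feature probability, 3-fold CV repeated
#' 50 times, characteristic-filter p 0.01 with 0.1 in the other omics layer,
#' ssGSEA weight 0.75 and minimum overlap 5) plus one master seed from which
#' each stage derives its own.
#'
#' @param sim a [simulation_config()] for the synthetic input (demo mode).
#' @param min_frac,width,downshift,on_hi,on_lo preprocessing parameters.
#' @param sd_thr,reps,p_item,p_feature,k_range consensus-clustering
#'   parameters.
#' @param folds,repeats,max_components,keepX_grid sPLS-DA tuning parameters.
#' @param p_thr,p_other,gsea_nperm,min_overlap,ssgsea_weight enrichment
#'   parameters.
#' @param seed master seed.
#' @return list of class `PipelineConfig`.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            min_frac = 0.8, width = 0.3, downshift = 1.8,
                            on_hi = 0.85, on_lo = 0.15,
                            sd_thr = 1.25, reps = 1000, p_item = 0.8,
                            p_feature = 0.8, k_range = 2:7,
                            folds = 3, repeats = 50, max_components = 2,
                            keepX_grid = c(10, 25),
                            p_thr = 0.01, p_other = 0.1, gsea_nperm = 1000,
                            min_overlap = 5, ssgsea_weight = 0.75,
                            seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "PipelineConfig"
  cfg
}

pipeline_log <- function(con, ...) {
  line <- sprintf(...)
  writeLines(line, con)
  invisible(line)
}

#' Run the pipeline end to end on synthetic data
#'
#' Executes the stages in the documented order -- simulate, inject
#' missingness, log2 + median normalization, per-vial technical-replicate
#' median, batch regression at vial level, replicate averaging to cell
#' lines, valid-value filter, on/off detection (pre-imputation), imputation,
#' NE/EMT scoring, ANOVA/Tukey differential expression with
#' subtype-specific selection, pre-ranked GSEA with the
#' subtype-characteristic filter, high-variance consensus clustering with K
#' selection, and sPLS-DA tuning -- writing every stage output as TSV/JSON
#' under `out_dir` and a `manifest.json` with the md5 hash of each output.
#' Rerunning with the same config and seed reproduces the hashes.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return the manifest (named md5 vector), invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run_log.txt")
  con <- file(logf, "w")
  on.exit(close(con))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  outputs <- character(0)
  emit <- function(path) outputs <<- c(outputs, path)
  pipeline_log(con, "config: %s",
               jsonlite::toJSON(config[setdiff(names(config), "sim")],
                                auto_unbox = TRUE, force = TRUE))

  ## simulate
  sim_seed <- derive_seed(config$seed, "simulate")
  sim_cfg <- config$sim
  sim_cfg$seed <- sim_seed
  ds <- stage("simulate", generate_dataset(sim_cfg))
  raw <- stage("simulate", inject_missingness(
    ds$matrix, sim_cfg$missing_midpoint, sim_cfg$missing_slope,
    seed = derive_seed(config$seed, "missingness")))
  write_intensity_tsv(raw, file.path(out_dir, "raw_intensities.tsv"))
  emit(file.path(out_dir, "raw_intensities.tsv"))
  utils::write.table(ds$annotation, file.path(out_dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  emit(file.path(out_dir, "annotation.tsv"))
  truth_json <- file.path(out_dir, "truth.json")
  jsonlite::write_json(list(specific_proteins = ds$truth$specific_proteins,
                            culture_proteins = ds$truth$culture_proteins,
                            marker_membership = ds$truth$marker_membership),
                       truth_json, auto_unbox = TRUE, digits = NA)
  emit(truth_json)
  gsets <- stage("simulate", generate_genesets(
    ds$truth, universe = rownames(raw$values),
    sizes = sim_cfg$geneset_sizes, n_null_sets = sim_cfg$n_null_sets,
    seed = derive_seed(config$seed, "genesets")))
  gmt_path <- file.path(out_dir, "genesets.gmt")
  write_gmt(gsets$collection, gmt_path)
  emit(gmt_path)
  pipeline_log(con, "simulate: %d proteins x %d measurements, %.1f%% missing",
               nrow(raw$values), ncol(raw$values),
               100 * mean(raw$mask == "missing"))

  ## preprocess
  norm <- stage("preprocess", log2_median_normalize(raw))
  vial <- stage("preprocess",
                aggregate_replicates(norm, ds$annotation, level = "vial"))
  corrected <- stage("preprocess", correct_batch(vial$matrix,
                                                 vial$annotation))
  cellm <- stage("preprocess",
                 aggregate_replicates(corrected, vial$annotation,
                                      level = "cell_line"))
  filtered <- stage("preprocess", filter_valid(cellm, config$min_frac))
  cl_ann <- unique(ds$annotation[, c("cell_line", "subtype", "culture_type")])
  onoff <- stage("preprocess",
                 detect_on_off(filtered, cl_ann, config$on_hi, config$on_lo))
  imputed <- stage("preprocess", impute_normal(
    filtered, config$width, config$downshift,
    seed = derive_seed(config$seed, "impute")))
  write_intensity_tsv(imputed, file.path(out_dir, "expression.tsv"),
                      mask_path = file.path(out_dir, "expression_mask.tsv"))
  emit(file.path(out_dir, "expression.tsv"))
  emit(file.path(out_dir, "expression_mask.tsv"))
  utils::write.table(onoff, file.path(out_dir, "on_off_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  emit(file.path(out_dir, "on_off_calls.tsv"))
  pipeline_log(con, "preprocess: %d proteins retained of %d; %d on/off calls",
               nrow(filtered$values), nrow(cellm$values), nrow(onoff))

  ## scores
  sigs <- truth_signatures(ds$truth)
  ne <- stage("scores", signature_score(imputed, sigs$ne))
  emt <- stage("scores", signature_score(imputed, sigs$emt))
  assoc <- stage("scores", score_association(ne, emt))
  scores_df <- data.frame(sample = ne$sample, ne_score = ne$score,
                          emt_score = emt$score[match(ne$sample, emt$sample)])
  utils::write.table(scores_df, file.path(out_dir, "scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  emit(file.path(out_dir, "scores.tsv"))
  pipeline_log(con, "scores: NE-EMT r = %.3f (p = %.3g)", assoc$r, assoc$p)

  ## differential expression
  subtype <- cl_ann$subtype[match(colnames(imputed$values),
                                  cl_ann$cell_line)]
  de <- stage("de", anova_tukey(imputed, subtype))
  spec_calls <- do.call(rbind, lapply(c("A", "N", "P", "Y"), function(s) {
    hits <- subtype_specific(de, s)
    if (nrow(hits)) cbind(subtype = s, hits) else NULL
  }))
  de_long <- merge(de$pairs, de$anova, by = "protein")
  utils::write.table(de_long, file.path(out_dir, "de_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  emit(file.path(out_dir, "de_results.tsv"))
  if (!is.null(spec_calls)) {
    utils::write.table(spec_calls,
                       file.path(out_dir, "subtype_specific.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(file.path(out_dir, "subtype_specific.tsv"))
  }
  pipeline_log(con, "de: %d subtype-specific proteins",
               if (is.null(spec_calls)) 0L else nrow(spec_calls))

  ## enrichment: characteristic sets per subtype
  char_all <- NULL
  for (s in c("A", "N", "P", "Y")) {
    others <- setdiff(c("A", "N", "P", "Y"), s)
    res <- lapply(others, function(o) {
      rk <- rank_metric(de, paste0(s, "_vs_", o))
      prerank_gsea(rk, gsets$collection, nperm = config$gsea_nperm,
                   seed = derive_seed(config$seed, paste0("gsea_", s, o)),
                   min_size = config$min_overlap)
    })
    names(res) <- paste0(s, "_vs_", others)
    calls <- subtype_characteristic(res, p_thr = config$p_thr)
    if (nrow(calls)) char_all <- rbind(char_all, cbind(subtype = s, calls))
  }
  if (!is.null(char_all)) {
    utils::write.table(char_all,
                       file.path(out_dir, "characteristic_sets.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(file.path(out_dir, "characteristic_sets.tsv"))
  }
  pipeline_log(con, "enrich: %d characteristic gene sets",
               if (is.null(char_all)) 0L else nrow(char_all))

  ## unsupervised
  hv <- stage("cluster", high_variance_filter(imputed, config$sd_thr))
  cc <- stage("cluster", consensus_cluster(
    hv, k_range = config$k_range, reps = config$reps,
    p_item = config$p_item, p_feature = config$p_feature,
    seed = derive_seed(config$seed, "consensus")))
  ksel <- stage("cluster", select_k(cc))
  assign_df <- data.frame(sample = colnames(hv$values),
                          cluster = cc$assignments[[as.character(ksel$k)]])
  utils::write.table(assign_df, file.path(out_dir, "cluster_assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  emit(file.path(out_dir, "cluster_assignments.tsv"))
  utils::write.table(ksel$table, file.path(out_dir, "silhouette.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  emit(file.path(out_dir, "silhouette.tsv"))
  pv <- stage("cluster", pvca(imputed, cl_ann,
                              factors = c("subtype", "culture_type")))
  utils::write.table(data.frame(factor = names(pv), fraction = pv),
                     file.path(out_dir, "pvca.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  emit(file.path(out_dir, "pvca.tsv"))
  pipeline_log(con, "cluster: selected K = %d (silhouette %.3f)", ksel$k,
               max(ksel$table$avg_sil))

  ## sPLS-DA
  X <- t(imputed$values)
  tun <- stage("splsda", tune_splsda(
    X, subtype, max_components = config$max_components,
    keepX_grid = config$keepX_grid, folds = config$folds,
    repeats = config$repeats, seed = derive_seed(config$seed, "splsda")))
  fit <- stage("splsda", fit_splsda(X, subtype, tun$choice$n_components,
                                    tun$choice$keepX))
  stab_df <- data.frame(protein = names(tun$stability),
                        stability = as.numeric(tun$stability))
  utils::write.table(stab_df[stab_df$stability > 0, ],
                     file.path(out_dir, "splsda_stability.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  emit(file.path(out_dir, "splsda_stability.tsv"))
  jsonlite::write_json(
    list(n_components = tun$choice$n_components, keepX = tun$choice$keepX,
         ber = tun$choice$ber,
         selected = lapply(fit$selected, identity)),
    file.path(out_dir, "splsda_model.json"), auto_unbox = TRUE, digits = NA)
  emit(file.path(out_dir, "splsda_model.json"))
  pipeline_log(con, "splsda: %d components, keepX = %s, CV BER = %.3f",
               tun$choice$n_components,
               paste(tun$choice$keepX, collapse = "/"), tun$choice$ber)

  manifest <- tools::md5sum(outputs)
  names(manifest) <- basename(names(manifest))
  jsonlite::write_json(as.list(manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}
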