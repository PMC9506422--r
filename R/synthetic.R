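#' Simulation configuration for synthetic SCLC-like proteome data
#'
#' Builds the configuration consumed by [generate_dataset()]. The defaults
#' describe the stated world the downstream analysis assumes: 26 cell lines in
#' the 8/7/4/7 SCLC-A/N/P/Y split, two MS batches with every cell line
#' measured in both, three technical injection replicates per vial, log-normal
#' protein intensities around a log2 baseline, 200 planted subtype-specific
#' proteins (Delta = 2 log2 units) among 2,000 null proteins, an additive
#' one-log2-unit batch shift, a culture-type effect on a disjoint protein set,
#' NE/non-NE and epithelial/mesenchymal marker blocks with negatively coupled
#' group structure, and intensity-dependent (left-censored) missingness under
#' a logistic detection model tuned to roughly 15% missing cells.
#'
#' @param n_proteins total number of proteins in the matrix.
#' @param samples data frame with columns `cell_line`, `subtype` (A/N/P/Y),
#'   `batch`, `culture_type`, `n_bio`, `n_tech`; each row expands into
#'   `n_bio * n_tech` measurements in that batch. Defaults to
#'   [default_sample_sheet()].
#' @param baseline_mean,protein_sd log2 baseline intensity and between-protein
#'   SD of the per-protein abundance offset.
#' @param subtype_effect planted log2 shift of subtype-specific proteins.
#' @param n_specific_per_subtype planted subtype-specific proteins per subtype.
#' @param prop_down fraction of planted proteins shifted down rather than up.
#' @param batch_shift SD (log2) of the protein-specific additive offsets of
#'   the second (and further) batches relative to the first.
#' @param culture_effect log2 shift of `n_culture_proteins` (disjoint from the
#'   planted subtype proteins) in suspension cultures; semi-adherent lines get
#'   half of it.
#' @param n_culture_proteins size of the culture-affected protein block.
#' @param noise_sd replicate-level (technical) log2 noise SD.
#' @param bio_sd SD of the per-protein, per-cell-line biological offset,
#'   shared by all measurements of a cell line. Without it, replicate
#'   averaging shrinks the effective noise by sqrt(n measurements) and group
#'   tests become unrealistically powerful; 0.5 log2 units is a typical
#'   between-line heterogeneity for cancer cell-line panels.
#' @param marker_effect,marker_counts log2 amplitude and sizes
#'   `(n_NE, n_nonNE, n_epi, n_mes)` of the marker blocks.
#' @param missing_midpoint,missing_slope logistic detection model: a log2
#'   intensity `x` is missing with probability
#'   `1 / (1 + exp(slope * (x - midpoint)))`.
#' @param geneset_sizes member counts for planted enriched gene sets.
#' @param n_null_sets number of unenriched gene sets for [generate_genesets()].
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_proteins = 2200,
                              samples = default_sample_sheet(),
                              baseline_mean = 20,
                              protein_sd = 1.5,
                              subtype_effect = 2,
                              n_specific_per_subtype = 50,
                              prop_down = 0.25,
                              batch_shift = 1.0,
                              culture_effect = 0.75,
                              n_culture_proteins = 100,
                              noise_sd = 0.5,
                              bio_sd = 0.5,
                              marker_effect = 1.5,
                              marker_counts = c(n_NE = 25, n_nonNE = 25,
                                                n_epi = 22, n_mes = 15),
                              missing_midpoint = 17.6,
                              missing_slope = 1,
                              geneset_sizes = rep(40L, 4L),
                              n_null_sets = 50L,
                              seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins), samples = samples,
              baseline_mean = baseline_mean, protein_sd = protein_sd,
              subtype_effect = subtype_effect,
              n_specific_per_subtype = as.integer(n_specific_per_subtype),
              prop_down = prop_down, batch_shift = batch_shift,
              culture_effect = culture_effect,
              n_culture_proteins = as.integer(n_culture_proteins),
              noise_sd = noise_sd, bio_sd = bio_sd,
              marker_effect = marker_effect,
              marker_counts = marker_counts,
              missing_midpoint = missing_midpoint,
              missing_slope = missing_slope,
              geneset_sizes = as.integer(geneset_sizes),
              n_null_sets = as.integer(n_null_sets),
              seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  s <- cfg$samples
  need <- c("cell_line", "subtype", "batch", "culture_type", "n_bio", "n_tech")
  miss <- setdiff(need, names(s))
  if (length(miss))
    stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(s$subtype %in% c("A", "N", "P", "Y")))
    stop("subtype must be one of A, N, P, Y")
  counts <- c(cfg$n_proteins, cfg$n_specific_per_subtype,
              cfg$n_culture_proteins, cfg$marker_counts, s$n_bio, s$n_tech)
  if (any(counts <= 0 | counts != floor(counts)) &&
      !(cfg$n_culture_proteins == 0))   # culture block may be absent
    stop("all counts must be positive integers")
  reserved <- 4L * cfg$n_specific_per_subtype + cfg$n_culture_proteins +
    sum(cfg$marker_counts)
  if (cfg$n_proteins < reserved)
    stop(sprintf("n_proteins (%d) below planted proteins needed (%d)",
                 cfg$n_proteins, reserved))
  if (cfg$missing_slope < 0) stop("missing_slope must be >= 0")
  invisible(cfg)
}

#' Default measurement layout: the study geometry
#'
#' 26 cell lines (8 SCLC-A, 7 SCLC-N, 4 SCLC-P, 7 SCLC-Y; 13 adherent, 3
#' semi-adherent, 10 suspension, mirroring the packaged cell-line table), each
#' measured in both of two MS batches with one vial per batch and three
#' technical injection replicates per vial.
#'
#' @param cell_lines cell-line annotation with columns `cell_line`, `subtype`,
#'   `culture_type`; defaults to the packaged table.
#' @param n_batches,n_tech batches per cell line and technical replicates per
#'   vial.
#' @return sample sheet data frame for [simulation_config()].
#' @export
default_sample_sheet <- function(cell_lines = NULL, n_batches = 2L,
                                 n_tech = 3L) {
  if (is.null(cell_lines)) {
    path <- system.file("extdata", "sclc_cell_lines.tsv",
                        package = "sclcsubtyper")
    cell_lines <- load_cell_line_table(path)
  }
  out <- do.call(rbind, lapply(seq_len(n_batches), function(b) {
    data.frame(cell_line = cell_lines$cell_line,
               subtype = cell_lines$subtype,
               batch = paste0("B", b),
               culture_type = cell_lines$culture_type,
               n_bio = 1L, n_tech = as.integer(n_tech),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

expand_sample_sheet <- function(samples) {
  rows <- lapply(seq_len(nrow(samples)), function(i) {
    r <- samples[i, ]
    grid <- expand.grid(tech_rep = seq_len(r$n_tech),
                        bio_rep = seq_len(r$n_bio))
    data.frame(measurement_id = sprintf("%s_%s_bio%d_tech%d", r$cell_line,
                                        r$batch, grid$bio_rep, grid$tech_rep),
               cell_line = r$cell_line, subtype = r$subtype, batch = r$batch,
               culture_type = r$culture_type, bio_rep = grid$bio_rep,
               tech_rep = grid$tech_rep, stringsAsFactors = FALSE)
  })
  ann <- do.call(rbind, rows)
  if (anyDuplicated(ann$measurement_id))
    stop("inconsistent sample list: duplicate measurement ids (",
         paste(unique(ann$measurement_id[duplicated(ann$measurement_id)]),
               collapse = ", "), ")")
  rownames(ann) <- NULL
  ann
}

# group-structure profiles for marker blocks: NE high in A/N, low in Y;
# mesenchymal high in Y -- so NE and EMT scores are negatively coupled.
.delta_ne  <- c(A = 1, N = 0.75, P = 0, Y = -1)
.delta_emt <- c(A = -0.75, N = 0.25, P = -0.5, Y = 1)

#' Generate a synthetic label-free proteome dataset with planted truth
#'
#' Simulates a raw (linear-scale) protein-by-measurement intensity matrix
#' under the additive log2 model
#' `baseline + protein offset + subtype effect + batch shift + culture effect
#' + marker effect + replicate noise`, together with the measurement
#' annotation and a `SyntheticTruth` object listing every planted structure
#' (the oracle for recovery tests).
#'
#' @param config a [simulation_config()].
#' @return list with elements `matrix` (raw-linear `IntensityMatrix`, fully
#'   observed; pass through [inject_missingness()] for censoring),
#'   `annotation` (measurement-level sample annotation) and `truth`.
#' @export
generate_dataset <- function(config) {
  validate_simulation_config(config)
  ann <- expand_sample_sheet(config$samples)
  n_meas <- nrow(ann)
  p <- config$n_proteins
  ids <- sprintf("P%04d", seq_len(p))

  # disjoint planted blocks, then null background
  idx <- seq_len(p)
  take <- function(n) {
    out <- idx[seq_len(n)]
    idx <<- idx[-seq_len(n)]
    out
  }
  subtypes <- c("A", "N", "P", "Y")
  spec <- lapply(subtypes, function(s) take(config$n_specific_per_subtype))
  names(spec) <- subtypes
  culture_idx <- if (config$n_culture_proteins > 0)
    take(config$n_culture_proteins) else integer(0)
  mk <- config$marker_counts
  marker_idx <- list(NE = take(mk[["n_NE"]]), nonNE = take(mk[["n_nonNE"]]),
                     epi = take(mk[["n_epi"]]), mes = take(mk[["n_mes"]]))

  n_down <- floor(config$prop_down * config$n_specific_per_subtype)
  specific <- do.call(rbind, lapply(subtypes, function(s) {
    k <- length(spec[[s]])
    sign <- rep(1, k)
    if (n_down > 0) sign[seq_len(n_down) + (k - n_down)] <- -1
    data.frame(protein = ids[spec[[s]]], subtype = s, sign = sign,
               stringsAsFactors = FALSE)
  }))

  with_seed(config$seed, {
    prot_eff <- stats::rnorm(p, 0, config$protein_sd)
    log2m <- matrix(config$baseline_mean + prot_eff, nrow = p, ncol = n_meas)
    dimnames(log2m) <- list(ids, ann$measurement_id)

    for (s in subtypes) {
      cols <- ann$subtype == s
      rows <- spec[[s]]
      sgn <- specific$sign[specific$subtype == s]
      if (any(cols) && length(rows))
        log2m[rows, cols] <- log2m[rows, cols] +
          sgn * config$subtype_effect
    }
    # protein-specific batch offsets (SD = batch_shift): a uniform column
    # shift would be silently removed by median normalization, whereas real
    # MS batch effects hit proteins unevenly and survive it
    batch_levels <- unique(ann$batch)
    for (b in seq_along(batch_levels)[-1]) {
      cols <- ann$batch == batch_levels[b]
      if (config$batch_shift > 0)
        log2m[, cols] <- log2m[, cols] +
          stats::rnorm(p, 0, config$batch_shift)
    }
    if (length(culture_idx)) {
      cult_mult <- c(adherent = 0, `semi-adherent` = 0.5, suspension = 1)
      shift <- config$culture_effect * cult_mult[ann$culture_type]
      log2m[culture_idx, ] <- log2m[culture_idx, ] +
        rep(shift, each = length(culture_idx))
    }
    marker_delta <- list(NE = .delta_ne, nonNE = -.delta_ne,
                         epi = -.delta_emt, mes = .delta_emt)
    for (blk in names(marker_idx)) {
      rows <- marker_idx[[blk]]
      if (!length(rows)) next
      shift <- config$marker_effect * marker_delta[[blk]][ann$subtype]
      log2m[rows, ] <- log2m[rows, ] + rep(shift, each = length(rows))
    }
    if (config$bio_sd > 0) {
      lines <- unique(ann$cell_line)
      bio <- matrix(stats::rnorm(p * length(lines), 0, config$bio_sd),
                    p, length(lines), dimnames = list(NULL, lines))
      log2m <- log2m + bio[, ann$cell_line]
    }
    log2m <- log2m + stats::rnorm(p * n_meas, 0, config$noise_sd)
  })

  marker_membership <- data.frame(
    protein = ids[unlist(marker_idx, use.names = FALSE)],
    block = rep(names(marker_idx), lengths(marker_idx)),
    stringsAsFactors = FALSE)

  truth <- structure(list(
    specific_proteins = specific,
    culture_proteins = ids[culture_idx],
    batch_assignment = stats::setNames(ann$batch, ann$measurement_id),
    marker_membership = marker_membership,
    enriched_sets = NULL,
    config = config), class = "SyntheticTruth")

  m <- intensity_matrix(2^log2m, scale = "raw-linear", stage = "raw")
  list(matrix = m, annotation = ann, truth = truth)
}

#' Inject intensity-dependent (left-censored) missingness
#'
#' Each cell of a raw matrix goes missing independently with probability
#' `1 / (1 + exp(slope * (x - midpoint)))` where `x` is the log2 intensity:
#' low-abundance measurements are the most likely to drop out, emulating the
#' left-censoring that motivates down-shifted normal imputation. `slope = 0`
#' collapses to uniform 50% missingness; a very small `midpoint` gives none.
#'
#' @param m raw-linear `IntensityMatrix`.
#' @param midpoint,slope logistic detection parameters (log2 units, 1/log2).
#' @param seed integer seed.
#' @return the matrix with missing cells set to `NA` and masked.
#' @export
inject_missingness <- function(m, midpoint, slope, seed = 1L) {
  stopifnot(inherits(m, "IntensityMatrix"))
  if (slope < 0) stop("slope must be >= 0")
  x <- if (m$scale == "raw-linear") log2(m$values) else m$values
  p_miss <- 1 / (1 + exp(slope * (x - midpoint)))
  with_seed(seed, {
    drop <- matrix(stats::runif(length(x)) < p_miss, nrow = nrow(x))
  })
  vals <- m$values
  vals[drop] <- NA_real_
  mask <- m$mask
  mask[drop] <- "missing"
  im_update(m, values = vals, mask = mask)
}

#' Generate planted-enrichment and null gene sets
#'
#' Builds a gene set collection in which each "enriched" set draws most of its
#' members (`frac_planted`) from the planted subtype-specific proteins of one
#' subtype (matching `direction`), cycling through the subtypes, while null
#' sets are uniform draws from the whole protein universe.
#'
#' @param truth a `SyntheticTruth` from [generate_dataset()].
#' @param universe character vector of all protein ids in the matrix.
#' @param sizes integer member counts, one enriched set per element (>= 5, the
#'   minimum overlap enrichment testing accepts).
#' @param n_null_sets number of null sets (size = mean of `sizes`).
#' @param seed integer seed; identical seeds give byte-identical GMT output.
#' @param frac_planted fraction of members of an enriched set drawn from the
#'   planted pool.
#' @param direction `"up"` or `"down"`: sign of the planted proteins used.
#' @param subtypes subtypes to cycle through for the enriched sets.
#' @return list with `collection` (named list of id vectors) and `enriched`
#'   (data frame set/subtype/direction); `truth$enriched_sets` is mirrored in
#'   the latter.
#' @export
generate_genesets <- function(truth, universe, sizes = rep(40L, 4L),
                              n_null_sets = 50L, seed = 1L,
                              frac_planted = 0.8, direction = "up",
                              subtypes = c("A", "N", "P", "Y")) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  if (any(sizes < 5)) stop("gene set sizes must be >= 5")
  if (any(sizes > length(universe)))
    stop("requested set size exceeds universe")
  want_sign <- if (direction == "up") 1 else -1
  sp <- truth$specific_proteins
  collection <- list()
  enriched <- NULL
  with_seed(seed, {
    for (i in seq_along(sizes)) {
      s <- subtypes[(i - 1) %% length(subtypes) + 1]
      pool <- sp$protein[sp$subtype == s & sp$sign == want_sign]
      n_pl <- min(length(pool), ceiling(frac_planted * sizes[i]))
      members <- sample(pool, n_pl)
      rest <- setdiff(universe, sp$protein)
      members <- c(members, sample(rest, sizes[i] - n_pl))
      nm <- sprintf("ENRICHED_%s_%s_%02d", s, toupper(direction), i)
      collection[[nm]] <- sort(members)
      enriched <- rbind(enriched,
                        data.frame(set = nm, subtype = s,
                                   direction = direction,
                                   stringsAsFactors = FALSE))
    }
    null_size <- as.integer(round(mean(sizes)))
    for (j in seq_len(n_null_sets)) {
      nm <- sprintf("NULL_SET_%03d", j)
      collection[[nm]] <- sort(sample(universe, null_size))
    }
  })
  list(collection = collection, enriched = enriched)
}
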