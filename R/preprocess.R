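#' Log2 transform and median normalization
#'
#' Raw linear intensities are log2-transformed and each measurement (column)
#' is median-centred onto the global median, where the global median is the
#' median of all observed log2 values before shifting. This removes
#' per-injection loading differences; the observed/missing mask is untouched.
#' Normalization is idempotent: applying it twice equals applying it once.
#'
#' @param raw a raw-linear `IntensityMatrix` (observed values must be > 0).
#' @return a log2, median-normalized `IntensityMatrix` (stage `"normalized"`).
#' @export
log2_median_normalize <- function(raw) {
  stopifnot(inherits(raw, "IntensityMatrix"))
  vals <- raw$values
  if (raw$scale == "raw-linear") {
    bad <- which(!is.na(vals) & vals <= 0, arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("non-positive observed intensity for protein %s in column %s",
                   rownames(vals)[bad[1, 1]], colnames(vals)[bad[1, 2]]))
    vals <- log2(vals)
  }
  global_med <- stats::median(vals, na.rm = TRUE)
  col_med <- matrixStats::colMedians(vals, na.rm = TRUE)
  vals <- sweep(vals, 2, col_med - global_med, "-")
  im_update(raw, values = vals, scale = "log2", stage = "normalized")
}

#' Aggregate replicate measurements
#'
#' Two-step replicate collapse: first the median over technical (injection)
#' repeats within the same vial and batch, then the arithmetic mean over the
#' remaining vial-level replicates of each cell line. Both steps ignore
#' missing values; a cell is missing in the output only when every
#' contributing measurement was missing. `level = "vial"` stops after step
#' one (so batch correction can run at the measurement level before cell
#' lines are collapsed); `level = "cell_line"` performs both steps.
#'
#' @param m a log2 `IntensityMatrix` at measurement (or vial) level.
#' @param ann sample annotation matching `m`'s columns: measurement-level for
#'   `level = "vial"` / full collapse; for collapsing a vial-level matrix,
#'   pass the vial annotation returned by the previous call.
#' @param level `"cell_line"` (default) or `"vial"`.
#' @return for `"vial"`, a list with `matrix` and the vial-level `annotation`;
#'   for `"cell_line"`, an `IntensityMatrix` with one column per cell line.
#' @export
aggregate_replicates <- function(m, ann, level = c("cell_line", "vial")) {
  level <- match.arg(level)
  stopifnot(inherits(m, "IntensityMatrix"))
  if (!all(c("cell_line", "bio_rep", "batch") %in% names(ann)))
    stop("annotation lacks replicate columns (cell_line, bio_rep, batch)")
  key <- if ("measurement_id" %in% names(ann)) ann$measurement_id else
    ann$vial_id
  ann <- ann[match(colnames(m$values), key), , drop = FALSE]

  collapse <- function(vals, obs, groups, fun) {
    idx <- split(seq_along(groups), groups)
    out <- vapply(idx, function(j) {
      apply(vals[, j, drop = FALSE], 1, fun, na.rm = TRUE)
    }, numeric(nrow(vals)))
    out[!is.finite(out)] <- NA_real_
    any_obs <- vapply(idx, function(j) {
      rowSums(obs[, j, drop = FALSE]) > 0
    }, logical(nrow(vals)))
    list(values = out, observed = any_obs)
  }

  obs <- im_observed(m)
  vial <- paste(ann$cell_line, ann$batch, ann$bio_rep, sep = "|")
  if ("tech_rep" %in% names(ann)) {
    st1 <- collapse(m$values, obs, vial, stats::median)
    vial_ann <- unique(data.frame(vial_id = vial, cell_line = ann$cell_line,
                                  subtype = ann$subtype, batch = ann$batch,
                                  culture_type = ann$culture_type,
                                  bio_rep = ann$bio_rep,
                                  stringsAsFactors = FALSE))
    vial_ann <- vial_ann[match(colnames(st1$values), vial_ann$vial_id), ]
    rownames(vial_ann) <- NULL
  } else {  # already vial level
    st1 <- list(values = m$values, observed = obs)
    vial_ann <- ann
  }
  mask1 <- ifelse(st1$observed, "observed", "missing")
  if (level == "vial") {
    mm <- intensity_matrix(st1$values, mask1, scale = "log2",
                           stage = "aggregated")
    return(list(matrix = mm, annotation = vial_ann))
  }
  st2 <- collapse(st1$values, st1$observed, vial_ann$cell_line, mean)
  mask2 <- ifelse(st2$observed, "observed", "missing")
  intensity_matrix(st2$values, mask2, scale = "log2", stage = "aggregated")
}

#' Valid-value filter
#'
#' Retains proteins quantified (observed, not imputed) in at least `min_frac`
#' of the samples; proteins with zero observations are always dropped. The
#' fraction rule is exact (>= 0.8 of 26 samples means 21 observed qualifies,
#' 20 does not) -- no integer rounding.
#'
#' @param m an `IntensityMatrix` at one column per cell line.
#' @param min_frac minimum observed fraction, in (0, 1].
#' @return the filtered `IntensityMatrix` (stage `"filtered"`).
#' @export
filter_valid <- function(m, min_frac = 0.8) {
  stopifnot(inherits(m, "IntensityMatrix"))
  if (!is.numeric(min_frac) || min_frac <= 0 || min_frac > 1)
    stop("min_frac must lie in (0, 1]")
  n_obs <- rowSums(im_observed(m))
  keep <- n_obs / ncol(m$values) >= min_frac & n_obs > 0
  im_update(m, values = m$values[keep, , drop = FALSE],
            mask = m$mask[keep, , drop = FALSE], stage = "filtered")
}

#' Batch-effect regression
#'
#' Removes additive batch differences per protein by univariate linear
#' regression on the batch indicator: observed values are replaced by the
#' regression residual plus the grand mean of the protein's observed values.
#' Proteins with no quantified value in one of the batches are excluded from
#' the correction (returned unchanged and flagged in the `"uncorrected"`
#' attribute); missing cells stay missing. With a single batch the matrix is
#' returned unchanged.
#'
#' @param m a log2 `IntensityMatrix`.
#' @param ann annotation for the columns of `m`, with a `batch` column (and
#'   `measurement_id` / `vial_id` matching the column names).
#' @return corrected `IntensityMatrix` (stage `"corrected"`), with attribute
#'   `uncorrected` listing the skipped proteins.
#' @export
correct_batch <- function(m, ann) {
  stopifnot(inherits(m, "IntensityMatrix"))
  key <- if ("measurement_id" %in% names(ann)) ann$measurement_id
  else if ("vial_id" %in% names(ann)) ann$vial_id else ann$cell_line
  batch <- ann$batch[match(colnames(m$values), key)]
  if (anyNA(batch)) stop("columns without batch annotation")
  levels_b <- unique(batch)
  if (any(!levels_b %in% batch)) stop("a batch has zero samples")
  if (length(levels_b) < 2) {
    out <- im_update(m, stage = "corrected")
    attr(out, "uncorrected") <- character(0)
    return(out)
  }
  vals <- m$values
  obs <- im_observed(m)
  bfac <- factor(batch, levels = levels_b)
  uncorrected <- character(0)
  for (i in seq_len(nrow(vals))) {
    oi <- obs[i, ]
    present <- table(bfac[oi]) > 0
    if (!all(present)) {
      uncorrected <- c(uncorrected, rownames(vals)[i])
      next
    }
    y <- vals[i, oi]
    b <- bfac[oi]
    bm <- tapply(y, b, mean)
    vals[i, oi] <- y - bm[as.character(b)] + mean(y)
  }
  out <- im_update(m, values = vals, stage = "corrected")
  attr(out, "uncorrected") <- uncorrected
  out
}

#' Left-censored normal imputation
#'
#' Per sample column with observed mean `mu` and SD `sigma`, every missing
#' cell is drawn independently from
#' `Normal(mu - downshift * sigma, (width * sigma)^2)` -- the down-shifted
#' narrow normal that mimics the abundance distribution of proteins falling
#' below the detection limit. Defaults `width = 0.3`, `downshift = 1.8` are
#' the standard proteomics convention. Imputed cells are flagged in the mask;
#' observed cells are untouched.
#'
#' @param m a filtered/corrected log2 `IntensityMatrix`.
#' @param width,downshift imputation parameters in units of the per-column SD.
#' @param seed integer seed; identical seeds give identical draws.
#' @return `IntensityMatrix` with no missing cells (stage `"imputed"`).
#' @export
impute_normal <- function(m, width = 0.3, downshift = 1.8, seed = 1L) {
  stopifnot(inherits(m, "IntensityMatrix"))
  vals <- m$values
  mask <- m$mask
  obs <- im_observed(m)
  n_obs <- colSums(obs)
  if (any(n_obs < 2))
    stop("column(s) with fewer than 2 observed values (SD undefined): ",
         paste(colnames(vals)[n_obs < 2], collapse = ", "))
  with_seed(seed, {
    for (j in seq_len(ncol(vals))) {
      miss <- which(!obs[, j] & mask[, j] == "missing")
      if (!length(miss)) next
      mu <- mean(vals[obs[, j], j])
      sigma <- stats::sd(vals[obs[, j], j])
      vals[miss, j] <- stats::rnorm(length(miss), mu - downshift * sigma,
                                    width * sigma)
      mask[miss, j] <- "imputed"
    }
  })
  im_update(m, values = vals, mask = mask, stage = "imputed")
}

#' Detect on/off proteins
#'
#' A protein is called 'on' in subtype `s` when it is present (observed
#' before imputation) in at least `hi` of the samples of `s` and in at most
#' `lo` of the samples of every other subtype; 'off' is the mirrored rule.
#' Presence is assessed on the pre-imputation mask at cell-line level, since
#' imputation would fabricate presence.
#'
#' @param m pre-imputation `IntensityMatrix` at one column per cell line.
#' @param ann cell-line-level annotation with `cell_line` and `subtype`.
#' @param hi,lo presence thresholds (fractions).
#' @return data frame with columns `protein`, `subtype`, `direction` and the
#'   per-subtype presence fractions (`frac_A` .. `frac_Y`); zero rows when
#'   nothing qualifies.
#' @export
detect_on_off <- function(m, ann, hi = 0.85, lo = 0.15) {
  stopifnot(inherits(m, "IntensityMatrix"))
  subtype <- ann$subtype[match(colnames(m$values), ann$cell_line)]
  if (anyNA(subtype)) stop("columns without subtype annotation")
  subtypes <- sort(unique(subtype))
  sizes <- table(subtype)
  if (any(sizes == 0)) stop("empty subtype group")
  obs <- im_observed(m)
  frac <- vapply(subtypes, function(s) {
    rowMeans(obs[, subtype == s, drop = FALSE])
  }, numeric(nrow(obs)))
  calls <- NULL
  for (s in subtypes) {
    others <- setdiff(subtypes, s)
    on <- frac[, s] >= hi &
      rowSums(frac[, others, drop = FALSE] <= lo) == length(others)
    off <- frac[, s] <= lo &
      rowSums(frac[, others, drop = FALSE] >= hi) == length(others)
    for (dir in c("on", "off")) {
      hit <- if (dir == "on") on else off
      if (!any(hit)) next
      df <- data.frame(protein = rownames(obs)[hit], subtype = s,
                       direction = dir, stringsAsFactors = FALSE)
      fr <- frac[hit, , drop = FALSE]
      colnames(fr) <- paste0("frac_", subtypes)
      calls <- rbind(calls, cbind(df, fr))
    }
  }
  if (is.null(calls))
    calls <- data.frame(protein = character(0), subtype = character(0),
                        direction = character(0), stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  calls
}
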