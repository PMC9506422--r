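#' Intensity matrix container
#'
#' An `IntensityMatrix` holds a protein-by-measurement abundance matrix
#' together with a per-cell provenance mask, the value scale and the pipeline
#' stage the matrix is at. The mask distinguishes observed values, missing
#' cells, and cells filled in by imputation, so downstream steps that must not
#' see fabricated values (valid-value filtering, on/off detection) can operate
#' on the pre-imputation support.
#'
#' @param values numeric matrix, proteins in rows (unique rownames), samples /
#'   measurements in columns (unique colnames). `NA` marks missing cells.
#' @param mask character matrix of the same shape with entries `"observed"`,
#'   `"missing"` or `"imputed"`; defaults to `"observed"` where `values` is
#'   finite and `"missing"` where it is `NA`.
#' @param scale `"raw-linear"` (as read from the quantitation software) or
#'   `"log2"`.
#' @param stage one of `"raw"`, `"normalized"`, `"aggregated"`, `"filtered"`,
#'   `"corrected"`, `"imputed"`.
#' @return an object of class `IntensityMatrix`.
#' @export
intensity_matrix <- function(values, mask = NULL,
                             scale = c("raw-linear", "log2"),
                             stage = c("raw", "normalized", "aggregated",
                                       "filtered", "corrected", "imputed")) {
  scale <- match.arg(scale)
  stage <- match.arg(stage)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("`values` must have unique rownames (protein ids)")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("`values` must have unique colnames (measurement ids)")
  if (is.null(mask)) {
    mask <- matrix(ifelse(is.na(values), "missing", "observed"),
                   nrow = nrow(values), dimnames = dimnames(values))
  }
  if (!identical(dim(mask), dim(values)))
    stop("`mask` must have the same dimensions as `values`")
  dimnames(mask) <- dimnames(values)
  bad <- !mask %in% c("observed", "missing", "imputed")
  if (any(bad)) stop("mask entries must be observed/missing/imputed")
  if (any(is.na(values) & mask != "missing"))
    stop("NA values must be masked as 'missing'")
  structure(list(values = values, mask = mask, scale = scale, stage = stage),
            class = "IntensityMatrix")
}

#' @export
print.IntensityMatrix <- function(x, ...) {
  cat(sprintf("IntensityMatrix: %d proteins x %d samples [%s, stage=%s]\n",
              nrow(x$values), ncol(x$values), x$scale, x$stage))
  tab <- table(factor(x$mask, levels = c("observed", "missing", "imputed")))
  cat(sprintf("  cells: %d observed, %d missing, %d imputed\n",
              tab[["observed"]], tab[["missing"]], tab[["imputed"]]))
  invisible(x)
}

#' @export
dim.IntensityMatrix <- function(x) dim(x$values)

im_update <- function(m, values = m$values, mask = m$mask, scale = m$scale,
                      stage = m$stage) {
  intensity_matrix(values, mask, scale = scale, stage = stage)
}

#' Observed-cell indicator of an intensity matrix
#'
#' `TRUE` where a value was actually measured (not missing, not imputed).
#' @param m an `IntensityMatrix`.
#' @return logical matrix.
#' @export
im_observed <- function(m) m$mask == "observed"

#' Read / write intensity TSV
#'
#' The on-disk format is a TSV with protein ids in the first column
#' (`protein_id`) and one column per measurement; empty cells are missing.
#' An optional side-car mask TSV with identical layout carries the
#' observed/missing/imputed provenance.
#'
#' @param m an `IntensityMatrix`.
#' @param path output TSV path.
#' @param mask_path optional path for the provenance mask TSV.
#' @return `write_intensity_tsv` returns `path` invisibly.
#' @export
write_intensity_tsv <- function(m, path, mask_path = NULL) {
  df <- data.frame(protein_id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  if (!is.null(mask_path)) {
    mdf <- data.frame(protein_id = rownames(m$mask), m$mask,
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(mdf, mask_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_intensity_tsv
#' @param scale,stage scale/stage tags to attach to the matrix read from disk.
#' @export
read_intensity_tsv <- function(path, mask_path = NULL, scale = "raw-linear",
                               stage = "raw") {
  df <- utils::read.delim(path, check.names = FALSE, na.strings = c("", "NA"),
                          stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- df[[1]]
  mask <- NULL
  if (!is.null(mask_path)) {
    mdf <- utils::read.delim(mask_path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    mask <- as.matrix(mdf[, -1, drop = FALSE])
    rownames(mask) <- mdf[[1]]
  }
  intensity_matrix(vals, mask, scale = scale, stage = stage)
}

#' Validate a sample annotation table against an intensity matrix
#'
#' Sample annotations are plain data frames with one row per measurement and
#' at least the columns `measurement_id`, `cell_line`, `subtype`, `batch`,
#' `culture_type`, `bio_rep`, `tech_rep` (the latter two only at measurement
#' level). Subtypes use the one-letter codes A/N/P/Y; culture types are
#' adherent / semi-adherent / suspension.
#'
#' @param ann data frame.
#' @param m optional `IntensityMatrix` whose columns must all be annotated.
#' @param level `"measurement"` (replicate columns required) or `"cell_line"`.
#' @return the annotation, invisibly, after validation.
#' @export
validate_annotation <- function(ann, m = NULL,
                                level = c("measurement", "cell_line")) {
  level <- match.arg(level)
  need <- c("cell_line", "subtype", "culture_type")
  if (level == "measurement")
    need <- c("measurement_id", need, "batch", "bio_rep", "tech_rep")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("annotation lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(ann$subtype %in% c("A", "N", "P", "Y")))
    stop("unknown subtype token(s): ",
         paste(unique(setdiff(ann$subtype, c("A", "N", "P", "Y"))),
               collapse = ", "))
  if (!all(ann$culture_type %in% c("adherent", "semi-adherent", "suspension")))
    stop("unknown culture_type token(s): ",
         paste(unique(setdiff(ann$culture_type,
                              c("adherent", "semi-adherent", "suspension"))),
               collapse = ", "))
  if (!is.null(m)) {
    key <- if (level == "measurement") ann$measurement_id else ann$cell_line
    if (anyDuplicated(key)) stop("duplicate measurement ids in annotation")
    absent <- setdiff(colnames(m$values), key)
    if (length(absent))
      stop("matrix columns not annotated: ", paste(absent, collapse = ", "))
  }
  invisible(ann)
}
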