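#' Read a database membership table
#'
#' TSV with columns `protein_id`, `database_id`, `category` (one row per
#' membership), where category is one of secretome, surfaceome, plasma,
#' plasma-actively-secreted, druggable. Databases are consumed as static
#' snapshots -- never fetched live.
#'
#' @param path TSV path.
#' @return the membership data frame.
#' @export
read_membership_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("protein_id", "database_id", "category")
  if (!all(need %in% names(df)))
    stop("membership table needs columns: ", paste(need, collapse = ", "))
  df
}

#' Database-overlap annotation
#'
#' Returns the proteins supported by at least `min_db` databases of a
#' category. The field conventions: secreted = listed in at least 2 of the 3
#' secretome databases; cell-surface = in both surfaceome databases; plasma
#' and druggable membership need a single database.
#'
#' @param mem membership table (see [read_membership_tsv()]).
#' @param category category to annotate.
#' @param min_db minimum databases; defaults to the per-category convention.
#' @return character vector of protein ids.
#' @export
annotate_overlap <- function(mem, category, min_db = NULL) {
  if (!category %in% mem$category) stop("unknown category: ", category)
  sub <- mem[mem$category == category, , drop = FALSE]
  n_db <- length(unique(sub$database_id))
  if (is.null(min_db)) {
    min_db <- switch(category, secretome = 2L, surfaceome = 2L, 1L)
  }
  if (min_db > n_db)
    stop(sprintf("min_db (%d) exceeds databases in category (%d)", min_db,
                 n_db))
  counts <- tapply(sub$database_id, sub$protein_id,
                   function(x) length(unique(x)))
  sort(names(counts)[counts >= min_db])
}

#' Read a drug-sensitivity table
#'
#' TSV with columns `cell_line`, `drug`, `ln_ic50` (natural-log IC50), plus
#' an optional target map TSV (`drug`, `target`) for multi-target drugs.
#'
#' @param path sensitivity TSV.
#' @param target_path optional target map TSV.
#' @return list with `ic50` (data frame) and `targets` (data frame or NULL).
#' @export
read_drug_tsv <- function(path, target_path = NULL) {
  ic50 <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cell_line", "drug", "ln_ic50")
  if (!all(need %in% names(ic50)))
    stop("drug table needs columns: ", paste(need, collapse = ", "))
  targets <- if (!is.null(target_path))
    utils::read.delim(target_path, stringsAsFactors = FALSE) else NULL
  list(ic50 = ic50, targets = targets)
}

#' Protein abundance vs drug sensitivity correlation
#'
#' Pearson correlation (two-sided t-test p) between a protein's abundance
#' across cell lines and the ln(IC50) of a drug, over the intersecting cell
#' lines. Fewer than 3 shared lines is an error; zero variance in either
#' vector returns a flagged missing result rather than a number.
#'
#' @param abund named numeric vector: protein abundance per cell line (one
#'   row of an `IntensityMatrix`).
#' @param drugs drug-sensitivity data frame (`cell_line`, `drug`, `ln_ic50`).
#' @param drug drug identifier.
#' @return list `r`, `p`, `n`, `flag` (`"ok"` or `"zero-variance"`).
#' @export
drug_correlation <- function(abund, drugs, drug) {
  d <- drugs[drugs$drug == drug & !is.na(drugs$ln_ic50), , drop = FALSE]
  common <- intersect(names(abund)[!is.na(abund)], d$cell_line)
  if (length(common) < 3)
    stop("fewer than 3 cell lines with both protein and IC50 values")
  x <- abund[common]
  y <- d$ln_ic50[match(common, d$cell_line)]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(common),
                flag = "zero-variance"))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(common),
       flag = "ok")
}

#' Per-subtype median drug sensitivity
#'
#' For every drug, the median ln(IC50) over the measured cell lines of each
#' subtype plus the subtype's rank (1 = most sensitive, i.e. lowest median).
#' Subtypes with no measured line are reported missing.
#'
#' @param drugs drug-sensitivity data frame.
#' @param ann cell-line annotation (`cell_line`, `subtype`).
#' @return data frame `drug`, `subtype`, `median_ln_ic50`, `rank`, `n_lines`.
#' @export
subtype_drug_summary <- function(drugs, ann) {
  subtypes <- sort(unique(ann$subtype))
  out <- NULL
  for (dg in unique(drugs$drug)) {
    d <- drugs[drugs$drug == dg & !is.na(drugs$ln_ic50), , drop = FALSE]
    st <- ann$subtype[match(d$cell_line, ann$cell_line)]
    med <- vapply(subtypes, function(s) {
      v <- d$ln_ic50[!is.na(st) & st == s]
      if (length(v)) stats::median(v) else NA_real_
    }, numeric(1))
    nl <- vapply(subtypes, function(s) sum(!is.na(st) & st == s), integer(1))
    rk <- rank(med, ties.method = "min", na.last = "keep")
    out <- rbind(out, data.frame(drug = dg, subtype = subtypes,
                                 median_ln_ic50 = unname(med),
                                 rank = unname(rk), n_lines = unname(nl),
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
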