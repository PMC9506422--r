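#' One-way ANOVA with Tukey HSD post hoc tests per protein
#'
#' For every protein, a one-way fixed-effects ANOVA F-test across the groups
#' (subtypes or culture types), Benjamini-Hochberg correction of the ANOVA
#' p-values across all proteins, and Tukey's honestly-significant-difference
#' p-value for every group pair from the studentized-range distribution with
#' the pooled within-group variance. `mean_diff` for pair `g1_vs_g2` is
#' `mean(g1) - mean(g2)` on the log2 scale (a log2 fold change). Proteins
#' with zero total variance are kept with `p = 1` and a degenerate flag so
#' downstream counts stay stable.
#'
#' @param m an imputed (complete) log2 `IntensityMatrix`.
#' @param groups character/factor group label per column of `m`.
#' @return a `DEResult`: list with `anova` (protein, anova_p, anova_fdr,
#'   degenerate), `pairs` (protein, pair, group1, group2, mean_diff, tukey_p)
#'   and `groups` (the level order).
#' @export
anova_tukey <- function(m, groups) {
  stopifnot(inherits(m, "IntensityMatrix"))
  vals <- m$values
  g <- factor(groups)
  if (length(g) != ncol(vals)) stop("groups must match matrix columns")
  if (nlevels(g) < 2) stop("need at least 2 groups")
  n_per <- table(g)
  if (any(n_per < 2)) stop("every group needs at least 2 samples")
  k <- nlevels(g)
  N <- ncol(vals)
  df1 <- k - 1
  df2 <- N - k

  idx <- split(seq_len(N), g)
  gmeans <- vapply(idx, function(j) rowMeans(vals[, j, drop = FALSE]),
                   numeric(nrow(vals)))
  gvars <- vapply(idx, function(j) {
    matrixStats::rowVars(vals[, j, drop = FALSE])
  }, numeric(nrow(vals)))
  if (nrow(vals) == 1) {  # vapply collapses single-row matrices
    gmeans <- matrix(gmeans, nrow = 1, dimnames = list(rownames(vals),
                                                       levels(g)))
    gvars <- matrix(gvars, nrow = 1, dimnames = list(rownames(vals),
                                                     levels(g)))
  }
  n_vec <- as.numeric(n_per[colnames(gmeans)])
  grand <- rowMeans(vals)
  ssb <- rowSums(sweep(sweep(gmeans, 1, grand, "-")^2, 2, n_vec, "*"))
  ssw <- rowSums(sweep(gvars, 2, n_vec - 1, "*"))
  s2p <- ssw / df2
  fstat <- (ssb / df1) / s2p
  anova_p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  degenerate <- (ssb + ssw) < .Machine$double.eps * 100
  anova_p[degenerate] <- 1
  anova_p[!degenerate & s2p == 0] <- 0  # separated groups, no within noise
  anova_fdr <- stats::p.adjust(anova_p, method = "BH")

  combs <- utils::combn(levels(g), 2)
  pair_rows <- lapply(seq_len(ncol(combs)), function(ci) {
    g1 <- combs[1, ci]; g2 <- combs[2, ci]
    diff <- gmeans[, g1] - gmeans[, g2]
    se <- sqrt(s2p / 2 * (1 / n_per[[g1]] + 1 / n_per[[g2]]))
    q <- abs(diff) / se
    q[se == 0 & abs(diff) > 0] <- Inf
    q[abs(diff) == 0] <- 0
    tp <- stats::ptukey(q, nmeans = k, df = df2, lower.tail = FALSE)
    tp[degenerate] <- 1
    data.frame(protein = rownames(vals),
               pair = paste0(g1, "_vs_", g2), group1 = g1, group2 = g2,
               mean_diff = unname(diff), tukey_p = unname(tp),
               stringsAsFactors = FALSE)
  })
  structure(list(
    anova = data.frame(protein = rownames(vals), anova_p = unname(anova_p),
                       anova_fdr = unname(anova_fdr),
                       degenerate = unname(degenerate),
                       stringsAsFactors = FALSE),
    pairs = do.call(rbind, pair_rows),
    groups = levels(g)), class = "DEResult")
}

de_pair <- function(r, pair) {
  hit <- r$pairs[r$pairs$pair == pair, , drop = FALSE]
  if (!nrow(hit)) {
    # accept the reversed order with flipped sign
    gs <- strsplit(pair, "_vs_")[[1]]
    rev_pair <- paste0(gs[2], "_vs_", gs[1])
    hit <- r$pairs[r$pairs$pair == rev_pair, , drop = FALSE]
    if (!nrow(hit)) stop("unknown pair: ", pair)
    hit$mean_diff <- -hit$mean_diff
    hit$pair <- pair
    hit$group1 <- gs[1]; hit$group2 <- gs[2]
  }
  hit
}

#' Significant proteins for one pairwise comparison
#'
#' A protein is significant for a pair when both its ANOVA BH-FDR and the
#' pair's Tukey HSD p-value fall below the thresholds.
#'
#' @param r a `DEResult`.
#' @param pair pair label, e.g. `"A_vs_N"` (either order accepted).
#' @param fdr,p thresholds (both 0.05 by default).
#' @return character vector of protein ids.
#' @export
significant_proteins <- function(r, pair, fdr = 0.05, p = 0.05) {
  pr <- de_pair(r, pair)
  fd <- r$anova$anova_fdr[match(pr$protein, r$anova$protein)]
  pr$protein[fd < fdr & pr$tukey_p < p]
}

#' Subtype-specific proteins
#'
#' A protein is specific for a subtype when its ANOVA FDR is below `fdr` and
#' all three Tukey HSD p-values of that subtype against the other subtypes
#' are below `p`. Direction is `"up"` when all three mean differences
#' (subtype minus other) are positive, `"down"` when all negative, `"mixed"`
#' otherwise.
#'
#' @param r a `DEResult` over the four subtypes.
#' @param subtype subtype of interest (`"A"`, `"N"`, `"P"` or `"Y"`).
#' @param fdr,p thresholds.
#' @return data frame `protein`, `direction`.
#' @export
subtype_specific <- function(r, subtype, fdr = 0.05, p = 0.05) {
  others <- setdiff(r$groups, subtype)
  if (!subtype %in% r$groups) stop("unknown subtype: ", subtype)
  per_pair <- lapply(others, function(o) {
    de_pair(r, paste0(subtype, "_vs_", o))
  })
  prot <- per_pair[[1]]$protein
  pmat <- vapply(per_pair, function(d) d$tukey_p[match(prot, d$protein)],
                 numeric(length(prot)))
  dmat <- vapply(per_pair, function(d) d$mean_diff[match(prot, d$protein)],
                 numeric(length(prot)))
  fd <- r$anova$anova_fdr[match(prot, r$anova$protein)]
  ok <- fd < fdr & rowSums(pmat < p) == length(others)
  direction <- ifelse(rowSums(dmat > 0) == length(others), "up",
                      ifelse(rowSums(dmat < 0) == length(others), "down",
                             "mixed"))
  data.frame(protein = prot[ok], direction = direction[ok],
             stringsAsFactors = FALSE)
}

#' Ranking metric for pre-ranked GSEA
#'
#' Score per protein for one pair: log2 fold change times
#' `-log10(Tukey p)`, in descending order with lexicographic protein-id
#' tie-breaking for determinism. Zero p-values are floored at the smallest
#' positive double and flagged.
#'
#' @param r a `DEResult`.
#' @param pair pair label.
#' @return data frame `protein`, `score` (descending), with a `floored`
#'   attribute naming proteins whose p was floored.
#' @export
rank_metric <- function(r, pair) {
  pr <- de_pair(r, pair)
  floored <- pr$protein[pr$tukey_p == 0]
  pclip <- pmax(pr$tukey_p, .Machine$double.xmin)
  score <- pr$mean_diff * (-log10(pclip))
  ord <- order(-score, pr$protein)
  out <- data.frame(protein = pr$protein[ord], score = score[ord],
                    stringsAsFactors = FALSE)
  attr(out, "floored") <- floored
  out
}

#' Culture-type group labels
#'
#' The adherent-vs-suspension comparison: semi-adherent lines are excluded by
#' default, or merged into the adherent class.
#'
#' @param ann cell-line annotation with `culture_type`.
#' @param semi `"exclude"` or `"adherent"`.
#' @return character vector with `NA` for excluded samples, aligned to `ann`.
#' @export
culture_groups <- function(ann, semi = c("exclude", "adherent")) {
  semi <- match.arg(semi)
  g <- ann$culture_type
  g[g == "semi-adherent"] <- if (semi == "exclude") NA_character_ else
    "adherent"
  g
}
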