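#' Read / write GMT gene set collections
#'
#' A collection is a named list of character id vectors. GMT lines are
#' tab-separated: set name, description, then the members.
#'
#' @param path GMT file path.
#' @return `read_gmt` returns the named list (descriptions in the
#'   `"description"` attribute).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  names <- vapply(parts, `[`, character(1), 1)
  if (anyDuplicated(names)) stop("duplicate gene set names in GMT")
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- names
  if (any(lengths(sets) == 0)) stop("empty gene set in GMT")
  attr(sets, "description") <- vapply(parts, `[`, character(1), 2)
  sets
}

#' @rdname read_gmt
#' @param gs named list of character vectors.
#' @param description per-set description (recycled).
#' @export
write_gmt <- function(gs, path, description = "na") {
  description <- rep_len(description, length(gs))
  lines <- vapply(seq_along(gs), function(i) {
    paste(c(names(gs)[i], description[i], gs[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Over-representation analysis
#'
#' Hypergeometric upper-tail test of the overlap between a hit list and each
#' gene set, after intersecting sets with the universe (background). Sets
#' disjoint from the universe are excluded and reported in the `"excluded"`
#' attribute. BH adjustment across the tested sets.
#'
#' @param hits character vector of significant protein ids (subset of
#'   `universe`).
#' @param universe background protein ids.
#' @param gs named list of gene sets.
#' @return data frame `set`, `set_size`, `overlap`, `p`, `fdr`.
#' @export
ora <- function(hits, universe, gs) {
  if (!length(hits)) stop("empty hit list")
  if (length(setdiff(hits, universe))) stop("hits must be a subset of universe")
  hits <- unique(hits); universe <- unique(universe)
  N <- length(universe); n <- length(hits)
  inter <- lapply(gs, intersect, universe)
  excluded <- names(gs)[lengths(inter) == 0]
  keep <- lengths(inter) > 0
  inter <- inter[keep]
  K <- lengths(inter)
  ov <- vapply(inter, function(s) length(intersect(s, hits)), integer(1))
  p <- stats::phyper(ov - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(set = names(inter), set_size = unname(K),
                    overlap = unname(ov), p = unname(p),
                    fdr = stats::p.adjust(unname(p), method = "BH"),
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  out
}

# weighted KS running-sum enrichment score for hit positions in a ranking
running_es <- function(scores, hit, weight = 1) {
  N <- length(scores)
  k <- sum(hit)
  w <- abs(scores)^weight
  denom <- sum(w[hit])
  step <- if (denom > 0) w * hit / denom else hit / k
  res <- cumsum(step - (1 - hit) / (N - k))
  mx <- max(res)
  mn <- min(res)
  # signed maximum deviation; an exact magnitude tie (possible in tiny
  # enumerations) breaks deterministically to the positive extremum
  es <- if (mx + mn >= -1e-12 * max(mx, -mn, 1)) mx else mn
  list(es = es, res = res)
}

#' Pre-ranked gene set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment: walking down the
#' ranking, set members increment the running sum proportionally to
#' `|score|^weight` and non-members decrement it uniformly; the enrichment
#' score (ES) is the signed maximum deviation. The null is built by permuting
#' gene labels (`nperm` draws with a fixed seed, or exhaustively for tiny
#' instances); NES = ES divided by the mean |null ES| of matching sign, and
#' the nominal p is the fraction of same-sign null ES at least as extreme.
#' BH adjustment across sets within the comparison. Sets with fewer than
#' `min_size` members in the ranking, or covering the entire ranking, are
#' excluded and logged in the `"excluded"` attribute.
#'
#' @param ranked data frame `protein`, `score` (any order; sorted internally,
#'   descending score with lexicographic tie-break).
#' @param gs named list of gene sets.
#' @param weight running-sum weight exponent (1 = classic weighted GSEA).
#' @param nperm number of label permutations, or `"exhaustive"` to enumerate
#'   every subset of the ranking of the set's size.
#' @param seed integer seed.
#' @param min_size minimum members present in the ranking.
#' @return `EnrichmentResult` data frame: `set`, `n_overlap`, `ES`, `NES`,
#'   `p`, `fdr`.
#' @export
prerank_gsea <- function(ranked, gs, weight = 1, nperm = 1000, seed = 1L,
                         min_size = 5) {
  stopifnot(all(c("protein", "score") %in% names(ranked)))
  if (!all(is.finite(ranked$score))) stop("scores must be finite")
  ord <- order(-ranked$score, ranked$protein)
  prot <- ranked$protein[ord]
  scr <- ranked$score[ord]
  N <- length(prot)
  overlap <- lapply(gs, function(s) which(prot %in% s))
  sizes <- lengths(overlap)
  excluded <- names(gs)[sizes < min_size | sizes >= N]
  keep <- sizes >= min_size & sizes < N
  rows <- vector("list", sum(keep))
  ki <- 0
  with_seed(seed, {
    for (nm in names(gs)[keep]) {
      k <- sizes[[nm]]
      hit <- logical(N)
      hit[overlap[[nm]]] <- TRUE
      es <- running_es(scr, hit, weight)$es
      if (identical(nperm, "exhaustive")) {
        combs <- utils::combn(N, k)
        null_es <- apply(combs, 2, function(ix) {
          h <- logical(N); h[ix] <- TRUE
          running_es(scr, h, weight)$es
        })
      } else {
        null_es <- vapply(seq_len(nperm), function(b) {
          h <- logical(N); h[sample.int(N, k)] <- TRUE
          running_es(scr, h, weight)$es
        }, numeric(1))
      }
      same <- null_es * sign(es) >= 0
      nes <- if (any(same)) es / mean(abs(null_es[same])) else NA_real_
      # ties counted with a small relative tolerance so the exhaustive mode
      # is robust to summation-order rounding
      tol <- 1e-9 * max(abs(es), 1)
      p <- if (any(same)) mean(abs(null_es[same]) >= abs(es) - tol) else
        1 / (length(null_es) + 1)
      ki <- ki + 1
      rows[[ki]] <- data.frame(set = nm, n_overlap = k, ES = es, NES = nes,
                               p = max(p, .Machine$double.xmin),
                               stringsAsFactors = FALSE)
    }
  })
  out <- if (ki) do.call(rbind, rows) else
    data.frame(set = character(0), n_overlap = integer(0), ES = numeric(0),
               NES = numeric(0), p = numeric(0), stringsAsFactors = FALSE)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Subtype-characteristic gene sets
#'
#' A gene set is characteristic for a subtype when its nominal p is below
#' `p_thr` in all three comparisons of that subtype against the other
#' subtypes and the NES carries the same sign in all three; the direction is
#' that common sign. Filtering deliberately uses the nominal p (adjusted p is
#' carried along in the inputs for reporting).
#'
#' @param results named list of the three `EnrichmentResult` tables for the
#'   subtype's comparisons.
#' @param p_thr nominal p threshold.
#' @return data frame `set`, `direction` (`"up"` / `"down"`).
#' @export
subtype_characteristic <- function(results, p_thr = 0.01) {
  if (length(results) < 2) stop("need the comparisons of the subtype")
  sets <- Reduce(intersect, lapply(results, `[[`, "set"))
  missing_sets <- unique(unlist(lapply(results, function(r)
    setdiff(r$set, sets))))
  pmat <- vapply(results, function(r) r$p[match(sets, r$set)],
                 numeric(length(sets)))
  smat <- vapply(results, function(r) sign(r$NES)[match(sets, r$set)],
                 numeric(length(sets)))
  if (length(sets) == 1) {
    pmat <- matrix(pmat, nrow = 1); smat <- matrix(smat, nrow = 1)
  }
  all_sig <- rowSums(pmat < p_thr) == ncol(pmat)
  same_sign <- abs(rowSums(smat)) == ncol(smat)
  ok <- all_sig & same_sign
  out <- data.frame(set = sets[ok],
                    direction = ifelse(smat[ok, 1] > 0, "up", "down"),
                    stringsAsFactors = FALSE)
  attr(out, "not_in_all_comparisons") <- missing_sets
  out
}

#' Cross-omics concordance of characteristic gene sets
#'
#' A gene set characteristic in one dataset (say proteomics) is supported by
#' `"both"` omics when, in the other dataset's three relevant comparisons,
#' its p-value is below `p_other` and the NES signs all match the
#' characteristic direction; otherwise it stays supported by the calling
#' dataset only.
#'
#' @param calls characteristic calls (data frame `set`, `direction`) from
#'   [subtype_characteristic()] on dataset X.
#' @param other_results named list of the three `EnrichmentResult` tables of
#'   the same comparisons in dataset Y.
#' @param p_other relaxed p threshold applied in dataset Y.
#' @param self_label support label when only dataset X qualifies.
#' @return `calls` with an added `support` column (`"both"` or `self_label`).
#' @export
cross_omics_concordance <- function(calls, other_results, p_other = 0.1,
                                    self_label = "proteomics-only") {
  if (!nrow(calls)) {
    calls$support <- character(0)
    return(calls)
  }
  want <- ifelse(calls$direction == "up", 1, -1)
  supported <- vapply(seq_len(nrow(calls)), function(i) {
    all(vapply(other_results, function(r) {
      j <- match(calls$set[i], r$set)
      !is.na(j) && r$p[j] < p_other && sign(r$NES[j]) == want[i]
    }, logical(1)))
  }, logical(1))
  calls$support <- ifelse(supported, "both", self_label)
  calls
}

#' Single-sample GSEA (rank-normalized, area under the running sum)
#'
#' Per sample, gene expression values are replaced by their within-sample
#' ranks and z-scored; walking down the ranking (highest expression first),
#' set members increment the running enrichment score proportionally to
#' `|z|^weight` and non-members decrement it uniformly. The per-sample
#' statistic is the area under the running sum, normalized against a
#' permutation null of random gene sets of the same size (NES, sign-matched
#' mean as in [prerank_gsea()]). Sets with fewer than `min_overlap` genes in
#' the matrix are excluded and logged. The second returned matrix min-max
#' scales each set's NES across samples onto [0, 1].
#'
#' @param expr non-negative gene-by-sample expression matrix (abundance-like,
#'   e.g. FPKM).
#' @param gs named list of gene sets.
#' @param weight weight exponent on the z-scored ranks.
#' @param min_overlap minimum set genes present in `expr`.
#' @param nperm random gene sets per (size, sample) for the null.
#' @param seed integer seed.
#' @return list with `nes` (set x sample), `scaled` (min-max per set),
#'   `areas` (the unnormalized area statistic) and `excluded`.
#' @export
ssgsea <- function(expr, gs, weight = 0.75, min_overlap = 5, nperm = 1000,
                   seed = 1L) {
  if (any(expr < 0, na.rm = TRUE)) stop("expression must be non-negative")
  genes <- rownames(expr)
  N <- nrow(expr)
  idx_sets <- lapply(gs, function(s) which(genes %in% s))
  sizes <- lengths(idx_sets)
  excluded <- names(gs)[sizes < min_overlap]
  keep <- sizes >= min_overlap & sizes < N
  idx_sets <- idx_sets[keep]
  if (!length(idx_sets)) stop("no gene set passes min_overlap")
  nes <- matrix(NA_real_, length(idx_sets), ncol(expr),
                dimnames = list(names(idx_sets), colnames(expr)))
  areas <- nes
  area <- function(z_ord, hit, k) {
    w <- abs(z_ord)^weight
    denom <- sum(w[hit])
    step <- if (denom > 0) w * hit / denom else hit / k
    sum(cumsum(step - (1 - hit) / (N - k)))
  }
  with_seed(seed, {
    for (j in seq_len(ncol(expr))) {
      r <- rank(expr[, j], ties.method = "average")
      z <- (r - mean(r)) / stats::sd(r)
      ord <- order(-r)
      z_ord <- z[ord]
      pos <- match(seq_len(N), ord)   # gene index -> position in ordering
      null_by_size <- list()
      for (si in seq_along(idx_sets)) {
        k <- length(idx_sets[[si]])
        hit <- logical(N)
        hit[pos[idx_sets[[si]]]] <- TRUE
        a <- area(z_ord, hit, k)
        key <- as.character(k)
        if (is.null(null_by_size[[key]])) {
          null_by_size[[key]] <- vapply(seq_len(nperm), function(b) {
            h <- logical(N); h[sample.int(N, k)] <- TRUE
            area(z_ord, h, k)
          }, numeric(1))
        }
        nulls <- null_by_size[[key]]
        same <- nulls * sign(a) >= 0
        areas[si, j] <- a
        nes[si, j] <- if (any(same)) a / mean(abs(nulls[same])) else NA_real_
      }
    }
  })
  rng <- cbind(matrixStats::rowMins(nes, na.rm = TRUE),
               matrixStats::rowMaxs(nes, na.rm = TRUE))
  scaled <- (nes - rng[, 1]) / ifelse(rng[, 2] > rng[, 1],
                                      rng[, 2] - rng[, 1], 1)
  list(nes = nes, scaled = scaled, areas = areas, excluded = excluded)
}
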