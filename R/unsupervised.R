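#' High-variance protein filter
#'
#' Restricts a matrix to proteins whose across-sample SD exceeds `sd_thr`
#' (strict), without Z-scoring -- absolute variability, not shape, decides
#' what enters the clustering.
#'
#' @param m an imputed `IntensityMatrix`.
#' @param sd_thr SD threshold in log2 units.
#' @return the restricted `IntensityMatrix`.
#' @export
high_variance_filter <- function(m, sd_thr = 1.25) {
  stopifnot(inherits(m, "IntensityMatrix"))
  keep <- row_sds(m$values) > sd_thr
  if (!any(keep))
    stop("no protein exceeds SD ", sd_thr, "; lower the threshold")
  im_update(m, values = m$values[keep, , drop = FALSE],
            mask = m$mask[keep, , drop = FALSE])
}

pearson_dist <- function(x) {
  # columns are samples
  d <- 1 - stats::cor(x, use = "pairwise.complete.obs")
  d[!is.finite(d)] <- 1
  diag(d) <- 0
  stats::as.dist(d)
}

#' Consensus clustering by resampled PAM
#'
#' Samples are repeatedly subsampled (without replacement, inclusion
#' probability `p_item`) together with a random subset of proteins
#' (`p_feature`) and partitioned around medoids (PAM) under the Pearson
#' distance for each candidate K. The consensus matrix entry (i, j) is the
#' fraction of co-subsampled runs in which i and j landed in the same
#' cluster. The final assignment per K cuts a complete-linkage hierarchical
#' clustering of `1 - consensus`. Replicate runs where a K exceeds the
#' subsample size are skipped and counted.
#'
#' @param m an `IntensityMatrix` (typically after [high_variance_filter()]).
#' @param k_range candidate cluster numbers.
#' @param reps number of resampling repetitions.
#' @param p_item,p_feature inclusion probabilities for samples and proteins.
#' @param seed integer seed.
#' @return `ConsensusResult`: list with `consensus` (list of sample x sample
#'   matrices per K), `assignments` (list of named integer vectors per K),
#'   `k_range`, `skipped`.
#' @export
consensus_cluster <- function(m, k_range = 2:7, reps = 1000, p_item = 0.8,
                              p_feature = 0.8, seed = 1L) {
  stopifnot(inherits(m, "IntensityMatrix"))
  vals <- m$values
  n <- ncol(vals)
  if (n < max(k_range) + 1) stop("need more samples than max(k_range)")
  ids <- colnames(vals)
  co_cluster <- lapply(k_range, function(k) matrix(0, n, n))
  names(co_cluster) <- as.character(k_range)
  co_sampled <- matrix(0, n, n)
  skipped <- 0L
  with_seed(seed, {
    for (b in seq_len(reps)) {
      items <- sort(sample.int(n, max(2, round(p_item * n))))
      feats <- sample.int(nrow(vals), max(2, round(p_feature * nrow(vals))))
      co_sampled[items, items] <- co_sampled[items, items] + 1
      d <- pearson_dist(vals[feats, items, drop = FALSE])
      for (k in k_range) {
        if (k >= length(items)) {
          skipped <- skipped + 1L
          next
        }
        cl <- cluster::pam(d, k = k, diss = TRUE, cluster.only = TRUE)
        same <- outer(cl, cl, "==")
        kk <- as.character(k)
        co_cluster[[kk]][items, items] <- co_cluster[[kk]][items, items] + same
      }
    }
  })
  consensus <- lapply(co_cluster, function(cc) {
    cm <- ifelse(co_sampled > 0, cc / co_sampled, 0)
    diag(cm) <- 1
    cm <- (cm + t(cm)) / 2
    dimnames(cm) <- list(ids, ids)
    cm
  })
  assignments <- lapply(seq_along(k_range), function(i) {
    cm <- consensus[[i]]
    hc <- stats::hclust(stats::as.dist(1 - cm), method = "complete")
    stats::setNames(stats::cutree(hc, k = k_range[i]), ids)
  })
  names(assignments) <- as.character(k_range)
  structure(list(consensus = consensus, assignments = assignments,
                 k_range = k_range, skipped = skipped),
            class = "ConsensusResult")
}

#' Select K by average silhouette width on the consensus dissimilarity
#'
#' Silhouette widths are computed on `1 - consensus` as the dissimilarity for
#' each candidate K's assignment; the K with the largest average silhouette
#' width wins, ties going to the smaller K. Singleton clusters contribute a
#' silhouette of 0 (the `cluster` package convention) and are flagged.
#'
#' @param cr a `ConsensusResult`.
#' @return list with `k` (selected), `table` (K, avg_sil, n_singleton).
#' @export
select_k <- function(cr) {
  stopifnot(inherits(cr, "ConsensusResult"))
  if (length(cr$k_range) < 2) stop("need at least 2 candidate K")
  rows <- lapply(seq_along(cr$k_range), function(i) {
    k <- cr$k_range[i]
    cl <- cr$assignments[[as.character(k)]]
    d <- stats::as.dist(1 - cr$consensus[[as.character(k)]])
    sil <- cluster::silhouette(cl, d)
    data.frame(K = k, avg_sil = mean(sil[, "sil_width"]),
               n_singleton = sum(table(cl) == 1))
  })
  tab <- do.call(rbind, rows)
  best <- tab$K[which.max(tab$avg_sil)]  # which.max takes the first: smaller K
  list(k = best, table = tab)
}

#' Principal variance component analysis (PVCA)
#'
#' Attributes expression variance to annotated factors: PCA on the Z-scored
#' matrix, leading PCs retained until their cumulative explained variance
#' reaches `var_explained_stop`; each retained PC is regressed on all factors
#' jointly and its variance partitioned by sequential sums of squares
#' (eta-squared) plus residual; per-PC fractions are weighted by the PC's
#' eigenvalue share and normalized to sum to one.
#'
#' @param m an `IntensityMatrix` (Z-scored internally per protein).
#' @param ann annotation for the columns of `m`.
#' @param factors names of categorical annotation columns to attribute.
#' @param var_explained_stop cumulative explained-variance threshold.
#' @return named numeric vector of variance fractions (factors + residual),
#'   summing to 1.
#' @export
pvca <- function(m, ann, factors = c("subtype", "culture_type"),
                 var_explained_stop = 0.6) {
  stopifnot(inherits(m, "IntensityMatrix"))
  key_col <- intersect(c("measurement_id", "vial_id", "cell_line"),
                       names(ann))[1]
  ann <- ann[match(colnames(m$values), ann[[key_col]]), , drop = FALSE]
  facs <- lapply(factors, function(f) {
    v <- ann[[f]]
    if (is.null(v)) stop("unknown factor: ", f)
    if (anyNA(v)) stop("missing labels in factor ", f)
    factor(v)
  })
  names(facs) <- factors
  # confounded factors carry identical sample partitions -> unidentifiable
  if (length(facs) > 1) {
    for (i in seq_len(length(facs) - 1)) {
      for (j in seq(i + 1, length(facs))) {
        ti <- as.integer(facs[[i]]); tj <- as.integer(facs[[j]])
        if (nlevels(facs[[i]]) == nlevels(facs[[j]]) &&
            all(tapply(tj, ti, function(x) length(unique(x))) == 1))
          stop("confounded factors: ", factors[i], " and ", factors[j])
      }
    }
  }
  z <- t(scale(t(m$values)))
  z <- z[stats::complete.cases(z), , drop = FALSE]
  pc <- stats::prcomp(t(z), center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  share <- ev / sum(ev)
  n_keep <- which(cumsum(share) >= var_explained_stop)[1]
  if (is.na(n_keep)) n_keep <- length(share)
  dat <- as.data.frame(facs)
  fml <- stats::as.formula(paste("y ~", paste(factors, collapse = " + ")))
  parts <- matrix(0, n_keep, length(factors) + 1,
                  dimnames = list(NULL, c(factors, "residual")))
  for (i in seq_len(n_keep)) {
    dat$y <- pc$x[, i]
    av <- stats::anova(stats::lm(fml, data = dat))
    ss <- av[["Sum Sq"]]
    labs <- rownames(av)
    total <- sum(ss)
    # a factor fully aliased by earlier ones has no ANOVA row: attribute 0
    for (f in factors) parts[i, f] <-
      if (any(labs == f)) ss[labs == f] / total else 0
    parts[i, "residual"] <- ss[labs == "Residuals"] / total
  }
  w <- share[seq_len(n_keep)] / sum(share[seq_len(n_keep)])
  frac <- colSums(parts * w)
  frac / sum(frac)
}
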