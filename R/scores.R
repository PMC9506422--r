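#' Marker signature
#'
#' A signature is a pair of disjoint marker sets: a positive set whose mean
#' Z-score is added (neuroendocrine markers for the NE score, mesenchymal
#' markers for the EMT score) and a negative set whose mean Z-score is
#' subtracted (non-NE markers, epithelial markers).
#'
#' @param name signature name.
#' @param positive_set,negative_set character vectors of protein/gene ids.
#' @return object of class `MarkerSignature`.
#' @export
marker_signature <- function(name, positive_set, negative_set) {
  if (!length(positive_set) || !length(negative_set))
    stop("both marker sets must be non-empty")
  if (length(intersect(positive_set, negative_set)))
    stop("positive and negative sets must be disjoint")
  structure(list(name = name, positive_set = unique(positive_set),
                 negative_set = unique(negative_set)),
            class = "MarkerSignature")
}

#' Read a marker signature from JSON
#'
#' Expects an object with fields `name`, `positive_set`, `negative_set`.
#' @param path JSON file path.
#' @return a [marker_signature()].
#' @export
read_signature_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  marker_signature(x$name, x$positive_set, x$negative_set)
}

#' @rdname read_signature_json
#' @param sig signature to serialize.
#' @export
write_signature_json <- function(sig, path) {
  jsonlite::write_json(unclass(sig), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Per-sample signature score
#'
#' Each quantified marker is Z-scored across samples (mean 0, sample SD with
#' the n-1 convention); the score of a sample is the mean Z over quantified
#' positive markers minus the mean Z over quantified negative markers. The NE
#' score uses NE vs non-NE markers, the EMT score mesenchymal vs epithelial
#' markers. Markers absent from the matrix, or with zero across-sample SD,
#' are dropped and counted. Because Z-scoring is per protein across samples,
#' scores are invariant to adding a constant to a protein row but NOT to
#' shifting a single sample column -- sample-level normalization must happen
#' upstream.
#'
#' @param m an imputed (complete) log2 `IntensityMatrix`.
#' @param sig a [marker_signature()].
#' @return data frame with `sample`, `score`, plus attributes
#'   `n_positive_used` / `n_negative_used`.
#' @export
signature_score <- function(m, sig) {
  stopifnot(inherits(m, "IntensityMatrix"), inherits(sig, "MarkerSignature"))
  vals <- m$values
  usable <- function(ids, label) {
    ids <- intersect(ids, rownames(vals))
    if (length(ids)) {
      sds <- row_sds(vals[ids, , drop = FALSE])
      ids <- ids[sds > 0]
    }
    if (!length(ids))
      stop("no quantified marker with non-zero variance in the ", label,
           " set of signature '", sig$name, "'")
    ids
  }
  pos <- usable(sig$positive_set, "positive")
  neg <- usable(sig$negative_set, "negative")
  zrow <- function(ids) {
    x <- vals[ids, , drop = FALSE]
    colMeans((x - rowMeans(x)) / row_sds(x))
  }
  score <- zrow(pos) - zrow(neg)
  out <- data.frame(sample = colnames(vals), score = as.numeric(score),
                    stringsAsFactors = FALSE)
  attr(out, "n_positive_used") <- length(pos)
  attr(out, "n_negative_used") <- length(neg)
  attr(out, "signature") <- sig$name
  out
}

#' Association between two score tables
#'
#' Pearson correlation (with the two-sided t-distribution p-value) between
#' two per-sample scores over their shared samples, e.g. the NE and EMT
#' scores of the same cell lines.
#'
#' @param a,b score tables from [signature_score()].
#' @return list with `r`, `p`, `n`.
#' @export
score_association <- function(a, b) {
  common <- intersect(a$sample, b$sample)
  if (length(common) < 3) stop("need at least 3 shared samples")
  x <- a$score[match(common, a$sample)]
  y <- b$score[match(common, b$sample)]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in a score table")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(common))
}

#' Marker signatures implied by a synthetic truth
#'
#' Convenience constructor turning the marker blocks planted by
#' [generate_dataset()] into the NE and EMT signatures used for scoring.
#'
#' @param truth a `SyntheticTruth`.
#' @return list with elements `ne` and `emt` ([marker_signature()] objects).
#' @export
truth_signatures <- function(truth) {
  mm <- truth$marker_membership
  pick <- function(b) mm$protein[mm$block == b]
  list(ne = marker_signature("NE", pick("NE"), pick("nonNE")),
       emt = marker_signature("EMT", pick("mes"), pick("epi")))
}
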