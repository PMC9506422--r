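#' Fit a sparse PLS discriminant analysis model
#'
#' PLS-DA with per-component hard feature selection: class labels are
#' dummy-coded, and for each component the PLS weight vector (dominant left
#' singular vector of `X'Y` on the deflated data) is sparsified by
#' soft-thresholding at the (keepX+1)-th largest |weight| -- retaining the
#' `keepX` largest-magnitude features and setting the rest exactly to zero --
#' then renormalized. Scores are `X w`; X is deflated by regression on the
#' score after every component (Y is left alone, a convention that keeps the
#' Y space stable). Class centroids live in the latent score space. The fit
#' is fully deterministic.
#'
#' @param X complete sample-by-feature numeric matrix (post-imputation);
#'   columns are standardized internally.
#' @param y class labels (e.g. subtype), one per row of `X`.
#' @param n_components number of latent components.
#' @param keepX integer vector (length `n_components`) of features to keep
#'   per component.
#' @return `SPLSDAModel`: weights, X-loadings, scores, centroids, selected
#'   features per component, standardization parameters.
#' @export
fit_splsda <- function(X, y, n_components, keepX) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X must be complete (impute first)")
  y <- factor(y)
  if (length(keepX) != n_components)
    stop("keepX must have length n_components")
  if (any(keepX > ncol(X))) stop("keepX exceeds the number of features")
  if (nlevels(y) < 2) stop("need at least 2 classes")
  if (any(table(y) < 2)) stop("every class needs at least 2 samples")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))

  ctr <- colMeans(X)
  scl <- matrixStats::colSds(X)
  scl[scl == 0] <- 1
  Xc <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
  Y <- stats::model.matrix(~ y - 1)
  Yc <- sweep(Y, 2, colMeans(Y), "-")

  p <- ncol(Xc)
  weights <- x_loads <- vector("list", n_components)
  scores <- matrix(0, nrow(Xc), n_components,
                   dimnames = list(rownames(X), paste0("comp", seq_len(n_components))))
  selected <- vector("list", n_components)
  Xd <- Xc
  for (h in seq_len(n_components)) {
    M <- crossprod(Xd, Yc)
    w <- svd(M, nu = 1, nv = 0)$u[, 1]
    if (keepX[h] < p) {
      a <- abs(w)
      thr <- sort(a, decreasing = TRUE)[keepX[h] + 1]
      w <- sign(w) * pmax(a - thr, 0)
    }
    if (all(w == 0)) stop("degenerate component ", h, ": all weights zero")
    w <- w / sqrt(sum(w^2))
    names(w) <- colnames(X)
    t_h <- drop(Xd %*% w)
    p_h <- drop(crossprod(Xd, t_h)) / sum(t_h^2)
    Xd <- Xd - tcrossprod(t_h, p_h)
    weights[[h]] <- w
    x_loads[[h]] <- p_h
    scores[, h] <- t_h
    selected[[h]] <- names(w)[w != 0]
  }
  classes <- levels(y)
  centroids <- do.call(rbind, lapply(classes, function(cl) {
    colMeans(scores[y == cl, , drop = FALSE])
  }))
  rownames(centroids) <- classes
  structure(list(weights = weights, x_loadings = x_loads, scores = scores,
                 centroids = centroids, classes = classes, y = y,
                 keepX = keepX, n_components = n_components,
                 selected = selected, center = ctr, scale = scl),
            class = "SPLSDAModel")
}

splsda_project <- function(model, X_new) {
  X_new <- as.matrix(X_new)
  if (!identical(colnames(X_new), names(model$center)))
    X_new <- X_new[, names(model$center), drop = FALSE]
  Xd <- sweep(sweep(X_new, 2, model$center, "-"), 2, model$scale, "/")
  T_new <- matrix(0, nrow(Xd), model$n_components)
  for (h in seq_len(model$n_components)) {
    t_h <- drop(Xd %*% model$weights[[h]])
    Xd <- Xd - tcrossprod(t_h, model$x_loadings[[h]])
    T_new[, h] <- t_h
  }
  rownames(T_new) <- rownames(X_new)
  T_new
}

#' Balanced error rate
#'
#' Mean over classes of the per-class misclassification rate; equals the
#' plain error rate when classes are balanced.
#'
#' @param predicted,truth label vectors.
#' @return numeric in [0, 1].
#' @export
balanced_error_rate <- function(predicted, truth) {
  truth <- factor(truth)
  per_class <- vapply(levels(truth), function(cl) {
    mean(predicted[truth == cl] != cl)
  }, numeric(1))
  mean(per_class)
}

#' Classify new samples by centroid distance
#'
#' Projects new samples into the model's latent space (same deflation chain
#' as training) and assigns each to the nearest class centroid (Euclidean).
#' Exact ties break deterministically to the lexicographically first class
#' and are flagged.
#'
#' @param model an `SPLSDAModel`.
#' @param X_new sample-by-feature matrix over the training feature space.
#' @param truth optional true labels; when given, the balanced error rate is
#'   returned too.
#' @return list with `predicted`, `tied` (logical), and `ber` if `truth`
#'   given.
#' @export
classify_centroid <- function(model, X_new, truth = NULL) {
  T_new <- splsda_project(model, X_new)
  cent <- model$centroids[sort(rownames(model$centroids)), , drop = FALSE]
  d2 <- vapply(rownames(cent), function(cl) {
    rowSums(sweep(T_new, 2, cent[cl, ], "-")^2)
  }, numeric(nrow(T_new)))
  if (nrow(T_new) == 1) d2 <- matrix(d2, nrow = 1,
                                     dimnames = list(NULL, rownames(cent)))
  pick <- apply(d2, 1, which.min)     # first minimum = lexicographic winner
  tied <- apply(d2, 1, function(r) sum(r == min(r)) > 1)
  pred <- colnames(d2)[pick]
  out <- list(predicted = pred, tied = tied)
  if (!is.null(truth)) out$ber <- balanced_error_rate(pred, truth)
  out
}

stratified_folds <- function(y, folds) {
  y <- factor(y)
  if (any(table(y) < folds)) stop("a class is smaller than the fold count")
  fold_id <- integer(length(y))
  for (cl in levels(y)) {
    ix <- sample(which(y == cl))
    fold_id[ix] <- rep_len(seq_len(folds), length(ix))
  }
  fold_id
}

#' Tune a sparse PLS-DA model by repeated stratified cross-validation
#'
#' Components are tuned sequentially: for each component, every candidate
#' `keepX` is evaluated by stratified K-fold cross-validation (repeated with
#' fresh seeded shuffles), keeping the previously chosen keepX values fixed,
#' and the candidate with the lowest mean balanced error rate wins (ties go
#' to fewer features). The number of components is then chosen as the one
#' minimizing the mean BER (ties to fewer components). Feature stability is
#' the fraction of all fold-fits of the chosen setting in which a feature was
#' selected on any component.
#'
#' @param X,y as in [fit_splsda()].
#' @param max_components components to explore.
#' @param keepX_grid candidate keepX values (shared across components).
#' @param folds,repeats cross-validation geometry.
#' @param seed integer seed.
#' @return `TuningResult`: `grid` (component, keepX, ber), `choice`
#'   (`n_components`, `keepX`, `ber`), `stability` (named, sorted
#'   decreasing), `ber_by_ncomp`.
#' @export
tune_splsda <- function(X, y, max_components = 3, keepX_grid = c(5, 10, 25),
                        folds = 3, repeats = 50, seed = 1L) {
  X <- as.matrix(X)
  y <- factor(y)
  if (folds < 2) stop("folds must be >= 2")
  if (any(table(y) < folds)) stop("a class is smaller than the fold count")

  cv_ber <- function(keepx_vec) {
    h <- length(keepx_vec)
    errs <- numeric(0)
    for (rep_i in seq_len(repeats)) {
      fold_id <- stratified_folds(y, folds)
      for (f in seq_len(folds)) {
        tr <- fold_id != f
        fit <- fit_splsda(X[tr, , drop = FALSE], y[tr], h, keepx_vec)
        res <- classify_centroid(fit, X[!tr, , drop = FALSE], y[!tr])
        errs <- c(errs, res$ber)
      }
    }
    mean(errs)
  }

  grid <- NULL
  chosen <- integer(0)
  ber_by_ncomp <- numeric(max_components)
  with_seed(seed, {
    for (h in seq_len(max_components)) {
      cand_ber <- vapply(keepX_grid, function(kx) cv_ber(c(chosen, kx)),
                         numeric(1))
      grid <- rbind(grid, data.frame(component = h, keepX = keepX_grid,
                                     ber = cand_ber))
      ord <- order(cand_ber, keepX_grid)
      chosen <- c(chosen, keepX_grid[ord[1]])
      ber_by_ncomp[h] <- cand_ber[ord[1]]
    }
    n_comp <- order(ber_by_ncomp, seq_len(max_components))[1]
    # stability pass at the chosen setting
    sel_count <- stats::setNames(numeric(ncol(X)), colnames(X))
    n_fits <- 0L
    for (rep_i in seq_len(repeats)) {
      fold_id <- stratified_folds(y, folds)
      for (f in seq_len(folds)) {
        fit <- fit_splsda(X[fold_id != f, , drop = FALSE], y[fold_id != f],
                          n_comp, chosen[seq_len(n_comp)])
        feats <- unique(unlist(fit$selected))
        sel_count[feats] <- sel_count[feats] + 1
        n_fits <- n_fits + 1L
      }
    }
    stability <- sort(sel_count / n_fits, decreasing = TRUE)
    result <- list(grid = grid,
                    choice = list(n_components = n_comp,
                                  keepX = chosen[seq_len(n_comp)],
                                  ber = ber_by_ncomp[n_comp]),
                    ber_by_ncomp = ber_by_ncomp,
                    stability = stability)
  })
  structure(result, class = "TuningResult")
}
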