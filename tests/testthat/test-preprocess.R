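raw_toy <- function(vals) {
  dimnames(vals) <- list(sprintf("P%02d", seq_len(nrow(vals))),
                         sprintf("S%02d", seq_len(ncol(vals))))
  intensity_matrix(vals, scale = "raw-linear", stage = "raw")
}

test_that("median normalization centres columns and is idempotent", {
  # 2x2 toy: log2 values [[2,4],[4,6]]; all column medians must agree
  m <- log2_median_normalize(raw_toy(matrix(c(4, 16, 16, 64), 2)))
  expect_equal(unname(diff(matrixStats::colMedians(m$values))), 0)
  # scaling one raw column by 8: the log2 shift of 3 is removed from that
  # column; only a constant matrix-wide offset (the global-median update)
  # can remain
  set.seed(1)
  vals <- matrix(2^rnorm(60, 20), 10)
  m1 <- log2_median_normalize(raw_toy(vals))
  vals2 <- vals
  vals2[, 3] <- vals2[, 3] * 8
  m2 <- log2_median_normalize(raw_toy(vals2))
  delta <- m2$values - m1$values
  expect_lt(max(delta) - min(delta), 1e-12)
  expect_lt(abs(delta[1, 1]), 1)
  # a column already at the global median is unchanged
  expect_equal(m1$values, log2_median_normalize(m1)$values,
               tolerance = 1e-12)
  # non-positive observed values are named in the error
  bad <- vals
  bad[2, 3] <- -1
  expect_error(log2_median_normalize(raw_toy(bad)), "P02.*S03")
})

test_that("replicate aggregation: median over tech, mean over vials", {
  vals <- matrix(2, nrow = 2, ncol = 6)
  # cell line CL1: vial 1 tech (1,3) -> 2 ; vial 2 tech (3,5) -> 4 ; mean 3
  vals[1, ] <- c(1, 3, 3, 5, 7, 7)
  dimnames(vals) <- list(c("Pa", "Pb"),
                         c("m1", "m2", "m3", "m4", "m5", "m6"))
  ann <- data.frame(
    measurement_id = colnames(vals),
    cell_line = c("CL1", "CL1", "CL1", "CL1", "CL2", "CL2"),
    subtype = "A", batch = c("B1", "B1", "B2", "B2", "B1", "B1"),
    culture_type = "adherent", bio_rep = 1,
    tech_rep = c(1, 2, 1, 2, 1, 2), stringsAsFactors = FALSE)
  m <- intensity_matrix(vals, scale = "log2", stage = "normalized")
  agg <- aggregate_replicates(m, ann)
  expect_equal(agg$values["Pa", "CL1"], 3)
  expect_equal(agg$values["Pa", "CL2"], 7)
  # single measurement per cell line is the identity
  one <- intensity_matrix(vals[, c(1, 5), drop = FALSE], scale = "log2",
                          stage = "normalized")
  agg1 <- aggregate_replicates(one, ann[c(1, 5), ])
  expect_equal(unname(agg1$values), unname(vals[, c(1, 5)]))
  # NA-aware: one vial fully missing -> mean of the observed vial only
  vals_na <- vals
  vals_na[1, 3:4] <- NA
  mna <- intensity_matrix(vals_na, scale = "log2", stage = "normalized")
  aggna <- aggregate_replicates(mna, ann)
  expect_equal(aggna$values["Pa", "CL1"], 2)
  expect_equal(aggna$mask["Pa", "CL1"], "observed")
  # annotation without replicate columns is rejected
  expect_error(aggregate_replicates(m, ann[, c("measurement_id", "subtype")]),
               "replicate columns")
})

test_that("valid-value filter applies the exact fraction rule", {
  vals <- matrix(rnorm(3 * 26, 20), nrow = 3)
  dimnames(vals) <- list(c("keep", "drop", "gone"), sprintf("S%02d", 1:26))
  vals["keep", 1:5] <- NA    # 21/26 = 0.8077 observed
  vals["drop", 1:6] <- NA    # 20/26 = 0.7692
  vals["gone", ] <- NA
  m <- intensity_matrix(vals, scale = "log2", stage = "aggregated")
  f <- filter_valid(m, 0.8)
  expect_identical(rownames(f$values), "keep")
  expect_error(filter_valid(m, 0), "min_frac")
  expect_error(filter_valid(m, 1.2), "min_frac")
})

test_that("batch regression removes a pure shift and honours exclusions", {
  set.seed(2)
  base <- matrix(rnorm(5 * 8, 20), 5)
  dimnames(base) <- list(sprintf("P%d", 1:5), sprintf("S%d", 1:8))
  batch <- rep(c("B1", "B2"), each = 4)
  shifted <- base
  shifted[, batch == "B2"] <- shifted[, batch == "B2"] + 1.5
  ann <- data.frame(measurement_id = colnames(base), batch = batch)
  m <- intensity_matrix(shifted, scale = "log2", stage = "aggregated")
  corr <- correct_batch(m, ann)
  # equal n: de-shifted values restored up to the protein's half-shift recentre
  b1 <- rowMeans(corr$values[, batch == "B1"])
  b2 <- rowMeans(corr$values[, batch == "B2"])
  expect_equal(b1, b2, tolerance = 1e-12)
  # closed form: value - own-batch mean + grand mean of the protein
  want <- t(vapply(seq_len(5), function(i) {
    bm <- tapply(shifted[i, ], batch, mean)
    shifted[i, ] - bm[batch] + mean(shifted[i, ])
  }, numeric(8)))
  expect_equal(unname(corr$values), unname(want), tolerance = 1e-12)
  # protein observed in only one batch stays untouched and flagged
  holed <- shifted
  holed[1, batch == "B2"] <- NA
  m2 <- intensity_matrix(holed, scale = "log2", stage = "aggregated")
  corr2 <- correct_batch(m2, ann)
  expect_equal(corr2$values[1, batch == "B1"], holed[1, batch == "B1"])
  expect_identical(attr(corr2, "uncorrected"), "P1")
  # single batch: unchanged
  ann1 <- ann; ann1$batch <- "B1"
  expect_equal(correct_batch(m, ann1)$values, m$values)
})

test_that("planted batch shift is annihilated on synthetic data", {
  cfg <- small_config(batch_shift = 1.0, seed = 11)
  ds <- generate_dataset(cfg)
  norm <- log2_median_normalize(ds$matrix)
  vial <- aggregate_replicates(norm, ds$annotation, level = "vial")
  corr <- correct_batch(vial$matrix, vial$annotation)
  batch <- vial$annotation$batch
  coefs <- rowMeans(corr$values[, batch == "B2"]) -
    rowMeans(corr$values[, batch == "B1"])
  expect_lte(mean(abs(coefs)), 1e-10)
})

test_that("imputation draws from the down-shifted normal, reproducibly", {
  set.seed(3)
  vals <- matrix(rnorm(2000, 20, 2), ncol = 2)
  dimnames(vals) <- list(sprintf("P%04d", seq_len(nrow(vals))), c("S1", "S2"))
  m0 <- intensity_matrix(vals, scale = "log2", stage = "filtered")
  expect_equal(impute_normal(m0, seed = 1)$values, vals)   # nothing to do
  vals[1:400, 1] <- NA
  m <- intensity_matrix(vals, scale = "log2", stage = "filtered")
  imp <- impute_normal(m, seed = 1)
  expect_false(anyNA(imp$values))
  expect_identical(sum(imp$mask == "imputed"), 400L)
  mu <- mean(vals[-(1:400), 1]); sg <- sd(vals[-(1:400), 1])
  ks <- stats::ks.test(imp$values[1:400, 1], "pnorm", mu - 1.8 * sg,
                       0.3 * sg)
  expect_gt(ks$p.value, 0.01)
  expect_identical(imp$values, impute_normal(m, seed = 1)$values)
  expect_false(identical(imp$values, impute_normal(m, seed = 2)$values))
  # a column with <2 observed values cannot provide mu/sigma
  vals[, 2] <- NA
  vals[1, 2] <- 20
  expect_error(impute_normal(intensity_matrix(vals, scale = "log2",
                                              stage = "filtered"), seed = 1),
               "fewer than 2 observed")
})

test_that("on/off detection matches the threshold rule and the oracle", {
  subtype <- rep(c("A", "N", "P", "Y"), c(8, 7, 4, 7))
  n <- length(subtype)
  mk <- function(present) {
    vals <- matrix(20, nrow = length(present) / n, ncol = n)
    vals[!present] <- NA
    dimnames(vals) <- list(sprintf("P%02d", seq_len(nrow(vals))),
                           sprintf("CL%02d", seq_len(n)))
    intensity_matrix(vals, scale = "log2", stage = "filtered")
  }
  ann <- data.frame(cell_line = sprintf("CL%02d", seq_len(n)),
                    subtype = subtype, stringsAsFactors = FALSE)
  # worked example: 7/8 in A, 1/7 in N, 0/4 in P, 1/7 in Y -> 'on' in A
  pres <- c(rep(TRUE, 7), FALSE, TRUE, rep(FALSE, 6), rep(FALSE, 4),
            TRUE, rep(FALSE, 6))
  calls <- detect_on_off(mk(rbind(pres, pres)), ann)
  expect_equal(unique(calls$subtype), "A")
  expect_equal(unique(calls$direction), "on")
  # everywhere-present and everywhere-absent proteins yield no call
  allp <- rep(TRUE, n)
  expect_equal(nrow(detect_on_off(mk(rbind(allp, allp)), ann)), 0)
  # random fixtures against the brute-force oracle
  set.seed(4)
  for (rep_i in 1:10) {
    pr <- matrix(runif(20 * n) < 0.5, nrow = 20)
    rownames(pr) <- sprintf("P%02d", 1:20)
    m <- mk(pr)
    got <- detect_on_off(m, ann)
    want <- onoff_brute(im_observed(m), subtype)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got[, c("protein", "subtype", "direction")],
                   want[order(want$subtype, want$direction, want$protein), ],
                   ignore_attr = TRUE)
    }
  }
})
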