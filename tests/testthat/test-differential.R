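# independent oracle: stats::aov + TukeyHSD on one protein at a time
aov_oracle <- function(x, g) {
  df <- data.frame(x = x, g = factor(g))
  fit <- stats::aov(x ~ g, data = df)
  av <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  list(F = av[1, "F value"], p = av[1, "Pr(>F)"], tukey = tk)
}

test_that("ANOVA F and Tukey p match the stats::aov/TukeyHSD oracle", {
  g <- rep(c("A", "B", "C", "D"), each = 3)
  fixed <- c(1, 2, 3, 2, 3, 4, 5, 6, 7, 5, 6, 8)
  set.seed(5)
  vals <- rbind(fixed, matrix(rnorm(5 * 12, 20), 5))
  rownames(vals) <- sprintf("P%d", 1:6)
  colnames(vals) <- sprintf("S%d", 1:12)
  m <- intensity_matrix(vals, scale = "log2", stage = "imputed")
  r <- anova_tukey(m, g)
  for (i in 1:6) {
    o <- aov_oracle(vals[i, ], g)
    expect_equal(r$anova$anova_p[i], o$p, tolerance = 1e-10)
    for (pr in rownames(o$tukey)) {
      gs <- rev(strsplit(pr, "-")[[1]])  # TukeyHSD reports "B-A" = B - A
      row <- r$pairs[r$pairs$protein == rownames(vals)[i] &
                       r$pairs$group1 == gs[1] & r$pairs$group2 == gs[2], ]
      expect_equal(row$mean_diff, -unname(o$tukey[pr, "diff"]),
                   tolerance = 1e-10)
      expect_equal(row$tukey_p, unname(o$tukey[pr, "p adj"]),
                   tolerance = 1e-8)
    }
  }
  expect_true(all(r$anova$anova_fdr >= r$anova$anova_p))
})

test_that("degenerate proteins keep p = 1 with a flag", {
  vals <- rbind(rep(20, 12), rnorm(12, 20))
  rownames(vals) <- c("flat", "ok"); colnames(vals) <- sprintf("S%d", 1:12)
  m <- intensity_matrix(vals, scale = "log2", stage = "imputed")
  r <- anova_tukey(m, rep(c("A", "B", "C", "D"), each = 3))
  expect_true(r$anova$degenerate[1])
  expect_equal(r$anova$anova_p[1], 1)
  expect_equal(unique(r$pairs$tukey_p[r$pairs$protein == "flat"]), 1)
  expect_false(r$anova$degenerate[2])
})

test_that("two groups: Tukey p equals the pooled two-sided t-test p", {
  set.seed(6)
  vals <- matrix(rnorm(3 * 10, 20), 3)
  rownames(vals) <- sprintf("P%d", 1:3); colnames(vals) <- sprintf("S%d", 1:10)
  m <- intensity_matrix(vals, scale = "log2", stage = "imputed")
  g <- rep(c("adherent", "suspension"), each = 5)
  r <- anova_tukey(m, g)
  for (i in 1:3) {
    tt <- stats::t.test(vals[i, g == "adherent"], vals[i, g == "suspension"],
                        var.equal = TRUE)
    row <- r$pairs[r$pairs$protein == rownames(vals)[i], ]
    expect_equal(row$tukey_p, tt$p.value, tolerance = 1e-6)
  }
})

test_that("Tukey p never undercuts the unadjusted pairwise t-test p", {
  set.seed(7)
  vals <- matrix(rnorm(20 * 12, 20), 20)
  rownames(vals) <- sprintf("P%d", 1:20)
  colnames(vals) <- sprintf("S%d", 1:12)
  g <- rep(c("A", "B", "C", "D"), each = 3)
  m <- intensity_matrix(vals, scale = "log2", stage = "imputed")
  r <- anova_tukey(m, g)
  # pooled-variance pairwise t on the same s2p
  s2p <- vapply(seq_len(20), function(i) {
    sum(tapply(vals[i, ], g, function(x) sum((x - mean(x))^2))) / (12 - 4)
  }, numeric(1))
  for (i in c(1, 7, 13)) {
    rows <- r$pairs[r$pairs$protein == rownames(vals)[i], ]
    for (j in seq_len(nrow(rows))) {
      tstat <- abs(rows$mean_diff[j]) / sqrt(s2p[i] * (2 / 3))
      pt2 <- 2 * stats::pt(-tstat, 8)
      expect_gte(rows$tukey_p[j] + 1e-12, pt2)
    }
  }
})

test_that("selection rules match brute-force filters", {
  set.seed(8)
  g <- rep(c("A", "B", "C", "D"), each = 4)
  vals <- matrix(rnorm(10 * 16, 20), 10)
  vals[1, g == "A"] <- vals[1, g == "A"] + 4
  rownames(vals) <- sprintf("P%02d", 1:10)
  colnames(vals) <- sprintf("S%02d", 1:16)
  m <- intensity_matrix(vals, scale = "log2", stage = "imputed")
  r <- anova_tukey(m, g)
  got <- significant_proteins(r, "A_vs_B")
  fd <- r$anova$anova_fdr[match(r$pairs$protein, r$anova$protein)]
  want <- unique(r$pairs$protein[r$pairs$pair == "A_vs_B" &
                                   fd < 0.05 & r$pairs$tukey_p < 0.05])
  expect_setequal(got, want)
  expect_error(significant_proteins(r, "A_vs_Z"), "unknown pair")
  # reversed pair order flips the sign but selects the same proteins
  expect_setequal(significant_proteins(r, "B_vs_A"), want)

  spec <- subtype_specific(r, "A")
  expect_true("P01" %in% spec$protein)
  expect_equal(spec$direction[spec$protein == "P01"], "up")
})

test_that("type-I error is controlled on null data", {
  set.seed(9)
  vals <- matrix(rnorm(5000 * 26, 20), 5000)
  rownames(vals) <- sprintf("P%04d", 1:5000)
  colnames(vals) <- sprintf("S%02d", 1:26)
  m <- intensity_matrix(vals, scale = "log2", stage = "imputed")
  r <- anova_tukey(m, rep(c("A", "N", "P", "Y"), c(8, 7, 4, 7)))
  expect_lte(mean(r$anova$anova_fdr < 0.05), 0.05)
})

test_that("rank metric is FC times -log10(p), deterministic and shift-safe", {
  pairs <- data.frame(protein = c("Pa", "Pb", "Pc", "Pd"),
                      pair = "A_vs_N", group1 = "A", group2 = "N",
                      mean_diff = c(2, -1, 0.5, 0.5),
                      tukey_p = c(0.01, 0.1, 1, 1),
                      stringsAsFactors = FALSE)
  r <- structure(list(anova = data.frame(protein = pairs$protein,
                                         anova_p = 0.01, anova_fdr = 0.02,
                                         degenerate = FALSE),
                      pairs = pairs, groups = c("A", "N")),
                 class = "DEResult")
  rk <- rank_metric(r, "A_vs_N")
  expect_equal(rk$score[rk$protein == "Pa"], 4)
  expect_equal(rk$score[rk$protein == "Pb"], -1)
  expect_equal(rk$score[rk$protein == "Pc"], 0)
  # tie between Pc and Pd broken lexicographically
  expect_identical(rk$protein, c("Pa", "Pc", "Pd", "Pb"))
  # p = 0 floored and flagged
  pairs$tukey_p[1] <- 0
  r$pairs <- pairs
  rk0 <- rank_metric(r, "A_vs_N")
  expect_identical(attr(rk0, "floored"), "Pa")
  expect_true(is.finite(rk0$score[rk0$protein == "Pa"]))
  # ordering invariant to a constant shift of both groups
  set.seed(10)
  vals <- matrix(rnorm(30 * 8, 20), 30)
  rownames(vals) <- sprintf("P%02d", 1:30)
  colnames(vals) <- sprintf("S%d", 1:8)
  g <- rep(c("A", "N"), each = 4)
  m1 <- intensity_matrix(vals, scale = "log2", stage = "imputed")
  m2 <- intensity_matrix(vals + 3, scale = "log2", stage = "imputed")
  rk1 <- rank_metric(anova_tukey(m1, g), "A_vs_N")
  rk2 <- rank_metric(anova_tukey(m2, g), "A_vs_N")
  expect_identical(rk1$protein, rk2$protein)
})

test_that("culture grouping handles semi-adherent lines per config", {
  ann <- data.frame(culture_type = c("adherent", "suspension",
                                     "semi-adherent"))
  expect_identical(culture_groups(ann), c("adherent", "suspension", NA))
  expect_identical(culture_groups(ann, semi = "adherent"),
                   c("adherent", "suspension", "adherent"))
})
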