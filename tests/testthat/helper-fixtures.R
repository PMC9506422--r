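# Shared fixtures and independent oracles for the test suite.

# small measurement layout: counts per subtype, culture types cycled so the
# factors are not confounded
make_sheet <- function(n_per = c(A = 4, N = 4, P = 3, Y = 3), n_batches = 2,
                       n_tech = 2) {
  cls <- NULL
  ct_cycle <- c("adherent", "suspension", "semi-adherent")
  i <- 0
  for (s in names(n_per)) {
    for (k in seq_len(n_per[[s]])) {
      i <- i + 1
      cls <- rbind(cls, data.frame(
        cell_line = sprintf("CL%02d", i), subtype = s,
        culture_type = ct_cycle[(i - 1) %% 3 + 1], stringsAsFactors = FALSE))
    }
  }
  default_sample_sheet(cls, n_batches = n_batches, n_tech = n_tech)
}

small_config <- function(...) {
  args <- list(...)
  defaults <- list(
    n_proteins = 400, samples = make_sheet(),
    n_specific_per_subtype = 20, n_culture_proteins = 20,
    marker_counts = c(n_NE = 10, n_nonNE = 10, n_epi = 8, n_mes = 6))
  defaults[names(args)] <- NULL
  do.call(simulation_config, c(defaults, args))
}

# independent adjusted Rand index (contingency-table formula)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  exp_ix <- sum_a * sum_b / comb2(n)
  max_ix <- (sum_a + sum_b) / 2
  if (max_ix == exp_ix) return(1)
  (sum_ij - exp_ix) / (max_ix - exp_ix)
}

# brute-force on/off caller: plain loops over proteins and subtypes
onoff_brute <- function(obs, subtype, hi = 0.85, lo = 0.15) {
  subtypes <- sort(unique(subtype))
  out <- NULL
  for (i in seq_len(nrow(obs))) {
    for (s in subtypes) {
      fr_s <- mean(obs[i, subtype == s])
      fr_o <- sapply(setdiff(subtypes, s),
                     function(o) mean(obs[i, subtype == o]))
      if (fr_s >= hi && all(fr_o <= lo))
        out <- rbind(out, data.frame(protein = rownames(obs)[i], subtype = s,
                                     direction = "on"))
      if (fr_s <= lo && all(fr_o >= hi))
        out <- rbind(out, data.frame(protein = rownames(obs)[i], subtype = s,
                                     direction = "off"))
    }
  }
  out
}

# step-by-step running-sum enrichment oracle (independent of running_es)
es_oracle <- function(scores, in_set, weight = 1) {
  N <- length(scores)
  hits <- which(in_set)
  res <- numeric(N)
  cur <- 0
  denom <- sum(abs(scores[hits])^weight)
  for (i in seq_len(N)) {
    if (i %in% hits) cur <- cur + abs(scores[i])^weight / denom
    else cur <- cur - 1 / (N - length(hits))
    res[i] <- cur
  }
  mx <- max(res)
  mn <- min(res)
  if (mx + mn >= -1e-12 * max(mx, -mn, 1)) mx else mn
}

# 4-class fixture: n_per samples per class, n_disc discriminative features
# shifted by `shift` noise-SD units, n_noise pure-noise features
splsda_fixture <- function(n_per = 8, n_disc = 10, n_noise = 90, shift = 4,
                           seed = 1) {
  set.seed(seed)
  classes <- rep(c("A", "N", "P", "Y"), each = n_per)
  n <- length(classes)
  centers <- matrix(rnorm(n_disc * 4), n_disc, 4) * shift
  X <- cbind(t(centers[, match(classes, c("A", "N", "P", "Y"))]) +
               matrix(rnorm(n * n_disc), n),
             matrix(rnorm(n * n_noise), n))
  colnames(X) <- c(sprintf("DISC%02d", seq_len(n_disc)),
                   sprintf("NOISE%02d", seq_len(n_noise)))
  rownames(X) <- sprintf("S%02d", seq_len(n))
  list(X = X, y = classes, disc = colnames(X)[seq_len(n_disc)])
}

# tiny complete intensity matrix fixture
toy_matrix <- function(vals, proteins = NULL, samples = NULL,
                       stage = "imputed") {
  if (is.null(proteins)) proteins <- sprintf("P%02d", seq_len(nrow(vals)))
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(vals)))
  dimnames(vals) <- list(proteins, samples)
  intensity_matrix(vals, scale = "log2", stage = stage)
}
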