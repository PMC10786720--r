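test_that("TPM normalization: length scaling and column sums", {
  counts <- manual_pheno(matrix(c(100, 100, 50, 50, 10, 80), 2, 3), tss = c(5e5, 7e5))
  ## explicit lengths: equal counts, 1 kb vs 2 kb -> TPM ratio 2:1
  tpm <- tpm_from_counts(counts, feature_lengths = c(F001 = 1000, F002 = 2000))
  expect_equal(unname(tpm$values[1, 1] / tpm$values[2, 1]), 2)
  expect_equal(unname(colSums(tpm$values)), rep(1e6, 3))
  ## single feature -> 1e6 everywhere
  single <- manual_pheno(matrix(c(5, 9, 2), 1, 3))
  expect_equal(unname(tpm_from_counts(single)$values[1, ]), rep(1e6, 3))
  ## random table column sums
  set.seed(1)
  rnd <- manual_pheno(matrix(rpois(15, 30), 5, 3), tss = seq(1e5, 5e5, 1e5))
  expect_equal(unname(colSums(tpm_from_counts(rnd)$values)), rep(1e6, 3),
               tolerance = 1e-6)
  ## zero-total sample errors with its name
  bad <- manual_pheno(matrix(c(1, 2, 0, 0), 2, 2), tss = c(1e5, 2e5))
  colnames(bad$values) <- c("good", "empty")
  bad$sample_ids <- colnames(bad$values)
  expect_error(tpm_from_counts(bad), "empty")
})

test_that("expression filter thresholds are strict and idempotent", {
  n <- 10
  mk <- function(tpmv, cntv) {
    t <- manual_pheno(matrix(tpmv, 1, n))
    c <- manual_pheno(matrix(cntv, 1, n))
    filter_lowly_expressed(t, c)
  }
  ## low TPM in 9/10 samples (90% > 80%) -> dropped
  expect_length(mk(c(rep(0, 9), 5), rep(100, n)), 0)
  ## low in exactly 8/10 (80%, not more) -> kept
  expect_length(mk(c(rep(0, 8), 5, 5), rep(100, n)), 1)
  ## clean feature kept
  expect_length(mk(rep(1, n), rep(100, n)), 1)
  ## counts rule alone drops
  expect_length(mk(rep(1, n), c(rep(2, 9), 100)), 0)
  ## idempotence on a random matrix
  set.seed(2)
  tpm <- manual_pheno(matrix(rexp(200, 2), 20, 10), tss = seq_len(20) * 1e4)
  cnt <- manual_pheno(matrix(rpois(200, 8), 20, 10), tss = seq_len(20) * 1e4)
  k1 <- filter_lowly_expressed(tpm, cnt)
  tpm2 <- subset_features(tpm, k1); cnt2 <- subset_features(cnt, k1)
  expect_identical(filter_lowly_expressed(tpm2, cnt2), k1)
})

test_that("TMM factors: invariances and agreement with independent oracles", {
  set.seed(3)
  x <- matrix(rpois(400 * 4, 50), 400, 4)
  ## identical columns -> unit factors
  same <- x[, c(1, 1, 1)]
  colnames(same) <- paste0("s", 1:3)
  expect_equal(unname(tmm_normalize(same)$factors), rep(1, 3))
  ## pure depth change -> unit factors
  depth <- cbind(x[, 1], 2 * x[, 1])
  colnames(depth) <- c("a", "b")
  expect_equal(unname(tmm_normalize(depth)$factors), rep(1, 2), tolerance = 1e-12)
  ## 5% of features up 8-fold in one sample: match edgeR (the field-standard
  ## implementation) and a naive brute-force trim rule
  y <- x
  up <- seq_len(20)
  y[up, 2] <- y[up, 2] * 8
  colnames(y) <- paste0("s", 1:4)
  ours <- tmm_normalize(y)
  er <- edgeR::calcNormFactors(y, method = "TMM")
  expect_equal(unname(ours$factors), unname(er), tolerance = 1e-8)
  ## brute-force re-implementation of the trim-and-weight rule for one pair
  ref <- ours$ref_column
  brute <- brute_tmm(y[, 2], y[, ref])
  raw <- c(brute_tmm(y[, 1], y[, ref]), brute,
           brute_tmm(y[, 3], y[, ref]), brute_tmm(y[, 4], y[, ref]))
  raw <- raw / exp(mean(log(raw)))
  expect_equal(unname(ours$factors[2]), raw[2], tolerance = 1e-8)
  ## all-zero sample errors
  z <- cbind(x[, 1], 0)
  colnames(z) <- c("ok", "dead")
  expect_error(tmm_normalize(z), "dead")
})

test_that("inverse normal transform: closed forms, ties, normality", {
  v <- inverse_normal_transform(c(10, 20, 30))
  expect_equal(v, qnorm(c(1, 3, 5) / 6), tolerance = 1e-10)
  expect_equal(v[2], 0)
  ## all tied -> zeros
  expect_equal(inverse_normal_transform(rep(7, 5)), rep(0, 5))
  ## ties averaged: [1,1,2] -> ranks (1.5, 1.5, 3)
  expect_equal(inverse_normal_transform(c(1, 1, 2)),
               qnorm(c(1, 1, 2.5) / 3), tolerance = 1e-12)
  expect_error(inverse_normal_transform(numeric(0)), "empty")
  ## output passes Shapiro-Wilk for n >= 50 distinct values
  set.seed(4)
  for (n in c(50, 200)) {
    tr <- inverse_normal_transform(rexp(n))
    expect_gt(shapiro.test(tr)$p.value, 0.01)
  }
  ## Blom variant differs but preserves order
  x <- rnorm(20)
  expect_equal(order(inverse_normal_transform(x, offset = 3 / 8)),
               order(inverse_normal_transform(x)))
})

test_that("PSI computation and the three intron filters", {
  n <- 50
  mk_introns <- function(counts, clusters) {
    nf <- nrow(counts)
    rownames(counts) <- sprintf("I%02d", seq_len(nf))
    colnames(counts) <- sprintf("S%02d", seq_len(ncol(counts)))
    new_phenotype_matrix(counts, data.table::data.table(
      feature_id = rownames(counts), chrom = "chr1",
      start = seq_len(nf) * 100L, end = seq_len(nf) * 100L + 50L,
      tss = 1000L, strand = "+", kind = "intron", group_id = clusters,
      gene_id = paste0("G_", clusters)))
  }
  ## PSI values are within-cluster fractions: (8, 2) -> (0.8, 0.2)
  set.seed(5)
  good <- matrix(rpois(4 * n, 40) + 1, 4)
  good[1, 1] <- 8; good[2, 1] <- 2
  ph <- mk_introns(good, c("c1", "c1", "c2", "c2"))
  res <- compute_psi_and_filter(ph)
  expect_equal(unname(res$psi_raw["I01", 1]), 0.8)
  expect_equal(unname(res$psi_raw["I02", 1]), 0.2)
  ## full surviving cluster: PSI sums to 1 per sample
  expect_equal(unname(colSums(res$psi_raw[1:2, ])), rep(1, n))

  ## an intron that is zero in >50% of samples is dropped (rule 1), and its
  ## cluster partner goes with it (rule 4)
  z <- good
  z[3, seq_len(26)] <- 0
  res2 <- compute_psi_and_filter(mk_introns(z, c("c1", "c1", "c2", "c2")))
  expect_setequal(res2$filter_log$feature_id, c("I03", "I04"))
  expect_setequal(res2$filter_log$rule, c("zero_in_most_samples", "cluster_below_two"))

  ## a constant intron fails the unique-value floor first
  const <- good
  const[3, ] <- 30; const[4, ] <- 70
  res3 <- compute_psi_and_filter(mk_introns(const, c("c1", "c1", "c2", "c2")))
  expect_true(all(c("I03", "I04") %in% res3$filter_log$feature_id))

  ## the low-complexity z rule: near-constant fraction with a couple of mild
  ## outliers -> many unique values (passes the floor) but
  ## sum(|z| < 0.25) >= n - 3 and sum(|z| > 6) <= 3 both hold -> dropped
  lc <- good
  frac3 <- c(rep(0.5, n - 2) + seq(-1, 1, length.out = n - 2) * 3e-4, 0.9, 0.9)
  tot_lc <- 1e6
  lc[3, ] <- round(frac3 * tot_lc)
  lc[4, ] <- tot_lc - lc[3, ]
  zj <- as.numeric(scale(frac3))
  expect_true(sum(abs(zj) < 0.25) >= n - 3 && sum(abs(zj) > 6) <= 3)
  res3b <- compute_psi_and_filter(mk_introns(lc, c("c1", "c1", "c2", "c2")))
  expect_true(all(c("I03", "I04") %in% res3b$filter_log$feature_id))
  expect_true("low_complexity" %in% res3b$filter_log$rule)

  ## unique-value floor is max(10, 0.1 n): few unique PSI values -> dropped
  few <- good
  few[3, ] <- rep(c(10, 20), length.out = n)
  few[4, ] <- rep(c(20, 10), length.out = n)
  res4 <- compute_psi_and_filter(mk_introns(few, c("c1", "c1", "c2", "c2")))
  expect_true("too_few_unique_values" %in% res4$filter_log$rule)
  ## splicing features inherit the owning gene's TSS as coordinate
  expect_true(all(res$psi$feature_meta$end == res$psi$feature_meta$tss))
})

test_that("hidden-factor estimation recovers planted subspaces", {
  set.seed(6)
  n <- 120; f <- 300
  planted <- matrix(rnorm(n * 3), n)
  load <- matrix(rnorm(f * 3, sd = 2), f)
  x <- load %*% t(planted) + matrix(rnorm(f * n, sd = 0.3), f)
  hf <- estimate_hidden_factors(x, k = 5)
  ## canonical correlation between recovered top-3 and planted subspaces
  cc <- stats::cancor(hf$factors[, 1:3], planted)
  expect_gt(min(cc$cor), 0.9)
  ## orthonormal factors
  expect_equal(crossprod(hf$factors), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  ## deterministic
  expect_identical(hf, estimate_hidden_factors(x, k = 5))
  expect_error(estimate_hidden_factors(x, k = 500), "k must satisfy")
  ## isotropic noise: no dominant factor (Marchenko-Pastur flatness)
  noise <- matrix(rnorm(1000 * 200), 1000, 200)
  hn <- estimate_hidden_factors(noise, k = 10)
  expect_lt(hn$weights[1] / hn$weights[10], 2)
})

test_that("genotype PCs follow the cohort-size rule and separate breeds", {
  for (n in c(150, 250)) {
    cfg <- base_config(n_samples = n, breed_af_drift = 0.2, seed = n)
    g <- simulate_genotypes(cfg)
    pcs <- genotype_pcs(g)
    expect_equal(ncol(pcs), if (n < 200) 5L else 10L)
    expect_equal(crossprod(pcs), diag(ncol(pcs)), tolerance = 1e-8,
                 ignore_attr = TRUE)
    ## breed predictable from PC1 by a midpoint split
    pc1 <- pcs[, 1]; lab <- g$samples$breed
    thr <- mean(tapply(pc1, lab, mean))
    pred <- ifelse(pc1 > thr, "A", "B")
    acc <- max(mean((pred == "A") == (lab == lab[1])),
               mean((pred == "B") == (lab == lab[1])))
    expect_gt(acc, 0.9)
  }
  mono <- manual_geno(matrix(1L, 30, 3), "chr1", c(1, 2, 3) * 1e5)
  expect_error(genotype_pcs(mono), "polymorphic")
})

test_that("covariate variance explained behaves like an R-squared", {
  set.seed(7)
  fac <- matrix(rnorm(200 * 5), 200)
  ## a known covariate equal to factor 1 -> R2 = 1
  expect_equal(unname(covariate_variance_explained(fac, fac[, 1, drop = FALSE])),
               1, tolerance = 1e-10)
  ## invariant to invertible remixing of the factors
  mix <- fac %*% matrix(rnorm(25), 5)
  y <- cbind(fac[, 2] + rnorm(200, sd = 0.5))
  expect_equal(covariate_variance_explained(fac, y),
               covariate_variance_explained(mix, y), tolerance = 1e-10)
  ## independent noise -> about k/n
  r2 <- mean(vapply(1:40, function(i)
    unname(covariate_variance_explained(fac, cbind(rnorm(200)))), numeric(1)))
  expect_lt(abs(r2 - 5 / 200), 0.02)
  expect_warning(covariate_variance_explained(fac, cbind(rep(1, 200))),
                 "constant")
})

test_that("tau tissue-specificity matches its closed forms", {
  m <- rbind(even = c(4, 4, 4), single = c(9, 0, 0))
  tau <- tau_specificity(m)
  expect_equal(unname(tau["even"]), 0)
  expect_equal(unname(tau["single"]), 1)
  ## normalized profile (1, 0.5, 0) -> (0 + 0.5 + 1)/2 = 0.75
  expect_equal(unname(tau_specificity(rbind(c(1, 0.5, 0)),
                                      log_transform = FALSE)), 0.75)
  expect_true(is.na(tau_specificity(rbind(c(0, 0, 0)))))
  expect_error(tau_specificity(rbind(c(-1, 2, 0))), "non-negative")
})
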