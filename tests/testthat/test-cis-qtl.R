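test_that("residualization: centering, annihilation, FWL equivalence", {
  set.seed(1)
  n <- 60
  Y <- matrix(rnorm(3 * n), 3, n)
  ## intercept only -> centered rows
  expect_equal(residualize(Y), Y - rowMeans(Y), tolerance = 1e-12)
  ## a phenotype equal to a covariate residualizes to ~0
  C <- cbind(rnorm(n), rnorm(n))
  Y2 <- rbind(C[, 1], rnorm(n))
  r <- residualize(Y2, C)
  expect_lt(max(abs(r[1, ])), 1e-10)
  ## residuals orthogonal to covariates
  expect_lt(max(abs(r %*% C)), 1e-8)
  ## rank-deficient covariates error names the column
  Cbad <- cbind(a = C[, 1], b = C[, 1])
  expect_error(residualize(Y, Cbad), "collinear")

  ## Frisch-Waugh-Lovell: scan-on-residuals equals joint multiple regression
  for (rep in 1:20) {
    set.seed(rep)
    n <- 40
    C <- matrix(rnorm(n * 3), n)
    g <- rbinom(n, 2, 0.3)
    y <- 0.4 * g + C %*% rnorm(3) + rnorm(n)
    joint <- coef(lm(y ~ g + C))["g"]
    gm <- manual_geno(cbind(g), "chr1", 5e5)
    ph <- manual_pheno(matrix(y, 1), tss = 5e5)
    sc <- nominal_scan(gm, ph, covariates = C, maf_min = 0, mac_min = 0)
    expect_equal(sc$slope, unname(joint), tolerance = 1e-8)
  }
})

test_that("nominal scan matches textbook simple regression exactly", {
  set.seed(2)
  n <- 80
  g <- rbinom(n, 2, 0.4)
  y <- 0.3 * g + rnorm(n)
  gm <- manual_geno(cbind(g), "chr1", 5e5)
  ph <- manual_pheno(matrix(y, 1), tss = 5e5)
  sc <- nominal_scan(gm, ph)
  o <- ols_oracle(y, g)
  expect_equal(sc$slope, o$slope, tolerance = 1e-10)
  expect_equal(sc$slope_se, o$se, tolerance = 1e-10)
  expect_equal(sc$p, o$p, tolerance = 1e-10)
})

test_that("cis window boundary is inclusive at 1 Mb; strand flips distance", {
  set.seed(3)
  n <- 60
  d <- matrix(rbinom(n * 3, 2, 0.4), n)
  gm <- manual_geno(d, "chr1", c(2e6, 3e6, 3000001))
  ph <- manual_pheno(matrix(rnorm(n), 1), tss = 2e6)   # exactly 1 Mb from v2
  sc <- nominal_scan(gm, ph)
  expect_setequal(sc$variant_id, gm$variants$variant_id[1:2])
  expect_equal(sc$tss_distance, c(0, 1e6))
  ## minus strand flips the sign
  phm <- manual_pheno(matrix(rnorm(n), 1), tss = 2e6, strand = "-")
  scm <- nominal_scan(gm, phm)
  expect_equal(scm$tss_distance, c(0, -1e6))
})

test_that("MAF/MAC filters apply to the analyzed sample subset", {
  set.seed(4)
  n <- 100
  common <- rbinom(n, 2, 0.4)
  rare <- c(rep(1L, 2), rep(0L, n - 2))       # MAF 0.01, MAC 2
  gm <- manual_geno(cbind(common, rare), "chr1", c(4e5, 6e5))
  ph <- manual_pheno(matrix(rnorm(n), 1), tss = 5e5)
  sc <- nominal_scan(gm, ph)
  expect_equal(sc$variant_id, gm$variants$variant_id[1])
  expect_true(all(sc$maf >= 0.05))
})

test_that("single-cis-variant features fit Beta shapes near (1, 1)", {
  set.seed(5)
  n <- 80
  shapes <- t(vapply(1:10, function(i) {
    g <- rbinom(n, 2, 0.35)
    gm <- manual_geno(cbind(g), "chr1", 5e5)
    ph <- manual_pheno(matrix(rnorm(n), 1), tss = 5e5)
    pr <- permutation_pass(gm, ph, max_perm = 1000, adaptive_stop = 1000,
                           seed = i)
    c(pr$beta_shape1, pr$beta_shape2)
  }, numeric(2)))
  expect_lt(abs(mean(shapes[, 1]) - 1), 0.1)
  expect_lt(abs(mean(shapes[, 2]) - 1), 0.1)
  expect_true(all(abs(shapes - 1) < 0.35))
})

test_that("grouped pass with singleton groups is bit-identical to ungrouped", {
  cfg <- base_config(n_samples = 80, n_variants = 60,
                     n_features_per_kind = c(gene = 6, intron_cluster = 2),
                     seed = 6)
  g <- simulate_genotypes(cfg)
  s <- simulate_molecular_phenotypes(g, cfg, n_qtl = 2)
  expr <- int_rows(log2(s$phenotypes$values + 1))
  pm <- new_phenotype_matrix(expr, s$phenotypes$feature_meta)
  a <- permutation_pass(g, pm, max_perm = 200, seed = 77)
  b <- grouped_permutation_pass(g, pm, group_by = pm$feature_meta$feature_id,
                                max_perm = 200, seed = 77)
  expect_identical(a, b)
})

test_that("group observed minimum p <= each member's observed minimum p", {
  cfg <- base_config(n_samples = 100, seed = 8)
  g <- simulate_genotypes(cfg)
  s <- simulate_intron_clusters(g, cfg)
  psi <- compute_psi_and_filter(s$phenotypes)
  grp <- grouped_permutation_pass(g, psi$psi, max_perm = 100, seed = 3)
  solo <- permutation_pass(g, psi$psi, max_perm = 100, seed = 3)
  solo[, group_id := psi$psi$feature_meta$group_id[
    match(feature_id, psi$psi$feature_meta$feature_id)]]
  for (gid in grp$group_id) {
    expect_lte(grp[group_id == gid]$lead_p,
               min(solo[group_id == gid]$lead_p) + 1e-12)
  }
})

test_that("call_egenes: degenerate and closed-form threshold cases", {
  rec <- data.table::data.table(
    group_id = sprintf("g%03d", 1:100), feature_id = sprintf("g%03d", 1:100),
    lead_variant = "v", lead_p = 1e-7, slope = 1, n_perm = 1000L,
    p_direct = 1e-3, beta_shape1 = 1, beta_shape2 = 1, p_beta = 1e-6)
  cs <- call_egenes(rec)
  expect_true(all(cs$egene))
  ## Beta(1,1) inverse CDF is the identity: threshold == pt
  expect_equal(cs$nominal_threshold, rep(attr(cs, "pt"), 100))
  ## q-values monotone in p
  rec$p_beta <- seq(1e-6, 0.5, length.out = 100)
  cs2 <- call_egenes(rec)
  expect_true(all(diff(cs2$q[order(cs2$p_beta)]) >= -1e-12))
  expect_error(call_egenes(rec[0]), "empty")
})

test_that("significant pairs respect per-feature thresholds", {
  cfg <- base_config(n_samples = 120, seed = 9)
  g <- simulate_genotypes(cfg)
  s <- simulate_molecular_phenotypes(g, cfg, n_qtl = 6,
                                     effect_sizes = rep(1.2, 6))
  expr <- int_rows(log2(s$phenotypes$values + 1))
  pm <- new_phenotype_matrix(expr, s$phenotypes$feature_meta)
  perm <- permutation_pass(g, pm, max_perm = 300, seed = 4)
  cs <- call_egenes(perm)
  nom <- nominal_scan(g, pm)
  sp <- significant_pairs(cs, nom)
  expect_true(all(sp$p <= sp$nominal_threshold))
  expect_true(all(sp$feature_id %in% cs[egene == TRUE]$feature_id))
})

test_that("conditional scan returns nothing for non-eMolecules", {
  cfg <- base_config(n_samples = 80, n_features_per_kind = c(gene = 4, intron_cluster = 2),
                     seed = 10)
  g <- simulate_genotypes(cfg)
  s <- simulate_molecular_phenotypes(g, cfg, n_qtl = 0)
  expr <- int_rows(log2(s$phenotypes$values + 1))
  pm <- new_phenotype_matrix(expr, s$phenotypes$feature_meta)
  perm <- permutation_pass(g, pm, max_perm = 100, seed = 2)
  cs <- call_egenes(perm)
  cs$egene <- FALSE                  # force: nothing called
  expect_equal(nrow(conditional_scan(g, pm, NULL, cs)), 0L)
})

test_that("aFC estimates carry the INT-scale sign and recover planted effects", {
  cfg <- base_config(n_samples = 300, noise_sd = 0.5, seed = 11)
  g <- simulate_genotypes(cfg)
  s <- simulate_molecular_phenotypes(g, cfg, n_qtl = 6,
                                     effect_sizes = c(1, 1, -1, 0.7, -0.7, 1.3))
  tr <- s$truth$planted_qtl
  afc <- estimate_afc(s$phenotypes, g, tr)
  expect_equal(afc$afc, tr$slope, tolerance = 0.2)
  ## sign agreement with the INT-scale slope
  expr <- int_rows(log2(s$phenotypes$values + 1))
  pm <- new_phenotype_matrix(expr, s$phenotypes$feature_meta)
  nom <- nominal_scan(g, pm)
  ints <- nom[paste(feature_id, variant_id) %in%
                paste(tr$feature_id, tr$variant_id)]
  m <- merge(afc, ints, by = c("feature_id", "variant_id"))
  expect_true(all(sign(m$afc) == sign(m$slope)))
  ## all-zero feature flagged
  s0 <- s
  s0$phenotypes$values[tr$feature_id[1], ] <- 0
  a0 <- estimate_afc(s0$phenotypes, g, tr[1])
  expect_true(is.na(a0$afc))
})

test_that("trans scan boundary and null behavior", {
  set.seed(12)
  n <- 100
  d <- matrix(rbinom(n * 3, 2, 0.4), n)
  gm <- manual_geno(d, "chr1", c(10e6 - 4.9e6, 10e6 - 5e6, 10e6 - 5.1e6))
  ph <- manual_pheno(matrix(rnorm(n), 1), tss = 10e6)
  tr <- trans_scan(gm, ph)
  ## 4.9 Mb excluded; exactly 5.0 Mb and 5.1 Mb tested
  expect_setequal(tr$variant_id, gm$variants$variant_id[2:3])
  ## another chromosome is always tested
  gm2 <- manual_geno(d, "chr9", c(1e5, 2e5, 3e5))
  tr2 <- trans_scan(gm2, ph)
  expect_equal(nrow(tr2), 3L)
  ## planted trans effect is found
  y <- 0.8 * scale(d[, 1])[, 1] + rnorm(n, sd = 0.6)
  ph3 <- manual_pheno(matrix(y, 1), tss = 10e6)
  tr3 <- trans_scan(gm2, ph3)
  expect_true(tr3[variant_id == gm2$variants$variant_id[1]]$significant)
})

test_that("ABF fine-mapping: degenerate cases and the Wakefield formula", {
  ## single variant -> PIP 1
  expect_equal(abf_finemap(3.0)$pip, 1)
  ## perfect LD, equal z -> symmetric PIP 0.5
  fm <- abf_finemap(c(5, 5), ld = matrix(1, 2, 2), n = 500)
  expect_equal(fm$pip, c(0.5, 0.5))
  expect_error(abf_finemap(c(1, 2, 3), ld = diag(2)), "dimensions")
  ## direct formula oracle
  z <- c(0.5, 2, 4.2, -3)
  se <- c(0.1, 0.2, 0.15, 0.12)
  fm2 <- abf_finemap(z, prior_sd = 0.15, se = se)
  W <- 0.15^2
  labf <- 0.5 * log(1 - W / (W + se^2)) + 0.5 * (W / (W + se^2)) * z^2
  expect_equal(fm2$labf, labf, tolerance = 1e-10)
  expect_equal(fm2$pip, exp(labf) / sum(exp(labf)), tolerance = 1e-10)
})

test_that("permutation records are reproducible and order-independent", {
  cfg <- base_config(n_samples = 80, n_features_per_kind = c(gene = 4, intron_cluster = 2),
                     seed = 13)
  g <- simulate_genotypes(cfg)
  s <- simulate_molecular_phenotypes(g, cfg, n_qtl = 2)
  expr <- int_rows(log2(s$phenotypes$values + 1))
  pm <- new_phenotype_matrix(expr, s$phenotypes$feature_meta)
  a <- permutation_pass(g, pm, max_perm = 100, seed = 5)
  ## reversing feature order must not change any per-feature record
  rev_pm <- subset_features(pm, rev(pm$feature_meta$feature_id))
  b <- permutation_pass(g, rev_pm, max_perm = 100, seed = 5)
  expect_equal(a[order(feature_id)], b[order(feature_id)], ignore_attr = TRUE)
  expect_error(permutation_pass(g, pm, max_perm = 5), "max_perm")
})
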