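mk_gwas <- function(z, chrom = "chr1", pos = NULL, n = 1000L, trait = "t1") {
  m <- length(z)
  pos <- pos %||% (seq_len(m) * 1e4)
  data.table::data.table(
    variant_id = sprintf("%s:%d:A:G", chrom, as.integer(pos)), chrom = chrom,
    pos = as.integer(pos), z = z, n = as.integer(n),
    n_cases = NA_integer_, n_controls = NA_integer_, trait_id = trait)
}

test_that("meta-GWAS combines cohorts by the sample-size-weighted formula", {
  z <- c(1, -2, 3)
  a <- mk_gwas(z); b <- mk_gwas(z)
  m <- meta_gwas(list(a, b))
  expect_equal(m$z, sqrt(2) * z, tolerance = 1e-12)
  expect_equal(m$n, rep(2000L, 3))
  ## opposite z cancel
  expect_equal(meta_gwas(list(a, mk_gwas(-z)))$z, rep(0, 3))
  ## three unequal cohorts match the hand-evaluated formula
  set.seed(41)
  zs <- list(rnorm(3), rnorm(3), rnorm(3)); ns <- c(500, 2000, 800)
  cs <- Map(function(zz, nn) mk_gwas(zz, n = nn), zs, ns)
  m3 <- meta_gwas(cs)
  hand <- Reduce(`+`, Map(function(zz, nn) sqrt(nn) * zz, zs, ns)) / sqrt(sum(ns))
  expect_equal(m3$z, hand, tolerance = 1e-12)
  ## single cohort passthrough; mismatched variants logged
  expect_identical(meta_gwas(list(a)), a)
  b2 <- b[-1]
  m4 <- meta_gwas(list(a, b2))
  expect_equal(nrow(m4), 2L)
  expect_equal(attr(m4, "dropped"), a$variant_id[1])
})

test_that("locus definition clumps by distance with a strict lead bound", {
  ## one significant variant -> one locus containing it
  z <- c(rep(0.5, 9), 5.5)
  g <- mk_gwas(z)
  l1 <- define_loci(g)
  expect_equal(nrow(l1), 1L)
  expect_equal(l1$lead_variant, g$variant_id[10])
  expect_true(l1$lead_p < 1e-5)
  ## two significant variants 0.5 Mb apart merge; 2 Mb apart split
  g2 <- mk_gwas(c(6, 5.5), pos = c(1e6, 1.5e6))
  expect_equal(nrow(define_loci(g2)), 1L)
  g3 <- mk_gwas(c(6, 5.5), pos = c(1e6, 3e6))
  expect_equal(nrow(define_loci(g3)), 2L)
  ## sub-threshold only -> empty
  expect_equal(nrow(define_loci(mk_gwas(rep(1, 5)))), 0L)
  ## lead p is the locus minimum
  l3 <- define_loci(g3)
  expect_true(all(l3$lead_p <= 1e-5))
})

test_that("overlap enrichment: lambda rescaling is exact, signal enriches", {
  set.seed(42)
  m <- 2000
  lead <- list(
    t1 = data.table::data.table(variant_id = sprintf("v%04d", 1:m),
                                p = runif(m)),
    t2 = data.table::data.table(variant_id = sprintf("v%04d", 1:m),
                                p = runif(m)))
  ## scaling: the median scaled chi-square equals lambda * null median
  sc <- qchisq(lead$t1$p, 1, lower.tail = FALSE)
  sc <- sc * (10 * qchisq(0.5, 1) / median(sc))
  expect_equal(median(sc), 10 * qchisq(0.5, 1), tolerance = 1e-9)
  ## planted loci at the strongest molQTL variants -> fold > 1, small p
  strong <- order(lead$t1$p)[1:50]
  loci <- data.table::data.table(members = list(sprintf("v%04d", strong)))
  enr <- qtl_gwas_overlap_enrichment(lead, loci)
  expect_gt(enr$fold, 1)
  expect_lt(enr$wilcoxon_p, 0.01)
  ## random loci -> fold near 1
  rnd <- data.table::data.table(members = list(sprintf("v%04d", sample(m, 50))))
  enr0 <- qtl_gwas_overlap_enrichment(lead, rnd)
  expect_lt(abs(log(enr0$fold)), log(2.5))
  expect_error(qtl_gwas_overlap_enrichment(lead,
    data.table::data.table(members = list("nope"))), "no overlap")
})

test_that("MAF-matched sampling reproduces the target MAF histogram", {
  set.seed(43)
  pool <- data.table::data.table(variant_id = sprintf("p%05d", 1:5000),
                                 maf = runif(5000, 0.0, 0.5))
  target <- data.table::data.table(variant_id = sprintf("t%03d", 1:200),
                                   maf = rbeta(200, 2, 5) / 2)
  ctrl <- maf_matched_sample(target, pool, seed = 9)
  expect_length(ctrl, 200)
  brk <- seq(0, 0.5, length.out = 21)
  expect_equal(
    tabulate(cut(pool[variant_id %in% ctrl]$maf, brk, labels = FALSE), 20),
    tabulate(cut(target$maf, brk, labels = FALSE), 20))
  ## sampling never returns a target variant; degenerate pool errors
  expect_false(any(ctrl %in% target$variant_id))
  expect_error(maf_matched_sample(target, target), "underfilled")
  ## distribution stable across seeds (chi-square on bin counts)
  ctrl2 <- maf_matched_sample(target, pool, seed = 10)
  expect_equal(
    tabulate(cut(pool[variant_id %in% ctrl]$maf, brk, labels = FALSE), 20),
    tabulate(cut(pool[variant_id %in% ctrl2]$maf, brk, labels = FALSE), 20))
})

test_that("colocalization posteriors: normalization, null dominance, invariance", {
  set.seed(44)
  ld <- diag(10)
  cl <- colocalize(rnorm(10), rnorm(10), ld, n_gwas = 10000, n_qtl = 10000)
  expect_equal(sum(cl$pp), 1, tolerance = 1e-9)
  expect_gt(cl$pp["PP0"], 0.9)
  expect_equal(cl$rcp, unname(cl$pp["PP4"]))
  expect_equal(sum(cl$per_variant$coloc_prob), 1, tolerance = 1e-9)
  ## a strong shared signal drives PP4
  z <- c(rep(0, 9), 10)
  cl2 <- colocalize(z, z, ld, n_gwas = 10000, n_qtl = 10000)
  expect_gt(cl2$rcp, 0.9)
  expect_equal(which.max(cl2$per_variant$coloc_prob), 10L)
  ## distinct unlinked signals drive PP3
  z2 <- c(10, rep(0, 9))
  cl3 <- colocalize(z, z2, ld, n_gwas = 10000, n_qtl = 10000)
  expect_gt(cl3$pp["PP3"], cl3$pp["PP4"])
  expect_error(colocalize(rnorm(3), rnorm(4)), "align")
})

test_that("SMR statistic: algebraic identities and BH bookkeeping", {
  ## equal z: T = z^2 / 2
  s <- smr_test(6, 6)
  expect_equal(s$t_smr, 18)
  expect_equal(s$p_smr, pchisq(18, 1, lower.tail = FALSE))
  ## null GWAS: T = 0, p = 1
  s0 <- smr_test(6, 0)
  expect_equal(s0$t_smr, 0)
  expect_equal(s0$p_smr, 1)
  ## direct formula on a random table
  set.seed(45)
  ze <- rnorm(5, 0, 8); zg <- rnorm(5, 0, 3)
  tab <- smr_test(ze, zg)
  expect_equal(tab$t_smr, ze^2 * zg^2 / (ze^2 + zg^2), tolerance = 1e-12)
  ## weak instruments are not tested
  tabw <- smr_test(c(2, 8), c(3, 3))
  expect_equal(tabw$tested, c(FALSE, TRUE))
  expect_true(is.na(tabw$q_smr[1]))
  ## monotone in min(|z_eqtl|, |z_gwas|) on a grid
  grid <- expand.grid(a = seq(5, 12, 1), b = seq(5, 12, 1))
  tg <- smr_test(grid$a, grid$b)
  ord <- order(pmin(grid$a, grid$b))
  ## p decreases (weakly) as the weaker z grows, comparing equal-min pairs
  agg <- tapply(tg$p_smr, pmin(grid$a, grid$b), max)
  expect_true(all(diff(agg) < 0))
})

test_that("HEIDI flags insufficient instruments", {
  ld <- diag(5)
  h <- heidi_test(c(10, 8, 0.1, 0.1, 0.1), rnorm(5), ld)
  expect_false(h$tested)     # nothing inside the r2 window
  expect_true(is.na(h$p_heidi))
})

test_that("TWAS training: signal retained, noise and infinite penalty rejected", {
  set.seed(46)
  n <- 300
  G <- matrix(rbinom(n * 30, 2, 0.3), n)
  colnames(G) <- sprintf("v%02d", 1:30)
  causal <- scale(G[, 7])[, 1]
  y <- sqrt(0.3) * causal + rnorm(n, sd = sqrt(0.7))
  m <- train_twas_model(G, y, seed = 1)
  expect_true(m$retained)
  expect_true(m$weights["v07"] != 0)
  ## pure noise is rejected (rho_cv near zero)
  m0 <- train_twas_model(G, rnorm(n), seed = 2)
  expect_false(m0$retained)
  ## infinite penalty zeroes all weights
  mInf <- train_twas_model(G, y, seed = 3, lambda = 1e9)
  expect_true(all(mInf$weights == 0))
  expect_false(mInf$retained)
  expect_error(train_twas_model(G[1:6, ], y[1:6]), "folds")
})

test_that("summary TWAS formula: collapse, sign flip, explicit evaluation", {
  set.seed(47)
  g <- base_geno()
  idx <- 20:40
  w <- rnorm(21) * rbinom(21, 1, 0.4); w[3] <- 0.5
  names(w) <- g$variants$variant_id[idx]
  zz <- rnorm(21); names(zz) <- names(w)
  model <- list(weights = w)
  st <- summary_twas(model, zz, g)
  ## explicit formula
  G <- g$dosage[, idx]; sig <- apply(G, 2, sd); R <- cor(G)
  sg <- sqrt(t(w) %*% diag(sig) %*% R %*% diag(sig) %*% w)
  expect_equal(st$z, sum(w * sig * zz) / as.numeric(sg), tolerance = 1e-10)
  ## sign flip of all weights flips the gene z
  stf <- summary_twas(list(weights = -w), zz, g)
  expect_equal(stf$z, -st$z, tolerance = 1e-12)
  ## single-variant model collapses to the variant z
  w1 <- c(0.7); names(w1) <- g$variants$variant_id[5]
  z1 <- c(2.2); names(z1) <- names(w1)
  expect_equal(summary_twas(list(weights = w1), z1, g)$z, 2.2, tolerance = 1e-12)
  ## zero predicted variance flagged
  w0 <- c(0); names(w0) <- g$variants$variant_id[5]
  expect_true(summary_twas(list(weights = w0), z1, g)$flagged)
})

test_that("multi-tissue combination: single tissue, duplicates, eigen filtering", {
  ## one tissue equals the two-sided normal test
  mt1 <- multi_tissue_twas(2.5)
  expect_equal(mt1$p, 2 * pnorm(-2.5))
  ## an exactly duplicated tissue collapses to the single-tissue result
  C <- matrix(1, 2, 2)
  mt2 <- multi_tissue_twas(c(2.5, 2.5), C)
  expect_equal(mt2$df, 1L)
  expect_equal(mt2$p, 2 * pnorm(-2.5), tolerance = 1e-12)
  ## independent tissues add degrees of freedom
  mt3 <- multi_tissue_twas(c(2, -1, 3), diag(3))
  expect_equal(mt3$df, 3L)
  expect_equal(mt3$stat, sum(c(2, -1, 3)^2), tolerance = 1e-12)
})

test_that("annotation enrichment: whole-genome unity, planted 3x, empty flag", {
  set.seed(48)
  n <- 400
  whole <- data.table::data.table(chrom = "chr1", start = 0L, end = 10000000L,
                                  label = "all")
  targets <- data.table::data.table(
    variant_id = sprintf("t%03d", 1:n), chrom = "chr1",
    pos = sample.int(9e6, n), pip = runif(n))
  bg <- data.table::data.table(
    variant_id = sprintf("b%03d", 1:n), chrom = "chr1",
    pos = sample.int(9e6, n))
  e1 <- annotation_enrichment(targets, whole, bg)
  expect_equal(e1$fold, 1)
  ## planted: targets inside the state at 3x the background rate
  state <- data.table::data.table(chrom = "chr1", start = 0L, end = 1000000L,
                                  label = "s")
  t2 <- data.table::data.table(
    variant_id = sprintf("t%03d", 1:n), chrom = "chr1",
    pos = c(sample.int(1e6, n * 0.3), 1e6 + sample.int(8e6, n * 0.7)),
    pip = rep(1, n))
  b2 <- data.table::data.table(
    variant_id = sprintf("b%03d", 1:n), chrom = "chr1",
    pos = c(sample.int(1e6, n * 0.1), 1e6 + sample.int(8e6, n * 0.9)))
  e2 <- annotation_enrichment(t2, state, b2, seed = 4)
  expect_lt(abs(e2$fold - 3), 0.5)
  expect_true(e2$sd > 0)
  ## empty annotation flagged
  e3 <- annotation_enrichment(t2, state[0], b2)
  expect_true(e3$flagged)
})

test_that("TAD enrichment: co-TAD construction and uniform null", {
  lens <- c(chr1 = 4e6)
  tads <- simulate_annotations(lens, tad_mean_bp = 4e5, seed = 5)$tads
  set.seed(49)
  ## pairs planted inside single TADs -> fold > 1 in the short-distance bin
  inside <- do.call(rbind, lapply(1:60, function(i) {
    row <- tads[sample(nrow(tads), 1)]
    width <- row$end - row$start
    t0 <- row$start + round(width * 0.3)
    data.frame(chrom = "chr1", tss = t0, pos = t0 + round(width * 0.3))
  }))
  enr <- tad_enrichment(data.table::as.data.table(inside), tads, lens,
                        distance_bins = c(0, 5e5), seed = 6)
  expect_gt(enr$fold[1], 1.2)
  expect_equal(enr$observed[1], 1)
  ## uniformly placed variants -> fold near 1
  unif <- data.table::data.table(
    chrom = "chr1", tss = runif(150, 5e5, 3.5e6),
    pos = runif(150, 5e5, 3.5e6))
  unif <- unif[abs(pos - tss) < 5e5]
  e0 <- tad_enrichment(unif, tads, lens, distance_bins = c(0, 5e5), seed = 7)
  expect_lt(abs(e0$fold[1] - 1), 0.35)
})

test_that("tissue relevance score formula and exclusions", {
  tt <- data.table::data.table(
    tissue = c("muscle", "liver", "rare"),
    n_coloc = c(10L, 0L, 4L), n_samples = c(100L, 150L, 50L),
    egene_prop = c(0.5, 0.3, 0.2))
  r <- tissue_relevance(tt)
  expect_equal(r$score, c(10 / (100 * 0.5), 0, 4 / (50 * 0.2)))
  expect_equal(r$score[1], 0.2)
  expect_equal(r$included, c(TRUE, TRUE, FALSE))
  ## linearity in the colocalized count
  tt2 <- data.table::copy(tt); tt2$n_coloc <- tt2$n_coloc * 2L
  expect_equal(tissue_relevance(tt2)$score, 2 * r$score)
  expect_error(tissue_relevance(data.table::data.table(
    tissue = "x", n_coloc = 1L, n_samples = 10L, egene_prop = 0)), "proportions")
})
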