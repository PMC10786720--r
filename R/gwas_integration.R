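#' Sample-size-weighted GWAS meta-analysis
#'
#' Combines cohort-level z-scores for the same trait:
#' `z_meta = sum(sqrt(n_i) z_i) / sqrt(sum(n_i))`, `n_meta = sum(n_i)`.
#' Cohorts are inner-joined on variant id (the chrom:pos:ref:alt convention
#' enforces allele alignment); variants missing from any cohort are logged in
#' the `dropped` attribute.
#'
#' @param cohorts list of `GwasSummary` data.tables (variant_id, chrom, pos,
#'   z, n, ...).
#' @param trait_id label for the output.
#' @return a `GwasSummary` data.table.
#' @export
meta_gwas <- function(cohorts, trait_id = NULL) {
  check_that(length(cohorts) >= 1, "no cohorts supplied")
  if (length(cohorts) == 1L) return(cohorts[[1]])
  ids <- Reduce(intersect, lapply(cohorts, function(x) x$variant_id))
  dropped <- setdiff(unique(unlist(lapply(cohorts, function(x) x$variant_id))), ids)
  num <- 0; den <- 0; ntot <- 0L
  for (co in cohorts) {
    co <- co[match(ids, co$variant_id)]
    num <- num + sqrt(co$n) * co$z
    den <- den + co$n
    ntot <- ntot + co$n
  }
  base <- cohorts[[1]][match(ids, cohorts[[1]]$variant_id)]
  out <- data.table::data.table(
    variant_id = ids, chrom = base$chrom, pos = base$pos,
    z = num / sqrt(den), n = as.integer(ntot),
    n_cases = NA_integer_, n_controls = NA_integer_,
    trait_id = trait_id %||% base$trait_id[1])
  data.table::setattr(out, "dropped", dropped)
  out
}

#' Define GWAS loci by greedy distance clumping
#'
#' Repeatedly takes the most significant remaining variant with
#' `p < p_threshold` as a locus lead and absorbs all significant variants
#' within `merge_bp` of it.
#'
#' @param gwas `GwasSummary` (z column; p computed as two-sided normal).
#' @param p_threshold lead significance bound (default 1e-5).
#' @param merge_bp absorption distance (default 1 Mb).
#' @return data.table of loci: locus_id, trait_id, lead_variant, lead_p,
#'   chrom, start, end, n_members, members (list column).
#' @export
define_loci <- function(gwas, p_threshold = 1e-5, merge_bp = 1e6) {
  g <- data.table::copy(gwas)
  check_that(all(is.finite(g$pos)), "variant positions must be finite")
  g[, p := 2 * pnorm(-abs(z))]
  sig <- g[p < p_threshold][order(p)]
  out <- list()
  while (nrow(sig) > 0) {
    lead <- sig[1]
    mem <- sig[variant_id == lead$variant_id |
                 (chrom == lead$chrom & abs(pos - lead$pos) <= merge_bp)]
    out[[length(out) + 1L]] <- data.table::data.table(
      locus_id = sprintf("%s_locus%02d", lead$trait_id, length(out) + 1L),
      trait_id = lead$trait_id, lead_variant = lead$variant_id,
      lead_p = lead$p, chrom = lead$chrom,
      start = min(mem$pos), end = max(mem$pos), n_members = nrow(mem),
      members = list(mem$variant_id))
    sig <- sig[!variant_id %in% mem$variant_id]
  }
  if (!length(out))
    return(data.table::data.table(locus_id = character(), trait_id = character(),
                                  lead_variant = character(), lead_p = numeric(),
                                  chrom = character(), start = integer(),
                                  end = integer(), n_members = integer(),
                                  members = list()))
  data.table::rbindlist(out)
}

#' Overlap enrichment of molQTL signal at GWAS loci
#'
#' Per tissue, the most significant nominal p per gene is converted to a
#' 1-df chi-square and rescaled so the median equals `lambda_target` times the
#' null median (the "comparable level" scaling). The per-variant maximum of
#' the scaled statistic across tissues (i.e. the minimum p) forms the
#' background; values at GWAS-locus member variants are compared against it
#' by a one-sided Wilcoxon rank-sum test, and the fold of median scaled
#' statistics is reported.
#'
#' @param lead_p_per_tissue named list, one data.table per tissue with columns
#'   variant_id and p (the gene-lead nominal p carried by that variant).
#' @param loci output of [define_loci()].
#' @param lambda_target target median inflation (default 10).
#' @return list: fold, wilcoxon_p, n_target, n_background, scaled_background
#'   (data.table variant_id, chisq_scaled).
#' @export
qtl_gwas_overlap_enrichment <- function(lead_p_per_tissue, loci,
                                        lambda_target = 10) {
  scaled <- lapply(lead_p_per_tissue, function(tt) {
    chi <- qchisq(tt$p, df = 1, lower.tail = FALSE)
    s <- lambda_target * qchisq(0.5, 1) / median(chi)
    data.table::data.table(variant_id = tt$variant_id, chisq_scaled = chi * s)
  })
  bg <- data.table::rbindlist(scaled)[, .(chisq_scaled = max(chisq_scaled)),
                                      by = variant_id]
  tgt_ids <- unique(unlist(loci$members))
  tgt <- bg[variant_id %in% tgt_ids]
  check_that(nrow(tgt) > 0, "no overlap between GWAS loci and the molQTL variant universe")
  wt <- wilcox.test(tgt$chisq_scaled, bg[!variant_id %in% tgt_ids]$chisq_scaled,
                    alternative = "greater")
  list(fold = median(tgt$chisq_scaled) /
         median(bg[!variant_id %in% tgt_ids]$chisq_scaled),
       wilcoxon_p = wt$p.value, n_target = nrow(tgt),
       n_background = nrow(bg) - nrow(tgt), scaled_background = bg)
}

#' MAF-matched control variant sampling
#'
#' Draws a control set of the same size as the target with identical per-bin
#' MAF counts, sampling without replacement from the pool after excluding the
#' targets themselves.
#'
#' @param target data.table/data.frame with variant_id and maf.
#' @param pool same columns; the sampling universe.
#' @param n_bins number of equal-width MAF bins over `[0, 0.5]` (default 20).
#' @param seed integer seed.
#' @return character vector of control variant ids, `nrow(target)` long.
#' @export
maf_matched_sample <- function(target, pool, n_bins = 20L, seed = 1L) {
  brk <- seq(0, 0.5, length.out = n_bins + 1)
  tb <- cut(target$maf, brk, include.lowest = TRUE, labels = FALSE)
  pool <- pool[!pool$variant_id %in% target$variant_id, ]
  pb <- cut(pool$maf, brk, include.lowest = TRUE, labels = FALSE)
  with_seed(seed, {
    unlist(lapply(sort(unique(tb)), function(b) {
      need <- sum(tb == b)
      avail <- which(pb == b)
      check_that(length(avail) >= need,
                 "MAF bin %d underfilled: need %d controls, pool has %d",
                 b, need, length(avail))
      pool$variant_id[sample(avail, need)]
    }))
  })
}

## ---- colocalization --------------------------------------------------------

#' Colocalization of a GWAS and a QTL signal by approximate Bayes factors
#'
#' Wakefield ABFs per variant for each trait under a single-causal-variant
#' assumption, combined into the standard five-hypothesis posterior:
#' PP0 no signal, PP1/PP2 signal in one trait only, PP3 two distinct causal
#' variants, PP4 one shared causal variant. The regional colocalization
#' probability (RCP) is PP4; per-variant colocalization probabilities are
#' proportional to the product of the two ABFs.
#'
#' @param z_gwas,z_qtl aligned per-variant z-scores.
#' @param ld LD correlation matrix (validated; the ABF model itself is
#'   per-variant).
#' @param p1,p2,p12 prior probabilities that a variant is causal for trait 1
#'   only, trait 2 only, or both (defaults 1e-4, 1e-4, 1e-5).
#' @param prior_sd_gwas,prior_sd_qtl effect priors for the ABFs (standardized
#'   effect scale when sample sizes are supplied).
#' @param n_gwas,n_qtl sample sizes; when given, the per-variant sampling
#'   variance is `1/n` (standardized effect scale), the usual ABF setup.
#' @param se_gwas,se_qtl explicit standard errors (override `n_*`; without
#'   either, V = 1, i.e. the z scale, which flattens the BFs).
#' @return `ColocResult` list: pp (named PP0..PP4), rcp, per_variant
#'   (data.table index, coloc_prob), n_variants.
#' @export
colocalize <- function(z_gwas, z_qtl, ld = NULL, p1 = 1e-4, p2 = 1e-4,
                       p12 = 1e-5, prior_sd_gwas = 0.15, prior_sd_qtl = 0.15,
                       n_gwas = NULL, n_qtl = NULL,
                       se_gwas = NULL, se_qtl = NULL) {
  check_that(length(z_gwas) == length(z_qtl), "z vectors must align")
  m <- length(z_gwas)
  degenerate <- m < 2
  if (is.null(se_gwas) && !is.null(n_gwas)) se_gwas <- rep(1 / sqrt(n_gwas), m)
  if (is.null(se_qtl) && !is.null(n_qtl)) se_qtl <- rep(1 / sqrt(n_qtl), m)
  l1 <- wakefield_labf(z_gwas, prior_sd_gwas, se_gwas)
  l2 <- wakefield_labf(z_qtl, prior_sd_qtl, se_qtl)
  s1 <- logsumexp(l1); s2 <- logsumexp(l2); s12 <- logsumexp(l1 + l2)
  ## sum over distinct pairs: sum_i sum_{j != i} BF1_i BF2_j
  s3 <- logsumexp(c(s1 + s2, s12))                 # log(sum_all_pairs)
  sum3 <- log(pmax(exp(s1 + s2 - s3) - exp(s12 - s3), 1e-300)) + s3
  lh <- c(H0 = 0,
          H1 = log(p1) + s1,
          H2 = log(p2) + s2,
          H3 = log(p1) + log(p2) + sum3,
          H4 = log(p12) + s12)
  pp <- exp(lh - logsumexp(lh))
  names(pp) <- paste0("PP", 0:4)
  pv <- exp(l1 + l2 - s12)
  structure(list(pp = pp, rcp = unname(pp["PP4"]),
                 per_variant = data.table::data.table(index = seq_len(m),
                                                      coloc_prob = pv),
                 n_variants = m, degenerate = degenerate),
            class = "ColocResult")
}

#' Summary-based Mendelian randomization test
#'
#' `T_SMR = z_eqtl^2 z_gwas^2 / (z_eqtl^2 + z_gwas^2)`, chi-square with 1 df.
#' Instruments whose eQTL z corresponds to p >= `instrument_p` are skipped
#' (flagged `tested = FALSE`), and BH correction is applied across tested
#' genes.
#'
#' @param z_eqtl,z_gwas z-scores at each gene's top cis variant.
#' @param gene_id optional labels.
#' @param instrument_p exposure strength requirement (default 1e-5).
#' @return data.table: gene_id, z_eqtl, z_gwas, t_smr, p_smr, tested, q_smr.
#' @export
smr_test <- function(z_eqtl, z_gwas, gene_id = NULL, instrument_p = 1e-5) {
  check_that(length(z_eqtl) == length(z_gwas), "z vectors must align")
  gene_id <- gene_id %||% sprintf("gene%04d", seq_along(z_eqtl))
  tested <- 2 * pnorm(-abs(z_eqtl)) < instrument_p
  denom <- z_eqtl^2 + z_gwas^2
  t_smr <- ifelse(denom > 0, z_eqtl^2 * z_gwas^2 / denom, NA_real_)
  p_smr <- pchisq(t_smr, df = 1, lower.tail = FALSE)
  out <- data.table::data.table(gene_id = gene_id, z_eqtl = z_eqtl,
                                z_gwas = z_gwas, t_smr = t_smr, p_smr = p_smr,
                                tested = tested & !is.na(t_smr))
  out[, q_smr := NA_real_]
  out[tested == TRUE, q_smr := p.adjust(p_smr, method = "BH")]
  out[]
}

#' HEIDI heterogeneity test (linkage vs a single shared causal variant)
#'
#' Compares the Wald ratio `b_xy = z_gwas / z_eqtl` at variants in moderate
#' LD with the top eQTL variant against the top variant's ratio. Deviations
#' `d_i = b_xy(i) - b_xy(top)` have a covariance implied by LD; the sum of
#' squared standardized deviations is referred to a Satterthwaite-scaled
#' chi-square. `p_heidi >= 0.05` means a single shared causal variant cannot
#' be rejected.
#'
#' @param z_eqtl,z_gwas aligned per-variant z-scores across the region.
#' @param ld LD correlation matrix.
#' @param r2_min,r2_max LD window with the top variant for usable instruments
#'   (defaults 0.05 and 0.9).
#' @param min_snps,max_snps usable-variant bounds (3 and 20); below
#'   `min_snps` the test is flagged untested.
#' @return list: p_heidi, n_snps, tested, top_index.
#' @export
heidi_test <- function(z_eqtl, z_gwas, ld, r2_min = 0.05, r2_max = 0.9,
                       min_snps = 3L, max_snps = 20L) {
  m <- length(z_eqtl)
  check_that(all(dim(ld) == c(m, m)), "LD matrix dimensions do not match z")
  top <- which.max(abs(z_eqtl))
  r2 <- ld[, top]^2
  usable <- setdiff(which(r2 >= r2_min & r2 <= r2_max & abs(z_eqtl) > 1e-8), top)
  if (length(usable) > max_snps)
    usable <- usable[order(-abs(z_eqtl[usable]))][seq_len(max_snps)]
  if (length(usable) < min_snps)
    return(list(p_heidi = NA_real_, n_snps = length(usable), tested = FALSE,
                top_index = top))
  bxy <- z_gwas / z_eqtl
  d <- bxy[usable] - bxy[top]
  ## delta-method variance/covariance of b_xy differences with unit-variance
  ## (z-scale) effects; correlations from LD apply to both traits
  var_bxy <- (1 + bxy^2) / z_eqtl^2
  cov_d <- matrix(0, length(usable), length(usable))
  for (a in seq_along(usable)) for (b in seq_along(usable)) {
    i <- usable[a]; j <- usable[b]
    cov_bb <- ld[i, j] / (z_eqtl[i] * z_eqtl[j]) +
      ld[i, j] * bxy[i] * bxy[j] / (z_eqtl[i] * z_eqtl[j])
    cov_bt_i <- ld[i, top] / (z_eqtl[i] * z_eqtl[top]) +
      ld[i, top] * bxy[i] * bxy[top] / (z_eqtl[i] * z_eqtl[top])
    cov_bt_j <- ld[j, top] / (z_eqtl[j] * z_eqtl[top]) +
      ld[j, top] * bxy[j] * bxy[top] / (z_eqtl[j] * z_eqtl[top])
    cov_d[a, b] <- (if (a == b) var_bxy[i] else cov_bb) - cov_bt_i - cov_bt_j +
      var_bxy[top]
  }
  sdv <- sqrt(pmax(diag(cov_d), 1e-12))
  zd <- d / sdv
  corr_d <- cov_d / tcrossprod(sdv)
  stat <- sum(zd^2)
  ## Satterthwaite: stat ~ a * chisq(df) matching mean/variance of the
  ## eigenvalue-weighted chi-square mixture
  ev <- pmax(eigen(corr_d, symmetric = TRUE, only.values = TRUE)$values, 0)
  mu <- sum(ev); v <- 2 * sum(ev^2)
  a <- v / (2 * mu); df <- 2 * mu^2 / v
  list(p_heidi = pchisq(stat / a, df = df, lower.tail = FALSE),
       n_snps = length(usable), tested = TRUE, top_index = top)
}

## ---- TWAS ------------------------------------------------------------------

#' Train a cis elastic-net expression prediction model with nested CV
#'
#' Elastic net (`mixing` between L1 and L2, penalty chosen by inner 5-fold
#' cross-validation) of residualized expression on cis dosages. Outer-fold
#' predictions give the cross-validated correlation `rho_cv` and its
#' correlation-test p-value; the model is retained iff `rho_cv > 0.1` and
#' `p < 0.05`. Final weights are refit on all samples at the inner-CV
#' penalty.
#'
#' @param cis_dosage samples x cis-variants dosage matrix (>= 1 variant).
#' @param expression numeric expression vector (already residualized on
#'   covariates).
#' @param n_folds_outer outer folds (default 5).
#' @param mixing elastic-net alpha (default 0.5).
#' @param seed integer seed (fold assignment and glmnet folds).
#' @param lambda optional fixed penalty (skips inner CV).
#' @return `TwasModel` list: weights (named), rho_cv, p_cv, retained,
#'   variant_ids, train_sd (per-variant dosage sd).
#' @export
train_twas_model <- function(cis_dosage, expression, n_folds_outer = 5L,
                             mixing = 0.5, seed = 1L, lambda = NULL) {
  n <- length(expression)
  check_that(nrow(cis_dosage) == n, "dosage/expression sample mismatch")
  check_that(n >= 2 * n_folds_outer, "fewer samples than folds allow")
  X <- as.matrix(cis_dosage)
  if (ncol(X) == 1L) X <- cbind(X, 0)          # glmnet needs >= 2 columns
  with_seed(seed, {
    fold <- sample(rep(seq_len(n_folds_outer), length.out = n))
    pred <- rep(NA_real_, n)
    for (f in seq_len(n_folds_outer)) {
      tr <- fold != f
      fit <- glmnet_fit(X[tr, , drop = FALSE], expression[tr], mixing, lambda)
      pred[!tr] <- glmnet_predict(fit, X[!tr, , drop = FALSE])
    }
    rho <- if (sd(pred) == 0) 0 else cor(pred, expression)
    p_cv <- if (sd(pred) == 0) 1 else cor.test(pred, expression)$p.value
    final <- glmnet_fit(X, expression, mixing, lambda)
    w <- glmnet_weights(final)[seq_len(ncol(cis_dosage))]
    names(w) <- colnames(cis_dosage)
    structure(list(weights = w, rho_cv = rho, p_cv = p_cv,
                   retained = rho > 0.1 && p_cv < 0.05,
                   variant_ids = colnames(cis_dosage),
                   train_sd = apply(as.matrix(cis_dosage), 2L, sd)),
              class = "TwasModel")
  })
}

glmnet_fit <- function(X, y, mixing, lambda) {
  if (!is.null(lambda) && is.finite(lambda) && lambda > 1e5)
    return(list(intercept = mean(y), beta = rep(0, ncol(X))))
  if (!is.null(lambda)) {
    f <- glmnet::glmnet(X, y, alpha = mixing, lambda = lambda)
    return(list(intercept = as.numeric(f$a0), beta = as.numeric(f$beta)))
  }
  cv <- glmnet::cv.glmnet(X, y, alpha = mixing, nfolds = 5)
  co <- as.numeric(coef(cv, s = "lambda.min"))
  list(intercept = co[1], beta = co[-1])
}

glmnet_predict <- function(fit, X) as.numeric(fit$intercept + X %*% fit$beta)

glmnet_weights <- function(fit) fit$beta

#' Summary-statistic TWAS association
#'
#' Gene-level z: `z_gene = sum(w_l sigma_l z_l) / sigma_g` with `sigma_l` the
#' variant dosage SD in the LD reference and
#' `sigma_g^2 = w' S R S w` the predicted-expression variance (S = diag of
#' sigma, R = LD correlation).
#'
#' @param model a [train_twas_model()] result (or list with `weights`).
#' @param gwas_z named vector of GWAS z-scores covering the model variants.
#' @param ld_ref `GenotypeMatrix` LD reference containing the model variants.
#' @return list: z, p, sigma_g; `NA` with a flag when sigma_g = 0.
#' @export
summary_twas <- function(model, gwas_z, ld_ref) {
  w <- model$weights
  idx <- match(names(w), ld_ref$variants$variant_id)
  check_that(!anyNA(idx), "model variants missing from the LD reference")
  G <- ld_ref$dosage[, idx, drop = FALSE]
  sig <- apply(G, 2L, sd)
  R <- suppressWarnings(cor(G))
  R[!is.finite(R)] <- 0; diag(R) <- 1
  S <- diag(sig, nrow = length(sig))
  sigma_g2 <- as.numeric(t(w) %*% S %*% R %*% S %*% w)
  if (sigma_g2 <= 0)
    return(list(z = NA_real_, p = NA_real_, sigma_g = 0, flagged = TRUE))
  z <- sum(w * sig * gwas_z[names(w)]) / sqrt(sigma_g2)
  list(z = z, p = 2 * pnorm(-abs(z)), sigma_g = sqrt(sigma_g2), flagged = FALSE)
}

#' Multi-tissue TWAS combination
#'
#' Projects the per-tissue gene z-scores onto the principal components of the
#' tissue-tissue predicted-expression correlation matrix, discarding
#' components with eigenvalue below `max(eigen) / condition_threshold`, and
#' refers the squared projection sum to a chi-square with as many degrees of
#' freedom as retained components.
#'
#' @param z per-tissue gene z-scores.
#' @param expr_cor tissue x tissue predicted-expression correlation matrix.
#' @param condition_threshold eigenvalue-ratio cutoff (default 30).
#' @return list: stat, df, p, n_dropped.
#' @export
multi_tissue_twas <- function(z, expr_cor = NULL, condition_threshold = 30) {
  Tn <- length(z)
  check_that(Tn >= 1, "need at least one tissue z")
  if (Tn == 1L)
    return(list(stat = z^2, df = 1L, p = 2 * pnorm(-abs(z)), n_dropped = 0L))
  expr_cor <- expr_cor %||% diag(Tn)
  eg <- eigen(expr_cor, symmetric = TRUE)
  keep <- eg$values >= max(eg$values) / condition_threshold
  if (!any(keep))
    return(list(stat = NA_real_, df = 0L, p = NA_real_,
                n_dropped = Tn, flagged = TRUE))
  V <- eg$vectors[, keep, drop = FALSE]
  lam <- eg$values[keep]
  proj <- as.numeric(crossprod(V, z)) / sqrt(lam)
  stat <- sum(proj^2)
  k <- sum(keep)
  p <- pchisq(stat, df = k, lower.tail = FALSE)
  list(stat = stat, df = k, p = p, n_dropped = Tn - k)
}

## ---- annotation / TAD enrichment ------------------------------------------

in_intervals <- function(pos, chrom, intervals) {
  vapply(seq_along(pos), function(i) {
    any(intervals$chrom == chrom[i] & intervals$start <= pos[i] - 1 &
          intervals$end >= pos[i])
  }, logical(1))
}

#' Enrichment of fine-mapped variants in an annotation
#'
#' Fold = (PIP-weighted fraction of target variants inside the annotation) /
#' (fraction of matched background variants inside), with a bootstrap
#' standard deviation over target variants.
#'
#' @param targets data.table: variant_id, chrom, pos, pip.
#' @param annotation data.table of intervals (chrom, start, end; 0-based
#'   half-open).
#' @param background data.table: variant_id, chrom, pos (MAF/TSS-distance
#'   matched upstream, e.g. via [maf_matched_sample()]).
#' @param n_boot bootstrap replicates (default 200).
#' @param seed integer seed.
#' @return list: fold, sd, frac_target, frac_background, flagged.
#' @export
annotation_enrichment <- function(targets, annotation, background,
                                  n_boot = 200L, seed = 1L) {
  if (nrow(annotation) == 0)
    return(list(fold = NA_real_, sd = NA_real_, frac_target = NA_real_,
                frac_background = NA_real_, flagged = TRUE))
  tin <- in_intervals(targets$pos, targets$chrom, annotation)
  bin_ <- in_intervals(background$pos, background$chrom, annotation)
  pip <- targets$pip %||% rep(1, nrow(targets))
  frac_t <- sum(pip * tin) / sum(pip)
  frac_b <- mean(bin_)
  if (frac_b == 0)
    return(list(fold = Inf, sd = NA_real_, frac_target = frac_t,
                frac_background = 0, flagged = TRUE))
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(nrow(targets), replace = TRUE)
    sum(pip[idx] * tin[idx]) / sum(pip[idx]) / frac_b
  }, numeric(1)))
  list(fold = frac_t / frac_b, sd = sd(boots), frac_target = frac_t,
       frac_background = frac_b, flagged = FALSE)
}

#' Enrichment of QTL variant-TSS pairs within the same TAD
#'
#' Per TSS-distance bin: observed fraction of pairs whose variant and TSS fall
#' in the same TAD over the expected fraction under distance-preserving random
#' relocation (the pair keeps |distance| but is placed at a random position
#' and direction on the chromosome), with bootstrap sd over pairs.
#'
#' @param pairs data.table: chrom, tss, pos (variant position).
#' @param tads data.table of non-overlapping intervals per chromosome with a
#'   `label` column.
#' @param chrom_lengths named vector for relocation bounds.
#' @param distance_bins breaks on |pos - tss| (bp).
#' @param n_null relocations per pair (default 20).
#' @param n_boot bootstrap replicates (default 100).
#' @param seed integer seed.
#' @return data.table per bin: bin, n_pairs, observed, expected, fold, sd.
#' @export
tad_enrichment <- function(pairs, tads, chrom_lengths,
                           distance_bins = c(0, 2e4, 1e5, 5e5, 1e6),
                           n_null = 20L, n_boot = 100L, seed = 1L) {
  tad_of <- function(chrom, pos) {
    hit <- tads[tads$chrom == chrom & tads$start <= pos - 1 & tads$end >= pos]
    if (nrow(hit)) hit$label[1] else NA_character_
  }
  d <- abs(pairs$pos - pairs$tss)
  bin <- cut(d, distance_bins, include.lowest = TRUE, labels = FALSE)
  same <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- tad_of(pairs$chrom[i], pairs$tss[i])
    b <- tad_of(pairs$chrom[i], pairs$pos[i])
    !is.na(a) && !is.na(b) && a == b
  }, logical(1))
  exp_same <- with_seed(seed, vapply(seq_len(nrow(pairs)), function(i) {
    L <- chrom_lengths[[pairs$chrom[i]]]
    mean(vapply(seq_len(n_null), function(r) {
      t2 <- runif(1, d[i], L - d[i])
      v2 <- t2 + sample(c(-1, 1), 1) * d[i]
      a <- tad_of(pairs$chrom[i], t2); b <- tad_of(pairs$chrom[i], v2)
      !is.na(a) && !is.na(b) && a == b
    }, logical(1)))
  }, numeric(1)))
  out <- lapply(sort(unique(bin)), function(b) {
    idx <- which(bin == b)
    obs <- mean(same[idx]); expd <- mean(exp_same[idx])
    boots <- with_seed(child_seed(seed, b), vapply(seq_len(n_boot), function(r) {
      ii <- sample(idx, replace = TRUE)
      if (mean(exp_same[ii]) == 0) NA_real_
      else mean(same[ii]) / mean(exp_same[ii])
    }, numeric(1)))
    data.table::data.table(bin = b, n_pairs = length(idx), observed = obs,
                           expected = expd,
                           fold = if (expd > 0) obs / expd else NA_real_,
                           sd = sd(boots, na.rm = TRUE))
  })
  data.table::rbindlist(out)
}

#' Tissue relevance score for a trait
#'
#' `score = n_colocalized / (n_samples * eGene_proportion)`; tissues below
#' the sample-size floor are excluded with a flag.
#'
#' @param tissues data.table: tissue, n_coloc, n_samples, egene_prop.
#' @param min_samples floor for inclusion (default 100).
#' @return the input with `score` and `included` columns.
#' @export
tissue_relevance <- function(tissues, min_samples = 100L) {
  check_that(all(tissues$n_samples > 0), "sample sizes must be positive")
  check_that(all(tissues$egene_prop > 0 & tissues$egene_prop <= 1),
             "eGene proportions must lie in (0, 1]")
  out <- data.table::copy(data.table::as.data.table(tissues))
  out[, score := n_coloc / (n_samples * egene_prop)]
  out[, included := n_samples >= min_samples]
  out[]
}
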