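#' Residualize phenotypes on covariates
#'
#' Projects each phenotype row onto the orthogonal complement of the covariate
#' space (intercept always included). By the Frisch-Waugh-Lovell theorem a
#' scan on residualized phenotypes and genotypes reproduces the multiple
#' regression slope exactly, which is how the whole mapping engine here
#' accounts for covariates.
#'
#' @param phenotypes `PhenotypeMatrix` or features x samples matrix.
#' @param covariates samples x k numeric matrix (no intercept column), or
#'   NULL for intercept-only centering.
#' @return object of the same type with residualized rows.
#' @export
residualize <- function(phenotypes, covariates = NULL) {
  if (inherits(phenotypes, "PhenotypeMatrix")) {
    phenotypes$values <- residualize(phenotypes$values, covariates)
    return(phenotypes)
  }
  Q <- covariate_basis(covariates, ncol(phenotypes))
  phenotypes - (phenotypes %*% Q) %*% t(Q)
}

## orthonormal basis of [1, C]; errors on rank deficiency naming columns
covariate_basis <- function(covariates, n) {
  C <- cbind(`(intercept)` = rep(1, n), covariates)
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) {
    dropped <- colnames(C)[qrC$pivot[(qrC$rank + 1):ncol(C)]]
    stop_config("covariates are rank deficient; collinear columns: %s",
                paste(dropped, collapse = ", "))
  }
  qr.Q(qrC)
}

## residualized + column-L2-normalized genotype dosages passing MAF/MAC
prep_genotypes <- function(genotypes, covariates, maf_min, mac_min) {
  g <- genotypes$dosage
  n <- nrow(g)
  af <- colMeans(g) / 2
  maf <- pmin(af, 1 - af)
  mac <- pmin(colSums(g), 2L * n - colSums(g))
  pass <- maf >= maf_min & mac >= mac_min
  Q <- covariate_basis(covariates, n)
  gr <- g - Q %*% crossprod(Q, g)
  norms <- sqrt(colSums(gr^2))
  ok <- pass & norms > 1e-10
  gs <- sweep(gr[, ok, drop = FALSE], 2L, norms[ok], "/")
  list(gs = gs, gr = gr[, ok, drop = FALSE],
       variants = genotypes$variants[ok],
       maf = maf[ok], df = n - (if (is.null(covariates)) 0 else ncol(covariates)) - 2L)
}

## residualized + row-L2-normalized phenotypes
prep_phenotypes <- function(phenotypes, covariates) {
  Q <- covariate_basis(covariates, ncol(phenotypes$values))
  yr <- phenotypes$values - (phenotypes$values %*% Q) %*% t(Q)
  norms <- sqrt(rowSums(yr^2))
  norms[norms == 0] <- 1
  list(ys = yr / norms, yr = yr)
}

r_to_p <- function(r, df) 2 * pt(-abs(r) * sqrt(df / pmax(1 - r^2, 1e-300)), df)

signed_tss_distance <- function(pos, tss, strand) (pos - tss) * ifelse(strand == "-", -1, 1)

cis_index <- function(variants, chrom, tss, window_bp) {
  which(variants$chrom == chrom & abs(variants$pos - tss) <= window_bp)
}

#' Nominal cis association scan
#'
#' Ordinary least squares of each phenotype on each cis variant (window
#' inclusive at `window_bp` around the TSS), with covariates removed from
#' both sides first. p-values use the t distribution with
#' `n - n_covariates - 2` degrees of freedom. Variants must pass the MAF and
#' minor-allele-count filters within the analyzed sample set.
#'
#' @param genotypes `GenotypeMatrix`.
#' @param phenotypes `PhenotypeMatrix` (normalized scale).
#' @param covariates samples x k matrix or NULL.
#' @param window_bp cis window half-width (default 1 Mb, inclusive).
#' @param maf_min,mac_min variant filters (defaults 0.05 and 6).
#' @return data.table of nominal pairs: feature_id, variant_id, slope,
#'   slope_se, tstat, p, maf, tss_distance (signed, strand-aware). Features
#'   with no cis variants are skipped (attribute `skipped`).
#' @export
nominal_scan <- function(genotypes, phenotypes, covariates = NULL,
                         window_bp = 1e6, maf_min = 0.05, mac_min = 6) {
  check_that(identical(rownames(genotypes$dosage), phenotypes$sample_ids),
             "genotype and phenotype sample sets differ")
  gp <- prep_genotypes(genotypes, covariates, maf_min, mac_min)
  pp <- prep_phenotypes(phenotypes, covariates)
  meta <- phenotypes$feature_meta
  out <- vector("list", nrow(meta)); skipped <- character()
  for (i in seq_len(nrow(meta))) {
    idx <- cis_index(gp$variants, meta$chrom[i], meta$tss[i], window_bp)
    if (!length(idx)) { skipped <- c(skipped, meta$feature_id[i]); next }
    r <- as.numeric(crossprod(gp$gs[, idx, drop = FALSE], pp$ys[i, ]))
    sxx <- colSums(gp$gr[, idx, drop = FALSE]^2)
    syy <- sum(pp$yr[i, ]^2)
    slope <- r * sqrt(syy / sxx)
    p <- r_to_p(r, gp$df)
    tstat <- r * sqrt(gp$df / pmax(1 - r^2, 1e-300))
    out[[i]] <- data.table::data.table(
      feature_id = meta$feature_id[i],
      variant_id = gp$variants$variant_id[idx],
      slope = slope, slope_se = slope / tstat, tstat = tstat, p = p,
      maf = gp$maf[idx],
      tss_distance = signed_tss_distance(gp$variants$pos[idx], meta$tss[i],
                                         meta$strand[i]))
  }
  res <- data.table::rbindlist(out)
  data.table::setattr(res, "skipped", skipped)
  res
}

## ---- adaptive permutation machinery ---------------------------------------

## ML fit of a Beta distribution to permutation minima; method-of-moments
## start, BFGS on log-shape scale. Ties are separated by machine epsilon
## before fitting so the likelihood stays finite.
fit_beta_mle <- function(p) {
  p <- pmin(pmax(p, 1e-300), 1 - 1e-16)
  dup <- duplicated(p)
  if (any(dup)) p[dup] <- pmin(p[dup] * (1 + .Machine$double.eps *
                                           seq_len(sum(dup))), 1 - 1e-16)
  m <- mean(p); v <- var(p)
  if (!is.finite(v) || v <= 0) return(c(shape1 = 1, shape2 = 1))
  common <- m * (1 - m) / v - 1
  start <- log(pmax(c(m * common, (1 - m) * common), 1e-3))
  nll <- function(ls) -sum(dbeta(p, exp(ls[1]), exp(ls[2]), log = TRUE))
  fit <- tryCatch(optim(start, nll, method = "BFGS"),
                  error = function(e) list(par = start))
  c(shape1 = exp(fit$par[1]), shape2 = exp(fit$par[2]))
}

#' Permutation pass with adaptive stopping and beta approximation
#'
#' For every feature: record the observed minimum nominal p over the cis
#' window, then repeatedly permute sample labels of the residualized
#' phenotype, recording each permutation's window-wide minimum p. Permutation
#' stops early once `adaptive_stop` permutations have beaten the observed
#' minimum, or at `max_perm`. The direct empirical p-value is
#' `(1 + #better) / (1 + #perms)`; a Beta distribution fitted to the minima by
#' maximum likelihood gives the beta-approximated empirical p-value
#' (its CDF at the observed minimum), which extrapolates well below `1/#perms`.
#' Per-feature seeds are derived from `seed` and the feature id, so results do
#' not depend on evaluation order.
#'
#' @inheritParams nominal_scan
#' @param max_perm maximum permutations per feature (>= 10).
#' @param adaptive_stop stop after this many permutation exceedances.
#' @param seed integer seed.
#' @return data.table: feature_id, lead_variant, lead_p, slope, n_perm,
#'   p_direct, beta_shape1, beta_shape2, p_beta.
#' @export
permutation_pass <- function(genotypes, phenotypes, covariates = NULL,
                             window_bp = 1e6, maf_min = 0.05, mac_min = 6,
                             max_perm = 1000L, adaptive_stop = 100L, seed = 1L) {
  grouped_permutation_pass(genotypes, phenotypes, covariates,
                           group_by = phenotypes$feature_meta$feature_id,
                           window_bp = window_bp, maf_min = maf_min,
                           mac_min = mac_min, max_perm = max_perm,
                           adaptive_stop = adaptive_stop, seed = seed)
}

#' Grouped permutation pass (sQTL mode)
#'
#' Identical machinery to [permutation_pass()] but the unit of inference is a
#' feature group (all intron clusters of a gene): the observed statistic is
#' the minimum nominal p over every feature-variant pair of the group, and
#' each permutation permutes samples once per group (the same permutation is
#' applied to every member feature, preserving intra-cluster correlation)
#' before taking the group-wide minimum. With singleton groups this reduces
#' bit-identically to the ungrouped pass.
#'
#' @inheritParams permutation_pass
#' @param group_by grouping vector aligned to features; defaults to the
#'   `group_id` metadata column.
#' @return data.table keyed by `group_id` with the lead feature/variant pair.
#' @export
grouped_permutation_pass <- function(genotypes, phenotypes, covariates = NULL,
                                     group_by = NULL,
                                     window_bp = 1e6, maf_min = 0.05,
                                     mac_min = 6, max_perm = 1000L,
                                     adaptive_stop = 100L, seed = 1L) {
  check_that(max_perm >= 10, "max_perm must be >= 10")
  check_that(identical(rownames(genotypes$dosage), phenotypes$sample_ids),
             "genotype and phenotype sample sets differ")
  gp <- prep_genotypes(genotypes, covariates, maf_min, mac_min)
  pp <- prep_phenotypes(phenotypes, covariates)
  meta <- phenotypes$feature_meta
  groups <- group_by %||% meta$group_id
  check_that(!anyNA(groups), "every feature needs a group id")
  n <- ncol(phenotypes$values)
  out <- list(); skipped <- character()
  for (g in unique(groups)) {
    rows <- which(groups == g)
    cis <- lapply(rows, function(i)
      cis_index(gp$variants, meta$chrom[i], meta$tss[i], window_bp))
    keep <- lengths(cis) > 0
    if (!any(keep)) { skipped <- c(skipped, g); next }
    rows <- rows[keep]; cis <- cis[keep]
    ## observed: max |r| over all member pairs
    obs_r <- -Inf; lead <- c(NA_integer_, NA_integer_)
    robs <- vector("list", length(rows))
    for (j in seq_along(rows)) {
      r <- as.numeric(crossprod(gp$gs[, cis[[j]], drop = FALSE], pp$ys[rows[j], ]))
      robs[[j]] <- r
      if (max(abs(r)) > obs_r) {
        obs_r <- max(abs(r)); lead <- c(j, which.max(abs(r)))
      }
    }
    ## adaptive permutations, chunked; same permutation per group member
    perm_max_r <- numeric(0); exceed <- 0L; done <- 0L
    gseed <- child_seed(seed, g)
    with_seed(gseed, {
      while (done < max_perm && exceed < adaptive_stop) {
        B <- min(100L, max_perm - done)
        piL <- replicate(B, sample.int(n), simplify = FALSE)
        mx <- rep(-Inf, B)
        for (j in seq_along(rows)) {
          Yp <- vapply(piL, function(pi_) pp$ys[rows[j], pi_], numeric(n))
          rmat <- abs(crossprod(gp$gs[, cis[[j]], drop = FALSE], Yp))
          mx <- pmax(mx, apply(rmat, 2L, max))
        }
        perm_max_r <- c(perm_max_r, mx)
        exceed <- exceed + sum(mx >= obs_r)
        done <- done + B
      }
    })
    perm_min_p <- r_to_p(perm_max_r, gp$df)
    obs_p <- r_to_p(obs_r, gp$df)
    shapes <- fit_beta_mle(perm_min_p)
    j <- lead[1]
    out[[length(out) + 1L]] <- data.table::data.table(
      group_id = g,
      feature_id = meta$feature_id[rows[j]],
      lead_variant = gp$variants$variant_id[cis[[j]][lead[2]]],
      lead_p = obs_p,
      slope = robs[[j]][lead[2]] *
        sqrt(sum(pp$yr[rows[j], ]^2) / sum(gp$gr[, cis[[j]][lead[2]]]^2)),
      n_perm = done,
      p_direct = (1 + sum(perm_max_r >= obs_r)) / (1 + done),
      beta_shape1 = shapes[1], beta_shape2 = shapes[2],
      p_beta = pbeta(obs_p, shapes[1], shapes[2]))
  }
  res <- data.table::rbindlist(out)
  data.table::setattr(res, "skipped", skipped)
  res
}

#' Two-layer FDR: call eMolecules and derive per-feature nominal thresholds
#'
#' Layer one is the permutation pass (beta-approximated empirical p-values per
#' feature); layer two applies Benjamini-Hochberg across features. Features
#' with q < `fdr` are eMolecules. The genome-wide empirical threshold `pt` is
#' the empirical p-value of the feature whose q-value is closest to `fdr`
#' (ties toward the smaller empirical p), and each feature's nominal
#' significance threshold is the Beta inverse CDF of `pt` at its fitted
#' shapes. A nominal pair is a significant QTL iff its nominal p falls below
#' its feature's threshold.
#'
#' @param records output of [permutation_pass()] / [grouped_permutation_pass()].
#' @param fdr target feature-level FDR (default 0.05).
#' @return a `CallSet`: the records augmented with `q`, `egene` and
#'   `nominal_threshold`, plus attributes `pt` and `fdr`.
#' @export
call_egenes <- function(records, fdr = 0.05) {
  check_that(nrow(records) >= 1, "empty permutation record set")
  res <- data.table::copy(records)
  res[, q := p.adjust(p_beta, method = "BH")]
  res[, egene := q < fdr]
  ord <- order(abs(res$q - fdr), res$p_beta)
  pt <- res$p_beta[ord[1]]
  res[, nominal_threshold := qbeta(pt, beta_shape1, beta_shape2)]
  data.table::setattr(res, "pt", pt)
  data.table::setattr(res, "fdr", fdr)
  data.table::setattr(res, "class", c("CallSet", class(res)))
  res
}

#' Significant cis pairs under a call set's per-feature thresholds
#'
#' @param callset a [call_egenes()] result.
#' @param nominal a [nominal_scan()] table.
#' @param egenes_only restrict to called eMolecules (default TRUE).
#' @return subset of `nominal` with the feature threshold attached.
#' @export
significant_pairs <- function(callset, nominal, egenes_only = TRUE) {
  key <- if ("feature_id" %in% names(nominal)) "feature_id" else "group_id"
  thr <- callset[, .(feature_id, nominal_threshold, egene)]
  m <- merge(nominal, thr, by = "feature_id")
  if (egenes_only) m <- m[m$egene]
  m[m$p < m$nominal_threshold]
}

#' Conditionally independent cis signals by forward-backward stepwise scan
#'
#' Forward: starting from the covariates, repeatedly rescan the cis window
#' conditioning on all previously selected variants and add the new lead
#' variant while its conditional p beats the feature's nominal threshold.
#' Backward: re-test each selected variant conditional on all the others,
#' dropping failures (worst first) until all survive. Signals are ranked by
#' conditional p (rank 1 = strongest).
#'
#' @inheritParams nominal_scan
#' @param callset a [call_egenes()] result supplying thresholds and eMolecule
#'   flags.
#' @param threshold_policy `"max_beta_egenes"` (default): the gene-level
#'   significance level is the maximum beta-approximated empirical p-value
#'   over all called eMolecules, mapped to each feature's nominal scale via
#'   its Beta shapes — the convention of the stepwise cis-QTL literature;
#'   `"per_feature"`: reuse each feature's `nominal_threshold` from the call
#'   set.
#' @param max_signals safety cap on the forward pass.
#' @return data.table: feature_id, rank, variant_id, slope, slope_se, p
#'   (conditional on all other signals). Non-eMolecules yield no rows.
#' @export
conditional_scan <- function(genotypes, phenotypes, covariates = NULL,
                             callset, window_bp = 1e6, maf_min = 0.05,
                             mac_min = 6,
                             threshold_policy = c("max_beta_egenes", "per_feature"),
                             max_signals = 10L) {
  threshold_policy <- match.arg(threshold_policy)
  meta <- phenotypes$feature_meta
  if (threshold_policy == "max_beta_egenes") {
    if (!any(callset$egene)) return(data.table::data.table(
      feature_id = character(), rank = integer(), variant_id = character(),
      slope = numeric(), slope_se = numeric(), p = numeric()))
    pt_cond <- max(callset$p_beta[callset$egene])
  }
  g <- genotypes$dosage
  af <- colMeans(g) / 2
  mac <- pmin(colSums(g), 2L * nrow(g) - colSums(g))
  pass <- pmin(af, 1 - af) >= maf_min & mac >= mac_min
  out <- list()
  for (i in seq_len(nrow(meta))) {
    rec <- callset[callset$feature_id == meta$feature_id[i]]
    if (nrow(rec) == 0 || !rec$egene[1]) next
    thr <- if (threshold_policy == "max_beta_egenes")
      qbeta(pt_cond, rec$beta_shape1[1], rec$beta_shape2[1])
    else rec$nominal_threshold[1]
    idx <- intersect(cis_index(genotypes$variants, meta$chrom[i], meta$tss[i],
                               window_bp), which(pass))
    if (!length(idx)) next
    y <- phenotypes$values[i, ]
    Gc <- g[, idx, drop = FALSE]
    ## inclusive comparison: the boundary eMolecule's lead sits numerically
    ## at its own threshold (qbeta of its own beta-CDF value)
    thr_eff <- thr * (1 + 1e-9)
    selected <- integer(0)
    repeat {                                     # forward
      C <- cbind(covariates, g[, selected, drop = FALSE])
      sc <- scan_one(y, Gc, C)
      sc$p[selected_local(idx, selected)] <- 1
      j <- which.min(sc$p)
      if (!length(j) || sc$p[j] > thr_eff || length(selected) >= max_signals) break
      cand <- idx[j]
      Ctry <- cbind(C, g[, cand])
      if (qr(cbind(1, Ctry))$rank < ncol(Ctry) + 1) {
        warning("collinear candidate dropped for ", meta$feature_id[i])
        break
      }
      selected <- c(selected, cand)
    }
    if (!length(selected)) next
    repeat {                                     # backward
      ps <- vapply(seq_along(selected), function(k) {
        C <- cbind(covariates, g[, selected[-k], drop = FALSE])
        scan_one(y, g[, selected[k], drop = FALSE], C)$p
      }, numeric(1))
      if (all(ps <= thr_eff) || length(selected) == 1L) break
      worst <- which.max(ps)
      if (ps[worst] <= thr_eff) break
      selected <- selected[-worst]
    }
    ps <- vapply(seq_along(selected), function(k) {
      C <- cbind(covariates, g[, selected[-k], drop = FALSE])
      s <- scan_one(y, g[, selected[k], drop = FALSE], C)
      c(s$slope, s$se, s$p)
    }, numeric(3))
    if (length(selected) == 1L && any(ps[3, ] > thr_eff)) next
    ord <- order(ps[3, ])
    out[[length(out) + 1L]] <- data.table::data.table(
      feature_id = meta$feature_id[i], rank = seq_along(ord),
      variant_id = genotypes$variants$variant_id[selected[ord]],
      slope = ps[1, ord], slope_se = ps[2, ord], p = ps[3, ord])
  }
  data.table::rbindlist(out)
}

selected_local <- function(idx, selected) which(idx %in% selected)

## OLS of y on each column of G given covariates C (both sides residualized)
scan_one <- function(y, G, C) {
  n <- length(y)
  Q <- covariate_basis(C, n)
  yr <- y - Q %*% crossprod(Q, y)
  Gr <- G - Q %*% crossprod(Q, G)
  sxx <- colSums(Gr^2); sxx[sxx < 1e-12] <- NA
  sxy <- as.numeric(crossprod(Gr, yr))
  slope <- sxy / sxx
  df <- n - ncol(Q) - 1L
  r <- sxy / sqrt(sxx * sum(yr^2))
  p <- r_to_p(r, df)
  tval <- r * sqrt(df / pmax(1 - r^2, 1e-300))
  list(slope = slope, se = slope / tval, p = ifelse(is.na(slope), 1, p))
}

#' Allelic fold change of a lead variant on raw counts
#'
#' Library-size-normalizes raw counts, regresses `log2(norm_count + 1)` on
#' dosage plus covariates, and reports the slope as the log2 fold change per
#' alternative allele.
#'
#' @param counts `PhenotypeMatrix` of raw counts.
#' @param genotypes `GenotypeMatrix`.
#' @param pairs data.table/data.frame with feature_id and variant_id.
#' @param covariates optional samples x k matrix.
#' @return data.table: feature_id, variant_id, afc, se, p. Features with all
#'   zero counts are flagged with `NA` aFC.
#' @export
estimate_afc <- function(counts, genotypes, pairs, covariates = NULL) {
  ## median-of-ratios size factors: robust to any single gene's (possibly
  ## genotype-driven) contribution to the library, unlike raw column totals
  x <- counts$values
  lg <- rowMeans(log(x + 0.5))
  sf <- apply(x, 2L, function(col) exp(median(log(col + 0.5) - lg)))
  norm <- sweep(x, 2L, sf / mean(sf), "/")
  out <- lapply(seq_len(nrow(pairs)), function(k) {
    fi <- match(pairs$feature_id[k], counts$feature_meta$feature_id)
    vi <- match(pairs$variant_id[k], genotypes$variants$variant_id)
    check_that(!is.na(fi) && !is.na(vi), "unknown feature/variant in pairs")
    y <- norm[fi, ]
    if (all(counts$values[fi, ] == 0))
      return(data.table::data.table(feature_id = pairs$feature_id[k],
                                    variant_id = pairs$variant_id[k],
                                    afc = NA_real_, se = NA_real_, p = NA_real_))
    s <- scan_one(log2(y + 1), genotypes$dosage[, vi, drop = FALSE], covariates)
    data.table::data.table(feature_id = pairs$feature_id[k],
                           variant_id = pairs$variant_id[k],
                           afc = s$slope, se = s$se, p = s$p)
  })
  data.table::rbindlist(out)
}

#' Genome-wide trans association scan
#'
#' Tests every variant-feature pair with the variant on another chromosome or
#' at least `exclusion_bp` from the feature's TSS, then applies
#' Benjamini-Hochberg across all tests.
#'
#' @inheritParams nominal_scan
#' @param exclusion_bp same-chromosome distance below which pairs are excluded
#'   (default 5 Mb; a pair at exactly the boundary is tested).
#' @param fdr FDR level for the `significant` flag.
#' @return data.table of tested pairs: feature_id, variant_id, slope, p, q,
#'   significant, trans = TRUE.
#' @export
trans_scan <- function(genotypes, phenotypes, covariates = NULL,
                       exclusion_bp = 5e6, fdr = 0.05,
                       maf_min = 0.05, mac_min = 6) {
  gp <- prep_genotypes(genotypes, covariates, maf_min, mac_min)
  pp <- prep_phenotypes(phenotypes, covariates)
  meta <- phenotypes$feature_meta
  R <- crossprod(gp$gs, t(pp$ys))          # variants x features correlations
  keep <- outer(seq_len(nrow(R)), seq_len(ncol(R)), function(vi, fi)
    gp$variants$chrom[vi] != meta$chrom[fi] |
      abs(gp$variants$pos[vi] - meta$tss[fi]) >= exclusion_bp)
  idx <- which(keep, arr.ind = TRUE)
  r <- R[idx]
  sxx <- colSums(gp$gr^2)[idx[, 1]]
  syy <- rowSums(pp$yr^2)[idx[, 2]]
  res <- data.table::data.table(
    feature_id = meta$feature_id[idx[, 2]],
    variant_id = gp$variants$variant_id[idx[, 1]],
    slope = r * sqrt(syy / sxx),
    p = r_to_p(r, gp$df), trans = TRUE)
  res[, q := p.adjust(p, method = "BH")]
  res[, significant := q < fdr]
  res[]
}

#' Single-causal approximate-Bayes-factor fine-mapping
#'
#' Wakefield approximate Bayes factors per variant under a `N(0, prior_sd^2)`
#' effect prior and a single-causal-variant assumption; posterior inclusion
#' probabilities are the BFs normalized over the region. With z-scores only
#' (no slope standard errors) the sampling variance defaults to 1, i.e. the
#' z-scale; pass `se` for calibrated effect-scale BFs.
#'
#' @param z vector of association z-scores in the region.
#' @param ld LD correlation matrix aligned to `z` (used only for dimension
#'   validation here; retained in the result for downstream consumers).
#' @param prior_sd prior effect standard deviation (default 0.15).
#' @param n sample size; when given, V = 1/n (standardized effect scale).
#' @param se optional per-variant standard errors (override `n`).
#' @return data.table: index, labf (log ABF), pip.
#' @export
abf_finemap <- function(z, ld = NULL, prior_sd = 0.15, n = NULL, se = NULL) {
  if (is.null(se) && !is.null(n)) se <- rep(1 / sqrt(n), length(z))
  if (!is.null(ld))
    check_that(nrow(ld) == length(z) && ncol(ld) == length(z),
               "LD matrix dimensions do not match z")
  labf <- wakefield_labf(z, prior_sd, se)
  pip <- exp(labf - logsumexp(labf))
  data.table::data.table(index = seq_along(z), labf = labf, pip = pip)
}

wakefield_labf <- function(z, prior_sd, se = NULL) {
  V <- if (is.null(se)) rep(1, length(z)) else se^2
  W <- prior_sd^2
  r <- W / (W + V)
  0.5 * log(1 - r) + 0.5 * r * z^2
}
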