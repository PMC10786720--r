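#' Genotype-by-context interaction scan (bieQTL / cieQTL style)
#'
#' For every cis feature-variant pair fits
#' `phenotype ~ genotype + context + genotype:context + covariates`
#' and reports the interaction term. The context is a continuous per-sample
#' covariate such as a breed-ancestry proportion or a cell-type enrichment
#' score. To avoid leverage artifacts the variant must pass `maf_min` within
#' both the lower and the upper half of the context distribution.
#' Benjamini-Hochberg correction is applied across all tested pairs of the
#' context.
#'
#' @inheritParams nominal_scan
#' @param context numeric per-sample vector (must vary).
#' @param context_name label recorded in the output.
#' @param fdr FDR level for the `significant` flag.
#' @return data.table: feature_id, variant_id, context, slope_g, slope_c,
#'   slope_gxc, se_gxc, p (interaction), q, significant.
#' @export
interaction_scan <- function(genotypes, phenotypes, covariates = NULL,
                             context, context_name = "context",
                             window_bp = 1e6, maf_min = 0.05, mac_min = 6,
                             fdr = 0.05) {
  check_that(length(context) == ncol(phenotypes$values),
             "context length must match the sample count")
  check_that(sd(context) > 0, "context covariate is constant")
  g <- genotypes$dosage
  n <- nrow(g)
  af <- colMeans(g) / 2
  mac <- pmin(colSums(g), 2L * n - colSums(g))
  lower <- context <= median(context)
  maf_in <- function(rows) {
    a <- colMeans(g[rows, , drop = FALSE]) / 2
    pmin(a, 1 - a)
  }
  pass <- pmin(af, 1 - af) >= maf_min & mac >= mac_min &
    maf_in(lower) >= maf_min & maf_in(!lower) >= maf_min
  meta <- phenotypes$feature_meta
  out <- list()
  for (i in seq_len(nrow(meta))) {
    idx <- intersect(cis_index(genotypes$variants, meta$chrom[i], meta$tss[i],
                               window_bp), which(pass))
    if (!length(idx)) next
    y <- phenotypes$values[i, ]
    rows <- lapply(idx, function(vi) {
      gg <- g[, vi]
      X <- cbind(1, gg, context, gg * context, covariates)
      fit <- tryCatch(lm.fit(X, y), error = function(e) NULL)
      if (is.null(fit) || fit$rank < ncol(X)) return(NULL)
      df <- n - ncol(X)
      sigma2 <- sum(fit$residuals^2) / df
      XtXi <- tryCatch(chol2inv(chol(crossprod(X))), error = function(e) NULL)
      if (is.null(XtXi)) return(NULL)
      se <- sqrt(diag(XtXi) * sigma2)
      tval <- fit$coefficients / se
      data.table::data.table(
        feature_id = meta$feature_id[i],
        variant_id = genotypes$variants$variant_id[vi],
        context = context_name,
        slope_g = fit$coefficients[2], slope_c = fit$coefficients[3],
        slope_gxc = fit$coefficients[4], se_gxc = se[4],
        p = 2 * pt(-abs(tval[4]), df))
    })
    out <- c(out, rows)
  }
  res <- data.table::rbindlist(out)
  check_that(nrow(res) > 0, "no testable cis pairs under the context filters")
  res[, q := p.adjust(p, method = "BH")]
  res[, significant := q < fdr]
  res[]
}

#' Per-context-bin genotype effects (interaction diagnostic)
#'
#' Splits samples into `n_bins` context-quantile bins, estimates the OLS
#' genotype slope within each bin, and summarizes the trend as the Spearman
#' correlation between bin index and slope. Bins with fewer than `min_bin`
#' samples are merged with their neighbor (warning).
#'
#' @param genotypes `GenotypeMatrix`.
#' @param phenotype numeric phenotype vector.
#' @param variant_id variant to stratify on.
#' @param context numeric per-sample context.
#' @param n_bins number of quantile bins (default 4).
#' @param breaks optional explicit context cut points (overrides `n_bins`).
#' @param min_bin minimum samples per bin (default 10).
#' @return list: `bins` (data.table bin, n, slope, se) and `trend_rho`.
#' @export
stratified_effect_summary <- function(genotypes, phenotype, variant_id, context,
                                      n_bins = 4L, breaks = NULL, min_bin = 10L) {
  vi <- match(variant_id, genotypes$variants$variant_id)
  check_that(!is.na(vi), "unknown variant id")
  gg <- genotypes$dosage[, vi]
  br <- breaks %||% unique(quantile(context, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(context, breaks = br, include.lowest = TRUE, labels = FALSE)
  ## merge underfilled bins into their left neighbor
  repeat {
    tab <- table(bin)
    small <- as.integer(names(tab)[tab < min_bin])
    if (!length(small) || length(tab) == 1L) break
    warning("merging underfilled context bin ", small[1])
    tgt <- if (small[1] == min(bin)) small[1] + 1L else small[1] - 1L
    bin[bin == small[1]] <- tgt
    bin <- as.integer(factor(bin))
  }
  stats <- lapply(sort(unique(bin)), function(b) {
    s <- scan_one(phenotype[bin == b], cbind(gg[bin == b]), NULL)
    data.table::data.table(bin = b, n = sum(bin == b),
                           slope = s$slope, se = s$se)
  })
  bins <- data.table::rbindlist(stats)
  rho <- if (nrow(bins) >= 2)
    suppressWarnings(cor(bins$bin, bins$slope, method = "spearman")) else NA_real_
  list(bins = bins, trend_rho = rho)
}
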