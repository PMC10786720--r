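#' Construct a PhenotypeMatrix
#'
#' Lightweight container tying a features x samples value matrix to per-feature
#' genomic metadata (chrom, 0-based half-open interval, 1-based TSS, strand,
#' kind, owning group). All downstream QTL operations consume this class.
#'
#' @param values numeric matrix, features x samples, rownames = feature ids.
#' @param feature_meta data.table with columns feature_id, chrom, start, end,
#'   tss, strand, kind, group_id (and optionally gene_id for introns).
#' @return object of class `PhenotypeMatrix`.
#' @export
new_phenotype_matrix <- function(values, feature_meta) {
  feature_meta <- data.table::as.data.table(feature_meta)
  check_that(!anyDuplicated(feature_meta$feature_id),
             "duplicate feature ids in feature_meta")
  check_that(identical(rownames(values), feature_meta$feature_id),
             "rownames(values) must equal feature_meta$feature_id")
  if (!"group_id" %in% names(feature_meta)) feature_meta$group_id <- feature_meta$feature_id
  check_that(!any(feature_meta$kind %in% c("intron", "exon") & is.na(feature_meta$group_id)),
             "introns/exons must carry a non-null group_id")
  gl <- feature_meta$kind %in% c("gene", "lncRNA", "enhancer")
  check_that(all(feature_meta$tss[gl] > feature_meta$start[gl] &
                   feature_meta$tss[gl] <= feature_meta$end[gl]),
             "TSS must fall inside the feature interval for gene-like features")
  structure(list(values = values, feature_meta = feature_meta,
                 sample_ids = colnames(values)),
            class = "PhenotypeMatrix")
}

#' @export
print.PhenotypeMatrix <- function(x, ...) {
  cat(sprintf("PhenotypeMatrix: %d features (%s) x %d samples\n",
              nrow(x$values),
              paste(names(table(x$feature_meta$kind)), collapse = "/"),
              ncol(x$values)))
  invisible(x)
}

#' Subset a PhenotypeMatrix by feature ids or indices
#' @param pheno `PhenotypeMatrix`.
#' @param keep character feature ids or integer indices.
#' @return the subsetted `PhenotypeMatrix`.
#' @export
subset_features <- function(pheno, keep) {
  idx <- if (is.character(keep)) match(keep, pheno$feature_meta$feature_id) else keep
  new_phenotype_matrix(pheno$values[idx, , drop = FALSE],
                       pheno$feature_meta[idx])
}

#' Transcripts-per-million normalization
#'
#' Per sample: divide counts by feature length in kb, then scale the column to
#' sum to one million.
#'
#' @param counts `PhenotypeMatrix` of raw counts.
#' @param feature_lengths named numeric vector of feature lengths in bp; when
#'   `NULL`, interval lengths from the feature metadata are used.
#' @return `PhenotypeMatrix` of TPM values.
#' @export
tpm_from_counts <- function(counts, feature_lengths = NULL) {
  stopifnot(inherits(counts, "PhenotypeMatrix"))
  x <- counts$values
  len <- feature_lengths %||%
    setNames(with(counts$feature_meta, end - start), counts$feature_meta$feature_id)
  len <- len[rownames(x)]
  check_that(!anyNA(len) && all(len > 0), "feature lengths must be positive and complete")
  check_that(all(x >= 0), "counts must be non-negative")
  rate <- x / (len / 1e3)
  tot <- colSums(rate)
  bad <- which(tot == 0)
  check_that(length(bad) == 0, "zero total count in sample(s): %s",
             paste(colnames(x)[bad], collapse = ", "))
  out <- sweep(rate, 2L, tot, "/") * 1e6
  new_phenotype_matrix(out, counts$feature_meta)
}

#' Expression filter: drop features lowly expressed in most samples
#'
#' A feature is removed iff TPM < `tpm_min` in strictly more than
#' `frac` of samples, or raw counts < `count_min` in strictly more than
#' `frac` of samples.
#'
#' @param tpm,counts `PhenotypeMatrix` objects sharing features and samples.
#' @param tpm_min,count_min,frac filter thresholds (defaults 0.1, 6, 0.80).
#' @return character vector of kept feature ids.
#' @export
filter_lowly_expressed <- function(tpm, counts, tpm_min = 0.1, count_min = 6,
                                   frac = 0.80) {
  check_that(identical(dim(tpm$values), dim(counts$values)) &&
               identical(rownames(tpm$values), rownames(counts$values)),
             "tpm and counts must share features and samples")
  n <- ncol(tpm$values)
  low_tpm <- rowMeans(tpm$values < tpm_min)
  low_cnt <- rowMeans(counts$values < count_min)
  keep <- !(low_tpm > frac | low_cnt > frac)   # strict: "more than 80%"
  rownames(tpm$values)[keep]
}

#' TMM library-composition normalization
#'
#' Weighted trimmed mean of log2 expression ratios (M-values) against a
#' reference sample, the canonical method for count matrices: trim the 30%
#' most extreme M and the 5% most extreme A values, average the surviving M
#' with inverse-asymptotic-variance weights, exponentiate. The reference is
#' the sample whose 75th count percentile (depth-adjusted) is closest to the
#' mean 75th percentile. Factors are rescaled to geometric mean 1.
#'
#' @param counts `PhenotypeMatrix` (or plain matrix) of raw counts.
#' @param logratio_trim,sum_trim trim fractions for M and A (0.30 / 0.05).
#' @param ref_column optional explicit reference column index.
#' @return list with `factors` (named per-sample scaling factors) and
#'   `normalized` (counts divided by libsize x factor, scaled to the mean
#'   effective library size).
#' @export
tmm_normalize <- function(counts, logratio_trim = 0.30, sum_trim = 0.05,
                          ref_column = NULL) {
  x <- if (inherits(counts, "PhenotypeMatrix")) counts$values else counts
  check_that(ncol(x) >= 2, "TMM needs at least two samples")
  lib <- colSums(x)
  check_that(all(lib > 0), "all-zero sample(s): %s",
             paste(colnames(x)[lib == 0], collapse = ", "))
  f75 <- apply(x, 2L, function(col) quantile(col / sum(col), 0.75))
  ref <- ref_column %||% which.min(abs(f75 - mean(f75)))
  fac <- vapply(seq_len(ncol(x)), function(j)
    tmm_pair_factor(x[, j], x[, ref], lib[j], lib[ref], logratio_trim, sum_trim),
    numeric(1))
  fac <- fac / exp(mean(log(fac)))
  names(fac) <- colnames(x)
  eff <- lib * fac
  normalized <- sweep(x, 2L, eff / mean(eff), "/")
  if (inherits(counts, "PhenotypeMatrix"))
    normalized <- new_phenotype_matrix(normalized, counts$feature_meta)
  list(factors = fac, normalized = normalized, ref_column = ref)
}

## single-pair TMM factor, the trim-and-weight rule itself
tmm_pair_factor <- function(obs, ref, n_obs, n_ref, logratio_trim, sum_trim) {
  M <- log2((obs / n_obs) / (ref / n_ref))
  A <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(M) & is.finite(A) & A > -1e10
  M <- M[fin]; A <- A[fin]; w <- w[fin]
  if (!length(M) || max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * sum_trim) + 1;      hiA <- n + 1 - loA
  keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  f <- sum(M[keep] / w[keep], na.rm = TRUE) / sum(1 / w[keep], na.rm = TRUE)
  if (!is.finite(f)) f <- 0
  2^f
}

#' Rank-based inverse normal transformation
#'
#' Maps values to `qnorm((rank - offset) / n)` with average ranks for ties
#' (all-tied vectors map to 0). `offset = 0.5` matches the convention of the
#' standard cis-QTL mapping tools; `offset = 3/8` with denominator `n + 1/4`
#' gives Blom scores.
#'
#' @param x numeric vector (one feature across samples).
#' @param offset rank offset; 0.5 (default) or 3/8 for Blom.
#' @return transformed vector, mean ~0 and symmetric.
#' @export
inverse_normal_transform <- function(x, offset = 0.5) {
  check_that(length(x) > 0, "empty vector")
  n <- length(x)
  if (length(unique(x)) == 1L) return(rep(0, n))
  r <- rank(x, ties.method = "average")
  denom <- if (isTRUE(all.equal(offset, 3 / 8))) n + 0.25 else n
  qnorm((r - offset) / denom)
}

#' Apply the inverse normal transform to every row of a matrix
#' @param mat numeric matrix or `PhenotypeMatrix` (features x samples).
#' @inheritParams inverse_normal_transform
#' @return object of the same type with transformed rows.
#' @export
int_rows <- function(mat, offset = 0.5) {
  if (inherits(mat, "PhenotypeMatrix")) {
    mat$values <- int_rows(mat$values, offset)
    return(mat)
  }
  t(apply(mat, 1L, inverse_normal_transform, offset = offset))
}

#' Percent-spliced-in computation and the splicing feature filters
#'
#' PSI = intron count / cluster total per sample. Filters, applied in order:
#' (1) drop introns with zero count in strictly more than half the samples;
#' (2) drop introns with fewer than `max(10, 0.1 n)` unique PSI values;
#' (3) drop "low-complexity" introns: with z-scores `z_i` of the intron's
#' cluster read fraction across individuals, drop when both
#' `sum(|z_i| < 0.25) >= n - 3` and `sum(|z_i| > 6) <= 3` hold;
#' (4) drop clusters reduced below two introns. Samples with a zero cluster
#' total have undefined PSI: they are imputed to the intron's mean over
#' defined samples and flagged. Surviving rows are z-scored, inverse-normal
#' transformed, and assigned the owning gene's TSS as their coordinate.
#'
#' @param intron_counts `PhenotypeMatrix` of intron counts with cluster ids in
#'   `group_id` and owning genes in `gene_id`.
#' @param int_transform apply the inverse normal transform after z-scoring.
#' @return list: `psi` (filtered, standardized `PhenotypeMatrix`),
#'   `psi_raw` (unstandardized PSI of surviving introns), `filter_log`
#'   (data.table feature_id, rule) and `imputed` (logical matrix of imputed
#'   cells for surviving introns).
#' @export
compute_psi_and_filter <- function(intron_counts, int_transform = TRUE) {
  stopifnot(inherits(intron_counts, "PhenotypeMatrix"))
  meta <- intron_counts$feature_meta
  check_that(all(table(meta$group_id) >= 2), "clusters must contain >= 2 introns")
  x <- intron_counts$values
  n <- ncol(x)
  tot <- rowsum(x, meta$group_id)[as.character(meta$group_id), , drop = FALSE]
  psi <- x / tot
  missing_cells <- tot == 0
  frac_psi <- psi                                 # cluster read fraction == PSI here
  log_rules <- list()
  drop <- rep(FALSE, nrow(x))

  ## (1) zero count in > 50% of samples
  r1 <- rowMeans(x == 0) > 0.5
  ## (2) unique-value floor max(10, 0.1 n) on defined PSI values
  uniq <- apply(psi, 1L, function(v) length(unique(v[is.finite(v)])))
  r2 <- uniq < max(10, 0.1 * n)
  ## (3) low complexity on z-scores of the cluster read fraction
  r3 <- vapply(seq_len(nrow(x)), function(i) {
    v <- frac_psi[i, ]; v[!is.finite(v)] <- mean(v[is.finite(v)])
    s <- sd(v)
    z <- if (is.na(s) || s == 0) rep(0, n) else (v - mean(v)) / s
    sum(abs(z) < 0.25) >= n - 3 && sum(abs(z) > 6) <= 3
  }, logical(1))
  for (nm in c("r1", "r2", "r3")) {
    hit <- get(nm) & !drop
    rule <- c(r1 = "zero_in_most_samples", r2 = "too_few_unique_values",
              r3 = "low_complexity")[[nm]]
    if (any(hit))
      log_rules[[nm]] <- data.table::data.table(
        feature_id = meta$feature_id[hit], rule = rule)
    drop <- drop | get(nm)
  }
  ## (4) clusters reduced below 2 introns
  surv <- meta$group_id[!drop]
  small <- names(which(table(surv) < 2))
  r4 <- !drop & meta$group_id %in% small
  if (any(r4))
    log_rules$r4 <- data.table::data.table(feature_id = meta$feature_id[r4],
                                           rule = "cluster_below_two")
  drop <- drop | r4

  keep <- which(!drop)
  check_that(length(keep) > 0, "all introns filtered out")
  psi_k <- psi[keep, , drop = FALSE]
  imput <- missing_cells[keep, , drop = FALSE]
  for (i in seq_len(nrow(psi_k))) {
    bad <- !is.finite(psi_k[i, ])
    if (any(bad)) psi_k[i, bad] <- mean(psi_k[i, !bad])
  }
  std <- t(apply(psi_k, 1L, function(v) {
    s <- sd(v); if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  if (int_transform) std <- int_rows(std)
  dimnames(std) <- dimnames(psi_k)
  meta_k <- data.table::copy(meta[keep])
  ## splicing phenotypes inherit the owning gene's TSS coordinate
  meta_k[, `:=`(start = tss - 1L, end = tss)]
  list(psi = new_phenotype_matrix(std, meta_k),
       psi_raw = psi_k,
       filter_log = if (length(log_rules)) data.table::rbindlist(log_rules)
                    else data.table::data.table(feature_id = character(), rule = character()),
       imputed = imput)
}

#' Estimate hidden expression confounders (probabilistic-PCA surrogate)
#'
#' Returns the top `k` sample-space factors of the feature-standardized
#' expression matrix, ranked by explained variance, with per-factor relative
#' weights. This is a deterministic surrogate for variational factor models
#' (PEER-like tools): downstream mapping only consumes the factor matrix, and
#' for covariate correction the PCA subspace is what matters.
#'
#' @param expression `PhenotypeMatrix` or features x samples matrix
#'   (normalized scale).
#' @param k number of factors; must be < min(features, samples).
#' @return list: `factors` (samples x k, orthonormal columns), `weights`
#'   (relative explained variance per factor).
#' @export
estimate_hidden_factors <- function(expression, k = 10L) {
  x <- if (inherits(expression, "PhenotypeMatrix")) expression$values else expression
  check_that(k >= 1 && k < min(dim(x)),
             "k must satisfy 1 <= k < min(features, samples)")
  xs <- t(apply(x, 1L, function(v) {
    s <- sd(v); if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  sv <- svd(xs, nu = 0, nv = k)
  fac <- sv$v
  ## deterministic sign: largest-magnitude coordinate positive
  for (j in seq_len(ncol(fac))) {
    i <- which.max(abs(fac[, j]))
    if (fac[i, j] < 0) fac[, j] <- -fac[, j]
  }
  dimnames(fac) <- list(colnames(x), sprintf("factor%02d", seq_len(k)))
  list(factors = fac, weights = sv$d[seq_len(k)]^2 / sum(sv$d^2))
}

#' Genotype principal components for population structure
#'
#' Computes PCs of the standardized dosage matrix. Mirroring common practice
#' for cohort-size-dependent covariate counts, 5 PCs are returned for cohorts
#' below 200 samples and 10 for larger ones (capped at matrix rank).
#'
#' @param genotypes `GenotypeMatrix` or samples x variants dosage matrix.
#' @param n_pcs explicit override of the PC count.
#' @return samples x PCs matrix with orthonormal columns.
#' @export
genotype_pcs <- function(genotypes, n_pcs = NULL) {
  g <- if (inherits(genotypes, "GenotypeMatrix")) genotypes$dosage else genotypes
  check_that(nrow(g) >= 2, "need at least two samples")
  poly <- apply(g, 2L, function(v) var(v) > 0)
  check_that(sum(poly) >= 2, "need at least two polymorphic variants")
  gs <- standardize_cols(g[, poly, drop = FALSE])
  k <- n_pcs %||% if (nrow(g) < 200) 5L else 10L
  k <- min(k, nrow(g) - 1L, sum(poly))
  sv <- svd(gs, nu = k, nv = 0)
  pcs <- sv$u
  for (j in seq_len(ncol(pcs))) {
    i <- which.max(abs(pcs[, j]))
    if (pcs[i, j] < 0) pcs[, j] <- -pcs[, j]
  }
  dimnames(pcs) <- list(rownames(g), sprintf("PC%02d", seq_len(k)))
  pcs
}

#' Variance of known covariates explained by hidden factors
#'
#' Regresses each known covariate on all hidden factors jointly and reports
#' the coefficient of determination.
#'
#' @param factors samples x k factor matrix.
#' @param known samples x c matrix/data.frame of known covariates.
#' @return named vector of R-squared values in `[0, 1]`; constant covariates
#'   yield `NA` with a warning.
#' @export
covariate_variance_explained <- function(factors, known) {
  known <- as.matrix(known)
  check_that(nrow(factors) == nrow(known), "sample sets differ")
  vapply(seq_len(ncol(known)), function(j) {
    y <- known[, j]
    if (sd(y) == 0) { warning("constant known covariate: column ", j); return(NA_real_) }
    fit <- lm.fit(cbind(1, factors), y)
    1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  }, numeric(1)) |> setNames(colnames(known) %||% paste0("cov", seq_len(ncol(known))))
}

#' Tissue-specificity index (tau)
#'
#' Yanai's tau on log-scaled per-tissue expression:
#' `tau = sum(1 - x_i / max(x)) / (N - 1)`; 0 for ubiquitous genes, 1 for
#' single-tissue genes.
#'
#' @param med_expr genes x tissues matrix of per-tissue median expression
#'   (linear scale, non-negative).
#' @param log_transform apply `log2(x + 1)` first (default TRUE).
#' @return named vector of tau values in `[0, 1]`; all-zero genes yield `NA`.
#' @export
tau_specificity <- function(med_expr, log_transform = TRUE) {
  check_that(ncol(med_expr) >= 2, "need at least two tissues")
  check_that(all(med_expr >= 0), "expression must be non-negative")
  x <- if (log_transform) log2(med_expr + 1) else med_expr
  apply(x, 1L, function(v) {
    m <- max(v)
    if (m == 0) return(NA_real_)
    sum(1 - v / m) / (length(v) - 1)
  })
}
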