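#' Fixed-effect meta-analysis of per-tissue effect estimates
#'
#' Inverse-variance-weighted mean of the per-tissue slopes:
#' `b_meta = sum(b_t / se_t^2) / sum(1 / se_t^2)`, `se_meta =
#' sqrt(1 / sum(1 / se_t^2))`.
#'
#' @param slopes,ses numeric vectors, one entry per tissue (`ses > 0`).
#' @return list: slope, se, z, p.
#' @export
fixed_effect_meta <- function(slopes, ses) {
  check_that(length(slopes) == length(ses) && all(ses > 0),
             "slopes/ses must align and ses must be positive")
  if (length(slopes) == 1L)
    warning("single-tissue input: fixed-effect meta is a passthrough")
  w <- 1 / ses^2
  b <- sum(w * slopes) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- b / se
  list(slope = b, se = se, z = z, p = 2 * pnorm(-abs(z)))
}

## log marginal likelihood ratio (BF) for an activity configuration under the
## shared-effect model: active tissues observe b_t = mu + e_t with
## mu ~ N(0, sigma0^2) and e_t ~ N(0, se_t^2); inactive tissues are null.
## Sherman-Morrison closed form on the diagonal-plus-rank-one covariance.
config_log_bf <- function(b, se, active, sigma0) {
  if (!any(active)) return(0)
  ba <- b[active]; va <- se[active]^2
  s <- sum(1 / va)
  m <- sum(ba / va)
  ## log N(b; 0, D + s0^2 11') - log N(b; 0, D)
  -0.5 * log1p(sigma0^2 * s) + 0.5 * sigma0^2 * m^2 / (1 + sigma0^2 * s)
}

#' Posterior tissue-activity probabilities (m-values)
#'
#' Posterior probability that a QTL effect exists in each tissue, marginalized
#' over all 2^T activity configurations. Active tissues share a common effect
#' with prior `N(0, prior_effect_sd^2)`; each configuration's prior is
#' `prior_active^k (1-prior_active)^(T-k)`. Exact enumeration for
#' `T <= max_exact_tissues`; above that, self-normalized importance sampling
#' with an independent-Bernoulli proposal built from single-tissue posteriors.
#' A tissue with m-value > 0.7 is flagged active, the conventional cutoff.
#'
#' @param slopes,ses per-tissue effect estimates and standard errors.
#' @param prior_effect_sd prior sd of the shared effect (default 0.2).
#' @param prior_active prior activity probability per tissue (default 0.5).
#' @param max_exact_tissues enumeration limit (default 12).
#' @param n_samples importance-sampling draws when above the limit.
#' @param seed seed for the sampling path.
#' @param force_exact force enumeration regardless of T (for validation).
#' @return list: `m` (per-tissue m-values in `[0,1]`), `active` (m > 0.7),
#'   `meta` (the [fixed_effect_meta()] result), `method`.
#' @export
m_values <- function(slopes, ses, prior_effect_sd = 0.2, prior_active = 0.5,
                     max_exact_tissues = 12L, n_samples = 20000L, seed = 1L,
                     force_exact = FALSE) {
  check_that(prior_effect_sd > 0, "prior_effect_sd must be positive")
  check_that(length(slopes) >= 2, "need at least two tissues")
  T <- length(slopes)
  meta <- fixed_effect_meta(slopes, ses)
  if (T <= max_exact_tissues || force_exact) {
    configs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), T)))
    logw <- apply(configs, 1L, function(a)
      config_log_bf(slopes, ses, a, prior_effect_sd) +
        sum(a) * log(prior_active) + (T - sum(a)) * log(1 - prior_active))
    w <- exp(logw - logsumexp(logw))
    m <- as.numeric(crossprod(configs, w))
    method <- "exact"
  } else {
    ## proposal: per-tissue posterior under a single-tissue model
    lbf1 <- vapply(seq_len(T), function(t)
      config_log_bf(slopes[t], ses[t], TRUE, prior_effect_sd), numeric(1))
    q <- prior_active * exp(lbf1) / (prior_active * exp(lbf1) + 1 - prior_active)
    q <- pmin(pmax(q, 0.05), 0.95)
    with_seed(seed, {
      A <- matrix(runif(n_samples * T) < rep(q, each = n_samples), n_samples, T)
      logw <- vapply(seq_len(n_samples), function(s) {
        a <- A[s, ]
        config_log_bf(slopes, ses, a, prior_effect_sd) +
          sum(a) * log(prior_active) + (T - sum(a)) * log(1 - prior_active) -
          sum(ifelse(a, log(q), log(1 - q)))
      }, numeric(1))
    })
    w <- exp(logw - logsumexp(logw))
    m <- as.numeric(crossprod(A, w))
    method <- "importance_sampling"
  }
  names(m) <- names(slopes)
  list(m = m, active = m > 0.7, meta = meta, method = method)
}

#' Pairwise cross-tissue correlation of QTL effect sizes
#'
#' Spearman correlation of effect estimates between every tissue pair,
#' computed over the feature-variant pairs significant in at least one tissue
#' of the pair (`mask_mode = "either"`), in both (`"both"`), or over all
#' shared pairs (`"all"`).
#'
#' @param effects matrix of effect sizes, rows = feature-variant pairs,
#'   columns = tissues (NA where untested).
#' @param significant logical matrix of the same shape.
#' @param mask_mode which pairs enter each correlation.
#' @param min_pairs minimum overlapping pairs; smaller overlaps yield NA.
#' @return symmetric tissue x tissue correlation matrix with unit diagonal.
#' @export
pairwise_effect_correlation <- function(effects, significant = NULL,
                                        mask_mode = c("either", "both", "all"),
                                        min_pairs = 2L) {
  mask_mode <- match.arg(mask_mode)
  Tn <- ncol(effects)
  if (is.null(significant)) significant <- matrix(TRUE, nrow(effects), Tn)
  out <- diag(1, Tn)
  dimnames(out) <- list(colnames(effects), colnames(effects))
  for (a in seq_len(Tn - 1)) for (b in (a + 1):Tn) {
    use <- complete.cases(effects[, c(a, b)])
    use <- use & switch(mask_mode,
                        either = significant[, a] | significant[, b],
                        both = significant[, a] & significant[, b],
                        all = TRUE)
    out[a, b] <- out[b, a] <- if (sum(use) >= min_pairs)
      suppressWarnings(cor(effects[use, a], effects[use, b], method = "spearman"))
    else NA_real_
  }
  out
}

#' Storey's pi1 replication statistic
#'
#' Estimates the fraction of true positives among replication p-values as
#' `1 - pi0`, with `pi0(lambda) = #[p > lambda] / (m (1 - lambda))` evaluated
#' on a lambda grid, smoothed by an inverse-variance-weighted cubic
#' polynomial (weights proportional to `1 - lambda`, each grid point's
#' binomial precision) and read off at the largest lambda, then clipped to
#' `[0, 1]`.
#'
#' @param p replication p-values of discovery-set hits.
#' @param lambda_grid grid of lambda values (default 0.05 to 0.95 by 0.05).
#' @return pi1 estimate in `[0, 1]`.
#' @export
pi1 <- function(p, lambda_grid = seq(0.05, 0.95, by = 0.05)) {
  check_that(length(p) > 0, "empty p-value vector")
  if (length(p) < 100) warning("pi1 is unstable below ~100 p-values")
  m <- length(p)
  pi0_l <- vapply(lambda_grid, function(l) sum(p > l) / (m * (1 - l)), numeric(1))
  fit <- lm(pi0_l ~ poly(lambda_grid, 3, raw = TRUE), weights = 1 - lambda_grid)
  pi0 <- unname(predict(fit, data.frame(lambda_grid = max(lambda_grid))))
  1 - min(max(pi0, 0), 1)
}

#' Unadjusted (or adjusted) Rand index between two clusterings
#'
#' Fraction of object pairs on which the two clusterings agree (same cluster
#' in both, or different in both).
#'
#' @param a,b integer/factor cluster labels of the same objects.
#' @param adjusted return the chance-corrected adjusted Rand index instead.
#' @return scalar in `[0, 1]` (adjusted version can be negative).
#' @export
rand_index <- function(a, b, adjusted = FALSE) {
  check_that(length(a) == length(b), "label vectors differ in length")
  tab <- table(a, b)
  n <- length(a)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  total <- ch2(n)
  if (!adjusted)
    return((total + 2 * sum_ij - sum_a - sum_b) / total)
  exp_ij <- sum_a * sum_b / total
  (sum_ij - exp_ij) / ((sum_a + sum_b) / 2 - exp_ij)
}

#' Clustering similarity across data types
#'
#' For each k in `k_range`, k-means-clusters the objects (tissues) of every
#' data matrix (seeded, `nstart` restarts, best inertia kept) and computes the
#' Rand index between every pair of data types; reports the median over k.
#'
#' @param matrices named list of objects x variables matrices sharing rows.
#' @param k_range candidate cluster counts (default 2:20; k >= n_objects is
#'   skipped with a warning).
#' @param nstart k-means restarts per k (default 50).
#' @param seed integer seed.
#' @param adjusted use the adjusted Rand index.
#' @return list: `median_rand` (data-type x data-type matrix of median Rand
#'   indices) and `per_k` (data.table type_a, type_b, k, rand).
#' @export
clustering_similarity <- function(matrices, k_range = 2:20, nstart = 50L,
                                  seed = 1L, adjusted = FALSE) {
  nm <- names(matrices) %||% paste0("type", seq_along(matrices))
  n_obj <- nrow(matrices[[1]])
  check_that(all(vapply(matrices, nrow, integer(1)) == n_obj),
             "all matrices must share objects (rows)")
  usable <- k_range[k_range < n_obj]
  if (length(usable) < length(k_range))
    warning("skipping k >= number of objects: ",
            paste(setdiff(k_range, usable), collapse = ", "))
  ## seed depends on k only, so identical matrices yield identical labels
  labels <- lapply(matrices, function(mat)
    lapply(usable, function(k)
      with_seed(child_seed(seed, k),
                kmeans(mat, centers = k, nstart = nstart,
                       iter.max = 100)$cluster)))
  per_k <- list()
  for (a in seq_along(matrices)) for (b in seq_along(matrices)) {
    if (a >= b) next
    for (ki in seq_along(usable))
      per_k[[length(per_k) + 1L]] <- data.table::data.table(
        type_a = nm[a], type_b = nm[b], k = usable[ki],
        rand = rand_index(labels[[a]][[ki]], labels[[b]][[ki]], adjusted))
  }
  per_k <- data.table::rbindlist(per_k)
  med <- diag(1, length(matrices))
  dimnames(med) <- list(nm, nm)
  for (r in seq_len(nrow(per_k))) {
    i <- match(per_k$type_a[r], nm); j <- match(per_k$type_b[r], nm)
    med[i, j] <- med[j, i] <- median(per_k$rand[per_k$type_a == nm[i] &
                                                  per_k$type_b == nm[j]])
  }
  list(median_rand = med, per_k = per_k)
}
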