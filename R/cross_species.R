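#' Cross-species correlation of TWAS effect sizes over orthologs
#'
#' Pearson correlation of absolute (default) TWAS effect sizes across
#' one-to-one orthologous genes, with a permutation null obtained by
#' shuffling the ortholog map (preserving each species' marginal effect
#' distribution). Genes with an effect in only one species are excluded
#' (complete-case).
#'
#' @param twas_a,twas_b TWAS tables (gene_id, effect, ...).
#' @param map `OrthologMap` data.table (gene_a, gene_b, strictly one-to-one).
#' @param n_perm permutations (default 1000).
#' @param seed integer seed.
#' @param absolute correlate |effect| (default) or signed effects.
#' @param min_genes minimum mapped genes; below this the pair is flagged
#'   untested (default 30).
#' @return list: r, p_perm, n_genes, tested.
#' @export
ortholog_effect_correlation <- function(twas_a, twas_b, map, n_perm = 1000L,
                                        seed = 1L, absolute = TRUE,
                                        min_genes = 30L) {
  check_that(!anyDuplicated(map$gene_a) && !anyDuplicated(map$gene_b),
             "ortholog map must be one-to-one")
  ea <- twas_a$effect[match(map$gene_a, twas_a$gene_id)]
  eb <- twas_b$effect[match(map$gene_b, twas_b$gene_id)]
  ok <- is.finite(ea) & is.finite(eb)
  ea <- ea[ok]; eb <- eb[ok]
  if (length(ea) < min_genes)
    return(list(r = NA_real_, p_perm = NA_real_, n_genes = length(ea),
                tested = FALSE))
  if (absolute) { ea <- abs(ea); eb <- abs(eb) }
  r_obs <- cor(ea, eb)
  r_null <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    cor(ea, eb[sample.int(length(eb))]), numeric(1)))
  list(r = r_obs,
       p_perm = (1 + sum(abs(r_null) >= abs(r_obs))) / (1 + n_perm),
       n_genes = length(ea), tested = TRUE)
}

#' Run ortholog effect correlations over many trait-tissue pairs with BH FDR
#'
#' @param pairs list of lists, each with `twas_a`, `twas_b`, `map` and an
#'   optional `label`.
#' @param fdr FDR level across pairs (default 0.10).
#' @inheritParams ortholog_effect_correlation
#' @return data.table: label, r, p_perm, n_genes, tested, q, significant.
#' @export
ortholog_correlation_table <- function(pairs, n_perm = 1000L, seed = 1L,
                                       fdr = 0.10, absolute = TRUE) {
  out <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    res <- ortholog_effect_correlation(pr$twas_a, pr$twas_b, pr$map,
                                       n_perm = n_perm,
                                       seed = child_seed(seed, i),
                                       absolute = absolute)
    data.table::data.table(label = pr$label %||% sprintf("pair%02d", i),
                           r = res$r, p_perm = res$p_perm,
                           n_genes = res$n_genes, tested = res$tested)
  })
  res <- data.table::rbindlist(out)
  res[, q := NA_real_]
  res[tested == TRUE, q := p.adjust(p_perm, method = "BH")]
  res[, significant := !is.na(q) & q < fdr]
  res[]
}

#' Effective sample size of a case-control GWAS
#'
#' `n_eff = 4 / (1/n_cases + 1/n_controls)`.
#'
#' @param n_cases,n_controls positive counts.
#' @return effective sample size.
#' @export
effective_sample_size <- function(n_cases, n_controls) {
  check_that(all(n_cases > 0) && all(n_controls > 0),
             "case and control counts must be positive")
  4 / (1 / n_cases + 1 / n_controls)
}

#' Cross-species meta-TWAS
#'
#' Combines per-gene TWAS z-statistics from two species with sample-size
#' weights: `z_meta = (n_a z_a + n_b z_b) / sqrt(n_a^2 + n_b^2)`. The weight
#' vector has unit norm, so z_meta is standard normal under the joint null
#' for any sample sizes. Case-control cohorts should pass
#' [effective_sample_size()] as n. Genes present in only one species are
#' skipped (logged in attribute `skipped`).
#'
#' @param twas_a,twas_b TWAS tables with gene_id, z, n.
#' @param map `OrthologMap`.
#' @param fdr BH FDR level across genes (default 0.05).
#' @return data.table: gene_a, gene_b, z_a, z_b, z_meta, p, q, significant.
#' @export
meta_twas <- function(twas_a, twas_b, map, fdr = 0.05) {
  ia <- match(map$gene_a, twas_a$gene_id)
  ib <- match(map$gene_b, twas_b$gene_id)
  ok <- !is.na(ia) & !is.na(ib) & is.finite(twas_a$z[ia]) & is.finite(twas_b$z[ib])
  skipped <- map$gene_a[!ok]
  za <- twas_a$z[ia[ok]]; zb <- twas_b$z[ib[ok]]
  na <- as.numeric(twas_a$n[ia[ok]]); nb <- as.numeric(twas_b$n[ib[ok]])
  denom <- sqrt(na^2 + nb^2)
  check_that(all(denom > 0), "both sample sizes zero for some gene")
  zm <- (na * za + nb * zb) / denom
  out <- data.table::data.table(
    gene_a = map$gene_a[ok], gene_b = map$gene_b[ok],
    z_a = za, z_b = zb, z_meta = zm, p = 2 * pnorm(-abs(zm)))
  out[, q := p.adjust(p, method = "BH")]
  out[, significant := q < fdr]
  data.table::setattr(out, "skipped", skipped)
  out[]
}

#' Genes gained or lost by cross-species meta-TWAS
#'
#' Compares meta-TWAS calls against single-species calls on the same gene
#' universe at the same FDR: `gain` = significant in meta only, `loss` =
#' significant in the single-species analysis only.
#'
#' @param meta a [meta_twas()] result.
#' @param single data.table with gene_id (matching `meta$gene_b` by default)
#'   and p (or q).
#' @param fdr FDR level (default 0.05).
#' @param by which meta column the single-species gene ids match.
#' @return list: gain, loss (character vectors), n_gain, n_loss.
#' @export
concordant_gain_analysis <- function(meta, single, fdr = 0.05, by = "gene_b") {
  check_that(setequal(meta[[by]], single$gene_id),
             "meta and single-species results cover different gene universes")
  sq <- if ("q" %in% names(single)) single$q else p.adjust(single$p, "BH")
  ssig <- single$gene_id[sq < fdr]
  msig <- meta[[by]][meta$significant]
  list(gain = setdiff(msig, ssig), loss = setdiff(ssig, msig),
       n_gain = length(setdiff(msig, ssig)), n_loss = length(setdiff(ssig, msig)))
}
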