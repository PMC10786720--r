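#' Run the full molQTL pipeline on a seeded toy world
#'
#' End-to-end orchestration on synthetic data: genotypes -> phenotype
#' preparation -> cis-QTL mapping with permutations and two-layer FDR ->
#' conditional signals and aFC -> a second tissue sharing half the planted
#' effects -> multi-tissue statistics (meta, m-values, pi1, effect
#' correlation) -> GWAS simulation with causal variants shared with planted
#' QTL -> locus definition, colocalization and tissue relevance ->
#' cross-species ortholog correlation and meta-TWAS. Fully deterministic
#' given `seed`.
#'
#' @param seed integer master seed.
#' @param n_samples cohort size (default 200).
#' @param n_variants marker count (default 400).
#' @param n_genes expression features (default 40).
#' @param max_perm permutations per feature (default 1000).
#' @param n_coloc_genes planted QTL whose variants also drive the GWAS trait
#'   (default 3).
#' @return list with every intermediate product and the truth ledgers; see
#'   the README for a walk-through.
#' @export
run_toy_pipeline <- function(seed = 1L, n_samples = 200L, n_variants = 400L,
                             n_genes = 40L, max_perm = 1000L,
                             n_coloc_genes = 3L) {
  cfg <- sim_config(n_samples = n_samples, n_variants = n_variants,
                    n_features_per_kind = c(gene = n_genes, intron_cluster = 10L),
                    effect_size_dist = list(mean = 0, sd = 1.2),
                    seed = seed)
  geno <- simulate_genotypes(cfg)
  sim1 <- simulate_molecular_phenotypes(geno, cfg, n_qtl = floor(n_genes / 3),
                                        tissue = "tissueA")
  ## second tissue: same features, half the planted QTL shared
  shared <- sim1$truth$planted_qtl[seq_len(ceiling(nrow(sim1$truth$planted_qtl) / 2))]
  sim2 <- simulate_molecular_phenotypes(
    geno, cfg,
    qtl_features = match(shared$feature_id,
                         sim1$phenotypes$feature_meta$feature_id),
    qtl_variants = shared$variant_id, effect_sizes = shared$slope,
    tissue = "tissueB", seed = child_seed(seed, "tissueB"))
  ## tissue B reuses tissue A's feature coordinates so ids stay joinable
  sim2$phenotypes$feature_meta <- sim1$phenotypes$feature_meta
  introns <- simulate_intron_clusters(geno, cfg)

  prep_tissue <- function(sim) {
    counts <- sim$phenotypes
    tpm <- tpm_from_counts(counts)
    keep <- filter_lowly_expressed(tpm, counts)
    counts <- subset_features(counts, keep)
    tmm <- tmm_normalize(counts)
    expr <- int_rows(tmm$normalized)
    fac <- estimate_hidden_factors(expr, k = 5L)
    pcs <- genotype_pcs(geno)
    cov <- cbind(pcs, fac$factors)
    list(counts = counts, expr = expr, covariates = cov)
  }
  prepA <- prep_tissue(sim1)
  prepB <- prep_tissue(sim2)

  map_tissue <- function(prep, label) {
    perm <- permutation_pass(geno, prep$expr, prep$covariates,
                             max_perm = max_perm,
                             seed = child_seed(seed, paste0("perm", label)))
    calls <- call_egenes(perm)
    nominal <- nominal_scan(geno, prep$expr, prep$covariates)
    list(perm = perm, calls = calls, nominal = nominal)
  }
  mapA <- map_tissue(prepA, "A")
  mapB <- map_tissue(prepB, "B")

  cond <- conditional_scan(geno, prepA$expr, prepA$covariates, mapA$calls)
  leads <- mapA$calls[egene == TRUE, .(feature_id, variant_id = lead_variant)]
  afc <- if (nrow(leads)) estimate_afc(prepA$counts, geno, leads,
                                       prepA$covariates) else NULL

  ## splicing arm
  psi <- compute_psi_and_filter(introns$phenotypes)
  sqtl <- grouped_permutation_pass(geno, psi$psi, prepA$covariates,
                                   max_perm = max_perm,
                                   seed = child_seed(seed, "sqtl"))
  sqtl_calls <- call_egenes(sqtl)

  ## multi-tissue statistics on shared lead pairs
  pairs_meta <- merge(
    mapA$calls[, .(feature_id, lead_variant, slope_a = slope, p_a = p_beta)],
    mapB$calls[, .(feature_id, slope_b = slope, p_b = p_beta)],
    by = "feature_id")
  mt <- lapply(seq_len(nrow(pairs_meta)), function(i) {
    key_a <- mapA$nominal[feature_id == pairs_meta$feature_id[i] &
                            variant_id == pairs_meta$lead_variant[i]]
    key_b <- mapB$nominal[feature_id == pairs_meta$feature_id[i] &
                            variant_id == pairs_meta$lead_variant[i]]
    if (!nrow(key_a) || !nrow(key_b)) return(NULL)
    mv <- m_values(c(A = key_a$slope, B = key_b$slope),
                   c(key_a$slope_se, key_b$slope_se),
                   seed = child_seed(seed, paste0("mv", i)))
    data.table::data.table(feature_id = pairs_meta$feature_id[i],
                           m_a = mv$m[1], m_b = mv$m[2],
                           meta_p = mv$meta$p)
  })
  mt <- data.table::rbindlist(mt)
  hitsA <- mapA$calls[egene == TRUE]
  rep_p <- mapB$calls[match(hitsA$feature_id, feature_id), p_beta]
  pi1_ab <- if (sum(is.finite(rep_p)) >= 5)
    suppressWarnings(pi1(rep_p[is.finite(rep_p)])) else NA_real_
  eff <- merge(mapA$nominal[, .(key = paste(feature_id, variant_id),
                                slope_a = slope)],
               mapB$nominal[, .(key = paste(feature_id, variant_id),
                                slope_b = slope)], by = "key")
  sharing_cor <- suppressWarnings(
    cor(eff$slope_a, eff$slope_b, method = "spearman"))

  ## GWAS with causal variants shared with the strongest planted QTL,
  ## greedily spaced > 1.2 Mb apart so each causal defines its own locus
  pq <- sim1$truth$planted_qtl[order(-abs(slope))]
  pq[, `:=`(chrom = sub(":.*", "", variant_id),
            pos = as.integer(sub("^[^:]+:([0-9]+):.*", "\\1", variant_id)))]
  sel <- integer(0)
  for (i in seq_len(nrow(pq))) {
    if (length(sel) >= n_coloc_genes) break
    ok <- all(pq$chrom[sel] != pq$chrom[i] |
                abs(pq$pos[sel] - pq$pos[i]) > 1.2e6)
    if (ok) sel <- c(sel, i)
  }
  causal <- pq[sel]
  gwas_sim <- lapply(1:2, function(k)
    simulate_gwas_cohort(geno,
                         causal_spec = data.table::data.table(
                           variant_id = causal$variant_id,
                           effect = sign(causal$slope)),
                         n_gwas = 4000, h2_locus = 0.05,
                         seed = child_seed(seed, paste0("gwas", k)),
                         trait_id = "toyTrait", shared_with_qtl = TRUE))
  gwas <- meta_gwas(lapply(gwas_sim, `[[`, "gwas"))
  loci <- define_loci(gwas)

  ## colocalize each locus against each eGene's cis z-scores
  coloc <- list()
  for (li in seq_len(nrow(loci))) {
    mem <- loci$members[[li]]
    ## widen single-member loci with their LD neighborhood for a usable region
    if (length(mem) < 5) {
      lv <- loci$lead_variant[li]
      lead_pos <- geno$variants[variant_id == lv]$pos
      mem <- union(mem, geno$variants[chrom == loci$chrom[li] &
                                        abs(pos - lead_pos) <= 2e5]$variant_id)
    }
    for (fi in hitsA$feature_id) {
      qz <- mapA$nominal[feature_id == fi][match(mem, variant_id)]
      ok <- is.finite(qz$tstat)
      if (sum(ok) < 5) next
      gz <- gwas$z[match(mem[ok], gwas$variant_id)]
      ld <- suppressWarnings(cor(geno$dosage[, mem[ok], drop = FALSE]))
      cl <- colocalize(gz, qz$tstat[ok], ld, n_gwas = gwas$n[1],
                       n_qtl = n_samples)
      coloc[[length(coloc) + 1L]] <- data.table::data.table(
        locus_id = loci$locus_id[li], feature_id = fi, rcp = cl$rcp,
        pp3 = cl$pp["PP3"])
    }
  }
  coloc <- data.table::rbindlist(coloc)
  n_coloc <- if (nrow(coloc)) length(unique(coloc[rcp > 0.9]$feature_id)) else 0L
  relevance <- tissue_relevance(data.table::data.table(
    tissue = "tissueA", n_coloc = n_coloc, n_samples = n_samples,
    egene_prop = max(mean(mapA$calls$egene), 1e-6)))

  ## cross-species arm
  xs <- simulate_ortholog_twas_pair(2000, 0.5, seed = child_seed(seed, "xsp"))
  xcor <- ortholog_effect_correlation(xs$twas_a, xs$twas_b, xs$map,
                                      n_perm = 200,
                                      seed = child_seed(seed, "xcor"))
  mtw <- meta_twas(xs$twas_a, xs$twas_b, xs$map)

  list(config = cfg, genotypes = geno, truth = sim1$truth,
       truth_b = sim2$truth, introns = introns,
       prepA = prepA, prepB = prepB, mapA = mapA, mapB = mapB,
       conditional = cond, afc = afc, psi = psi, sqtl_calls = sqtl_calls,
       multi_tissue = list(m_values = mt, pi1 = pi1_ab,
                           sharing_cor = sharing_cor),
       gwas = gwas, loci = loci, coloc = coloc, relevance = relevance,
       causal = causal,
       cross_species = list(correlation = xcor, meta = mtw))
}
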