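#' Simulation configuration for the synthetic molQTL world
#'
#' Bundles every knob of the synthetic-data generators: cohort size, marker
#' panel, breed structure, LD decay, hidden confounders and planted effect
#' sizes. Defaults describe a two-breed, two-chromosome toy cohort that is
#' large enough for the downstream QTL machinery to behave like it does on
#' real data (MAF/MAC filters bite, LD is non-trivial, hidden factors inflate
#' naive scans) while staying desk-scale.
#'
#' @param n_samples number of diploid individuals (>= 20).
#' @param n_variants number of biallelic SNPs across all chromosomes (>= 10).
#' @param n_features_per_kind named integer vector; how many features of each
#'   kind (currently `gene` and `intron_cluster`) to simulate.
#' @param breed_proportions fractions per breed, summing to 1.
#' @param breed_af_drift per-breed allele-frequency drift magnitude; 0 gives a
#'   panmictic cohort, ~0.2 gives clearly separable breeds on PC1.
#' @param maf_range pair inside `[0.05, 0.5]`; population allele frequencies are
#'   drawn uniformly from this range.
#' @param ld_decay correlation half-distance in bp for the AR(1) haplotype
#'   model: latent correlation between adjacent markers is `exp(-d/ld_decay)`.
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param n_hidden_factors number of hidden confounders loaded onto phenotypes.
#' @param hidden_factor_sd standard deviation of hidden-factor loadings
#'   (log2 scale).
#' @param effect_size_dist list with `mean` and `sd` of planted cis slopes on
#'   the log2-per-allele (allelic fold change) scale.
#' @param noise_sd residual log2-scale biological noise.
#' @param baseline_log2_mean,baseline_log2_sd mean/sd of baseline log2
#'   expression across features.
#' @param seed integer seed fixing every generated byte.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples = 200L,
                       n_variants = 400L,
                       n_features_per_kind = c(gene = 40L, intron_cluster = 12L),
                       breed_proportions = c(Duroc = 0.5, Landrace = 0.5),
                       breed_af_drift = 0.1,
                       maf_range = c(0.1, 0.5),
                       ld_decay = 50e3,
                       chrom_lengths = c(chr1 = 2e6, chr2 = 2e6),
                       n_hidden_factors = 3L,
                       hidden_factor_sd = 0.3,
                       effect_size_dist = list(mean = 0, sd = 0.8),
                       noise_sd = 0.5,
                       baseline_log2_mean = 8,
                       baseline_log2_sd = 1,
                       seed = 1L) {
  check_that(length(breed_proportions) >= 1 && all(breed_proportions > 0),
             "breed_proportions must be a non-empty positive vector")
  check_that(abs(sum(breed_proportions) - 1) <= 1e-9,
             "breed_proportions must sum to 1 (got %.12f)", sum(breed_proportions))
  check_that(n_samples >= 20, "n_samples must be >= 20 (got %d)", n_samples)
  check_that(n_variants >= 10, "n_variants must be >= 10 (got %d)", n_variants)
  check_that(length(maf_range) == 2 && maf_range[1] <= maf_range[2] &&
               maf_range[1] >= 0 && maf_range[2] <= 0.5,
             "maf_range must be an increasing pair inside [0, 0.5]")
  check_that(all(chrom_lengths > 0), "chromosome lengths must be positive")
  check_that(ld_decay >= 0, "ld_decay must be non-negative")
  check_that(noise_sd > 0, "noise_sd must be positive")
  if (is.null(names(breed_proportions)))
    names(breed_proportions) <- paste0("breed", seq_along(breed_proportions))
  structure(list(
    n_samples = as.integer(n_samples), n_variants = as.integer(n_variants),
    n_features_per_kind = n_features_per_kind,
    breed_proportions = breed_proportions, breed_af_drift = breed_af_drift,
    maf_range = maf_range, ld_decay = ld_decay,
    chrom_lengths = chrom_lengths, n_hidden_factors = as.integer(n_hidden_factors),
    hidden_factor_sd = hidden_factor_sd,
    effect_size_dist = effect_size_dist, noise_sd = noise_sd,
    baseline_log2_mean = baseline_log2_mean, baseline_log2_sd = baseline_log2_sd,
    seed = as.integer(seed)), class = "sim_config")
}

## Gaussian-copula AR(1) haplotypes: latent z follows an AR(1) along each
## chromosome with step correlation exp(-d/ld_decay); allele = z < qnorm(freq).
## One latent chain per haplotype keeps haplotypes independent within a sample.
sample_haplotypes <- function(n_hap, freqs, pos, ld_decay) {
  m <- length(freqs)
  z <- matrix(rnorm(n_hap * m), n_hap, m)
  if (ld_decay > 0 && m > 1) {
    rho <- exp(-diff(pos) / ld_decay)
    for (j in 2:m)
      z[, j] <- rho[j - 1] * z[, j - 1] + sqrt(1 - rho[j - 1]^2) * z[, j]
  }
  thresh <- qnorm(pmin(pmax(freqs, 1e-6), 1 - 1e-6))
  matrix(as.integer(z < rep(thresh, each = n_hap)), n_hap, m)
}

#' Simulate multi-breed genotypes with LD and population structure
#'
#' Draws biallelic SNP dosages for a cohort of diploid individuals split into
#' discrete breeds. Population allele frequencies are drawn from
#' `config$maf_range` and drifted per breed by `breed_af_drift`, so genotype
#' principal components separate breeds. Within each haplotype, alleles follow
#' a Gaussian-copula AR(1) along the chromosome with latent correlation
#' `exp(-d / ld_decay)`, giving LD that decays with distance. Variants whose
#' realized MAF falls below 0.05 are resampled at a boosted frequency.
#'
#' @param config a [sim_config()].
#' @param cohort_seed optional separate seed for the individual draws; the
#'   variant panel (positions, per-breed frequencies) depends only on
#'   `config$seed`, so two calls with different `cohort_seed` yield
#'   independent cohorts on an identical panel (used for oracle GWAS
#'   cohorts).
#' @return a `GenotypeMatrix`: list with `dosage` (samples x variants integer
#'   matrix in 0/1/2), `variants` (data.table: variant_id, chrom, pos, ref,
#'   alt, maf) and `samples` (data.table: sample_id, breed, ancestry — a
#'   continuous ancestry proportion for the first breed).
#' @export
simulate_genotypes <- function(config, cohort_seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  nb <- length(config$breed_proportions)
  n <- config$n_samples
  L <- config$chrom_lengths
  ## panel: variant positions and per-breed frequencies, cohort-independent
  nv_chr <- pmax(1L, round(config$n_variants * L / sum(L)))
  nv_chr[length(nv_chr)] <- config$n_variants - sum(nv_chr[-length(nv_chr)])
  panel <- with_seed(child_seed(config$seed, "panel"), {
    lapply(seq_along(L), function(ci) {
      m <- nv_chr[ci]
      pos <- sort(sample.int(L[ci] - 1L, m))
      p0 <- runif(m, config$maf_range[1], config$maf_range[2])
      freqs <- vapply(seq_len(nb), function(b)
        pmin(pmax(p0 + runif(m, -config$breed_af_drift, config$breed_af_drift),
                  0.02), 0.98), numeric(m))
      list(pos = pos, freqs = matrix(freqs, nrow = m))
    })
  })
  with_seed(cohort_seed %||% child_seed(config$seed, "cohort"), {
    counts <- floor(config$breed_proportions * n)
    rem <- n - sum(counts)
    if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1
    breed <- rep(names(config$breed_proportions), counts)
    ## continuous ancestry proportion for breed 1 (e.g. "Duroc enrichment"):
    ## concentrated near 1 for breed-1 animals, near 0 otherwise
    ancestry <- ifelse(breed == names(config$breed_proportions)[1],
                       rbeta(n, 8, 2), rbeta(n, 2, 8))
    sample_ids <- sprintf("S%04d", seq_len(n))
    dosage <- matrix(0L, n, 0)
    vtab <- list()
    for (ci in seq_along(L)) {
      pos <- panel[[ci]]$pos; freqs <- panel[[ci]]$freqs
      m <- length(pos)
      d_chr <- matrix(0L, n, m)
      for (b in seq_len(nb)) {
        idx <- which(breed == names(config$breed_proportions)[b])
        hap <- sample_haplotypes(2L * length(idx), freqs[, b], pos, config$ld_decay)
        d_chr[idx, ] <- hap[seq_along(idx), ] +
          hap[length(idx) + seq_along(idx), ]
      }
      ## enforce realized MAF >= 0.05 by resampling offending variants at a
      ## frequency pushed into [0.2, 0.5]
      for (it in 1:25) {
        af <- colMeans(d_chr) / 2
        low <- which(pmin(af, 1 - af) < 0.05)
        if (!length(low)) break
        for (j in low) {
          f <- runif(1, 0.2, 0.5)
          d_chr[, j] <- rbinom(n, 1L, f) + rbinom(n, 1L, f)
        }
      }
      af <- colMeans(d_chr) / 2
      vtab[[ci]] <- data.table::data.table(
        chrom = names(L)[ci], pos = as.integer(pos), ref = "A", alt = "G",
        maf = pmin(af, 1 - af))
      dosage <- cbind(dosage, d_chr)
    }
    variants <- data.table::rbindlist(vtab)
    variants[, `:=`(variant_id = sprintf("%s:%d:%s:%s", chrom, pos, ref, alt))]
    data.table::setcolorder(variants, "variant_id")
    dimnames(dosage) <- list(sample_ids, variants$variant_id)
    structure(list(
      dosage = dosage, variants = variants,
      samples = data.table::data.table(sample_id = sample_ids, breed = breed,
                                       ancestry = ancestry)),
      class = "GenotypeMatrix")
  })
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat(sprintf("GenotypeMatrix: %d samples x %d variants on %d chromosome(s); breeds: %s\n",
              nrow(x$dosage), ncol(x$dosage),
              length(unique(x$variants$chrom)),
              paste(unique(x$samples$breed), collapse = ", ")))
  invisible(x)
}

empty_truth <- function() {
  list(planted_qtl = data.table::data.table(
         feature_id = character(), variant_id = character(), slope = numeric(),
         kind = character(), tissue = character()),
       planted_gwas = data.table::data.table(
         variant_id = character(), effect = numeric(), shared_with_qtl = logical(),
         trait_id = character()),
       planted_factors = NULL,
       planted_interactions = data.table::data.table(
         feature_id = character(), variant_id = character(), context = character(),
         interaction_slope = numeric()))
}

place_features <- function(config, n_feat, prefix) {
  L <- config$chrom_lengths
  nf_chr <- pmax(1L, round(n_feat * L / sum(L)))
  nf_chr[length(nf_chr)] <- n_feat - sum(nf_chr[-length(nf_chr)])
  out <- list()
  k <- 0
  for (ci in seq_along(L)) {
    tss <- sort(sample.int(L[ci] - 20000L, nf_chr[ci]) + 10000L)
    out[[ci]] <- data.table::data.table(
      feature_id = sprintf("%s%04d", prefix, k + seq_len(nf_chr[ci])),
      chrom = names(L)[ci], start = as.integer(tss - 1L),
      end = as.integer(tss + 999L), tss = as.integer(tss), strand = "+")
    k <- k + nf_chr[ci]
  }
  data.table::rbindlist(out)
}

## pick a cis variant within +/- window of the TSS, polymorphic by construction;
## an optional MAF floor (interaction effects are planted on common variants so
## the context-stratified MAF filter keeps them testable)
pick_cis_variant <- function(geno, chrom, tss, window = 1e6, maf_floor = 0) {
  v <- geno$variants
  ok <- which(v$chrom == chrom & abs(v$pos - tss) <= window & v$maf >= maf_floor)
  if (!length(ok) && maf_floor > 0)
    ok <- which(v$chrom == chrom & abs(v$pos - tss) <= window)
  check_that(length(ok) > 0, "no cis variant within %g bp of %s:%d", window, chrom, tss)
  sample(ok, 1L)
}

#' Simulate count-scale molecular phenotypes with planted cis effects
#'
#' Generates per-gene RNA-seq-like counts via a log-normal-Poisson model:
#' `log2 mu = baseline + slope * dosage + loadings %*% hidden_factors +
#' N(0, noise_sd)`, scaled by per-sample library sizes, then Poisson-sampled.
#' The planted slope is therefore a log2 allelic fold change recoverable by
#' OLS on log2 counts. Hidden factors emulate technical confounders (batch,
#' RIN, ...) shared across genes; leaving them uncorrected inflates a naive
#' scan.
#'
#' @param genotypes a `GenotypeMatrix`.
#' @param config a [sim_config()].
#' @param n_qtl number of genes given a planted cis-eQTL (default: half).
#' @param effect_sizes optional vector of planted slopes (log2 per alt allele);
#'   drawn from `config$effect_size_dist` when `NULL`.
#' @param qtl_features optional feature indices to plant on.
#' @param qtl_variants optional variant ids to plant (must be polymorphic and
#'   within 1 Mb of the feature TSS).
#' @param n_interactions number of genes additionally given a genotype x
#'   ancestry interaction effect.
#' @param interaction_slope interaction effect size (log2 scale per allele per
#'   unit context).
#' @param tissue label recorded in the truth ledger.
#' @param seed optional override of `config$seed` (offset internally so
#'   phenotypes are not coupled to the genotype draw).
#' @return list with `phenotypes` (a `PhenotypeMatrix` of counts, kind
#'   "gene") and `truth` (a `SimTruth` ledger).
#' @export
simulate_molecular_phenotypes <- function(genotypes, config,
                                          n_qtl = NULL, effect_sizes = NULL,
                                          qtl_features = NULL, qtl_variants = NULL,
                                          n_interactions = 0L,
                                          interaction_slope = 0.8,
                                          tissue = "tissue1", seed = NULL) {
  stopifnot(inherits(genotypes, "GenotypeMatrix"), inherits(config, "sim_config"))
  seed <- seed %||% child_seed(config$seed, "phenotypes")
  n_feat <- as.integer(config$n_features_per_kind[["gene"]])
  n <- nrow(genotypes$dosage)
  with_seed(seed, {
    feats <- place_features(config, n_feat, "GENE")
    feats[, `:=`(kind = "gene", group_id = feature_id)]
    n_qtl <- n_qtl %||% floor(n_feat / 2)
    check_that(n_qtl <= n_feat, "n_qtl exceeds the number of genes")
    truth <- empty_truth()

    qtl_rows <- if (!is.null(qtl_features)) qtl_features else
      sort(sample.int(n_feat, n_qtl))
    slopes <- effect_sizes %||%
      rnorm(length(qtl_rows), config$effect_size_dist$mean, config$effect_size_dist$sd)
    vidx <- integer(length(qtl_rows))
    for (i in seq_along(qtl_rows)) {
      vidx[i] <- if (!is.null(qtl_variants))
        match(qtl_variants[i], genotypes$variants$variant_id)
      else pick_cis_variant(genotypes, feats$chrom[qtl_rows[i]], feats$tss[qtl_rows[i]])
      mafv <- genotypes$variants$maf[vidx[i]]
      check_that(is.finite(mafv) && mafv > 0,
                 "planted effect requested on a monomorphic variant")
    }

    factors <- matrix(rnorm(n * config$n_hidden_factors), n)
    ## the first hidden factor is partially aligned with ancestry (batch and
    ## population are confounded in real cohorts); uncorrected scans on such
    ## data show genomic inflation, corrected scans do not
    if (config$n_hidden_factors >= 1) {
      anc <- as.numeric(scale(genotypes$samples$ancestry))
      factors[, 1] <- 0.8 * anc + sqrt(1 - 0.8^2) * factors[, 1]
    }
    loadings <- matrix(rnorm(n_feat * config$n_hidden_factors,
                             sd = config$hidden_factor_sd), n_feat)
    truth$planted_factors <- list(factors = factors, loadings = loadings)

    baseline <- rnorm(n_feat, config$baseline_log2_mean, config$baseline_log2_sd)
    log2mu <- matrix(baseline, n_feat, n) +
      loadings %*% t(factors) +
      matrix(rnorm(n_feat * n, sd = config$noise_sd), n_feat)
    for (i in seq_along(qtl_rows))
      log2mu[qtl_rows[i], ] <- log2mu[qtl_rows[i], ] +
        slopes[i] * genotypes$dosage[, vidx[i]]

    if (n_interactions > 0) {
      ctx <- genotypes$samples$ancestry
      cand <- setdiff(seq_len(n_feat), qtl_rows)
      irows <- sort(sample(cand, n_interactions))
      for (r in irows) {
        vi <- pick_cis_variant(genotypes, feats$chrom[r], feats$tss[r],
                               maf_floor = 0.15)
        log2mu[r, ] <- log2mu[r, ] +
          0.2 * genotypes$dosage[, vi] +
          interaction_slope * genotypes$dosage[, vi] * ctx
        truth$planted_interactions <- rbind(truth$planted_interactions,
          data.table::data.table(feature_id = feats$feature_id[r],
                                 variant_id = genotypes$variants$variant_id[vi],
                                 context = "ancestry",
                                 interaction_slope = interaction_slope))
      }
    }

    libsize <- exp(rnorm(n, 0, 0.2))           # relative depth per sample
    mu <- 2^log2mu %*% diag(libsize)
    counts <- matrix(rpois(length(mu), mu), n_feat, n,
                     dimnames = list(feats$feature_id, rownames(genotypes$dosage)))

    if (length(qtl_rows))
      truth$planted_qtl <- data.table::data.table(
        feature_id = feats$feature_id[qtl_rows],
        variant_id = genotypes$variants$variant_id[vidx],
        slope = slopes, kind = "gene", tissue = tissue)

    list(phenotypes = new_phenotype_matrix(counts, feats), truth = truth)
  })
}

#' Simulate intron-excision clusters with planted splicing QTL
#'
#' Each cluster owns 2-4 introns belonging to a simulated gene. Per-sample
#' cluster totals are drawn log-normal-Poisson and split multinomially among
#' the introns. A planted sQTL shifts the first intron's share on the logit
#' scale by `logit_shift` per alt allele (planted clusters have exactly two
#' introns so the logit of the first intron's fraction shifts by exactly the
#' planted amount in expectation).
#'
#' @inheritParams simulate_molecular_phenotypes
#' @param n_sqtl number of clusters with a planted splicing effect.
#' @param logit_shift planted per-allele shift on the logit intron fraction.
#' @return list with `phenotypes` (PhenotypeMatrix of intron counts, kind
#'   "intron", group_id = cluster, gene_id column in feature_meta) and `truth`.
#' @export
simulate_intron_clusters <- function(genotypes, config, n_sqtl = NULL,
                                     logit_shift = 1.0, tissue = "tissue1",
                                     seed = NULL) {
  stopifnot(inherits(genotypes, "GenotypeMatrix"), inherits(config, "sim_config"))
  seed <- seed %||% child_seed(config$seed, "introns")
  n_clu <- as.integer(config$n_features_per_kind[["intron_cluster"]])
  n <- nrow(genotypes$dosage)
  with_seed(seed, {
    genes <- place_features(config, n_clu, "SGENE")
    n_sqtl <- n_sqtl %||% floor(n_clu / 2)
    check_that(n_sqtl <= n_clu, "n_sqtl exceeds the number of clusters")
    sqtl_rows <- sort(sample.int(n_clu, n_sqtl))
    sizes <- sample(2:4, n_clu, replace = TRUE)
    sizes[sqtl_rows] <- 2L
    check_that(all(sizes >= 2), "every cluster must contain at least 2 introns")

    truth <- empty_truth()
    rows <- list(); meta <- list()
    for (ci in seq_len(n_clu)) {
      k <- sizes[ci]
      base <- rexp(k) + 0.25
      alpha <- log(base / sum(base))
      shift <- matrix(0, k, n)
      if (ci %in% sqtl_rows) {
        vi <- pick_cis_variant(genotypes, genes$chrom[ci], genes$tss[ci])
        check_that(genotypes$variants$maf[vi] > 0,
                   "planted sQTL requested on a monomorphic variant")
        shift[1, ] <- logit_shift * genotypes$dosage[, vi]
        truth$planted_qtl <- rbind(truth$planted_qtl,
          data.table::data.table(feature_id = sprintf("CLU%03d", ci),
                                 variant_id = genotypes$variants$variant_id[vi],
                                 slope = logit_shift, kind = "intron",
                                 tissue = tissue))
      }
      pmat <- exp(alpha + shift)
      pmat <- sweep(pmat, 2L, colSums(pmat), "/")
      tot <- rpois(n, exp(rnorm(n, log(300), 0.3)))
      cnt <- vapply(seq_len(n), function(s) rmultinom(1, tot[s], pmat[, s])[, 1],
                    numeric(k))
      cid <- sprintf("CLU%03d", ci)
      rows[[ci]] <- cnt
      meta[[ci]] <- data.table::data.table(
        feature_id = sprintf("%s:INT%d", cid, seq_len(k)),
        chrom = genes$chrom[ci],
        start = genes$start[ci] + (seq_len(k) - 1L) * 100L,
        end = genes$start[ci] + seq_len(k) * 100L,
        tss = genes$tss[ci], strand = "+", kind = "intron",
        group_id = cid, gene_id = genes$feature_id[ci])
    }
    meta <- data.table::rbindlist(meta)
    counts <- do.call(rbind, rows)
    dimnames(counts) <- list(meta$feature_id, rownames(genotypes$dosage))
    ## truth ledger references clusters; keep ids joinable with group_id
    list(phenotypes = new_phenotype_matrix(counts, meta), truth = truth)
  })
}

#' Simulate GWAS summary statistics over a genotype reference
#'
#' Default mode draws per-variant z-scores directly from the regression with
#' summary statistics (RSS) model: `z ~ MVN(R lambda, R)` where `R` is the LD
#' correlation matrix of the reference panel and `lambda_j = sqrt(n) *
#' beta_std_j` the standardized causal effects scaled so the causal variants
#' jointly explain `h2_locus` of trait variance. The `individual` mode
#' simulates an actual cohort (fresh genotypes from the same generative
#' process, a quantitative trait, marginal OLS z per variant) and serves as
#' the oracle for the RSS shortcut.
#'
#' @param genotypes `GenotypeMatrix` used as the LD reference.
#' @param causal_spec data.table/data.frame with `variant_id` and relative
#'   `effect` (any scale; rescaled to meet `h2_locus`), or NULL for no signal.
#' @param n_gwas GWAS sample size.
#' @param h2_locus fraction of trait variance explained by the causal set,
#'   in `[0, 1)`.
#' @param seed integer seed.
#' @param mode `"summary"` (RSS draw) or `"individual"` (cohort simulation).
#' @param config required for `mode = "individual"`: the [sim_config()] the
#'   reference was generated from (for LD decay and breed frequencies).
#' @param trait_id label for the output.
#' @param shared_with_qtl logical flag copied into the truth ledger.
#' @return list with `gwas` (a `GwasSummary` data.table: variant_id, chrom,
#'   pos, z, n, n_cases, n_controls, trait_id) and `truth`.
#' @export
simulate_gwas_cohort <- function(genotypes, causal_spec = NULL, n_gwas = 5000,
                                 h2_locus = 0.01, seed = 1L,
                                 mode = c("summary", "individual"),
                                 config = NULL, trait_id = "trait1",
                                 shared_with_qtl = NA) {
  mode <- match.arg(mode)
  check_that(h2_locus >= 0 && h2_locus < 1, "h2_locus must lie in [0, 1)")
  v <- genotypes$variants
  beta_std <- rep(0, nrow(v))
  if (!is.null(causal_spec) && nrow(causal_spec) > 0) {
    idx <- match(causal_spec$variant_id, v$variant_id)
    check_that(!anyNA(idx), "causal variants absent from the reference panel")
    b <- causal_spec$effect
    if (h2_locus > 0) {
      b <- b / sqrt(sum(b^2)) * sqrt(h2_locus)   # ignores causal-causal LD; toy loci are sparse
    } else b <- rep(0, length(b))
    beta_std[idx] <- b
  }
  G <- standardize_cols(genotypes$dosage)
  with_seed(seed, {
    if (mode == "summary") {
      R <- crossprod(G) / (nrow(G) - 1)
      lam <- sqrt(n_gwas) * beta_std
      ch <- chol(R + diag(1e-6, nrow(R)))
      z <- as.numeric(R %*% lam + crossprod(ch, rnorm(nrow(R))))
    } else {
      check_that(inherits(config, "sim_config"),
                 "individual mode requires the generating sim_config")
      cfg2 <- config
      cfg2$n_samples <- as.integer(max(20, n_gwas))
      ref2 <- simulate_genotypes(cfg2, cohort_seed = child_seed(seed, "gwas-cohort"))
      check_that(identical(ref2$variants$variant_id, v$variant_id),
                 "individual-mode cohort has a different variant panel")
      Gs <- standardize_cols(ref2$dosage)
      g_comp <- as.numeric(Gs %*% beta_std)
      y <- g_comp + rnorm(nrow(Gs), sd = sqrt(max(1 - h2_locus, 1e-8)))
      y <- (y - mean(y)) / sd(y)
      r <- as.numeric(crossprod(Gs, y)) / (nrow(Gs) - 1)
      z <- r * sqrt((nrow(Gs) - 2) / pmax(1 - r^2, 1e-12))
    }
    gwas <- data.table::data.table(
      variant_id = v$variant_id, chrom = v$chrom, pos = v$pos, z = z,
      n = as.integer(n_gwas), n_cases = NA_integer_, n_controls = NA_integer_,
      trait_id = trait_id)
    truth <- empty_truth()
    if (any(beta_std != 0))
      truth$planted_gwas <- data.table::data.table(
        variant_id = v$variant_id[beta_std != 0],
        effect = beta_std[beta_std != 0],
        shared_with_qtl = shared_with_qtl, trait_id = trait_id)
    list(gwas = gwas, truth = truth)
  })
}

#' Simulate interval annotations: chromatin-state tracks and TADs
#'
#' State tracks are built from fixed-width windows assigned without overlap so
#' realized genome coverage matches the requested fraction up to window
#' rounding; TADs tile each chromosome exactly (no gaps, no overlap).
#'
#' @param chrom_lengths named numeric vector (bp).
#' @param state_spec data.frame with `state` and `coverage` (fraction of the
#'   genome each state should cover; coverages may sum to < 1).
#' @param tad_mean_bp average TAD size in bp.
#' @param window_bp placement granularity for state tracks.
#' @param seed integer seed.
#' @return `AnnotationSet`: list with `states` and `tads` data.tables
#'   (chrom, start, end, label; 0-based half-open).
#' @export
simulate_annotations <- function(chrom_lengths,
                                 state_spec = data.frame(
                                   state = c("Enhancer", "Promoter", "Quiescent"),
                                   coverage = c(0.10, 0.05, 0.50)),
                                 tad_mean_bp = 2e5, window_bp = 2e3, seed = 1L) {
  check_that(all(chrom_lengths > 0), "chromosome lengths must be positive")
  check_that(all(state_spec$coverage > 0 & state_spec$coverage <= 1) &&
               sum(state_spec$coverage) <= 1,
             "state coverages must be positive and sum to <= 1")
  with_seed(seed, {
    states <- list(); tads <- list()
    for (ci in seq_along(chrom_lengths)) {
      chrom <- names(chrom_lengths)[ci]; L <- chrom_lengths[ci]
      nw <- floor(L / window_bp)
      pool <- sample.int(nw)              # random non-overlapping assignment
      off <- 0L
      for (si in seq_len(nrow(state_spec))) {
        nwin <- round(state_spec$coverage[si] * nw)
        take <- sort(pool[off + seq_len(nwin)]); off <- off + nwin
        if (!length(take)) next
        ## merge adjacent windows into maximal intervals
        brk <- c(0, which(diff(take) > 1), length(take))
        iv <- data.table::data.table(
          start = (take[brk[-length(brk)] + 1] - 1L) * window_bp,
          end = take[brk[-1]] * window_bp)
        iv[, `:=`(chrom = chrom, label = state_spec$state[si])]
        states[[length(states) + 1L]] <- iv
      }
      b <- 0; bounds <- c(0)
      while (b < L) {
        b <- min(L, b + tad_mean_bp * runif(1, 0.5, 1.5))
        bounds <- c(bounds, b)
      }
      bounds[length(bounds)] <- L
      tads[[ci]] <- data.table::data.table(
        chrom = chrom, start = as.integer(head(bounds, -1)),
        end = as.integer(tail(bounds, -1)),
        label = sprintf("%s_TAD%03d", chrom, seq_len(length(bounds) - 1)))
    }
    structure(list(states = data.table::rbindlist(states, use.names = TRUE),
                   tads = data.table::rbindlist(tads)),
              class = "AnnotationSet")
  })
}

#' Simulate a pair of single-tissue TWAS tables for two species
#'
#' Gene-level absolute effect sizes are built from shared and idiosyncratic
#' positive components so that `cor(|effect_A|, |effect_B|)` equals the
#' planted correlation exactly in expectation; signs are independent fair
#' coin flips. z-statistics are `effect / se` with constant unit se.
#'
#' @param n_genes number of one-to-one orthologous genes.
#' @param planted_correlation target correlation of absolute effects, in
#'   `[0, 1]`.
#' @param seed integer seed.
#' @param trait_a,trait_b,tissue labels; `n_a`,`n_b` cohort sizes recorded.
#' @return list with `twas_a`, `twas_b` (data.tables: gene_id, effect, z,
#'   trait_id, tissue_id, n) and `map` (OrthologMap data.table gene_a,
#'   gene_b).
#' @export
simulate_ortholog_twas_pair <- function(n_genes, planted_correlation, seed = 1L,
                                        trait_a = "pigTrait", trait_b = "humanTrait",
                                        tissue = "muscle", n_a = 1000L, n_b = 5000L) {
  check_that(planted_correlation >= 0 && planted_correlation <= 1,
             "planted_correlation must lie in [0, 1] (negative sharing of absolute effects is not representable)")
  with_seed(seed, {
    rho <- planted_correlation
    shared <- abs(rnorm(n_genes))
    ua <- abs(rnorm(n_genes)); ub <- abs(rnorm(n_genes))
    mag_a <- sqrt(rho) * shared + sqrt(1 - rho) * ua
    mag_b <- sqrt(rho) * shared + sqrt(1 - rho) * ub
    sa <- sample(c(-1, 1), n_genes, TRUE); sb <- sample(c(-1, 1), n_genes, TRUE)
    ga <- sprintf("PIG%05d", seq_len(n_genes))
    gb <- sprintf("HUM%05d", seq_len(n_genes))
    list(
      twas_a = data.table::data.table(gene_id = ga, effect = sa * mag_a,
                                      z = sa * mag_a, trait_id = trait_a,
                                      tissue_id = tissue, n = as.integer(n_a)),
      twas_b = data.table::data.table(gene_id = gb, effect = sb * mag_b,
                                      z = sb * mag_b, trait_id = trait_b,
                                      tissue_id = tissue, n = as.integer(n_b)),
      map = data.table::data.table(gene_a = ga, gene_b = gb))
  })
}
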