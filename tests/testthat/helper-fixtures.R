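# Shared fixtures, built once per test run and memoized.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

base_config <- function(...) {
  args <- utils::modifyList(list(seed = 42L), list(...))
  do.call(sim_config, args)
}

base_geno <- function() fixture("geno", function() simulate_genotypes(base_config()))

# hand-built genotype object for surgical tests (monomorphic columns, exact
# positions, perfect-LD duplicates)
manual_geno <- function(dosage, chrom, pos) {
  n <- nrow(dosage)
  ids <- sprintf("%s:%d:A:G", chrom, pos)
  dimnames(dosage) <- list(sprintf("S%04d", seq_len(n)), ids)
  af <- colMeans(dosage) / 2
  structure(list(
    dosage = dosage,
    variants = data.table::data.table(variant_id = ids, chrom = chrom,
                                      pos = as.integer(pos), ref = "A",
                                      alt = "G", maf = pmin(af, 1 - af)),
    samples = data.table::data.table(sample_id = rownames(dosage),
                                     breed = "X", ancestry = 0.5)),
    class = "GenotypeMatrix")
}

# single-feature phenotype with explicit TSS
manual_pheno <- function(values, chrom = "chr1", tss = 5e5, kind = "gene",
                         strand = "+", group_id = NULL) {
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  nf <- nrow(values)
  rownames(values) <- sprintf("F%03d", seq_len(nf))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%04d", seq_len(ncol(values)))
  if (length(tss) == 1L) tss <- rep(tss, nf)
  new_phenotype_matrix(values, data.table::data.table(
    feature_id = rownames(values), chrom = chrom, start = as.integer(tss - 1L),
    end = as.integer(tss + 999L), tss = as.integer(tss), strand = strand,
    kind = kind,
    group_id = group_id %||% rownames(values)))
}

# direct simple-regression stats (independent oracle for the scan engine)
ols_oracle <- function(y, x, covs = NULL) {
  X <- cbind(1, covs, x)
  fit <- stats::lm.fit(X, y)
  k <- ncol(X)
  df <- length(y) - k
  sigma2 <- sum(fit$residuals^2) / df
  XtXi <- solve(crossprod(X))
  se <- sqrt(XtXi[k, k] * sigma2)
  slope <- fit$coefficients[k]
  t <- slope / se
  list(slope = unname(slope), se = unname(se), t = unname(t),
       p = unname(2 * stats::pt(-abs(t), df)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# naive brute-force TMM pair factor: explicit sort-based trimming
brute_tmm <- function(obs, ref, lt = 0.3, st = 0.05) {
  no <- sum(obs); nr <- sum(ref)
  M <- log2((obs / no) / (ref / nr))
  A <- 0.5 * log2((obs / no) * (ref / nr))
  w <- (no - obs) / (no * obs) + (nr - ref) / (nr * ref)
  fin <- is.finite(M) & is.finite(A)
  M <- M[fin]; A <- A[fin]; w <- w[fin]
  n <- length(M)
  loM <- floor(n * lt) + 1; hiM <- n + 1 - loM
  loA <- floor(n * st) + 1; hiA <- n + 1 - loA
  keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
}

# brute-force Rand index by explicit pair enumeration
brute_rand <- function(a, b) {
  n <- length(a)
  agree <- 0; total <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    total <- total + 1
    agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
  }
  agree / total
}
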