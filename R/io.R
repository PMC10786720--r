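#' Write genotypes as a plain-text VCF (GT fields, 1-based positions)
#'
#' @param genotypes `GenotypeMatrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  v <- genotypes$variants
  gt <- apply(genotypes$dosage, 2L, function(d)
    c("0/0", "0/1", "1/1")[d + 1L])           # variants in columns here
  gt <- t(gt)
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s>", unique(v$chrom)),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(genotypes$dosage)),
                    collapse = "\t"))
  body <- data.table::data.table(v$chrom, v$pos, v$variant_id, v$ref, v$alt,
                                 ".", "PASS", ".", "GT")
  body <- cbind(body, data.table::as.data.table(gt))
  writeLines(header, path)
  data.table::fwrite(body, path, sep = "\t", append = TRUE, col.names = FALSE)
  invisible(path)
}

#' Read a GT-only VCF written by [write_genotypes_vcf()]
#'
#' @param path VCF file.
#' @return `GenotypeMatrix` (breed/ancestry metadata absent: NA columns).
#' @export
read_genotypes_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#CHROM")]
  cols <- strsplit(hdr, "\t")[[1]]
  dt <- data.table::fread(text = lines[!startsWith(lines, "#")], header = FALSE,
                          sep = "\t")
  data.table::setnames(dt, cols)
  samples <- cols[-(1:9)]
  gt_to_dosage <- function(x) {
    d <- integer(length(x))
    d[x %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    d[x %in% c("1/1", "1|1")] <- 2L
    d
  }
  dosage <- vapply(samples, function(s) gt_to_dosage(dt[[s]]),
                   integer(nrow(dt)))
  rownames(dosage) <- dt$ID
  dosage <- t(dosage)
  af <- colMeans(dosage) / 2
  structure(list(
    dosage = dosage,
    variants = data.table::data.table(variant_id = dt$ID, chrom = dt$`#CHROM`,
                                      pos = dt$POS, ref = dt$REF, alt = dt$ALT,
                                      maf = pmin(af, 1 - af)),
    samples = data.table::data.table(sample_id = samples, breed = NA_character_,
                                     ancestry = NA_real_)),
    class = "GenotypeMatrix")
}

#' Write a phenotype matrix in the BED-like tab-separated dialect
#'
#' Columns: chrom, start, end (0-based half-open), feature id, group id,
#' strand, then one column per sample.
#'
#' @param pheno `PhenotypeMatrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_phenotype_bed <- function(pheno, path) {
  m <- pheno$feature_meta
  dt <- data.table::data.table(`#chrom` = m$chrom, start = m$start, end = m$end,
                               feature_id = m$feature_id, group_id = m$group_id,
                               strand = m$strand)
  dt <- cbind(dt, data.table::as.data.table(pheno$values))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a BED-like phenotype matrix written by [write_phenotype_bed()]
#'
#' @param path input file.
#' @param kind feature kind to record (default "gene").
#' @param tss optional named TSS positions; defaults to start + 1 ("+"
#'   strand convention of the writer).
#' @return `PhenotypeMatrix`.
#' @export
read_phenotype_bed <- function(path, kind = "gene", tss = NULL) {
  dt <- data.table::fread(path, sep = "\t")
  meta_cols <- names(dt)[1:6]
  vals <- as.matrix(dt[, -(1:6), with = FALSE])
  rownames(vals) <- dt[[4]]
  meta <- data.table::data.table(
    feature_id = dt[[4]], chrom = dt[[1]], start = dt[[2]], end = dt[[3]],
    tss = if (is.null(tss)) dt[[2]] + 1L else as.integer(tss[dt[[4]]]),
    strand = dt[[6]], kind = kind, group_id = dt[[5]])
  new_phenotype_matrix(vals, meta)
}

#' Write GWAS summary statistics as TSV
#' @param gwas `GwasSummary` data.table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gwas_tsv <- function(gwas, path) {
  data.table::fwrite(gwas, path, sep = "\t")
  invisible(path)
}

#' Read GWAS summary statistics TSV
#' @param path input file.
#' @return `GwasSummary` data.table.
#' @export
read_gwas_tsv <- function(path) data.table::fread(path, sep = "\t")

#' Write an annotation track (states or TADs) as BED
#' @param intervals data.table chrom, start, end, label.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotations_bed <- function(intervals, path) {
  data.table::fwrite(intervals[, c("chrom", "start", "end", "label")], path,
                     sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write the planted-truth ledger as TSV files under a directory
#' @param truth `SimTruth` list.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_truth_tsv <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(truth$planted_qtl, file.path(dir, "planted_qtl.tsv"), sep = "\t")
  data.table::fwrite(truth$planted_gwas, file.path(dir, "planted_gwas.tsv"), sep = "\t")
  data.table::fwrite(truth$planted_interactions,
                     file.path(dir, "planted_interactions.tsv"), sep = "\t")
  invisible(dir)
}

#' Write a samples x covariates TSV
#' @param covariates matrix with sample rownames.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_covariates_tsv <- function(covariates, path) {
  dt <- data.table::data.table(sample_id = rownames(covariates))
  dt <- cbind(dt, data.table::as.data.table(covariates))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
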