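#' Haploid case-control genotype table
#'
#' The central container of the package: an n-individual by m-SNP matrix of
#' haploid mtDNA allele codes (0 = reference, 1 = alternate, NA = missing),
#' with per-sample phenotypes (1 = control, 2 = case, NA = missing, mirroring
#' PLINK's 1/2/-9 convention) and per-SNP metadata.
#'
#' @param geno integer matrix (n x m) over {0L, 1L, NA}.
#' @param sample_ids character vector of unique sample identifiers (length n).
#' @param phenotype integer vector: 1 control, 2 case, NA missing (length n).
#' @param snp_meta data.frame with columns \code{id} (unique SNP ids),
#'   \code{pos} (1-based rCRS position in 1..16569), \code{ref}, \code{alt}
#'   (single bases; \code{alt} may be NA for a monomorphic SNP).
#' @param platform free-text label of the genotyping platform.
#' @return an object of class \code{genotype_table}.
#' @export
genotype_table <- function(geno, sample_ids, phenotype, snp_meta,
                           platform = "synthetic") {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  n <- nrow(geno); m <- ncol(geno)
  if (length(sample_ids) != n)
    abort("sample_ids length (%d) != genotype rows (%d)", length(sample_ids), n)
  if (anyDuplicated(sample_ids))
    abort("duplicate sample ids")
  if (length(phenotype) != n)
    abort("phenotype length (%d) != genotype rows (%d)", length(phenotype), n)
  phenotype <- as.integer(phenotype)
  if (!all(phenotype %in% c(1L, 2L) | is.na(phenotype)))
    abort("phenotype codes must be 1 (control), 2 (case) or NA")
  req <- c("id", "pos", "ref", "alt")
  if (!all(req %in% names(snp_meta)))
    abort("snp_meta must have columns: %s", paste(req, collapse = ", "))
  if (nrow(snp_meta) != m)
    abort("snp_meta rows (%d) != genotype columns (%d)", nrow(snp_meta), m)
  if (anyDuplicated(snp_meta$id)) abort("duplicate SNP ids")
  if (any(snp_meta$pos < 1L | snp_meta$pos > MT_LENGTH))
    abort("SNP positions must lie in 1..%d", MT_LENGTH)
  bad <- !(geno %in% c(0L, 1L)) & !is.na(geno)
  if (any(bad)) abort("genotype codes must be 0, 1 or NA")
  rownames(geno) <- sample_ids
  colnames(geno) <- snp_meta$id
  structure(
    list(geno = geno,
         sample_ids = as.character(sample_ids),
         phenotype = phenotype,
         snp_meta = as.data.frame(snp_meta, stringsAsFactors = FALSE),
         platform = platform),
    class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf(
    "genotype_table: %d individuals x %d SNPs [%s]\n  cases: %d  controls: %d  missing phenotype: %d\n  missing genotype calls: %d\n",
    n_samples(x), n_snps(x), x$platform,
    sum(x$phenotype == 2L, na.rm = TRUE),
    sum(x$phenotype == 1L, na.rm = TRUE),
    sum(is.na(x$phenotype)),
    sum(is.na(x$geno))))
  invisible(x)
}

#' Number of individuals / SNPs in a genotype table
#' @param g a \code{genotype_table}.
#' @return integer count.
#' @export
n_samples <- function(g) nrow(g$geno)

#' @rdname n_samples
#' @export
n_snps <- function(g) ncol(g$geno)

#' Subset a genotype table by samples and/or SNPs
#'
#' @param g a \code{genotype_table}.
#' @param samples logical/integer index over individuals (default: keep all).
#' @param snps logical/integer index over SNPs (default: keep all).
#' @return a \code{genotype_table}.
#' @export
gt_subset <- function(g, samples = NULL, snps = NULL) {
  if (is.null(samples)) samples <- seq_len(n_samples(g))
  if (is.null(snps))    snps    <- seq_len(n_snps(g))
  genotype_table(
    g$geno[samples, snps, drop = FALSE],
    g$sample_ids[samples],
    g$phenotype[samples],
    g$snp_meta[snps, , drop = FALSE],
    platform = g$platform)
}

#' Per-SNP alternate-allele frequency and minor-allele frequency
#'
#' Frequencies are computed over non-missing calls only. \code{snp_maf} folds
#' the alternate-allele frequency to the minor allele, so values lie in
#' [0, 0.5]; SNPs with zero calls get NA.
#'
#' @param g a \code{genotype_table}.
#' @return numeric vector of length \code{n_snps(g)}.
#' @export
snp_alt_freq <- function(g) {
  called <- colSums(!is.na(g$geno))
  alt    <- colSums(g$geno == 1L, na.rm = TRUE)
  ifelse(called > 0, alt / called, NA_real_)
}

#' @rdname snp_alt_freq
#' @export
snp_maf <- function(g) {
  f <- snp_alt_freq(g)
  pmin(f, 1 - f)
}

#' Per-SNP call rate and per-individual missingness
#' @param g a \code{genotype_table}.
#' @return numeric vector (per SNP or per individual).
#' @export
snp_call_rate <- function(g) colMeans(!is.na(g$geno))

#' @rdname snp_call_rate
#' @export
individual_missingness <- function(g) rowMeans(is.na(g$geno))

# internal: logical case/control vectors (NA phenotype excluded from both)
is_case    <- function(g) !is.na(g$phenotype) & g$phenotype == 2L
is_control <- function(g) !is.na(g$phenotype) & g$phenotype == 1L
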