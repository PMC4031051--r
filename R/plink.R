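#' Write a genotype table as a PLINK text PED/MAP pair
#'
#' mtDNA is written with chromosome code "26"; haploid calls are emitted as
#' homozygous diploid genotypes (the PLINK convention for mtDNA), missing
#' genotypes as "0 0" and missing phenotypes as "-9".
#'
#' @param g a \code{\link{genotype_table}}.
#' @param path_prefix output path without extension; \code{<prefix>.ped} and
#'   \code{<prefix>.map} are created.
#' @return invisibly, the two file paths.
#' @export
write_plink <- function(g, path_prefix) {
  map <- data.frame(chr = "26", id = g$snp_meta$id, cm = 0L,
                    pos = g$snp_meta$pos)
  utils::write.table(map, paste0(path_prefix, ".map"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  n <- n_samples(g); m <- n_snps(g)
  alle <- matrix("0", n, m)
  for (j in seq_len(m)) {
    aj <- g$geno[, j]
    alle[, j] <- ifelse(is.na(aj), "0",
                        ifelse(aj == 1L, g$snp_meta$alt[j], g$snp_meta$ref[j]))
  }
  # monomorphic SNP with unknown alt: alt calls cannot occur, ref is defined
  if (anyNA(alle)) abort("undefined allele symbol while writing PED")
  phen <- ifelse(is.na(g$phenotype), "-9", as.character(g$phenotype))
  lead <- cbind(g$sample_ids, g$sample_ids, "0", "0", "0", phen)
  body <- alle[, rep(seq_len(m), each = 2), drop = FALSE]  # haploid -> homozygous diploid
  lines <- apply(cbind(lead, body), 1L, paste, collapse = "\t")
  writeLines(lines, paste0(path_prefix, ".ped"))
  invisible(c(ped = paste0(path_prefix, ".ped"),
              map = paste0(path_prefix, ".map")))
}

#' Load a PLINK text PED/MAP pair as a haploid genotype table
#'
#' Haploid coding is recovered from the homozygous-diploid convention:
#' heterozygous mtDNA calls are set missing (and counted in attribute
#' \code{"het_calls_masked"}). Allele polarity is taken from
#' \code{ref_alleles} when supplied; otherwise the first allele seen in file
#' order is taken as the reference.
#'
#' @param path_prefix path without extension.
#' @param ref_alleles optional data.frame with columns \code{id}, \code{ref}
#'   and optionally \code{alt}, fixing the reference (rCRS) allele per SNP.
#' @param platform platform label to attach.
#' @return a \code{\link{genotype_table}}.
#' @export
load_plink <- function(path_prefix, ref_alleles = NULL, platform = "unknown") {
  ped_path <- paste0(path_prefix, ".ped")
  map_path <- paste0(path_prefix, ".map")
  if (!file.exists(ped_path) || !file.exists(map_path))
    abort("PED/MAP pair not found at prefix '%s'", path_prefix)
  map <- utils::read.table(map_path, header = FALSE, sep = "",
                           colClasses = "character")
  if (ncol(map) < 4) abort("MAP file must have 4 columns")
  snp_id <- map[[2]]; pos <- as.integer(map[[4]])
  m <- length(snp_id)
  rows <- strsplit(readLines(ped_path), "[ \t]+")
  lens <- lengths(rows)
  if (any(lens != 6L + 2L * m))
    abort("PED row length mismatch: expected %d fields, got %d (row %d)",
          6L + 2L * m, lens[which(lens != 6L + 2L * m)[1]],
          which(lens != 6L + 2L * m)[1])
  ped <- do.call(rbind, rows)
  sample_ids <- ped[, 2]
  phen_raw <- ped[, 6]
  phenotype <- ifelse(phen_raw %in% c("1", "2"), as.integer(phen_raw), NA_integer_)
  a1 <- ped[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  a2 <- ped[, 6L + 2L * seq_len(m), drop = FALSE]
  het <- a1 != a2 & a1 != "0" & a2 != "0"
  n_het <- sum(het)
  call <- ifelse(a1 == "0" | a2 == "0" | het, NA_character_, a1)
  geno <- matrix(NA_integer_, nrow(ped), m)
  ref <- alt <- rep(NA_character_, m)
  for (j in seq_len(m)) {
    obs <- unique(call[!is.na(call[, j]), j])
    if (length(obs) > 2L)
      abort("SNP '%s' is not biallelic (%s)", snp_id[j], paste(obs, collapse = "/"))
    if (!is.null(ref_alleles)) {
      k <- match(snp_id[j], ref_alleles$id)
      if (!is.na(k)) {
        ref[j] <- ref_alleles$ref[k]
        if (!is.null(ref_alleles$alt)) alt[j] <- ref_alleles$alt[k]
      }
    }
    if (is.na(ref[j])) ref[j] <- if (length(obs)) obs[1] else "0"
    other <- setdiff(obs, ref[j])
    if (length(other) > 1L)
      abort("SNP '%s': alleles %s inconsistent with supplied reference '%s'",
            snp_id[j], paste(obs, collapse = "/"), ref[j])
    if (is.na(alt[j])) alt[j] <- if (length(other)) other else NA_character_
    geno[, j] <- ifelse(is.na(call[, j]), NA_integer_,
                        ifelse(call[, j] == ref[j], 0L,
                               ifelse(call[, j] == alt[j], 1L, NA_integer_)))
    stray <- !is.na(call[, j]) & is.na(geno[, j])
    if (any(stray))
      abort("SNP '%s': allele '%s' matches neither ref nor alt",
            snp_id[j], call[stray, j][1])
  }
  g <- genotype_table(geno, sample_ids, phenotype,
                      data.frame(id = snp_id, pos = pos, ref = ref, alt = alt,
                                 stringsAsFactors = FALSE),
                      platform = platform)
  attr(g, "het_calls_masked") <- n_het
  g
}
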