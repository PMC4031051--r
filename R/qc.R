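#' QC thresholds
#'
#' Defaults are the canonical values used throughout the package: lexical
#' cascade call rate 0.95 and MAF 0.005; primary cascade SNP/individual
#' missingness 0.1 and MAF 1e-5; worst-individual trim 2%; worst-SNP trim
#' 50%; rare-haplotype count 5; differential-missingness P 1e-4; control
#' discordance P 0.05.
#'
#' @param snp_call_rate_min lexical cascade: minimum per-SNP call rate.
#' @param snp_maf_min lexical cascade: minimum MAF.
#' @param primary_snp_maf_min primary cascade: minimum MAF.
#' @param individual_missing_max primary cascade: maximum per-individual
#'   missingness.
#' @param snp_missing_max primary cascade: maximum per-SNP missingness.
#' @param worst_individual_fraction lexical cascade: fraction of individuals
#'   with the most missing sites to remove (count rounded down).
#' @param worst_snp_fraction lexical cascade: fraction of SNPs with the most
#'   missing samples to remove (count rounded down).
#' @param rare_haplotype_min_count lexical cascade: minimum haplotype count.
#' @param diff_missing_p removal threshold for differential missingness.
#' @param control_discordance_p removal threshold when comparing control
#'   cohorts before merging.
#' @return an object of class \code{qc_thresholds}.
#' @export
qc_thresholds <- function(snp_call_rate_min = 0.95,
                          snp_maf_min = 0.005,
                          primary_snp_maf_min = 1e-5,
                          individual_missing_max = 0.1,
                          snp_missing_max = 0.1,
                          worst_individual_fraction = 0.02,
                          worst_snp_fraction = 0.50,
                          rare_haplotype_min_count = 5L,
                          diff_missing_p = 1e-4,
                          control_discordance_p = 0.05) {
  t <- list(snp_call_rate_min = snp_call_rate_min,
            snp_maf_min = snp_maf_min,
            primary_snp_maf_min = primary_snp_maf_min,
            individual_missing_max = individual_missing_max,
            snp_missing_max = snp_missing_max,
            worst_individual_fraction = worst_individual_fraction,
            worst_snp_fraction = worst_snp_fraction,
            rare_haplotype_min_count = as.integer(rare_haplotype_min_count),
            diff_missing_p = diff_missing_p,
            control_discordance_p = control_discordance_p)
  props <- unlist(t[c("snp_call_rate_min", "snp_maf_min", "primary_snp_maf_min",
                      "individual_missing_max", "snp_missing_max",
                      "worst_individual_fraction", "worst_snp_fraction")])
  if (any(props < 0 | props > 1)) abort("proportions must lie in [0,1]")
  if (t$rare_haplotype_min_count < 0) abort("rare_haplotype_min_count must be >= 0")
  structure(t, class = "qc_thresholds")
}

# ---- QC report (ordered removal ledger, Table-1 style) ----------------------

new_qc_report <- function(input_n, input_m) {
  structure(list(stages = data.frame(stage = character(0),
                                     individuals_removed = integer(0),
                                     snps_removed = integer(0),
                                     stringsAsFactors = FALSE),
                 input_n = input_n, input_m = input_m,
                 final_n = input_n, final_m = input_m),
            class = "qc_report")
}

add_stage <- function(rep, stage, ind = 0L, snp = 0L) {
  rep$stages <- rbind(rep$stages,
                      data.frame(stage = stage,
                                 individuals_removed = as.integer(ind),
                                 snps_removed = as.integer(snp),
                                 stringsAsFactors = FALSE))
  rep$final_n <- rep$final_n - as.integer(ind)
  rep$final_m <- rep$final_m - as.integer(snp)
  rep
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d -> %d individuals, %d -> %d SNPs\n",
              x$input_n, x$final_n, x$input_m, x$final_m))
  print(x$stages, row.names = FALSE)
  invisible(x)
}

#' Write a QC report ledger as TSV
#' @param rep a \code{qc_report}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_qc_report <- function(rep, path) {
  utils::write.table(rep$stages, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- primary cascade --------------------------------------------------------

#' Primary-association QC cascade
#'
#' Ordered stages: (1) drop individuals with missing phenotype; (2) drop SNPs
#' with missingness above \code{snp_missing_max}; (3) drop individuals with
#' missingness above \code{individual_missing_max} (computed on the SNPs
#' remaining after stage 2); (4) drop non-European lineages by the diagnostic
#' triplet (\code{\link{filter_non_european}}); (5) drop SNPs with MAF below
#' \code{primary_snp_maf_min}.
#'
#' @param g a \code{\link{genotype_table}}.
#' @param t a \code{\link{qc_thresholds}}.
#' @return list with elements \code{table} (filtered genotype_table) and
#'   \code{report} (a \code{qc_report}).
#' @export
primary_qc <- function(g, t = qc_thresholds()) {
  rep <- new_qc_report(n_samples(g), n_snps(g))
  bail <- function(g, rep, stage) {
    warning(sprintf("table empty after stage '%s'; stopping cascade", stage),
            call. = FALSE)
    list(table = g, report = rep)
  }
  # 1: missing phenotypes
  keep <- !is.na(g$phenotype)
  rep <- add_stage(rep, "missing_phenotype", ind = sum(!keep))
  g <- gt_subset(g, samples = keep)
  if (n_samples(g) == 0) return(bail(g, rep, "missing_phenotype"))
  # 2: SNP missingness
  keep_snp <- (1 - snp_call_rate(g)) <= t$snp_missing_max
  rep <- add_stage(rep, "snp_missingness", snp = sum(!keep_snp))
  g <- gt_subset(g, snps = keep_snp)
  if (n_snps(g) == 0) return(bail(g, rep, "snp_missingness"))
  # 3: individual missingness
  keep <- individual_missingness(g) <= t$individual_missing_max
  rep <- add_stage(rep, "individual_missingness", ind = sum(!keep))
  g <- gt_subset(g, samples = keep)
  if (n_samples(g) == 0) return(bail(g, rep, "individual_missingness"))
  # 4: non-European lineages
  fe <- filter_non_european(g)
  rep <- add_stage(rep, "non_european", ind = length(fe$removed_ids))
  g <- fe$table
  if (n_samples(g) == 0) return(bail(g, rep, "non_european"))
  # 5: MAF
  keep_snp <- !is.na(snp_maf(g)) & snp_maf(g) >= t$primary_snp_maf_min
  rep <- add_stage(rep, "maf", snp = sum(!keep_snp))
  g <- gt_subset(g, snps = keep_snp)
  list(table = g, report = rep)
}

#' European-lineage filter by the mtDNA diagnostic triplet
#'
#' European (macrohaplogroup N background) mtDNAs are identified by m.8701A,
#' m.8540T and m.10873T. An individual is retained only if, at every
#' *testable* diagnostic position (genotyped on the array and called for that
#' individual), the called base equals the European-defining allele. If none
#' of the three positions is genotyped, the table is returned unchanged with
#' a warning and attribute \code{"untestable" = TRUE}.
#'
#' @param g a \code{\link{genotype_table}}.
#' @return list with elements \code{table} and \code{removed_ids}.
#' @export
filter_non_european <- function(g) {
  idx <- match(EURO_DIAGNOSTIC$pos, g$snp_meta$pos)
  testable <- !is.na(idx)
  if (!any(testable)) {
    warning("none of the European diagnostic positions (8701, 8540, 10873) ",
            "is genotyped; filter is a no-op", call. = FALSE)
    out <- list(table = g, removed_ids = character(0))
    attr(out$table, "untestable") <- TRUE
    return(out)
  }
  keep <- rep(TRUE, n_samples(g))
  for (k in which(testable)) {
    j <- idx[k]
    euro <- EURO_DIAGNOSTIC$allele[k]
    called_base <- ifelse(is.na(g$geno[, j]), NA_character_,
                          ifelse(g$geno[, j] == 0L, g$snp_meta$ref[j],
                                 g$snp_meta$alt[j]))
    keep <- keep & (is.na(called_base) | called_base == euro)
  }
  list(table = gt_subset(g, samples = keep),
       removed_ids = g$sample_ids[!keep])
}

# ---- lexical-tree cascade ---------------------------------------------------

#' Lexical-tree QC cascade
#'
#' The stricter, ordered cascade required before tree building, applied
#' strictly in sequence: (1) remove SNPs with call rate below
#' \code{snp_call_rate_min} or MAF below \code{snp_maf_min}; (2) remove the
#' \code{worst_individual_fraction} of individuals with the most missing
#' sites; (3) remove the \code{worst_snp_fraction} of SNPs with the most
#' missing samples; (4) remove individuals with any missing data on the
#' remaining SNPs; (5) remove individuals whose full haplotype (over the
#' remaining SNPs) is absent from controls or carried by fewer than
#' \code{rare_haplotype_min_count} individuals. The output has zero missing
#' genotypes. Trim counts in stages 2-3 are rounded down; ties in missingness
#' are broken by sample-id order (stage 2) and ascending position (stage 3).
#'
#' @param g a \code{\link{genotype_table}} (no missing phenotypes unless
#'   \code{controls_mask} is given).
#' @param controls_mask logical vector marking control individuals; defaults
#'   to \code{phenotype == 1}.
#' @param t a \code{\link{qc_thresholds}}.
#' @return list with elements \code{table} and \code{report}.
#' @export
lextree_qc <- function(g, controls_mask = NULL, t = qc_thresholds()) {
  if (is.null(controls_mask)) {
    if (anyNA(g$phenotype))
      abort("missing phenotypes present; prune them or supply controls_mask")
    controls_mask <- g$phenotype == 1L
  }
  stopifnot(length(controls_mask) == n_samples(g))
  rep <- new_qc_report(n_samples(g), n_snps(g))

  # 1: call rate / MAF
  cr  <- snp_call_rate(g)
  maf <- snp_maf(g)
  keep_snp <- cr >= t$snp_call_rate_min & !is.na(maf) & maf >= t$snp_maf_min
  rep <- add_stage(rep, "call_rate_or_maf", snp = sum(!keep_snp))
  g <- gt_subset(g, snps = keep_snp); controls_mask <- controls_mask
  if (n_snps(g) == 0) abort("all SNPs removed at the call-rate/MAF stage")

  # 2: worst individuals by missing-site count
  k_ind <- floor(t$worst_individual_fraction * n_samples(g))
  if (k_ind > 0) {
    miss <- rowSums(is.na(g$geno))
    ord <- order(-miss, seq_len(n_samples(g)))
    drop <- ord[seq_len(k_ind)]
    keep <- !(seq_len(n_samples(g)) %in% drop)
  } else keep <- rep(TRUE, n_samples(g))
  rep <- add_stage(rep, "worst_individuals", ind = sum(!keep))
  controls_mask <- controls_mask[keep]
  g <- gt_subset(g, samples = keep)

  # 3: worst SNPs by missing-sample count
  k_snp <- floor(t$worst_snp_fraction * n_snps(g))
  if (k_snp > 0) {
    miss <- colSums(is.na(g$geno))
    ord <- order(-miss, g$snp_meta$pos)
    keep_snp <- !(seq_len(n_snps(g)) %in% ord[seq_len(k_snp)])
  } else keep_snp <- rep(TRUE, n_snps(g))
  rep <- add_stage(rep, "worst_snps", snp = sum(!keep_snp))
  g <- gt_subset(g, snps = keep_snp)
  if (n_snps(g) == 0) abort("all SNPs removed at the worst-SNP stage")

  # 4: individuals with any remaining missing call
  keep <- rowSums(is.na(g$geno)) == 0L
  rep <- add_stage(rep, "any_missing", ind = sum(!keep))
  controls_mask <- controls_mask[keep]
  g <- gt_subset(g, samples = keep)

  # 5: rare haplotypes / haplotypes absent from controls
  hap <- apply(g$geno, 1L, paste, collapse = "")
  cnt <- table(hap)
  in_controls <- unique(hap[controls_mask])
  keep <- cnt[hap] >= t$rare_haplotype_min_count & hap %in% in_controls
  rep <- add_stage(rep, "rare_haplotypes", ind = sum(!keep))
  controls_mask <- controls_mask[keep]
  g <- gt_subset(g, samples = keep)

  list(table = g, report = rep)
}

# ---- control merging & differential missingness -----------------------------

#' Merge two control cohorts after a per-SNP frequency concordance check
#'
#' SNPs are intersected by id (requiring identical position and ref/alt
#' alleles; others are logged as removed). Per shared SNP, a haploid 2x2
#' Pearson chi-square compares alternate-allele counts between the two
#' cohorts; SNPs with P strictly below \code{control_discordance_p} are
#' removed, and the remaining samples concatenated.
#'
#' @param c1,c2 \code{\link{genotype_table}}s of control individuals.
#' @param t a \code{\link{qc_thresholds}}.
#' @return list with elements \code{table}, \code{report} and
#'   \code{discordance} (per-SNP statistic/p table).
#' @export
merge_controls <- function(c1, c2, t = qc_thresholds()) {
  shared <- intersect(c1$snp_meta$id, c2$snp_meta$id)
  i1 <- match(shared, c1$snp_meta$id); i2 <- match(shared, c2$snp_meta$id)
  consistent <- c1$snp_meta$pos[i1] == c2$snp_meta$pos[i2] &
    c1$snp_meta$ref[i1] == c2$snp_meta$ref[i2] &
    (is.na(c1$snp_meta$alt[i1]) | is.na(c2$snp_meta$alt[i2]) |
       c1$snp_meta$alt[i1] == c2$snp_meta$alt[i2])
  shared <- shared[consistent]; i1 <- i1[consistent]; i2 <- i2[consistent]
  if (length(shared) == 0) abort("no overlapping SNPs between control cohorts")
  dropped_overlap <- (n_snps(c1) - length(shared)) + (n_snps(c2) - length(shared))

  g1 <- gt_subset(c1, snps = i1); g2 <- gt_subset(c2, snps = i2)
  alt1 <- colSums(g1$geno == 1L, na.rm = TRUE)
  ref1 <- colSums(g1$geno == 0L, na.rm = TRUE)
  alt2 <- colSums(g2$geno == 1L, na.rm = TRUE)
  ref2 <- colSums(g2$geno == 0L, na.rm = TRUE)
  chi2 <- chisq_2x2(alt1, ref1, alt2, ref2)
  p <- chisq_p(chi2)
  keep_snp <- !(p < t$control_discordance_p)

  rep <- new_qc_report(n_samples(c1) + n_samples(c2), n_snps(c1) + n_snps(c2))
  rep <- add_stage(rep, "non_overlapping_snps", snp = dropped_overlap)
  rep <- add_stage(rep, "discordant_frequency", snp = sum(!keep_snp))

  g1 <- gt_subset(g1, snps = keep_snp); g2 <- gt_subset(g2, snps = keep_snp)
  ids <- make.unique(c(g1$sample_ids, g2$sample_ids))
  merged <- genotype_table(rbind(g1$geno, g2$geno), ids,
                           c(g1$phenotype, g2$phenotype), g1$snp_meta,
                           platform = if (identical(c1$platform, c2$platform))
                             c1$platform else "merged")
  list(table = merged, report = rep,
       discordance = data.frame(id = shared, chi2 = chi2, p = p,
                                removed = !keep_snp,
                                stringsAsFactors = FALSE))
}

#' Differential-missingness filter
#'
#' Per shared SNP, a 2x2 Pearson chi-square of missing/called status against
#' case/control cohort; SNPs with P strictly below \code{diff_missing_p}
#' are flagged for removal. A SNP with no missing calls anywhere has
#' statistic 0 (zero margin) and is kept.
#'
#' @param cases,controls \code{\link{genotype_table}}s sharing SNP ids.
#' @param t a \code{\link{qc_thresholds}}.
#' @return list with \code{kept_snps}, \code{removed_snps} (ids) and a
#'   per-SNP \code{table} of counts, statistics and p-values.
#' @export
differential_missingness <- function(cases, controls, t = qc_thresholds()) {
  shared <- intersect(cases$snp_meta$id, controls$snp_meta$id)
  if (length(shared) == 0) abort("no shared SNPs")
  gc_ <- gt_subset(cases, snps = match(shared, cases$snp_meta$id))
  gk  <- gt_subset(controls, snps = match(shared, controls$snp_meta$id))
  miss_ca <- colSums(is.na(gc_$geno)); call_ca <- n_samples(gc_) - miss_ca
  miss_co <- colSums(is.na(gk$geno));  call_co <- n_samples(gk) - miss_co
  chi2 <- chisq_2x2(miss_ca, call_ca, miss_co, call_co)
  p <- chisq_p(chi2)
  removed <- p < t$diff_missing_p
  list(kept_snps = shared[!removed], removed_snps = shared[removed],
       table = data.frame(id = shared, missing_cases = miss_ca,
                          missing_controls = miss_co, chi2 = chi2, p = p,
                          removed = removed, stringsAsFactors = FALSE))
}
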