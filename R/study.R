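#' Run an end-to-end mtDNA case-control study from a YAML configuration
#'
#' The configuration drives the full workflow: cohort acquisition (either a
#' \code{simulate:} block handed to \code{\link{simulate_cohort}}, or a
#' \code{data:} block with PED/MAP path prefixes for a case cohort and one or
#' two control cohorts), primary QC (\code{\link{primary_qc}}, plus
#' \code{\link{merge_controls}} and \code{\link{differential_missingness}}
#' when two control cohorts are given), haploid allelic association with the
#' risk-direction tally, and the lexical-tree permutation test
#' (\code{\link{run_tree_test}}). Results are written as TSV files under
#' \code{output_dir} together with a run log recording the seed and
#' thresholds; the run is deterministic given the config.
#'
#' Config keys (all thresholds optional, defaulting to
#' \code{\link{qc_thresholds}}): \code{seed}, \code{n_perm},
#' \code{output_dir}, \code{thresholds: {...}}, and one of
#' \preformatted{
#' simulate:
#'   n_cases: 200
#'   n_controls: 200
#'   n_neutral_snps: 9
#'   baseline_odds: 0.05
#'   clades:
#'     - {name: H, frequency: 0.45, odds_ratio: 1.0, positions: [7028]}
#'     - {name: U, frequency: 0.15, odds_ratio: 1.0, positions: [12308]}
#' data:
#'   cases: path/prefix
#'   controls: [path/prefix1, path/prefix2]
#' }
#'
#' @param config_path path to the YAML configuration.
#' @return an object of class \code{study_report}: \code{cohort_summary}
#'   (cohort, removed_by_qc, rare_haplotypes_removed, sample_size,
#'   whole_tree_p), \code{association}, \code{tally}, \code{tree_result},
#'   \code{qc_reports} and \code{metadata}.
#' @export
run_study <- function(config_path) {
  if (!file.exists(config_path))
    abort("config file not found: %s", config_path)
  cfg <- yaml::read_yaml(config_path)
  seed <- as.integer(cfg$seed %||% 1L)
  n_perm <- as.integer(cfg$n_perm %||% 999L)
  thr <- do.call(qc_thresholds, cfg$thresholds %||% list())
  out_dir <- cfg$output_dir %||% "."

  if (!is.null(cfg$simulate)) {
    g <- simulate_cohort(config_from_yaml(cfg$simulate, seed))
  } else if (!is.null(cfg$data)) {
    g <- assemble_cohort(cfg$data, thr)
  } else abort("config needs a 'simulate' or 'data' block")

  pq <- primary_qc(g, thr)
  if (n_samples(pq$table) == 0 || n_snps(pq$table) == 0)
    abort("stage 'primary_qc': no data left")
  assoc <- allelic_test(pq$table)
  tally <- risk_direction_tally(assoc)
  tt <- run_tree_test(g, t = thr, n_perm = n_perm, seed = seed)

  removed_qc <- sum(tt$report$stages$individuals_removed[
    tt$report$stages$stage != "rare_haplotypes"])
  rare_rm <- sum(tt$report$stages$individuals_removed[
    tt$report$stages$stage == "rare_haplotypes"])
  summary <- data.frame(
    cohort = g$platform,
    removed_by_qc = removed_qc,
    rare_haplotypes_removed = rare_rm,
    sample_size = tt$report$final_n,
    whole_tree_p = tt$result$p_perm,
    stringsAsFactors = FALSE)

  report <- structure(list(
    cohort_summary = summary, association = assoc, tally = tally,
    tree_result = tt$result, tree = tt$tree,
    qc_reports = list(primary = pq$report, lextree = tt$report),
    metadata = list(seed = seed, n_perm = n_perm, thresholds = unclass(thr),
                    config = config_path)), class = "study_report")

  if (!is.null(cfg$output_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(summary, file.path(out_dir, "study_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(assoc, file.path(out_dir, "association.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    export_node_table(tt$tree, tt$result, file.path(out_dir, "tree_nodes.tsv"))
    export_tree_newick(tt$tree, file.path(out_dir, "tree.nwk"))
    write_qc_report(pq$report, file.path(out_dir, "qc_primary.tsv"))
    write_qc_report(tt$report, file.path(out_dir, "qc_lextree.tsv"))
    log <- c(sprintf("seed\t%d", seed), sprintf("n_perm\t%d", n_perm),
             sprintf("%s\t%s", names(unclass(thr)),
                     vapply(unclass(thr), format, "")))
    writeLines(log, file.path(out_dir, "run_log.tsv"))
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("study_report\n")
  print(x$cohort_summary, row.names = FALSE)
  cat(sprintf("significant variants: %d (risk %d / protective %d, binomial p = %s)\n",
              sum(x$association$significant), x$tally$n_risk,
              x$tally$n_protective, format(x$tally$binomial_p, digits = 3)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# build a sim_config from the YAML 'simulate' block (study seed is the default)
config_from_yaml <- function(sim, seed) {
  clades <- lapply(sim$clades %||% list(), function(cl)
    clade_def(name = cl$name, frequency = cl$frequency,
              variants = data.frame(pos = unlist(cl$positions)),
              odds_ratio = cl$odds_ratio %||% 1,
              parent = cl$parent %||% NA_character_))
  sim_config(
    clades = clades,
    n_cases = sim$n_cases, n_controls = sim$n_controls,
    n_neutral_snps = sim$n_neutral_snps %||% 0L,
    neutral_maf_range = unlist(sim$neutral_maf_range %||% c(0.05, 0.4)),
    snp_missing_rate = sim$snp_missing_rate %||% 0,
    individual_missing_rate = sim$individual_missing_rate %||% 0,
    phenotype_missing_rate = sim$phenotype_missing_rate %||% 0,
    baseline_odds = sim$baseline_odds %||% 1,
    seed = sim$seed %||% seed)
}

# load case + control cohorts from PED/MAP prefixes; two control cohorts are
# concordance-checked and merged, then case/control differential missingness
# removes unstable SNPs before the tables are combined
assemble_cohort <- function(data, thr) {
  if (is.null(data$cases)) abort("data block needs a 'cases' prefix")
  if (!file.exists(paste0(data$cases, ".ped")))
    abort("missing file: %s.ped", data$cases)
  cases <- load_plink(data$cases, platform = "cases")
  ctl_prefixes <- unlist(data$controls)
  if (is.null(ctl_prefixes)) abort("data block needs 'controls' prefix(es)")
  for (p in ctl_prefixes)
    if (!file.exists(paste0(p, ".ped"))) abort("missing file: %s.ped", p)
  ctls <- lapply(ctl_prefixes, load_plink, platform = "controls")
  controls <- if (length(ctls) == 2L) merge_controls(ctls[[1]], ctls[[2]], thr)$table
              else ctls[[1]]
  dm <- differential_missingness(cases, controls, thr)
  keep_ca <- match(dm$kept_snps, cases$snp_meta$id)
  keep_co <- match(dm$kept_snps, controls$snp_meta$id)
  cases <- gt_subset(cases, snps = keep_ca)
  controls <- gt_subset(controls, snps = keep_co)
  genotype_table(rbind(cases$geno, controls$geno),
                 make.unique(c(cases$sample_ids, controls$sample_ids)),
                 c(cases$phenotype, controls$phenotype),
                 cases$snp_meta, platform = "case-control")
}

#' Export association results as a Manhattan-style table
#'
#' One row per variant: rCRS position, -log10(p) and a gene label from an
#' annotation interval lookup. The annotation is supplied as BED (0-based,
#' half-open), converted internally to 1-based inclusive rCRS coordinates;
#' positions covered by no interval are labelled "non-coding". Overlapping
#' intervals resolve to the first match, with a warning.
#'
#' @param results output of \code{\link{allelic_test}}.
#' @param annotation data.frame with BED-style columns \code{start},
#'   \code{end} (0-based half-open) and \code{name}; or NULL for no
#'   annotation.
#' @param path output TSV (NULL to return the data.frame).
#' @return the table, invisibly when written.
#' @export
export_manhattan_table <- function(results, annotation = NULL, path = NULL) {
  stopifnot(all(results$pos >= 1 & results$pos <= MT_LENGTH))
  gene <- rep("non-coding", nrow(results))
  if (!is.null(annotation) && nrow(annotation) > 0) {
    start1 <- annotation$start + 1L   # BED -> 1-based inclusive
    end1 <- annotation$end
    for (i in seq_len(nrow(results))) {
      hit <- which(results$pos[i] >= start1 & results$pos[i] <= end1)
      if (length(hit) > 1)
        warning(sprintf("position %d overlaps %d intervals; using first",
                        results$pos[i], length(hit)), call. = FALSE)
      if (length(hit)) gene[i] <- annotation$name[hit[1]]
    }
  }
  out <- data.frame(pos = results$pos,
                    minus_log10_p = -log10(results$p),
                    gene = gene, stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
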