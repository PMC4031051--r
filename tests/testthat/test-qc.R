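test_that("primary cascade removes nothing from clean all-European data", {
  g <- make_gt(matrix(rep(c(0L, 1L), 20), 10, 4), rep(c(1L, 2L), 5))
  out <- suppressWarnings(primary_qc(g))  # diagnostic positions not genotyped
  expect_equal(sum(out$report$stages$individuals_removed), 0L)
  expect_equal(sum(out$report$stages$snps_removed), 0L)
})

test_that("individual above the missingness threshold is removed at its stage", {
  geno <- matrix(rep(c(0L, 1L), 100), 10, 20)
  geno[3, 1:3] <- NA  # 15% missing
  g <- make_gt(geno, rep(c(1L, 2L), 5))
  out <- suppressWarnings(primary_qc(g))
  st <- out$report$stages
  expect_equal(st$individuals_removed[st$stage == "individual_missingness"], 1L)
  expect_false("i03" %in% out$table$sample_ids)
})

test_that("European diagnostic triplet keeps and removes the right individuals", {
  pos <- c(8540L, 8701L, 10873L, 4000L)
  ref <- mtlextree:::ref_base(pos)
  alt <- vapply(ref, function(r) c(A = "G", C = "T", G = "A", T = "C")[r], "")
  geno <- matrix(0L, 4, 4)
  geno[2, 2] <- 1L          # i2 carries 8701G -> removed
  geno[3, 1] <- NA          # i3 untestable at 8540, European elsewhere -> kept
  geno[4, 4] <- 1L          # non-diagnostic variant is irrelevant
  g <- make_gt(geno, c(1L, 2L, 1L, 2L), pos = pos, ref = unname(ref),
               alt = unname(alt))
  out <- filter_non_european(g)
  expect_identical(out$removed_ids, "i02")
  expect_identical(out$table$sample_ids, c("i01", "i03", "i04"))
})

test_that("European filter is a warned no-op when no diagnostic position is genotyped", {
  g <- make_gt(matrix(0:1, 4, 2), rep(1:2, 2))
  expect_warning(out <- filter_non_european(g), "no-op")
  expect_identical(out$table$sample_ids, g$sample_ids)
  expect_true(attr(out$table, "untestable"))
})

test_that("lexical cascade: complete common data loses only the worst-SNP trim", {
  # 6 SNPs, no missingness, every haplotype common: stage 3 removes
  # floor(6/2) = 3 SNPs, ties at zero missing broken by ascending position
  hap <- rbind(c(0,0,0,0,0,0), c(1,1,0,1,0,1), c(0,1,1,0,1,0))
  geno <- hap[rep(1:3, each = 10), ]
  g <- make_gt(matrix(as.integer(geno), 30, 6), rep(c(1L, 2L), 15))
  out <- lextree_qc(g, t = qc_thresholds(worst_individual_fraction = 0))
  st <- out$report$stages
  expect_equal(st$snps_removed[st$stage == "worst_snps"], 3L)
  expect_identical(out$table$snp_meta$id, c("s04", "s05", "s06"))
  expect_equal(sum(st$individuals_removed), 0L)
  expect_equal(n_samples(out$table), 30L)
})

test_that("rare and case-only haplotypes are removed at the final stage", {
  # hap (1,1): 6 carriers but all cases -> removed despite count >= 5
  # hap (1,0): 4 carriers incl. controls -> removed by count
  geno <- rbind(matrix(0L, 10, 2),
                matrix(rep(c(1L, 1L), 6), 6, 2, byrow = TRUE),
                matrix(rep(c(1L, 0L), 4), 4, 2, byrow = TRUE))
  phen <- c(rep(c(1L, 2L), 5), rep(2L, 6), c(1L, 2L, 1L, 2L))
  g <- make_gt(geno, phen)
  out <- lextree_qc(g, t = qc_thresholds(worst_individual_fraction = 0,
                                         worst_snp_fraction = 0))
  st <- out$report$stages
  expect_equal(st$individuals_removed[st$stage == "rare_haplotypes"], 10L)
  expect_equal(n_samples(out$table), 10L)
  # post-conditions: no missingness, every haplotype common and in controls
  hap <- apply(out$table$geno, 1, paste, collapse = "")
  expect_true(all(table(hap)[hap] >= 5))
  expect_true(all(hap %in% hap[out$table$phenotype == 1L]))
})

test_that("lexical cascade output never contains missing genotypes", {
  g <- simulate_cohort(sim_config(clades = demo_clades(), n_cases = 150L,
                                  n_controls = 150L, n_neutral_snps = 6L,
                                  snp_missing_rate = 0.03,
                                  baseline_odds = 0.2, seed = 31))
  out <- lextree_qc(g)
  expect_false(anyNA(out$table$geno))
  # ledger conservation
  expect_equal(out$report$final_n,
               n_samples(g) - sum(out$report$stages$individuals_removed))
  expect_equal(out$report$final_m,
               n_snps(g) - sum(out$report$stages$snps_removed))
  expect_equal(out$report$final_n, n_samples(out$table))
  expect_equal(out$report$final_m, n_snps(out$table))
})

test_that("the lexical cascade is order-sensitive on a crafted fixture", {
  fx <- lextree_fixture()
  out <- lextree_qc(fx$g, t = fx$thresholds)
  # swapping the worst-individual and worst-SNP stages changes who is removed:
  # with SNPs trimmed first, i11's missing call at s7 outranks i30 by id order
  g <- fx$g
  miss_snp <- colSums(is.na(g$geno[, 3:8]))  # post stage-1 SNP set
  expect_equal(unname(miss_snp), c(4L, 4L, 3L, 3L, 1L, 0L))
  swapped_first_trim <- c("s03", "s04", "s05")  # most missing, tie by position
  g_sw <- gt_subset(g, snps = match(c("s06", "s07", "s08"), g$snp_meta$id))
  miss_ind <- rowSums(is.na(g_sw$geno))
  ord <- order(-miss_ind, seq_len(30))[1:3]
  expect_equal(sort(g$sample_ids[ord]), c("i11", "i28", "i29"))
  expect_false(setequal(g$sample_ids[ord], c("i28", "i29", "i30")))
  # the implementation followed the stated order, not the swapped one
  expect_false("i30" %in% out$table$sample_ids)
  expect_equal(out$report$stages$individuals_removed[
    out$report$stages$stage == "worst_individuals"], 3L)
})

test_that("merging a control cohort with its own copy removes no SNP", {
  g <- simulate_cohort(sim_config(clades = demo_clades(), n_cases = 1L,
                                  n_controls = 60L, n_neutral_snps = 4L,
                                  baseline_odds = 0.05, seed = 17))
  ctl <- gt_subset(g, samples = g$phenotype == 1L)
  out <- merge_controls(ctl, ctl)
  expect_equal(sum(out$report$stages$snps_removed), 0L)
  expect_true(all(out$discordance$p == 1))
  expect_equal(n_samples(out$table), 2L * n_samples(ctl))
})

test_that("frequency-discordant SNPs are removed when merging controls", {
  # SNP1: 90:10 vs 50:50 (chi-square 38.1); SNP2 concordant
  g1 <- make_gt(cbind(rep(c(1L, 0L), c(90, 10)), rep(0:1, 50)), rep(1L, 100))
  g2 <- make_gt(cbind(rep(c(1L, 0L), c(50, 50)), rep(0:1, 50)), rep(1L, 100))
  out <- merge_controls(g1, g2)
  expect_identical(out$discordance$removed, c(TRUE, FALSE))
  expect_equal(out$discordance$chi2[1], 38.0952381, tolerance = 1e-8)
  expect_identical(out$table$snp_meta$id, "s02")
  # oracle: identical decision from stats::chisq.test without correction
  p_oracle <- stats::chisq.test(rbind(c(90, 10), c(50, 50)),
                                correct = FALSE)$p.value
  expect_equal(out$discordance$p[1], p_oracle, tolerance = 1e-12)
  # degenerate threshold: nothing can be "strictly below 0"
  out0 <- merge_controls(g1, g2, qc_thresholds(control_discordance_p = 0))
  expect_equal(sum(out0$report$stages$snps_removed[
    out0$report$stages$stage == "discordant_frequency"]), 0L)
})

test_that("merge_controls keeps the same SNP set regardless of argument order", {
  g <- simulate_cohort(sim_config(clades = demo_clades(), n_cases = 1L,
                                  n_controls = 80L, n_neutral_snps = 5L,
                                  baseline_odds = 0.05, seed = 23))
  ctl <- gt_subset(g, samples = g$phenotype == 1L)
  c1 <- gt_subset(ctl, samples = 1:40)
  c2 <- gt_subset(ctl, samples = 41:80)
  m12 <- merge_controls(c1, c2)
  m21 <- merge_controls(c2, c1)
  expect_setequal(m12$table$snp_meta$id, m21$table$snp_meta$id)
})

test_that("differential missingness removes only significantly imbalanced SNPs", {
  geno_ca <- matrix(rep(0:1, 150), 100, 3)
  geno_ca[1:30, 1] <- NA           # 30/100 missing in cases at SNP1
  geno_co <- matrix(rep(0:1, 150), 100, 3)
  geno_co[1:2, 2] <- NA;
  geno_ca[1:2, 2] <- NA            # SNP2: equal low missingness
  cases <- make_gt(geno_ca, rep(2L, 100))
  controls <- make_gt(geno_co, rep(1L, 100))
  out <- differential_missingness(cases, controls)
  expect_identical(out$removed_snps, "s01")
  expect_setequal(out$kept_snps, c("s02", "s03"))
  # Fisher-exact oracle agrees that SNP1 is far below 1e-4
  expect_lt(stats::fisher.test(rbind(c(30, 70), c(0, 100)))$p.value, 1e-4)
  # SNP3 has no missingness anywhere: zero margin, statistic defined as 0
  expect_equal(out$table$chi2[out$table$id == "s03"], 0)
})
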