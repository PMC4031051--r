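# Shared fixture builders and independent oracles for the test suite.
# All fixtures are generated in code; nothing is read from disk.

# quick genotype-table constructor: geno given as a plain matrix,
# positions default to 100, 200, ... and alleles to A (ref) / G (alt)
make_gt <- function(geno, phenotype, pos = NULL, ref = NULL, alt = NULL,
                    platform = "fixture") {
  geno <- as.matrix(geno)
  m <- ncol(geno)
  if (is.null(pos)) pos <- 100L * seq_len(m)
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("G", m)
  genotype_table(geno, sprintf("i%02d", seq_len(nrow(geno))), phenotype,
                 data.frame(id = sprintf("s%02d", seq_len(m)), pos = pos,
                            ref = ref, alt = alt, stringsAsFactors = FALSE),
                 platform = platform)
}

# the demo clade structure used across simulation tests: three European-style
# top-level haplogroups; ORs overridable per test
demo_clades <- function(or_H = 1, or_U = 1, or_J = 1, u_pos = 12308L) {
  list(clade_def("H", 0.45, data.frame(pos = 7028L), odds_ratio = or_H),
       clade_def("U", 0.15, data.frame(pos = u_pos), odds_ratio = or_U),
       clade_def("J", 0.10, data.frame(pos = 4216L), odds_ratio = or_J))
}

# null cohort: 12 SNPs (3 clade-defining, all ORs 1, + 9 neutral)
null_sim_config <- function(seed, n_cases = 200L, n_controls = 200L) {
  sim_config(clades = demo_clades(), n_cases = n_cases,
             n_controls = n_controls, n_neutral_snps = 9L,
             baseline_odds = 0.05, seed = seed)
}

# planted-effect cohort: clade U at frequency 0.15 with OR = 3; its defining
# variant sits high on the genome (m.15218-style) so the worst-SNP trim,
# which breaks zero-missingness ties by ascending position, leaves it in
planted_sim_config <- function(seed, n_cases = 500L, n_controls = 500L,
                               or = 3) {
  sim_config(clades = demo_clades(or_U = or, u_pos = 15218L),
             n_cases = n_cases, n_controls = n_controls,
             n_neutral_snps = 9L, baseline_odds = 0.05, seed = seed)
}

# does any selected node's defining path include the mutant branch at snp_id?
recovered_planted_node <- function(tree, result, snp_id) {
  j <- match(snp_id, tree$snp_meta$id)
  if (is.na(j)) return(FALSE)  # planted SNP removed by QC
  hit <- function(id) {
    while (!is.na(id)) {
      if (!is.na(tree$nodes$snp[id]) && tree$nodes$snp[id] == j &&
          tree$nodes$branch[id] == "mutant") return(TRUE)
      id <- tree$nodes$parent[id]
    }
    FALSE
  }
  any(vapply(result$selected_nodes$node_id, hit, TRUE))
}

# ---- hand-crafted 30-sample QC fixtures -------------------------------------

# Lexical-cascade fixture. Designed removals, in order:
#   stage 1: s1 (call rate 25/30 < 0.85), s2 (monomorphic)
#   stage 2: i28, i29, i30 (3 missing sites each; trim floor(0.1*30) = 3)
#   stage 3: s3, s4 (2 missing each) + s5 (tie at 1 vs s7, lower position)
#   stage 4: i11 (missing at surviving s7)
#   stage 5: hapC = (0,1,1) carried by 4 < 5 -> i23..i26;
#            hapD = (1,0,1) case-only -> i27
# leaving 21 individuals on s6, s7, s8.
lextree_fixture <- function() {
  n <- 30L
  g <- matrix(0L, n, 8)
  hapB <- 14:22; hapC <- 23:26; hapD <- 27L
  g[hapB, 1] <- 1L                 # s1 polymorphic (removed by call rate)
  # s2 stays all-ref (monomorphic)
  g[hapC, 3] <- 1L                 # s3 polymorphic
  g[hapB, 4] <- 1L                 # s4 polymorphic
  g[hapC, 5] <- 1L                 # s5 polymorphic
  g[c(hapB, hapD), 6] <- 1L        # s6: hapB and hapD carry the mutant
  g[c(hapB, hapC), 7] <- 1L        # s7
  g[c(hapC, hapD), 8] <- 1L        # s8
  g[1:5, 1] <- NA                  # s1 call rate 25/30
  g[c(6, 8, 28, 29), 3] <- NA
  g[c(7, 9, 28, 30), 4] <- NA
  g[c(10, 29, 30), 5] <- NA
  g[28:30, 6] <- NA
  g[11, 7] <- NA
  phen <- rep(1L, n)
  phen[c(1:6, 14:18, 23, 24, 27, 11)] <- 2L   # 15 cases / 15 controls
  list(g = make_gt(g, phen),
       thresholds = qc_thresholds(snp_call_rate_min = 0.85,
                                  worst_individual_fraction = 0.1,
                                  worst_snp_fraction = 0.5,
                                  rare_haplotype_min_count = 5L),
       expected = list(
         stage_snps = c(2L, 0L, 3L, 0L, 0L),
         stage_inds = c(0L, 3L, 0L, 1L, 5L),
         final_ids  = sprintf("i%02d", setdiff(1:27, c(11, 23:27))),
         final_snps = c("s06", "s07", "s08")))
}

# Primary-cascade fixture. Designed removals, in order:
#   stage 1 (missing phenotype): i01, i02
#   stage 2 (SNP missingness > 0.1): s01 (4/28 missing)
#   stage 3 (individual missingness > 0.1): i07 (1/5 = 0.2)
#   stage 4 (non-European): i08 (m.8701G)
#   stage 5 (MAF < 1e-5): s06 (monomorphic) + the three diagnostic SNPs
#            (monomorphic once the only alt carrier is removed at stage 4)
primary_fixture <- function() {
  n <- 30L
  pos <- c(500L, 1000L, 8540L, 8701L, 10873L, 2000L)
  ref <- mtlextree:::ref_base(pos)
  alt <- vapply(ref, function(r) c(A = "G", C = "T", G = "A", T = "C")[r], "")
  g <- matrix(0L, n, 6)
  g[15:25, 2] <- 1L                # s02 polymorphic (survives everything)
  g[3:6, 1] <- NA                  # s01: 4 of 28 post-pruning missing
  g[7, 2] <- NA                    # i07: 1 of 5 remaining SNPs missing
  g[8, 4] <- 1L                    # i08 carries m.8701G (non-European)
  phen <- rep(c(2L, 1L), 15)
  phen[1:2] <- NA                  # -9 phenotypes
  list(g = make_gt(g, phen, pos = pos, ref = unname(ref), alt = unname(alt)),
       expected = list(
         stage_inds = c(2L, 0L, 1L, 1L, 0L),
         stage_snps = c(0L, 1L, 0L, 0L, 4L),
         final_ids  = sprintf("i%02d", setdiff(3:30, 7:8)),
         final_snps = "s02"))
}

# ---- independent oracles ----------------------------------------------------

# greedy top-k antichain, written from first principles against parent
# pointers only (no shared code with the implementation)
oracle_greedy <- function(nodes_df, stats_df, k = 5L) {
  anc <- function(id) {
    out <- integer(0)
    p <- nodes_df$parent[match(id, nodes_df$id)]
    while (!is.na(p)) { out <- c(out, p); p <- nodes_df$parent[match(p, nodes_df$id)] }
    out
  }
  related <- function(x, y) (x %in% anc(y)) || (y %in% anc(x))
  o <- order(-stats_df$statistic, stats_df$depth, stats_df$node_id)
  picked <- integer(0)
  for (i in o) {
    cand <- stats_df$node_id[i]
    if (!any(vapply(picked, related, TRUE, y = cand))) {
      picked <- c(picked, cand)
      if (length(picked) == k) break
    }
  }
  picked
}

# random tree as a minimal haplotype_tree skeleton: node 1 is the root and
# every later node attaches to a uniformly chosen earlier node
random_tree_skeleton <- function(n_nodes) {
  parent <- c(NA_integer_, vapply(2:n_nodes, function(i)
    sample.int(i - 1L, 1L), 1L))
  depth <- integer(n_nodes)
  for (i in 2:n_nodes) depth[i] <- depth[parent[i]] + 1L
  structure(list(nodes = data.frame(id = seq_len(n_nodes), parent = parent,
                                    depth = depth),
                 root_id = 1L),
            class = "haplotype_tree")
}

# exact two-sided binomial p by direct enumeration (minlike convention)
oracle_binom_p <- function(x, n, p0 = 0.5) {
  d <- dbinom(0:n, n, p0)
  min(1, sum(d[d <= d[x + 1] * (1 + 1e-7)]))
}
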